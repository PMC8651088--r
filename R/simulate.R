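#' Configuration for the synthetic-data generator
#'
#' The generator emulates the statistical structure of a bacterial
#' multi-omics experiment: single-gene transcription units laid out
#' without overlap on both strands; log-normal UTR length distributions
#' (target medians 53 nt for 5'-UTRs and 92 nt for 3'-UTRs, with heavy
#' right tails); negative-binomial read counts with planted condition
#' effects and per-sample library size factors; piecewise-constant
#' RNA-seq depth over each TU; Ribo-seq (RPF) depth confined to the CDS
#' plus short margins, elevated by `stall_factor` inside the extremity
#' windows under the designated stress condition; and Term-seq 3'-end
#' counts peaked at planted intrinsic terminators (GC stem, loop, U-tract).
#'
#' @param seed integer RNG seed; fully determines all outputs
#' @param n_genes number of genes/TUs
#' @param genome_length contig length in bp, or `NULL` to fit the genes
#'   exactly; an explicit value too small for the gene layout is an error
#' @param utr5_meanlog,utr5_sdlog log-normal parameters of 5'-UTR length
#'   (median `exp(meanlog)` = 53 nt by default)
#' @param utr3_meanlog,utr3_sdlog log-normal parameters of 3'-UTR length
#'   (median 92 nt by default; lengths floored at 1 nt)
#' @param cds_len_range CDS length range in bp (rounded to multiples of 3)
#' @param conditions condition labels; the first is the reference
#' @param stress_condition condition receiving the ribosome-stalling signal
#' @param n_replicates replicates per condition
#' @param nb_dispersion negative-binomial dispersion (0 gives Poisson)
#' @param deg_fraction fraction of genes with a planted expression change
#'   in each non-reference condition
#' @param deg_log2fc magnitude of the planted log2 fold change
#' @param stall_factor multiplier (>= 1) applied to RPF depth inside the
#'   extremity windows for the stress condition only
#' @param term_peak_prob probability a Term-seq end-read falls exactly on
#'   the planted TEP (the remainder form a geometric upstream tail)
#' @param term_depth_mean mean Term-seq reads per terminator per replicate
#' @param noise_sd Gaussian depth noise, as a fraction of the local mean
#'   (applied to RNA/RPF tracks; 0 disables)
#' @param spacer minimum intergenic spacer between TUs, bp
#' @param baseline_range per-gene baseline expression range (log-uniform)
#' @param size_factor_range per-sample library size factor range
#'   (log-uniform; `c(1, 1)` gives equal libraries)
#' @param rpf_margin_up,rpf_margin_down bp of RPF signal extending 5' of
#'   the start codon and 3' of the stop codon
#' @param track_depth_per_count total track depth contributed per counted
#'   read (conservation constant linking counts to tracks)
#' @return list of class `sim_config`
#' @export
sim_config <- function(seed = 1L, n_genes = 100L, genome_length = NULL,
                       utr5_meanlog = log(53), utr5_sdlog = 1.0,
                       utr3_meanlog = log(92), utr3_sdlog = 0.5,
                       cds_len_range = c(300L, 3000L),
                       conditions = c("CTRL", "HL", "LT"),
                       stress_condition = "LT",
                       n_replicates = 3L, nb_dispersion = 0.05,
                       deg_fraction = 0.1, deg_log2fc = 2,
                       stall_factor = 3, term_peak_prob = 0.8,
                       term_depth_mean = 20, noise_sd = 0.05,
                       spacer = 50L, baseline_range = c(200, 2000),
                       size_factor_range = c(0.5, 2),
                       rpf_margin_up = 30L, rpf_margin_down = 15L,
                       track_depth_per_count = 100) {
  stopifnot(n_genes >= 1L, n_replicates >= 1L, nb_dispersion >= 0,
            deg_fraction >= 0, deg_fraction <= 1, stall_factor >= 1,
            term_peak_prob >= 0, term_peak_prob <= 1, term_depth_mean >= 0,
            spacer >= 0L, all(cds_len_range > 0L))
  if (!stress_condition %in% conditions)
    stop("stress_condition must be one of the conditions")
  structure(as.list(environment()), class = "sim_config")
}

# random codon sequence with no internal stop codons, transcript sense
.random_cds <- function(n_codons) {
  codons <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                  paste0), c("A", "C", "G", "T"), paste0))
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  body <- sample(codons, n_codons - 2L, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

# intrinsic-terminator tail ending at the TEP: GC stem, loop, reverse
# complement stem, then a U-tract (T on the coding strand); total <= 40 nt
.terminator_tail <- function() {
  k <- sample(8:12, 1L)
  m <- sample(4:8, 1L)
  tmax <- min(9L, 40L - 2L * k - m)
  tt <- sample(6:tmax, 1L)
  stem <- sample(c("G", "C"), k, replace = TRUE)
  loop <- sample(c("A", "C", "G", "T"), m, replace = TRUE)
  stem_rc <- rev(chartr("GC", "CG", stem))
  list(seq = paste0(paste(stem, collapse = ""), paste(loop, collapse = ""),
                    paste(stem_rc, collapse = ""), strrep("T", tt)),
       stem_len = k, utract_len = tt)
}

#' Simulate a toy genome with planted transcription units
#'
#' Genes are placed sequentially on alternating random strands, each TU
#' (TSS..TEP) separated by at least `spacer` bp of intergenic sequence.
#' Every gene gets a planted TSS at `start_codon - l_5utr` and a planted
#' TEP at `stop_codon_end + l_3utr` (strand-aware), with an intrinsic
#' terminator (GC hairpin + U-tract) written into the coding-strand
#' sequence so that the U-tract ends exactly at the TEP.
#'
#' @param config a [sim_config()]
#' @return list with `genome` ([genome_sequence()]), `genes`
#'   ([gene_models()]), `tss` ([tss_records()]) and `truth` (per-gene
#'   truth manifest data.frame: TSS, TEP, UTR/CDS lengths, planted
#'   log2 fold changes per condition, stall flag, terminator stem and
#'   U-tract lengths)
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  l5 <- pmax(0L, as.integer(round(stats::rlnorm(n, config$utr5_meanlog,
                                                config$utr5_sdlog))))
  l3 <- pmax(1L, as.integer(round(stats::rlnorm(n, config$utr3_meanlog,
                                                config$utr3_sdlog))))
  n_codons <- sample(seq(config$cds_len_range[1] %/% 3L,
                         config$cds_len_range[2] %/% 3L), n, replace = TRUE)
  cds_len <- 3L * n_codons
  strand <- sample(c("+", "-"), n, replace = TRUE)
  tu_len <- l5 + cds_len + l3
  sp <- as.integer(config$spacer)
  required <- sum(tu_len) + sp * (n + 1L)
  glen <- if (is.null(config$genome_length)) required
          else as.integer(config$genome_length)
  if (glen < required)
    stop("genes do not fit: genome_length must be at least ", required, " bp")

  tss <- tep <- cds_start <- cds_end <- integer(n)
  cursor <- sp + 1L
  for (i in seq_len(n)) {
    lo <- cursor; hi <- cursor + tu_len[i] - 1L
    if (strand[i] == "+") {
      tss[i] <- lo
      cds_start[i] <- lo + l5[i]
      cds_end[i] <- cds_start[i] + cds_len[i] - 1L
      tep[i] <- hi
    } else {
      tss[i] <- hi
      cds_end[i] <- hi - l5[i]
      cds_start[i] <- cds_end[i] - cds_len[i] + 1L
      tep[i] <- lo
    }
    cursor <- hi + sp + 1L
  }

  base <- sample(c("A", "C", "G", "T"), glen, replace = TRUE)
  stem_len <- utract_len <- integer(n)
  for (i in seq_len(n)) {
    cds_seq <- strsplit(.random_cds(n_codons[i]), "")[[1]]
    term <- .terminator_tail()
    stem_len[i] <- term$stem_len; utract_len[i] <- term$utract_len
    tseq <- strsplit(term$seq, "")[[1]]
    if (strand[i] == "+") {
      base[cds_start[i]:cds_end[i]] <- cds_seq
      base[(tep[i] - length(tseq) + 1L):tep[i]] <- tseq
    } else {
      # descending index walks transcript sense; assign complements
      base[cds_end[i]:cds_start[i]] <- chartr("ACGT", "TGCA", cds_seq)
      base[(tep[i] + length(tseq) - 1L):tep[i]] <- chartr("ACGT", "TGCA", tseq)
    }
  }
  genome <- genome_sequence("synthetic_chr", paste(base, collapse = ""))

  gene_id <- sprintf("gene%04d", seq_len(n))
  genes <- gene_models(gene_id, genome$contig_id, strand, cds_start, cds_end)
  tssr <- tss_records(gene_id, tss, strand)

  truth <- data.frame(gene_id = gene_id, strand = strand,
                      tss = tss, tep = tep,
                      l_5utr = l5, l_3utr = l3, cds_len = cds_len,
                      stalled = config$stall_factor > 1,
                      stem_len = stem_len, utract_len = utract_len,
                      stringsAsFactors = FALSE)
  for (cond in config$conditions) {
    lfc <- numeric(n)
    if (cond != config$conditions[1] && config$deg_fraction > 0) {
      is_deg <- stats::runif(n) < config$deg_fraction
      lfc[is_deg] <- sample(c(-1, 1), sum(is_deg), replace = TRUE) *
        config$deg_log2fc
    }
    truth[[paste0("lfc_", cond)]] <- lfc
  }
  attr(truth, "genome_length") <- glen
  attr(truth, "conditions") <- config$conditions
  list(genome = genome, genes = genes, tss = tssr, truth = truth)
}

# sample ids in deterministic condition x replicate order
.sample_ids <- function(config) {
  as.vector(t(outer(config$conditions, seq_len(config$n_replicates),
                    function(a, b) paste0(a, "_", b))))
}

#' Simulate RNA and RPF count matrices
#'
#' Counts are negative binomial with mean
#' `baseline * 2^(planted log2FC) * library size factor`; baselines are
#' log-uniform over `baseline_range`, size factors log-uniform in
#' \[0.5, 2\]. The same planted fold change drives RNA and RPF counts.
#'
#' @param truth truth manifest from [simulate_genome()]
#' @param config the same [sim_config()]
#' @return list with integer matrices `rna` and `rpf` (genes x samples,
#'   sample ids `<condition>_<replicate>`), plus the drawn `size_factors`
#' @export
simulate_counts <- function(truth, config) {
  set.seed(config$seed + 1L)
  n <- nrow(truth)
  samples <- .sample_ids(config)
  cond_of <- sub("_[0-9]+$", "", samples)
  baseline <- exp(stats::runif(n, log(config$baseline_range[1]),
                               log(config$baseline_range[2])))
  sf <- exp(stats::runif(length(samples), log(config$size_factor_range[1]),
                         log(config$size_factor_range[2])))
  names(sf) <- samples
  draw <- function() {
    m <- matrix(0L, n, length(samples),
                dimnames = list(truth$gene_id, samples))
    for (j in seq_along(samples)) {
      mu <- baseline * 2^truth[[paste0("lfc_", cond_of[j])]] * sf[j]
      m[, j] <- if (config$nb_dispersion > 0)
        stats::rnbinom(n, mu = mu, size = 1 / config$nb_dispersion)
      else stats::rpois(n, mu)
    }
    m
  }
  list(rna = draw(), rpf = draw(), size_factors = sf)
}

#' Simulate strand-specific coverage tracks
#'
#' RNA depth is piecewise-constant over each TU and proportional to the
#' gene's RNA count; RPF depth is uniform over the CDS plus short
#' margins, proportional to the RPF count, and multiplied by
#' `stall_factor` inside the extremity windows for the stress condition;
#' Term-seq tracks place `Poisson(term_depth_mean)` end-reads per
#' terminator per replicate, each exactly on the planted TEP with
#' probability `term_peak_prob` and otherwise `1 + Geometric(0.5)` nt
#' upstream. Gaussian noise (sd = `noise_sd` x local mean) is added to
#' RNA/RPF depth and clipped at zero; Term-seq counts stay integral.
#'
#' @inheritParams simulate_counts
#' @param counts optional result of [simulate_counts()]; regenerated
#'   deterministically from `truth`/`config` when omitted
#' @return flat list of [coverage_track()] objects: RNA and RPF per
#'   condition x replicate x strand, TERM per replicate x strand
#' @export
simulate_tracks <- function(truth, config, counts = NULL) {
  if (is.null(counts)) counts <- simulate_counts(truth, config)
  set.seed(config$seed + 2L)
  glen <- attr(truth, "genome_length")
  samples <- .sample_ids(config)
  cond_of <- sub("_[0-9]+$", "", samples)
  rep_of <- as.integer(sub("^.*_", "", samples))
  part <- extremity_partition()   # planted stall windows
  scale <- config$track_depth_per_count
  sgn <- ifelse(truth$strand == "+", 1L, -1L)

  # per-gene position sets (computed once)
  gene_rows <- lapply(seq_len(nrow(truth)), function(i) {
    g <- truth[i, ]
    s <- if (g$strand == "+") g$tss + g$l_5utr else g$tss - g$l_5utr
    e <- s + sgn[i] * (g$cds_len - 1L)
    gm <- list(gene_id = g$gene_id, strand = g$strand,
               start_codon_pos = s, stop_codon_end_pos = e)
    tu <- seq.int(g$tss, g$tep)
    rpf_span <- seq.int(s - sgn[i] * config$rpf_margin_up,
                        e + sgn[i] * config$rpf_margin_down)
    stall <- region_positions(gm, part, "extremity")
    list(tu = tu, rpf_span = rpf_span, stall = stall)
  })

  add_noise <- function(depth) {
    if (config$noise_sd > 0) {
      nz <- depth > 0
      depth[nz] <- depth[nz] +
        stats::rnorm(sum(nz), 0, config$noise_sd * depth[nz])
      depth[depth < 0] <- 0
    }
    depth
  }

  tracks <- list()
  for (j in seq_along(samples)) {
    for (str in c("+", "-")) {
      on_str <- truth$strand == str
      rna <- rpf <- numeric(glen)
      for (i in which(on_str)) {
        pr <- gene_rows[[i]]
        rna[pr$tu] <- rna[pr$tu] +
          counts$rna[i, j] * scale / length(pr$tu)
        base_rpf <- counts$rpf[i, j] * scale / length(pr$rpf_span)
        rpf[pr$rpf_span] <- rpf[pr$rpf_span] + base_rpf
        if (cond_of[j] == config$stress_condition &&
            config$stall_factor > 1)
          rpf[pr$stall] <- rpf[pr$stall] * config$stall_factor
      }
      tracks[[length(tracks) + 1L]] <-
        coverage_track("RNA", cond_of[j], rep_of[j], str, add_noise(rna))
      tracks[[length(tracks) + 1L]] <-
        coverage_track("RPF", cond_of[j], rep_of[j], str, add_noise(rpf))
    }
  }
  for (r in seq_len(config$n_replicates)) {
    for (str in c("+", "-")) {
      term <- numeric(glen)
      for (i in which(truth$strand == str)) {
        n_reads <- stats::rpois(1L, config$term_depth_mean)
        if (n_reads == 0L) next
        at_peak <- stats::runif(n_reads) < config$term_peak_prob
        off <- integer(n_reads)
        n_tail <- sum(!at_peak)
        if (n_tail > 0) off[!at_peak] <- 1L + stats::rgeom(n_tail, 0.5)
        pos <- truth$tep[i] - sgn[i] * off
        pos <- pos[pos >= 1L & pos <= glen]
        tb <- table(pos)
        idx <- as.integer(names(tb))
        term[idx] <- term[idx] + as.integer(tb)
      }
      tracks[[length(tracks) + 1L]] <-
        coverage_track("TERM", "ALL", r, str, term)
    }
  }
  tracks
}

#' Select coverage tracks by metadata
#'
#' @param tracks list of [coverage_track()]
#' @param assay,condition,replicate,strand filters; `NULL` matches all
#' @return sublist of matching tracks
#' @export
tracks_find <- function(tracks, assay = NULL, condition = NULL,
                        replicate = NULL, strand = NULL) {
  keep <- vapply(tracks, function(t)
    (is.null(assay) || t$assay == assay) &&
    (is.null(condition) || t$condition == condition) &&
    (is.null(replicate) || t$replicate == replicate) &&
    (is.null(strand) || t$strand == strand), logical(1))
  tracks[keep]
}

#' Position-wise mean depth across replicate tracks
#'
#' @inheritParams tracks_find
#' @return numeric vector of per-position depth averaged over the
#'   matching replicates
#' @export
tracks_mean_depth <- function(tracks, assay, condition = NULL, strand) {
  sel <- tracks_find(tracks, assay = assay, condition = condition,
                     strand = strand)
  if (length(sel) == 0L)
    stop("no ", assay, " track for condition ", condition,
         " strand ", strand)
  Reduce(`+`, lapply(sel, `[[`, "depth")) / length(sel)
}
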