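#' Pipeline configuration
#'
#' Bundles every tunable constant of the full analysis with its default:
#' DEG gates (`fc_threshold` 1, `p_threshold` 0.05), expression floor
#' (10), TEP detection (`min_count` 5), P/S classification window
#' (`downstream_window` 250 nt), metagene half-width (`W` 200),
#' extremity windows (-30..+60 / -33..+15), composition flank (50),
#' terminator upstream length (40), intergenic background size (10000),
#' cluster counts (7 for extremity fold changes, 9 for UED patterns) and
#' the ratio pseudocount (1). The configuration is serialized into the
#' metadata header of every output table.
#'
#' @param sim a [sim_config()]; when `simulate = TRUE` it defines the
#'   synthetic inputs and the master seed
#' @param simulate generate inputs with the synthetic-data module
#'   (`TRUE`) or read them from `paths` (`FALSE`)
#' @param paths named list of input paths used when `simulate = FALSE`:
#'   `genome` (FASTA), `annotation` (GFF3), `tss` (TSV), `rna_counts`,
#'   `rpf_counts` (TSV matrices) and `tracks` (data.frame with `path`,
#'   `assay`, `condition`, `replicate`, `strand`)
#' @param fc_threshold,p_threshold,expression_floor,min_count,
#'   downstream_window,W,flank,upstream_seq_len,n_background,
#'   k_extremity,k_ued,pseudocount analysis constants (see above)
#' @param start_window,stop_window fallback extremity windows used when
#'   the data-driven boundary scan fails
#' @param write_tracks also write every coverage track as bedGraph
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(sim = sim_config(), simulate = TRUE,
                            paths = list(),
                            fc_threshold = 1.0, p_threshold = 0.05,
                            expression_floor = 10, min_count = 5L,
                            downstream_window = 250L, W = 200L,
                            start_window = c(-30L, 60L),
                            stop_window = c(-33L, 15L),
                            flank = 50L, upstream_seq_len = 40L,
                            n_background = 10000L,
                            k_extremity = 7L, k_ued = 9L,
                            pseudocount = 1,
                            write_tracks = FALSE) {
  stopifnot(fc_threshold > 0, p_threshold > 0, expression_floor >= 0,
            min_count > 0, downstream_window > 0, W > 0, flank > 0,
            upstream_seq_len > 0, n_background >= 0, k_extremity >= 1,
            k_ued >= 1, pseudocount >= 0)
  structure(as.list(environment()), class = "pipeline_config")
}

# stable hash of the configuration for output provenance headers
.config_hash <- function(config) {
  f <- tempfile()
  writeLines(deparse(config[setdiff(names(config), "paths")]), f)
  h <- unname(tools::md5sum(f))
  unlink(f)
  h
}

.write_tsv <- function(df, path, meta) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# ", names(meta), ": ", meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_count_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                          comment.char = "#", check.names = FALSE)
  as.matrix(df)
}

#' Run the full transcription-unit architecture pipeline
#'
#' Stage order: input (simulate or read) -> count normalization ->
#' differential expression and translation efficiency -> metagene
#' profiles and extremity/torso boundary -> region fold changes and
#' clustering -> TEP detection/classification and 3'-UTRs -> TU assembly
#' -> UED table, cross-condition comparison and clustering -> terminator
#' sequence characterization. Every output table lands in `out_dir` with
#' a metadata header (config hash, seed, package version); rerunning
#' with the same configuration is byte-identical.
#'
#' @param config a [pipeline_config()]
#' @param out_dir output directory (created if needed)
#' @return invisibly, a list with all intermediate results
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- config$sim
  if (!config$simulate) {
    need <- c("genome", "annotation", "tss", "rna_counts", "rpf_counts")
    for (nm in need) {
      p <- config$paths[[nm]]
      if (is.null(p) || !file.exists(p))
        stop("missing input '", nm, "': ",
             if (is.null(p)) "not configured" else p)
    }
    if (is.null(config$paths$tracks))
      stop("missing input 'tracks': not configured")
    if (!all(file.exists(config$paths$tracks$path)))
      stop("missing track file(s): ",
           paste(config$paths$tracks$path[
             !file.exists(config$paths$tracks$path)], collapse = ","))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- c(config_hash = .config_hash(config), seed = sim$seed,
            tool = paste0("tuarch ",
                          as.character(utils::packageVersion("tuarch"))))
  log_stage <- function(...) message("[tuarch] ", ...)

  ## stage 1: inputs
  if (config$simulate) {
    world <- simulate_genome(sim)
    counts <- simulate_counts(world$truth, sim)
    tracks <- simulate_tracks(world$truth, sim, counts)
    genome <- world$genome; genes <- world$genes; tss <- world$tss
    conditions <- sim$conditions
    n_replicates <- sim$n_replicates
    write_genome_fasta(genome, file.path(out_dir, "genome.fa"))
    write_annotation_gff(genes, file.path(out_dir, "annotation.gff3"))
    write_table(tss, file.path(out_dir, "tss.tsv"), meta)
    .write_tsv(world$truth, file.path(out_dir, "truth.tsv"), meta)
    .write_tsv(data.frame(gene_id = rownames(counts$rna), counts$rna,
                          check.names = FALSE),
               file.path(out_dir, "counts_rna.tsv"), meta)
    .write_tsv(data.frame(gene_id = rownames(counts$rpf), counts$rpf,
                          check.names = FALSE),
               file.path(out_dir, "counts_rpf.tsv"), meta)
    if (isTRUE(config$write_tracks))
      for (tr in tracks)
        write_coverage_bedgraph(tr, genome$contig_id, file.path(
          out_dir, sprintf("track_%s_%s_rep%d_%s.bedgraph", tr$assay,
                           tr$condition, tr$replicate,
                           if (tr$strand == "+") "fwd" else "rev")))
  } else {
    genome <- read_genome_fasta(config$paths$genome)
    genes <- read_annotation_gff(config$paths$annotation)
    tss <- read_table(config$paths$tss)
    counts <- list(rna = .read_count_tsv(config$paths$rna_counts),
                   rpf = .read_count_tsv(config$paths$rpf_counts))
    tt <- config$paths$tracks
    tracks <- lapply(seq_len(nrow(tt)), function(i)
      read_coverage_bedgraph(tt$path[i], tt$strand[i], tt$assay[i],
                             tt$condition[i], tt$replicate[i],
                             genome$length))
    conditions <- unique(tt$condition[tt$assay == "RNA"])
    n_replicates <- max(tt$replicate[tt$assay == "RNA"])
  }
  stress <- if (config$simulate) sim$stress_condition
            else conditions[length(conditions)]
  reference <- conditions[1]
  log_stage("inputs: ", nrow(genes), " genes, ", length(tracks),
            " tracks, conditions ", paste(conditions, collapse = "/"))

  ## stage 2: normalization
  samples <- colnames(counts$rna)
  design <- sub("_[0-9]+$", "", samples)
  names(design) <- samples
  sf_rna <- size_factors(counts$rna)
  sf_rpf <- size_factors(counts$rpf)
  rna_norm <- normalize_counts(counts$rna, sf_rna)
  rpf_norm <- normalize_counts(counts$rpf, sf_rpf)
  .write_tsv(data.frame(sample = samples, size_factor_rna = sf_rna,
                        size_factor_rpf = sf_rpf),
             file.path(out_dir, "size_factors.tsv"), meta)

  ## stage 3: DEG + TE
  degs <- list()
  for (cc in setdiff(conditions, reference)) {
    d <- call_degs(rna_norm, design, cc, reference,
                   fc_threshold = config$fc_threshold,
                   p_threshold = config$p_threshold,
                   pseudocount = config$pseudocount)
    degs[[cc]] <- d
    write_table(d, file.path(out_dir, paste0("deg_", cc, "_vs_",
                                             reference, ".tsv")), meta)
    log_stage("DEG ", cc, " vs ", reference, ": ", sum(d$is_deg),
              " of ", nrow(d))
  }
  part_default <- extremity_partition(config$start_window,
                                      config$stop_window)
  torso_m <- torso_count_matrix(tracks, genes, part_default, conditions,
                                n_replicates)
  te <- translation_efficiency(rna_norm, rpf_norm, design,
                               pseudocount = config$pseudocount,
                               floor = config$expression_floor,
                               rpf_torso_norm = normalize_counts(
                                 torso_m[, samples, drop = FALSE], sf_rpf))
  write_table(te, file.path(out_dir, "te.tsv"), meta)
  log_stage("TE: ", length(unique(te$gene_id)), " genes past floor ",
            config$expression_floor)

  ## stage 4: metagene profiles + boundary
  profiles <- list()
  for (anchor in c("start_codon", "stop_codon"))
    for (cc in conditions)
      profiles[[paste(anchor, cc, sep = ".")]] <-
        metagene_profile(tracks, genes, anchor, assay = "RPF",
                         condition = cc, W = config$W)
  prof_df <- do.call(rbind, profiles)
  .write_tsv(prof_df, file.path(out_dir, "metagene_profiles.tsv"), meta)
  ctrl_conds <- setdiff(conditions, stress)
  partition <- tryCatch(
    determine_boundary(
      profiles[[paste0("start_codon.", stress)]],
      profiles[paste0("start_codon.", ctrl_conds)],
      profiles[[paste0("stop_codon.", stress)]],
      profiles[paste0("stop_codon.", ctrl_conds)]),
    error = function(e) {
      log_stage("boundary scan failed (", conditionMessage(e),
                "); using configured windows")
      part_default
    })
  .write_tsv(data.frame(window = c("start", "stop"),
                        from = c(partition$start_window[1],
                                 partition$stop_window[1]),
                        to = c(partition$start_window[2],
                               partition$stop_window[2])),
             file.path(out_dir, "extremity_partition.tsv"), meta)
  log_stage("extremity windows: start [",
            partition$start_window[1], ",", partition$start_window[2],
            "] stop [", partition$stop_window[1], ",",
            partition$stop_window[2], "]")

  ## stage 5: region fold changes + clustering
  region_fc <- region_fold_changes(tracks, genes, partition, stress,
                                   reference, sf_rpf, n_replicates,
                                   pseudocount = config$pseudocount)
  .write_tsv(region_fc, file.path(out_dir, "region_fold_changes.tsv"), meta)
  ext <- region_fc[region_fc$region == "extremity", ]
  ext_mat <- matrix(ext$log2fc, ncol = 1,
                    dimnames = list(ext$gene_id, "log2fc_extremity"))
  ext_clusters <- if (nrow(ext_mat) >= config$k_extremity)
    cluster_rows(ext_mat, config$k_extremity) else NULL
  if (!is.null(ext_clusters))
    .write_tsv(data.frame(gene_id = names(ext_clusters),
                          cluster = ext_clusters),
               file.path(out_dir, "extremity_clusters.tsv"), meta)

  ## stage 6: TEPs
  tep_cand <- list()
  for (str in c("+", "-")) {
    tt <- tracks_find(tracks, "TERM", strand = str)
    tep_cand[[str]] <- detect_teps(tt, min_count = config$min_count)
  }
  cand <- do.call(rbind, tep_cand)
  teps <- classify_teps(cand, genes,
                        downstream_window = config$downstream_window)
  write_table(teps, file.path(out_dir, "teps.tsv"), meta)
  log_stage("TEPs: ", nrow(cand), " candidates -> ",
            paste(names(table(teps$category)), table(teps$category),
                  sep = "=", collapse = " "))

  ## stage 7: TUs + UED
  tus <- build_tus(tss, teps, genes)
  write_table(tus, file.path(out_dir, "tus.tsv"), meta)
  log_stage("TUs: ", nrow(tus), " genes with both TSS and P-TEP")
  ued_tab <- ued_table(tracks, tus, conditions = conditions)
  write_table(ued_tab, file.path(out_dir, "ued.tsv"), meta)
  ued_tests <- list()
  for (assay in c("RNA", "RPF")) for (reg in c("utr5", "utr3"))
    ued_tests[[paste(assay, reg, sep = ".")]] <-
      tryCatch(ued_compare(ued_tab, assay, reg, stress, reference),
               error = function(e) NULL)
  ued_clust <- tryCatch(
    ued_compare_and_cluster(ued_tab, "RPF", "utr5", reference,
                            k = config$k_ued),
    error = function(e) NULL)
  if (!is.null(ued_clust))
    .write_tsv(data.frame(gene_id = names(ued_clust$labels),
                          cluster = ued_clust$labels),
               file.path(out_dir, "ued_clusters.tsv"), meta)

  ## stage 8: terminator sequence characterization
  p_teps <- teps[teps$category == "P", , drop = FALSE]
  comp <- NULL; mfe <- NULL
  if (nrow(p_teps) > 0L) {
    comp <- nucleotide_composition(p_teps, genome, flank = config$flank)
    .write_tsv(data.frame(offset = as.integer(rownames(comp)), comp),
               file.path(out_dir, "tep_composition.tsv"), meta)
    ups <- upstream_sequences(p_teps, genome,
                              width = config$upstream_seq_len)
    bg <- sample_intergenic(genome, genes, n = config$n_background,
                            length = config$upstream_seq_len,
                            seed = sim$seed + 3L)
    mfe <- mfe_background_test(ups$seq, bg)
    log_stage("terminator MFE screen: median ", round(mfe$median_tep, 2),
              " vs background ", round(mfe$median_bg, 2),
              ", p = ", format(mfe$p, digits = 3))
  }

  invisible(list(genome = genome, genes = genes, tss = tss,
                 counts = counts, tracks = tracks,
                 size_factors = list(rna = sf_rna, rpf = sf_rpf),
                 degs = degs, te = te, profiles = profiles,
                 partition = partition, region_fc = region_fc,
                 extremity_clusters = ext_clusters,
                 teps = teps, tus = tus, ued = ued_tab,
                 ued_tests = ued_tests, ued_clusters = ued_clust,
                 composition = comp, mfe = mfe,
                 truth = if (config$simulate) world$truth else NULL))
}
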