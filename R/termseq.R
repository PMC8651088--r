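#' Detect transcript 3'-end positions from Term-seq tracks
#'
#' A candidate in one replicate is a position whose 3'-end count is at
#' least `min_count` and is a local maximum within +/-3 nt (ties are
#' kept once, at the 5'-most position of the tie run in genomic order).
#' A candidate is retained iff every replicate has a candidate within
#' `match_tolerance` nt of it; the reported position is the candidate of
#' replicate 1.
#'
#' @param term_tracks list of TERM [coverage_track()]s, one per
#'   replicate, all on the same strand
#' @param min_count minimum 3'-end count (default 5)
#' @param match_tolerance allowed positional slack between replicates,
#'   nt (default 0 = exact)
#' @param allow_single_replicate permit detection from one replicate
#' @return data.frame with `position`, `strand`, and one count column
#'   per replicate (`count_rep<r>`), plus `count_total`
#' @export
detect_teps <- function(term_tracks, min_count = 5L, match_tolerance = 0L,
                        allow_single_replicate = FALSE) {
  if (length(term_tracks) < 2L && !allow_single_replicate)
    stop("need >= 2 Term-seq replicates (set allow_single_replicate to ",
         "override)")
  strand <- unique(vapply(term_tracks, `[[`, character(1), "strand"))
  if (length(strand) != 1L)
    stop("all replicate tracks must be on the same strand")
  cand <- lapply(term_tracks, function(tr) {
    d <- tr$depth
    idx <- which(d >= min_count)
    keep <- vapply(idx, function(p) {
      w <- d[max(1L, p - 3L):min(length(d), p + 3L)]
      if (d[p] < max(w)) return(FALSE)
      # tie run: keep only the smallest genomic position with this count
      lo <- max(1L, p - 3L)
      ties <- lo - 1L + which(d[lo:min(length(d), p + 3L)] == d[p])
      p == min(ties)
    }, logical(1))
    idx[keep]
  })
  if (length(cand[[1]]) == 0L ||
      any(vapply(cand, length, integer(1)) == 0L))
    return(data.frame(position = integer(0), strand = character(0)))
  keep1 <- vapply(cand[[1]], function(p)
    all(vapply(cand[-1], function(cs)
      any(abs(cs - p) <= match_tolerance), logical(1))), logical(1))
  pos <- cand[[1]][keep1]
  out <- data.frame(position = pos, strand = rep(strand, length(pos)),
                    stringsAsFactors = FALSE)
  total <- 0
  for (r in seq_along(term_tracks)) {
    out[[paste0("count_rep", r)]] <- term_tracks[[r]]$depth[pos]
    total <- total + term_tracks[[r]]$depth[pos]
  }
  out$count_total <- total
  out[order(out$position), , drop = FALSE]
}

# genomic interval of the sense downstream window of a gene
.downstream_window <- function(gene, width) {
  if (gene$strand == "+")
    c(gene$stop_codon_end_pos + 1L, gene$stop_codon_end_pos + width)
  else
    c(gene$stop_codon_end_pos - width, gene$stop_codon_end_pos - 1L)
}

#' Classify TEP candidates relative to gene models
#'
#' Categories, in precedence order per candidate:
#' * **P/S** - inside some same-strand gene's downstream window
#'   (default 250 nt past the stop codon): the candidate with the
#'   highest total count in that gene's window is primary (P), the rest
#'   secondary (S); count ties break toward the position nearest the
#'   stop codon. When two same-strand downstream windows overlap, the
#'   candidate goes to the nearer stop codon (with a warning).
#' * **I** - inside a same-strand CDS.
#' * **A** - overlapping a gene on the opposite strand.
#' * **U** - within `upstream_window` nt sense-upstream of a start codon.
#' * otherwise the candidate is dropped (reported via a message).
#'
#' @param candidates data.frame from [detect_teps()] (needs `position`,
#'   `strand` and, if available, `count_total`; candidates of both
#'   strands may be concatenated)
#' @param genes a [gene_models()] table
#' @param downstream_window nt past the stop codon scanned for P/S TEPs
#' @param upstream_window nt before the start codon scanned for U TEPs
#' @return data.frame of class `tep_records` with `position`, `strand`,
#'   `category`, `gene_id` and any count columns carried through
#' @export
classify_teps <- function(candidates, genes, downstream_window = 250L,
                          upstream_window = 150L) {
  n <- nrow(candidates)
  category <- rep(NA_character_, n)
  gene_id <- rep(NA_character_, n)
  counts <- if ("count_total" %in% names(candidates))
    candidates$count_total else rep(1, n)

  # 1) assign candidates to downstream windows (nearer stop on overlap)
  ds_gene <- rep(NA_integer_, n)
  for (ci in seq_len(n)) {
    p <- candidates$position[ci]; str <- candidates$strand[ci]
    hits <- which(genes$strand == str)
    dist <- rep(NA_integer_, length(hits))
    for (h in seq_along(hits)) {
      g <- genes[hits[h], ]
      win <- .downstream_window(g, downstream_window)
      if (p >= win[1] && p <= win[2])
        dist[h] <- strand_distance(g$stop_codon_end_pos, p, str) - 1L
    }
    inside <- which(!is.na(dist))
    if (length(inside) > 1L)
      warning("TEP candidate at ", p, " (", str, ") falls in overlapping ",
              "downstream windows; assigned to the nearer stop codon")
    if (length(inside)) ds_gene[ci] <- hits[inside[which.min(dist[inside])]]
  }
  for (gi in unique(ds_gene[!is.na(ds_gene)])) {
    members <- which(ds_gene == gi)
    g <- genes[gi, ]
    d_stop <- abs(candidates$position[members] - g$stop_codon_end_pos)
    best <- members[order(-counts[members], d_stop)][1]
    category[best] <- "P"
    category[setdiff(members, best)] <- "S"
    gene_id[members] <- g$gene_id
  }

  # 2-4) remaining candidates
  for (ci in which(is.na(category))) {
    p <- candidates$position[ci]; str <- candidates$strand[ci]
    in_cds <- genes$cds_start <= p & p <= genes$cds_end
    sense <- which(in_cds & genes$strand == str)
    if (length(sense)) {
      category[ci] <- "I"; gene_id[ci] <- genes$gene_id[sense[1]]
      next
    }
    anti <- which(in_cds & genes$strand != str)
    if (length(anti)) {
      category[ci] <- "A"; gene_id[ci] <- genes$gene_id[anti[1]]
      next
    }
    up <- which(vapply(seq_len(nrow(genes)), function(i) {
      g <- genes[i, ]
      if (g$strand != str) return(FALSE)
      d <- strand_distance(p, g$start_codon_pos, str) - 1L
      d >= 1L && d <= upstream_window
    }, logical(1)))
    if (length(up)) {
      g <- genes[up, , drop = FALSE]
      d <- abs(g$start_codon_pos - p)
      category[ci] <- "U"; gene_id[ci] <- g$gene_id[which.min(d)]
    }
  }

  drop <- is.na(category)
  if (any(drop))
    message("dropping ", sum(drop), " unassignable TEP candidate(s) at: ",
            paste(candidates$position[drop], collapse = ","))
  out <- candidates[!drop, , drop = FALSE]
  out$category <- category[!drop]
  out$gene_id <- gene_id[!drop]
  rownames(out) <- NULL
  class(out) <- c("tep_records", "data.frame")
  out
}

#' 3'-UTR lengths from primary TEPs
#'
#' For every gene with a P-TEP, the 3'-UTR length is the strand-aware
#' distance from the first base past the stop codon through the TEP
#' inclusive (so a TEP immediately after the stop codon gives length 1).
#'
#' @param teps a [classify_teps()] result
#' @param genes a [gene_models()] table
#' @return named integer vector gene_id -> l_3utr
#' @export
assign_3utr <- function(teps, genes) {
  p_teps <- teps[teps$category == "P", , drop = FALSE]
  out <- integer(0)
  for (i in seq_len(nrow(p_teps))) {
    g <- genes[genes$gene_id == p_teps$gene_id[i], ]
    out[g$gene_id] <- strand_distance(g$stop_codon_end_pos, p_teps$position[i],
                                      g$strand) - 1L
  }
  out
}

#' Positional nucleotide composition around TEPs
#'
#' Per offset in -flank..+flank (offset 0 = the TEP), the fraction of
#' each base over all TEPs, with sequences read transcript-sense
#' (reverse-complemented for minus-strand TEPs). TEPs too near a contig
#' edge are skipped for their out-of-range offsets only.
#'
#' @param teps data.frame with `position` and `strand`
#' @param genome a [genome_sequence()]
#' @param flank half-width in nt (default 50)
#' @return numeric matrix (2*flank+1) x 4 of base fractions, rownames
#'   the offsets, colnames A/C/G/T; each row sums to 1
#' @export
nucleotide_composition <- function(teps, genome, flank = 50L) {
  if (nrow(teps) == 0L) stop("no TEPs supplied")
  offsets <- seq.int(-flank, flank)
  bases <- strsplit(genome$sequence, "")[[1]]
  tab <- matrix(0, length(offsets), 4L,
                dimnames = list(offsets, c("A", "C", "G", "T")))
  for (i in seq_len(nrow(teps))) {
    sgn <- .strand_sign(teps$strand[i])
    pos <- teps$position[i] + sgn * offsets
    ok <- pos >= 1L & pos <= genome$length
    b <- bases[pos[ok]]
    if (sgn < 0) b <- chartr("ACGT", "TGCA", b)
    known <- b %in% colnames(tab)
    rows <- which(ok)[known]
    tab[cbind(rows, match(b[known], colnames(tab)))] <-
      tab[cbind(rows, match(b[known], colnames(tab)))] + 1
  }
  sums <- rowSums(tab)
  if (any(sums == 0)) stop("an offset received no sequence; flank too wide")
  tab / sums
}

#' Transcript-sense sequences upstream of TEPs
#'
#' Extracts the `width`-nt transcript-sense sequence ending at each TEP
#' (the region folded when screening for intrinsic-terminator hairpins).
#' TEPs closer than `width` to the contig edge return a shorter sequence
#' and are flagged.
#'
#' @inheritParams nucleotide_composition
#' @param width sequence length in nt (default 40)
#' @return data.frame with `position`, `strand`, `seq`, `truncated`
#' @export
upstream_sequences <- function(teps, genome, width = 40L) {
  seqs <- character(nrow(teps)); trunc <- logical(nrow(teps))
  for (i in seq_len(nrow(teps))) {
    p <- teps$position[i]
    if (teps$strand[i] == "+") {
      lo <- max(1L, p - width + 1L)
      s <- substr(genome$sequence, lo, p)
    } else {
      hi <- min(genome$length, p + width - 1L)
      s <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(substr(genome$sequence, p, hi))))
    }
    trunc[i] <- nchar(s) < width
    seqs[i] <- s
  }
  data.frame(position = teps$position, strand = teps$strand, seq = seqs,
             truncated = trunc, stringsAsFactors = FALSE)
}

#' Sample random intergenic sequences
#'
#' Draws `n` windows of `length` nt uniformly over the intergenic space
#' (positions overlapping no annotated CDS), each assigned a random
#' strand; minus-strand windows are reverse-complemented.
#'
#' @param genome a [genome_sequence()]
#' @param genes a [gene_models()] table
#' @param n number of sequences (default 10000)
#' @param length window length in nt (default 40)
#' @param seed RNG seed
#' @return character vector of `n` sequences
#' @export
sample_intergenic <- function(genome, genes, n = 10000L, length = 40L,
                              seed = 1L) {
  cds <- IRanges::reduce(IRanges::IRanges(genes$cds_start, genes$cds_end))
  inter <- IRanges::setdiff(IRanges::IRanges(1L, genome$length), cds)
  inter <- inter[IRanges::width(inter) >= length]
  if (sum(IRanges::width(inter)) < length)
    stop("insufficient intergenic space for windows of ", length, " nt")
  if (n == 0L) return(character(0))
  starts_ok <- IRanges::width(inter) - length + 1L
  set.seed(seed)
  seg <- sample.int(length(inter), n, replace = TRUE,
                    prob = starts_ok / sum(starts_ok))
  off <- floor(stats::runif(n) * starts_ok[seg])
  st <- IRanges::start(inter)[seg] + as.integer(off)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  vapply(seq_len(n), function(i) {
    s <- substr(genome$sequence, st[i], st[i] + length - 1L)
    if (strand[i] == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }, character(1))
}

#' Folding adapters for terminator free-energy screens
#'
#' `fold_gc_stub()` is a trivial structure-free stand-in returning
#' `-(#G + #C)` kcal/mol-like scores, useful for deterministic tests.
#' `fold_rnafold()` shells out to the ViennaRNA `RNAfold` executable and
#' returns the minimum free energy of each sequence (NA on failure).
#'
#' @param seqs character vector of sequences
#' @return numeric vector of free-energy scores, one per sequence
#' @export
fold_gc_stub <- function(seqs) {
  -(nchar(gsub("[^G]", "", seqs)) + nchar(gsub("[^C]", "", seqs)))
}

#' @rdname fold_gc_stub
#' @export
fold_rnafold <- function(seqs) {
  exe <- Sys.which("RNAfold")
  if (exe == "") stop("RNAfold executable not found on PATH")
  inp <- tempfile(fileext = ".fa")
  writeLines(as.vector(rbind(paste0(">s", seq_along(seqs)), seqs)), inp)
  out <- system2(exe, c("--noPS", "-i", inp), stdout = TRUE)
  unlink(inp)
  mfe_lines <- grep("\\(\\s*-?[0-9.]+\\)$", out, value = TRUE)
  if (length(mfe_lines) != length(seqs))
    warning(length(seqs) - length(mfe_lines), " sequence(s) failed to fold")
  vals <- rep(NA_real_, length(seqs))
  vals[seq_along(mfe_lines)] <-
    as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)$", "\\1", mfe_lines))
  vals
}

#' Compare terminator free energies against a background
#'
#' Folds both sequence sets with the supplied adapter and performs a
#' one-sided rank-sum (Wilcoxon) test of whether the TEP-upstream
#' sequences have lower free energy (more stable structure) than the
#' background sequences.
#'
#' @param tep_seqs,bg_seqs character vectors of sequences
#' @param fold adapter `function(seqs) -> numeric` (e.g. [fold_gc_stub()]
#'   or [fold_rnafold()])
#' @return list with `median_tep`, `median_bg`, `statistic`, `p`,
#'   `n_skipped`
#' @export
mfe_background_test <- function(tep_seqs, bg_seqs, fold = fold_gc_stub) {
  g_tep <- fold(tep_seqs)
  g_bg <- fold(bg_seqs)
  n_skip <- sum(is.na(g_tep)) + sum(is.na(g_bg))
  if (n_skip > 0)
    warning(n_skip, " sequence(s) skipped (folding failed)")
  g_tep <- g_tep[!is.na(g_tep)]; g_bg <- g_bg[!is.na(g_bg)]
  wt <- stats::wilcox.test(g_tep, g_bg, alternative = "less", exact = FALSE)
  list(median_tep = stats::median(g_tep), median_bg = stats::median(g_bg),
       statistic = unname(wt$statistic), p = wt$p.value, n_skipped = n_skip)
}
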