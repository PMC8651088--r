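#' Median-of-ratios size factors
#'
#' The classic median-of-ratios estimator: per sample, the median over
#' genes (restricted to genes with a positive geometric mean across all
#' samples) of the ratio of the gene's count to its across-sample
#' geometric mean.
#'
#' @param counts non-negative integer matrix, genes x samples
#' @return positive numeric vector, one size factor per sample
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  log_geo <- rowMeans(log(counts))
  use <- is.finite(log_geo)
  if (!any(use))
    stop("no gene with nonzero counts in every sample; cannot estimate ",
         "size factors")
  sf <- apply(counts, 2L, function(col)
    exp(stats::median(log(col[use]) - log_geo[use])))
  if (any(!is.finite(sf) | sf <= 0))
    stop("degenerate size factor estimate")
  sf
}

#' Normalize a count matrix by size factors
#'
#' @param counts genes x samples matrix
#' @param factors positive size factors, one per sample
#' @return numeric matrix `counts[g, j] / factors[j]`
#' @export
normalize_counts <- function(counts, factors = size_factors(counts)) {
  counts <- as.matrix(counts)
  if (length(factors) != ncol(counts))
    stop("length(factors) must equal ncol(counts)")
  if (any(factors <= 0)) stop("size factors must be positive")
  sweep(counts, 2L, factors, "/")
}

# condition of each sample from a design map (named vector sample -> condition)
.check_design <- function(normalized, design) {
  if (is.null(names(design)) || !all(colnames(normalized) %in% names(design)))
    stop("design must be a named vector mapping every sample id to its ",
         "condition")
  design[colnames(normalized)]
}

# per-condition means of a normalized matrix (always a genes x conditions
# matrix, also for a single gene)
.condition_means <- function(normalized, design) {
  cond <- .check_design(normalized, design)
  u <- unique(cond)
  m <- vapply(u, function(cc)
    rowMeans(normalized[, cond == cc, drop = FALSE]),
    numeric(nrow(normalized)))
  matrix(m, nrow = nrow(normalized),
         dimnames = list(rownames(normalized), u))
}

#' Genes passing the expression floor in every condition
#'
#' A gene is kept when its mean normalized value per condition is at
#' least `floor` in every condition (default floor 10).
#'
#' @param normalized normalized matrix from [normalize_counts()]
#' @param design named vector mapping sample ids to condition labels
#' @param floor expression floor
#' @return character vector of gene ids
#' @export
expressed_genes <- function(normalized, design, floor = 10) {
  m <- .condition_means(normalized, design)
  rownames(normalized)[apply(m >= floor, 1L, all)]
}

#' Differential expression calls
#'
#' log2 fold changes are computed from per-condition means of normalized
#' counts (with a pseudocount); p-values come from the pluggable `test`
#' function, by default a two-sided Welch t-test on log2(normalized + 1).
#' A gene is called differentially expressed iff `|log2fc| > fc_threshold`
#' and `p < p_threshold`.
#'
#' @param normalized normalized matrix
#' @param design named vector mapping sample ids to condition labels
#' @param condition,reference the contrasted condition labels
#' @param fc_threshold log2 fold-change gate (default 1)
#' @param p_threshold p-value gate (default 0.05)
#' @param pseudocount added to condition means before the log ratio
#' @param test function(x, y) -> p-value given the two groups' normalized
#'   values for one gene; `NULL` uses the default Welch t-test on
#'   log2(x + 1)
#' @return data.frame of class `deg_results` with `gene_id`, `log2fc`,
#'   `p_value`, `is_deg`, `direction`
#' @export
call_degs <- function(normalized, design, condition, reference,
                      fc_threshold = 1.0, p_threshold = 0.05,
                      pseudocount = 1, test = NULL) {
  cond <- .check_design(normalized, design)
  if (!condition %in% cond || !reference %in% cond)
    stop("condition/reference not present in design")
  xs <- normalized[, cond == condition, drop = FALSE]
  ys <- normalized[, cond == reference, drop = FALSE]
  if (is.null(test)) {
    if (ncol(xs) < 2L || ncol(ys) < 2L)
      stop("need >= 2 replicates per condition for the default test")
    test <- function(x, y) {
      lx <- log2(x + 1); ly <- log2(y + 1)
      if (stats::var(lx) + stats::var(ly) == 0)
        return(if (isTRUE(all.equal(mean(lx), mean(ly)))) 1 else 0)
      stats::t.test(lx, ly)$p.value
    }
  }
  log2fc <- log2(rowMeans(xs) + pseudocount) -
    log2(rowMeans(ys) + pseudocount)
  p <- vapply(seq_len(nrow(normalized)),
              function(i) test(xs[i, ], ys[i, ]), numeric(1))
  is_deg <- abs(log2fc) > fc_threshold & p < p_threshold
  df <- data.frame(gene_id = rownames(normalized), log2fc = log2fc,
                   p_value = p, is_deg = is_deg,
                   direction = ifelse(!is_deg, "none",
                                      ifelse(log2fc > 0, "up", "down")),
                   row.names = NULL, stringsAsFactors = FALSE)
  class(df) <- c("deg_results", "data.frame")
  df
}

#' Translation efficiency per gene and condition
#'
#' TE is the translation-to-transcription ratio
#' `(mean normalized RPF + pseudocount) / (mean normalized RNA +
#' pseudocount)` per condition, restricted to genes passing the RNA
#' expression floor. When a torso-restricted RPF matrix is supplied
#' (see [torso_count_matrix()]), a `torso_te` column is computed the same
#' way from it.
#'
#' @param rna_norm,rpf_norm normalized matrices with matching sample ids
#' @param design named vector mapping sample ids to condition labels
#' @param pseudocount ratio pseudocount (default 1)
#' @param floor RNA expression floor for gene eligibility
#' @param rpf_torso_norm optional normalized torso-restricted RPF matrix
#' @return data.frame of class `te_results` with `gene_id`, `condition`,
#'   `te` and `torso_te` (NA when no torso matrix given)
#' @export
translation_efficiency <- function(rna_norm, rpf_norm, design,
                                   pseudocount = 1, floor = 10,
                                   rpf_torso_norm = NULL) {
  keep <- expressed_genes(rna_norm, design, floor = floor)
  missing_rpf <- setdiff(keep, rownames(rpf_norm))
  if (length(missing_rpf)) {
    warning("skipping ", length(missing_rpf),
            " gene(s) absent from the RPF matrix")
    keep <- setdiff(keep, missing_rpf)
  }
  if (length(keep) == 0L) stop("no genes pass the expression floor")
  rna_m <- .condition_means(rna_norm[keep, , drop = FALSE], design)
  rpf_m <- .condition_means(rpf_norm[keep, , drop = FALSE], design)
  conds <- colnames(rna_m)
  torso_m <- NULL
  if (!is.null(rpf_torso_norm)) {
    keep_t <- intersect(keep, rownames(rpf_torso_norm))
    torso_m <- .condition_means(rpf_torso_norm[keep_t, , drop = FALSE],
                                design)
  }
  out <- do.call(rbind, lapply(conds, function(cc) {
    tt <- rep(NA_real_, length(keep))
    if (!is.null(torso_m)) {
      idx <- match(keep, rownames(torso_m))
      tt <- ifelse(is.na(idx), NA_real_,
                   (torso_m[idx, cc] + pseudocount) /
                     (rna_m[, cc] + pseudocount))
    }
    data.frame(gene_id = keep, condition = cc,
               te = (rpf_m[, cc] + pseudocount) /
                 (rna_m[, cc] + pseudocount),
               torso_te = tt, row.names = NULL, stringsAsFactors = FALSE)
  }))
  class(out) <- c("te_results", "data.frame")
  out
}

#' Torso-restricted RPF depth of one gene
#'
#' Sum of RPF depth over the CDS positions strictly inside the torso,
#' i.e. excluding both extremity windows.
#'
#' @param rpf_track a [coverage_track()] on the gene's strand
#' @param gene single-row [gene_models()] entry
#' @param partition an [extremity_partition()]
#' @return numeric scalar
#' @export
torso_counts <- function(rpf_track, gene, partition = extremity_partition()) {
  pos <- region_positions(gene, partition, "torso")
  sum(rpf_track$depth[pos])
}

#' Gene x sample matrix of torso-restricted RPF sums
#'
#' Convenience builder feeding the `torso_te` column of
#' [translation_efficiency()] and the torso rows of
#' [region_fold_changes()]-style analyses. Genes whose torso would be
#' empty under `partition` are dropped with a warning.
#'
#' @param tracks list of [coverage_track()] including RPF tracks for all
#'   samples
#' @param genes a [gene_models()] table
#' @param partition an [extremity_partition()]
#' @param conditions,n_replicates sample layout of the RPF tracks
#' @return numeric matrix genes x samples of torso depth sums
#' @export
torso_count_matrix <- function(tracks, genes,
                               partition = extremity_partition(),
                               conditions, n_replicates) {
  ok <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    cds_len <- abs(g$stop_codon_end_pos - g$start_codon_pos) + 1L
    cds_len - partition$start_window[2] + partition$stop_window[1] > 0L
  }, logical(1))
  if (!all(ok))
    warning("dropping ", sum(!ok), " gene(s) with empty torso: ",
            paste(genes$gene_id[!ok], collapse = ","))
  genes <- genes[ok, , drop = FALSE]
  samples <- as.vector(t(outer(conditions, seq_len(n_replicates), paste,
                               sep = "_")))
  m <- matrix(0, nrow(genes), length(samples),
              dimnames = list(genes$gene_id, samples))
  for (cc in conditions) for (r in seq_len(n_replicates)) {
    j <- paste0(cc, "_", r)
    for (str in c("+", "-")) {
      tr <- tracks_find(tracks, "RPF", cc, r, str)
      if (length(tr) != 1L)
        stop("expected exactly one RPF track for ", j, " strand ", str)
      idx <- which(genes$strand == str)
      for (i in idx)
        m[i, j] <- torso_counts(tr[[1]], genes[i, ], partition)
    }
  }
  m
}

#' Hypergeometric functional enrichment with BH correction
#'
#' Upper-tail hypergeometric test per term (probability of observing at
#' least the seen overlap between the query set and the term's genes,
#' drawing `|query|` genes from the background), Benjamini-Hochberg
#' adjusted across terms.
#'
#' @param query character vector of gene ids, a subset of `background`
#' @param term_map named list: term -> character vector of member genes
#' @param background character vector of background gene ids
#' @param alpha adjusted-p significance cutoff (default 0.05)
#' @return data.frame with `term`, `overlap`, `term_size`, `p`,
#'   `p_adjusted`, `enriched`
#' @export
hypergeom_enrichment <- function(query, term_map, background, alpha = 0.05) {
  background <- unique(background)
  if (length(background) == 0L) stop("empty background")
  query <- unique(query)
  if (!all(query %in% background))
    stop("query must be a subset of the background")
  res <- do.call(rbind, lapply(names(term_map), function(term) {
    members <- intersect(unique(term_map[[term]]), background)
    k <- length(intersect(query, members))
    m <- length(members)
    p <- stats::phyper(k - 1L, m, length(background) - m, length(query),
                       lower.tail = FALSE)
    data.frame(term = term, overlap = k, term_size = m, p = p,
               stringsAsFactors = FALSE)
  }))
  res$p_adjusted <- stats::p.adjust(res$p, method = "BH")
  res$enriched <- res$p_adjusted < alpha
  res
}
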