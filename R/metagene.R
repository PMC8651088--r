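#' Metagene ribosome-occupancy profile around a codon anchor
#'
#' For each profile offset in -W..+W (offset 0 = the anchor base, first
#' base of the start codon or last base of the stop codon; positive
#' offsets run 3' in transcript sense), the depth at the strand-aware
#' offset is averaged over genes. With `per_gene_norm` each gene's depth
#' is first divided by its mean CDS depth, so highly expressed genes do
#' not dominate; genes with zero mean CDS depth are dropped. Genes whose
#' window exits the contig are dropped for the out-of-range offsets only.
#'
#' @param tracks list of [coverage_track()] (one assay/condition; all
#'   replicates found are averaged position-wise per strand)
#' @param genes a [gene_models()] table
#' @param anchor `"start_codon"` or `"stop_codon"`
#' @param assay,condition track selectors passed to [tracks_mean_depth()]
#' @param W half-width in bp (default 200)
#' @param per_gene_norm divide each gene's depth by its mean CDS depth
#' @return data.frame of class `metagene_profile` with `anchor`,
#'   `offset` (-W..W), `mean_depth`, `condition`, `n_genes`
#' @export
metagene_profile <- function(tracks, genes, anchor = c("start_codon",
                                                       "stop_codon"),
                             assay = "RPF", condition = NULL, W = 200L,
                             per_gene_norm = TRUE) {
  anchor <- match.arg(anchor)
  if (nrow(genes) == 0L) stop("empty gene list")
  offsets <- seq.int(-W, W)
  depth_by_strand <- list(
    "+" = tracks_mean_depth(tracks, assay, condition, "+"),
    "-" = tracks_mean_depth(tracks, assay, condition, "-"))
  glen <- length(depth_by_strand[["+"]])
  acc <- numeric(length(offsets))
  n_at <- integer(length(offsets))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    d <- depth_by_strand[[g$strand]]
    norm <- 1
    if (per_gene_norm) {
      cds <- seq.int(min(g$cds_start, g$cds_end), max(g$cds_start, g$cds_end))
      norm <- mean(d[cds])
      if (norm == 0) next
    }
    pos <- offset_to_genomic(g, anchor, offsets)
    in_range <- pos >= 1L & pos <= glen
    acc[in_range] <- acc[in_range] + d[pos[in_range]] / norm
    n_at[in_range] <- n_at[in_range] + 1L
  }
  if (all(n_at == 0L)) stop("no gene contributed to the profile")
  df <- data.frame(anchor = anchor, offset = offsets,
                   mean_depth = ifelse(n_at > 0L, acc / pmax(n_at, 1L), NA_real_),
                   condition = if (is.null(condition)) NA_character_
                               else condition,
                   n_genes = n_at, stringsAsFactors = FALSE)
  class(df) <- c("metagene_profile", "data.frame")
  df
}

# first profile offset along `path` where stress <= reference, or NA
.first_crossing <- function(stress, ref, offsets, path) {
  for (o in path) {
    i <- match(o, offsets)
    if (stress[i] <= ref[i]) return(o)
  }
  NA_integer_
}

#' Determine the extremity/torso boundary from metagene profiles
#'
#' The reference is the offset-wise mean of the control profiles. From
#' each anchor the stress profile is scanned outward (into the CDS and
#' away from it); the boundary is the last profile offset before the
#' first position where the stress profile has decreased to (<=) the
#' reference. The four boundaries are converted to signed window
#' coordinates and returned as an [extremity_partition()]. An offset
#' where stress exactly equals the reference counts as crossed (it
#' belongs to the torso).
#'
#' @param start_stress,stop_stress stress-condition [metagene_profile()]s
#'   anchored at the start and stop codon
#' @param start_ctrl_list,stop_ctrl_list lists of control profiles with
#'   the same offsets
#' @param smooth odd width of an optional centered moving average applied
#'   to every profile before scanning (1 = none)
#' @return an [extremity_partition()]
#' @export
determine_boundary <- function(start_stress, start_ctrl_list,
                               stop_stress, stop_ctrl_list, smooth = 1L) {
  smooth_fun <- function(x) {
    if (smooth <= 1L) return(x)
    as.numeric(stats::filter(x, rep(1 / smooth, smooth), sides = 2))
  }
  prep <- function(stress, ctrl_list) {
    offs <- stress$offset
    for (p in ctrl_list)
      if (!identical(p$offset, offs))
        stop("profiles must share the same offsets")
    ref <- Reduce(`+`, lapply(ctrl_list, `[[`, "mean_depth")) /
      length(ctrl_list)
    list(offsets = offs, stress = smooth_fun(stress$mean_depth),
         ref = smooth_fun(ref))
  }
  st <- prep(start_stress, start_ctrl_list)
  sp <- prep(stop_stress, stop_ctrl_list)
  W <- max(st$offsets)

  cross_err <- function(which) {
    stop("stress profile never decreases to the reference while scanning ",
         which, " within +/-", W, "; supply the window manually")
  }
  # start anchor: into the CDS = increasing offsets from 0
  o_in <- .first_crossing(st$stress, st$ref, st$offsets, 0:W)
  if (is.na(o_in) || o_in == 0L) {
    if (is.na(o_in)) cross_err("downstream of the start codon")
    stop("extremity window must straddle the start codon (stress is not ",
         "elevated at the codon itself)")
  }
  b1 <- o_in       # profile boundary o_in - 1 -> window coordinate o_in
  # away from the CDS = decreasing offsets from -1
  o_out <- .first_crossing(st$stress, st$ref, st$offsets, -(1:W))
  if (is.na(o_out)) cross_err("upstream of the start codon")
  if (o_out == -1L)
    stop("extremity window must straddle the start codon")
  a1 <- o_out + 1L
  # stop anchor: into the CDS = decreasing offsets from 0
  o_in2 <- .first_crossing(sp$stress, sp$ref, sp$offsets, 0:-W)
  if (is.na(o_in2) || o_in2 == 0L) {
    if (is.na(o_in2)) cross_err("upstream of the stop codon")
    stop("extremity window must straddle the stop codon")
  }
  a2 <- o_in2      # profile boundary o_in2 + 1 -> window coordinate o_in2
  o_out2 <- .first_crossing(sp$stress, sp$ref, sp$offsets, 1:W)
  if (is.na(o_out2)) cross_err("downstream of the stop codon")
  if (o_out2 == 1L)
    stop("extremity window must straddle the stop codon")
  b2 <- o_out2 - 1L
  extremity_partition(c(a1, b1), c(a2, b2))
}

#' Extremity and torso RPF fold changes per gene
#'
#' For each gene and region (extremity = start window + stop window sum;
#' torso = the remaining internal CDS), the log2 ratio of
#' size-factor-scaled RPF depth sums between a stress condition and the
#' reference condition, with a pseudocount. Genes whose torso would be
#' empty are flagged `excluded` rather than dropped.
#'
#' @param tracks list of [coverage_track()] with RPF tracks
#' @param genes a [gene_models()] table
#' @param partition an [extremity_partition()]
#' @param condition,reference contrasted condition labels
#' @param sf named size factors per sample id (`<condition>_<replicate>`)
#' @param n_replicates replicates per condition
#' @param pseudocount added to the scaled sums before the ratio
#' @return data.frame of class `region_fc` with `gene_id`, `region`,
#'   `log2fc`, `excluded`
#' @export
region_fold_changes <- function(tracks, genes, partition, condition,
                                reference, sf, n_replicates,
                                pseudocount = 1) {
  region_sum <- function(gene, cond, region) {
    pos <- region_positions(gene, partition, region)
    tot <- 0
    for (r in seq_len(n_replicates)) {
      tr <- tracks_find(tracks, "RPF", cond, r, gene$strand)
      if (length(tr) != 1L)
        stop("expected one RPF track for ", cond, " rep ", r,
             " strand ", gene$strand)
      tot <- tot + sum(tr[[1]]$depth[pos]) / sf[paste0(cond, "_", r)]
    }
    tot / n_replicates
  }
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    cds_len <- abs(g$stop_codon_end_pos - g$start_codon_pos) + 1L
    torso_ok <- cds_len - partition$start_window[2] +
      partition$stop_window[1] > 0L
    ext_fc <- log2((region_sum(g, condition, "extremity") + pseudocount) /
                   (region_sum(g, reference, "extremity") + pseudocount))
    rows[[length(rows) + 1L]] <-
      data.frame(gene_id = g$gene_id, region = "extremity", log2fc = ext_fc,
                 excluded = FALSE, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- if (torso_ok)
      data.frame(gene_id = g$gene_id, region = "torso",
                 log2fc = log2((region_sum(g, condition, "torso") +
                                  pseudocount) /
                               (region_sum(g, reference, "torso") +
                                  pseudocount)),
                 excluded = FALSE, stringsAsFactors = FALSE)
    else
      data.frame(gene_id = g$gene_id, region = "torso", log2fc = NA_real_,
                 excluded = TRUE, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("region_fc", "data.frame")
  out
}

#' Deterministic hierarchical clustering of a feature matrix
#'
#' Agglomerative clustering (default Ward linkage on Euclidean
#' distances) cut at `k` clusters, with labels 1..k relabeled stably by
#' decreasing cluster mean of the first feature column.
#'
#' @param x numeric matrix, rows = genes, columns = features; no NAs
#' @param k number of clusters, `1 <= k <= nrow(x)`
#' @param linkage `hclust` agglomeration method (default `"ward.D2"`)
#' @param metric `dist` method (default `"euclidean"`)
#' @return integer vector of cluster labels named by rownames of `x`
#' @export
cluster_rows <- function(x, k, linkage = "ward.D2", metric = "euclidean") {
  x <- as.matrix(x)
  bad <- apply(x, 1L, function(r) any(!is.finite(r)))
  if (any(bad))
    stop("non-finite feature rows for: ",
         paste(rownames(x)[bad], collapse = ","))
  if (k < 1L || k > nrow(x))
    stop("k must be between 1 and the number of rows (", nrow(x), ")")
  if (k == 1L) {
    labels <- rep(1L, nrow(x))
  } else {
    hc <- stats::hclust(stats::dist(x, method = metric), method = linkage)
    labels <- stats::cutree(hc, k = k)
  }
  # stable relabeling: cluster 1 has the highest mean of the first feature
  means <- tapply(x[, 1L], labels, mean)
  new_id <- integer(length(means))
  new_id[order(means, decreasing = TRUE)] <- seq_along(means)
  labels <- new_id[labels]
  names(labels) <- rownames(x)
  labels
}
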