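#' Assemble transcription units from TSSs and primary TEPs
#'
#' A TU is built for every gene that has both an assigned TSS and a
#' primary (P) TEP. When several TSSs map to a gene, the one nearest the
#' start codon with a non-negative 5'-UTR length is used; a TSS lying
#' strictly inside the CDS is ignored with a warning. Length fields
#' (strand-aware): `l_5utr` = bases from the TSS through the base before
#' the start codon; `l_3utr` = bases from the first base past the stop
#' codon through the TEP; `l_tu` = TSS through TEP inclusive, so
#' `l_tu = l_5utr + CDS length + l_3utr`.
#'
#' @param tss a [tss_records()] table
#' @param teps a [classify_teps()] result (only P-TEPs are used)
#' @param genes a [gene_models()] table
#' @return data.frame of class `transcription_units` with `gene_id`,
#'   `strand`, `tss_pos`, `tep_pos`, `start_codon_pos`,
#'   `stop_codon_end_pos`, `l_5utr`, `l_3utr`, `l_tu`
#' @export
build_tus <- function(tss, teps, genes) {
  p_teps <- teps[teps$category == "P", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    tp <- p_teps[p_teps$gene_id == g$gene_id, , drop = FALSE]
    ts <- tss[tss$gene_id == g$gene_id, , drop = FALSE]
    if (nrow(tp) == 0L || nrow(ts) == 0L) next
    l5 <- strand_distance(ts$position, g$start_codon_pos, g$strand) - 1L
    inside <- l5 < 0L
    if (any(inside)) {
      warning("ignoring TSS inside the CDS of ", g$gene_id, " at ",
              paste(ts$position[inside], collapse = ","))
      ts <- ts[!inside, , drop = FALSE]; l5 <- l5[!inside]
    }
    if (nrow(ts) == 0L) next
    j <- which.min(l5)
    l3 <- strand_distance(g$stop_codon_end_pos, tp$position[1], g$strand) - 1L
    cds_len <- abs(g$stop_codon_end_pos - g$start_codon_pos) + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = g$gene_id, strand = g$strand,
      tss_pos = ts$position[j], tep_pos = tp$position[1],
      start_codon_pos = g$start_codon_pos,
      stop_codon_end_pos = g$stop_codon_end_pos,
      l_5utr = l5[j], l_3utr = l3, l_tu = l5[j] + cds_len + l3,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), strand = character(0),
               tss_pos = integer(0), tep_pos = integer(0),
               start_codon_pos = integer(0), stop_codon_end_pos = integer(0),
               l_5utr = integer(0), l_3utr = integer(0), l_tu = integer(0),
               stringsAsFactors = FALSE)
  class(out) <- c("transcription_units", "data.frame")
  out
}

#' Summarize UTR lengths over transcription units
#'
#' @param tus a [build_tus()] table
#' @param which `"utr5"` or `"utr3"`
#' @param gene_subset optional character vector restricting the summary
#' @return list with `median` (lower middle for even n), `min`, `max`, `n`
#' @export
utr_length_summary <- function(tus, which = c("utr5", "utr3"),
                               gene_subset = NULL) {
  which <- match.arg(which)
  if (!is.null(gene_subset)) {
    tus <- tus[tus$gene_id %in% gene_subset, , drop = FALSE]
    if (nrow(tus) == 0L) stop("gene_subset shares no genes with the TUs")
  }
  if (nrow(tus) == 0L) stop("no transcription units")
  x <- sort(if (which == "utr5") tus$l_5utr else tus$l_3utr)
  list(median = x[ceiling(length(x) / 2)], min = min(x), max = max(x),
       n = length(x))
}

# strand-aware genomic positions of a TU region
.tu_positions <- function(tu, region = c("tu", "utr5", "utr3")) {
  region <- match.arg(region)
  sgn <- .strand_sign(tu$strand)
  switch(region,
    tu = seq.int(tu$tss_pos, tu$tep_pos),
    utr5 = if (tu$l_5utr >= 1L)
      seq.int(tu$tss_pos, by = sgn, length.out = tu$l_5utr)
    else integer(0),
    utr3 = seq.int(tu$stop_codon_end_pos + sgn, by = sgn,
                   length.out = tu$l_3utr))
}

#' UTR enrichment degree (UED)
#'
#' The UED of a UTR is the mean depth over the UTR's positions divided
#' by the mean depth over the whole TU (TSS through TEP): values above 1
#' indicate depth enrichment in the UTR. Undefined (NA) when the TU has
#' zero total depth, or for the 5'-UTR of a leaderless TU
#' (`l_5utr = 0`).
#'
#' @param track a [coverage_track()] on the TU's strand (or a bare
#'   numeric depth vector)
#' @param tu single row of a [build_tus()] table
#' @param region `"utr5"` or `"utr3"`
#' @return numeric scalar, or NA when undefined
#' @export
ued <- function(track, tu, region = c("utr5", "utr3")) {
  region <- match.arg(region)
  depth <- if (inherits(track, "coverage_track")) track$depth else track
  tu_pos <- .tu_positions(tu, "tu")
  denom <- sum(depth[tu_pos]) / tu$l_tu
  if (denom == 0) return(NA_real_)
  reg_pos <- .tu_positions(tu, region)
  if (length(reg_pos) == 0L) return(NA_real_)
  (sum(depth[reg_pos]) / length(reg_pos)) / denom
}

#' UED table over all TUs, assays and conditions
#'
#' Replicate tracks are averaged position-wise per assay x condition x
#' strand before the UED is computed. One record per TU x assay x
#' condition; undefined entries carry NA and are flagged.
#'
#' @param tracks list of [coverage_track()] covering every assay x
#'   condition in `assays`/`conditions`
#' @param tus a [build_tus()] table
#' @param assays assays to tabulate (default RNA and RPF)
#' @param conditions condition labels present in the tracks
#' @return data.frame of class `ued_records` with `gene_id`, `assay`,
#'   `condition`, `ued5`, `ued3`, `defined5`, `defined3`
#' @export
ued_table <- function(tracks, tus, assays = c("RNA", "RPF"), conditions) {
  rows <- list()
  for (assay in assays) for (cond in conditions) {
    depth <- list("+" = tracks_mean_depth(tracks, assay, cond, "+"),
                  "-" = tracks_mean_depth(tracks, assay, cond, "-"))
    for (i in seq_len(nrow(tus))) {
      tu <- tus[i, ]
      u5 <- ued(depth[[tu$strand]], tu, "utr5")
      u3 <- ued(depth[[tu$strand]], tu, "utr3")
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = tu$gene_id, assay = assay, condition = cond,
        ued5 = u5, ued3 = u3,
        defined5 = !is.na(u5), defined3 = !is.na(u3),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ued_records", "data.frame")
  out
}

#' Cross-condition UED comparison
#'
#' Paired one-sided Wilcoxon signed-rank test, across genes, of whether
#' the UED under `condition` exceeds the UED under `reference` for a
#' given assay and UTR side.
#'
#' @param table a [ued_table()] result
#' @param assay `"RNA"` or `"RPF"`
#' @param region `"utr5"` or `"utr3"`
#' @param condition,reference contrasted conditions
#' @return list with `n` (paired genes), `median_condition`,
#'   `median_reference`, `p` (one-sided, greater)
#' @export
ued_compare <- function(table, assay, region = c("utr5", "utr3"),
                        condition, reference) {
  region <- match.arg(region)
  col <- if (region == "utr5") "ued5" else "ued3"
  a <- table[table$assay == assay & table$condition == condition, ]
  b <- table[table$assay == assay & table$condition == reference, ]
  m <- merge(a[, c("gene_id", col)], b[, c("gene_id", col)],
             by = "gene_id", suffixes = c("_c", "_r"))
  m <- m[stats::complete.cases(m), ]
  if (nrow(m) < 2L) stop("fewer than 2 genes with defined UED in both ",
                         "conditions")
  wt <- stats::wilcox.test(m[[paste0(col, "_c")]], m[[paste0(col, "_r")]],
                           paired = TRUE, alternative = "greater",
                           exact = FALSE)
  list(n = nrow(m),
       median_condition = stats::median(m[[paste0(col, "_c")]]),
       median_reference = stats::median(m[[paste0(col, "_r")]]),
       p = wt$p.value)
}

#' Cluster genes by cross-condition UED changes
#'
#' Builds, per gene, the feature vector
#' `log2(UED_condition / UED_reference)` over every non-reference
#' condition for the chosen assay and UTR side, then clusters the rows
#' with [cluster_rows()]. Genes with an undefined UED in any condition
#' are excluded and reported.
#'
#' @param table a [ued_table()] result
#' @param assay,region assay and UTR side to cluster on
#' @param reference reference condition for the log-ratios
#' @param k number of clusters (default 9)
#' @return list with `labels` (gene -> cluster), `features` (the change
#'   matrix) and `excluded` (gene ids dropped for undefined UED)
#' @export
ued_compare_and_cluster <- function(table, assay = "RPF",
                                    region = c("utr5", "utr3"),
                                    reference, k = 9L) {
  region <- match.arg(region)
  col <- if (region == "utr5") "ued5" else "ued3"
  sub <- table[table$assay == assay, ]
  conds <- unique(sub$condition)
  if (!reference %in% conds) stop("reference condition absent from table")
  wide <- stats::reshape(sub[, c("gene_id", "condition", col)],
                         idvar = "gene_id", timevar = "condition",
                         direction = "wide")
  colnames(wide) <- sub(paste0("^", col, "\\."), "", colnames(wide))
  complete <- stats::complete.cases(wide)
  excluded <- wide$gene_id[!complete]
  wide <- wide[complete, , drop = FALSE]
  others <- setdiff(conds, reference)
  feats <- as.matrix(log2(wide[, others, drop = FALSE] /
                            wide[, reference]))
  rownames(feats) <- wide$gene_id
  colnames(feats) <- paste0("log2_", others, "_vs_", reference)
  if (k > nrow(feats))
    stop("k (", k, ") exceeds the number of clusterable genes (",
         nrow(feats), ")")
  list(labels = cluster_rows(feats, k), features = feats,
       excluded = excluded)
}
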