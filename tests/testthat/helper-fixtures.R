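# shared fixture builders; everything is generated in code at test time

# one gene on a bare contig; defaults give a 90-bp CDS at 101..190
fix_gene <- function(strand = "+", cds_start = 101L, cds_end = 190L,
                     gene_id = "g1") {
  gene_models(gene_id, "chr", strand, cds_start, cds_end)
}

fix_track <- function(depth, assay = "RPF", condition = "CTRL",
                      replicate = 1L, strand = "+") {
  coverage_track(assay, condition, replicate, strand, depth)
}

# a flat metagene profile data.frame for boundary tests
fix_profile <- function(mean_depth, anchor = "start_codon", W = 200L,
                        condition = "CTRL") {
  stopifnot(length(mean_depth) == 2L * W + 1L)
  structure(data.frame(anchor = anchor, offset = seq.int(-W, W),
                       mean_depth = mean_depth, condition = condition,
                       n_genes = 1L, stringsAsFactors = FALSE),
            class = c("metagene_profile", "data.frame"))
}

# a single-TU track/TU pair with piecewise-constant depth
# (utr5 l5 nt at depth u5, CDS at depth c, utr3 l3 nt at depth u3)
fix_tu <- function(strand = "+", l5 = 10L, cds = 80L, l3 = 10L,
                   u5 = 4, cc = 2, u3 = 1, pad = 20L) {
  l_tu <- l5 + cds + l3
  glen <- l_tu + 2L * pad
  depth <- numeric(glen)
  if (strand == "+") {
    t <- pad + 1L; p <- t + l_tu - 1L
    s <- t + l5; e <- s + cds - 1L
    if (l5 > 0) depth[t:(s - 1L)] <- u5
    depth[s:e] <- cc
    depth[(e + 1L):p] <- u3
  } else {
    p <- pad + 1L; t <- p + l_tu - 1L
    s <- t - l5; e <- s - cds + 1L
    if (l5 > 0) depth[(s + 1L):t] <- u5
    depth[e:s] <- cc
    depth[p:(e - 1L)] <- u3
  }
  tu <- data.frame(gene_id = "g1", strand = strand, tss_pos = t,
                   tep_pos = p, start_codon_pos = s,
                   stop_codon_end_pos = e, l_5utr = l5, l_3utr = l3,
                   l_tu = l_tu, stringsAsFactors = FALSE)
  class(tu) <- c("transcription_units", "data.frame")
  list(tu = tu, depth = depth)
}

# brute-force UED oracle: explicit position-by-position summation,
# independent of the package's region helpers
oracle_ued <- function(depth, tu, region) {
  step <- if (tu$strand == "+") 1L else -1L
  walk <- function(from, to) seq(from, to, by = step)
  tu_pos <- walk(tu$tss_pos, tu$tep_pos)
  denom <- sum(depth[tu_pos]) / length(tu_pos)
  if (denom == 0) return(NA_real_)
  reg <- if (region == "utr5") {
    if (tu$l_5utr == 0L) return(NA_real_)
    walk(tu$tss_pos, tu$start_codon_pos - step)
  } else walk(tu$stop_codon_end_pos + step, tu$tep_pos)
  mean(depth[reg]) / denom
}

# TU table straight from the generator's truth manifest
truth_tus <- function(sim) {
  out <- do.call(rbind, lapply(seq_len(nrow(sim$truth)), function(i) {
    tr <- sim$truth[i, ]
    g <- sim$genes[i, ]
    data.frame(gene_id = tr$gene_id, strand = tr$strand, tss_pos = tr$tss,
               tep_pos = tr$tep, start_codon_pos = g$start_codon_pos,
               stop_codon_end_pos = g$stop_codon_end_pos,
               l_5utr = tr$l_5utr, l_3utr = tr$l_3utr,
               l_tu = tr$l_5utr + tr$cds_len + tr$l_3utr,
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("transcription_units", "data.frame")
  out
}
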