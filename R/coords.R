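#' Coordinate conventions
#'
#' All internal computation uses 1-based inclusive genomic coordinates.
#' bedGraph's 0-based half-open intervals are converted at I/O only.
#'
#' Two relative-coordinate systems are used around codon anchors:
#'
#' * **Signed window coordinates** (no zero), matching the common "-1
#'   position of the start codon" phrasing: relative to the start codon,
#'   +1 is the first base of the start codon and -1 the base immediately
#'   5' of it; relative to the stop codon, -1 is the last base of the stop
#'   codon and +1 the first base 3' of it. Extremity windows and the torso
#'   are expressed in these coordinates.
#' * **Profile offsets** for metagene profiles: integers -W..+W including
#'   0, where offset 0 is the anchor base itself (first base of the start
#'   codon, or last base of the stop codon) and positive offsets run 3'
#'   in transcript sense.
#'
#' @name tuarch-coordinates
#' @keywords internal
NULL

# strand-aware step: +1 base in transcript sense moves +1 genomic on "+",
# -1 genomic on "-"
.strand_sign <- function(strand) ifelse(strand == "+", 1L, -1L)

#' Map signed window coordinates to genomic positions
#'
#' @param gene a single-row gene model (see [gene_models()])
#' @param anchor `"start_codon"` or `"stop_codon"`
#' @param w integer vector of signed window coordinates (no zero)
#' @return integer vector of 1-based genomic positions
#' @export
window_to_genomic <- function(gene, anchor, w) {
  stopifnot(all(w != 0L))
  sgn <- .strand_sign(gene$strand)
  if (anchor == "start_codon") {
    a <- gene$start_codon_pos
    # +1 -> anchor base itself; -1 -> one base 5' of anchor
    as.integer(a + sgn * ifelse(w > 0L, w - 1L, w))
  } else {
    a <- gene$stop_codon_end_pos
    # -1 -> anchor base itself; +1 -> one base 3' of anchor
    as.integer(a + sgn * ifelse(w < 0L, w + 1L, w))
  }
}

#' Map metagene profile offsets to genomic positions
#'
#' Offset 0 is the anchor base; positive offsets run 3' in transcript sense.
#' @inheritParams window_to_genomic
#' @param offsets integer vector (may include 0)
#' @export
offset_to_genomic <- function(gene, anchor, offsets) {
  a <- if (anchor == "start_codon") gene$start_codon_pos else gene$stop_codon_end_pos
  as.integer(a + .strand_sign(gene$strand) * offsets)
}

#' Strand-aware distance between two genomic positions
#'
#' Number of bases from `from` through `to` inclusive when walking in
#' transcript sense on `strand`; 0 when `to` lies immediately 5' of `from`.
#' @param from,to 1-based genomic positions
#' @param strand `"+"` or `"-"`
#' @export
strand_distance <- function(from, to, strand) {
  as.integer(.strand_sign(strand) * (to - from) + 1L)
}

#' Genomic positions of an extremity/torso region of a CDS
#'
#' The start-extremity window `[a1, b1]` covers signed start-relative
#' coordinates a1..-1 (5' of the start codon) and +1..b1 (into the CDS);
#' the stop-extremity window `[a2, b2]` covers a2..-1 (into the CDS) and
#' +1..b2 (3' of the stop codon). The torso is the CDS strictly between
#' the two extremity windows: start-relative b1+1 through stop-relative
#' a2-1.
#'
#' @param gene single-row gene model
#' @param partition an [extremity_partition()]
#' @param region `"torso"`, `"extremity"`, `"start_extremity"` or
#'   `"stop_extremity"`
#' @return integer vector of genomic positions (transcript-sense order)
#' @export
region_positions <- function(gene, partition,
                             region = c("torso", "extremity",
                                        "start_extremity", "stop_extremity")) {
  region <- match.arg(region)
  a1 <- partition$start_window[1]; b1 <- partition$start_window[2]
  a2 <- partition$stop_window[1];  b2 <- partition$stop_window[2]
  no_zero <- function(lo, hi) setdiff(seq.int(lo, hi), 0L)
  switch(region,
    start_extremity = window_to_genomic(gene, "start_codon", no_zero(a1, b1)),
    stop_extremity  = window_to_genomic(gene, "stop_codon",  no_zero(a2, b2)),
    extremity = c(window_to_genomic(gene, "start_codon", no_zero(a1, b1)),
                  window_to_genomic(gene, "stop_codon",  no_zero(a2, b2))),
    torso = {
      cds_len <- abs(gene$stop_codon_end_pos - gene$start_codon_pos) + 1L
      n_torso <- cds_len - b1 - (-a2)
      if (n_torso <= 0L)
        stop("torso is empty for gene ", gene$gene_id,
             " (CDS ", cds_len, " bp with windows [", a1, ",", b1, "]/[",
             a2, ",", b2, "])")
      first <- window_to_genomic(gene, "start_codon", b1 + 1L)
      seq.int(first, by = .strand_sign(gene$strand), length.out = n_torso)
    })
}

#' Extremity/torso partition of coding sequences
#'
#' Holds the two windows, in signed (no-zero) codon-relative coordinates,
#' that separate gene extremities from the torso. Defaults are the
#' windows -30..+60 around the start codon and -33..+15 around the stop
#' codon; both windows must straddle their codon boundary.
#'
#' @param start_window integer length-2, `c(a1, b1)` with `a1 < 0 < b1`
#' @param stop_window integer length-2, `c(a2, b2)` with `a2 < 0 < b2`
#' @return object of class `extremity_partition`
#' @export
extremity_partition <- function(start_window = c(-30L, 60L),
                                stop_window = c(-33L, 15L)) {
  start_window <- as.integer(start_window)
  stop_window <- as.integer(stop_window)
  if (length(start_window) != 2L || !(start_window[1] < 0L && start_window[2] > 0L))
    stop("start_window must straddle the start codon (a1 < 0 < b1)")
  if (length(stop_window) != 2L || !(stop_window[1] < 0L && stop_window[2] > 0L))
    stop("stop_window must straddle the stop codon (a2 < 0 < b2)")
  structure(list(start_window = start_window, stop_window = stop_window),
            class = "extremity_partition")
}

#' @export
print.extremity_partition <- function(x, ...) {
  cat("extremity partition: start [", x$start_window[1], ",",
      x$start_window[2], "]  stop [", x$stop_window[1], ",",
      x$stop_window[2], "]\n")
  invisible(x)
}
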