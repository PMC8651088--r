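#' Genome sequence container
#'
#' A single-contig genome: contig id plus an uppercase A/C/G/T/N string.
#'
#' @param contig_id contig name
#' @param sequence nucleotide string; lower case is folded to upper
#' @return object of class `genome_sequence` with fields `contig_id`,
#'   `sequence` and `length`
#' @export
genome_sequence <- function(contig_id, sequence) {
  sequence <- toupper(as.character(sequence))
  bad <- gsub("[ACGTN]", "", sequence)
  if (nzchar(bad))
    stop("genome sequence contains characters outside {A,C,G,T,N}: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ","))
  structure(list(contig_id = contig_id, sequence = sequence,
                 length = nchar(sequence)),
            class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat("genome_sequence ", x$contig_id, ": ", x$length, " bp\n", sep = "")
  invisible(x)
}

#' Read a single-contig genome FASTA
#'
#' @param path FASTA file; must contain exactly one record
#' @return a [genome_sequence()]
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- tryCatch(Biostrings::readDNAStringSet(path),
                   error = function(e) stop("malformed FASTA ", path, ": ",
                                            conditionMessage(e)))
  if (length(seqs) == 0L) stop("no FASTA records in ", path)
  if (length(seqs) > 1L) stop("multiple contigs unsupported (", length(seqs),
                              " records in ", path, ")")
  genome_sequence(sub("\\s.*$", "", names(seqs)[1]), as.character(seqs[[1]]))
}

#' Write a genome FASTA
#' @param genome a [genome_sequence()]
#' @param path output path
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome$sequence)
  names(x) <- genome$contig_id
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Build a gene-model table
#'
#' One row per protein-coding gene with strand-aware codon anchor
#' positions: `start_codon_pos` is the first transcribed base of the
#' start codon (`cds_start` on "+", `cds_end` on "-"), `stop_codon_end_pos`
#' the last transcribed base of the stop codon.
#'
#' @param gene_id,contig_id,strand,cds_start,cds_end parallel vectors;
#'   coordinates 1-based inclusive, `cds_start <= cds_end`, CDS length a
#'   positive multiple of 3
#' @return data.frame of class `gene_models`
#' @export
gene_models <- function(gene_id, contig_id, strand, cds_start, cds_end) {
  cds_start <- as.integer(cds_start); cds_end <- as.integer(cds_end)
  strand <- rep(as.character(strand), length.out = length(cds_start))
  if (any(!strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(cds_start > cds_end)) stop("cds_start must be <= cds_end")
  len <- cds_end - cds_start + 1L
  if (any(len %% 3L != 0L))
    stop("CDS length not a multiple of 3 for: ",
         paste(gene_id[len %% 3L != 0L], collapse = ","))
  df <- data.frame(
    gene_id = as.character(gene_id), contig_id = as.character(contig_id),
    strand = as.character(strand),
    cds_start = cds_start, cds_end = cds_end,
    start_codon_pos = ifelse(strand == "+", cds_start, cds_end),
    stop_codon_end_pos = ifelse(strand == "+", cds_end, cds_start),
    stringsAsFactors = FALSE)
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Read gene models from a GFF3 annotation
#'
#' One gene model is built per distinct gene identifier among CDS
#' features (attribute `gene_id`, `ID` or `Parent`, first available).
#' CDS features whose length is not a multiple of 3 are skipped with a
#' warning.
#'
#' @param path GFF3 file
#' @return a [gene_models()] data.frame
#' @export
read_annotation_gff <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0L) stop("no CDS features in ", path)
  md <- S4Vectors::mcols(gr)
  ids <- NULL
  for (col in c("gene_id", "ID", "Parent")) {
    if (col %in% colnames(md)) {
      v <- md[[col]]
      if (is(v, "List")) v <- vapply(v, function(z)
        if (length(z)) as.character(z[1]) else NA_character_, character(1))
      ids <- as.character(v)
      if (!all(is.na(ids))) break
    }
  }
  if (is.null(ids) || all(is.na(ids)))
    stop("CDS features in ", path, " carry no gene identifiers")
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*")) stop("CDS feature without strand in ", path)
  st <- BiocGenerics::start(gr); en <- BiocGenerics::end(gr)
  len <- en - st + 1L
  bad <- len %% 3L != 0L
  if (any(bad)) {
    warning("skipping ", sum(bad), " CDS feature(s) with length not a ",
            "multiple of 3: ", paste(ids[bad], collapse = ","))
    st <- st[!bad]; en <- en[!bad]; strand <- strand[!bad]; ids <- ids[!bad]
    gr <- gr[!bad]
  }
  if (length(st) == 0L) stop("no usable CDS features in ", path)
  gene_models(ids, as.character(GenomicRanges::seqnames(gr)), strand, st, en)
}

#' Write gene models as GFF3
#' @param genes a [gene_models()] table
#' @param path output path
#' @export
write_annotation_gff <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig_id,
    ranges = IRanges::IRanges(genes$cds_start, genes$cds_end),
    strand = genes$strand)
  gr$type <- "CDS"
  gr$source <- "tuarch"
  gr$phase <- 0L
  gr$ID <- genes$gene_id
  gr$gene_id <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Per-base coverage track
#'
#' Dense per-position depth over one strand of the contig for one
#' assay/condition/replicate. `TERM` tracks hold transcript 3'-end read
#' counts, not read-body coverage.
#'
#' @param assay `"RNA"`, `"RPF"` or `"TERM"`
#' @param condition condition label
#' @param replicate integer replicate index
#' @param strand `"+"` or `"-"`
#' @param depth numeric vector, one value per genomic position, all >= 0
#' @return object of class `coverage_track`
#' @export
coverage_track <- function(assay, condition, replicate, strand, depth) {
  assay <- match.arg(assay, c("RNA", "RPF", "TERM"))
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  depth <- as.numeric(depth)
  if (any(depth < 0)) stop("coverage depth must be non-negative")
  structure(list(assay = assay, condition = as.character(condition),
                 replicate = as.integer(replicate), strand = strand,
                 depth = depth),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track ", x$assay, " ", x$condition, " rep", x$replicate,
      " (", x$strand, "): ", length(x$depth), " bp, total ",
      format(sum(x$depth)), "\n", sep = "")
  invisible(x)
}

#' Read a bedGraph file into a dense coverage track
#'
#' bedGraph intervals are 0-based half-open and must not overlap;
#' positions absent from the file get depth 0.
#'
#' @param path bedGraph file
#' @param strand strand the track describes
#' @param assay,condition,replicate track metadata
#' @param genome_length contig length in bp
#' @return a [coverage_track()]
#' @export
read_coverage_bedgraph <- function(path, strand, assay, condition, replicate,
                                   genome_length) {
  if (!file.exists(path)) stop("no such file: ", path)
  genome_length <- as.integer(genome_length)
  depth <- numeric(genome_length)
  info <- file.info(path)
  if (!is.na(info$size) && info$size > 0) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (length(gr)) {
      st <- BiocGenerics::start(gr)   # rtracklayer converts to 1-based
      en <- BiocGenerics::end(gr)
      if (any(en > genome_length) || any(st < 1L))
        stop("bedGraph interval beyond genome length ", genome_length,
             " in ", path)
      o <- order(st)
      if (any(st[o][-1] <= en[o][-length(o)]))
        stop("overlapping bedGraph intervals in ", path)
      w <- en - st + 1L
      depth[sequence(w, from = st)] <- rep(gr$score, w)
    }
  }
  coverage_track(assay, condition, replicate, strand, depth)
}

#' Write a coverage track as bedGraph
#' @param track a [coverage_track()]
#' @param contig_id contig name for the bedGraph lines
#' @param path output path
#' @export
write_coverage_bedgraph <- function(track, contig_id, path) {
  d <- track$depth
  r <- rle(d)
  en <- cumsum(r$lengths)
  st <- en - r$lengths + 1L
  keep <- r$values != 0
  if (any(keep)) {
    gr <- GenomicRanges::GRanges(contig_id,
                                 IRanges::IRanges(st[keep], en[keep]),
                                 score = r$values[keep])
    rtracklayer::export(gr, path, format = "bedGraph")
  } else {
    file.create(path)
  }
  invisible(path)
}

#' TSS record table
#'
#' @param gene_id,position,strand parallel vectors; `position` is the
#'   1-based genomic position of the transcription start site on the
#'   gene's strand
#' @return data.frame of class `tss_records`
#' @export
tss_records <- function(gene_id, position, strand) {
  if (any(!strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  df <- data.frame(gene_id = as.character(gene_id),
                   position = as.integer(position),
                   strand = as.character(strand), stringsAsFactors = FALSE)
  class(df) <- c("tss_records", "data.frame")
  df
}

# table types known to write_table()/read_table(); maps class -> column spec
.table_classes <- c("tss_records", "tep_records", "transcription_units",
                    "ued_records", "deg_results", "te_results",
                    "gene_models")

#' Write a typed record table as TSV
#'
#' Tab-separated, header row, UTF-8, deterministic column order; optional
#' `# key: value` metadata header lines. Round-trips through
#' [read_table()].
#'
#' @param records a data.frame carrying one of the package's table
#'   classes (gene models, TSS/TEP records, transcription units, UED,
#'   DEG or TE tables)
#' @param path output path
#' @param metadata named character vector written as `# key: value` lines
#' @export
write_table <- function(records, path, metadata = NULL) {
  cls <- intersect(class(records), .table_classes)
  if (length(cls) != 1L)
    stop("records must carry exactly one known table class; got: ",
         paste(class(records), collapse = ","))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# class: ", cls), con)
  if (!is.null(metadata))
    writeLines(paste0("# ", names(metadata), ": ", metadata), con)
  utils::write.table(as.data.frame(records), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a table written by [write_table()]
#' @param path TSV path
#' @return data.frame with its table class restored
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  cls <- sub("^# class: ", "", first)
  if (identical(cls, first))
    stop("not a tuarch table (missing '# class:' header): ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, quote = "")
  if (cls %in% .table_classes) class(df) <- c(cls, "data.frame")
  df
}
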