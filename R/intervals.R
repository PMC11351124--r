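#' Genome annotation container
#'
#' Bundles contig sequences with gene intervals. Intervals are held as a
#' `GRanges` (1-based, closed — the Bioconductor convention); BED input
#' (0-based half-open) and GFF3 input (1-based closed) are converted at the
#' boundary by the readers, so round-trips through either format restore the
#' original coordinates.
#'
#' @param sequences named character vector or `DNAStringSet` of contig
#'   sequences.
#' @param genes `GRanges` of gene intervals (strand `+`/`-`).
#' @return a `genome_annotation` object.
#' @export
genome_annotation <- function(sequences, genes) {
  if (!methods::is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  if (is.null(names(sequences)) || anyNA(names(sequences)))
    stop("contig sequences must be named")
  stopifnot(methods::is(genes, "GRanges"))
  sl <- stats::setNames(Biostrings::width(sequences), names(sequences))
  unknown <- setdiff(as.character(GenomeInfoDb::seqnames(genes)), names(sl))
  if (length(unknown))
    stop("gene interval on unknown contig: ", paste(unknown, collapse = ", "))
  GenomeInfoDb::seqlevels(genes) <- names(sl)
  GenomeInfoDb::seqlengths(genes) <- sl
  if (any(GenomicRanges::start(genes) < 1L) ||
      any(GenomicRanges::end(genes) > sl[as.character(GenomeInfoDb::seqnames(genes))]))
    stop("gene interval outside its contig")
  structure(list(sequences = sequences, genes = genes),
            class = "genome_annotation")
}

#' Read gene intervals from BED or GFF3
#'
#' BED is interpreted as 0-based half-open and GFF3 as 1-based closed, both
#' converted to the internal `GRanges` (1-based closed) convention. For GFF3
#' only `gene` features are kept.
#'
#' @param path interval file.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @return `GRanges` of gene intervals.
#' @export
read_gene_intervals <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read interval file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed"
    else if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3"
    else stop("cannot infer interval format from extension: ", path)
  }
  gr <- tryCatch(
    if (format == "bed") rtracklayer::import(path, format = "bed")
    else rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (format == "gff3" && "type" %in% names(S4Vectors::mcols(gr)))
    gr <- gr[as.character(gr$type) == "gene"]
  if (any(BiocGenerics::width(gr) < 1L))
    stop("parse error in ", path, ": interval with start > end")
  gr
}

#' Write gene intervals
#'
#' Exports the internal `GRanges` back to BED (0-based half-open) or GFF3
#' (1-based closed). Conversions are involutive with the readers.
#'
#' @param genes `GRanges`.
#' @param path output file.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_gene_intervals <- function(genes, path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed"
    else if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3"
    else stop("cannot infer interval format from extension: ", path)
  }
  if (format == "gff3") {
    if (is.null(genes$type)) genes$type <- "gene"
    if (!is.null(genes$score) && anyNA(genes$score)) genes$score <- NULL
    if (!is.null(genes$phase) && anyNA(genes$phase)) genes$phase <- NULL
  }
  rtracklayer::export(genes, path, format = format)
  invisible(path)
}
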