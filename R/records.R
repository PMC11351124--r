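#' sORF record sets
#'
#' A `sorf_records` object is a data frame with one row per candidate sORF
#' and columns `id`, `flank` (upstream flanking sequence, 5'->3', so the last
#' character sits at position -1 relative to the start codon), `orf` (start
#' codon through stop codon), `label` (`"coding"`, `"noncoding"` or `NA`) and
#' `annotation_class` (one of the supported genomic-context classes or `NA`).
#'
#' @param id character vector of record identifiers.
#' @param flank,orf character vectors of nucleotide sequences.
#' @param label optional labels, `"coding"` / `"noncoding"`.
#' @param annotation_class optional annotation classes (see
#'   [annotation_classes()]).
#' @param validate validate and drop invalid records (default `TRUE`); the
#'   dropped records are attached as the `"rejections"` attribute.
#' @param ... validation options passed to [validate_sorf_records()].
#' @return a `sorf_records` data frame.
#' @export
sorf_records <- function(id, flank, orf, label = NA_character_,
                         annotation_class = NA_character_,
                         validate = TRUE, ...) {
  df <- data.frame(id = as.character(id),
                   flank = toupper(as.character(flank)),
                   orf = toupper(as.character(orf)),
                   label = rep_len(as.character(label), length(id)),
                   annotation_class = rep_len(as.character(annotation_class),
                                              length(id)),
                   stringsAsFactors = FALSE)
  class(df) <- c("sorf_records", "data.frame")
  if (validate) df <- validate_sorf_records(df, ...)
  df
}

#' Supported annotation classes
#' @return character vector of the genomic-context classes a record may carry.
#' @export
annotation_classes <- function() .ANNOTATION_CLASSES

#' Validate sORF records
#'
#' Applies the record invariants: sequences restricted to A/C/G/T, ORF length
#' a multiple of 3 and at least 6 nt, a start codon from `start_codons` at the
#' 5' end and (if `require_stop`) a stop codon at the 3' end. Invalid records
#' are removed, never silently fixed; each removed record appears exactly once
#' in the `"rejections"` attribute with a machine-readable reason.
#'
#' @param records a `sorf_records` data frame (or compatible).
#' @param start_codons allowed start codons; default `"ATG"` only.
#' @param require_stop require a terminal stop codon (`TRUE` for training
#'   data; prediction-only input may relax this, in which case a missing stop
#'   is only a warning).
#' @param max_aa optional protein-length filter: records with more than
#'   `max_aa` amino acids (ORF length / 3 - 1) are rejected. Use `100` for
#'   sORF-mode input; `NULL` (default) disables the filter, as training
#'   positives are full-length proteins.
#' @return validated `sorf_records` with a `"rejections"` attribute
#'   (data frame of `id`, `reason`).
#' @export
validate_sorf_records <- function(records, start_codons = "ATG",
                                  require_stop = TRUE, max_aa = NULL) {
  stopifnot(all(c("id", "flank", "orf") %in% names(records)))
  n_soft <- sum(grepl("[acgtn]", records$flank)) +
    sum(grepl("[acgtn]", records$orf))
  if (n_soft > 0)
    warning(sprintf("%d record(s) contained soft-masked (lowercase) bases; treated as uppercase", n_soft))
  records$flank <- toupper(records$flank)
  records$orf <- toupper(records$orf)

  reason <- rep(NA_character_, nrow(records))
  bad_alpha <- grepl("[^ACGT]", records$orf) | grepl("[^ACGT]", records$flank)
  reason[bad_alpha] <- "ambiguous base"
  len <- nchar(records$orf)
  sel <- is.na(reason) & len < 6L
  reason[sel] <- "orf too short"
  sel <- is.na(reason) & len %% 3L != 0L
  reason[sel] <- "orf length not a multiple of 3"
  sel <- is.na(reason) & !(substr(records$orf, 1L, 3L) %in% start_codons)
  reason[sel] <- "invalid start codon"
  has_stop <- substr(records$orf, len - 2L, len) %in% .STOP_CODONS
  if (require_stop) {
    sel <- is.na(reason) & !has_stop
    reason[sel] <- "missing stop codon"
  } else if (any(!has_stop[is.na(reason)])) {
    warning(sprintf("%d record(s) lack a terminal stop codon", sum(!has_stop[is.na(reason)])))
  }
  if (!is.null(max_aa)) {
    sel <- is.na(reason) & (len / 3L - 1L) > max_aa
    reason[sel] <- sprintf("exceeds %d amino acids", max_aa)
  }

  keep <- is.na(reason)
  rejections <- data.frame(id = records$id[!keep], reason = reason[!keep],
                           stringsAsFactors = FALSE)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sorf_records", "data.frame")
  attr(out, "rejections") <- rejections
  attr(out, "n_softmasked") <- n_soft
  out
}

#' Read candidate sORFs from FASTA
#'
#' Each FASTA entry is the upstream flank immediately followed by the ORF;
#' `flank_length` gives the split point. Entries shorter than
#' `flank_length + 6` nt and records violating the sequence invariants are
#' rejected with a reason (see [validate_sorf_records()]); valid records are
#' returned.
#'
#' @param path FASTA file.
#' @param flank_length upstream flank length in nt (default 100).
#' @inheritParams validate_sorf_records
#' @return `sorf_records` with a `"rejections"` attribute.
#' @export
read_sorf_fasta <- function(path, flank_length = 100L, start_codons = "ATG",
                            require_stop = TRUE, max_aa = NULL) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  seqs <- Biostrings::readBStringSet(path) # BStringSet keeps case for the
  ids <- sub("\\s.*$", "", names(seqs))    # soft-mask counter
  seqchar <- as.character(seqs)
  too_short <- nchar(seqchar) < flank_length + 6L
  pre_rej <- data.frame(id = ids[too_short],
                        reason = rep("entry shorter than flank + minimal ORF",
                                     sum(too_short)),
                        stringsAsFactors = FALSE)
  ids <- ids[!too_short]
  seqchar <- seqchar[!too_short]
  recs <- data.frame(id = ids,
                     flank = substr(seqchar, 1L, flank_length),
                     orf = substr(seqchar, flank_length + 1L, nchar(seqchar)),
                     label = rep(NA_character_, length(ids)),
                     annotation_class = rep(NA_character_, length(ids)),
                     stringsAsFactors = FALSE)
  class(recs) <- c("sorf_records", "data.frame")
  out <- validate_sorf_records(recs, start_codons = start_codons,
                               require_stop = require_stop, max_aa = max_aa)
  attr(out, "rejections") <- rbind(pre_rej, attr(out, "rejections"))
  out
}

#' Write sORF records to FASTA
#'
#' Writes `flank` and `orf` concatenated, one entry per record, so that
#' [read_sorf_fasta()] with the same flank length round-trips the sequences
#' byte-identically.
#'
#' @param records `sorf_records`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sorf_fasta <- function(records, path) {
  seqs <- Biostrings::BStringSet(paste0(records$flank, records$orf))
  names(seqs) <- records$id
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}
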