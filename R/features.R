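#' Feature extraction configuration
#'
#' Controls how the coding-potential (CP) representation is assembled.
#'
#' @param cc_window coding-composition window length in nt: 54, 99, 180, or
#'   `"auto"` to pick the longest window that fits each record (the
#'   predictor's default behaviour).
#' @param skip_signal_peptide skip the first 90 nt after the start codon
#'   before the CC window, avoiding the compositionally atypical
#'   signal-peptide region. On for training-set extraction by convention,
#'   off at prediction time.
#' @param frequency_normalized divide 3-mer counts by the number of 3-mers
#'   in the window (`TRUE`, default) or keep raw counts.
#' @param feature_set which block(s) to emit: `"cp"` (TIS + CC, 100 values),
#'   `"cc"` (64), or `"tis"` (36).
#' @return a `feature_config` list.
#' @export
feature_config <- function(cc_window = "auto", skip_signal_peptide = FALSE,
                           frequency_normalized = TRUE,
                           feature_set = c("cp", "cc", "tis")) {
  feature_set <- match.arg(feature_set)
  if (!(identical(cc_window, "auto") || cc_window %in% c(54, 99, 180)))
    stop("cc_window must be 54, 99, 180 or \"auto\"")
  structure(list(cc_window = cc_window,
                 skip_signal_peptide = isTRUE(skip_signal_peptide),
                 frequency_normalized = isTRUE(frequency_normalized),
                 feature_set = feature_set,
                 tis_upstream = 7L, tis_downstream = 2L),
            class = "feature_config")
}

.CC_WINDOWS <- c(180L, 99L, 54L)

#' Extract the 9-nt TIS window
#'
#' The translation-initiation-site context covers positions -7..+5 with the
#' start codon occupying +1..+3 and excluded, i.e. the last 7 flank
#' nucleotides followed by the 2 nucleotides immediately after the start
#' codon (+4, +5).
#'
#' @param flank,orf character vectors (vectorised; recycled to equal length).
#' @return character vector of 9-nt windows.
#' @export
extract_tis_window <- function(flank, orf) {
  if (any(nchar(flank) < 7L))
    stop("insufficient upstream context: flank shorter than 7 nt")
  if (any(nchar(orf) < 5L))
    stop("orf shorter than 5 nt; cannot extract +4..+5")
  nf <- nchar(flank)
  paste0(substr(flank, nf - 6L, nf), substr(orf, 4L, 5L))
}

# per-base one-hot rows in bit order (G,T,C,A): G=1000, T=0100, C=0010, A=0001
.TIS_CODE <- matrix(c(0, 0, 0, 1,   # A
                      0, 0, 1, 0,   # C
                      1, 0, 0, 0,   # G
                      0, 1, 0, 0),  # T
                    nrow = 4, byrow = TRUE,
                    dimnames = list(.BASES, c("G", "T", "C", "A")))

.tis_colnames <- function() {
  pos <- c(-7:-1, 4L, 5L)
  lab <- ifelse(pos < 0, as.character(pos), paste0("+", pos))
  as.vector(vapply(lab, function(p) paste0("tis_p", p, "_", c("G", "T", "C", "A")),
                   character(4)))
}

#' One-hot encode TIS windows
#'
#' Each of the 9 positions is encoded with the maximal-Hamming-distance code
#' A=0001, C=0010, T=0100, G=1000, giving 36 binary values per window.
#'
#' @param windows character vector of 9-nt windows over A/C/G/T.
#' @return numeric matrix (n x 36) with stable column names.
#' @export
encode_tis <- function(windows) {
  if (any(nchar(windows) != 9L)) stop("TIS window must be exactly 9 nt")
  chars <- matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
                  ncol = 9L, byrow = TRUE)
  if (any(!chars %in% .BASES)) stop("TIS window contains a non-ACGT character")
  out <- matrix(0, nrow = length(windows), ncol = 36L,
                dimnames = list(NULL, .tis_colnames()))
  for (p in 1:9) {
    block <- .TIS_CODE[chars[, p], , drop = FALSE]
    out[, (4L * (p - 1L) + 1L):(4L * p)] <- block
  }
  out
}

#' Select the CC window size and offset for a record
#'
#' The available coding span excludes the start codon, the stop codon and —
#' when the signal-peptide skip is on — the first 90 nt after the start
#' codon. With `cc_window = "auto"` the longest of 180, 99, 54 nt that fits
#' is chosen (the predictor default); a fixed window must fit or the record
#' fails. Records whose available span is below 54 nt (<19 codons) cannot be
#' profiled and are reported as such.
#'
#' @param orf_length integer vector of ORF lengths in nt.
#' @param config a [feature_config()].
#' @return data frame with columns `window` and `offset` (0-based from the
#'   ORF start; `NA` where no window fits) and a `reason` column for
#'   failures.
#' @export
select_cc_window <- function(orf_length, config = feature_config()) {
  skip <- if (config$skip_signal_peptide) 90L else 0L
  available <- orf_length - 6L - skip
  offset <- rep(3L + skip, length(orf_length))
  window <- rep(NA_integer_, length(orf_length))
  reason <- rep(NA_character_, length(orf_length))
  if (identical(config$cc_window, "auto")) {
    for (w in .CC_WINDOWS) window[is.na(window) & available >= w] <- w
  } else {
    w <- as.integer(config$cc_window)
    window[available >= w] <- w
  }
  reason[is.na(window) & available < 54L] <-
    "sORF too short for smallest CC window"
  reason[is.na(window) & available >= 54L] <-
    sprintf("sORF too short for the fixed %s-nt CC window", config$cc_window)
  offset[is.na(window)] <- NA_integer_
  data.frame(window = window, offset = offset, reason = reason,
             stringsAsFactors = FALSE)
}

#' Extract an in-frame CC window from an ORF
#'
#' @param orf character vector of ORF sequences.
#' @param window window size in nt (multiple of 3).
#' @param offset 0-based in-frame offset from the ORF start (multiple of 3);
#'   the window never overlaps the stop codon.
#' @return character vector of window sequences.
#' @export
extract_cc_window <- function(orf, window, offset) {
  if (any(offset %% 3L != 0L) || any(window %% 3L != 0L))
    stop("internal frame error: CC window offset/size not in frame")
  if (any(offset + window > nchar(orf) - 3L))
    stop("internal frame error: CC window overlaps the stop codon")
  substr(orf, offset + 1L, offset + window)
}

#' In-frame 3-mer frequency profile
#'
#' Counts the 64 possible 3-mers at step 3 (codon positions) over each
#' window; in normalized mode the counts are divided by the number of 3-mers
#' so the 64 values sum to one. Column order is the fixed lexicographic
#' codon order AAA, AAC, ..., TTT.
#'
#' @param windows character vector of in-frame windows (length a positive
#'   multiple of 3).
#' @param normalized divide by the number of 3-mers (default `TRUE`).
#' @return numeric matrix (n x 64) with columns `cc_AAA` ... `cc_TTT`.
#' @export
codon_frequencies <- function(windows, normalized = TRUE) {
  n <- nchar(windows)
  if (any(n == 0L)) stop("empty CC window")
  if (any(n %% 3L != 0L)) stop("CC window length not a multiple of 3")
  codons <- .codon_order()
  out <- matrix(0, nrow = length(windows), ncol = 64L,
                dimnames = list(NULL, paste0("cc_", codons)))
  for (len in unique(n)) {
    rows <- which(n == len)
    starts <- seq.int(1L, len - 2L, by = 3L)
    # one row per record, one column per codon position
    cod <- vapply(starts, function(s) substr(windows[rows], s, s + 2L),
                  character(length(rows)))
    cod <- matrix(cod, nrow = length(rows))
    idx <- matrix(match(cod, codons), nrow = length(rows))
    if (anyNA(idx)) stop("CC window contains a non-ACGT character")
    for (r in seq_along(rows))
      out[rows[r], ] <- tabulate(idx[r, ], nbins = 64L)
    if (normalized) out[rows, ] <- out[rows, , drop = FALSE] / length(starts)
  }
  out
}

#' Assemble coding-potential feature vectors
#'
#' Runs TIS extraction/encoding and CC window selection/profiling for a set
#' of records and concatenates the blocks per `config$feature_set`: the full
#' CP vector is the 36 TIS bits followed by the 64 CC frequencies (100
#' values). Records failing any feature precondition (flank < 7 nt, ORF too
#' short for the smallest window, ...) are excluded and reported.
#'
#' @param records `sorf_records`.
#' @param config a [feature_config()].
#' @return list with `features` (numeric matrix, rownames = record ids),
#'   `meta` (data frame `id`, `window_used`, `skip_used`) and `exclusions`
#'   (data frame `id`, `reason`).
#' @export
assemble_features <- function(records, config = feature_config()) {
  stopifnot(nrow(records) >= 0)
  reason <- rep(NA_character_, nrow(records))
  need_cc <- config$feature_set %in% c("cp", "cc")
  need_tis <- config$feature_set %in% c("cp", "tis")

  if (need_tis) {
    reason[nchar(records$flank) < 7L] <- "insufficient upstream context"
    reason[is.na(reason) & nchar(records$orf) < 5L] <- "orf too short for TIS"
  }
  sel <- select_cc_window(nchar(records$orf), config)
  if (need_cc) reason[is.na(reason) & is.na(sel$window)] <-
      sel$reason[is.na(reason) & is.na(sel$window)]

  keep <- which(is.na(reason))
  exclusions <- data.frame(id = records$id[is.na(reason) == FALSE],
                           reason = reason[!is.na(reason)],
                           stringsAsFactors = FALSE)
  blocks <- list()
  if (need_tis && length(keep))
    blocks$tis <- encode_tis(extract_tis_window(records$flank[keep],
                                                records$orf[keep]))
  if (need_cc && length(keep)) {
    win <- extract_cc_window(records$orf[keep], sel$window[keep],
                             sel$offset[keep])
    blocks$cc <- codon_frequencies(win, normalized = config$frequency_normalized)
  }
  features <- if (length(keep)) do.call(cbind, blocks)
  else matrix(0, 0, 36L * need_tis + 64L * need_cc)
  rownames(features) <- records$id[keep]
  meta <- data.frame(id = records$id[keep],
                     window_used = if (need_cc) sel$window[keep] else NA_integer_,
                     skip_used = config$skip_signal_peptide,
                     stringsAsFactors = FALSE)
  list(features = features, meta = meta, exclusions = exclusions)
}

#' Export a feature matrix as TSV
#'
#' One row per record: `id`, `window_used`, then the feature columns with
#' their stable headers (`tis_p-7_G` ... `cc_TTT`).
#'
#' @param fx result of [assemble_features()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(fx, path) {
  df <- data.frame(id = fx$meta$id, window_used = fx$meta$window_used,
                   fx$features, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
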