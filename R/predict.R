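#' Classify candidate sORFs
#'
#' The end-user predictor: for each record the longest fitting CC window is
#' selected (54, 99 or 180 nt; or a fixed window via `config`), features are
#' assembled with predictor defaults (signal-peptide skip off unless enabled
#' in `config`), the record is routed to the matching per-window model, and
#' the calibrated score is thresholded. Scores strictly above the threshold
#' are called coding; a score exactly at the threshold is non-coding.
#'
#' @param records `sorf_records`.
#' @param models named list of `sorfcp_model`s keyed by window size
#'   (`"54"`, `"99"`, `"180"`); every window the selection can produce on
#'   this input must be present.
#' @param config a [feature_config()]; default auto window, no skip.
#' @param threshold calling threshold in `[0, 1]` (default 0.5; 0.9 is the
#'   high-precision mode).
#' @return data frame with columns `id`, `window_used`, `score`, `call`,
#'   `threshold_used`; records failing feature extraction are absent from
#'   the rows and listed in the `"exclusions"` attribute.
#' @export
predict_sorfs <- function(records, models, config = feature_config(),
                          threshold = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1)
  sel <- select_cc_window(nchar(records$orf), config)
  needed <- sort(unique(sel$window[!is.na(sel$window)]))
  missing <- setdiff(as.character(needed), names(models))
  if (length(missing)) {
    n_aff <- sum(sel$window %in% as.integer(missing))
    stop(sprintf("no model for window(s) %s (%d record(s) affected)",
                 paste(missing, collapse = ", "), n_aff))
  }
  rows <- vector("list", length(needed))
  exclusions <- data.frame(id = records$id[!is.na(sel$reason)],
                           reason = sel$reason[!is.na(sel$reason)],
                           stringsAsFactors = FALSE)
  for (wi in seq_along(needed)) {
    w <- needed[wi]
    model <- models[[as.character(w)]]
    sub <- records[!is.na(sel$window) & sel$window == w, , drop = FALSE]
    cfg <- feature_config(cc_window = w,
                          skip_signal_peptide = config$skip_signal_peptide,
                          frequency_normalized = model$config$frequency_normalized,
                          feature_set = model$config$feature_set)
    fx <- assemble_features(sub, cfg)
    if (nrow(fx$exclusions)) exclusions <- rbind(exclusions, fx$exclusions)
    if (nrow(fx$features) == 0L) next
    s <- score_sorfs(model, fx$features, window_used = fx$meta$window_used)
    rows[[wi]] <- data.frame(id = fx$meta$id, window_used = w, score = s,
                             call = s > threshold,
                             threshold_used = threshold,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(id = character(), window_used = integer(),
                      score = numeric(), call = logical(),
                      threshold_used = numeric(), stringsAsFactors = FALSE)
  out <- out[match(records$id[records$id %in% out$id], out$id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- exclusions
  out
}
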