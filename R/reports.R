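#' Per-annotation-class positivity report
#'
#' For every annotation class and metric, counts the records called positive
#' at the metric's cutoff and the percentage of the class's non-missing
#' records, emulating the per-class comparison of a classifier against
#' external metrics (FLOSS, ORFscore, PhyloP, PhastCon). Rows with a missing
#' metric value are excluded from that metric's denominator; a metric with
#' no values in a class reports `NA` counts. Classes absent from the table
#' are omitted and listed in the `"omitted_classes"` attribute.
#'
#' @param table a `sorf_table`.
#' @param classifier_calls optional named logical vector (names = record
#'   ids) of this package's own calls, reported as metric `"sorfcp"`.
#' @param cutoffs named cutoff overrides passed to [metric_calls()];
#'   an unknown metric name is an error.
#' @return data frame `annotation_class`, `metric`, `n_positive`, `n_total`,
#'   `percentage`.
#' @export
class_positivity_report <- function(table, classifier_calls = NULL,
                                    cutoffs = NULL) {
  calls <- metric_calls(table, cutoffs)
  if (!is.null(classifier_calls)) {
    own <- unname(classifier_calls[table$id])
    calls <- cbind(calls, sorfcp = own)
  }
  classes <- intersect(.ANNOTATION_CLASSES, unique(table$annotation_class))
  rows <- list()
  for (cl in classes) {
    in_cl <- table$annotation_class == cl
    for (m in colnames(calls)) {
      v <- calls[in_cl, m]
      n_total <- sum(!is.na(v))
      n_pos <- sum(v, na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        annotation_class = cl, metric = m,
        n_positive = if (n_total == 0L) NA_integer_ else n_pos,
        n_total = n_total,
        percentage = if (n_total == 0L) NA_real_ else 100 * n_pos / n_total,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "omitted_classes") <- setdiff(.ANNOTATION_CLASSES, classes)
  out
}

#' Intersection-region counts of positive call sets
#'
#' Venn-style decomposition: rows lacking a value for any metric in the
#' subset are excluded first; among the remaining rows positive in at least
#' one metric, each of the `2^k - 1` exclusive intersection regions is
#' counted. The region counts sum to the number of rows positive anywhere.
#'
#' @param calls logical matrix (rows = records, columns = metrics; `NA` =
#'   missing value).
#' @param metrics character vector of 2-5 column names to intersect.
#' @return data frame `region` (metric names joined by `&`), `count`, plus
#'   attribute `"n_complete"` (rows with all metrics present).
#' @export
overlap_counts <- function(calls, metrics = colnames(calls)) {
  if (length(metrics) < 2L || length(metrics) > 5L)
    stop("metric subset must contain 2 to 5 metrics")
  if (!all(metrics %in% colnames(calls)))
    stop("unknown metric(s): ",
         paste(setdiff(metrics, colnames(calls)), collapse = ", "))
  m <- calls[, metrics, drop = FALSE]
  complete <- stats::complete.cases(m)
  m <- m[complete, , drop = FALSE]
  any_pos <- rowSums(m) > 0
  m <- m[any_pos, , drop = FALSE]
  k <- length(metrics)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1L, , drop = FALSE]
  names(combos) <- metrics
  region <- apply(combos, 1L, function(r) paste(metrics[as.logical(r)],
                                                collapse = "&"))
  count <- apply(combos, 1L, function(r)
    sum(apply(m, 1L, function(row) all(row == as.logical(r)))))
  out <- data.frame(region = region, count = as.integer(count),
                    stringsAsFactors = FALSE)
  attr(out, "n_complete") <- sum(complete)
  out
}

#' Benchmark metrics against labelled annotation classes
#'
#' Uses one annotation class as truth-positive (default `ensembl_sORF`,
#' i.e. annotated micropeptides) and another as truth-negative (default
#' `intronic`, the most non-coding-like class), ignores all other rows, and
#' reports the confusion metrics of every metric's calls.
#'
#' @param table a `sorf_table`.
#' @param calls logical call matrix as produced by [metric_calls()] (may
#'   include a classifier column).
#' @param pos_class,neg_class annotation classes used as truth.
#' @return data frame, one row per metric, with the [confusion_metrics()]
#'   columns.
#' @export
benchmark_confusion <- function(table, calls, pos_class = "ensembl_sORF",
                                neg_class = "intronic") {
  for (cl in c(pos_class, neg_class))
    if (!cl %in% table$annotation_class)
      stop("annotation class absent from table: ", cl)
  sel <- table$annotation_class %in% c(pos_class, neg_class)
  truth <- table$annotation_class[sel] == pos_class
  rows <- lapply(colnames(calls), function(m) {
    v <- calls[sel, m]
    ok <- !is.na(v)
    cbind(data.frame(metric = m, stringsAsFactors = FALSE),
          confusion_metrics(v[ok], truth[ok]))
  })
  do.call(rbind, rows)
}
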