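#' External-metric registry
#'
#' The benchmark table may carry pre-computed per-sORF metrics from Ribo-Seq
#' analysis (FLOSS, ORFscore) and nucleotide conservation (PhyloP, PhastCon).
#' The registry records, per metric, the direction in which values indicate
#' coding potential and a default calling cutoff. The defaults follow the
#' tools' reference usage (FLOSS: values below the extreme-outlier bound look
#' ribosome-like; ORFscore, PhyloP, PhastCon: larger is more coding-like) and
#' are plain configuration — override them per analysis via the `cutoffs`
#' arguments of the report functions.
#'
#' @return data frame with columns `metric`, `direction`
#'   (`"higher"`/`"lower"`), `cutoff`.
#' @export
metric_registry <- function() {
  data.frame(metric = c("FLOSS", "ORFscore", "PhyloP", "PhastCon"),
             direction = c("lower", "higher", "higher", "higher"),
             cutoff = c(0.26, 6.044, 1.0, 0.5),
             stringsAsFactors = FALSE)
}

#' Read a tab-delimited sORF benchmark table
#'
#' Expects a header with required columns `id`, `sequence`, `upstream`,
#' `annotation_class` and any subset of the registry metric columns. Metric
#' cells that fail to parse as numbers become `NA` (missing, never zero);
#' an unknown annotation class is a schema error.
#'
#' @param path TSV file.
#' @return a `sorf_table` data frame; the `"metrics"` attribute lists the
#'   metric columns present.
#' @export
read_sorf_table <- function(path) {
  if (!file.exists(path)) stop("cannot read sORF table: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  required <- c("id", "sequence", "upstream", "annotation_class")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("sORF table schema error: missing required column(s) ",
         paste(missing, collapse = ", "))
  bad <- setdiff(unique(df$annotation_class), .ANNOTATION_CLASSES)
  if (length(bad))
    stop("sORF table schema error: unknown annotation_class value(s) ",
         paste(sprintf('"%s"', bad), collapse = ", "))
  metrics <- intersect(metric_registry()$metric, names(df))
  for (m in metrics)
    df[[m]] <- suppressWarnings(as.numeric(df[[m]]))
  class(df) <- c("sorf_table", "data.frame")
  attr(df, "metrics") <- metrics
  df
}

#' Derive boolean metric calls from cutoffs
#'
#' @param table a `sorf_table`.
#' @param cutoffs named numeric vector of cutoffs; defaults to the registry
#'   values for the metrics present in the table. Metrics with direction
#'   `"higher"` call a row positive when `score > cutoff`, direction
#'   `"lower"` when `score < cutoff`; missing scores give `NA` calls.
#' @return logical matrix, one column per metric, rownames = record ids.
#' @export
metric_calls <- function(table, cutoffs = NULL) {
  reg <- metric_registry()
  present <- attr(table, "metrics")
  if (is.null(present)) present <- intersect(reg$metric, names(table))
  if (is.null(cutoffs))
    cutoffs <- stats::setNames(reg$cutoff, reg$metric)[present]
  unknown <- setdiff(names(cutoffs), reg$metric)
  if (length(unknown))
    stop("unknown metric in cutoffs: ", paste(unknown, collapse = ", "))
  use <- intersect(names(cutoffs), present)
  calls <- sapply(use, function(m) {
    dir <- reg$direction[reg$metric == m]
    if (dir == "higher") table[[m]] > cutoffs[[m]] else table[[m]] < cutoffs[[m]]
  })
  calls <- matrix(calls, nrow = nrow(table),
                  dimnames = list(table$id, use))
  calls
}
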