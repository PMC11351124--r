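#' Confusion-matrix metrics
#'
#' Exact integer confusion counts plus the four ratio metrics used
#' throughout: precision TP/(TP+FP), sensitivity TP/(TP+FN), specificity
#' TN/(TN+FP) and accuracy (TP+TN)/total. Undefined ratios (zero
#' denominator) are reported as `NA`, never 0.
#'
#' @param calls logical vector of positive calls.
#' @param truth `"coding"`/`"noncoding"` labels (or logical, `TRUE` =
#'   coding).
#' @return one-row data frame `TP`, `FP`, `TN`, `FN`, `precision`,
#'   `sensitivity`, `specificity`, `accuracy`.
#' @export
confusion_metrics <- function(calls, truth) {
  if (length(calls) != length(truth))
    stop("calls and truth labels differ in length")
  pos <- if (is.logical(truth)) truth else as.character(truth) == "coding"
  TP <- sum(calls & pos); FP <- sum(calls & !pos)
  FN <- sum(!calls & pos); TN <- sum(!calls & !pos)
  ratio <- function(num, den) if (den == 0L) NA_real_ else num / den
  data.frame(TP = TP, FP = FP, TN = TN, FN = FN,
             precision = ratio(TP, TP + FP),
             sensitivity = ratio(TP, TP + FN),
             specificity = ratio(TN, TN + FP),
             accuracy = ratio(TP + TN, TP + FP + TN + FN))
}

#' ROC curve points and AUC
#'
#' Sweeps a calling threshold over every distinct score, yielding one
#' (FPR, TPR) point per threshold; the curve starts at (0, 0) and ends at
#' (1, 1) and the AUC is the trapezoid-rule area.
#'
#' @param scores numeric scores, larger = more coding-like.
#' @param truth labels as in [confusion_metrics()]; both classes required.
#' @return list with `points` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_points <- function(scores, truth) {
  pos <- if (is.logical(truth)) truth else as.character(truth) == "coding"
  if (!any(pos) || all(pos)) stop("ROC requires both classes")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; p <- pos[o]
  last <- !duplicated(s, fromLast = TRUE)
  tpr <- cumsum(p)[last] / sum(pos)
  fpr <- cumsum(!p)[last] / sum(!pos)
  pts <- data.frame(threshold = c(Inf, s[last]),
                    fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + pts$tpr[-1]) / 2)
  list(points = pts, auc = auc)
}

.SUITE_KEYS <- c("tis", "cc54", "cc99", "cc180", "cp54", "cp99", "cp180")

.suite_config <- function(key, skip, normalized = TRUE) {
  if (key == "tis")
    return(feature_config(cc_window = "auto", skip_signal_peptide = skip,
                          frequency_normalized = normalized,
                          feature_set = "tis"))
  set <- substr(key, 1, 2)
  w <- as.numeric(sub("^(cc|cp)", "", key))
  feature_config(cc_window = w, skip_signal_peptide = skip,
                 frequency_normalized = normalized,
                 feature_set = if (set == "cc") "cc" else "cp")
}

.content_keys <- function(records) paste(records$flank, records$orf)

#' Train the seven-feature-set model suite
#'
#' Trains one calibrated model per feature configuration — TIS alone,
#' CC alone at 54/99/180 nt, and the combined CP = CC+TIS at 54/99/180 nt —
#' from the same source records (records too short for a window are simply
#' not used for that window's model). Each model is grid-searched by
#' cross-validation on the training split and Platt-calibrated on the
#' validation split.
#'
#' @param train_records,val_records labelled `sorf_records` (disjoint).
#' @param grid a [hyper_grid()] (default: RBF-SVM with a compact grid).
#' @param keys which suite members to train (default all seven).
#' @param k_folds cross-validation folds.
#' @param seed RNG seed.
#' @param skip_signal_peptide apply the 90-nt skip during extraction
#'   (applied symmetrically to both classes; default off — appropriate for
#'   sORF-scale data where the skip would consume most of the ORF).
#' @return named list of `sorfcp_model`s (class `sorfcp_suite`) with the
#'   training content keys attached for disjointness checks.
#' @export
train_feature_suite <- function(train_records, val_records,
                                grid = hyper_grid("svm",
                                  svm = list(kernel = "rbf", C = c(1, 10),
                                             gamma = c("0.02", "0.1"))),
                                keys = .SUITE_KEYS, k_folds = 10L, seed = 1L,
                                skip_signal_peptide = FALSE) {
  stopifnot(all(keys %in% .SUITE_KEYS))
  if (any(.content_keys(train_records) %in% .content_keys(val_records)))
    stop("training and validation sets overlap")
  suite <- list()
  for (key in keys) {
    cfg <- .suite_config(key, skip_signal_peptide)
    ftr <- assemble_features(train_records, cfg)
    fva <- assemble_features(val_records, cfg)
    ytr <- train_records$label[match(ftr$meta$id, train_records$id)]
    yva <- val_records$label[match(fva$meta$id, val_records$id)]
    gs <- grid_search(ftr$features, ytr, grid, k_folds = k_folds, seed = seed)
    fit <- train_final(ftr$features, ytr, gs$best, seed = seed, config = cfg,
                       window = if (key == "tis") NA_integer_
                       else as.integer(sub("^(cc|cp)", "", key)),
                       cv_score = gs$table$mean_accuracy[gs$best_index])
    suite[[key]] <- calibrate_platt(fit, fva$features, yva)
  }
  attr(suite, "train_keys") <- .content_keys(train_records)
  attr(suite, "val_keys") <- .content_keys(val_records)
  class(suite) <- "sorfcp_suite"
  suite
}

#' Balanced / unbalanced evaluation harness
#'
#' Scores a positive and a negative evaluation set with every model of a
#' trained suite at every threshold and tabulates the confusion metrics,
#' mirroring the seven-feature-set comparison (TIS, CC54/99/180,
#' CP54/99/180) on balanced (1:1) and unbalanced (negatives
#' over-represented) data. Evaluation records must be disjoint from the
#' suite's training and validation content, which is enforced.
#'
#' @param suite a `sorfcp_suite` from [train_feature_suite()].
#' @param pos_records,neg_records labelled evaluation `sorf_records`.
#' @param mode `"balanced"` or `"unbalanced"` (recorded in the output).
#' @param thresholds non-empty numeric vector of calling thresholds.
#' @return data frame with one row per (model, threshold): feature set,
#'   window, threshold, confusion counts and ratio metrics, plus the number
#'   of records each model could not score (`n_excluded`).
#' @export
evaluate_harness <- function(suite, pos_records, neg_records,
                             mode = c("balanced", "unbalanced"),
                             thresholds = c(0.5)) {
  mode <- match.arg(mode)
  if (length(thresholds) == 0L) stop("empty threshold list")
  eval_records <- rbind(pos_records, neg_records)
  class(eval_records) <- c("sorf_records", "data.frame")
  ek <- .content_keys(eval_records)
  if (any(ek %in% attr(suite, "train_keys")))
    stop("evaluation set overlaps the training set")
  out <- list()
  for (key in names(suite)) {
    model <- suite[[key]]
    cfg <- model$config
    fx <- assemble_features(eval_records, cfg)
    y <- eval_records$label[match(fx$meta$id, eval_records$id)]
    s <- score_sorfs(model, fx$features, window_used = fx$meta$window_used)
    for (t in thresholds) {
      cm <- confusion_metrics(s > t, y)
      out[[length(out) + 1L]] <- cbind(
        data.frame(feature_set = key, window = model$window, mode = mode,
                   threshold = t, n_excluded = nrow(fx$exclusions),
                   stringsAsFactors = FALSE),
        cm)
    }
  }
  do.call(rbind, out)
}
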