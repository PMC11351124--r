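#' Hyper-parameter grid
#'
#' Exhaustive grids for the three supported algorithms. The tuned dimensions
#' are: SVM — kernel, penalty `C`, RBF coefficient `gamma` (`"scale"` is the
#' `1 / (n_features * var(X))` heuristic); k-NN — neighbour count, vote
#' weighting, neighbour-search algorithm; random forest — tree count, split
#' criterion, features per split. Values are package defaults and fully
#' user-overridable.
#'
#' @param algorithm `"svm"`, `"knn"` or `"rf"`.
#' @param svm,knn,rf named lists of candidate values for the respective
#'   algorithm's dimensions.
#' @return a `hyper_grid` data frame, one row per combination, in
#'   lexicographic order of the supplied value lists (the deterministic
#'   tie-break order of [grid_search()]).
#' @export
hyper_grid <- function(algorithm = c("svm", "knn", "rf"),
                       svm = list(kernel = c("linear", "rbf"),
                                  C = c(0.1, 1, 10, 100),
                                  gamma = c("scale", "0.01", "0.1", "1")),
                       knn = list(k = c(3L, 5L, 11L, 21L),
                                  weights = c("uniform", "distance"),
                                  nn_algorithm = c("kd_tree", "brute")),
                       rf = list(n_trees = c(100L, 300L, 500L),
                                 criterion = c("gini", "entropy"),
                                 max_features = c("sqrt", "log2"))) {
  algorithm <- match.arg(algorithm)
  vals <- switch(algorithm, svm = svm, knn = knn, rf = rf)
  if (any(lengths(vals) == 0L)) stop("empty hyper-parameter set")
  g <- rev(expand.grid(rev(vals), stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE))
  g <- g[, names(vals), drop = FALSE]
  g$algorithm <- algorithm
  class(g) <- c("hyper_grid", "data.frame")
  g
}

# stratified fold ids 1..k, deterministic under seed
.cv_folds <- function(y01, k_folds, seed) {
  fold <- integer(length(y01))
  .with_seed(seed, {
    for (cl in unique(y01)) {
      idx <- which(y01 == cl)
      fold[idx] <- sample(rep_len(seq_len(k_folds), length(idx)))
    }
  })
  fold
}

.as_y01 <- function(labels) {
  y <- as.integer(as.character(labels) == "coding")
  if (anyNA(y)) stop("labels must be \"coding\"/\"noncoding\"")
  y
}

#' Exhaustive grid search with k-fold cross-validation
#'
#' Evaluates every grid row by stratified k-fold cross-validated accuracy at
#' the 0.5 decision point and returns the full score table plus the winning
#' combination. Ties are broken deterministically: highest mean accuracy,
#' then lowest accuracy standard deviation, then lexicographic grid order.
#'
#' @param X numeric feature matrix.
#' @param labels `"coding"`/`"noncoding"` labels.
#' @param grid a [hyper_grid()].
#' @param k_folds number of folds (default 10).
#' @param seed RNG seed for fold assignment (and any stochastic learner).
#' @param standardize z-scale features column-wise inside each fold fit
#'   (default `TRUE`); the TIS and CC blocks live on different scales and
#'   distance-based learners need this.
#' @return list with `best` (one-row parameter data frame), `table` (grid
#'   with `mean_accuracy`, `sd_accuracy`) and `best_index`.
#' @export
grid_search <- function(X, labels, grid, k_folds = 10L, seed = 1L,
                        standardize = TRUE) {
  y01 <- .as_y01(labels)
  if (length(unique(y01)) < 2L) stop("degenerate labels: single class")
  if (min(table(y01)) < k_folds)
    stop("need at least k_folds examples per class")
  fold <- .cv_folds(y01, k_folds, seed)
  thr <- function(fit) if (fit$algorithm == "svm") 0 else 0.5
  scores <- matrix(NA_real_, nrow(grid), k_folds)
  for (gi in seq_len(nrow(grid))) {
    params <- as.list(grid[gi, , drop = FALSE])
    for (f in seq_len(k_folds)) {
      tr <- fold != f
      fit <- .fit_classifier(X[tr, , drop = FALSE], y01[tr], params,
                             seed = seed + f, standardize = standardize)
      d <- .decision_values(fit, X[!tr, , drop = FALSE])
      scores[gi, f] <- mean((d > thr(fit)) == (y01[!tr] == 1L))
    }
  }
  tab <- grid
  tab$mean_accuracy <- rowMeans(scores)
  tab$sd_accuracy <- apply(scores, 1L, stats::sd)
  best_index <- order(-tab$mean_accuracy, tab$sd_accuracy,
                      seq_len(nrow(tab)))[1L]
  list(best = grid[best_index, , drop = FALSE], table = tab,
       best_index = best_index)
}

# keys for train/validation disjointness checks: record ids when the matrix
# carries them as rownames (feature rows of distinct records can collide for
# low-cardinality blocks like the 36-bit TIS), raw row content otherwise
.row_keys <- function(X) {
  if (!is.null(rownames(X))) return(rownames(X))
  apply(round(X, 10), 1L, paste, collapse = ",")
}

#' Train the final (uncalibrated) classifier
#'
#' Refits the chosen hyper-parameter combination on the full training set.
#' The fit records a training fingerprint (data hash, seed, optional CV
#' score) used downstream to enforce training/validation/evaluation
#' disjointness.
#'
#' @param X numeric feature matrix (no NaN; features are closed-form, so NaN
#'   signals an upstream bug and is an error).
#' @param labels `"coding"`/`"noncoding"`.
#' @param params one-row parameter data frame (e.g. `grid_search()$best`).
#' @param seed RNG seed (relevant for the random forest).
#' @param config the [feature_config()] that produced `X`.
#' @param window CC window size backing `X` (`NA` for TIS-only models).
#' @param cv_score optional cross-validation score to record.
#' @param standardize z-scale features column-wise (default `TRUE`); the
#'   scaler is fitted on the training data and stored in the model.
#' @return an uncalibrated `sorfcp_fit` with fingerprint attributes.
#' @export
train_final <- function(X, labels, params, seed = 1L, config = NULL,
                        window = NA_integer_, cv_score = NA_real_,
                        standardize = TRUE) {
  y01 <- .as_y01(labels)
  fit <- .fit_classifier(X, y01, as.list(params), seed = seed,
                         standardize = standardize)
  fit$fingerprint <- list(train = .fingerprint(.row_keys(X)), seed = seed,
                          cv_score = cv_score, n_train = nrow(X))
  fit$train_keys <- .row_keys(X)
  fit$config <- config
  fit$window <- window
  fit
}

#' Platt-calibrate a fitted classifier
#'
#' Fits the sigmoid `P(coding | d) = 1 / (1 + exp(A d + B))` to the
#' classifier's decision values on a held-out validation set (which must be
#' disjoint from the training rows — enforced through the stored
#' fingerprint keys). Calibration is monotone, so it never changes the
#' ranking the classifier induces.
#'
#' @param fit result of [train_final()].
#' @param Xval validation feature matrix.
#' @param labels validation labels.
#' @return a calibrated `sorfcp_model`.
#' @export
calibrate_platt <- function(fit, Xval, labels) {
  stopifnot(inherits(fit, "sorfcp_fit"))
  y01 <- .as_y01(labels)
  vk <- .row_keys(Xval)
  if (identical(.fingerprint(vk), fit$fingerprint$train) ||
      any(vk %in% fit$train_keys))
    stop("validation set overlaps the training fingerprint")
  d <- .decision_values(fit, Xval)
  platt <- platt_fit(d, y01)
  model <- list(algorithm = fit$algorithm,
                params = fit[intersect(c("kernel", "gamma", "C", "k",
                                         "weights", "nn_algorithm", "mtry",
                                         "criterion", "n_trees"),
                                       names(fit))],
                window = fit$window, config = fit$config,
                fit = fit, platt = platt,
                fingerprint = fit$fingerprint)
  class(model) <- "sorfcp_model"
  model
}

#' Calibrated coding-potential score
#'
#' Maps feature vectors through the model's decision function and Platt
#' sigmoid to a probability-like score in `[0, 1]`; higher means more
#' coding-like. Feature vectors must have been extracted with the model's
#' CC window (window routing is the caller's job; a mismatch is an error,
#' not a silent rescoring).
#'
#' @param model a `sorfcp_model`.
#' @param X feature matrix.
#' @param window_used optional vector of per-record CC windows used during
#'   extraction, checked against the model's window.
#' @return numeric scores in `[0, 1]`.
#' @export
score_sorfs <- function(model, X, window_used = NULL) {
  stopifnot(inherits(model, "sorfcp_model"))
  if (!is.null(window_used) && !is.na(model$window) &&
      any(window_used != model$window, na.rm = TRUE))
    stop(sprintf("routing error: window-%s features scored against window-%s model",
                 paste(unique(window_used), collapse = "/"), model$window))
  d <- .decision_values(model$fit, X)
  .platt_apply(model$platt, d)
}

## ---- persistence ---------------------------------------------------------

.MODEL_FORMAT <- "sorfcp-model/1"

# exact text round-trip for doubles ("%.17g" preserves all bits)
.num_out <- function(x) sprintf("%.17g", as.numeric(x))
.num_in <- function(x) as.numeric(x)

#' Save / load a calibrated model
#'
#' Plain-text JSON archive embedding a format version, the feature
#' configuration, Platt parameters and training fingerprint. Numeric
#' parameters are stored as full-precision decimal strings so that a loaded
#' model reproduces scores bit-identically. A version mismatch on load is an
#' explicit error, never a silent reinterpretation.
#'
#' @param model a `sorfcp_model`.
#' @param path file path.
#' @return `save_model`: `path`, invisibly; `load_model`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "sorfcp_model"))
  fit <- model$fit
  est <- switch(fit$algorithm,
    svm = list(kernel = fit$kernel,
               gamma = .num_out(fit$gamma), C = .num_out(fit$C),
               b = .num_out(fit$b), coef = .num_out(fit$coef),
               sv = .num_out(fit$sv), sv_dim = dim(fit$sv)),
    knn = list(k = fit$k, weights = fit$weights,
               nn_algorithm = fit$nn_algorithm, y = fit$y,
               X = .num_out(fit$X), X_dim = dim(fit$X)),
    rf = list(n_trees = fit$n_trees, mtry = fit$mtry,
              criterion = fit$criterion,
              trees = lapply(fit$trees, function(tr)
                list(feature = tr$feature, threshold = .num_out(tr$threshold),
                     left = tr$left, right = tr$right,
                     value = .num_out(tr$value)))))
  obj <- list(format = .MODEL_FORMAT,
              algorithm = fit$algorithm,
              window = model$window,
              config = model$config[c("cc_window", "skip_signal_peptide",
                                      "frequency_normalized", "feature_set")],
              feature_names = fit$feature_names,
              scaler = if (is.null(fit$scaler)) NULL else
                list(center = .num_out(fit$scaler$center),
                     scale = .num_out(fit$scaler$scale)),
              platt = list(A = .num_out(model$platt$A),
                           B = .num_out(model$platt$B)),
              fingerprint = model$fingerprint,
              estimator = est)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = FALSE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE,
                                      simplifyDataFrame = FALSE,
                                      simplifyMatrix = FALSE),
                  error = function(e) stop("corrupted model file: ", path,
                                           " (", conditionMessage(e), ")",
                                           call. = FALSE))
  if (is.null(obj$format) || !identical(obj$format, .MODEL_FORMAT))
    stop(sprintf("model format mismatch: file has %s, this build reads %s",
                 if (is.null(obj$format)) "<none>" else obj$format,
                 .MODEL_FORMAT))
  est <- obj$estimator
  fit <- switch(obj$algorithm,
    svm = list(algorithm = "svm", kernel = est$kernel,
               gamma = .num_in(est$gamma), C = .num_in(est$C),
               b = .num_in(est$b), coef = .num_in(est$coef),
               sv = matrix(.num_in(est$sv), nrow = est$sv_dim[1])),
    knn = list(algorithm = "knn", k = as.integer(est$k),
               weights = est$weights, nn_algorithm = est$nn_algorithm,
               y = as.integer(est$y),
               X = matrix(.num_in(est$X), nrow = est$X_dim[1])),
    rf = list(algorithm = "rf", n_trees = as.integer(est$n_trees),
              mtry = as.integer(est$mtry), criterion = est$criterion,
              trees = lapply(est$trees, function(tr)
                list(feature = as.integer(tr$feature),
                     threshold = .num_in(tr$threshold),
                     left = as.integer(tr$left),
                     right = as.integer(tr$right),
                     value = .num_in(tr$value)))),
    stop("unknown algorithm in model file: ", obj$algorithm))
  fit$feature_names <- obj$feature_names
  if (!is.null(obj$scaler))
    fit$scaler <- list(center = .num_in(obj$scaler$center),
                       scale = .num_in(obj$scaler$scale))
  class(fit) <- "sorfcp_fit"
  cfg <- obj$config
  config <- feature_config(cc_window = if (identical(cfg$cc_window, "auto"))
                             "auto" else as.numeric(cfg$cc_window),
                           skip_signal_peptide = cfg$skip_signal_peptide,
                           frequency_normalized = cfg$frequency_normalized,
                           feature_set = cfg$feature_set)
  if (fit$algorithm == "svm") {
    colnames(fit$sv) <- obj$feature_names
  } else if (fit$algorithm == "knn") {
    colnames(fit$X) <- obj$feature_names
  }
  model <- list(algorithm = obj$algorithm, params = NULL,
                window = if (is.null(obj$window) || is.na(obj$window))
                  NA_integer_ else as.integer(obj$window),
                config = config, fit = fit,
                platt = list(A = .num_in(obj$platt$A),
                             B = .num_in(obj$platt$B)),
                fingerprint = obj$fingerprint)
  class(model) <- "sorfcp_model"
  model
}
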