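# Classifier backends behind the model module: kernel SVM (compiled SMO),
# k-NN (FNN neighbour search), random forest (compiled CART bagging).
# All work on a numeric feature matrix and 0/1 labels (1 = coding) and expose
# a real-valued decision function oriented so that larger means more
# coding-like; probability calibration sits on top (platt_fit).

.resolve_gamma <- function(gamma, X) {
  if (identical(gamma, "scale")) {
    v <- stats::var(as.vector(X))
    if (v <= 0) v <- 1
    1 / (ncol(X) * v)
  } else as.numeric(gamma)
}

# Gram matrix between the rows of A and B via BLAS
.kernel_matrix <- function(A, B, kernel, gamma) {
  G <- tcrossprod(A, B)
  if (kernel == "linear") return(G)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * G
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

# column-wise z-scaling fitted on training data; constant columns pass
# through untouched. The TIS block (binary) and CC block (small frequencies)
# live on very different scales, and distance-based learners (RBF SVM, k-NN)
# would otherwise see only the TIS block; trees are unaffected either way.
.fit_scaler <- function(X) {
  center <- colMeans(X)
  s <- apply(X, 2L, stats::sd)
  s[s == 0 | !is.finite(s)] <- 1
  list(center = center, scale = s)
}

.apply_scaler <- function(scaler, X) {
  if (is.null(scaler)) return(X)
  X <- sweep(X, 2L, scaler$center, "-")
  sweep(X, 2L, scaler$scale, "/")
}

.fit_classifier <- function(X, y01, params, seed = 1L, standardize = TRUE) {
  stopifnot(is.matrix(X), length(y01) == nrow(X))
  if (anyNA(X)) stop("feature matrix contains NaN/NA; upstream feature bug")
  if (length(unique(y01)) < 2L) stop("degenerate labels: single class")
  algorithm <- params$algorithm
  scaler <- if (standardize) .fit_scaler(X) else NULL
  raw_names <- colnames(X)
  X <- .apply_scaler(scaler, X)
  fit <- switch(algorithm,
    svm = {
      gamma <- .resolve_gamma(params$gamma, X)
      y <- ifelse(y01 == 1L, 1, -1)
      K <- .kernel_matrix(X, X, params$kernel, gamma)
      res <- .svm_smo_solve(K, y, as.numeric(params$C))
      sv <- which(res$alpha > 1e-12)
      list(algorithm = "svm", kernel = params$kernel,
           gamma = gamma, C = as.numeric(params$C),
           sv = X[sv, , drop = FALSE], coef = res$alpha[sv] * y[sv],
           b = res$b, iterations = res$iterations)
    },
    knn = {
      list(algorithm = "knn", X = X, y = y01, k = as.integer(params$k),
           weights = params$weights, nn_algorithm = params$nn_algorithm)
    },
    rf = {
      d <- ncol(X)
      mtry <- switch(params$max_features,
                     sqrt = max(1L, floor(sqrt(d))),
                     log2 = max(1L, floor(log2(d))),
                     as.integer(params$max_features))
      crit <- match(params$criterion, c("gini", "entropy")) - 1L
      trees <- .rf_train(X, as.integer(y01), as.integer(params$n_trees),
                         mtry, crit, 5L, as.integer(seed))
      list(algorithm = "rf", trees = trees, mtry = mtry,
           criterion = params$criterion, n_trees = as.integer(params$n_trees))
    },
    stop("unknown algorithm: ", algorithm))
  fit$feature_names <- raw_names
  fit$scaler <- scaler
  class(fit) <- "sorfcp_fit"
  fit
}

.decision_values <- function(fit, X) {
  stopifnot(inherits(fit, "sorfcp_fit"))
  if (!is.null(fit$feature_names) && !is.null(colnames(X)) &&
      !identical(colnames(X), fit$feature_names))
    stop("feature columns do not match the fitted model")
  X <- .apply_scaler(fit$scaler, X)
  switch(fit$algorithm,
    svm = as.numeric(.kernel_matrix(X, fit$sv, fit$kernel, fit$gamma) %*%
                       fit$coef + fit$b),
    knn = {
      nn <- FNN::get.knnx(fit$X, X, k = fit$k,
                          algorithm = fit$nn_algorithm)
      votes <- matrix(fit$y[nn$nn.index], ncol = fit$k)
      if (fit$weights == "uniform") rowMeans(votes)
      else {
        w <- 1 / (nn$nn.dist + 1e-12)
        rowSums(votes * w) / rowSums(w)
      }
    },
    rf = as.numeric(.rf_predict(fit$trees, X)))
}

#' Platt sigmoid calibration fit
#'
#' Fits `P(coding | d) = 1 / (1 + exp(A d + B))` to decision values by
#' regularised maximum likelihood with the robust Newton iteration of
#' Platt's procedure (prior-corrected targets, backtracking line search).
#' For a classifier whose decision values rank positives above negatives the
#' fitted `A` is negative, making the calibrated score monotone
#' non-decreasing in the decision value.
#'
#' @param decision numeric decision values.
#' @param y01 0/1 labels (1 = coding).
#' @return list with elements `A` and `B`.
#' @export
platt_fit <- function(decision, y01) {
  if (length(unique(decision)) < 2L)
    stop("degenerate calibration input: constant decision values")
  if (length(unique(y01)) < 2L)
    stop("degenerate calibration input: single class")
  n <- length(decision)
  prior1 <- sum(y01 == 1L); prior0 <- n - prior1
  hi <- (prior1 + 1) / (prior1 + 2); lo <- 1 / (prior0 + 2)
  t <- ifelse(y01 == 1L, hi, lo)
  A <- 0; B <- log((prior0 + 1) / (prior1 + 1))
  fval <- function(A, B) {
    f <- A * decision + B
    sum(ifelse(f >= 0, t * f + log1p(exp(-f)), (t - 1) * f + log1p(exp(f))))
  }
  fcur <- fval(A, B)
  for (it in 1:100) {
    f <- A * decision + B
    p <- ifelse(f >= 0, exp(-f) / (1 + exp(-f)), 1 / (1 + exp(f)))
    q <- 1 - p
    d1 <- t - p
    d2 <- p * q
    g1 <- sum(decision * d1); g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    h11 <- sum(decision * decision * d2) + 1e-12
    h22 <- sum(d2) + 1e-12
    h21 <- sum(decision * d2)
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    repeat {
      newA <- A + step * dA; newB <- B + step * dB
      fnew <- fval(newA, newB)
      if (fnew < fcur + 1e-4 * step * gd) {
        A <- newA; B <- newB; fcur <- fnew
        break
      }
      step <- step / 2
      if (step < 1e-10) return(list(A = A, B = B))
    }
  }
  list(A = A, B = B)
}

.platt_apply <- function(platt, decision) {
  f <- platt$A * decision + platt$B
  ifelse(f >= 0, exp(-f) / (1 + exp(-f)), 1 / (1 + exp(f)))
}
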