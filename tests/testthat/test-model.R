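# well-separated two-class Gaussian features for classifier mechanics
gauss_data <- function(n_per_class, d = 10, sep = 3, seed = 1) {
  withr::with_seed(seed, {
    X <- rbind(matrix(stats::rnorm(n_per_class * d), ncol = d),
               matrix(stats::rnorm(n_per_class * d, mean = sep), ncol = d))
    colnames(X) <- paste0("f", seq_len(d))
    rownames(X) <- sprintf("s%d_%04d", seed, seq_len(2 * n_per_class))
    list(X = X, y = rep(c("noncoding", "coding"), each = n_per_class))
  })
}

test_that("hyper_grid enumerates combinations in lexicographic order", {
  g <- hyper_grid("svm", svm = list(kernel = c("linear", "rbf"),
                                    C = c(1, 10), gamma = "scale"))
  expect_equal(nrow(g), 4)
  expect_equal(g$kernel, c("linear", "linear", "rbf", "rbf"))
  expect_equal(g$C, c(1, 10, 1, 10))
  expect_error(hyper_grid("knn", knn = list(k = integer(0),
                                            weights = "uniform",
                                            nn_algorithm = "brute")),
               "empty")
})

test_that("grid search evaluates every point and breaks ties deterministically", {
  dat <- gauss_data(30, seed = 2)
  g1 <- hyper_grid("svm", svm = list(kernel = "rbf", C = 1, gamma = "scale"))
  gs1 <- grid_search(dat$X, dat$y, g1, k_folds = 5, seed = 1)
  expect_equal(nrow(gs1$table), 1)
  expect_equal(gs1$best$C, 1)

  # duplicated grid point: identical scores, first one wins
  g2 <- rbind(g1, g1)
  class(g2) <- c("hyper_grid", "data.frame")
  gs2 <- grid_search(dat$X, dat$y, g2, k_folds = 5, seed = 1)
  expect_equal(gs2$table$mean_accuracy[1], gs2$table$mean_accuracy[2])
  expect_equal(gs2$best_index, 1L)

  # separable data: near-perfect cross-validated accuracy
  expect_gte(gs1$table$mean_accuracy[1], 0.95)

  expect_error(grid_search(dat$X, rep("coding", nrow(dat$X)), g1,
                           k_folds = 5), "single class")
})

test_that("all three algorithms learn a separable problem", {
  dat <- gauss_data(40, seed = 3)
  probe <- gauss_data(40, seed = 4)
  for (params in list(
    list(algorithm = "svm", kernel = "rbf", C = 1, gamma = "scale"),
    list(algorithm = "knn", k = 5L, weights = "distance",
         nn_algorithm = "kd_tree"),
    list(algorithm = "rf", n_trees = 100L, criterion = "gini",
         max_features = "sqrt"))) {
    fit <- train_final(dat$X, dat$y, params, seed = 1)
    thr <- if (params$algorithm == "svm") 0 else 0.5
    d_tr <- sorfcp:::.decision_values(fit, dat$X)
    expect_equal(mean((d_tr > thr) == (dat$y == "coding")), 1,
                 info = params$algorithm) # 100% training accuracy
    d_pr <- sorfcp:::.decision_values(fit, probe$X)
    expect_gte(mean((d_pr > thr) == (probe$y == "coding")), 0.95)
    # retraining with the same inputs/seed reproduces predictions exactly
    fit2 <- train_final(dat$X, dat$y, params, seed = 1)
    expect_identical(d_pr, sorfcp:::.decision_values(fit2, probe$X))
  }
})

test_that("label-shuffled data scores at chance on held-out examples", {
  withr::with_seed(10, {
    X <- matrix(stats::rnorm(2000 * 10), ncol = 10)
    colnames(X) <- paste0("f", 1:10)
    rownames(X) <- sprintf("x%04d", 1:2000)
    y <- sample(rep(c("coding", "noncoding"), each = 1000))
  })
  fit <- train_final(X[1:1600, ], y[1:1600],
                     list(algorithm = "svm", kernel = "rbf", C = 1,
                          gamma = "scale"), seed = 1)
  d <- sorfcp:::.decision_values(fit, X[1601:2000, ])
  acc <- mean((d > 0) == (y[1601:2000] == "coding"))
  expect_gte(acc, 0.45)
  expect_lte(acc, 0.55)
})

test_that("NaN features are an error, not a silent fit", {
  dat <- gauss_data(20, seed = 5)
  dat$X[3, 2] <- NaN
  expect_error(train_final(dat$X, dat$y,
                           list(algorithm = "svm", kernel = "linear",
                                C = 1, gamma = "scale")),
               "NaN")
})

test_that("Platt calibration maps decisions to oriented probabilities", {
  # perfectly separated validation scores
  d <- c(-3, -2, -1.5, 1.2, 2, 3)
  y <- c(0, 0, 0, 1, 1, 1)
  pl <- platt_fit(d, y)
  expect_lt(pl$A, 0)
  p <- sorfcp:::.platt_apply(pl, d)
  expect_true(all(p[y == 0] < 0.5))
  expect_true(all(p[y == 1] > 0.5))
  expect_error(platt_fit(rep(1, 6), y), "degenerate calibration")
  expect_error(platt_fit(d, rep(1, 6)), "degenerate calibration")

  # monotone, rank-preserving calibration for random decision values
  withr::with_seed(6, {
    for (i in 1:20) {
      dec <- stats::rnorm(60)
      lab <- as.integer(dec + stats::rnorm(60, sd = 0.7) > 0)
      if (length(unique(lab)) < 2) next
      pl <- platt_fit(dec, lab)
      sc <- sorfcp:::.platt_apply(pl, sort(dec))
      expect_true(all(diff(sc) >= 0))
      expect_equal(stats::cor(rank(dec), rank(sorfcp:::.platt_apply(pl, dec))),
                   1)
    }
  })
})

test_that("calibration requires a validation set disjoint from training", {
  dat <- gauss_data(30, seed = 7)
  fit <- train_final(dat$X, dat$y,
                     list(algorithm = "svm", kernel = "rbf", C = 1,
                          gamma = "scale"), seed = 1)
  expect_error(calibrate_platt(fit, dat$X, dat$y), "overlaps")
  val <- gauss_data(20, seed = 8)
  m <- calibrate_platt(fit, val$X, val$y)
  expect_s3_class(m, "sorfcp_model")
  s <- score_sorfs(m, val$X)
  expect_true(all(s >= 0 & s <= 1))
  expect_identical(s, score_sorfs(m, val$X)) # pure function
})

test_that("window routing is enforced at scoring time", {
  dat <- gauss_data(30, seed = 9)
  val <- gauss_data(15, seed = 10)
  fit <- train_final(dat$X, dat$y,
                     list(algorithm = "svm", kernel = "rbf", C = 1,
                          gamma = "scale"), seed = 1, window = 180L)
  m <- calibrate_platt(fit, val$X, val$y)
  expect_error(score_sorfs(m, val$X, window_used = rep(99L, nrow(val$X))),
               "routing error")
  expect_silent(score_sorfs(m, val$X, window_used = rep(180L, nrow(val$X))))
})

test_that("model files round-trip scores bit-identically for all algorithms", {
  dat <- gauss_data(25, seed = 11)
  val <- gauss_data(15, seed = 12)
  probe <- gauss_data(20, seed = 13)$X
  for (params in list(
    list(algorithm = "svm", kernel = "rbf", C = 10, gamma = "0.05"),
    list(algorithm = "knn", k = 5L, weights = "distance",
         nn_algorithm = "brute"),
    list(algorithm = "rf", n_trees = 50L, criterion = "entropy",
         max_features = "log2"))) {
    fit <- train_final(dat$X, dat$y, params, seed = 2,
                       config = feature_config(cc_window = 99),
                       window = 99L)
    m <- calibrate_platt(fit, val$X, val$y)
    f <- tempfile(fileext = ".json")
    save_model(m, f)
    m2 <- load_model(f)
    expect_identical(score_sorfs(m, probe), score_sorfs(m2, probe),
                     info = params$algorithm)
    expect_equal(m2$window, 99L)
    expect_equal(m2$config$cc_window, 99)
  }
})

test_that("model files fail loudly on corruption or version mismatch", {
  dat <- gauss_data(20, seed = 14)
  val <- gauss_data(10, seed = 15)
  fit <- train_final(dat$X, dat$y,
                     list(algorithm = "svm", kernel = "linear", C = 1,
                          gamma = "scale"), seed = 1)
  m <- calibrate_platt(fit, val$X, val$y)
  f <- tempfile(fileext = ".json")
  save_model(m, f)

  legacy <- jsonlite::read_json(f)
  legacy$format <- "sorfcp-model/0"
  f2 <- tempfile(fileext = ".json")
  jsonlite::write_json(legacy, f2, auto_unbox = TRUE)
  expect_error(load_model(f2), "sorfcp-model/0")

  f3 <- tempfile(fileext = ".json")
  writeLines("{ not json", f3)
  expect_error(load_model(f3), "corrupted")
})

test_that("on strong-signal synthetic data SVM(RBF) >= RF >= k-NN in accuracy", {
  cfg <- synthetic_config(n_pos = 600, n_neg = 600,
                          length_range_aa = c(62, 100), signal_strength = 1)
  recs <- generate_labeled_set(cfg, seed = 1)
  sp <- split_dataset(recs, seed = 1)
  fc <- feature_config(cc_window = 180)
  ftr <- assemble_features(sp$train, fc)
  fva <- assemble_features(sp$validation, fc)
  fte <- assemble_features(sp$test, fc)
  lab <- function(s, f) s$label[match(f$meta$id, s$id)]
  grids <- list(
    svm = hyper_grid("svm", svm = list(kernel = "rbf", C = c(1, 10),
                                       gamma = c("scale", "0.005"))),
    knn = hyper_grid("knn", knn = list(k = c(5L, 11L, 21L),
                                       weights = c("uniform", "distance"),
                                       nn_algorithm = "kd_tree")),
    rf = hyper_grid("rf", rf = list(n_trees = 200L,
                                    criterion = c("gini", "entropy"),
                                    max_features = c("sqrt", "log2"))))
  acc <- vapply(names(grids), function(alg) {
    gs <- grid_search(ftr$features, lab(sp$train, ftr), grids[[alg]],
                      k_folds = 5, seed = 1)
    fit <- train_final(ftr$features, lab(sp$train, ftr), gs$best, seed = 1,
                       config = fc, window = 180L)
    m <- calibrate_platt(fit, fva$features, lab(sp$validation, fva))
    s <- score_sorfs(m, fte$features, fte$meta$window_used)
    mean((s > 0.5) == (lab(sp$test, fte) == "coding"))
  }, numeric(1))
  expect_gte(acc[["svm"]], acc[["rf"]])
  expect_gte(acc[["rf"]], acc[["knn"]])
  expect_gte(acc[["svm"]], 0.9)
})
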