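models_cache <- new.env(parent = emptyenv())
get_models <- function() {
  if (is.null(models_cache$m)) models_cache$m <- tiny_model_suite()
  models_cache$m
}

test_that("the predictor routes records to the longest fitting window", {
  models <- get_models()
  recs <- rbind(
    toy_record("long", orf = paste0("ATG", strrep("GCA", 98), "TAA")),   # 300 nt
    toy_record("mid", orf = paste0("ATG", strrep("GCA", 38), "TAA")),    # 120 nt
    toy_record("small", orf = paste0("ATG", strrep("GCA", 19), "TAA")),  # 63 nt
    toy_record("tiny", orf = paste0("ATG", strrep("GCA", 10), "TAA")))   # 36 nt
  class(recs) <- c("sorf_records", "data.frame")
  pred <- predict_sorfs(recs, models)
  expect_equal(pred$window_used[pred$id == "long"], 180L)
  expect_equal(pred$window_used[pred$id == "mid"], 99L)
  expect_equal(pred$window_used[pred$id == "small"], 54L)
  expect_false("tiny" %in% pred$id)
  excl <- attr(pred, "exclusions")
  expect_equal(excl$id, "tiny")
  expect_true(all(pred$score >= 0 & pred$score <= 1))
  expect_equal(pred$call, pred$score > 0.5)

  # a score exactly at the threshold is called non-coding
  t_edge <- pred$score[1]
  pred_edge <- predict_sorfs(recs, models, threshold = t_edge)
  expect_false(pred_edge$call[pred_edge$id == pred$id[1]])

  # thresholding is monotone in the threshold
  pred_hi <- predict_sorfs(recs, models, threshold = 0.9)
  expect_lte(sum(pred_hi$call), sum(pred$call))

  # a missing window model is an error naming the affected record count
  expect_error(predict_sorfs(recs, models[c("54", "99")]),
               "180.*1 record")
})

test_that("confusion metrics compute exact ratios with NA for 0/0", {
  calls <- c(rep(TRUE, 3), TRUE, rep(FALSE, 5), FALSE)
  truth <- c(rep("coding", 3), "noncoding", rep("noncoding", 5), "coding")
  cm <- confusion_metrics(calls, truth)
  expect_equal(cm$TP, 3); expect_equal(cm$FP, 1)
  expect_equal(cm$TN, 5); expect_equal(cm$FN, 1)
  expect_equal(cm$precision, 0.75)
  expect_equal(cm$sensitivity, 0.75)
  expect_equal(cm$specificity, 5 / 6)
  expect_equal(cm$accuracy, 0.8)

  perfect <- confusion_metrics(truth == "coding", truth)
  expect_equal(unlist(perfect[c("precision", "sensitivity", "specificity",
                                "accuracy")]),
               c(precision = 1, sensitivity = 1, specificity = 1,
                 accuracy = 1))

  none <- confusion_metrics(rep(FALSE, 10), truth)
  expect_true(is.na(none$precision)) # undefined, never 0
  expect_error(confusion_metrics(calls[1:3], truth), "length")
})

test_that("ROC points and AUC behave canonically", {
  s <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
  y <- c("coding", "coding", "coding", "noncoding", "noncoding", "noncoding")
  roc <- roc_points(s, y)
  expect_equal(roc$auc, 1)
  expect_equal(roc$points$fpr[1], 0)
  expect_equal(roc$points$tpr[1], 0)
  expect_equal(utils::tail(roc$points$fpr, 1), 1)
  expect_equal(utils::tail(roc$points$tpr, 1), 1)

  # sign reversal mirrors the curve
  mixed <- withr::with_seed(3, stats::rnorm(200))
  ymix <- rep(c("coding", "noncoding"), 100)
  expect_equal(roc_points(-mixed, ymix)$auc, 1 - roc_points(mixed, ymix)$auc,
               tolerance = 1e-12)

  # independent scores: AUC near 1/2
  withr::with_seed(4, {
    s0 <- stats::rnorm(10000)
    y0 <- sample(rep(c("coding", "noncoding"), 5000))
  })
  expect_gte(roc_points(s0, y0)$auc, 0.48)
  expect_lte(roc_points(s0, y0)$auc, 0.52)

  expect_error(roc_points(s, rep("coding", 6)), "both classes")
})

test_that("the harness rejects bad inputs", {
  cfg <- synthetic_config(n_pos = 30, n_neg = 30, length_range_aa = c(35, 60))
  recs <- generate_labeled_set(cfg, seed = 21)
  sp <- split_dataset(recs, seed = 21)
  grid <- hyper_grid("svm", svm = list(kernel = "rbf", C = 1,
                                       gamma = "scale"))
  suite <- train_feature_suite(sp$train, sp$validation, grid = grid,
                               keys = "cp54", k_folds = 3, seed = 1)
  expect_error(
    evaluate_harness(suite, sp$train[sp$train$label == "coding", ],
                     sp$train[sp$train$label == "noncoding", ],
                     thresholds = 0.5),
    "overlaps")
  expect_error(
    evaluate_harness(suite, sp$test[sp$test$label == "coding", ],
                     sp$test[sp$test$label == "noncoding", ],
                     thresholds = numeric(0)),
    "empty threshold")
  expect_error(train_feature_suite(sp$train, sp$train, grid = grid,
                                   keys = "cp54", k_folds = 3),
               "overlap")

  tab <- evaluate_harness(suite, sp$test[sp$test$label == "coding", ],
                          sp$test[sp$test$label == "noncoding", ],
                          thresholds = c(0.5, 0.9))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$feature_set, c("cp54", "cp54"))
  expect_true(all(tab$TP + tab$FN == sum(sp$test$label == "coding")))
})

toy_table <- function() {
  tab <- tempfile(fileext = ".tsv")
  rows <- c(
    sprintf("e%d\tATGGCATAA\tAAAA\tensembl_sORF\t%s\t%s", 1:4,
            c("0.1", "0.1", "0.1", "0.9"),  # FLOSS: lower is positive
            c("7", "7", "7", "1")),         # ORFscore: higher is positive
    sprintf("i%d\tATGGCCTAA\tCCCC\tintronic\t%s\t%s", 1:6,
            c("0.9", "0.9", "0.9", "0.9", "0.9", "0.1"),
            c("1", "1", "1", "1", "1", "7")))
  writeLines(c("id\tsequence\tupstream\tannotation_class\tFLOSS\tORFscore",
               rows), tab)
  read_sorf_table(tab)
}

test_that("class positivity report counts per class and metric", {
  st <- toy_table()
  rep1 <- class_positivity_report(st)
  cell <- rep1[rep1$annotation_class == "ensembl_sORF" &
                 rep1$metric == "FLOSS", ]
  expect_equal(cell$n_positive, 3)
  expect_equal(cell$n_total, 4)
  expect_equal(cell$percentage, 75)
  # percentages recompute exactly from their own counts
  ok <- !is.na(rep1$percentage)
  expect_equal(rep1$percentage[ok],
               100 * rep1$n_positive[ok] / rep1$n_total[ok])
  expect_true("exonic" %in% attr(rep1, "omitted_classes"))

  # an all-missing metric reports NA counts for that class
  st2 <- st
  st2$ORFscore <- NA_real_
  rep2 <- class_positivity_report(st2)
  expect_true(all(is.na(rep2$percentage[rep2$metric == "ORFscore"])))

  expect_error(class_positivity_report(st, cutoffs = c(nope = 1)),
               "unknown metric")

  # own classifier calls appear as an extra metric column
  own <- stats::setNames(rep(c(TRUE, FALSE), c(4, 6)), st$id)
  rep3 <- class_positivity_report(st, classifier_calls = own)
  cell3 <- rep3[rep3$annotation_class == "ensembl_sORF" &
                  rep3$metric == "sorfcp", ]
  expect_equal(cell3$percentage, 100)
})

test_that("overlap counts decompose the positive-anywhere set", {
  calls <- cbind(A = c(TRUE, TRUE, FALSE, FALSE),
                 B = c(FALSE, TRUE, TRUE, FALSE))
  rownames(calls) <- paste0("r", 1:4)
  oc <- overlap_counts(calls, c("A", "B"))
  expect_equal(oc$count[oc$region == "A"], 1)
  expect_equal(oc$count[oc$region == "B"], 1)
  expect_equal(oc$count[oc$region == "A&B"], 1)
  expect_equal(sum(oc$count), sum(rowSums(calls) > 0))

  same <- cbind(A = c(TRUE, TRUE, FALSE), B = c(TRUE, TRUE, FALSE))
  oc2 <- overlap_counts(same)
  expect_equal(oc2$count[oc2$region == "A&B"], 2)
  expect_equal(sum(oc2$count[oc2$region != "A&B"]), 0)

  disjoint <- cbind(A = c(TRUE, FALSE), B = c(FALSE, TRUE))
  oc3 <- overlap_counts(disjoint)
  expect_equal(oc3$count[oc3$region == "A&B"], 0)

  # rows missing any metric are excluded before counting
  withna <- cbind(A = c(TRUE, NA, TRUE), B = c(TRUE, TRUE, FALSE))
  oc4 <- overlap_counts(withna)
  expect_equal(attr(oc4, "n_complete"), 2)
  expect_equal(sum(oc4$count), 2)

  expect_error(overlap_counts(calls, "A"), "2 to 5")
})

test_that("benchmark confusion treats annotation classes as truth", {
  st <- toy_table()
  calls <- metric_calls(st)
  bc <- benchmark_confusion(st, calls)
  floss <- bc[bc$metric == "FLOSS", ]
  expect_equal(floss$TP, 3); expect_equal(floss$FP, 1)
  expect_equal(floss$accuracy, 0.8)
  expect_equal(floss$precision, 0.75)

  # degenerate calls
  all_pos <- matrix(TRUE, nrow(st), 1, dimnames = list(st$id, "AllPos"))
  bc2 <- benchmark_confusion(st, all_pos)
  expect_equal(bc2$sensitivity, 1)
  expect_equal(bc2$specificity, 0)
  none <- matrix(FALSE, nrow(st), 1, dimnames = list(st$id, "NonePos"))
  expect_true(is.na(benchmark_confusion(st, none)$precision))

  expect_error(benchmark_confusion(st, calls, pos_class = "5UTR"),
               "absent")
})
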