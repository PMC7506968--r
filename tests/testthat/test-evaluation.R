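test_that("confusion counts tally with FC as the positive class", {
  truth <- rep(c("FC", "NFC"), each = 10)
  cm <- confusion_counts(truth, truth)
  expect_equal(unclass(cm)[c("tp", "tn", "fp", "fn")],
               list(tp = 10L, tn = 10L, fp = 0L, fn = 0L))
  all_fc <- confusion_counts(truth, rep("FC", 20))
  expect_equal(unclass(all_fc)[c("tp", "fp", "tn", "fn")],
               list(tp = 10L, fp = 10L, tn = 0L, fn = 0L))
  expect_error(confusion_counts(character(0), character(0)), "non-empty")
  expect_error(confusion_counts(truth, truth[-1]), "equal length")
})

test_that("metrics reproduce hand-computed percentages", {
  cm <- structure(list(tp = 45L, tn = 40L, fp = 10L, fn = 5L),
                  class = "confusion_matrix")
  m <- classification_metrics(cm)
  expect_equal(unname(m["accuracy"]), 85)
  expect_equal(unname(m["sensitivity"]), 90)
  expect_equal(unname(m["specificity"]), 80)
  expect_equal(unname(m["ppv"]), 100 * 45 / 55, tolerance = 1e-12)
  expect_equal(unname(m["npv"]), 100 * 40 / 45, tolerance = 1e-12)
})

test_that("perfect classification is the all-100 fixed point", {
  truth <- rep(c("FC", "NFC"), c(7, 13))
  m <- classification_metrics(confusion_counts(truth, truth))
  expect_equal(as.numeric(m), rep(100, 5))
})

test_that("zero-denominator metrics are flagged, not zeroed", {
  cm <- confusion_counts(rep("NFC", 10), rep("NFC", 10))  # no positives
  m <- classification_metrics(cm)
  expect_true(is.nan(m["sensitivity"]))
  expect_true("sensitivity" %in% attr(m, "undefined"))
  expect_equal(unname(m["specificity"]), 100)
})

test_that("t screening matches the closed-form pooled-variance test", {
  set.seed(31)
  a <- matrix(rnorm(50 * 4), 50, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  b <- matrix(rnorm(50 * 4, mean = 0.3), 50, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  res <- t_screen(a, b, alpha = 0.01)
  for (j in 1:4) {
    o <- oracle_pooled_t(a[, j], b[, j])
    expect_equal(res$t[j], unname(o["t"]), tolerance = 1e-10)
    expect_equal(res$p[j], unname(o["p"]), tolerance = 1e-10)
  }
  # identical groups: t = 0, p = 1, dropped
  same <- t_screen(a, a)
  expect_equal(same$t, rep(0, 4))
  expect_true(all(same$p > 0.99))
  expect_false(any(same$keep))
  # huge separation: kept at any reasonable alpha
  far <- t_screen(matrix(rnorm(50), 50, 1), matrix(rnorm(50, 10), 50, 1))
  expect_true(far$keep)
  expect_lt(far$p, 1e-20)
})

test_that("stratified folds preserve class proportions", {
  labels <- rep(c("FC", "NFC"), each = 100)
  fold <- stratified_folds(labels, k = 10, seed = 1)
  for (f in 1:10) {
    expect_equal(sum(fold == f & labels == "FC"), 10)
    expect_equal(sum(fold == f & labels == "NFC"), 10)
  }
  expect_identical(fold, stratified_folds(labels, k = 10, seed = 1))
  expect_false(identical(fold, stratified_folds(labels, k = 10, seed = 2)))
  expect_error(stratified_folds(rep(c("FC", "NFC"), c(5, 100)), k = 10),
               "at least k")
})

test_that("cross-validation pools fold counts and tests each record once", {
  task_X <- rbind(matrix(rnorm(2 * 60), ncol = 2),
                  matrix(rnorm(2 * 60, mean = 4), ncol = 2))
  task_y <- rep(c("NFC", "FC"), each = 60)
  cv <- stratified_kfold_cv(task_X, task_y, k = 10, seed = 3)
  fold_sum <- Reduce(fwhteeg:::add_confusion,
                     lapply(cv$per_fold, `[[`, "confusion"))
  expect_equal(unclass(cv$pooled)[1:4], unclass(fold_sum)[1:4])
  total <- with(cv$pooled, tp + tn + fp + fn)
  expect_equal(total, 120)
  expect_equal(sort(unique(cv$fold)), 1:10)
  # separable task: near-perfect pooled accuracy
  expect_gte(cv$metrics[["accuracy"]], 95)
  # determinism
  cv2 <- stratified_kfold_cv(task_X, task_y, k = 10, seed = 3)
  expect_identical(cv$fold, cv2$fold)
  expect_equal(unclass(cv$pooled)[1:4], unclass(cv2$pooled)[1:4])
})
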