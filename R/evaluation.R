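#' Confusion counts for a binary NFC/FC task
#'
#' Tallies true/false positives and negatives with FC as the positive class
#' (a "positive" is a record flagged as focal).
#'
#' @param truth,predicted equal-length label vectors (`"NFC"`/`"FC"`,
#'   factors, or 0/1 with 1 = FC).
#' @return A list of class `confusion_matrix` with integer fields `tp`,
#'   `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, predicted) {
  if (length(truth) == 0L)
    stop("'truth' must be non-empty", call. = FALSE)
  if (length(truth) != length(predicted))
    stop("'truth' and 'predicted' must have equal length", call. = FALSE)
  t01 <- encode_labels(truth)
  p01 <- encode_labels(predicted)
  structure(
    list(tp = sum(t01 == 1 & p01 == 1),
         tn = sum(t01 == 0 & p01 == 0),
         fp = sum(t01 == 0 & p01 == 1),
         fn = sum(t01 == 1 & p01 == 0)),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2L, 2L,
              dimnames = list(truth = c("FC", "NFC"),
                              predicted = c("FC", "NFC")))
  print(m)
  invisible(x)
}

add_confusion <- function(a, b) {
  structure(list(tp = a$tp + b$tp, tn = a$tn + b$tn,
                 fp = a$fp + b$fp, fn = a$fn + b$fn),
            class = "confusion_matrix")
}

#' Classification performance metrics
#'
#' The five standard ratios, each expressed as a percentage in \[0, 100\]:
#' \deqn{\mathrm{Accuracy} = \frac{T_+ + T_-}{T_+ + T_- + F_+ + F_-}\times 100}
#' \deqn{\mathrm{Sensitivity} = \frac{T_+}{T_+ + F_-}\times 100,\quad
#'       \mathrm{Specificity} = \frac{T_-}{T_- + F_+}\times 100}
#' \deqn{\mathrm{PPV} = \frac{T_+}{T_+ + F_+}\times 100,\quad
#'       \mathrm{NPV} = \frac{T_-}{T_- + F_-}\times 100}
#' A ratio with a zero denominator (e.g. sensitivity when no positive
#' records were evaluated) is returned as `NaN` and listed in the
#' `undefined` attribute rather than silently reported as 0.
#'
#' @param cm a [confusion_counts()] result.
#' @return Named numeric vector `accuracy`, `sensitivity`, `specificity`,
#'   `ppv`, `npv` (percent), with attribute `undefined` naming any
#'   zero-denominator metrics.
#' @examples
#' classification_metrics(confusion_counts(
#'   rep(c("FC", "NFC"), c(50, 50)),
#'   rep(c("FC", "NFC", "FC", "NFC"), c(45, 5, 10, 40))))
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$tn + cm$fp + cm$fn
  if (total == 0L) stop("empty confusion matrix", call. = FALSE)
  ratio <- function(num, den) if (den == 0) NaN else 100 * num / den
  out <- c(accuracy = ratio(cm$tp + cm$tn, total),
           sensitivity = ratio(cm$tp, cm$tp + cm$fn),
           specificity = ratio(cm$tn, cm$tn + cm$fp),
           ppv = ratio(cm$tp, cm$tp + cm$fp),
           npv = ratio(cm$tn, cm$tn + cm$fn))
  attr(out, "undefined") <- names(out)[is.nan(out)]
  out
}

#' Per-feature Student's t screening
#'
#' Two-sample pooled-variance Student's t-test of each feature between the
#' two classes; features with `p < alpha` are kept. This is the screening
#' step applied to the entropy features before classification — in practice
#' all five entropies separate the classes far below the 0.01 level, so the
#' screen documents significance rather than prunes. A feature with zero
#' pooled variance and equal means is reported with `p = 1` and dropped.
#'
#' @param class_a,class_b numeric matrices (records in rows) with the same
#'   named feature columns; at least two rows each.
#' @param alpha significance level for the keep mask.
#' @param welch use the Welch (unequal-variance) variant instead of the
#'   pooled-variance test.
#' @return A data.frame with columns `feature`, `t`, `p`, `keep`.
#' @export
t_screen <- function(class_a, class_b, alpha = 0.01, welch = FALSE) {
  a <- as.matrix(class_a); b <- as.matrix(class_b)
  if (ncol(a) != ncol(b))
    stop("both classes must have the same features", call. = FALSE)
  if (nrow(a) < 2L || nrow(b) < 2L)
    stop("need at least 2 records per class", call. = FALSE)
  res <- lapply(seq_len(ncol(a)), function(j) {
    x <- a[, j]; y <- b[, j]
    if (stats::var(x) == 0 && stats::var(y) == 0 && mean(x) == mean(y))
      return(c(t = 0, p = 1))
    tt <- stats::t.test(x, y, var.equal = !welch)
    c(t = unname(tt$statistic), p = tt$p.value)
  })
  res <- do.call(rbind, res)
  data.frame(feature = colnames(a) %||% paste0("V", seq_len(ncol(a))),
             t = res[, "t"], p = res[, "p"], keep = res[, "p"] < alpha,
             row.names = NULL)
}

#' Stratified k-fold splits
#'
#' Partitions record indices into `k` folds preserving class proportions
#' (per-fold class counts differ from the global proportion by at most one
#' record), from a seeded shuffle.
#'
#' @param labels class labels of all records.
#' @param k number of folds.
#' @param seed shuffle seed.
#' @return Integer vector of fold assignments (1..k) per record.
#' @export
stratified_folds <- function(labels, k = 10L, seed = 1L) {
  y <- encode_labels(labels)
  k <- as.integer(k)
  if (any(table(y) < k))
    stop(sprintf("every class needs at least k = %d records", k),
         call. = FALSE)
  rs <- local_rng(seed)
  on.exit(restore_rng(rs))
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation of the MLP classifier
#'
#' The evaluation protocol of the pipeline: records are split into `k`
#' stratified folds; for each fold an [mlp_lm()] network is trained on the
#' remaining folds (standardising on training statistics only) and the
#' held-out records are predicted. Per-fold confusion matrices and metrics
#' are reported alongside the pooled (micro-averaged) matrix, whose counts
#' are the element-wise sum over folds — every record is tested exactly
#' once. The run is deterministic given `seed` (fold shuffle and per-fold
#' weight initialisations are both derived from it).
#'
#' @param features numeric feature matrix, records in rows.
#' @param labels class labels (`"NFC"`/`"FC"` or 0/1).
#' @param k number of folds (default 10).
#' @param n_hidden hidden-layer width for each fold's network.
#' @param control an [mlp_lm_control()] shared by all folds.
#' @param seed integer seed.
#' @return A list of class `cv_result`: `fold` (assignment vector),
#'   `per_fold` (list with `confusion` and `metrics` per fold), `pooled`
#'   (confusion), `metrics` (pooled percentages), `k`, `seed`.
#' @export
stratified_kfold_cv <- function(features, labels, k = 10L, n_hidden = 10L,
                                control = mlp_lm_control(), seed = 1L) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  y <- encode_labels(labels)
  fold <- stratified_folds(y, k = k, seed = seed)
  per_fold <- vector("list", k)
  pooled <- structure(list(tp = 0L, tn = 0L, fp = 0L, fn = 0L),
                      class = "confusion_matrix")
  for (f in seq_len(k)) {
    tr <- fold != f
    fit <- mlp_lm(X[tr, , drop = FALSE], y[tr], n_hidden = n_hidden,
                  seed = seed + f, control = control)
    pred <- predict(fit, X[!tr, , drop = FALSE], type = "class")
    cm <- confusion_counts(y[!tr], pred)
    per_fold[[f]] <- list(confusion = cm,
                          metrics = classification_metrics(cm))
    pooled <- add_confusion(pooled, cm)
  }
  structure(
    list(fold = fold, per_fold = per_fold, pooled = pooled,
         metrics = classification_metrics(pooled),
         k = as.integer(k), seed = as.integer(seed)),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Stratified %d-fold cross-validation (seed %d)\n", x$k, x$seed))
  cat("Pooled confusion counts:\n")
  print(x$pooled)
  m <- x$metrics
  cat(sprintf(paste0("accuracy %.2f%%  sensitivity %.2f%%  ",
                     "specificity %.2f%%  ppv %.2f%%  npv %.2f%%\n"),
              m["accuracy"], m["sensitivity"], m["specificity"],
              m["ppv"], m["npv"]))
  invisible(x)
}
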