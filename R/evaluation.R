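#' Four-stage confusion matrix
#'
#' Counts actual-versus-predicted labels over the four stages, presented in
#' the conventional reporting order (mild, moderate, severe, normal). Two
#' per-class true-positive bookkeeping conventions are computed, because
#' published summaries mix them:
#' \itemize{
#'   \item `tp_diagonal`: the strict diagonal count;
#'   \item `tp_row_nonnormal`: for keratoconus classes, the row total minus
#'     the cases missed as normal (i.e. any keratoconus label counts as a
#'     hit); the diagonal for the normal class.
#' }
#' The binary normal-versus-keratoconus reading of the normal row is also
#' summarised: `TN` = normal predicted normal, `FP` = normal predicted as
#' any keratoconus stage, and `FN_normal_row = FP` (the normal row's
#' misses).
#'
#' @param actual,predicted Equal-length label vectors over the four stages.
#' @return A `kerato_confusion`: list with `counts` (4 x 4 matrix),
#'   `row_totals`, `tp_diagonal`, `tp_row_nonnormal`, `fn_diagonal`, and
#'   `binary` (TN/FP for the normal row).
#' @export
confusion <- function(actual, predicted) {
  lev <- c("mild", "moderate", "severe", "normal")
  actual <- as.character(actual); predicted <- as.character(predicted)
  if (length(actual) != length(predicted))
    kerato_error("actual and predicted differ in length", "kerato3d_config_error")
  bad <- setdiff(unique(c(actual, predicted)), lev)
  if (length(bad) > 0)
    kerato_error(paste("unknown stage label(s):", paste(bad, collapse = ", ")),
                 "kerato3d_config_error")
  counts <- table(factor(actual, lev), factor(predicted, lev))
  counts <- matrix(as.integer(counts), 4, 4, dimnames = list(actual = lev, predicted = lev))
  tp_diag <- diag(counts)
  tp_rnn <- tp_diag
  ker <- setdiff(lev, "normal")
  for (s in ker) tp_rnn[s] <- sum(counts[s, ker])
  structure(list(
    counts = counts,
    row_totals = rowSums(counts),
    tp_diagonal = tp_diag,
    tp_row_nonnormal = tp_rnn,
    fn_diagonal = rowSums(counts) - tp_diag,
    binary = c(TN = counts["normal", "normal"],
               FP = sum(counts["normal", ker]))
  ), class = "kerato_confusion")
}

#' @export
print.kerato_confusion <- function(x, ...) {
  cat("confusion matrix (actual x predicted):\n")
  print(x$counts)
  invisible(x)
}

#' Accuracy, sensitivity and specificity from summary counts
#'
#' Computes the three headline statistics from TP/TN/FP/FN counts using the
#' literal report-style formulas:
#' \deqn{Accuracy = (TP + TN) / (TP + FP + FN + TN)}
#' \deqn{Sensitivity = TP / (TP + FP)}
#' \deqn{Specificity = TN / (TN + FN)}
#' Note the sensitivity/specificity forms divide by FP and FN respectively
#' -- that is how the reproduced published summaries are computed, not the
#' textbook definitions. The textbook variants (recall `TP/(TP+FN)` and
#' true-negative rate `TN/(TN+FP)`) are returned alongside under distinct
#' names.
#'
#' @param TP,TN,FP,FN Non-negative counts.
#' @return A `class_metrics` list of percentages: `accuracy`,
#'   `sensitivity`, `specificity` (literal forms), `sensitivity_recall`,
#'   `specificity_tnr` (textbook forms), plus the input counts.
#' @export
class_metrics <- function(TP, TN, FP, FN) {
  if (any(c(TP, TN, FP, FN) < 0)) kerato_error("counts must be non-negative",
                                               "kerato3d_config_error")
  div <- function(num, den, what) {
    if (den == 0)
      kerato_error(paste("undefined metric:", what, "has a zero denominator"),
                   "kerato3d_undefined_metric")
    100 * num / den
  }
  structure(list(
    TP = TP, TN = TN, FP = FP, FN = FN,
    accuracy = div(TP + TN, TP + FP + FN + TN, "accuracy"),
    sensitivity = div(TP, TP + FP, "sensitivity"),
    specificity = div(TN, TN + FN, "specificity"),
    sensitivity_recall = div(TP, TP + FN, "recall"),
    specificity_tnr = div(TN, TN + FP, "true-negative rate")
  ), class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%% (literal forms)\n",
              x$accuracy, x$sensitivity, x$specificity))
  cat(sprintf("  textbook: recall %.2f%%, TNR %.2f%%\n",
              x$sensitivity_recall, x$specificity_tnr))
  invisible(x)
}

#' Bundled reference confusion matrix
#'
#' A published reference evaluation of automated four-stage keratoconus
#' grading against clinician diagnosis (268 cases: 58 mild, 70 moderate, 40
#' severe, 100 normal), bundled as plain CSV for metric verification. Two
#' tables are provided: the full 4 x 4 confusion counts and the published
#' per-class TP/FN/TN/FP summary columns (whose TP bookkeeping mixes the
#' two conventions of [confusion()]; the summary is reproduced as printed).
#'
#' @return List with `counts` (4 x 4 matrix) and `summary` (data frame with
#'   columns `class`, `total`, `TP`, `FN`, `TN`, `FP`).
#' @export
reference_confusion <- function() {
  path <- system.file("extdata", package = "kerato3d")
  counts <- as.matrix(read.csv(file.path(path, "reference_confusion.csv"),
                               row.names = 1, check.names = FALSE))
  summary <- read.csv(file.path(path, "reference_confusion_summary.csv"),
                      check.names = FALSE)
  dimnames(counts) <- list(actual = rownames(counts), predicted = colnames(counts))
  list(counts = counts, summary = summary)
}

#' Stratified k-fold partition
#'
#' Assigns every case to exactly one test fold, stratified by class: within
#' each class the (shuffled) members are dealt round-robin, so per-class
#' fold sizes differ by at most one.
#'
#' @param labels Class label vector.
#' @param k Number of folds (>= 2); every class must have at least `k`
#'   members.
#' @param seed Integer seed.
#' @return Integer vector of fold assignments in `1..k`.
#' @export
kfold_split <- function(labels, k, seed = 1L) {
  if (k < 2) kerato_error("k must be >= 2", "kerato3d_config_error")
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < k))
    kerato_error(sprintf("class '%s' has fewer than k = %d members",
                         names(tab)[which.min(tab)], k), "kerato3d_config_error")
  fold <- integer(length(labels))
  with_seed(seed, {
    offset <- 0L
    for (cls in names(tab)) {
      idx <- sample(which(labels == cls))
      # rotate the starting fold per class so remainders spread over folds
      fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- offset + length(idx)
    }
  })
  fold
}

#' k-fold cross-validated evaluation
#'
#' Trains and tests a classifier in `k` iterations over a stratified
#' partition: each fold serves once as the test set while the remaining
#' `k - 1` folds train. Model accuracy is the average accuracy over the
#' iterations; macro-averaged precision, recall and F1 are reported
#' alongside.
#'
#' @param x List (or vector) of cases, passed to the fit/predict closures.
#' @param labels Class labels, one per case.
#' @param k Number of folds.
#' @param seed Integer seed for the partition.
#' @param fit `function(x_train, labels_train)` returning a fitted object.
#' @param predict_fn `function(fitted, x_test)` returning predicted labels.
#' @return List with `folds` (assignment), `per_fold` (data frame) and
#'   `mean_accuracy`, `mean_precision`, `mean_recall`, `mean_f1` (as
#'   percentages).
#' @export
kfold_evaluate <- function(x, labels, k, seed = 1L, fit, predict_fn) {
  fold <- kfold_split(labels, k, seed)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  per <- data.frame(fold = seq_len(k), n_test = NA_real_, accuracy = NA_real_,
                    precision = NA_real_, recall = NA_real_, f1 = NA_real_)
  subset_cases <- function(sel) if (is.list(x)) x[sel] else x[sel]
  for (f in seq_len(k)) {
    te <- fold == f
    fitted <- fit(subset_cases(!te), labels[!te])
    pred <- as.character(predict_fn(fitted, subset_cases(te)))
    act <- labels[te]
    per$n_test[f] <- sum(te)
    per$accuracy[f] <- 100 * mean(pred == act)
    prf <- vapply(classes, function(cl) {
      tp <- sum(pred == cl & act == cl)
      prec <- if (sum(pred == cl) > 0) tp / sum(pred == cl) else NA_real_
      rec <- if (sum(act == cl) > 0) tp / sum(act == cl) else NA_real_
      f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
        2 * prec * rec / (prec + rec) else NA_real_
      c(prec, rec, f1)
    }, numeric(3))
    per$precision[f] <- 100 * mean(prf[1, ], na.rm = TRUE)
    per$recall[f] <- 100 * mean(prf[2, ], na.rm = TRUE)
    per$f1[f] <- 100 * mean(prf[3, ], na.rm = TRUE)
  }
  list(folds = fold, per_fold = per,
       mean_accuracy = mean(per$accuracy), mean_precision = mean(per$precision),
       mean_recall = mean(per$recall), mean_f1 = mean(per$f1))
}

#' Pearson correlation coefficient (sample form)
#'
#' The sample correlation with `n - 1` normalisation and sample standard
#' deviations,
#' \deqn{r = \frac{1}{n-1}\sum_i \frac{x_i-\bar x}{SD_x}\,\frac{y_i-\bar y}{SD_y},}
#' computed directly from that formula.
#'
#' @param x,y Numeric vectors of equal length >= 3 with positive variance.
#' @return `r` in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  n <- length(x)
  if (n != length(y)) kerato_error("x and y differ in length", "kerato3d_config_error")
  if (n < 3) kerato_error("need at least 3 pairs", "kerato3d_config_error")
  sdx <- sd(x); sdy <- sd(y)
  if (sdx == 0 || sdy == 0)
    kerato_error("undefined correlation: zero variance", "kerato3d_undefined_metric")
  sum(((x - mean(x)) / sdx) * ((y - mean(y)) / sdy)) / (n - 1)
}

#' Bland-Altman agreement statistics
#'
#' For paired measurements (e.g. predicted versus clinician curvature
#' angles) the per-pair differences and means are tabulated; the limits of
#' agreement are the mean difference plus/minus 1.96 standard deviations of
#' the differences (the 95% limits under normality).
#'
#' @param measured_a,measured_b Equal-length numeric vectors (>= 3).
#' @return An `agreement_stats` list: `n`, `mean_diff`, `sd_diff`,
#'   `lower_limit`, `upper_limit`, and `table` (per-pair `mean`, `diff`)
#'   for plotting.
#' @export
bland_altman <- function(measured_a, measured_b) {
  if (length(measured_a) != length(measured_b))
    kerato_error("inputs differ in length", "kerato3d_config_error")
  if (length(measured_a) < 3) kerato_error("need at least 3 pairs", "kerato3d_config_error")
  d <- measured_a - measured_b
  m <- (measured_a + measured_b) / 2
  sdd <- sd(d)
  structure(list(n = length(d), mean_diff = mean(d), sd_diff = sdd,
                 lower_limit = mean(d) - 1.96 * sdd,
                 upper_limit = mean(d) + 1.96 * sdd,
                 table = data.frame(mean = m, diff = d)),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("Bland-Altman: n=%d, mean diff %.3f, limits [%.3f, %.3f]\n",
              x$n, x$mean_diff, x$lower_limit, x$upper_limit))
  invisible(x)
}
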