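# The demo classifier is deliberately pluggable: length normalization is a
# preprocessing step, independent of whatever learner consumes the matrix.
# A classifier here is any function(x_train, y_train, x_test) returning a
# numeric score per test row, higher meaning more class-1-like.

#' Baseline classifiers for the demo pipeline
#'
#' `classifier_nearest_centroid()` scores a test row by the difference of
#' its Euclidean distances to the class-0 and class-1 training centroids
#' (higher = closer to class 1). `classifier_logistic()` fits an
#' unpenalized logistic regression on the feature columns and scores by
#' the fitted probability of class 1.
#'
#' @param x_train,x_test Numeric matrices (rows = sequences).
#' @param y_train Integer 0/1 labels for `x_train`.
#' @return Numeric score vector, one per row of `x_test`.
#' @export
classifier_nearest_centroid <- function(x_train, y_train, x_test) {
  c0 <- colMeans(x_train[y_train == 0L, , drop = FALSE])
  c1 <- colMeans(x_train[y_train == 1L, , drop = FALSE])
  d0 <- sqrt(rowSums(sweep(x_test, 2L, c0)^2))
  d1 <- sqrt(rowSums(sweep(x_test, 2L, c1)^2))
  d0 - d1
}

#' @rdname classifier_nearest_centroid
#' @export
classifier_logistic <- function(x_train, y_train, x_test) {
  df <- as.data.frame(x_train)
  df$.y <- y_train
  fit <- suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
  suppressWarnings(
    as.numeric(stats::predict(fit, newdata = as.data.frame(x_test),
                              type = "response")))
}

#' Rank-based (trapezoidal) AUC estimate
#'
#' The area under the ROC curve computed with the Mann-Whitney rank
#' statistic, which equals the trapezoidal area under the empirical ROC
#' curve (ties handled by mid-ranks).
#'
#' @param scores Numeric scores, higher = more class-1-like.
#' @param labels Integer 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_rank(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) abort("both classes must be present.")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ROC points (FPR, TPR) swept over score thresholds, ties collapsed
roc_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  labels <- as.integer(labels)[ord]
  scores <- scores[ord]
  tp <- cumsum(labels == 1L); fp <- cumsum(labels == 0L)
  last <- !duplicated(scores, fromLast = TRUE)
  tibble(
    threshold = c(Inf, scores[last]),
    fpr = c(0, fp[last] / sum(labels == 0L)),
    tpr = c(0, tp[last] / sum(labels == 1L)))
}

#' Cross-validated demonstration classification of a feature matrix
#'
#' Runs stratified k-fold cross-validation of a pluggable binary
#' classifier on a feature matrix and reports out-of-fold scores, ROC
#' points, and the rank/trapezoidal AUC. This is a demonstration that the
#' preprocessing preserves class signal, not a production learner.
#'
#' @param data A [build_feature_matrix()] tibble (or any data frame with
#'   feature columns `p1..pD`).
#' @param labels Integer 0/1 vector, or the name of a label column in
#'   `data` (default `"label"` when present).
#' @param classifier A `function(x_train, y_train, x_test)` returning
#'   scores; default [classifier_nearest_centroid()].
#' @param folds Number of cross-validation folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return An object of class `demo_classification`: list with `auc`,
#'   `roc` (tibble of ROC points), `scores` (tibble of out-of-fold scores
#'   with fold assignment), `folds`, `n`.
#' @examples
#' synth <- generate_synthetic(synth_config(n0 = 60, n1 = 60, seed = 7))
#' fm <- build_feature_matrix(synth, dims = 35)
#' fit <- demo_classification(fm, seed = 7)
#' glance(fit)
#' @export
demo_classification <- function(data, labels = NULL,
                                classifier = classifier_nearest_centroid,
                                folds = 5L, seed = 1L) {
  pc <- feature_columns(data)
  if (length(pc) == 0L) abort("`data` has no feature columns p1..pD.")
  x <- as.matrix(as.data.frame(data)[, pc, drop = FALSE])
  y <- if (is.null(labels)) {
    if (!"label" %in% names(data))
      abort("no `labels` given and `data` has no `label` column.")
    data[["label"]]
  } else if (is.character(labels) && length(labels) == 1L) {
    data[[labels]]
  } else labels
  y <- as.integer(y)
  if (length(y) != nrow(x)) abort("`labels` length must match the number of rows.")
  if (length(unique(y)) < 2L) abort("both classes must be present in `labels`.")
  if (!all(y %in% 0:1)) abort("`labels` must be 0/1.")
  folds <- as.integer(folds)
  if (folds < 2L || folds > nrow(x)) abort("`folds` must be in 2..n.")

  fold_id <- integer(length(y))
  withr_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  scores <- numeric(length(y))
  for (k in seq_len(folds)) {
    test <- fold_id == k
    scores[test] <- classifier(x[!test, , drop = FALSE], y[!test],
                               x[test, , drop = FALSE])
  }
  structure(
    list(auc = auc_rank(scores, y),
         roc = roc_points(scores, y),
         scores = tibble(id = if ("id" %in% names(data)) data$id
                              else seq_along(y),
                         label = y, score = scores, fold = fold_id),
         folds = folds, n = length(y)),
    class = "demo_classification")
}

# evaluate expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

#' @export
print.demo_classification <- function(x, ...) {
  cat(sprintf("<demo_classification> %d-fold CV on %d sequences: AUC = %.4f\n",
              x$folds, x$n, x$auc))
  invisible(x)
}

#' @rdname demo_classification
#' @param x A `demo_classification` object.
#' @param ... Unused.
#' @export
tidy.demo_classification <- function(x, ...) x$roc

#' @rdname demo_classification
#' @export
glance.demo_classification <- function(x, ...) {
  tibble(auc = x$auc, folds = x$folds, n = x$n,
         n_pos = sum(x$scores$label == 1L),
         n_neg = sum(x$scores$label == 0L))
}
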