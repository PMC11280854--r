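# Evaluation protocols and metrics: pooled confusion matrix, accuracy,
# Cohen's kappa, Weka-style probability RMSE, stratified k-fold
# cross-validation and the per-sign train/test split protocol.

proba_to_class <- function(model, P) {
  tie <- attr(P, "tie_order")
  if (!is.null(tie)) model$classes[tie]
  else model$classes[max.col(P, ties.method = "first")]
}

#' Cohen's kappa from a confusion matrix
#'
#' `(p_o - p_e) / (1 - p_e)` with observed agreement `p_o = trace/total` and
#' chance agreement `p_e = sum(row_i * col_i) / total^2`; returns 1 when
#' both are 1.
#'
#' @param confusion square nonnegative count matrix (rows = truth)
#' @return kappa statistic (<= 1)
#' @export
kappa_statistic <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (!nrow(confusion) || nrow(confusion) != ncol(confusion) ||
      any(confusion < 0))
    stop_invalid("`confusion` must be a square nonnegative matrix")
  total <- sum(confusion)
  if (total <= 0) stop_invalid("`confusion` must have a positive total")
  po <- sum(diag(confusion)) / total
  pe <- sum(rowSums(confusion) * colSums(confusion)) / total^2
  if (pe == 1) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Weka-style probability RMSE
#'
#' Root mean square over all instance-class cells of the difference between
#' the predicted class probability and the 0/1 truth indicator. One-hot
#' correct predictions give 0; uniform probabilities over C classes give
#' `sqrt(C - 1) / C`.
#'
#' @param proba matrix of per-class probability rows (columns named by
#'   class, or in the order of `classes`)
#' @param truth true labels
#' @param classes class levels ordering the columns (default: column names)
#' @return RMSE >= 0
#' @export
rmse_probability <- function(proba, truth, classes = colnames(proba)) {
  proba <- as.matrix(proba)
  if (is.null(classes)) stop_invalid("`classes` (or column names) required")
  ci <- match(as.character(truth), classes)
  if (anyNA(ci)) stop_invalid("truth labels outside `classes`")
  Y <- matrix(0, nrow(proba), ncol(proba))
  Y[cbind(seq_len(nrow(proba)), ci)] <- 1
  sqrt(mean((proba - Y)^2))
}

confusion_matrix <- function(truth, pred, classes) {
  table(factor(truth, levels = classes), factor(pred, levels = classes))
}

eval_result <- function(confusion, proba, truth, classes) {
  structure(list(
    accuracy = 100 * sum(diag(confusion)) / sum(confusion),
    kappa = kappa_statistic(confusion),
    rmse = rmse_probability(proba, truth, classes),
    confusion = confusion), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("Accuracy (%%)            %.4f\n", x$accuracy))
  cat(sprintf("Kappa statistic         %.4f\n", x$kappa))
  cat(sprintf("Root mean squared error %.4f\n", x$rmse))
  invisible(x)
}

#' Serialize an evaluation result to JSON
#'
#' @param x an `eval_result`
#' @param path optional output file; if `NULL` the JSON string is returned
#' @return the JSON string, invisibly when written to file
#' @export
eval_result_json <- function(x, path = NULL) {
  obj <- list(accuracy = x$accuracy, kappa = x$kappa, rmse = x$rmse,
              confusion = unclass(as.matrix(x$confusion)))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

resolve_xy <- function(x, y) {
  if (inherits(x, "sign_dataset")) {
    if (is.null(x$features))
      stop_invalid("dataset has no feature table; run extract_features() first")
    list(X = x$features, y = x$labels)
  } else list(X = as.matrix(x), y = as.character(y))
}

#' Stratified k-fold cross-validation
#'
#' Seeded stratified fold assignment (plain unstratified folds, with a
#' message, when some class has fewer than `k` examples); per-fold test
#' predictions are pooled into one confusion matrix, and standardization is
#' fit on the training folds only (inside [fit_classifier()]).
#'
#' @param spec a [classifier_spec()]
#' @param x feature matrix or `sign_dataset` with features
#' @param y labels (ignored for a dataset)
#' @param k number of folds (>= 2)
#' @param seed integer seed for folds and stochastic fits
#' @return an `eval_result`; the fold assignment is attached as attribute
#'   `"folds"`
#' @export
cross_validate <- function(spec, x, y = NULL, k = 10, seed = 1) {
  if (k < 2) stop_invalid("`k` must be >= 2")
  d <- resolve_xy(x, y)
  X <- d$X; y <- d$y
  n <- length(y)
  classes <- sort(unique(y))
  folds <- integer(n)
  with_seed(seed, {
    if (min(table(y)) >= k) {
      for (cl in classes) {
        idx <- which(y == cl)
        folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    } else {
      message("some class has fewer than k examples; using plain folds")
      folds <- sample(rep_len(seq_len(k), n))
    }
  })
  pred <- character(n)
  proba <- matrix(0, n, length(classes), dimnames = list(NULL, classes))
  for (f in seq_len(k)) {
    te <- folds == f
    model <- fit_classifier(spec, X[!te, , drop = FALSE], y[!te],
                            seed = seed + f)
    P <- predict_proba(model, X[te, , drop = FALSE])
    pred[te] <- proba_to_class(model, P)
    proba[te, model$classes] <- P
  }
  res <- eval_result(confusion_matrix(y, pred, classes), proba, y, classes)
  attr(res, "folds") <- folds
  res
}

#' Per-sign train/test split evaluation
#'
#' For every sign, `n_train` records are drawn without replacement (seeded)
#' for training and `n_test` of the remaining records for testing; results
#' are aggregated over all signs.
#'
#' @param spec a [classifier_spec()]
#' @param x feature matrix or `sign_dataset` with features
#' @param y labels (ignored for a dataset)
#' @param n_train,n_test records per sign; `n_train + n_test` must not
#'   exceed the smallest per-sign record count
#' @param seed integer seed
#' @return an `eval_result`
#' @export
split_evaluate <- function(spec, x, y = NULL, n_train = 9, n_test = 1,
                           seed = 1) {
  d <- resolve_xy(x, y)
  X <- d$X; y <- d$y
  classes <- sort(unique(y))
  counts <- table(y)
  if (n_train < 1 || n_test < 1 || any(counts < n_train + n_test))
    stop_invalid("infeasible protocol: need n_train + n_test <= records per sign")
  tr <- integer(0); te <- integer(0)
  with_seed(seed, for (cl in classes) {
    idx <- sample(which(y == cl))
    tr <- c(tr, idx[seq_len(n_train)])
    te <- c(te, idx[n_train + seq_len(n_test)])
  })
  model <- fit_classifier(spec, X[tr, , drop = FALSE], y[tr], seed = seed)
  P <- predict_proba(model, X[te, , drop = FALSE])
  pred <- proba_to_class(model, P)
  res <- eval_result(confusion_matrix(y[te], pred, classes), P, y[te], classes)
  attr(res, "train_idx") <- tr
  attr(res, "test_idx") <- te
  res
}
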