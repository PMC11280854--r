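# Multiclass classifiers over feature vectors.
#
# No classifier library is assumed: the five algorithms are self-contained
# implementations behind a common spec/fit/predict interface. Every fit
# z-scores features with training-set statistics (stored in the model) and
# receives the run seed, so training is deterministic.

#' Declare a classifier
#'
#' Known algorithms and their parameters (defaults in parentheses):
#' `knn` (`k = 3`), `random_forest` (`ntree = 100`, `mtry = floor(sqrt(p))`,
#' `n_thresholds = 8`), `mlp` (`hidden = 32`, `epochs = 120`, `lr = 0.05`),
#' `naive_bayes` (`var_eps = 1e-6`), `svm` (`lambda = 1e-4`, `iters = 150`).
#'
#' @param algorithm one of `"knn"`, `"random_forest"`, `"mlp"`,
#'   `"naive_bayes"`, `"svm"`
#' @param ... algorithm parameters overriding the defaults
#' @return a `classifier_spec`
#' @export
#' @examples
#' classifier_spec("knn", k = 1)
classifier_spec <- function(algorithm, ...) {
  known <- list(
    knn = list(k = 3L),
    random_forest = list(ntree = 100L, mtry = NULL, n_thresholds = 8L),
    mlp = list(hidden = 32L, epochs = 120L, lr = 0.05),
    naive_bayes = list(var_eps = 1e-6),
    svm = list(lambda = 1e-4, iters = 150L))
  if (!algorithm %in% names(known))
    stop_invalid("unknown algorithm '", algorithm, "'; known: ",
                 paste(names(known), collapse = ", "))
  params <- utils::modifyList(known[[algorithm]], list(...))
  extra <- setdiff(names(list(...)), names(known[[algorithm]]))
  if (length(extra))
    stop_invalid("unknown parameter(s) for ", algorithm, ": ",
                 paste(extra, collapse = ", "))
  structure(list(algorithm = algorithm, params = params),
            class = "classifier_spec")
}

#' Parse a one-line classifier declaration
#'
#' Format: `algorithm key=value ...`, e.g. `"knn k=3"` or
#' `"random_forest ntree=50"` (the plain-text `algorithms.txt` idiom).
#'
#' @param line a single declaration string
#' @return a `classifier_spec`
#' @export
parse_classifier_spec <- function(line) {
  parts <- strsplit(trimws(line), "\\s+")[[1L]]
  if (!length(parts)) stop_invalid("empty classifier declaration")
  kv <- list()
  for (p in parts[-1L]) {
    m <- strsplit(p, "=", fixed = TRUE)[[1L]]
    if (length(m) != 2L) stop_invalid("malformed parameter '", p, "'")
    num <- suppressWarnings(as.numeric(m[2L]))
    kv[[m[1L]]] <- if (is.na(num)) m[2L] else num
  }
  do.call(classifier_spec, c(list(algorithm = parts[1L]), kv))
}

#' Read classifier declarations from a text file
#'
#' One declaration per line; blank lines and `#` comments are skipped.
#'
#' @param path text file path
#' @return list of `classifier_spec`
#' @export
read_algorithms_txt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, parse_classifier_spec)
}

standardize_fit <- function(X) {
  center <- colMeans(X)
  scale <- sqrt(colMeans(sweep(X, 2L, center)^2))
  scale[scale == 0] <- 1
  list(center = center, scale = scale)
}

standardize_apply <- function(X, std) {
  sweep(sweep(X, 2L, std$center), 2L, std$scale, `/`)
}

#' Train a classifier
#'
#' @param spec a [classifier_spec()]
#' @param X numeric feature matrix (rows = instances)
#' @param y labels (character or factor); every class needs >= 1 example
#' @param seed integer seed given to stochastic algorithms
#' @return a `sign_model` carrying the spec, the class levels, the training
#'   standardization parameters and the feature-registry hash
#' @export
fit_classifier <- function(spec, X, y, seed = 1) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- as.matrix(X)
  y <- as.character(y)
  if (nrow(X) != length(y)) stop_invalid("nrow(X) must equal length(y)")
  classes <- sort(unique(y))
  if (length(classes) < 1L || any(table(y) < 1L))
    stop_invalid("every class needs at least one training example")
  std <- standardize_fit(X)
  Xs <- standardize_apply(X, std)
  yi <- match(y, classes)
  fit <- with_seed(seed, switch(
    spec$algorithm,
    knn = list(X = Xs, y = yi),
    random_forest = rf_fit(Xs, yi, length(classes), spec$params),
    mlp = mlp_fit(Xs, yi, length(classes), spec$params),
    naive_bayes = nb_fit(Xs, yi, length(classes), spec$params),
    svm = svm_fit(Xs, yi, length(classes), spec$params)))
  structure(list(spec = spec, classes = classes, std = std, fit = fit,
                 seed = seed, p = ncol(X),
                 registry_hash = fnv1a_hash(colnames(X) %||% character(0))),
            class = "sign_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-class probability predictions
#'
#' Rows are nonnegative and sum to 1; the argmax equals the plain class
#' prediction.
#'
#' @param model a `sign_model`
#' @param X feature matrix with the training feature dimension
#' @return matrix (instances x classes) with class column names
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "sign_model"))
  X <- as.matrix(X)
  if (ncol(X) != model$p)
    stop_invalid("feature dimension mismatch: model has ", model$p,
                 ", data has ", ncol(X))
  Xs <- standardize_apply(X, model$std)
  C <- length(model$classes)
  P <- switch(model$spec$algorithm,
              knn = knn_proba(model$fit, Xs, C, model$spec$params$k),
              random_forest = rf_proba(model$fit, Xs, C),
              mlp = mlp_proba(model$fit, Xs),
              naive_bayes = nb_proba(model$fit, Xs),
              svm = svm_proba(model$fit, Xs))
  colnames(P) <- model$classes
  P
}

#' @export
predict.sign_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  P <- predict_proba(object, newdata)
  if (type == "prob") return(P)
  tie <- attr(P, "tie_order")
  idx <- if (is.null(tie)) max.col(P, ties.method = "first") else tie
  object$classes[idx]
}

# --- k-nearest neighbours ---------------------------------------------------

knn_proba <- function(fit, Xs, C, k) {
  k <- as.integer(k)
  n_tr <- nrow(fit$X)
  k <- min(k, n_tr)
  # squared Euclidean distances, vectorised
  d2 <- outer(rowSums(Xs^2), rowSums(fit$X^2), `+`) - 2 * Xs %*% t(fit$X)
  P <- matrix(0, nrow(Xs), C)
  pick <- integer(nrow(Xs))
  for (i in seq_len(nrow(Xs))) {
    o <- order(d2[i, ])[seq_len(k)]
    votes <- tabulate(fit$y[o], C)
    P[i, ] <- votes / k
    top <- which(votes == max(votes))
    if (length(top) > 1L) {
      # tie-break: smallest mean distance to the tied class, then lowest index
      md <- vapply(top, function(cl) mean(d2[i, o[fit$y[o] == cl]]), 0)
      top <- top[order(md, top)]
    }
    pick[i] <- top[1L]
  }
  attr(P, "tie_order") <- pick
  P
}

# --- random forest ----------------------------------------------------------
#
# Bagged CART trees: each tree sees a bootstrap sample and, at every node,
# `mtry` randomly drawn features with quantile candidate thresholds scored
# by Gini impurity; trees grow to purity. Prediction averages leaf class
# frequencies over trees.

rf_fit <- function(Xs, yi, C, params) {
  p <- ncol(Xs)
  mtry <- params$mtry %||% max(1L, floor(sqrt(p)))
  mtry <- min(as.integer(mtry), p)
  ntree <- as.integer(params$ntree)
  nthr <- as.integer(params$n_thresholds)
  n <- nrow(Xs)
  trees <- vector("list", ntree)
  for (b in seq_len(ntree)) {
    boot <- sample.int(n, n, replace = TRUE)
    trees[[b]] <- grow_tree(Xs, yi, boot, C, mtry, nthr)
  }
  list(trees = trees, C = C)
}

grow_tree <- function(Xs, yi, idx, C, mtry, nthr) {
  nodes <- list()
  build <- function(idx) {
    yn <- yi[idx]
    counts <- tabulate(yn, C)
    n <- length(idx)
    me <- length(nodes) + 1L
    if (sum(counts > 0) == 1L || n < 2L) {
      nodes[[me]] <<- list(leaf = TRUE, prob = counts / sum(counts))
      return(me)
    }
    feats <- sample.int(ncol(Xs), mtry)
    best <- list(score = Inf)
    for (f in feats) {
      v <- Xs[idx, f]
      sv <- sort.int(v, method = "quick")
      if (sv[1L] == sv[n]) next
      thr <- unique(sv[unique(ceiling(seq_len(nthr) / (nthr + 1) * n))])
      for (t in thr) {
        left <- v <= t
        nl <- sum(left)
        if (nl == 0L || nl == n) next
        cl <- tabulate(yn[left], C)
        cr <- counts - cl
        # weighted Gini impurity of the two children
        sc <- (nl - sum(cl^2) / nl) + ((n - nl) - sum(cr^2) / (n - nl))
        if (sc < best$score) best <- list(score = sc, f = f, t = t, left = left)
      }
    }
    if (!is.finite(best$score)) {
      nodes[[me]] <<- list(leaf = TRUE, prob = counts / sum(counts))
      return(me)
    }
    nodes[[me]] <<- list(leaf = FALSE, f = best$f, t = best$t)
    nodes[[me]]$l <<- build(idx[best$left])
    nodes[[me]]$r <<- build(idx[!best$left])
    me
  }
  build(idx)
  nodes
}

tree_proba <- function(nodes, Xs, C) {
  n <- nrow(Xs)
  P <- matrix(0, n, C)
  assign_node <- function(node_id, rows) {
    nd <- nodes[[node_id]]
    if (nd$leaf) { P[rows, ] <<- matrix(nd$prob, length(rows), C, byrow = TRUE); return(invisible()) }
    left <- Xs[rows, nd$f] <= nd$t
    if (any(left)) assign_node(nd$l, rows[left])
    if (any(!left)) assign_node(nd$r, rows[!left])
  }
  assign_node(1L, seq_len(n))
  P
}

rf_proba <- function(fit, Xs, C) {
  P <- matrix(0, nrow(Xs), C)
  for (tr in fit$trees) P <- P + tree_proba(tr, Xs, C)
  P / length(fit$trees)
}

# --- multilayer perceptron --------------------------------------------------
#
# One hidden tanh layer, softmax output, cross-entropy loss, full-batch
# gradient descent with momentum.

mlp_fit <- function(Xs, yi, C, params) {
  p <- ncol(Xs); h <- as.integer(params$hidden)
  W1 <- matrix(rnorm(p * h, 0, 1 / sqrt(p)), p, h); b1 <- numeric(h)
  W2 <- matrix(rnorm(h * C, 0, 1 / sqrt(h)), h, C); b2 <- numeric(C)
  Y <- diag(C)[yi, , drop = FALSE]
  n <- nrow(Xs)
  lr <- params$lr; mom <- 0.9
  vW1 <- W1 * 0; vb1 <- b1; vW2 <- W2 * 0; vb2 <- b2
  for (ep in seq_len(as.integer(params$epochs))) {
    H <- tanh(sweep(Xs %*% W1, 2L, b1, `+`))
    Z <- sweep(H %*% W2, 2L, b2, `+`)
    Z <- Z - apply(Z, 1L, max)
    E <- exp(Z); Pm <- E / rowSums(E)
    dZ <- (Pm - Y) / n
    gW2 <- t(H) %*% dZ; gb2 <- colSums(dZ)
    dH <- dZ %*% t(W2) * (1 - H^2)
    gW1 <- t(Xs) %*% dH; gb1 <- colSums(dH)
    vW2 <- mom * vW2 - lr * gW2; W2 <- W2 + vW2
    vb2 <- mom * vb2 - lr * gb2; b2 <- b2 + vb2
    vW1 <- mom * vW1 - lr * gW1; W1 <- W1 + vW1
    vb1 <- mom * vb1 - lr * gb1; b1 <- b1 + vb1
  }
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

mlp_proba <- function(fit, Xs) {
  H <- tanh(sweep(Xs %*% fit$W1, 2L, fit$b1, `+`))
  Z <- sweep(H %*% fit$W2, 2L, fit$b2, `+`)
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# --- Gaussian naive Bayes ---------------------------------------------------

nb_fit <- function(Xs, yi, C, params) {
  mu <- rowsum(Xs, yi) / as.vector(table(factor(yi, levels = seq_len(C))))
  v <- rowsum(Xs^2, yi) / as.vector(table(factor(yi, levels = seq_len(C)))) - mu^2
  v <- pmax(v, params$var_eps)
  prior <- tabulate(yi, C) / length(yi)
  list(mu = mu, var = v, prior = prior)
}

nb_proba <- function(fit, Xs) {
  C <- nrow(fit$mu)
  LL <- vapply(seq_len(C), function(c) {
    -0.5 * rowSums(sweep(Xs, 2L, fit$mu[c, ])^2 / rep(fit$var[c, ],
                                                      each = nrow(Xs))) -
      0.5 * sum(log(2 * pi * fit$var[c, ])) + log(fit$prior[c])
  }, numeric(nrow(Xs)))
  LL <- matrix(LL, nrow = nrow(Xs))
  LL <- LL - apply(LL, 1L, max)
  E <- exp(LL)
  E / rowSums(E)
}

# --- linear SVM (one-vs-rest, batch subgradient) ----------------------------

svm_fit <- function(Xs, yi, C, params) {
  n <- nrow(Xs); p <- ncol(Xs)
  Y <- matrix(-1, n, C); Y[cbind(seq_len(n), yi)] <- 1
  W <- matrix(0, p, C); b <- numeric(C)
  lambda <- params$lambda
  for (it in seq_len(as.integer(params$iters))) {
    eta <- 1 / (lambda * (it + 10))
    M <- sweep(Xs %*% W, 2L, b, `+`) * Y
    viol <- M < 1
    G <- -t(Xs) %*% (Y * viol) / n + lambda * W
    gb <- -colSums(Y * viol) / n
    W <- W - eta * G
    b <- b - eta * gb
  }
  list(W = W, b = b)
}

svm_proba <- function(fit, Xs) {
  M <- sweep(Xs %*% fit$W, 2L, fit$b, `+`)
  M <- M - apply(M, 1L, max)
  E <- exp(M)
  E / rowSums(E)
}
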