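# Small separable playground used across classifier tests.
toy_data <- function(n_per = 10, C = 3, p = 6, sd = 0.1, seed = 101) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(C), function(cl) {
    m <- matrix(rnorm(n_per * p, mean = 0, sd = sd), n_per, p)
    m[, ((cl - 1L) %% p) + 1L] <- m[, ((cl - 1L) %% p) + 1L] + 4  # own axis
    m
  }))
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = rep(letters[seq_len(C)], each = n_per))
}

test_that("classifier specs validate algorithms and parameters", {
  expect_equal(classifier_spec("knn", k = 1)$params$k, 1)
  expect_error(classifier_spec("boosting"), "unknown algorithm")
  expect_error(classifier_spec("knn", trees = 5), "unknown parameter")
  sp <- parse_classifier_spec("knn k=3")
  expect_equal(sp$algorithm, "knn")
  expect_equal(sp$params$k, 3)
  f <- tempfile()
  writeLines(c("knn k=1", "", "# comment", "random_forest ntree=5"), f)
  specs <- read_algorithms_txt(f)
  expect_length(specs, 2L)
  expect_equal(specs[[2]]$algorithm, "random_forest")
})

test_that("fit/predict basics hold for every algorithm", {
  d <- toy_data()
  for (alg in c("knn", "random_forest", "mlp", "naive_bayes", "svm")) {
    spec <- if (alg == "knn") classifier_spec(alg, k = 1)
            else if (alg == "random_forest") classifier_spec(alg, ntree = 10)
            else classifier_spec(alg)
    m1 <- fit_classifier(spec, d$X, d$y, seed = 1)
    m2 <- fit_classifier(spec, d$X, d$y, seed = 1)
    p1 <- predict(m1, d$X)
    expect_identical(p1, predict(m2, d$X))  # determinism given seed
    P <- predict_proba(m1, d$X)
    expect_true(all(P >= 0))
    expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-9)
    # argmax of proba agrees with predict (modulo documented tie-breaks)
    expect_identical(signstream:::proba_to_class(m1, P), p1)
    expect_equal(mean(p1 == d$y), 1)  # separable training data
  }
  expect_error(fit_classifier(classifier_spec("knn"), d$X[1:5, ], d$y),
               "nrow")
})

test_that("knn k=1 returns one-hot rows and its own label on training points", {
  d <- toy_data()
  m <- fit_classifier(classifier_spec("knn", k = 1), d$X, d$y, seed = 1)
  P <- predict_proba(m, d$X)
  expect_true(all(P %in% c(0, 1)))
  expect_identical(predict(m, d$X), d$y)
  expect_error(predict_proba(m, d$X[, 1:3]), "dimension mismatch")
})

test_that("kappa matches the textbook formula", {
  perfect <- diag(5) * 10
  expect_equal(kappa_statistic(perfect), 1)
  # balanced 2-class truth, one-sided predictions
  one_sided <- matrix(c(50, 0, 50, 0), 2, 2, byrow = TRUE)
  expect_equal(kappa_statistic(one_sided), 0)
  expect_error(kappa_statistic(matrix(0, 2, 2)), "positive total")
  expect_error(kappa_statistic(matrix(1, 2, 3)), "square")
  set.seed(44)
  for (i in 1:100) {
    cm <- matrix(rpois(16, 5), 4, 4)
    if (sum(cm) == 0) next
    expect_equal(kappa_statistic(cm), oracle_kappa(cm), tolerance = 1e-12)
  }
})

test_that("probability RMSE matches its closed forms and a double loop", {
  P <- diag(4)[c(1, 2, 3, 4), ]
  colnames(P) <- letters[1:4]
  expect_equal(rmse_probability(P, letters[1:4]), 0)
  U <- matrix(0.5, 6, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(rmse_probability(U, rep(c("a", "b"), 3)), 0.5)
  # sqrt(C-1)/C for uniform rows in general
  for (C in 3:5) {
    U <- matrix(1 / C, 10, C, dimnames = list(NULL, letters[1:C]))
    expect_equal(rmse_probability(U, rep(letters[1], 10)), sqrt(C - 1) / C)
  }
  set.seed(45)
  for (i in 1:50) {
    Pm <- matrix(runif(30), 10, 3)
    Pm <- Pm / rowSums(Pm)
    colnames(Pm) <- letters[1:3]
    ti <- sample(1:3, 10, replace = TRUE)
    expect_equal(rmse_probability(Pm, letters[ti]), oracle_rmse(Pm, ti),
                 tolerance = 1e-12)
  }
})

test_that("cross-validation partitions the data and scores separable classes", {
  d <- toy_data(n_per = 12, C = 4)
  ev <- cross_validate(classifier_spec("knn", k = 1), d$X, d$y, k = 4,
                       seed = 2)
  folds <- attr(ev, "folds")
  expect_length(folds, length(d$y))
  expect_setequal(unique(folds), 1:4)
  # stratified: every class appears in every fold
  expect_true(all(table(d$y, folds) == 3))
  expect_equal(ev$accuracy, 100)
  expect_equal(ev$kappa, 1)
  expect_equal(sum(ev$confusion), length(d$y))
  expect_error(cross_validate(classifier_spec("knn"), d$X, d$y, k = 1), ">= 2")
})

test_that("label-shuffled data scores at chance", {
  set.seed(46)
  C <- 20; n_per <- 10
  X <- matrix(rnorm(C * n_per * 10), C * n_per, 10)
  y <- sample(rep(letters[1:C], n_per))
  ev <- cross_validate(classifier_spec("knn", k = 3), X, y, k = 5, seed = 3)
  expect_lt(ev$accuracy, 15)           # chance is 5%
  expect_lt(abs(ev$kappa), 0.1)
})

test_that("split protocol draws disjoint per-sign train/test sets", {
  d <- toy_data(n_per = 10, C = 3, sd = 0.05)
  ev <- split_evaluate(classifier_spec("knn", k = 1), d$X, d$y,
                       n_train = 9, n_test = 1, seed = 4)
  expect_equal(ev$accuracy, 100)
  tr <- attr(ev, "train_idx"); te <- attr(ev, "test_idx")
  expect_length(intersect(tr, te), 0L)
  for (cl in unique(d$y)) {
    expect_equal(sum(d$y[tr] == cl), 9)
    expect_equal(sum(d$y[te] == cl), 1)
  }
  expect_error(split_evaluate(classifier_spec("knn"), d$X, d$y,
                              n_train = 9, n_test = 5), "infeasible")
})

test_that("accuracy from the confusion matrix equals pooled accuracy", {
  d <- toy_data(n_per = 8, C = 3, sd = 2, seed = 9)  # overlapping classes
  ev <- cross_validate(classifier_spec("naive_bayes"), d$X, d$y, k = 4,
                       seed = 5)
  expect_equal(ev$accuracy, 100 * sum(diag(ev$confusion)) / sum(ev$confusion))
  expect_lte(ev$kappa, 1)
  expect_gte(ev$rmse, 0)
})
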