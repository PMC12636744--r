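# Small forests keep the suite fast; separability, not forest size, drives
# every assertion here.
fast_forest <- forest_settings(n_trees = 100)

signal_matrix <- function(n = 80, p = 60, k = 10, shift = 2, seed = 31) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("f%02d", 1:p)))
  X[, seq_len(k)] <- X[, seq_len(k)] + shift * y
  list(X = X, y = y)
}

test_that("ROC AUC follows the Mann-Whitney tie convention", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(0, 0, 1, 1)), 0)
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("Mann-Whitney AUC equals trapezoidal ROC integration", {
  trapezoid_auc <- function(scores, labels) {
    th <- sort(unique(scores), decreasing = TRUE)
    tpr <- c(0, vapply(th, function(t) mean(scores[labels == 1] >= t),
                       numeric(1)), 1)
    fpr <- c(0, vapply(th, function(t) mean(scores[labels == 0] >= t),
                       numeric(1)), 1)
    sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  }
  set.seed(32)
  for (i in 1:20) {
    n <- 30
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    scores <- round(runif(n), 2)  # force ties
    expect_equal(roc_auc(scores, labels), trapezoid_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("repeated CV separates planted signal and is deterministic", {
  dat <- signal_matrix()
  sch <- evaluation_scheme(folds = 5, repetitions = 3, seed = 1)
  cv <- repeated_cv(dat$X, dat$y, sch, fast_forest)
  expect_gte(min(cv$auc), 0.9)
  cv2 <- repeated_cv(dat$X, dat$y, sch, fast_forest)
  expect_identical(cv$auc, cv2$auc)
  expect_identical(cv$oof_scores, cv2$oof_scores)
})

test_that("permuted labels give chance-level AUC", {
  dat <- signal_matrix()
  set.seed(33)
  yperm <- sample(dat$y)
  cv <- repeated_cv(dat$X, yperm, evaluation_scheme(folds = 5,
                                                    repetitions = 5,
                                                    seed = 2), fast_forest)
  expect_gt(cv$mean_auc, 0.35); expect_lt(cv$mean_auc, 0.65)
})

test_that("stratification failure is reported with guidance", {
  dat <- signal_matrix(n = 20)
  y_rare <- c(rep(0L, 17), rep(1L, 3))
  expect_error(repeated_cv(dat$X, y_rare,
                           evaluation_scheme(folds = 10, repetitions = 1)),
               "fewer folds")
})

test_that("training-only ranking puts a perfectly separating feature first", {
  dat <- signal_matrix(p = 20, k = 0, shift = 0)
  X <- dat$X
  X[, "f07"] <- dat$y + rnorm(length(dat$y), 0, 0.01)
  rk <- rank_features_training_only(X, dat$y,
                                    evaluation_scheme(folds = 5,
                                                      repetitions = 2,
                                                      seed = 3),
                                    fast_forest)
  expect_identical(rk$feature[1], "f07")
  # order invariance under feature-column shuffling
  set.seed(34)
  rk2 <- rank_features_training_only(X[, sample(ncol(X))], dat$y,
                                     evaluation_scheme(folds = 5,
                                                       repetitions = 2,
                                                       seed = 3),
                                     fast_forest)
  expect_identical(rk2$feature[1], "f07")
})

test_that("top-k equal to all features reproduces plain CV", {
  dat <- signal_matrix(n = 40, p = 15, k = 5)
  sch_all <- evaluation_scheme(folds = 4, repetitions = 2, seed = 5)
  sch_topk <- evaluation_scheme(folds = 4, repetitions = 2, seed = 5,
                                top_k = 15)
  cv_plain <- repeated_cv(dat$X, dat$y, sch_all, fast_forest)
  cv_topk <- repeated_cv(dat$X, dat$y, sch_topk, fast_forest)
  expect_equal(cv_topk$auc, cv_plain$auc, tolerance = 1e-12)
  expect_error(repeated_cv(dat$X, dat$y,
                           evaluation_scheme(folds = 4, top_k = 99),
                           fast_forest),
               "top_k")
})

test_that("top-k selection finds planted taxa without leakage", {
  dat <- signal_matrix(n = 60, p = 80, k = 20, shift = 1.5)
  train <- 1:40; test <- 41:60
  res <- vaxbiome:::fit_score_split(dat$X, dat$y, train, test, fast_forest,
                                    top_k = 40, seed = 7)
  # leakage mutation: corrupt the test labels; nothing may change
  y_bad <- dat$y
  y_bad[test] <- 1L - y_bad[test]
  res_bad <- vaxbiome:::fit_score_split(dat$X, y_bad, train, test,
                                        fast_forest, top_k = 40, seed = 7)
  expect_identical(res$scores, res_bad$scores)
  expect_identical(res$importance, res_bad$importance)
})

test_that("LODO transfers signal across distribution-matched cohorts", {
  d1 <- signal_matrix(seed = 41); d2 <- signal_matrix(seed = 42)
  d3 <- signal_matrix(seed = 43)
  ds <- list(c1 = d1, c2 = d2, c3 = d3)
  aucs <- lodo(ds, fast_forest, seed = 8)
  expect_true(all(aucs >= 0.85))
  # permuted held-out labels: chance
  set.seed(44)
  d3p <- list(X = d3$X, y = sample(d3$y))
  aucp <- lodo(list(c1 = d1, c2 = d2, c3 = d3p), fast_forest, seed = 8)
  expect_gt(aucp["c3"], 0.3); expect_lt(aucp["c3"], 0.7)
  expect_error(lodo(list(c1 = d1), fast_forest), ">= 2 cohorts")
})

test_that("two-cohort LODO equals the off-diagonal matrix entries", {
  d1 <- signal_matrix(n = 40, seed = 45); d2 <- signal_matrix(n = 40, seed = 46)
  ds <- list(a = d1, b = d2)
  sch <- evaluation_scheme(folds = 4, repetitions = 2, seed = 9)
  cpm <- cross_prediction_matrix(ds, sch, fast_forest, seed = 10)
  aucs <- lodo(ds, fast_forest, seed = 10)
  expect_equal(unname(cpm$auc["LODO", ]), unname(aucs[colnames(cpm$auc)]))
  # with 2 cohorts, LODO trains on the single other cohort = off-diagonal
  expect_equal(unname(cpm$auc["LODO", "b"]), unname(cpm$auc["a", "b"]))
  expect_equal(unname(cpm$auc["LODO", "a"]), unname(cpm$auc["b", "a"]))
  expect_true(all(cpm$auc >= 0 & cpm$auc <= 1))
  expect_identical(dim(cpm$auc), c(4L, 2L))
})

test_that("X-LODO with a single cohort degenerates to plain CV", {
  dat <- signal_matrix(n = 40, p = 20)
  sch <- evaluation_scheme(folds = 4, repetitions = 2, seed = 11)
  xl <- xlodo(list(only = dat), sch, fast_forest)
  cv <- repeated_cv(dat$X, dat$y, sch, fast_forest)
  expect_identical(xl$only$auc, cv$auc)
  expect_identical(xl$only$oof_scores, cv$oof_scores)
})

test_that("cohorts with disjoint extra features harmonize by union", {
  d1 <- signal_matrix(n = 40, p = 20, seed = 47)
  d2 <- signal_matrix(n = 40, p = 20, seed = 48)
  colnames(d2$X)[20] <- "only_in_2"
  aucs <- lodo(list(a = d1, b = d2), fast_forest, seed = 12)
  expect_length(aucs, 2)
  expect_error(
    lodo(list(a = list(X = matrix(1, 4, 2,
                                  dimnames = list(NULL, c("u", "v"))),
                       y = c(0, 1, 0, 1)),
              b = list(X = matrix(1, 4, 2,
                                  dimnames = list(NULL, c("w", "x"))),
                       y = c(0, 1, 0, 1))),
         fast_forest, harmonize = "intersection"),
    "no shared features")
})
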