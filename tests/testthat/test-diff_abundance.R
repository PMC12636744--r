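test_that("gamma GLM two-group contrast equals log ratio of group means", {
  # {1,2,3} vs {2,4,6}: indicator is 1 for cluster 0, so put the doubled
  # group in cluster 0 to get +log 2
  y <- c(1, 2, 3, 2, 4, 6)
  cl <- c(1, 1, 1, 0, 0, 0)
  fit <- fit_gamma_glm(y, cl)
  expect_equal(fit$coefficient, log(2), tolerance = 1e-8)
  # equal group means -> zero coefficient
  fit0 <- fit_gamma_glm(c(1, 2, 3, 3, 2, 1), cl)
  expect_equal(fit0$coefficient, 0, tolerance = 1e-8)
})

test_that("closed-form identity holds over random two-group instances", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(6:30, 1)
    cl <- rbinom(n, 1, 0.5)
    if (length(unique(cl)) < 2) next
    y <- rgamma(n, shape = 2, rate = 0.5)
    fit <- fit_gamma_glm(y, cl)
    expect_equal(fit$coefficient, log(mean(y[cl == 0]) / mean(y[cl == 1])),
                 tolerance = 1e-6)
  }
})

test_that("gamma fit agrees with stats::glm including covariates", {
  set.seed(12)
  n <- 60
  cl <- rbinom(n, 1, 0.5)
  age <- runif(n, 20, 70)
  sex <- rbinom(n, 1, 0.5)
  y <- rgamma(n, shape = 3,
              rate = 3 / exp(0.5 * (cl == 0) + 0.01 * age + 0.2 * sex))
  fit <- fit_gamma_glm(y, cl, data.frame(age = age, sex = sex))
  ref <- stats::glm(y ~ I(cl == 0) + age + sex, family = Gamma(link = "log"),
                    control = stats::glm.control(epsilon = 1e-12))
  expect_equal(fit$coefficient, unname(coef(ref)[2]), tolerance = 1e-6)
  expect_equal(fit$std_error,
               unname(summary(ref)$coefficients[2, 2]), tolerance = 1e-4)
})

test_that("multiplying responses by a constant shifts only the intercept", {
  set.seed(13)
  y <- rgamma(40, 2, 1)
  cl <- rep(c(0, 1), 20)
  f1 <- fit_gamma_glm(y, cl)
  f2 <- fit_gamma_glm(y * 7.3, cl)
  expect_equal(f2$coefficient, f1$coefficient, tolerance = 1e-7)
  expect_equal(unname(f2$coefficients[1] - f1$coefficients[1]), log(7.3),
               tolerance = 1e-7)
})

test_that("gamma Wald intervals are calibrated on planted effects", {
  set.seed(14)
  reps <- 200
  est <- se <- numeric(reps)
  for (i in seq_len(reps)) {
    n <- 200
    cl <- rep(c(0, 1), each = n / 2)
    mu <- exp(1.0 * (cl == 0))
    y <- rgamma(n, shape = 5, rate = 5 / mu)
    f <- fit_gamma_glm(y, cl)
    est[i] <- f$coefficient; se[i] <- f$std_error
  }
  expect_equal(mean(est), 1.0, tolerance = 0.05)
  cover <- mean(abs(est - 1.0) < 1.96 * se)
  expect_gt(cover, 0.90); expect_lt(cover, 0.99)
})

test_that("negative-binomial fit matches the log mean ratio and MASS", {
  fit <- fit_negbin_glm(c(2, 4, 6, 4, 8, 12), c(1, 1, 1, 0, 0, 0))
  expect_equal(fit$coefficient, log(2), tolerance = 1e-6)

  skip_if_not_installed("MASS")
  set.seed(15)
  n <- 100
  cl <- rep(c(0, 1), each = 50)
  y <- rnbinom(n, size = 3, mu = exp(3 + 0.7 * (cl == 0)))
  fit2 <- fit_negbin_glm(y, cl)
  ref <- MASS::glm.nb(y ~ I(cl == 0))
  expect_equal(fit2$coefficient, unname(coef(ref)[2]), tolerance = 1e-4)
  expect_equal(fit2$theta, ref$theta, tolerance = 1e-2)
})

test_that("negbin collapses to Poisson when dispersion vanishes", {
  set.seed(16)
  n <- 150
  cl <- rep(c(0, 1), length.out = n)
  y <- rpois(n, lambda = exp(2 + 0.5 * (cl == 0)))
  fit <- fit_negbin_glm(y, cl)
  ref <- stats::glm(y ~ I(cl == 0), family = poisson())
  expect_equal(fit$coefficient, unname(coef(ref)[2]), tolerance = 1e-4)
})

test_that("degenerate groups are rejected with a reason", {
  expect_error(fit_negbin_glm(c(0, 0, 0, 5, 6, 7), c(1, 1, 1, 0, 0, 0)),
               "degenerate group")
  expect_error(fit_gamma_glm(c(0, 1, 2), c(0, 1, 0)), "strictly positive")
})

test_that("BY step-up matches the hand formula and p.adjust", {
  expect_equal(by_fdr(0.05), 0.05)          # m = 1 -> q = p
  expect_equal(by_fdr(c(0.01, 0.02, 0.03)), rep(0.055, 3), tolerance = 1e-12)
  set.seed(17)
  for (i in 1:20) {
    p <- runif(sample(2:200, 1))
    q <- by_fdr(p)
    expect_equal(q, p.adjust(p, method = "BY"), tolerance = 1e-12)
    expect_true(all(q >= p.adjust(p, method = "BH") - 1e-12))
    # monotone in p and order-invariant
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
    perm <- sample(length(p))
    expect_equal(by_fdr(p[perm]), q[perm], tolerance = 1e-12)
  }
  expect_error(by_fdr(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("run_per_feature recovers planted taxa with correct signs", {
  spec <- small_spec(n_taxa = 120, n_signal_taxa = 10,
                     log_fold_change = 1.5, n_samples_per_cohort = 120,
                     n_cohorts = 1, cohort_batch_sd = 0)
  set <- simulate_cohort_set(spec)
  res <- run_per_feature(set$abundance$cohort1, set$metadata$cohort1)
  truth <- set$truth$signal_taxa
  hit <- res[res$feature_id %in% names(truth), ]
  # planted effect raises cluster-1 abundance => negative coefficient
  expect_gt(mean(hit$q_value < 0.2 &
                   sign(hit$coefficient) == -sign(truth[hit$feature_id])),
            0.8)
  called <- res$feature_id[res$q_value < 0.2]
  fdr <- mean(!called %in% names(truth))
  expect_lt(fdr, 0.25)
  # q-values monotone in p within the cohort
  o <- order(res$p_value)
  expect_true(all(diff(res$q_value[o]) >= -1e-12))
})

test_that("null data yields almost no BY discoveries", {
  spec <- small_spec(n_taxa = 150, n_signal_taxa = 0,
                     n_samples_per_cohort = 80, n_cohorts = 1)
  set <- simulate_cohort_set(spec)
  res <- run_per_feature(set$abundance$cohort1, set$metadata$cohort1)
  expect_lte(sum(res$q_value < 0.2), 2)
})

test_that("prevalence filter skips sparse features with a reason", {
  spec <- small_spec(n_taxa = 30, n_samples_per_cohort = 30, n_cohorts = 1,
                     zero_inflation = 0)
  set <- simulate_cohort_set(spec)
  tab <- set$abundance$cohort1
  tab$values[, 1] <- 0
  tab$values[6:30, 2] <- 0  # present in 5 samples but check per-cluster
  res <- run_per_feature(tab, set$metadata$cohort1)
  skipped <- attr(res, "skipped")
  expect_true(tab$taxon_ids[1] %in% names(skipped))
  expect_match(unname(skipped[tab$taxon_ids[1]]), "prevalence")
  expect_false(tab$taxon_ids[1] %in% res$feature_id)
})

test_that("single tested feature gets q equal to p", {
  spec <- small_spec(n_taxa = 5, n_samples_per_cohort = 30, n_cohorts = 1,
                     zero_inflation = 0, n_signal_taxa = 0)
  set <- simulate_cohort_set(spec)
  tab <- set$abundance$cohort1
  tab$values[, 2:5] <- 0  # only one feature survives the filter
  res <- run_per_feature(tab, set$metadata$cohort1)
  expect_identical(nrow(res), 1L)
  expect_equal(res$q_value, res$p_value)
})
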