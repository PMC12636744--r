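## Random-effects meta-analysis: inverse-variance pooling with Paule-Mandel
## between-cohort variance, features pooled when fitted in >= 2 cohorts,
## Benjamini-Yekutieli adjustment over all pooled features.

pm_qgen <- function(tau2, y, se2) {
  w <- 1 / (se2 + tau2)
  yw <- sum(w * y) / sum(w)
  sum(w * (y - yw)^2)
}

#' Paule-Mandel between-study variance
#'
#' Solves `Q_gen(tau2) = sum w_i(tau2) (y_i - y_bar_w(tau2))^2 = k - 1` with
#' `w_i = 1/(se_i^2 + tau2)` by bisection (Q_gen is monotone decreasing in
#' tau2, so bisection on `[0, 10 x DerSimonian-Laird]` always converges);
#' returns 0 when `Q_gen(0) <= k - 1`.
#'
#' @param effects per-cohort effect estimates (length k >= 2).
#' @param std_errors their standard errors (> 0).
#' @param tol bisection tolerance, default 1e-8.
#' @return tau-squared (>= 0).
#' @export
paule_mandel_tau2 <- function(effects, std_errors, tol = 1e-8) {
  k <- length(effects)
  if (k < 2) stop("need >= 2 cohorts", call. = FALSE)
  if (length(std_errors) != k || any(std_errors <= 0)) {
    stop("std_errors must be positive and match effects", call. = FALSE)
  }
  se2 <- std_errors^2
  target <- k - 1
  if (pm_qgen(0, effects, se2) <= target) return(0)
  ## DL estimate for the upper bracket
  w0 <- 1 / se2
  q0 <- pm_qgen(0, effects, se2)
  c0 <- sum(w0) - sum(w0^2) / sum(w0)
  dl <- max((q0 - target) / c0, 1e-8)
  hi <- dl * 10
  while (pm_qgen(hi, effects, se2) > target) hi <- hi * 10
  lo <- 0
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (pm_qgen(mid, effects, se2) > target) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' Inverse-variance random-effects pooling
#'
#' Weights `w_i = 1/(se_i^2 + tau2)` with tau2 from [paule_mandel_tau2()];
#' pooled effect `sum(w y)/sum(w)`, pooled SE `(sum w)^(-1/2)`, two-sided
#' normal z test (no small-sample adjustment, matching a plain z synthesis).
#'
#' @inheritParams paule_mandel_tau2
#' @return List: `pooled_coefficient`, `pooled_se`, `tau2`, `z`, `p_value`,
#'   `k`.
#' @export
pool_random_effects <- function(effects, std_errors) {
  tau2 <- paule_mandel_tau2(effects, std_errors)
  w <- 1 / (std_errors^2 + tau2)
  pooled <- sum(w * effects) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- pooled / se
  list(pooled_coefficient = pooled, pooled_se = se, tau2 = tau2, z = z,
       p_value = 2 * pnorm(-abs(z)), k = length(effects))
}

#' Meta-analyze per-cohort feature associations
#'
#' Pools, feature by feature, the regression coefficients of every feature
#' successfully fitted in at least `min_cohorts` cohorts; features below the
#' threshold are reported in the `excluded` attribute. Benjamini-Yekutieli
#' adjustment is applied over all pooled features.
#'
#' @param per_cohort list of per-cohort data.frames from
#'   [run_per_feature()].
#' @param min_cohorts minimum number of cohorts a feature must be fitted in
#'   (default 2).
#' @return data.frame of class `meta_result` (`feature_id`,
#'   `pooled_coefficient`, `pooled_se`, `tau2`, `z`, `p_value`, `q_value`,
#'   `k`), with attributes `excluded` and `per_cohort` (long echo of the
#'   pooled inputs).
#' @export
meta_analyze <- function(per_cohort, min_cohorts = 2) {
  stopifnot(is.list(per_cohort), length(per_cohort) >= 1)
  long <- do.call(rbind, per_cohort)
  counts <- table(long$feature_id)
  poolable <- names(counts)[counts >= min_cohorts]
  excluded <- setdiff(names(counts), poolable)
  if (!length(poolable)) {
    warning("no features fitted in >= min_cohorts cohorts", call. = FALSE)
    out <- data.frame(feature_id = character(0),
                      pooled_coefficient = numeric(0), pooled_se = numeric(0),
                      tau2 = numeric(0), z = numeric(0), p_value = numeric(0),
                      q_value = numeric(0), k = integer(0))
    attr(out, "excluded") <- excluded
    return(out)
  }
  rows <- lapply(sort(poolable), function(f) {
    sub <- long[long$feature_id == f, , drop = FALSE]
    pl <- pool_random_effects(sub$coefficient, sub$std_error)
    data.frame(feature_id = f, pooled_coefficient = pl$pooled_coefficient,
               pooled_se = pl$pooled_se, tau2 = pl$tau2, z = pl$z,
               p_value = pl$p_value, k = pl$k, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- by_fdr(out$p_value)
  out <- out[, c("feature_id", "pooled_coefficient", "pooled_se", "tau2",
                 "z", "p_value", "q_value", "k")]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "per_cohort") <- long[long$feature_id %in% poolable, ,
                                  drop = FALSE]
  class(out) <- c("meta_result", "data.frame")
  out
}

#' Forest-plot-ready long format of a meta-analysis
#'
#' One row per (feature, cohort) estimate plus a pooled row per feature.
#'
#' @param meta a `meta_result` from [meta_analyze()].
#' @return A long data.frame with `feature_id`, `source`, `coefficient`,
#'   `std_error`.
#' @export
forest_table <- function(meta) {
  per <- attr(meta, "per_cohort")
  rbind(
    data.frame(feature_id = per$feature_id, source = per$cohort,
               coefficient = per$coefficient, std_error = per$std_error),
    data.frame(feature_id = meta$feature_id, source = "pooled",
               coefficient = meta$pooled_coefficient,
               std_error = meta$pooled_se)
  )
}
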