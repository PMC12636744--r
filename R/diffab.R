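## Per-feature differential abundance: log-link gamma regression for relative
## abundances, log-link negative-binomial regression for RPK counts. Both
## fitters are in-package IRLS implementations (the closed-form two-group
## identity and external GLM fits serve as test oracles, not as the engine).

## IRLS for a log-link GLM. For the gamma family with log link the working
## weights are identically 1; for NB2 they are mu / (1 + mu/theta).
irls_loglink <- function(y, X, weight_fun, tol = 1e-8, max_iter = 100L) {
  ## start from log of response (floored) regressed on X
  eta <- log(pmax(y, min(y[y > 0]) / 2))
  beta <- qr.coef(qr(X), eta)
  if (anyNA(beta)) stop("rank-deficient design", call. = FALSE)
  dev_old <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    w <- weight_fun(mu)
    z <- eta + (y - mu) / mu
    fit <- lm.wfit(X, z, w)
    beta_new <- fit$coefficients
    if (anyNA(beta_new)) stop("rank-deficient design", call. = FALSE)
    crit <- max(abs(beta_new - beta)) / max(1, max(abs(beta)))
    beta <- beta_new
    if (crit < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  mu <- exp(eta)
  list(beta = beta, mu = mu, W = weight_fun(mu), converged = converged)
}

glm_wald <- function(fit, X, dispersion = 1) {
  XtWX <- crossprod(X * sqrt(fit$W))
  cov <- tryCatch(solve(XtWX) * dispersion, error = function(e) NULL)
  if (is.null(cov)) return(NULL)
  se <- sqrt(diag(cov))
  z <- fit$beta / se
  list(se = se, z = z, p = 2 * pnorm(-abs(z)))
}

build_design <- function(cluster, covariates = NULL) {
  ## indicator = 1 for cluster 0 (non-reactive), so a taxon enriched in the
  ## reactive cluster 1 gets a negative coefficient, matching the reported
  ## sign convention.
  ind <- as.numeric(cluster == 0)
  X <- cbind(`(Intercept)` = 1, cluster0 = ind)
  if (!is.null(covariates) && ncol(covariates)) {
    for (nm in colnames(covariates)) {
      v <- covariates[, nm]
      if (is.character(v) || is.factor(v)) {
        v <- as.numeric(factor(v)) - 1
      }
      X <- cbind(X, setNames(list(v), nm)[[1]])
      colnames(X)[ncol(X)] <- nm
    }
  }
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design", call. = FALSE)
  X
}

#' Fit a log-link gamma GLM for one feature
#'
#' Maximum-likelihood IRLS fit of a gamma-family GLM with logarithmic link;
#' the coefficient of the cluster indicator (coded 1 for cluster 0) is the
#' effect size. Standard errors come from the expected information at
#' convergence scaled by the Pearson dispersion estimate; p-values are
#' two-sided Wald.
#'
#' @param y strictly positive response (relative abundances after zero
#'   handling).
#' @param cluster 0/1 cluster labels.
#' @param covariates optional data.frame/matrix of adjustment covariates
#'   (e.g. age, sex).
#' @return List: `coefficient`, `std_error`, `p_value`, `z`, `converged`,
#'   plus the full coefficient vector.
#' @export
fit_gamma_glm <- function(y, cluster, covariates = NULL) {
  if (any(y <= 0)) stop("gamma response must be strictly positive",
                        call. = FALSE)
  X <- build_design(cluster, covariates)
  fit <- irls_loglink(y, X, weight_fun = function(mu) rep(1, length(mu)))
  phi <- sum(((y - fit$mu) / fit$mu)^2) / (length(y) - ncol(X))
  wald <- glm_wald(fit, X, dispersion = phi)
  if (is.null(wald)) stop("singular information matrix", call. = FALSE)
  list(coefficient = unname(fit$beta["cluster0"]),
       std_error = unname(wald$se[2]), z = unname(wald$z[2]),
       p_value = unname(wald$p[2]), converged = fit$converged,
       coefficients = fit$beta, dispersion = phi, model = "gamma")
}

## Profile log-likelihood in theta for NB2 given mu
nb_theta_loglik <- function(log_theta, y, mu) {
  th <- exp(log_theta)
  sum(lgamma(y + th) - lgamma(th) - lgamma(y + 1) +
        th * log(th / (th + mu)) + y * log(mu / (th + mu) + (y == 0)))
}

#' Fit a log-link negative-binomial GLM for one feature
#'
#' Alternates IRLS for the regression coefficients with per-feature maximum
#' likelihood for the dispersion (theta on a log grid via `optimize`). When
#' the dispersion estimate hits its upper bound (Poisson limit) the fit falls
#' back to Poisson weights. Responses are rounded to the nearest integer
#' (RPKs are continuous; the count model requires integers).
#'
#' @inheritParams fit_gamma_glm
#' @param y non-negative count-like response.
#' @return As [fit_gamma_glm()], plus `theta`.
#' @export
fit_negbin_glm <- function(y, cluster, covariates = NULL) {
  y <- round(y)
  if (any(y < 0)) stop("negative counts", call. = FALSE)
  for (g in c(0, 1)) {
    if (all(y[cluster == g] == 0)) {
      stop("degenerate group: all-zero response in one cluster", call. = FALSE)
    }
  }
  X <- build_design(cluster, covariates)
  theta <- 10
  fit <- NULL
  for (outer in 1:25) {
    wf <- function(mu) mu / (1 + mu / theta)
    fit <- irls_loglink(y, X, weight_fun = wf)
    opt <- stats::optimize(nb_theta_loglik, c(log(1e-3), log(1e7)),
                           y = y, mu = fit$mu, maximum = TRUE, tol = 1e-10)
    theta_new <- exp(opt$maximum)
    if (abs(log(theta_new) - log(theta)) < 1e-6) { theta <- theta_new; break }
    theta <- theta_new
  }
  poisson_limit <- theta > 1e5
  if (poisson_limit) {
    fit <- irls_loglink(y, X, weight_fun = function(mu) mu)
  }
  wald <- glm_wald(fit, X, dispersion = 1)
  if (is.null(wald)) stop("singular information matrix", call. = FALSE)
  list(coefficient = unname(fit$beta["cluster0"]),
       std_error = unname(wald$se[2]), z = unname(wald$z[2]),
       p_value = unname(wald$p[2]), converged = fit$converged,
       coefficients = fit$beta, theta = theta,
       poisson_fallback = poisson_limit, model = "negbin")
}

#' Benjamini-Yekutieli step-up q-values
#'
#' `q_(i) = min_{j >= i} min(1, p_(j) * m * H(m) / j)` with
#' `H(m) = sum_{k=1..m} 1/k`; valid under arbitrary dependence, always at
#' least as conservative as Benjamini-Hochberg.
#'
#' @param p_values numeric vector in `[0,1]`.
#' @return q-values in the input order.
#' @export
by_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1) || anyNA(p_values)) {
    stop("p-values must lie in [0,1]", call. = FALSE)
  }
  m <- length(p_values)
  if (m == 0) return(numeric(0))
  hm <- sum(1 / seq_len(m))
  o <- order(p_values)
  q_sorted <- pmin(1, p_values[o] * m * hm / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Differential abundance across every feature of a table
#'
#' Fits one model per feature (gamma on relative abundances, negative
#' binomial on RPK counts), adjusting for the requested covariates, and
#' attaches Benjamini-Yekutieli q-values computed over the features actually
#' tested in the cohort. Features failing the prevalence filter (detected in
#' fewer than `min_prevalence` samples overall or fewer than
#' `min_per_cluster` per cluster) or whose fit fails are reported in the
#' `skipped` attribute with a reason. For the gamma model, zeros are replaced
#' by half the smallest nonzero value of that feature within the cohort.
#'
#' @param table an [abundance_table()] (gamma) or [gene_family_table()]
#'   (negbin).
#' @param metadata a [covariate_table()] covering every sample.
#' @param cluster named 0/1 vector or the name of a metadata column.
#' @param model `"gamma"` or `"negbin"` (default chosen from the table
#'   class).
#' @param covariates character vector of metadata columns to adjust for
#'   (default `c("age","sex")`).
#' @param min_prevalence,min_per_cluster prevalence filter.
#' @param cohort cohort label recorded in the result.
#' @return data.frame of feature associations (`feature_id`, `coefficient`,
#'   `std_error`, `p_value`, `q_value`, `n_used`, prevalences, `cohort`,
#'   `model`), ordered by feature id, with attribute `skipped`.
#' @export
run_per_feature <- function(table, metadata, cluster = "cluster",
                            model = NULL,
                            covariates = c("age", "sex"),
                            min_prevalence = 5, min_per_cluster = 2,
                            cohort = "cohort1") {
  model <- model %||% if (inherits(table, "gene_family_table")) "negbin" else "gamma"
  model <- match.arg(model, c("gamma", "negbin"))
  md <- align_metadata(table, metadata, require = covariates)
  if (is.character(cluster) && length(cluster) == 1) {
    if (!cluster %in% names(md)) {
      stop(sprintf("metadata has no '%s' column", cluster), call. = FALSE)
    }
    cl <- md[[cluster]]
  } else {
    cl <- cluster[table$sample_ids]
  }
  if (!all(cl %in% c(0, 1))) stop("cluster labels must be 0/1", call. = FALSE)
  covs <- if (length(covariates)) md[, covariates, drop = FALSE] else NULL
  vals <- table$values
  features <- colnames(vals)
  res <- vector("list", length(features))
  skipped <- character(0)
  for (fi in seq_along(features)) {
    f <- features[fi]
    y <- vals[, f]
    present <- y > 0
    if (sum(present) < min_prevalence ||
        sum(present & cl == 0) < min_per_cluster ||
        sum(present & cl == 1) < min_per_cluster) {
      skipped[f] <- "prevalence filter"
      next
    }
    fit <- tryCatch({
      if (model == "gamma") {
        y2 <- y
        y2[y2 == 0] <- min(y2[y2 > 0]) / 2
        fit_gamma_glm(y2, cl, covs)
      } else {
        fit_negbin_glm(y, cl, covs)
      }
    }, error = function(e) conditionMessage(e))
    if (is.character(fit)) { skipped[f] <- fit; next }
    if (!fit$converged) { skipped[f] <- "non-convergence"; next }
    res[[fi]] <- data.frame(
      feature_id = f, coefficient = fit$coefficient,
      std_error = fit$std_error, p_value = fit$p_value,
      n_used = length(y),
      prevalence_cluster0 = mean(present[cl == 0]),
      prevalence_cluster1 = mean(present[cl == 1]),
      cohort = cohort, model = model, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out) || !nrow(out)) {
    out <- data.frame(feature_id = character(0), coefficient = numeric(0),
                      std_error = numeric(0), p_value = numeric(0),
                      q_value = numeric(0), n_used = integer(0),
                      prevalence_cluster0 = numeric(0),
                      prevalence_cluster1 = numeric(0),
                      cohort = character(0), model = character(0))
  } else {
    out$q_value <- by_fdr(out$p_value)
    out <- out[, c("feature_id", "coefficient", "std_error", "p_value",
                   "q_value", "n_used", "prevalence_cluster0",
                   "prevalence_cluster1", "cohort", "model")]
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
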