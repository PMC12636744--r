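# Shared fixture builders. Everything is generated in code at test time.

small_spec <- function(...) {
  args <- modifyList(list(
    n_cohorts = 2, n_samples_per_cohort = 40, n_taxa = 60,
    n_signal_taxa = 8, log_fold_change = 1.0, responder_fraction = 0.5,
    zero_inflation = 0.2, cohort_batch_sd = 0.3, gamma_shape = 2,
    n_cytokines = 12, responder_fold = 8, seed = 42L), list(...))
  do.call(simulation_spec, args)
}

# A hand-written MetaPhlAn-style merged TSV exercising the dialect:
# comments, multi-rank rows, SGB terminal rows, unclassified mass.
write_metaphlan_fixture <- function(path, sums100 = TRUE) {
  s <- if (sums100) c(60, 40, 70, 30) else c(57, 38, 66.5, 28.5)
  lines <- c(
    "#mpa_vJan21 synthetic fixture",
    paste(c("clade_name", "sampleA", "sampleB"), collapse = "\t"),
    paste(c("k__Bacteria", 100, 100), collapse = "\t"),
    paste(c("k__Bacteria|p__Firmicutes", 100, 100), collapse = "\t"),
    paste(c("k__Bacteria|p__Firmicutes|c__C|o__O|f__F|g__G|s__Faecalibacterium_prausnitzii",
            s[1], s[3]), collapse = "\t"),
    paste(c("k__Bacteria|p__Firmicutes|c__C|o__O|f__F|g__G|s__Faecalibacterium_prausnitzii|t__SGB15322",
            s[1], s[3]), collapse = "\t"),
    paste(c("k__Bacteria|p__Firmicutes|c__C|o__O|f__F|g__G2|s__Dorea_longicatena",
            s[2], s[4]), collapse = "\t"),
    paste(c("k__Bacteria|p__Firmicutes|c__C|o__O|f__F|g__G2|s__Dorea_longicatena|t__SGB4571",
            s[2], s[4]), collapse = "\t")
  )
  writeLines(lines, path)
  path
}

# Two-block binary call matrix with optional flip noise: the reactive
# cluster is positive on a broad (Th1-like) analyte block, the non-reactive
# cluster on a small disjoint (inflammatory) block, mirroring the
# polyreactive-vs-background structure the clustering consumes.
planted_calls <- function(n = 20, k = 8, flip = 0, seed = 1) {
  set.seed(seed)
  truth <- rep(c(1L, 0L), length.out = n)
  m <- matrix(0L, n, k,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("a%02d", 1:k)))
  broad <- seq_len(ceiling(0.6 * k))
  narrow <- seq(max(broad) + 1, k)
  m[truth == 1L, broad] <- 1L
  m[truth == 0L, narrow[seq_len(max(1, floor(length(narrow) / 2)))]] <- 1L
  if (flip > 0) {
    idx <- which(matrix(runif(n * k) < flip, n, k))
    m[idx] <- 1L - m[idx]
  }
  list(calls = m, truth = truth)
}

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# Independent ML oracle for the gamma log-link GLM: maximize the
# shape-profiled log-likelihood (beta MLE does not depend on the shape).
gamma_glm_oracle <- function(y, X) {
  nll <- function(beta) {
    mu <- exp(drop(X %*% beta))
    sum(y / mu + log(mu))
  }
  start <- qr.coef(qr(X), log(y))
  opt <- optim(start, nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  opt$par
}
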