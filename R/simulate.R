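## Synthetic multi-cohort generator. The stated world: zero-inflated
## compositional abundance profiles with planted cluster-associated taxa,
## per-cohort batch effects on the log scale, covariates, and cytokine panels
## with planted responder structure. Everything is driven by one seed so a
## SimulationSpec maps to bit-identical output.

#' Define a synthetic multi-cohort simulation
#'
#' @param n_cohorts,n_samples_per_cohort,n_taxa,n_signal_taxa counts (>= 1;
#'   `n_signal_taxa <= n_taxa`, may be 0).
#' @param log_fold_change natural-log scale effect of the reactive cluster on
#'   signal-taxon mean abundance (applied before compositional closure).
#' @param responder_fraction fraction of samples in the reactive cluster,
#'   strictly inside (0,1).
#' @param zero_inflation probability in `[0,1)` that a taxon is absent from a
#'   sample.
#' @param cohort_batch_sd SD (log scale) of per-cohort, per-taxon offsets.
#' @param gamma_shape shape of the per-sample gamma noise on taxon means.
#' @param n_cytokines number of analytes in the synthetic panel.
#' @param responder_fold expected stimulated/control ratio of responders on
#'   the Th1 analyte subset; must exceed 2, the positivity rule's ratio cut.
#' @param sex_cluster_log_odds optional log-odds linking sex to cluster, to
#'   exercise confounder adjustment (default 0 = independent).
#' @param seed integer seed; identical specs give identical outputs.
#' @return A validated list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_cohorts = 3, n_samples_per_cohort = 60,
                            n_taxa = 300, n_signal_taxa = 20,
                            log_fold_change = 1.0, responder_fraction = 0.5,
                            zero_inflation = 0.3, cohort_batch_sd = 0.5,
                            gamma_shape = 2, n_cytokines = 27,
                            responder_fold = 8, sex_cluster_log_odds = 0,
                            seed = 1L) {
  spec <- list(
    n_cohorts = n_cohorts, n_samples_per_cohort = n_samples_per_cohort,
    n_taxa = n_taxa, n_signal_taxa = n_signal_taxa,
    log_fold_change = log_fold_change,
    responder_fraction = responder_fraction,
    zero_inflation = zero_inflation, cohort_batch_sd = cohort_batch_sd,
    gamma_shape = gamma_shape, n_cytokines = n_cytokines,
    responder_fold = responder_fold,
    sex_cluster_log_odds = sex_cluster_log_odds,
    seed = as.integer(seed)
  )
  counts <- c("n_cohorts", "n_samples_per_cohort", "n_taxa", "n_cytokines")
  for (f in counts) {
    v <- spec[[f]]
    if (length(v) != 1 || !is.finite(v) || v < 1 || v != round(v)) {
      stop_field(f, "must be a count >= 1")
    }
  }
  v <- spec$n_signal_taxa
  if (length(v) != 1 || !is.finite(v) || v < 0 || v != round(v)) {
    stop_field("n_signal_taxa", "must be a count >= 0")
  }
  if (spec$n_signal_taxa > spec$n_taxa) {
    stop_field("n_signal_taxa", "cannot exceed n_taxa")
  }
  if (spec$responder_fraction <= 0 || spec$responder_fraction >= 1) {
    stop_field("responder_fraction", "must be strictly inside (0,1)")
  }
  if (spec$zero_inflation < 0 || spec$zero_inflation >= 1) {
    stop_field("zero_inflation", "must be in [0,1)")
  }
  if (spec$cohort_batch_sd < 0) stop_field("cohort_batch_sd", "must be >= 0")
  if (spec$gamma_shape <= 0) stop_field("gamma_shape", "must be > 0")
  if (spec$responder_fold <= 2) {
    stop_field("responder_fold",
               "must exceed 2; planted responders would be undetectable by the ratio > 2 rule")
  }
  class(spec) <- "simulation_spec"
  spec
}

## Signed planted effects: odd-indexed signal taxa up in cluster 1, even down,
## so both coefficient signs are exercised downstream.
signal_effects <- function(spec) {
  if (spec$n_signal_taxa == 0) return(numeric(0))
  sgn <- rep(c(1, -1), length.out = spec$n_signal_taxa)
  setNames(sgn * spec$log_fold_change,
           sprintf("SGB%05d", seq_len(spec$n_signal_taxa)))
}

placeholder_taxonomy <- function(taxon_ids) {
  setNames(sprintf(
    "k__Bacteria|p__Synthetica|c__Synthia|o__Synthetales|f__Synthetaceae|g__Synthgenus|s__Synth_species_%s|t__%s",
    taxon_ids, taxon_ids), taxon_ids)
}

#' Generate a synthetic relative-abundance table for one cohort
#'
#' Per-taxon baselines are drawn log-normal, the planted cluster effect is
#' added on the log scale for signal taxa, per-sample gamma noise
#' (shape = `gamma_shape`) is applied to the mean, entries are zeroed with
#' probability `zero_inflation`, and rows are closed to 100. The matrix before
#' closure is attached as attribute `"prenorm"` (the closure step attenuates
#' realized fold-changes; effect checks use the pre-closure values).
#'
#' @param spec a [simulation_spec()].
#' @param cluster_labels binary vector (1 = reactive cluster) of length
#'   `n_samples_per_cohort`.
#' @param cohort_offset optional per-taxon log offsets (batch effect); drawn
#'   `Normal(0, cohort_batch_sd)` by [simulate_cohort_set()].
#' @param sample_ids optional sample identifiers.
#' @return An [abundance_table()] whose rows sum to 100.
#' @export
generate_abundances <- function(spec, cluster_labels, cohort_offset = NULL,
                                sample_ids = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  n <- length(cluster_labels)
  if (!all(cluster_labels %in% c(0, 1))) {
    stop_field("cluster_labels", "must be binary 0/1")
  }
  p <- spec$n_taxa
  taxon_ids <- sprintf("SGB%05d", seq_len(p))
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(n))
  eff <- signal_effects(spec)
  log_base <- rnorm(p, mean = 0, sd = 1.5)
  names(log_base) <- taxon_ids
  if (!is.null(cohort_offset)) log_base <- log_base + cohort_offset
  ## log-mean per sample x taxon
  logmu <- matrix(log_base, n, p, byrow = TRUE)
  if (length(eff)) {
    idx <- match(names(eff), taxon_ids)
    logmu[, idx] <- logmu[, idx] +
      outer(as.numeric(cluster_labels), eff)
  }
  mu <- exp(logmu)
  shp <- spec$gamma_shape
  vals <- matrix(rgamma(n * p, shape = shp, rate = shp) , n, p) * mu
  if (spec$zero_inflation > 0) {
    keep <- matrix(rbinom(n * p, 1, 1 - spec$zero_inflation), n, p)
    ## never zero out an entire sample
    allz <- rowSums(keep) == 0
    keep[allz, 1] <- 1L
    vals <- vals * keep
  }
  prenorm <- vals
  dimnames(prenorm) <- list(sample_ids, taxon_ids)
  vals <- 100 * vals / rowSums(vals)
  out <- abundance_table(vals, sample_ids, taxon_ids,
                         taxonomy = placeholder_taxonomy(taxon_ids))
  attr(out, "prenorm") <- prenorm
  attr(out, "signal_effects") <- eff
  out
}

#' Generate a synthetic cytokine panel for one cohort
#'
#' Emulates a multiplex readout with paired pre-vaccination values: control
#' concentrations are log-normal; post-vaccination stimulated/control ratios
#' are centred at `responder_fold` for responders on a designated Th1 analyte
#' subset (first third of the panel) and at 1 otherwise; pre-vaccination
#' ratios are centred at 1 for everyone.
#'
#' @inheritParams generate_abundances
#' @param noise_sd log-scale SD of the multiplicative assay noise
#'   (default 0.35; set near 0 for the separable limit).
#' @return A [cytokine_panel()] (assay `"multiplex-PBMC"`).
#' @export
generate_cytokine_panel <- function(spec, cluster_labels, sample_ids = NULL,
                                    noise_sd = 0.35) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (spec$responder_fold <= 2) {
    stop_field("responder_fold", "must exceed 2")
  }
  n <- length(cluster_labels)
  if (!all(cluster_labels %in% c(0, 1))) {
    stop_field("cluster_labels", "must be binary 0/1")
  }
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(n))
  k <- spec$n_cytokines
  analytes <- sprintf("CYT%02d", seq_len(k))
  th1 <- analytes[seq_len(max(1, ceiling(k / 3)))]
  grid <- expand.grid(sample_id = sample_ids, analyte = analytes,
                      stringsAsFactors = FALSE)
  m <- nrow(grid)
  ctrl <- rlnorm(m, meanlog = log(5), sdlog = 0.5)
  resp <- cluster_labels[match(grid$sample_id, sample_ids)] == 1 &
    grid$analyte %in% th1
  ratio <- exp(rnorm(m, mean = ifelse(resp, log(spec$responder_fold), 0),
                     sd = noise_sd))
  pre_ctrl <- rlnorm(m, meanlog = log(5), sdlog = 0.5)
  pre_ratio <- exp(rnorm(m, mean = 0, sd = noise_sd))
  panel <- data.frame(
    grid,
    stimulated = ctrl * ratio,
    control = ctrl,
    pre_stimulated = pre_ctrl * pre_ratio,
    pre_control = pre_ctrl
  )
  out <- cytokine_panel(panel, assay = "multiplex-PBMC")
  attr(out, "th1_analytes") <- th1
  out
}

#' Generate a synthetic gene-family (EC) RPK table for one cohort
#'
#' Negative-binomially distributed counts with planted multiplicative cluster
#' effects of `exp(log_fold_change)` on a designated EC subset (the first
#' `n_signal_taxa` gene families; the spec reuses the taxon effect fields for
#' the functional table).
#'
#' @inheritParams generate_abundances
#' @return A [gene_family_table()] of non-negative integer counts.
#' @export
generate_gene_families <- function(spec, cluster_labels, sample_ids = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  n <- length(cluster_labels)
  if (!all(cluster_labels %in% c(0, 1))) {
    stop_field("cluster_labels", "must be binary 0/1")
  }
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(n))
  p <- spec$n_taxa
  ec_ids <- sprintf("%d.%d.%d.%d",
                    1 + (seq_len(p) - 1) %% 6,
                    1 + (seq_len(p) - 1) %% 20,
                    1 + (seq_len(p) - 1) %% 50,
                    seq_len(p))
  eff <- numeric(p)
  if (spec$n_signal_taxa > 0) {
    sgn <- rep(c(1, -1), length.out = spec$n_signal_taxa)
    eff[seq_len(spec$n_signal_taxa)] <- sgn * spec$log_fold_change
  }
  base <- rlnorm(p, meanlog = log(100), sdlog = 1)
  logmu <- matrix(log(base), n, p, byrow = TRUE) +
    outer(as.numeric(cluster_labels), eff)
  size <- 5  # NB dispersion of the synthetic RPK counts
  vals <- matrix(rnbinom(n * p, size = size, mu = exp(logmu)), n, p)
  out <- gene_family_table(vals, sample_ids, ec_ids)
  attr(out, "signal_effects") <- setNames(eff, ec_ids)
  out
}

#' Simulate a complete multi-cohort dataset
#'
#' Draws cluster labels per cohort (exactly
#' `round(n * responder_fraction)` reactive samples, shuffled), per-cohort
#' batch offsets, then abundance, gene-family and cytokine tables plus a
#' metadata table (age ~ Uniform(20,70), sex ~ Bernoulli(0.5) optionally tied
#' to cluster via `sex_cluster_log_odds`). The `truth` element records planted
#' signal taxa with signed effects and the true cluster labels.
#'
#' @param spec a [simulation_spec()].
#' @return A list of class `synthetic_cohort_set` with elements `abundance`,
#'   `gene_families`, `cytokines`, `metadata` (lists over cohorts) and
#'   `truth`.
#' @export
simulate_cohort_set <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$seed, {
    cohorts <- sprintf("cohort%d", seq_len(spec$n_cohorts))
    n <- spec$n_samples_per_cohort
    out <- list(abundance = list(), gene_families = list(),
                cytokines = list(), metadata = list())
    truth_labels <- list()
    for (ci in seq_along(cohorts)) {
      co <- cohorts[ci]
      n1 <- round(n * spec$responder_fraction)
      n1 <- min(max(n1, 1), n - 1)
      labels <- sample(c(rep(1L, n1), rep(0L, n - n1)))
      sample_ids <- sprintf("%s_S%03d", co, seq_len(n))
      offs <- if (spec$cohort_batch_sd > 0) {
        rnorm(spec$n_taxa, 0, spec$cohort_batch_sd)
      } else rep(0, spec$n_taxa)
      out$abundance[[co]] <- generate_abundances(spec, labels, offs, sample_ids)
      out$gene_families[[co]] <- generate_gene_families(spec, labels, sample_ids)
      out$cytokines[[co]] <- generate_cytokine_panel(spec, labels, sample_ids)
      age <- runif(n, 20, 70)
      if (spec$sex_cluster_log_odds != 0) {
        pr <- stats::plogis(spec$sex_cluster_log_odds * (labels - 0.5))
        sex <- ifelse(rbinom(n, 1, pr) == 1, "F", "M")
      } else {
        sex <- ifelse(rbinom(n, 1, 0.5) == 1, "F", "M")
      }
      out$metadata[[co]] <- covariate_table(data.frame(
        sample_id = sample_ids,
        subject_id = sprintf("%s_P%03d", co, seq_len(n)),
        cohort = co, age = age, sex = sex, timepoint = "baseline",
        cluster = labels
      ))
      truth_labels[[co]] <- setNames(labels, sample_ids)
    }
    out$truth <- list(
      signal_taxa = signal_effects(spec),
      signal_genes = attr(out$gene_families[[1]], "signal_effects"),
      cluster_labels = truth_labels
    )
    out$spec <- spec
    class(out) <- "synthetic_cohort_set"
    out
  })
}
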