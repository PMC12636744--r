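## Core data containers. Plain lists with light S3 classes, in the spirit of
## how vegan/ape hold their objects: matrices plus id vectors, validated on
## construction, no hidden state.

#' Construct a sample-by-taxon relative abundance table
#'
#' The central metagenomic container: a numeric matrix of relative abundances
#' in percent (MetaPhlAn convention), rows = samples, columns = taxa
#' (SGB-level identifiers), with an optional map from taxon id to its
#' pipe-delimited lineage string.
#'
#' @param values numeric matrix, samples x taxa, percent scale, no missing
#'   entries (absence is an exact 0).
#' @param sample_ids,taxon_ids unique character vectors matching the matrix
#'   dimensions; defaults taken from `dimnames(values)`.
#' @param taxonomy optional named character vector mapping taxon id to a
#'   pipe-delimited lineage (`k__...|...|t__SGBxxxxx`).
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(values, sample_ids = rownames(values),
                            taxon_ids = colnames(values), taxonomy = NULL) {
  values <- as.matrix(values)
  if (is.null(sample_ids) || is.null(taxon_ids)) {
    stop("abundance_table requires sample and taxon identifiers", call. = FALSE)
  }
  sample_ids <- as.character(sample_ids)
  taxon_ids <- as.character(taxon_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids", call. = FALSE)
  if (anyDuplicated(taxon_ids)) stop("duplicate taxon ids", call. = FALSE)
  if (nrow(values) != length(sample_ids) || ncol(values) != length(taxon_ids)) {
    stop("values dimensions do not match identifier lengths", call. = FALSE)
  }
  if (anyNA(values)) stop("abundance values must not contain NA", call. = FALSE)
  if (any(values < 0)) stop("abundance values must be >= 0", call. = FALSE)
  dimnames(values) <- list(sample_ids, taxon_ids)
  structure(
    list(values = values, sample_ids = sample_ids, taxon_ids = taxon_ids,
         taxonomy = taxonomy),
    class = "abundance_table"
  )
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d taxa (percent scale)\n",
              length(x$sample_ids), length(x$taxon_ids)))
  rs <- rowSums(x$values)
  cat(sprintf("  row sums: %.4g - %.4g\n", min(rs), max(rs)))
  invisible(x)
}

#' Construct a gene-family (EC number) RPK abundance table
#'
#' @param values numeric matrix of non-negative RPK abundances,
#'   samples x gene families.
#' @param sample_ids,ec_ids identifiers; EC ids must be four dot-separated
#'   fields (trailing fields may be dashes), e.g. `"1.1.1.41"` or `"4.1.1.-"`.
#' @return An object of class `gene_family_table`.
#' @export
gene_family_table <- function(values, sample_ids = rownames(values),
                              ec_ids = colnames(values)) {
  values <- as.matrix(values)
  sample_ids <- as.character(sample_ids)
  ec_ids <- as.character(ec_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids", call. = FALSE)
  if (anyDuplicated(ec_ids)) stop("duplicate EC ids", call. = FALSE)
  ok <- grepl("^[0-9]+\\.([0-9]+|-)\\.([0-9]+|-)\\.([0-9]+|-)$", ec_ids)
  if (!all(ok)) {
    stop(sprintf("malformed EC ids: %s", paste(head(ec_ids[!ok], 5), collapse = ", ")),
         call. = FALSE)
  }
  if (anyNA(values) || any(values < 0)) {
    stop("RPK values must be non-negative and non-missing", call. = FALSE)
  }
  dimnames(values) <- list(sample_ids, ec_ids)
  structure(list(values = values, sample_ids = sample_ids, ec_ids = ec_ids),
            class = "gene_family_table")
}

#' Construct a cytokine/immunoassay panel
#'
#' Long-format container of stimulated and unstimulated (control)
#' concentrations per sample and analyte, optionally with paired
#' pre-vaccination values for rules that require them.
#'
#' @param data data.frame with columns `sample_id`, `analyte`, `stimulated`,
#'   `control` and optionally `pre_stimulated`, `pre_control`.
#' @param assay one of `"multiplex-PBMC"`, `"whole-blood-multiplex"`,
#'   `"whole-blood-IFNg"`.
#' @return An object of class `cytokine_panel`.
#' @export
cytokine_panel <- function(data,
                           assay = c("multiplex-PBMC", "whole-blood-multiplex",
                                     "whole-blood-IFNg")) {
  assay <- match.arg(assay)
  req <- c("sample_id", "analyte", "stimulated", "control")
  miss <- setdiff(req, names(data))
  if (length(miss)) {
    stop(sprintf("cytokine panel missing columns: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  num <- intersect(c("stimulated", "control", "pre_stimulated", "pre_control"),
                   names(data))
  for (cc in num) {
    if (anyNA(data[[cc]]) || any(data[[cc]] < 0)) {
      stop_field(cc, "concentrations must be non-negative and non-missing")
    }
  }
  if (assay == "multiplex-PBMC" &&
      !all(c("pre_stimulated", "pre_control") %in% names(data))) {
    stop("multiplex-PBMC assay requires paired pre-vaccination columns",
         call. = FALSE)
  }
  structure(list(data = as.data.frame(data), assay = assay),
            class = "cytokine_panel")
}

#' Construct a sample metadata (covariate) table
#'
#' @param data data.frame with at least `sample_id`, `subject_id`, `cohort`;
#'   typically also `age`, `sex`, `timepoint` and optional outcome flags.
#' @return An object of class `covariate_table`.
#' @export
covariate_table <- function(data) {
  req <- c("sample_id", "subject_id", "cohort")
  miss <- setdiff(req, names(data))
  if (length(miss)) {
    stop(sprintf("metadata missing columns: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(data$sample_id)) {
    stop("duplicate sample_id in metadata", call. = FALSE)
  }
  structure(list(data = as.data.frame(data)), class = "covariate_table")
}

#' Pipeline configuration with the study's printed constants
#'
#' All thresholds used across the pipeline, each with the value printed in the
#' source study as default: the multiplex positivity ratio (> 2), the
#' whole-blood IFN-gamma threshold (0.08 IU/mL), the 10% analyte frequency
#' filter, the ELISPOT median (110 spots per 3e5 PBMC), the antibody booster
#' rule (fold > 2, post-titer > 20 ug/mL), the q-value tiers (0.2 for taxa,
#' 0.1 single-cohort / 0.01 and 0.1 meta for genes), the TOPOSCORE upper
#' threshold 0.79, 999 permutations, and the random-forest settings (1000
#' trees, 10% feature fraction, min leaf 3, gini impurity).
#'
#' @param ... named overrides of any default.
#' @return A named list of class `analysis_config`.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    positivity_ratio_threshold = 2,
    ifng_threshold_iu_ml = 0.08,
    low_frequency_cutoff = 0.10,
    elispot_median_default = 110,
    booster_fold = 2,
    booster_min_titer = 20,
    q_taxa = 0.2,
    q_genes_single = 0.1,
    q_genes_meta_strict = 0.01,
    q_genes_meta = 0.1,
    toposcore_upper = 0.79,
    toposcore_lower = 0.5,
    permutations = 999,
    control_floor = 0.01,
    rf = list(n_trees = 1000, feature_fraction = 0.10, min_samples_leaf = 3,
              impurity = "gini"),
    cv_folds = 10, cv_reps = 10, top_k = 40,
    seed = 1L
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) {
    stop(sprintf("unknown config fields: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  cfg <- modifyList(cfg, ov)
  if (cfg$low_frequency_cutoff <= 0 || cfg$low_frequency_cutoff >= 1) {
    stop_field("low_frequency_cutoff", "must be in (0,1)")
  }
  for (f in c("positivity_ratio_threshold", "ifng_threshold_iu_ml",
              "booster_fold", "booster_min_titer", "control_floor")) {
    if (cfg[[f]] <= 0) stop_field(f, "must be positive")
  }
  class(cfg) <- "analysis_config"
  cfg
}
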