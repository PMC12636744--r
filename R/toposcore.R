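## Ecological scoring: classify samples into SIG1 / Grey / SIG2 categories
## from configurable lists of harmful (SIG1, tolerogenic) and beneficial
## (SIG2, immunogenic) species. The species lists and the score function are
## configuration: the default S = n2/(n1+n2) is a documented stand-in, the
## pluggable interface is the contract.

#' SIG1/SIG2 scoring configuration
#'
#' @param sig1_species,sig2_species disjoint character vectors of taxon ids
#'   (harmful / beneficial species sets).
#' @param detection_threshold relative abundance strictly above which a
#'   species counts as detected (default 0 = any positive abundance).
#' @param score_function map `(n1, n2) -> S in [0,1]`; default
#'   `n2 / (n1 + n2)`.
#' @param lower_threshold,upper_threshold category boundaries:
#'   `S < lower` is SIG1, `lower <= S < upper` is Grey, `S >= upper` is
#'   SIG2. The upper default is 0.79; the lower boundary is user-supplied.
#' @return List of class `sig_config`.
#' @export
sig_config <- function(sig1_species, sig2_species, detection_threshold = 0,
                       score_function = function(n1, n2) n2 / (n1 + n2),
                       lower_threshold = 0.5, upper_threshold = 0.79) {
  if (!length(sig1_species) || !length(sig2_species)) {
    stop("SIG species lists must be non-empty", call. = FALSE)
  }
  if (length(intersect(sig1_species, sig2_species))) {
    stop("SIG1 and SIG2 lists must be disjoint", call. = FALSE)
  }
  if (!(lower_threshold >= 0 && lower_threshold < upper_threshold &&
        upper_threshold <= 1)) {
    stop("need 0 <= lower < upper <= 1", call. = FALSE)
  }
  structure(list(sig1_species = sig1_species, sig2_species = sig2_species,
                 detection_threshold = detection_threshold,
                 score_function = score_function,
                 lower_threshold = lower_threshold,
                 upper_threshold = upper_threshold),
            class = "sig_config")
}

#' Count detected SIG1 and SIG2 species in a profile
#'
#' @param profile named relative-abundance vector (one sample).
#' @param config a [sig_config()].
#' @return Integer vector `c(n1, n2)`.
#' @export
count_sig_hits <- function(profile, config) {
  stopifnot(inherits(config, "sig_config"))
  detected <- names(profile)[profile > config$detection_threshold]
  c(n1 = length(intersect(config$sig1_species, detected)),
    n2 = length(intersect(config$sig2_species, detected)))
}

#' Compute the topology score and category for one or more samples
#'
#' `S = score_function(n1, n2)`; category SIG1 if `S < lower`, Grey if
#' `lower <= S < upper`, SIG2 if `S >= upper` (boundaries half-open, so
#' every S maps to exactly one category). Samples detecting no listed
#' species get category `"undetermined"` and `NA` score.
#'
#' @param profiles an [abundance_table()] or a named vector (one sample).
#' @param config a [sig_config()].
#' @return data.frame: `sample_id`, `n_sig1_detected`, `n_sig2_detected`,
#'   `s_score`, `category`.
#' @export
compute_toposcore <- function(profiles, config) {
  stopifnot(inherits(config, "sig_config"))
  m <- if (inherits(profiles, "abundance_table")) profiles$values
       else matrix(profiles, 1, dimnames = list("sample1", names(profiles)))
  rows <- lapply(seq_len(nrow(m)), function(i) {
    hits <- count_sig_hits(m[i, ], config)
    if (sum(hits) == 0) {
      data.frame(sample_id = rownames(m)[i], n_sig1_detected = 0L,
                 n_sig2_detected = 0L, s_score = NA_real_,
                 category = "undetermined", stringsAsFactors = FALSE)
    } else {
      s <- config$score_function(hits[["n1"]], hits[["n2"]])
      cat <- if (s < config$lower_threshold) "SIG1"
             else if (s < config$upper_threshold) "Grey"
             else "SIG2"
      data.frame(sample_id = rownames(m)[i], n_sig1_detected = hits[["n1"]],
                 n_sig2_detected = hits[["n2"]], s_score = s,
                 category = cat, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare category frequencies between groups
#'
#' Builds the category x group contingency table and tests it with Fisher's
#' exact test when feasible (and requested), otherwise a chi-squared test;
#' the method used is recorded. The chi-squared variant applies the Yates
#' continuity correction on 2x2 tables when `correct = TRUE`.
#'
#' @param categories character vector of per-sample categories (or any
#'   factor, e.g. TOPOSCORE categories).
#' @param groups parallel grouping vector (>= 2 non-empty groups).
#' @param method `"auto"` (Fisher when the table is small), `"fisher"`, or
#'   `"chisq"`.
#' @param correct continuity correction for the 2x2 chi-squared.
#' @return List: `table`, `p_value`, `statistic` (chi-squared only),
#'   `method`.
#' @export
compare_category_frequencies <- function(categories, groups,
                                         method = c("auto", "fisher", "chisq"),
                                         correct = TRUE) {
  method <- match.arg(method)
  groups <- as.character(groups)
  if (length(unique(groups)) < 2) stop("need >= 2 groups", call. = FALSE)
  tab <- table(categories, groups)
  if (any(colSums(tab) == 0)) stop("empty group", call. = FALSE)
  use_fisher <- switch(method,
                       fisher = TRUE,
                       chisq = FALSE,
                       auto = sum(tab) <= 1000 && all(dim(tab) <= 5))
  if (use_fisher) {
    ft <- fisher.test(tab)
    list(table = tab, p_value = ft$p.value, statistic = NA_real_,
         method = "fisher")
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = correct))
    list(table = tab, p_value = ct$p.value,
         statistic = unname(ct$statistic), method = "chisq")
  }
}

#' Chi-squared test on a prebuilt 2x2 count table
#'
#' Convenience wrapper for worked examples where the contingency table is
#' given directly as printed counts (e.g. functional-category enrichment of
#' significant genes against the full tested gene set).
#'
#' @param counts 2x2 numeric matrix.
#' @param correct apply the Yates continuity correction (default `TRUE`).
#' @return List: `statistic`, `p_value`.
#' @export
chisq_2x2 <- function(counts, correct = TRUE) {
  stopifnot(is.matrix(counts), all(dim(counts) == c(2, 2)))
  ct <- suppressWarnings(chisq.test(counts, correct = correct))
  list(statistic = unname(ct$statistic), p_value = ct$p.value)
}
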