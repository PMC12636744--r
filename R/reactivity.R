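## Reactivity calling: raw immunoassay readouts -> binary positivity calls ->
## two-cluster reactive/non-reactive assignment. All "superior to" criteria
## are strict inequalities, so boundary values are negative.

#' Multiplex PBMC positivity calls
#'
#' For each sample and analyte, three criteria must all hold:
#' delta = stimulated - control must exceed half the absolute value of the
#' smallest delta seen for that analyte across the cohort; the
#' stimulated/control ratio must exceed 2; and the post-vaccination delta
#' minus the paired pre-vaccination delta must exceed zero. When all cohort
#' deltas for an analyte are positive the threshold falls back to the
#' smallest positive delta / 2 (conservative; the rule's reference case has a
#' negative minimum). Ratios against a zero control use `control_floor`.
#'
#' @param panel a [cytokine_panel()] with paired pre-vaccination values.
#' @param config an [analysis_config()].
#' @return A binary samples x analytes matrix of calls.
#' @export
call_positivity_multiplex <- function(panel, config = analysis_config()) {
  stopifnot(inherits(panel, "cytokine_panel"))
  d <- panel$data
  if (!all(c("pre_stimulated", "pre_control") %in% names(d))) {
    stop("multiplex positivity requires paired pre-vaccination values",
         call. = FALSE)
  }
  d$delta <- d$stimulated - d$control
  d$pre_delta <- d$pre_stimulated - d$pre_control
  floor_ <- config$control_floor
  d$ratio <- d$stimulated / pmax(d$control, floor_)
  thr <- tapply(d$delta, d$analyte, function(x) abs(min(x)) / 2)
  d$thr <- thr[d$analyte]
  call <- (d$delta > d$thr) &
    (d$ratio > config$positivity_ratio_threshold) &
    (d$delta - d$pre_delta > 0)
  calls_matrix(d$sample_id, d$analyte, call)
}

#' Whole-blood ratio positivity calls
#'
#' Positive iff stimulated/control strictly exceeds 2 (control floored at
#' `control_floor` when zero); a sample with both concentrations zero is
#' negative.
#'
#' @inheritParams call_positivity_multiplex
#' @return A binary samples x analytes matrix.
#' @export
call_positivity_wholeblood_ratio <- function(panel,
                                             config = analysis_config()) {
  stopifnot(inherits(panel, "cytokine_panel"))
  d <- panel$data
  ratio <- ifelse(d$stimulated == 0 & d$control == 0, 0,
                  d$stimulated / pmax(d$control, config$control_floor))
  calls_matrix(d$sample_id, d$analyte,
               ratio > config$positivity_ratio_threshold)
}

calls_matrix <- function(sample_id, analyte, call) {
  s <- unique(sample_id); a <- unique(analyte)
  m <- matrix(NA, length(s), length(a), dimnames = list(s, a))
  m[cbind(match(sample_id, s), match(analyte, a))] <- as.integer(call)
  storage.mode(m) <- "integer"
  m
}

#' Whole-blood IFN-gamma (ELFA) positivity call
#'
#' Positive iff the test concentration exceeds the threshold while the
#' negative control stays below it, or the test minus the control exceeds the
#' threshold. Assay range is 0-8 IU/mL.
#'
#' @param test_conc,nil_conc IFN-gamma concentrations (IU/mL), vectors
#'   recycled together.
#' @param threshold positivity threshold, default 0.08 IU/mL.
#' @return Logical vector of calls.
#' @export
call_vidas_ifng <- function(test_conc, nil_conc, threshold = 0.08) {
  if (any(test_conc < 0) || any(nil_conc < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  (test_conc > threshold & nil_conc < threshold) |
    (test_conc - nil_conc > threshold)
}

#' Drop low-frequency analytes before clustering
#'
#' Analytes positive in less than `cutoff` (strictly) of samples are
#' excluded; an analyte at exactly the cutoff is retained.
#'
#' @param calls binary samples x analytes matrix.
#' @param cutoff frequency cutoff, default 0.10.
#' @return Character vector of retained analyte names.
#' @export
filter_low_frequency <- function(calls, cutoff = 0.10) {
  freq <- colMeans(calls)
  keep <- names(freq)[freq >= cutoff]
  if (!length(keep)) {
    stop("no analytes retained for clustering", call. = FALSE)
  }
  keep
}

#' Cluster samples into reactive / non-reactive groups
#'
#' Agglomerative clustering of binary positivity calls with the asymmetric
#' binary (Jaccard) dissimilarity and Ward.D2 linkage, cut at two clusters.
#' The cluster with the higher mean positivity frequency is labeled 1
#' (reactive), removing dendrogram-orientation arbitrariness. If every
#' retained call row is identical the split is degenerate: all samples get
#' cluster 0 and `degenerate = TRUE`.
#'
#' @param calls binary samples x analytes matrix (typically already filtered
#'   with [filter_low_frequency()]).
#' @param retained_analytes optional subset of analyte columns to use.
#' @return List of class `reactivity_result`: `calls`, `retained_analytes`,
#'   `cluster` (named 0/1 vector), `hclust`, `degenerate`.
#' @export
cluster_reactivity <- function(calls, retained_analytes = colnames(calls)) {
  calls <- calls[, retained_analytes, drop = FALSE]
  if (nrow(calls) < 2) stop("need >= 2 samples", call. = FALSE)
  if (ncol(calls) < 1) stop("need >= 1 retained analyte", call. = FALSE)
  if (nrow(unique(calls)) == 1) {
    return(structure(list(
      calls = calls, retained_analytes = retained_analytes,
      cluster = setNames(rep(0L, nrow(calls)), rownames(calls)),
      hclust = NULL, degenerate = TRUE), class = "reactivity_result"))
  }
  d <- dist(calls, method = "binary")
  ## all-negative pairs have no positive analyte in either sample: base
  ## "binary" distance is 0/0 there; identical all-zero rows are distance 0
  d[is.na(d)] <- 0
  hc <- hclust(d, method = "ward.D2")
  cl <- cutree(hc, k = 2)
  freq <- tapply(rowMeans(calls), cl, mean)
  reactive <- as.integer(names(freq)[which.max(freq)])
  cluster <- as.integer(cl == reactive)
  structure(list(
    calls = calls, retained_analytes = retained_analytes,
    cluster = setNames(cluster, rownames(calls)),
    hclust = hc, degenerate = FALSE), class = "reactivity_result")
}

#' Median split of per-subject scalar scores
#'
#' Scores strictly above the median go to group 1, scores at or below to
#' group 0 (ties fall on the non-reactive side). The median defaults to the
#' midpoint-of-order-statistics convention but an external reference value
#' (e.g. the 110 spots / 3e5 PBMC ELISPOT median) can be supplied.
#'
#' @param scores numeric vector, named by subject.
#' @param median_value optional externally supplied median.
#' @return Integer 0/1 vector named like `scores`.
#' @export
median_split <- function(scores, median_value = NULL) {
  if (length(scores) < 2) stop("need >= 2 subjects", call. = FALSE)
  if (length(unique(scores)) == 1) stop("no split possible: all scores equal",
                                        call. = FALSE)
  m <- median_value %||% median(scores)
  setNames(as.integer(scores > m), names(scores))
}

#' Antibody booster response call
#'
#' Responder iff post/pre titer ratio strictly exceeds `fold` and the
#' post-booster titer strictly exceeds `min_titer` (ug/mL). A zero
#' pre-booster titer is treated as infinite fold, so the call reduces to the
#' post-titer criterion.
#'
#' @param pre_titer,post_titer antibody titers, recycled together.
#' @param fold fold-increase threshold, default 2.
#' @param min_titer minimum post-booster titer, default 20 ug/mL.
#' @return Logical vector of responder calls.
#' @export
call_booster_response <- function(pre_titer, post_titer, fold = 2,
                                  min_titer = 20) {
  if (any(pre_titer < 0) || any(post_titer < 0)) {
    stop("titers must be non-negative", call. = FALSE)
  }
  ratio <- ifelse(pre_titer == 0, Inf, post_titer / pre_titer)
  ratio > fold & post_titer > min_titer
}
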