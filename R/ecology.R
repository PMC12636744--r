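## Alpha/beta diversity, ordination, PERMANOVA, intra- vs inter-individual
## distance comparison. Profiles arrive in percent and are converted to
## proportions here, exactly once.

as_profile_matrix <- function(x) {
  if (inherits(x, "abundance_table")) x$values else as.matrix(x)
}

#' Alpha diversity of a single profile
#'
#' `richness()` counts strictly positive entries (absence in a relative
#' abundance profile is an exact 0, so any positive mass counts).
#' `shannon()` is the natural-log entropy of the proportions,
#' `inverse_simpson()` is `1 / sum(p^2)`.
#'
#' @param profile non-negative numeric vector (any scale; normalized
#'   internally where proportions are needed).
#' @param base logarithm base for `shannon()`; natural log by default.
#' @return A single number.
#' @name alpha_diversity
#' @export
richness <- function(profile) {
  if (any(profile < 0)) stop("profile must be non-negative", call. = FALSE)
  sum(profile > 0)
}

#' @rdname alpha_diversity
#' @export
shannon <- function(profile, base = exp(1)) {
  if (any(profile < 0)) stop("profile must be non-negative", call. = FALSE)
  s <- sum(profile)
  if (s == 0) stop("all-zero profile", call. = FALSE)
  p <- profile[profile > 0] / s
  -sum(p * log(p, base = base))
}

#' @rdname alpha_diversity
#' @export
inverse_simpson <- function(profile) {
  if (any(profile < 0)) stop("profile must be non-negative", call. = FALSE)
  s <- sum(profile)
  if (s == 0) stop("all-zero profile", call. = FALSE)
  p <- profile / s
  1 / sum(p^2)
}

#' Pairwise Bray-Curtis dissimilarities
#'
#' `BC(x, y) = 1 - 2 * sum(min(x_i, y_i)) / (sum x + sum y)`, computed on the
#' raw (non-normalized) profiles.
#'
#' @param table an [abundance_table()] or samples x taxa matrix.
#' @return A symmetric `dissimilarity_matrix` (values in `[0,1]`, zero
#'   diagonal) with a `sample_ids` attribute.
#' @export
bray_curtis <- function(table) {
  m <- as_profile_matrix(table)
  rs <- rowSums(m)
  if (any(rs == 0)) {
    stop(sprintf("all-zero sample(s): %s",
                 paste(rownames(m)[rs == 0], collapse = ", ")), call. = FALSE)
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    ## vectorized over the remaining rows
    xi <- m[i, ]
    rest <- (i + 1):n
    mins <- rowSums(pmin(m[rest, , drop = FALSE],
                         matrix(xi, length(rest), ncol(m), byrow = TRUE)))
    bc <- 1 - 2 * mins / (rs[rest] + rs[i])
    d[i, rest] <- bc
    d[rest, i] <- bc
  }
  structure(d, class = c("dissimilarity_matrix", "matrix"),
            sample_ids = rownames(m))
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centering eigendecomposition of the squared dissimilarities; axes
#' are ordered by eigenvalue, components with non-positive eigenvalues are
#' dropped (up to `k` axes returned), and each axis is oriented so that its
#' largest-magnitude loading is positive, making outputs reproducible.
#'
#' @param d symmetric dissimilarity matrix.
#' @param k number of axes, default 2 (must be `< n`).
#' @return List with `points` (n x <=k), `eigenvalues`, and the proportion of
#'   positive-eigenvalue variance explained per returned axis.
#' @export
classical_mds <- function(d, k = 2) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (k >= n) stop("k must be < number of samples", call. = FALSE)
  fit <- cmdscale(d, k = k, eig = TRUE)
  pts <- fit$points
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 1)
  for (j in seq_len(ncol(pts))) {
    i <- which.max(abs(pts[, j]))
    if (pts[i, j] < 0) pts[, j] <- -pts[, j]
  }
  rownames(pts) <- rownames(d)
  pos <- fit$eig[fit$eig > 0]
  list(points = pts, eigenvalues = fit$eig,
       explained = fit$eig[seq_len(ncol(pts))] / sum(pos))
}

permanova_stat <- function(d2, labels) {
  ## Anderson's pseudo-F from squared dissimilarities
  n <- length(labels)
  groups <- split(seq_len(n), labels)
  a <- length(groups)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- sum(vapply(groups, function(idx) {
    sub <- d2[idx, idx, drop = FALSE]
    sum(sub[upper.tri(sub)]) / length(idx)
  }, numeric(1)))
  ss_among <- ss_total - ss_within
  (ss_among / (a - 1)) / (ss_within / (n - a))
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Pseudo-F from total vs within-group sums of squared dissimilarities, with
#' a seeded label-permutation null. The p-value uses the inclusive (add-one)
#' estimator `p = (1 + #{F* >= F}) / (1 + n_perm)`, so `p >= 1/(n_perm+1)`.
#'
#' @param d dissimilarity matrix (e.g. from [bray_curtis()]).
#' @param labels grouping vector; at least two groups, each with at least two
#'   samples.
#' @param n_perm number of permutations, default 999.
#' @param seed RNG seed for the permutations.
#' @return List of class `permanova_result`: `pseudo_F`, `p_value`,
#'   `n_permutations`, `seed`.
#' @export
permanova <- function(d, labels, n_perm = 999, seed = 1L) {
  d <- as.matrix(d)
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(tab < 2)) {
    stop(sprintf("group(s) of size 1: %s",
                 paste(names(tab)[tab < 2], collapse = ", ")), call. = FALSE)
  }
  d2 <- d^2
  obs <- permanova_stat(d2, labels)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      permanova_stat(d2, sample(labels)) >= obs
    }, logical(1)))
  })
  structure(list(pseudo_F = obs,
                 p_value = (1 + exceed) / (1 + n_perm),
                 n_permutations = n_perm, seed = seed),
            class = "permanova_result")
}

## Dunn's post-hoc z tests on rank sums after a Kruskal-Wallis test,
## with tie correction; q-values by Benjamini-Hochberg.
dunn_posthoc <- function(values, groups, p_adjust = "BH") {
  r <- rank(values)
  n <- length(values)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  gl <- split(r, groups)
  means <- vapply(gl, mean, numeric(1))
  sizes <- vapply(gl, length, numeric(1))
  gn <- names(gl)
  combs <- utils::combn(gn, 2)
  z <- apply(combs, 2, function(pair) {
    se <- sqrt((n * (n + 1) / 12 - tie_term) *
                 (1 / sizes[pair[1]] + 1 / sizes[pair[2]]))
    (means[pair[1]] - means[pair[2]]) / se
  })
  p <- 2 * pnorm(-abs(z))
  data.frame(group1 = combs[1, ], group2 = combs[2, ], z = z, p = p,
             q = p.adjust(p, method = p_adjust))
}

#' Intra- vs inter-individual beta-diversity comparison
#'
#' Classifies all sample pairs as intra-individual (same subject, different
#' timepoints) or inter-individual, subdividing inter pairs by cluster
#' concordance (both cluster 0, both cluster 1, discordant); compares groups
#' with Kruskal-Wallis and Dunn's post-hoc (BH-adjusted). By default the full
#' set of qualifying pairs is used; `subsample` draws a seeded subset.
#'
#' @param d dissimilarity matrix.
#' @param subject_ids subject id per sample (same order as `d`).
#' @param cluster_labels 0/1 reactivity cluster per sample.
#' @param subsample optional number of pairs to draw per group.
#' @param seed RNG seed for subsampling.
#' @return List: `pairs` (long data.frame with `group` and `distance`),
#'   `kruskal` (statistic, df, p), `dunn` (pairwise table).
#' @export
intra_inter_comparison <- function(d, subject_ids, cluster_labels,
                                   subsample = NULL, seed = 1L) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(length(subject_ids) == n, length(cluster_labels) == n)
  ij <- which(upper.tri(d), arr.ind = TRUE)
  same_subj <- subject_ids[ij[, 1]] == subject_ids[ij[, 2]]
  cl1 <- cluster_labels[ij[, 1]]; cl2 <- cluster_labels[ij[, 2]]
  group <- ifelse(same_subj, "intra",
                  ifelse(cl1 != cl2, "inter_discordant",
                         ifelse(cl1 == 1, "inter_cluster1", "inter_cluster0")))
  if (!any(same_subj)) {
    stop("no intra-individual pairs (no subject with >= 2 timepoints)",
         call. = FALSE)
  }
  pairs <- data.frame(i = ij[, 1], j = ij[, 2], group = group,
                      distance = d[ij])
  if (!is.null(subsample)) {
    pairs <- with_seed(seed, {
      do.call(rbind, lapply(split(pairs, pairs$group), function(g) {
        g[sample(nrow(g), min(subsample, nrow(g))), , drop = FALSE]
      }))
    })
  }
  kw <- kruskal.test(pairs$distance, factor(pairs$group))
  dunn <- dunn_posthoc(pairs$distance, pairs$group)
  list(pairs = pairs,
       kruskal = list(statistic = unname(kw$statistic),
                      df = unname(kw$parameter), p_value = kw$p.value),
       dunn = dunn)
}
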