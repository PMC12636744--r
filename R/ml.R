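## Random-forest prediction of the reactivity cluster from microbiome
## composition: repeated stratified CV, training-fold-only top-k selection,
## LODO, X-LODO and the full cross-prediction matrix.

#' Random-forest hyperparameters
#'
#' Defaults are the study settings: 1000 trees, 10% of the feature space per
#' split, no maximum depth, minimum 3 samples per leaf, gini impurity.
#'
#' @param n_trees,feature_fraction,min_samples_leaf forest settings.
#' @return List of class `forest_settings`.
#' @export
forest_settings <- function(n_trees = 1000, feature_fraction = 0.10,
                            min_samples_leaf = 3) {
  if (n_trees < 1 || min_samples_leaf < 1) {
    stop("forest settings must be positive", call. = FALSE)
  }
  if (feature_fraction <= 0 || feature_fraction > 1) {
    stop_field("feature_fraction", "must be in (0,1]")
  }
  structure(list(n_trees = as.integer(n_trees),
                 feature_fraction = feature_fraction,
                 min_samples_leaf = as.integer(min_samples_leaf),
                 impurity = "gini"),
            class = "forest_settings")
}

#' Cross-validation scheme
#'
#' @param folds folds per repetition (10 by default; 5 for small cohorts).
#' @param repetitions number of repeated CVs (10).
#' @param top_k optional training-fold-only feature-selection size (40 in
#'   the top-k experiments; `NULL` = use all features).
#' @param seed base seed; repetition `r` uses `seed + r`.
#' @return List of class `evaluation_scheme`.
#' @export
evaluation_scheme <- function(folds = 10, repetitions = 10, top_k = NULL,
                              seed = 1L) {
  if (folds < 2) stop_field("folds", "must be >= 2")
  structure(list(folds = as.integer(folds),
                 repetitions = as.integer(repetitions),
                 top_k = top_k, stratified = TRUE, seed = as.integer(seed)),
            class = "evaluation_scheme")
}

#' Train a random forest
#'
#' @param X numeric samples x features matrix.
#' @param y 0/1 labels.
#' @param settings a [forest_settings()].
#' @param seed RNG seed (forest growth uses R's RNG).
#' @return List of class `rf_model` with `forest` (opaque), `importance`
#'   (named impurity importances) and `features`.
#' @export
rf_train <- function(X, y, settings = forest_settings(), seed = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)), nrow(X) == length(y))
  mtry <- max(1L, floor(settings$feature_fraction * ncol(X)))
  forest <- with_seed(seed, {
    rf_grow_cpp(X, y, settings$n_trees, mtry, settings$min_samples_leaf)
  })
  structure(list(forest = forest,
                 importance = setNames(forest$importance, colnames(X)),
                 features = colnames(X)),
            class = "rf_model")
}

#' Predict class-1 probability scores
#'
#' Scores are the fraction of trees voting positive.
#'
#' @param model an `rf_model`.
#' @param X matrix with the training feature columns.
#' @return Numeric scores in `[0,1]`.
#' @export
rf_predict <- function(model, X) {
  X <- as.matrix(X)[, model$features, drop = FALSE]
  setNames(rf_predict_cpp(model$forest, X), rownames(X))
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' `AUC = P(score_pos > score_neg) + 0.5 P(tie)`, computed from midranks.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return AUC in `[0,1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## Seeded stratified fold assignment: shuffle within each class stratum and
## deal samples round-robin into folds.
stratified_folds <- function(y, folds, seed) {
  if (min(sum(y == 1), sum(y == 0)) < folds) {
    stop(sprintf(
      "stratification infeasible: a class has fewer than %d members; use fewer folds",
      folds), call. = FALSE)
  }
  with_seed(seed, {
    assign <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
    assign
  })
}

## One train/test pass shared by the CV variants: optional training-only
## top-k selection, fit, score the test rows. aug_X/aug_y are extra training
## samples (X-LODO); they never enter the test fold.
fit_score_split <- function(X, y, train, test, settings, top_k = NULL,
                            aug_X = NULL, aug_y = NULL, seed = NULL) {
  Xtr <- X[train, , drop = FALSE]
  ytr <- y[train]
  if (!is.null(aug_X)) {
    Xtr <- rbind(Xtr, aug_X[, colnames(X), drop = FALSE])
    ytr <- c(ytr, aug_y)
  }
  if (!is.null(top_k)) {
    if (top_k > ncol(X)) stop("top_k exceeds number of features", call. = FALSE)
    rank_model <- rf_train(Xtr, ytr, settings, seed = seed)
    keep <- names(sort(rank_model$importance, decreasing = TRUE))[seq_len(top_k)]
    ## keep original column order so top_k = p reduces exactly to plain CV
    Xtr <- Xtr[, intersect(colnames(Xtr), keep), drop = FALSE]
  }
  model <- rf_train(Xtr, ytr, settings, seed = seed)
  list(scores = rf_predict(model, X[test, , drop = FALSE]),
       importance = model$importance)
}

#' Repeated stratified cross-validation
#'
#' For each repetition a fresh seeded stratified partition is drawn
#' (`seed + r`); out-of-fold scores are concatenated within a repetition and
#' one ROC AUC computed per repetition. When `scheme$top_k` is set, every
#' split re-ranks features on its training fold only and refits on the top
#' k, so test information never enters selection.
#'
#' @param X samples x features matrix.
#' @param y 0/1 labels.
#' @param scheme an [evaluation_scheme()].
#' @param settings a [forest_settings()].
#' @param aug_X,aug_y optional augmentation samples added to every training
#'   fold (the X-LODO construction); test folds stay target-cohort only.
#' @return List: `auc` (per repetition), `mean_auc`, `sd_auc`, `oof_scores`
#'   (repetitions x n matrix), `importance` (mean training-fold importance).
#' @export
repeated_cv <- function(X, y, scheme = evaluation_scheme(),
                        settings = forest_settings(),
                        aug_X = NULL, aug_y = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (nrow(X) < scheme$folds) stop("n < folds", call. = FALSE)
  aucs <- numeric(scheme$repetitions)
  oof <- matrix(NA_real_, scheme$repetitions, nrow(X))
  imp <- numeric(ncol(X))
  for (r in seq_len(scheme$repetitions)) {
    fold_of <- stratified_folds(y, scheme$folds, seed = scheme$seed + r)
    for (f in seq_len(scheme$folds)) {
      test <- which(fold_of == f)
      train <- which(fold_of != f)
      res <- fit_score_split(X, y, train, test, settings,
                             top_k = scheme$top_k, aug_X = aug_X,
                             aug_y = aug_y,
                             seed = scheme$seed + r * 1000L + f)
      oof[r, test] <- res$scores
      imp <- imp + res$importance[colnames(X)]
    }
    aucs[r] <- roc_auc(oof[r, ], y)
  }
  list(auc = aucs, mean_auc = mean(aucs), sd_auc = sd(aucs),
       oof_scores = oof,
       importance = setNames(imp / (scheme$repetitions * scheme$folds),
                             colnames(X)))
}

#' Training-fold-only feature ranking
#'
#' Impurity importances are computed within each training fold of a repeated
#' stratified CV and their ranks averaged across all folds and repetitions;
#' test samples never contribute.
#'
#' @inheritParams repeated_cv
#' @return data.frame ordered best-first: `feature`, `mean_rank`.
#' @export
rank_features_training_only <- function(X, y, scheme = evaluation_scheme(),
                                        settings = forest_settings()) {
  X <- as.matrix(X)
  y <- as.integer(y)
  rank_sum <- numeric(ncol(X))
  n_fits <- 0L
  for (r in seq_len(scheme$repetitions)) {
    fold_of <- stratified_folds(y, scheme$folds, seed = scheme$seed + r)
    for (f in seq_len(scheme$folds)) {
      train <- which(fold_of != f)
      model <- rf_train(X[train, , drop = FALSE], y[train], settings,
                        seed = scheme$seed + r * 1000L + f)
      rank_sum <- rank_sum + rank(-model$importance[colnames(X)],
                                  ties.method = "average")
      n_fits <- n_fits + 1L
    }
  }
  out <- data.frame(feature = colnames(X), mean_rank = rank_sum / n_fits)
  out[order(out$mean_rank), , drop = FALSE]
}

#' Leave-one-dataset-out evaluation
#'
#' For each cohort: train one forest on all other cohorts pooled, test on
#' the held-out cohort. Cohorts must share a feature space; by default the
#' union of features is used with absent taxa as 0 (merged-profile
#' behaviour), or the intersection with `harmonize = "intersection"`.
#'
#' @param datasets named list of `list(X = matrix, y = labels)` per cohort.
#' @param settings a [forest_settings()].
#' @param seed RNG seed.
#' @param harmonize `"union"` (absent features zero-filled) or
#'   `"intersection"`.
#' @return Named numeric vector of held-out AUCs.
#' @export
lodo <- function(datasets, settings = forest_settings(), seed = 1L,
                 harmonize = c("union", "intersection")) {
  harmonize <- match.arg(harmonize)
  if (length(datasets) < 2) stop("need >= 2 cohorts", call. = FALSE)
  datasets <- harmonize_features(datasets, harmonize)
  vapply(names(datasets), function(target) {
    rest <- datasets[setdiff(names(datasets), target)]
    Xtr <- do.call(rbind, lapply(rest, `[[`, "X"))
    ytr <- unlist(lapply(rest, `[[`, "y"), use.names = FALSE)
    model <- rf_train(Xtr, ytr, settings, seed = seed)
    roc_auc(rf_predict(model, datasets[[target]]$X), datasets[[target]]$y)
  }, numeric(1))
}

#' Cross-validation augmented with the other cohorts (X-LODO)
#'
#' CV on the target cohort in which every training fold additionally
#' contains all samples of the other cohorts; test folds hold
#' target-cohort samples only. With a single cohort this reduces exactly to
#' plain [repeated_cv()].
#'
#' @inheritParams lodo
#' @param scheme an [evaluation_scheme()] (or a named list of schemes, one
#'   per cohort, e.g. 5 folds for a small cohort).
#' @return Named list of [repeated_cv()] results per target cohort.
#' @export
xlodo <- function(datasets, scheme = evaluation_scheme(),
                  settings = forest_settings(),
                  harmonize = c("union", "intersection")) {
  harmonize <- match.arg(harmonize)
  datasets <- harmonize_features(datasets, harmonize)
  schemes <- if (inherits(scheme, "evaluation_scheme")) {
    setNames(rep(list(scheme), length(datasets)), names(datasets))
  } else scheme
  out <- lapply(names(datasets), function(target) {
    rest <- datasets[setdiff(names(datasets), target)]
    aug_X <- if (length(rest)) do.call(rbind, lapply(rest, `[[`, "X")) else NULL
    aug_y <- if (length(rest)) unlist(lapply(rest, `[[`, "y"), use.names = FALSE) else NULL
    repeated_cv(datasets[[target]]$X, datasets[[target]]$y,
                scheme = schemes[[target]], settings = settings,
                aug_X = aug_X, aug_y = aug_y)
  })
  setNames(out, names(datasets))
}

harmonize_features <- function(datasets, harmonize) {
  spaces <- lapply(datasets, function(d) colnames(d$X))
  feats <- if (harmonize == "union") {
    Reduce(union, spaces)
  } else {
    Reduce(intersect, spaces)
  }
  if (!length(feats)) stop("no shared features across cohorts", call. = FALSE)
  lapply(datasets, function(d) {
    X <- matrix(0, nrow(d$X), length(feats),
                dimnames = list(rownames(d$X), feats))
    common <- intersect(colnames(d$X), feats)
    X[, common] <- d$X[, common]
    list(X = X, y = as.integer(d$y))
  })
}

#' Cross-prediction matrix over cohorts
#'
#' Train-on-row / test-on-column AUC grid: diagonal entries are repeated-CV
#' AUC means, off-diagonal entries come from a forest trained on the full
#' row cohort and tested on the full column cohort. Two extra rows append
#' the LODO and X-LODO AUC per target cohort.
#'
#' @inheritParams xlodo
#' @param seed seed for the off-diagonal and LODO forests.
#' @return List of class `cross_prediction_matrix`: `auc` matrix
#'   ((k+2) x k), `cv` (per-cohort [repeated_cv()] results), `xlodo`
#'   results.
#' @export
cross_prediction_matrix <- function(datasets, scheme = evaluation_scheme(),
                                    settings = forest_settings(), seed = 1L,
                                    harmonize = c("union", "intersection")) {
  harmonize <- match.arg(harmonize)
  datasets <- harmonize_features(datasets, harmonize)
  k <- length(datasets)
  cohorts <- names(datasets)
  schemes <- if (inherits(scheme, "evaluation_scheme")) {
    setNames(rep(list(scheme), k), cohorts)
  } else scheme
  m <- matrix(NA_real_, k + 2, k,
              dimnames = list(c(cohorts, "LODO", "X-LODO"), cohorts))
  cv <- list()
  for (tr in cohorts) {
    cv[[tr]] <- repeated_cv(datasets[[tr]]$X, datasets[[tr]]$y,
                            scheme = schemes[[tr]], settings = settings)
    m[tr, tr] <- cv[[tr]]$mean_auc
    model <- rf_train(datasets[[tr]]$X, datasets[[tr]]$y, settings,
                      seed = seed)
    for (te in setdiff(cohorts, tr)) {
      m[tr, te] <- roc_auc(rf_predict(model, datasets[[te]]$X),
                           datasets[[te]]$y)
    }
  }
  m["LODO", ] <- lodo(datasets, settings, seed = seed)[cohorts]
  xl <- xlodo(datasets, schemes, settings)
  m["X-LODO", ] <- vapply(cohorts, function(co) xl[[co]]$mean_auc, numeric(1))
  structure(list(auc = m, cv = cv, xlodo = xl),
            class = "cross_prediction_matrix")
}
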