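---
title: "Methods: linking baseline gut metagenomes to vaccine immune reactivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking baseline gut metagenomes to vaccine immune reactivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaxbiome)
```

## The problem

A recurring observation in vaccine immunology is that a substantial minority
of vaccinees — on the order of 20–25% for non-replicating formulations —
fail to mount protective Th1/Tc1 cellular responses or durable antibody
titers, and that this failure correlates with the composition of the gut
microbiome at baseline. `vaxbiome` packages the statistical machinery needed
to test that association end to end: it turns raw immunoassay readouts into
a binary reactive/non-reactive grouping, models each microbial species (or
gene family) against that grouping, pools cohorts by random-effects
meta-analysis, benchmarks cross-cohort predictability with random forests,
and scores samples ecologically. A synthetic multi-cohort generator with
planted truth makes every stage testable without access to any deposited
sequencing data.

## Response-group construction

Immunoassay readouts are reduced to binary positivity calls by assay-specific
rules, all using strict inequalities (a value exactly at a threshold is
negative):

* **Multiplex PBMC panels** (`call_positivity_multiplex()`): for each
  analyte, delta = stimulated − control. A sample is positive when its delta
  exceeds half the absolute value of the smallest delta observed for that
  analyte across the cohort, its stimulated/control ratio exceeds 2, and its
  post-vaccination delta exceeds its paired pre-vaccination delta. The
  "smallest delta" scope is per analyte across all cohort samples; when all
  deltas are positive the threshold falls back to the smallest positive
  delta / 2, the conservative reading of a case the rule's reference
  formulation does not cover. Ratios against a zero control use a
  configurable concentration floor (default 0.01, standing in for the assay
  lower limit of quantification) rather than dropping the sample.
* **Whole-blood multiplex** (`call_positivity_wholeblood_ratio()`):
  stimulated/control > 2.
* **Whole-blood IFN-γ release** (`call_vidas_ifng()`): positive when the
  test exceeds 0.08 IU/mL with the negative control below it, or when the
  test minus control exceeds 0.08 IU/mL.
* **ELISPOT / antibody-decay median splits** (`median_split()`): scores
  strictly above the median go to group 1; ties fall on the non-reactive
  side, the conservative choice.
* **Booster response** (`call_booster_response()`): post/pre fold > 2 and
  post-titer > 20 µg/mL; a zero pre-titer counts as infinite fold so the
  absolute-titer criterion alone decides.

Calls are clustered with the asymmetric binary (Jaccard) dissimilarity —
discordant analytes over analytes positive in at least one of the pair;
double negatives are uninformative — and Ward.D2 linkage, cut at two
clusters. Analytes positive in fewer than 10% of samples are dropped first.
The cluster with the higher mean positivity frequency is labeled 1
(reactive), which removes dendrogram-orientation arbitrariness. Two
properties of this distance are worth knowing: pairs with no positive calls
at all have an undefined ratio, which we define as distance 0 (identical
rows); and a mostly-negative sample with a single false-positive call lies
at distance (k−1)/k from a fully positive sample but at distance 1 from a
clean all-negative sample, so recovery of planted structure requires each
cluster to have its own positive analyte block (which is what real
polyreactive-vs-background panels look like), not an all-ones/all-zeros
contrast.

## Differential abundance

Relative abundances of a species across samples are positive, right-skewed
and heteroscedastic, which motivates a gamma GLM with log link fit per
feature (`fit_gamma_glm()`): IRLS to convergence 1e-8 (max 100 iterations),
Pearson-based dispersion, standard errors from the expected information,
two-sided Wald p-values. For a lone binary group indicator the fitted
contrast equals the log ratio of group sample means — the package's tests
hold the fitter to that closed form at 1e-6 and to an independent BFGS
maximizer of the gamma likelihood at 1e-5. Gene-family RPK counts get a
negative-binomial GLM with per-feature maximum-likelihood dispersion
(Poisson fallback when the dispersion estimate hits its bound); RPKs are
rounded to integers first — applying a count model to continuous RPKs is a
tension inherited from the analysis being reproduced, recorded rather than
resolved.

Two modelling conventions matter for interpreting signs and q-values:

* The cluster indicator codes 1 for cluster 0 (non-reactive), so a taxon
  enriched in the reactive cluster gets a **negative** coefficient.
* FDR is controlled with Benjamini–Yekutieli, valid under arbitrary
  dependence, applied per cohort and per feature space (taxa and gene
  families adjusted separately). Thresholds follow the source analysis:
  q < 0.2 for taxa (single-cohort and meta), q < 0.1 for genes per cohort,
  q < 0.01 and q < 0.1 tiers for gene meta-analysis.

Zeros are outside the gamma support; they are replaced by half the smallest
nonzero value of that feature within the cohort, a rank-preserving
pseudo-count (configurable). Features detected in fewer than 5 samples
overall or fewer than 2 per cluster are skipped with a logged reason —
these filters are implementation choices, exposed as arguments, since the
reference analysis does not state its policy.

## Meta-analysis

Per-cohort coefficients for every feature fitted in at least two cohorts
are pooled by inverse-variance weighting with between-cohort variance τ²
estimated by Paule–Mandel: τ² solves Σ wᵢ(τ²)(yᵢ − ȳ_w)² = k − 1 with
wᵢ = 1/(seᵢ² + τ²), found by bisection (the generalized Q statistic is
monotone in τ², so bisection on [0, 10 × DerSimonian–Laird] always
converges; tolerance 1e-8). Inference is a plain normal z test; a
Knapp–Hartung-type small-k adjustment is deliberately not applied, matching
the plain synthesis being reproduced. "Found in a minimum of two cohorts"
is read as *successfully fitted* in ≥ 2 cohorts (configurable). One limit
worth remembering: a single very precise cohort dominates the pooled
estimate only when the cohort effects are compatible (τ² = 0); with
discordant effects τ² caps every study's weight at 1/τ², by design of the
random-effects model.

## Machine-learning benchmark

Random forests (1000 trees, 10% of the feature space per split, no depth
cap, minimum 3 samples per leaf, gini impurity) predict the reactivity
cluster from composition. The forest is implemented in C++ inside the
package (no forest package is part of the supported dependency stack) and
draws all randomness from R's RNG, so a seed makes folds, trees and
rankings bit-reproducible. Scores are the fraction of trees voting
positive; leaf ties contribute 0.5.

Evaluation schemes:

* **Repeated stratified CV** — 10 repetitions of 10-fold stratified CV
  (5-fold for small cohorts); out-of-fold scores are concatenated within a
  repetition, one ROC AUC per repetition (Mann–Whitney formulation, ties
  counted half), summarized as mean ± SD. Per-fold AUC averaging is an
  alternative convention; concatenation was chosen because each repetition
  then yields one ROC curve.
* **Top-k selection** — inside every split, features are ranked by
  impurity importance on the training fold only, the top 40 kept, and the
  forest refit; test-fold information cannot reach selection by
  construction, and a mutation test that corrupts test labels verifies
  bit-identical rankings and scores.
* **LODO** — train on all other cohorts pooled, test on the held-out one.
* **X-LODO** — CV on the target cohort with every training fold augmented
  by all samples of the other cohorts; test folds stay target-only. With a
  single cohort this reduces exactly to plain CV.

Cohorts are harmonized to the union of their feature spaces with absent
taxa as zero relative abundance (how merged profile tables behave);
intersection is available as an option.

## Ecology

Alpha diversity: richness is the count of strictly positive entries (in a
relative-abundance profile absence is an exact zero); Shannon entropy uses
the natural log by default (a log-10 option exists because figure-level
conventions sometimes differ from methods text); inverse Simpson is
1/Σpᵢ². Beta diversity is Bray–Curtis, ordinated by classical (Torgerson)
MDS with each axis oriented so its largest-magnitude loading is positive.
PERMANOVA uses Anderson's pseudo-F on squared dissimilarities with seeded
label permutations and the inclusive estimator p = (1 + #{F* ≥ F})/(1 + n);
p can therefore never be 0 and equals 1/(n+1) only when no permutation ties
or beats the observed statistic — note that permutations recreating the
observed partition tie exactly, which matters for tiny degenerate examples.
The intra- vs inter-individual comparison classifies all qualifying sample
pairs (optionally a seeded subsample; the reference analysis subsampled but
did not specify how), subdivides inter pairs by cluster concordance, and
applies Kruskal–Wallis with Dunn's post-hoc, BH-adjusted (the reference
reports "q" without naming a method).

## Ecological topology score

Samples are classified SIG1 / Grey / SIG2 from configurable lists of
harmful (SIG1) and beneficial (SIG2) species. The score function is
pluggable; the default S = n₂/(n₁+n₂) is a documented stand-in — the
published score's exact formula is not part of this package's scope, and
the published species lists are user-supplied configuration (tests ship a
synthetic placeholder list only). Categories use half-open boundaries
(S < lower → SIG1, lower ≤ S < upper → Grey, S ≥ upper → SIG2) with upper
defaulting to 0.79; the lower boundary must be supplied. A sample detecting
no listed species is reported "undetermined" rather than silently scored.
For the functional-enrichment worked example, the 2×2 layout that
reproduces the printed continuity-corrected chi-squared of 4.9 compares the
significant-gene set against the full tested set (overlapping margins);
this layout was reverse-engineered from the printed value and is pinned in
a test.

## The synthetic cohort generator

`simulate_cohort_set()` emulates exactly the structure the analysis
assumes, no more:

* per-taxon log-normal baselines (meanlog 0, sdlog 1.5 — several orders of
  magnitude of abundance, as in real profiles);
* the planted cluster effect added on the log scale to designated signal
  taxa (alternating signs so both enrichment directions occur), **before**
  compositional closure to 100 — closure attenuates realized fold-changes,
  which the recovery tolerances acknowledge;
* per-sample gamma noise (shape = `gamma_shape`, default 2) on the mean,
  matching the downstream model family;
* Bernoulli zero-inflation (default 0.3, a typical species-level absence
  rate);
* per-cohort, per-taxon log-offsets ~ Normal(0, `cohort_batch_sd`) so LODO
  transfer is genuinely harder than within-cohort CV;
* cytokine panels with responders' stimulated/control ratios centred at
  `responder_fold` on a Th1-like analyte subset (first third of the panel)
  and paired pre-vaccination values centred at ratio 1; `responder_fold`
  must exceed 2 or planted responders would be undetectable by the ratio
  rule;
* gene-family counts drawn negative-binomial (size 5) with multiplicative
  planted effects; the simulation spec reuses its taxon fields (feature
  count, signal count, log fold change) for the functional table;
* ages ~ Uniform(20, 70), sex ~ Bernoulli(0.5) with an optional log-odds
  link to cluster for confounding experiments.

What the generator does **not** emulate: read-level sequencing noise,
phylogenetic correlation between taxa, realistic taxonomies beyond
placeholder SGB identifiers, longitudinal drift, or covariate-driven batch
structure. A green recovery test therefore establishes that the estimators
are correct for data matching their own assumptions — it does not validate
the biological conclusions of any particular study.

## Numerical choices and degenerate inputs

* Identical simulation specs (including seed) give bit-identical outputs;
  every stochastic routine runs under a scoped seed that restores the
  caller's RNG state.
* All-zero profiles error in diversity metrics; all-zero samples are named
  in Bray–Curtis errors; groups of size 1 are rejected by PERMANOVA.
* Clustering of identical call rows returns a degenerate flag instead of an
  arbitrary split.
* Gamma IRLS non-convergence skips the feature with a recorded reason;
  rank-deficient designs error.
* Monte-Carlo acceptance checks average over independent replicate batches
  where a single batch's sampling SD would exceed the stated tolerance band
  (details in the test file comments); thresholds themselves are never
  relaxed.

## Limitations

The package reproduces an analysis pipeline, not a biological claim: it
assumes the reactivity grouping is meaningful, treats cohorts as
exchangeable in the meta-analysis, and inherits the count-model-on-RPK and
pseudo-count tensions documented above. Zero-inflated and compositional
log-ratio models, longitudinal random-effect models, survival analysis and
alternative learners are out of scope.
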