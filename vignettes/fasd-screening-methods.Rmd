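---
title: "Methods: multimodal FASD screening classifiers and screening economics"
author: "fasdscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal FASD screening classifiers and screening economics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fasdscreen)
```

# Overview

`fasdscreen` implements a screening analysis for fetal alcohol spectrum
disorder (FASD) built from up to six assessments per child: three
structured saccadic eye-movement tasks (prosaccade, antisaccade,
memory-guided saccade), free viewing of natural videos, a psychometric
battery, and diffusion tensor imaging (DTI) of the corpus callosum.
Each assessment yields a classifier that outputs a probability of FASD;
the probabilities are fused across assessments; and the resulting
operating characteristics feed a value-of-information model of annual
screening.  This vignette documents the models, their assumptions, the
tunable parameters, and the design decisions taken where the design was
genuinely open.  It states no empirical result beyond what the
package's tests and the acceptance script themselves compute.

# The synthetic cohort generator

Real multimodal clinical data cannot ship with a methods package, so
`cohortSpec()` / `generateCohort()` produce cohorts with the structure
the analysis assumes.  The defaults are the study conditions:

* **Group sizes and demographics.** 91 FASD / 116 control (44.0% FASD),
  ages 5–18 drawn from truncated normals (FASD 11.9 ± 3.4 years,
  control 10.8 ± 3.5), sex and handedness drawn at the cohort's
  observed proportions.  Sex and handedness have no effect on features
  by default.
* **Completion pattern.** Per-assessment completer counts (prosaccade
  71/115, memory-guided 61/93, antisaccade 67/106, natural viewing
  47/53, DTI 41/35, psychometric 58/71) with exactly 22 FASD and 24
  controls completing *all six* assessments.  Completion is assigned
  deterministically: the all-six completers are the first participants
  of each group, and the remaining per-assessment "missing" quotas are
  filled greedily (largest remaining quota first, then fixed assessment
  order) so that every other participant misses at least one
  assessment.  Determinism makes cohorts bit-reproducible given the
  seed.
* **Feature distributions.** Features are Gaussian per dimension: the
  sources give no distributional detail beyond summary statistics, and
  Gaussian noise is the neutral choice for testing a linear-classifier
  pipeline.  Saccade features are standard-normal baseline;
  psychometric scores are calibrated to the population standard
  (mean 10, SD 3); DTI eigenvalues use typical corpus-callosum
  diffusivities (λ1 ≈ 1.70, λ2 ≈ 0.55, λ3 ≈ 0.35 ×10⁻³ mm²/s, sorted
  to preserve λ1 ≥ λ2 ≥ λ3 > 0) with fiber length ≈ 70 mm and angle
  ≈ 35°.  FA, MD, and perpendicular diffusivity are *derived* from the
  eigenvalues by the standard tensor formulas (`deriveDTIScalars()`),
  giving the derived columns the same deterministic dependence on the
  eigenvalues that real DTI scalars have.
* **Group effects.** Each assessment has a configurable number of
  informative features shifted down (deficit direction) in the FASD
  group by `d` pooled standard deviations.  Defaults: d = 0.8 on as
  many features as each assessment's reported selected-feature count
  (prosaccade 11, antisaccade 9, memory-guided 15, DTI 6 — the genu
  length, rostral and splenium λ3, posterior λ1 and angle, splenium
  length — psychometric 3: quantitative concepts, inhibition total
  errors, digit recall).  d = 0.8 is a large-but-plausible
  neurodevelopmental contrast, consistent with single assessments
  classifying in the 65–80% range rather than perfectly.
* **Age trends.** A linear age component (default 0.03 SD/year) is
  added to the saccade features only, since age corrections are part of
  the saccade preprocessing; other assessments can be given trends
  through configuration.
* **Attentional eye traces.** Natural-viewing completers receive one
  trace per video snippet (default 70 snippets of 2–4 s at 500 Hz,
  durations shared across participants as a common video set).  Each
  of the 10 channels (C, I, O, F, M, J, Var, CIOFM, CIOFMJ, top-down)
  is a unit-variance AR(1) series (ρ = 0.9), matching the temporal
  smoothness of saliency values along a gaze path; the FASD group
  effect is a mean shift on a configurable subset of snippets and
  channels (default: snippets 1–10 on F, J, CIOFMJ, top-down,
  reflecting that dynamic, complex content discriminates best).

**What the generator does not emulate:** real saccade-metric
distributions (skewed reaction times, bounded percentages), site
effects in the imaging data, nonlinear age trajectories, inter-feature
correlation within an assessment beyond the DTI eigenvalue–scalar
dependence, and real video statistics.  Passing tests therefore
demonstrate that the *pipeline* behaves correctly (calibration under
the null, recovery of planted signal, reproducibility), not that any
particular accuracy will be attained on clinical data.

# Preprocessing

Normalization is min-max to the 0–1 range *within each feature,
referenced to the training data*: test values outside the training
range deliberately stay outside [0, 1] (the contract is "normalize by
the training range", not truncate), and a feature constant in training
maps to 0 everywhere, which removes its influence without dividing by
zero.

Age correction (`ageCorrect()`) fits, per feature, an OLS line
feature ~ age on the *control* participants of the training set and
subtracts the centered fitted component `slope · (age − mean(control
age))` from all rows.  Referencing controls keeps group contrasts that
are not age-driven; centering preserves the feature's location.  Which
reference population the original analysis used is not documented; the
control-referenced choice is the standard residualization for
case-control designs.

# SVM recursive feature elimination

`rfeTrain()` trains a linear soft-margin SVM (cost 1 by default; the
original cost is undocumented, so it is a configuration knob) on the
active features, records the exact leave-one-out accuracy, eliminates
the feature with the smallest *squared weight* — the original RFE
ranking criterion, matching "lowest contribution weight"; ties break
toward the lowest column index — and repeats until one feature
remains, so `d` input features yield exactly `d` candidate sets.  The
iteration with the best LOO accuracy is selected, ties resolved toward
*fewer* features (parsimony).  Two implementation notes:

* The LOO loop uses the exact support-vector shortcut: removing a
  non-support vector leaves the SVM solution unchanged, so only
  support vectors need refits.  This is an exact optimization, not an
  approximation.
* Probabilities come from a Platt sigmoid `P(FASD | f) = 1 / (1 +
  exp(A f + B))` fit by maximum likelihood on the training decision
  values with the usual smoothed targets.  The original probability
  method is undocumented; Platt scaling is the standard choice for
  margin classifiers.

The selected model's weights are additionally reported normalized so
their absolute values sum to 1, the convention used for feature-weight
tables.

For DTI, classification uses the 30 raw measurements (three
eigenvalues, mean fiber length, mean angle per region); FA, MD, and
perpendicular diffusivity are dropped because they are deterministic
functions of the eigenvalues and add collinearity rather than
information at small training sizes.

# The natural-viewing classifier

Attentional eye traces are encoded per saliency channel by a two-layer
topographic ICA (TICA) network (`trainTICA()`), each layer minimizing
the topographic sparse objective — the sum over pooled units of the
square root of pooled squared filter responses — under orthonormal
filters, by projected gradient descent with symmetric-orthogonalization
retraction and a backtracking step, so the recorded objective is
non-increasing by construction.

Geometry defaults (`ticaConfig()`): 32 filters on 32-sample windows
with 50% overlap, filters arranged on an 8 × 4 torus with 2 × 2
pooling, the same geometry stacked twice (layer two consumes layer
one's pooled activation vectors).  The filter bank is square because
row-orthonormality is only attainable with at most as many filters as
input dimensions; the architecture family is otherwise free, and these
sizes keep training well-posed at desk scale.  Whitening is
*uncentered* PCA whitening and encoding uses the exact (un-smoothed)
square root: traces are standardized to begin with, and this keeps the
encoder exactly linear up to the pooling nonlinearity — a zero trace
encodes to exactly zero, and doubling a trace doubles first-layer
responses.  The smoothing constant ε = 10⁻⁴ appears only inside the
training objective for differentiability.  The network is pre-trained
on a held-out synthetic trace corpus generated with no group effect,
mirroring pre-training on viewers outside the study cohort.

Classification then proceeds: per-dimension min-max normalization
across participants; a two-tailed Welch t-test filter with Bonferroni
correction (the correction method is otherwise undocumented;
Bonferroni is the conservative default) whose family is *all*
dimensions across all snippets; one L1-logistic weak classifier per
snippet (C fixed at 1 by default — selecting 70 separate C values by
inner cross-validation at these sample sizes would be noise);
out-of-fold LOO snippet probabilities stacked into one vector per
participant; and a second-layer L1-logistic classifier whose C is
chosen by LOO over {0.01, 0.1, 1, 10, 100}.  "Selected snippets" are
those with exactly non-zero second-layer coefficients — the natural
sparse-model reading of coefficient selection.  A missing snippet is
imputed with the training-mean representation, keeping the 70-vector
shape.

The printed L1-logistic objective is stated with 0/1 labels, under
which `log(1 + exp(−y wᵀx))` is degenerate for y = 0; the package uses
the standard ±1 label convention internally (control → −1, FASD → +1),
under which the printed form is exactly the usual L1-regularized
logistic loss.  An unpenalized intercept is included by default and can
be disabled.  The solver splits w = u − v with u, v ≥ 0 and runs
bound-constrained L-BFGS-B, which yields *exact* zeros when both parts
sit on the bound; the test suite verifies the optimum against a dense
grid search and against an independent convex solver.

# Fusion and subset evaluation

`iterativeTrainTest()` fuses per-assessment probabilities for the
complete-data participants: one participant is held out per iteration,
an L1-logistic classifier (C by inner LOO over {0.01, 0.1, 1, 10,
100}) is trained on the rest, and the held-out participant is
predicted; the loop ends when everyone has been the test sample once.
Labels use the 0.5 threshold; the 0.55 threshold belongs to the
screening procedure, not to fusion accuracy.  Whether single-assessment
probabilities should be recomputed on the complete-data subsample or
reused from the full training runs is undocumented; the pipeline
reuses them (the classifiers were trained on the larger sets, which is
the better-posed choice).  `evaluateSubsets()` ranks any family of
subsets — all 15 pairs via `assessmentPairs()` — by fused accuracy.

# Cross-assessment regression

`fitMultilinear()` is plain OLS (no regularization, by design) with
r² reported as the squared correlation of response and fit and an
overall F-test; a rank-deficient design returns the minimum-norm
solution with a warning.  The significant-ratio matrix counts, for
each ordered assessment pair, the percentage of the target
assessment's features whose regression on the source assessment's
features is significant at p < 0.05, uncorrected — the stated
convention.  Regressions pool both groups (whether the original
analysis ran within-group is undocumented; pooling matches the stated
goal of replacing one assessment by another for everyone).  The DTI
regressor set keeps 42 of 48 columns, dropping only perpendicular
diffusivity.

# Classifier comparison and reporting conventions

`bootstrapCompare()` repeats, 20 times by default: stratified
resampling of the training set with replacement (class counts
preserved exactly), retraining, and testing on the *fixed* test set —
resampling the test set would contradict "tested on the test set".
The per-classifier accuracy samples are compared by one-way ANOVA plus
Tukey HSD at α = 0.05.  If every accuracy ties (e.g., identical
deterministic classifiers) the comparison reports p = 1 rather than a
0/0 F statistic.

"Chance level" is the majority-class rate of the evaluation set (the
prior-only classifier): for 22 FASD / 24 controls, 24/46 = 52.17%.
Percentages are reported rounded half-up to two decimals; dollar
amounts are truncated toward zero.

# Screening economics

The annual screening decision tree values one screened individual at

EV = r_D·p_F·(G − C_D − C_S) − r_FA·(1 − p_F)·(C_D + C_S)
     − r_TN·(1 − p_F)·C_S − r_M·p_F·(L + C_S)

with prevalence p_F, confusion rates (r_D + r_M = 1, r_FA + r_TN = 1),
screening cost C_S (default $50), diagnostic cost C_D ($4,000), annual
gain from early detection G ($20,000/year), and annual loss from a
miss L ($20,000/year) — the published bounding assumptions.  Under
annual re-screening L should not exceed G; a scenario violating this is
allowed but flagged.  A case missed in one year is re-screened the
next, so per-FASD savings accumulate geometrically,
`EV_F · Σ_{k<years} r_M^k`, and the probability of missing a case in
every year of the horizon is `r_M^years`.  Cohort savings are linear in
the number screened.  `riskClassification()` flags high risk when the
FASD score strictly exceeds 0.55.  A Monte-Carlo simulator of the same
tree (`simulateExpectedValue()`) provides an independent check of the
analytic value.

# Orchestration

`runFullPipeline()` follows the study's split: the participants who
completed *all* assessments form the test set, the remaining completers
of each assessment its training set.  Saccade tables are age-corrected
on training controls, all tables min-max normalized by training
ranges, classifiers trained, test probabilities fused, subsets ranked,
and the economics model evaluated at the measured confusion rates of
the configured screening pair (default prosaccade + natural viewing).
Every report embeds the configuration hash and seed; two runs of the
same configuration are identical apart from the timestamp.  Each stage
derives its own RNG stream from the global seed, so adding or removing
a stage does not silently shift another stage's draws.

# Numerical choices and test scales

* SVM LOO: exact support-vector shortcut; soft-margin cost 1.
* Platt calibration: BFGS on the two-parameter sigmoid likelihood,
  smoothed targets.
* L1-logistic: L-BFGS-B on the positive/negative split, factr 10³,
  warm starts inside cross-validation loops; exact zeros from the
  bound constraints.
* TICA: symmetric orthogonalization every step keeps filter banks
  orthonormal to machine precision (validity enforces 10⁻⁶); ε = 10⁻⁴
  in training only; backtracking halves the step until the objective
  does not increase.
* OLS: QR when full rank, SVD minimum-norm with a warning otherwise;
  F-test from the rank-based degrees of freedom.
* Ties: RFE elimination → lowest column index; RFE selection → fewer
  features; C grids → smallest (sparsest) C.

The test suite exercises the calibration properties at these scales,
chosen to make the checks statistically meaningful at desk scale: null
SVM-RFE calibration on 100 zero-effect cohorts at the prosaccade
training size (49 + 91 train, 22 + 24 test); F-test type-I error over
1000 null regressions; the L1 solver against a dense 10⁶-point grid;
the decision-tree Monte Carlo at 10⁶ draws; the natural-viewing stack
end-to-end at n = 100 participants with 70 snippets (traces sampled at
50 Hz for the test, a rate at which the window geometry is unchanged);
and the fusion-beats-best-single property over 15 replicate cohorts of
n = 100 fusing five assessments with d = 0.7 effects.

# Known limitations

* Gaussian, feature-independent synthetic data understate the
  collinearity of real assessment batteries; RFE behavior under heavy
  collinearity is exercised only through the DTI eigenvalue/scalar
  dependence.
* The TICA geometry is a default, not a reproduction of the original
  (undocumented) architecture; representations are comparable in
  spirit, not numerically.
* Fusion reuses probabilities from classifiers trained on the full
  training sets rather than refitting on complete-data participants.
* The economics model has no discounting, no age-dependent costs, and
  a single decision threshold; it values one screening policy, it does
  not optimize over policies.
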