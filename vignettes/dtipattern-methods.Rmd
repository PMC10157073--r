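---
title: "Classifying white-matter feature tables with nested cross-validated SVM ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying white-matter feature tables with nested cross-validated SVM ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtipattern)
```

## The problem

Small case-control neuroimaging cohorts routinely show no per-feature group
differences after multiple-testing correction, yet a multivariate classifier
trained on the same features can separate the groups well above chance. The
canonical setting this package targets is a diffusion-MRI study design: a
few dozen subjects, 72 white-matter features (17 regions of interest times
the four DTI scalars FA/MD/RD/AD, plus 4 amygdala-prefrontal structural
connectivity estimates), binary group labels coded +1 (clinical group) and
-1 (controls), and a small table of sociodemographic and forensic covariates
for the positive class only.

`dtipattern` implements the full analysis stack for this design:

1. a repeated, nested, stratified cross-validation (CV) engine around a
   linear maximum-margin classifier, with per-fold min-max rescaling and
   greedy forward wrapper feature selection in the inner cycle;
2. permutation-based significance of the cross-validated balanced accuracy;
3. feature-stability interpretation: the cross-validation ratio (CVR) and
   sign-based consistency with FDR control;
4. confusion-derived and prevalence-adjusted diagnostic metrics (balanced
   accuracy, NND, PPV/NPV, PSI, NNP);
5. univariate group statistics (Mann-Whitney U, 2x2 chi-square, BH-FDR);
6. a post-hoc stepwise regression of ensemble decision scores on covariates;
7. a synthetic cohort generator that reproduces the statistical regime above,
   so that every stage is testable without access to any clinical data.

## The model and pipeline

### Nested cross-validation

The outer cycle (default 10 folds, 10 repeats) estimates generalization;
the inner cycle (default 10 folds, 10 repeats), run within each outer
training partition, drives model selection. Fold assignment is stratified so
every fold contains both classes; with `k` equal to the sample size the plan
degenerates to leave-one-out and stratification is waived.

Within each outer training partition, greedy forward wrapper selection
starts from the empty feature set (chance balanced accuracy 0.5) and
repeatedly adds the feature-penalty pair `(j, C)` that maximizes mean inner
validation balanced accuracy, stopping as soon as the best candidate fails
to improve it by more than `epsilon = 1e-6`. Ties prefer the lower feature
index and the smaller penalty, and the stopping rule itself prefers fewer
features. The winning configuration is then refit on the full outer training
partition — scaler included — and applied to the held-out fold. If nothing
beats the chance baseline (as on pure-noise data), the best single-feature
candidate is kept so that a fold-level model always exists.

Scaling is min-max to `[0, 1]`, fit strictly on training rows; held-out
values are clipped to `[0, 1]` and features constant in training map to 0.5.
Scaling inside every training partition (rather than once on the whole
table) is what makes the no-leakage guarantee testable: corrupting a
held-out label must leave the corresponding trained model bit-identical,
and the test suite checks exactly that.

The classifier is the libsvm C-classification solver (via `e1071`) with a
linear kernel; the primal weights and bias are extracted and oriented so a
positive decision score predicts the positive class. A subject's
cross-validated score is the mean of its out-of-fold scores across repeats
(exactly one per repeat); its cross-validated prediction is the sign of that
mean, with ties resolved to the negative class — the conservative choice
when the positive phenotype is rare and costly to over-call. The refit
fold-level models are retained as an ensemble whose external decision score
is the mean of member scores, preserving a continuous score for the
post-hoc regression (majority voting would discard it).

### Significance and stability

The permutation test reruns the *entire* pipeline — selection included — on
label-permuted tables and compares the observed balanced accuracy with the
null distribution, using the add-one-corrected p-value
`(1 + #(null >= observed)) / (1 + n_perm)`.

For interpretation, the per-feature CVR is the mean weight across the models
that selected the feature divided by the standard error of that mean — a
Z-score-like stability index. The standard error denominator follows the
bootstrap-ratio ancestry of the statistic; a plain-SD variant is available
behind a flag since conventions differ. Features never selected have no CVR;
zero weight spread yields a signed infinite sentinel with a warning.
Sign-based consistency tests, per feature, whether the sign of its weight
across selecting models departs from a fair coin: an exact two-sided
binomial test (exactness matters because selection counts can be small),
followed by BH-FDR across all evaluated features at `q = 0.05` — all
features, not only the final model's, since the evaluated family is the
full vocabulary. Only models in which the wrapper selected a feature count
toward its statistics: a zero weight means the feature cannot influence the
decision score, so it carries no sign information.

### Diagnostic metrics and the prevalence sweep

From confusion counts with +1 positive: sensitivity, specificity, balanced
accuracy, PPV, NPV, the number needed to diagnose `NND = 1/(sens+spec-1)`
(infinite when the Youden index is not positive), the predictive summary
index `PSI = PPV + NPV - 1`, and the number needed to predict `NNP = 1/PSI`.
Undefined ratios are reported as absent (`NA`), never as zero, so ensemble
sweeps do not abort on degenerate folds. Prevalence-adjusted PPV/NPV follow
Bayes' theorem; at the sample prevalence they coincide with the count-based
values to machine precision (a tested invariant).

`prevalence_sweep(..., printed_rounding = TRUE)` first rounds sensitivity
and specificity half-up to one percentage decimal. This mode exists because
published prevalence tables are typically derived from the rounded
percentages the running text reports, and the two arithmetics differ
visibly (e.g. NNP at 1% prevalence is 23.57 from rounded inputs but 23.64
from the exact fractions 9/14 and 13/15). The default mode uses full
precision; display rounding is half-up (1 decimal for percentages, 2 for
NND/NNP, 3 for PSI), matching how such tables are printed. Balanced
accuracy is always computed from the formula `(sens + spec)/2`; where a
published table disagrees with its own running text at the last printed
digit (75.0 vs 75.5 for sens 64.3 / spec 86.7), the formula value is
reported and the discrepancy is left to the reader.

### Univariate statistics

The Mann-Whitney U statistic is reported for the first-listed group
(`U1 = sum of ranks - n1(n1+1)/2`), exact for `n1*n2 <= 400` without ties
and tie-corrected normal approximation otherwise — exact enumeration is
cheap at cohort scale and the switch point is far above it. The 2x2
chi-square is the uncorrected Pearson statistic: on the kind of handedness
table these studies print (13/1 vs 14/1), the uncorrected statistic is what
reproduces the published value, so no Yates correction is applied. The FDR
family is always an explicit argument: the covariate family and the
72-feature family are corrected separately.

### Post-hoc stepwise regression

Decision scores are regressed on covariates by classical forward-backward
stepping on partial F-test p-values (entry 0.05, removal 0.10 — the
defaults of the widely used MATLAB `stepwiselm` routine this procedure
mirrors; for a single term the partial F equals the squared t statistic).
The response is the repeat-averaged out-of-fold decision score — the only
per-subject score the pipeline defines that is not contaminated by training
on that subject. Main effects only; subjects with incomplete covariates are
dropped listwise with a logged count. The final term set is refit by OLS,
and a tested invariant is that this refit reproduces the stepping result
exactly.

## The synthetic cohort generator

`generate_cohort()` draws features from a block-correlated Gaussian:
exchangeable correlation `rho` (default 0.3) within each modality block
(FA, MD, RD, AD, SC), implemented by a one-factor construction that is
positive definite for any `rho` in `[0, 1)`. Class means differ by a sparse
effect vector: by default 21 of 72 features carry standardized shifts of
0.3-0.8 SD with mixed signs, placed to mimic the qualitative discriminative
map such studies report (anterior cingulate FA raised in the positive
class, left-amygdala MD/RD lowered, left structural connectivity raised and
right lowered). Features are then affinely mapped onto plausible DTI scales
(FA around 0.45 +/- 0.08 in (0,1); diffusivities positive, in 1e-3 mm^2/s;
connectivity in [0,1]); monotone affine maps leave the correlation/effect
geometry and all rank statistics untouched, which is why no attempt is made
to simulate imaging physics.

The defining property of the default configuration is the
*multivariate-signal, univariate-null* regime at n = 14 vs 15: per-feature
effects of 0.3-0.8 SD are individually undetectable by Mann-Whitney tests
after FDR at this sample size (median flagged count 0 across seeds), while
jointly they support above-chance cross-validated classification. Magnitudes
and `rho` were fixed once when the generator was designed; nothing in the
published study constrains them numerically (no per-feature effect sizes are
printed), so they are free package choices documented here. At the nominal
|effect| sum used, the theoretical latent group separation is about 2.3 SD,
but its realized value varies strongly from cohort to cohort at n = 29 —
individual synthetic datasets range from barely separable to cleanly
separable, exactly as one expects of small-sample neuroimaging data.

Covariates regress linearly on each subject's standardized latent
discriminant score with fixed loadings, plus pure-noise distractors (age,
education, verbal IQ). One covariate is a 3-level ordinal risk rating
obtained by thresholding a latent normal (cutpoints chosen to give roughly
7/29/64% of levels 0/1/2), because the strongest post-hoc predictor in this
study family is an ordinal professional risk assessment.

What passing tests on these cohorts do **not** show about real data: the
generator is Gaussian with exchangeable within-block correlation and exact
affine scaling; real DTI features have heavier tails, site and motion
artifacts, and non-exchangeable spatial correlation. Pipeline performance on
the synthetic default is therefore a software correctness statement, not an
effect-size claim about any real cohort.

## Problem sizes and numerical choices

The published design (10x10 outer and inner cycles over 72 features and an
11-point penalty grid) implies on the order of 10^8 classifier fits once
wrapper selection is counted; that is a cluster-scale computation. The
package exposes exactly that configuration as the default arguments, while
its own test and demonstration runs use desk-scale plans chosen as package
defaults for verification:

- planted-signal recovery: the default 29 x 72 cohort, outer 5 folds x 2
  repeats, inner 5 x 2, penalty grid {1}, 8 generator seeds; medians across
  seeds are compared against chance, against the planted sign map (>= 80%
  CVR sign agreement), and against the univariate screen (median 0 flagged
  features);
- permutation-test calibration: 50 null datasets (6 vs 6, 3 features) x 200
  permutations, outer 2 x 1, inner 2 x 1 — empirical type-I error at
  alpha = 0.05 must stay inside its binomial 95% band;
- wrapper and stepwise oracles: exhaustive subset enumeration at <= 4
  features/candidates.

Other numerical choices: the penalty grid default is logarithmic
`2^(-6..4)` (the study names no grid; this spans under- to over-regularized
regimes for features rescaled to [0,1]); greedy ties break toward the lower
feature index and the smaller penalty; zero ensemble decision scores
predict the negative class; division by zero in any diagnostic ratio
returns `NA`/`Inf` rather than raising; and all RNG flows through a single
master seed expanded by a fixed integer-mixing scheme into per-stage,
per-fold seeds, so identical inputs give bit-identical results on any
platform with R's default RNG.

## Known limitations

- The wrapper's inner criterion is balanced accuracy only (that is the
  published optimization target); no alternative criteria are wired in.
- At n around 30, cross-validated accuracy on a single dataset has large
  variance; apparent below-chance runs on weak datasets are expected
  finite-sample behavior (selection bias conditional on a fixed sample),
  which is why all generator-level guarantees are stated as medians across
  seeds.
- The ensemble holds the outer-level refit winners (one per outer fold and
  repeat). The transient inner-cycle fits are search evaluations and are not
  retained; stability statistics therefore aggregate over `r2 * k2` models,
  not over the much larger inner count.
- No nonlinear kernels, probability calibration, class weighting, or
  alternative learners; no confidence intervals on predictive values.

## A worked example

```{r example, eval = FALSE}
library(dtipattern)

co <- generate_cohort(synthetic_spec(seed = 7))
res <- run_nested_cv(co$features, outer_k = 5, outer_repeats = 2,
                     inner_k = 5, inner_repeats = 2, C_grid = 1, seed = 11)
res$confusion

# prevalence-adjusted metrics from the cross-validated confusion matrix
format_prevalence_table(
  prevalence_sweep(res$confusion$sens, res$confusion$spec))

# stability map and univariate screen
head(feature_stability(res)[order(-abs(feature_stability(res)$cvr)), ])
attr(group_screen(co$features), "n_significant")

# post-hoc regression on the positive class
inp <- assemble_posthoc_inputs(res, co$covariates)
stepwise_fit(inp$response, inp$candidates)
```
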