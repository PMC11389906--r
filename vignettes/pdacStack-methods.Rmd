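---
title: "Diagnosis-specific stacked ensembles for PDAC serum biomarker panels"
author: "pdacStack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosis-specific stacked ensembles for PDAC serum biomarker panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdacStack)
```

# The problem

Pancreatic ductal adenocarcinoma (PDAC) presents late, with symptoms that
overlap heavily with benign hepatobiliary and gastrointestinal disease. In
a symptomatic secondary-care referral population the prevalence of PDAC is
low (on the order of 8%), and the serum marker used in the clinic, CA19-9,
is confounded by exactly the benign conditions — biliary obstruction,
pancreatitis, cystic lesions — that refer patients in the first place. A
useful biomarker classifier in this setting must therefore separate PDAC
not from healthy donors but from each of many confounding diagnoses at
once.

`pdacStack` implements a complete protocol for this problem: instead of one
classifier contrasting PDAC against a pooled control group, it trains one
*diagnosis-specific base learner* per control class (each contrasting that
class's controls against the same PDAC cases) and combines the resulting
classifiers with a logistic *stacking* meta-model. The diagnosis-specific
design has two motivations: each base problem is far better balanced than
cases-versus-all-controls, and each learner is free to select the features
that discriminate PDAC from *its* confounder, which differ across
confounders.

Because the patient-level data such studies rest on are consented and not
public, the package is driven by a synthetic cohort generator that
reproduces the statistical structure the analysis assumes. Every stage is
therefore testable end-to-end, with known ground truth, on any machine.

# The cohort container

A cohort is a `PdacCohort`, a `SummarizedExperiment` with one assay
(`npx`): a markers-by-samples matrix on the NPX log2 scale (the five ELISA
markers — CA19-9, IL6ST, VWF, PKM2, THBS2 — are kept log2-transformed so
that additive effects have the same meaning across the panel). `colData`
carries the diagnosis class (16 control classes plus PDAC), tumour stage
for cases, age, gender, BMI, diabetes, ethnicity, twelve binary
presenting-symptom flags, an optional QCancer percent-risk score, and a
batch identifier. Screening-derived healthy controls carry `NA` symptoms
and QCancer scores: that information is never collected in a screening
trial, and the code treats it as structurally missing rather than zero.

Model features are the marker panel plus five clinical covariates. The
encoding (`featureMatrix()`) is: markers on the NPX scale; age and BMI in
native units; gender as male = 1; diabetes as yes = 1; ethnicity
one-versus-rest against Caucasian by default. For the one-hot ambiguity in
ethnicity modelling, both encodings are available — `featureMatrix()` takes
an `ethnicityRef` argument for one-vs-rest, and a full dummy encoding can
be built by calling it once per category — but all defaults use
Caucasian-versus-rest, which is the contrast reported alongside the
cohort table this package's acceptance values come from.

# The synthetic cohort generator

`simulateCohort(cohortConfig(), seed)` draws a cohort whose **defaults
emulate the marginal structure of a 539-sample symptomatic study**: 46
PDAC cases staged 4/15/10/16/1 (I/II/III/IV/unknown), 421 symptomatic
controls across 15 benign diagnosis classes, and 72 screening-derived
healthy controls (all female, ages ~50–77, separate batch). Case/control
covariate models (age 69.7 ± 10 vs 57.4 ± 15; male fraction 0.67 vs 0.43;
diabetes 0.22 vs 0.18; BMI 24.8 vs 25.3; ethnicity mixes) reproduce the
cohort table's marginals — they are *targets of the generator, not fitted
values*. Marker values are

$$x_{ms} = \mu_m + \delta_{m,g(s)} + b_{m,\text{batch}(s)} + \varepsilon,
\qquad \varepsilon \sim N(0, \sigma^2),$$

with baseline $\mu_m = 5$ NPX, a configurable effect map
$\delta_{m,g}$ of mean shifts per (marker, group), per-assay batch offsets
$b$ drawn with SD 0.3 NPX for the screening batch, and residual SD
$\sigma = 1$ NPX. A Gaussian model on the NPX log2 scale is the platform
convention (per-assay NPX distributions are approximately normal), and it
keeps the effect map's additive semantics exact. The default effect map
plants an elevated-CA19-9 PDAC signature plus class-specific confounding
(CA19-9 elevation in pancreatitis, biliary disease and cysts; CRP in
inflammatory classes; bilirubin in obstruction) — the structure that makes
diagnosis-specific ensembles worth building. Symptom prevalences (e.g.
jaundice 0.50 in cases vs 0.06 in controls; reflux and bloating elevated
in controls) mirror the qualitative case–control symptom pattern of such
cohorts. The QCancer score is a logistic link of age, gender, symptom
count and case status plus logit noise, scaled to percent, so case scores
stochastically dominate control scores; its coefficients are configuration,
not estimates. Missingness defaults to zero, with a `missingRate` option.

What the generator does **not** emulate: assay chemistry (LOD/QC flags,
plate layouts), correlated marker co-expression (markers are conditionally
independent given class), non-Gaussian tails, longitudinal sampling, and
draw-date/centre matching of screening controls. Tests passing on this
generator therefore demonstrate that the *pipeline machinery* is correct
and leakage-free under the assumed structure — not that any particular
marker panel will attain a given AUC on real serum.

`generateBridgePairs()` re-measures a subset of samples (default 16, the
conventional bridging set size) under both batches' offsets with fresh
noise, emulating shared samples plated together in both studies.

# Splitting, bridging, univariate screens

**Split.** `assignSplit()` allocates two thirds of each stratum to
discovery, stratifying on age bin ((18,28], (28,38], …, (68,78], 79+ —
taken verbatim from the protocol this mirrors), diabetes, case/control
label, control diagnosis class, and tumour stage for cases. Rounding
direction within each stratum is randomized by seed so neither arm
inflates systematically (the realized discovery count never deviates from
round(2n/3) by more than one); the protocol source is silent on rounding,
so this is the package's choice. Screening-source controls may carry a
fixed external assignment (`external=`), mirroring reuse of a split
inherited from a prior study; by default they enter the stratified split
like everyone else. Ages below 18 are rejected at load (the emulated
cohort's minimum is 19).

**Bridging.** `bridgeNormalize()` subtracts, per assay, the median over
bridge pairs of (new − reference). The white-paper-style reference-sample
adjustment is a location shift; the median is used for robustness. After
correction the per-assay median bridge difference is exactly zero, the
operation is idempotent, and adding a constant to an assay of the new
batch leaves corrected values unchanged.

**Screen.** `screenFeatures()` fits a univariate Firth model per feature
on discovery, trains the single-feature logistic score there, and scores
both arms — validation is *scored, never refit*. Raw p-values are
reported (with an optional Benjamini–Hochberg column for display only);
constant features are flagged with p = 1 by convention.
`youdenCutoff()` maximizes J = sensitivity + specificity − 1 over
midpoints between adjacent observed scores, breaking exact ties toward
the candidate nearest the score median.

# Firth logistic regression

The univariate screens, symptom associations and separation fallbacks all
rest on `firthFit()`, implemented from first principles. The estimator
maximizes the Jeffreys-penalized log-likelihood
$\ell^*(\beta) = \ell(\beta) + \tfrac12 \log \det I(\beta)$,
which keeps estimates finite under complete separation and, for a single
binary covariate, reduces exactly to the add-½ cross-product odds ratio —
a closed-form oracle the tests exploit.

Numerics: Newton iterations on the modified score
$U^*(\beta) = X^\top(y - \pi + h(\tfrac12 - \pi))$ (h = hat diagonals),
with step-halving on any decrease of $\ell^*$; convergence when the
largest modified-score component falls below `tol = 1e-8`; `maxIter = 50`.
Columns are scaled (not centred) internally so covariates of very
different magnitudes condition the solve equally; estimates are returned
on the original scale (the penalized MLE is equivariant under affine
reparameterization, so this is exact, not approximate). Confidence
intervals profile $\ell^*$: the bound is where twice the drop from the
maximum equals the $\chi^2_1$ quantile, found by doubling-step bracketing
from the estimate and `uniroot`; profiled refits are warm-started at the
unconstrained optimum. Unbracketable roots yield one-sided intervals with
an infinite bound, reported as such. Per-term p-values are penalized
likelihood-ratio tests with the term profiled to zero, matching the
interval construction.

# Subsampling inside folds

Three balancing modes operate strictly on fold-training slices:
oversampling of the minority class (the default for all downstream
modelling, chosen for its generalization in this protocol), undersampling
of the majority class, and SMOTE. SMOTE uses k = 5 neighbours (the classic
default; capped at minority−1), Euclidean distance on features
standardized by the training slice's own statistics, and interpolants
$x_i + u(x_{nn} - x_i)$, $u \sim U(0,1)$; with fewer than two minority
rows it falls back to plain oversampling with a warning. Held-out rows are
never touched by construction: subsampling is invoked only on the
fold-training matrix inside the cross-validation loop.

# Base learners

`trainBaseLearner()` takes one control class's discovery controls plus all
discovery PDAC cases (PDAC coded 1 throughout) and runs leave-one-out
cross-validation over that subset. Inside every fold: standardize by
fold-training statistics → subsample → rank features by recursive feature
elimination (RFE) → fit a logistic model at each candidate subset size →
score the held-out row. RFE drops, at each step, the feature with the
smallest absolute standardized coefficient from a ridge-stabilized
logistic fit (ridge 1e-4, for numerical stability in tiny folds — the
final reported model is refit unpenalized); exact ties are broken
lexicographically, the alphabetically earlier name surviving. The subset
size maximizing the *pooled*-LOOCV AUC wins (per-fold AUC is undefined
for single held-out rows; pooling the held-out probabilities is the
standard resolution, and AUC — consistent with every other metric in the
package — is the selection criterion). Ties go to the smaller size. The
final model is refit on the full subset (standardize → subsample → fit at
the winning size); complete separation switches the final fit to Firth
penalization with a warning. The default size grid is
{1, …, 10, 15, 20, 30, 45, 60, all}, spanning the signature sizes such
protocols report; tests and examples use shorter grids, trading
resolution for runtime.

`predict()` on a `BaseLearner` standardizes by the stored training
parameters and is defined for any sample regardless of diagnosis class.

# Stacking

`fitStack()` builds one meta-feature per learner — the logit of its PDAC
probability, clipped to [1e-6, 1−1e-6] (clipping linearizes the meta
problem and keeps separable learners finite; standard stacking practice) —
and fits a logistic meta-model of PDAC status. By default the meta-inputs
are the learners' in-sample probabilities on the whole discovery set
(`insample`, matching the evaluation convention of the protocol this
mirrors); `out_of_fold` substitutes each learner's LOOCV held-out
probabilities for its own training rows as a leakage-safe alternative.
Both modes are recorded in the model. Separation in the meta problem
triggers the Firth fallback; exactly collinear meta-columns (e.g. two
learners emitting identical clipped logits) are resolved by fitting on an
independent column basis and assigning redundant learners coefficient
zero, which leaves predictions unchanged. Per-learner meta-coefficient
p-values are Wald tests (penalized LRTs under the Firth fallback).

`recursiveLearnerElimination()` greedily removes the learner whose removal
least degrades a stratified 5-fold cross-validated AUC of the meta-fit,
computed on the discovery arm only — the validation arm is never
consulted. `buildReducedSignature()` re-runs the entire ensemble protocol
on a restricted candidate list; the default list is the 8-feature reduced
signature (CA19-9, VWF, CPE, CTSV, CEACAM1, CD160, Diabetes, Age).

# Comparators

`trainRfeGlmWhole()` applies the identical RFE/LOOCV machinery to all
discovery controls versus all cases — one model, no stacking — and is the
fair single-model baseline: it consumes exactly the same candidate
features and splits as the ensemble. `trainTreeComparator()` fits random
forests (`ranger`) or gradient boosted trees (`xgboost`) with a random
hyperparameter search over a declared grid (the number of draws is an
argument; the emulated protocol used 1000), scored by pooled
cross-validated AUC with in-fold subsampling; LOOCV is the default with a
k-fold downgrade for speed. The tree baselines delegate the tree fitting
itself to those established libraries — they are baselines, not the
package's contribution.

# Evaluation

`rocAuc()` is the Mann–Whitney statistic with ties credited ½, computed
via midranks (equal to exhaustive pair counting, which the tests verify).
`metricsAtSpecificity()` reports sensitivity, PPV and NPV at a fixed
specificity (default 90%): the operating threshold is the smallest
*observed* score achieving at least the target specificity when scores at
or above the threshold are called positive — no interpolation, which keeps
operating points reproducible and conservative. If the specificity is
unattainable the threshold is reported above the maximum score and
sensitivity is zero. `stratifiedBootstrapCi()` resamples cases and
controls separately (percentile interval; 2000 resamples by default) and
redraws resamples on which the metric is undefined, logging the count.
PPV/NPV intervals re-derive the operating threshold on every resample
rather than conditioning on the original threshold — the less favourable,
more honest convention. `compareAucBootstrap()` performs the one-sided
paired comparison (default 10000 resamples): the observed difference
divided by the bootstrap SD of the difference, referred to the upper
normal tail; sensitivity at fixed specificity can substitute for AUC in
the same machinery. `evaluateSymptomSubset()` concatenates already-trained
model probabilities across discovery and validation restricted to
carriers of one symptom — no refitting, matching the
probability-concatenation evaluation for small symptom strata — and flags
subsets with fewer than two cases or controls unstable, suppressing
intervals. `qcancerAnalysis()` evaluates the model and the raw QCancer
score above risk thresholds 2, 2.5 and 3 percent and reports the Pearson
correlation between the score and the model's log-odds with its t-test
p-value.

# Feature importance

`permutationImportance()` measures, for each selected feature, the mean
AUC drop over 20 independent permutations of that feature's column;
non-selected candidates score exactly zero without computation.
Permutation drop was chosen as the canonical model-agnostic ranking
measure; the emulated protocol names only a model-agnostic method, so the
specific measure is this package's declared choice.
`aggregateImportance()` scales each learner's importances so its maximum
is 100 and averages across learners with zeros included — features a
learner never selected count as zero for it — sorting ties
lexicographically. On heterogeneous cohorts the per-learner selected sets
genuinely differ, which the tests assert structurally.

# Reproducibility and problem sizes

Every stochastic operation takes a seed; derived stage seeds come from a
deterministic 32-bit map, and the caller's RNG state is always restored.
`runPipeline()` chains simulate → bridge-normalize → split → screen →
train → stack → evaluate (→ importance) and writes a TSV/JSON bundle that
is byte-identical under an identical (config, seed) pair.

The shipped tests run the full protocol at reduced problem sizes chosen to
exercise every code path with known ground truth: cohorts of tens of
samples per class, candidate panels of 4–30 markers, subset-size grids of
3–4 points, LOOCV over 25–50 folds, and bootstrap depths of 200–2000.
The system-level checks use: 100-seed Monte-Carlo runs for planted-feature
recovery (two markers at +2 NPX, 15 controls vs 12 cases); 25-seed
comparisons of stack versus single learners on cohorts with complementary
class-specific masking (four classes of 25 controls, 24 cases, six
markers at ±2 NPX); and 200-replicate coverage simulations at true AUC
0.80 with 100 cases and 100 controls.

# Known limitations

* **Naive bootstrap intervals around pooled cross-validation estimates
  undercover.** Under the null, the pooled-LOOCV AUC of a base learner is
  not exactly centred at 0.5 (small-sample pessimism of leave-one-out
  pooling, partly offset by optimism from subset-size selection), and the
  stratified bootstrap of the pooled held-out scores understates the
  across-replication variance of a cross-validation estimate — there is no
  unbiased variance estimator for cross-validation (Bengio & Grandvalet,
  JMLR 2004). In our null simulations the nominal 95% interval covers 0.5
  in roughly 85% of replicates at realistic base-learner sizes, with
  misses on *both* sides — evidence of interval undercoverage, not of
  leakage (leakage would push AUC systematically above 0.5, which does not
  occur; the in-fold placement of standardization, subsampling and RFE is
  verified structurally). The same caveat applies to any pipeline that
  bootstraps pooled cross-validation scores, including the standard
  caret-plus-pROC practice this package mirrors. Fixed-score evaluations
  (a trained model on a held-out arm) do not have this problem, and their
  interval coverage verifies at 93–97% in simulation.
* The generator draws markers conditionally independent given class;
  correlated co-expression would change feature-selection behaviour and
  is not modelled.
* The whole-cohort tree comparators are baselines delegating to `ranger`
  and `xgboost`; their hyperparameter grids are declared defaults, not
  tuned reproductions.
* The cohort table's diabetes odds ratio is not reproduced by a
  single-covariate 2×2 fit (the add-½ oracle gives ≈1.32 against a
  printed 1.34); additional covariates or slightly different counts were
  evidently involved, so the package does not assert that value anywhere.

# A minimal run

```{r example, eval = FALSE}
cfg <- cohortConfig(
  nPerClass = c("Chronic Pancreatitis" = 25, "Liver Disease" = 25,
                "Other Cancer" = 25, Healthy = 25),
  nCases = 24)
res <- runPipeline(cfg, seed = 1, outDir = "pdac-run",
                   subsetSizes = c(1, 2, 4, 8), nBoot = 500)
res$evaluation$validation
```
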