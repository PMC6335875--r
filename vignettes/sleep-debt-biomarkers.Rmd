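---
title: "Penalized-regression biomarker panels for sleep debt: models, design choices, and what the synthetic benchmarks show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Penalized-regression biomarker panels for sleep debt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepmarkr)
```

## The problem

Acute total sleep deprivation and chronically restricted sleep both leave
signatures in the whole-blood transcriptome, and a practical biomarker of
sleep debt would read that signature from one blood sample. The obstacle
is that blood gene expression is highly *trait-like*: stable differences
between individuals are typically far larger than the *state* effect of
having been awake too long or having slept too little for a week. A
classifier can therefore look excellent under naive cross-validation — by
memorizing people rather than physiology — and collapse on new subjects.

`sleepmarkr` implements the full discovery-and-validation workflow for
this setting: penalized regression (elastic net and ridge) over ~20k
expression features, lambda tuning by repeated stratified 10-fold
cross-validation, subject-aware data partitioning, leave-one-subject-out
cross-validation (LOSO-CV), and independent validation, for five
sleep-debt variables (time awake; wakefulness beyond 24 h; acute sleep
loss; chronic sleep insufficiency; sleep increase/decrease). A synthetic
crossover-cohort generator with per-feature ground truth makes the whole
chain testable.

## The models

For a quantitative target (hours awake) the prediction model is linear,

$$\hat y = \beta_0 + \beta_1 x_1 + \dots + \beta_n x_n,$$

and for two-class targets it is logistic,
$\hat y = e^{\eta} / (1 + e^{\eta})$ with $\eta$ the same linear
predictor, read as the positive-class probability. Coefficients are
estimated by penalized likelihood with the elastic-net penalty

$$\min_{\beta_0, \beta}\; L(\beta_0, \beta) +
  \lambda\left[\alpha\|\beta\|_1 +
  \tfrac{1-\alpha}{2}\|\beta\|_2^2\right],$$

where $L$ is $\frac{1}{2n}\sum_i (y_i - \beta_0 - x_i'\beta)^2$ for the
linear family and the mean negative Bernoulli log-likelihood for the
logistic family. `alpha = 0.5` (elastic net) yields sparse panels —
features with exactly nonzero coefficients are the biomarkers — while
tolerating correlated features; `alpha = 0` (ridge) retains every input
feature and is paired with the a-priori screened sets. The solver is
cyclic coordinate descent over internally standardized features with an
unpenalized intercept, soft-thresholding updates, warm-started
regularization paths, sequential strong-rule screening with exact KKT
verification, and penalized IRLS for the logistic family (probabilities
clipped at $10^{-5}$ for weight stability). The `1/(2n)` normalization
makes lambda values stable in the sample size. Tests verify the solver
against the ridge closed form, the orthonormal-design soft-threshold
closed form, subgradient optimality conditions, and glmnet as an
independent oracle (for the gaussian family glmnet internally scales the
response to unit variance, which rescales the effective L2 penalty; the
comparison therefore uses unit-variance responses).

## Lambda tuning

Folds are assigned randomly but stratified — on the class for logistic
targets, optionally on a covariate for linear ones — and the held-out
error (squared error, or binomial deviance for logistic: the ecosystem
default, declared here) is averaged per lambda over a shared
log-spaced grid. The per-repeat optimum is the argmin, with ties resolved
to the larger lambda (the sparser model), and the final lambda is the
*arithmetic mean* of the per-repeat optima on the raw scale — the
workflow's tuning rule, applied here exactly. The full-scale rule uses
500 repeats; desk-scale runs in this package default to 20 (and fewer
inside LOSO folds, `loso_repeats = 5`), which the stability test shows
moves the mean lambda by less than three repeat-wise standard errors.

Grid defaults follow the solver convention of a 100-point log-spaced grid
down to `1e-3` of $\lambda_{max}$; the pipeline and the benchmark
scenarios use a 50-point grid down to `1e-2`, the usual choice when
features far outnumber samples (the deep tail of the path is then a
saturated-interpolation regime that no argmin selects but that dominates
run time).

## Partitioning and leakage control

Two training/validation constructions are implemented. **UPUS** (unique
participants, unique samples) assigns whole subjects to sides by a
stratified draw — strata default to sex; for the sleep-change variable the
clinic-visit order is an additional stratum, since it determines the
direction of each subject's change. Per-stratum training counts are
floored and remainders handed out by largest fractional part, so a 36
subject cohort splits exactly 18/18. **OPUS** (overlapping participants,
unique samples) sends each subject's two condition blocks to opposite
sides, with the condition-to-side assignment randomized under a
$\pm 1$ balance constraint.

All training-side computations — 75th-percentile normalization is
per-sample and safe, but flagged-feature removal (strictly more than 10%
of *training* samples flagged), a-priori screening, lambda tuning, and
the final fit — see training data only. LOSO-CV repeats that entire chain
with each subject's units removed, so a held-out subject's samples never
influence the model that predicts them; a test verifies that changing a
held-out subject's labels leaves that subject's predictions bit-identical.

Boundary conventions (decision thresholds are part of the contract):
probability 0.5 and predicted-time-awake 24 h classify *negative* when
hit exactly; metrics with zero denominators are reported `NA`, never 0.

## A-priori screening

The two screened feature sets are defined by three desk-scale tests, each
with subject fixed effects: a per-condition OLS trend on hours awake
(two-sided t), a cosinor fit — cosine and sine of clock time after a
linear hours-awake term, joint F test, amplitude
$\sqrt{\beta_c^2+\beta_s^2}$ — and a paired t test of subject-level
condition means. The "hours awake" set requires a sign-concordant
significant trend in both conditions and no circadian or condition
signal; the "sleep sufficiency" set requires a condition difference and
no circadian or trend signal. The original analysis derived these
criteria from a mixed-model time-course framework that is out of scope
here; these tests are declared substitutes with the same selection
semantics. No multiple-testing correction is applied at the screen, and
`alpha_screen` defaults to 0.05.

One property worth stating precisely: shrinking `alpha_screen` shrinks
each *positive* criterion monotonically, but the full sets are
conjunctions with negated exclusion criteria (which grow as alpha
falls), so the set sizes themselves are not monotone in alpha. The test
suite asserts the monotone part.

## The synthetic cohort

The generator emulates the study design: 36 subjects (sexes alternating),
a balanced crossover of one week of sufficient vs insufficient sleep,
and ten 3-hourly samples per visit spanning 7.5–34.5 h awake, with clock
time wrapping at 24 h so that sample #9 recurs at sample #1's clock time
— reproducing the circadian/homeostatic confound of a constant routine.
Feature classes add, on the log2 scale: a linear time-awake trend, a
24-h cosine in clock time with random acrophase, a sleep-condition
shift, both (mixed), or nothing (null), plus a subject random effect
drawn once per (feature, subject) and shared across visits, and iid
Gaussian noise. Defaults `trait_sd = 1.0` and `noise_sd = 0.4` log2
units are package choices (the real within/between variance ratio is not
published); they put the trait variance well above the state effects,
which is the regime the workflow exists for. Quality flags are iid
Bernoulli, default 1%.

What the generator does *not* emulate: probe-level artifacts, spatial or
batch effects, heavy-tailed noise, correlated feature blocks beyond the
shared subject effect, and realistic sample dropout. Passing benchmarks
therefore demonstrate that the pipeline recovers structure it was built
for — not that real data are this clean.

## Benchmark scenarios and their sizing

Four fixed scenarios (exported as `scenario_*`) exercise the chain; all
effect sizes were set by design-time power arithmetic, not adjusted to
outcomes.

- **Tuning recovery** (`scenario_tuning`): 12 subjects, 2,000 features of
  which 10 carry a time-awake trend with per-feature standardized effect
  1.5 (slope times the sampling-range sd of hours awake, over the total
  noise sd). Repeated-CV elastic net recovers all ten in every tested
  seed. The panel also admits a small fraction of the 1,990 null
  features — around 5% — which is the well-documented behavior of
  argmin-based cross-validation (an independent `cv.glmnet` run on the
  identical problem selects a panel of similar composition); panel
  *purity* is therefore not a meaningful target at this scale, and the
  benchmark tracks the null-pool selection rate instead.
- **Acute sleep loss** (`scenario_acute`): 30 trend features with slope
  0.03 log2/h. Between samples #1 and #9 (24 h apart, same clock time)
  each feature moves 0.72 log2 units against a between-subject sd of
  $\sqrt{1 + 0.25^2} \approx 1.03$, a per-feature d of 0.67; thirty
  independent such features give a combined separation of
  $\sqrt{30}\,d \approx 3.7$, i.e. a Bayes error near 3% — the "clearly
  solvable between subjects" regime.
- **Chronic insufficiency** (`scenario_chronic`): condition shift 0.15
  log2 units against trait sd 1.0 ($\delta \ll \tau$). Forty such
  features give a combined between-subject separation of only
  $\sqrt{40}\cdot 0.146 \approx 0.9$ (Bayes accuracy ≈ 68%, and far less
  is realized at n = 36 training samples), while the within-subject
  visit difference cancels trait, trend, and circadian terms entirely,
  leaving $d \approx 0.85$ per feature and a near-perfect Bayes ceiling.
  The within arm uses ridge on the screened sleep-sufficiency set — the
  configuration that performs best for this variable in the study — and
  the between arm uses elastic net over all features.
- **Subject-confounded OPUS** (`scenario_confounded_opus`): no condition
  effect at all. Any fitted signal is subject memorization; under OPUS
  the same subject reappears in validation with the *opposite* label, so
  the classifier anti-predicts (IV MCC near −1 in practice), while
  subject-disjoint LOSO-CV stays at chance. This reproduces, in pure
  form, the negative-MCC pathology that motivates subject-aware
  validation.

Desk-scale problem sizes throughout (12–36 subjects, 500–2,000 features,
20 tuning repeats) were chosen so the full suite and the acceptance
script each run in minutes on a single core.

## Numerical choices and degenerate inputs

Convergence is declared when the largest absolute coefficient change in
a sweep falls below `tol` (`1e-7` for single fits; `1e-5` inside
cross-validation, where held-out error is insensitive at that level).
$\lambda_{max}$ is nudged up by one part in $10^9$ so the top-of-grid
fit is exactly null; the `alpha = 0` grid uses the conventional 0.001
floor in the $\lambda_{max}$ formula. Zero-variance features are pinned
at zero coefficient; all-constant targets, single-class logistic
targets, missing reference samples, and strata or folds too small to
stratify either error with a named cause or reduce `k` with a warning,
as documented on each function.

## Known limitations

The percentile normalization is a per-sample shift on the log2 scale
(the idempotent analogue of 75th-percentile scaling); vendor software
may scale instead, so absolute intercepts are not comparable across
conventions. The screening tests assume additive subject effects and a
single 24-h harmonic. The generator's independence of features given the
subject effect understates the correlation structure of real
transcriptomes, which elastic net exploits; real-data panel sizes and
accuracies will differ. Counts from the original cohort (e.g. per-set
sample totals after dropout) are data-dependent and are not targets of
the synthetic benchmarks.
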