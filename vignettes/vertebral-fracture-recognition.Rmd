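---
title: "Recognising morphometric vertebral fracture burden: evolutionary neural networks versus stepwise logistic regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognising morphometric vertebral fracture burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdiann)
```

## The problem

Morphometric vertebral fractures — vertebral deformities detectable by
height measurement on spinal radiographs — are the earliest and most
prevalent manifestation of osteoporosis, are frequently silent, and are
among the strongest predictors of further fractures. The Spinal Deformity
Index (SDI) integrates their number and severity: each of the 13 vertebrae
T4–L4 receives a semiquantitative (Genant) grade 0–3 from its height
compression, and the SDI is the sum of the grades (0–39).

`sdiann` rebuilds, as a tested and reusable pipeline, an analysis that asks:
from 45 routine clinical variables (44 clinical parameters plus a
densitometric low-BMD flag), how well can a classifier recognise women with
any fracture (SDI ≥ 1 vs SDI = 0) or with a high fracture burden (SDI ≥ 5 vs
SDI = 0)? Two arms are compared on identical resampling partitions:

* an **evolutionary neural-network pipeline** — a genetic algorithm
  co-optimises a distribution-balanced train/test split and an
  input-variable mask, scored by twin four-hidden-unit perceptrons trained
  crosswise on the two halves; and
* **forward stepwise logistic regression** over all 45 variables.

Because the original patient-level data were never deposited, the package
ships a seeded synthetic-cohort generator calibrated to the published
marginal distributions and multivariable odds ratios; every stage of the
pipeline is exercised against it.

## Morphometry and grading

Six-point morphometry places superior/inferior landmarks at the anterior,
middle and posterior vertebral borders; heights are Euclidean distances
between the pairs (`heights_from_landmarks()`), hence invariant to rigid
motion of the film. `sq_grade()` computes the compression

$$c = \max\left(1 - \frac{h_a}{h_p},\; 1 - \frac{h_m}{h_p},\;
  1 - \frac{h_p}{h_p^{\mathrm{ref}}}\right)$$

and bands it: grade 0 below 20 %, grade 1 (mild) 20–25 %, grade 2
(moderate) 25–40 %, grade 3 (severe) above 40 %. The printed bands share
the 25 % edge, so a tie-break convention is needed: exactly 20 % is grade 1
and exactly 25 % and exactly 40 % are grade 2 (half-open mild band, closed
moderate band). Compressions are rounded to nine decimals before banding so
that heights constructed to sit exactly on an edge are not pushed across it
by floating-point error.

Two further choices the source text leaves open:

* **Vertebral span.** The text says "13 vertebrae from T5 to L4", but
  T5–L4 is 12 vertebrae while the accompanying sum enumerates
  T4 … L4. We use T4–L4: it is the only reading consistent with both the
  count of 13 and the SDI's definition over T4–L4.
* **Crush reference.** A crush deformity lowers the posterior height
  itself, so its compression needs an external reference. We use the mean
  posterior height of the two adjacent vertebrae (the single neighbour at
  the T4/L4 ends, the vertebra's own height when nothing else is
  available).

`generate_vertebral_heights()` inverts the grading for testing: it draws
posterior heights around a cranio-caudal gradient (20 mm at T4 to 34 mm at
L4, ±3 %) and compresses the anterior height to a target strictly inside
the requested band (grade 0 < 15 %, grade 1 in 20.5–24.5 %, grade 2 in
25.5–39.5 %, grade 3 in 40.5–60 %), middle height at 60 % of the anterior
compression. Keeping targets strictly inside the bands, and posterior
noise well below the 20 % threshold, makes the round trip
(heights → grades) exact — a property the tests assert on a thousand
random grade vectors.

## The 45-variable design

`variable_spec()` documents the analysis matrix: six continuous variables
(age, BMI, years since menopause, pregnancies, months of breast feeding,
daily calcium intake), derived bins (age at 68, BMI at 21 and 30 kg/m²,
YSM at 18 years, calcium at 300 mg/day) and yes/no risk-factor pairs in
*complement coding* — each factor contributes a yes column and a no column
summing to one, so a wrapper selector can pick either member and carry the
same information. Boundary values belong to the upper bin (age 68 counts
as ≥ 68, and so on), following the printed "≥" labels.

The published table enumerates 43 input rows yet the study counts 45
variables. The participant description records family history of
osteoporosis separately from family history of hip fracture, while the
table lists only the latter; adding the osteoporosis-family-history pair
is the only reading we found that reaches exactly 45, so the design
includes it (prevalence default 0.25 — not printed anywhere, chosen as
realistic for an osteoporosis out-patient population).

Unit conversions follow the questionnaire rules: one alcohol unit is 8 g
of pure alcohol, the analysis dichotomises at ≥ 3 units/day, and intakes
above 100 g/day flag the record for exclusion; one dairy serving carries
300 mg calcium, converted to mg/day as weekly servings × 300 / 7. There is
no imputation: `exclude_incomplete()` applies the study's complete-case
rule and logs what was missing for whom.

## The synthetic cohort

`cohort_config()` defaults *are* the study conditions:

* continuous marginals from the published cohort description — age
  truncated-normal 68.0 ± 8.5 (40–95), calcium 636 ± 404 mg/day (0–3000),
  BMI 23.5 ± 3.5 (16–41); years since menopause is derived as age minus an
  age at menopause ~ N(50, 4) truncated to 35–60, which preserves the
  age–YSM coupling that makes both correlate with fracture burden;
* binary prevalences from the same table (hypertension 0.296, low BMD
  0.651, current smokers 0.153, COPD 0.038, …);
* a fracture liability whose coefficients default to the published
  multivariable odds ratios for the any-fracture endpoint: 1.07 per year
  since menopause, 1.28 previous fragility fracture, 1.54 hypertension,
  2.63 COPD, 1.00 per mg/day calcium, 1.06 low BMD, 2.21 absence of
  dyslipidemia.

Fracture generation is two-stage. Case status (SDI ≥ 1) is Bernoulli with
logit exactly `intercept + β'x` — the intercept (−2.2492) was calibrated
once, by simulation against the covariate defaults, to the observed case
fraction 176/372. Making the endpoint model *exactly* logistic is a
deliberate design choice: it is what lets a large generated cohort return
the configured odds ratios when the same seven-covariate model is refitted
(the package's calibration-recovery check). Drawing 13 independent
per-vertebra Bernoullis from the same liability instead would make
P(SDI ≥ 1 | x) non-logistic and bias the refit. Within cases, fractures
are then placed on the 13 vertebrae: one index fracture plus an
overdispersed count of additional fractured vertebrae
(negative binomial, size 0.6, log-mean 0.1 + 0.15 × liability, capped at
12), each graded 1–3 with probabilities 0.6/0.3/0.1. The severity-stage
constants were likewise frozen once against the published fracture-burden
marginals: they give ~13 % of patients at SDI ≥ 5 (published 51/372 =
13.7 %), a median case SDI of 2–3 (published 2) and a long right tail
(maxima in the high twenties; published 24). Because both stages increase
with the same liability, raising any positive-coefficient covariate can
only raise the expected SDI — the monotonicity property the tests check by
simulation contrast.

What the generator does *not* emulate: correlations among risk factors
(smoking × COPD, say — the source reports none, so factors are independent
given the liability); any nonlinearity or interaction in the true risk
(the signal is exactly logistic); and measurement error in the grades.
The last point matters when reading the arm comparison below.

All randomness flows from one master seed through named substreams, so a
change in how many draws one stage consumes cannot shift another stage's
output, and identical seeds give bit-identical cohorts.

## The classifier and the wrapper

`mlp_train()` is the classical fully connected perceptron
(inputs → 4 hidden sigmoid units → 1 sigmoid output) trained by
backpropagation — gradient descent with momentum on the sum-of-squared
errors (cross-entropy is available as an option). Inputs are min–max
scaled to [0, 1] with training-subset extremes (`scale_inputs()`), test
values clipped. The single output in (0, 1) is thresholded at 0.5, with
0.5 itself read as class 0 (the source's 0–0.5 / 0.51–1 wording). The
original software's training hyper-parameters are not published; defaults
here are learning rate 0.1, momentum 0.9, at most 500 epochs with
patience-25 early stopping on the training error, weights initialised
uniform(−0.5, 0.5) — all configurable and all seeded. With full-batch
sums, learning rates much above 0.1 saturate the output sigmoid on
a few hundred records; the tiny-sample XOR fixtures in the tests use
larger rates deliberately.

`run_twist()` approximates the proprietary evolutionary wrapper with a
standard generational GA, documented as such: tournament selection (size
3), uniform crossover (rate 0.9), per-bit mutation at one expected flip
per chromosome part (1/n for the split bits, 1/L for the mask bits),
elitism (2), and a "doping" step replacing the worst 5 % with random
immigrants each generation. A chromosome is a train/test half-assignment
plus a variable mask; a repair operator keeps halves class-stratified and
within ±10 % of half the sample, and masks non-empty. Fitness is the mean
balanced accuracy of twin, freshly initialised perceptrons trained
crosswise (a–b and b–a) on the masked variables, minus λ (default 0.5)
times the split's distribution penalty — the mean over variables of the
two-sample Kolmogorov–Smirnov statistic (continuous) or absolute
prevalence difference (binary). The source states both goals (balanced
splits, informative variables) but not their coupling; λ makes the
coupling explicit and testable: at λ = 0 the fitness is exactly the mean
crossover accuracy. Within a generation all individuals share one
network-initialisation seed, so chromosome comparisons are not confounded
by initialisation luck. Whether the original split and mask optimisations
ran jointly or in sequence is ambiguous in the source; both modes are
implemented (`mode = "joint"` is the default, `"sequential"` runs the
split phase first, then the mask under the frozen split).

## Evaluation protocol

`five_by_two_cv()` implements the validation protocol: five seeded random
stratified halvings, each used twice with training and testing roles
reversed; models are trained, their weights frozen, and only then shown
the test half; ten fold reports result. **Overall accuracy is
(SN + SP)/2** — balanced accuracy — because that is the arithmetic the
published tables use (72.5/78.5 → 75.5 and so on); the raw proportion
correct is kept as a secondary field. A pooled empirical ROC is built from
all out-of-sample scores; `roc_auc()` computes the non-parametric curve
whose trapezoidal area equals the Mann–Whitney pair-count probability
(ties one half) — asserted exactly against a brute-force pair-counting
oracle. `compare_auc()` implements the correlated-AUC z-test with
Hanley–McNeil standard errors; the correlation between the two areas is
estimated as the mean of the within-case and within-control Pearson
correlations of the two score vectors (the source cites the method but not
its r; this estimator is the conventional one, and r = 0 recovers the
unpaired test). `fold_homogeneity_chi2()` reads the published fold-table
footnote as a goodness-of-fit chi-square of per-fold correct/incorrect
counts against the pooled rate — one reasonable interpretation, flagged as
such.

Group comparisons (`group_compare()`) follow the published statistical
methods: a Kolmogorov–Smirnov normality gate per group chooses t-test or
Mann–Whitney for continuous variables; binaries use the chi-square with
Yates continuity correction — the corrected form reproduces the published
hypertension contingency p = 0.017 where the plain Pearson gives 0.013.
One published p-value (anxiety/depression, 0.048) is reproduced by
neither: Fisher's exact on the printed counts gives 0.048, so that row was
likely tested differently; the package leaves Yates as the default and
documents the discrepancy. Percentages are reported to one decimal and
p-values to three, rounding half away from zero, for parity with the
tables.

`forward_stepwise()` uses likelihood-ratio entry/removal tests (the
conventional SPSS "forward: LR" choice; the source does not say which
statistic) at the published, unusual levels — enter at p < 0.30, stay at
p ≤ 0.35 — implemented verbatim. Exact ties break lexicographically, so
the result does not depend on candidate order. The complement-coded
design is deliberately redundant; a second pair member offered to the
model is exactly collinear, detected by rank check, and simply skipped as
a candidate. `fit_logistic()` is iteratively reweighted least squares
with step-halving (the log-likelihood trace is returned and asserted
non-decreasing); quasi-separation at small n is flagged, reported with
pseudo-inverse-based standard errors, and never silently "fixed" (no
penalised fallback — noted as a possible extension).

## The pipeline and what passing means

`run_pipeline()` wires the stages together for one endpoint: simulate (or
load) → encode → complete-case filter → evolutionary selection →
twin-perceptron 5×2 cross-validation on the selected variables → stepwise
logistic regression on all 45 variables over the *identical* partitions →
paired correlated-AUC comparison. The regression arm deliberately sees all
45 variables while the network arm sees the selected mask, mirroring the
published variable counts (45 vs 17/25). Every run directory carries a
manifest of derived stage seeds sufficient to reproduce any stage; reruns
with the same master seed are byte-identical.

Two caveats on interpretation. First, on the synthetic cohort the true
signal *is* logistic, so the correctly specified regression arm is
expected to match or beat the network arm there — the pipeline's arm
comparison on simulated data is a wiring check, not a replication of the
published superiority, which arose on real data with whatever
nonlinearities it contained. The tests therefore verify the network arm's
advantage where one provably exists: a planted XOR-style interaction of
two binaries, invisible to any main-effects logistic model. Second,
passing tests on this generator say nothing about radiograph reading,
measurement error, or risk-factor correlation structure, none of which
are emulated.

## Problem sizes and numerical choices

The test-suite and analysis scripts run the search at reduced sizes
(population ~20, ~20 generations, 60–100-epoch inner networks; recovery
simulations at n = 600–1,000; calibration refits at n = 50,000), chosen so
the full suite completes comfortably on a single core while leaving each
property statistically decidable; all sizes are configuration, not code.
Degenerate inputs fail loudly and early: empty halves, all-missing
records, constant columns (scaled to zero with a warning), absent classes,
non-finite inputs, diverging training (non-finite error stops with a
diagnostic rather than returning a broken model). A liability intercept of
−Inf is a supported degenerate configuration producing a fracture-free
cohort, which in turn exercises the endpoint guards.

## Known limitations

* The proprietary evolutionary optimiser is approximated by a documented
  standard GA; no operator-level fidelity is claimed, and the published
  selected-variable lists are not expected to be reproduced.
* The published real-data performance figures (sensitivities,
  specificities, AUCs 0.714/0.823) are not reproducible without the
  patient-level data and are not targets of any test; only the published
  worked-example arithmetic, one printed contingency statistic, and the
  odds-ratio calibration are pinned numerically.
* Confidence intervals on the published AUCs are narrower than
  Hanley–McNeil standard errors imply for the stated group sizes; the CI
  method here is Hanley–McNeil and no parity is claimed.
* The stepwise arm refits within every training half, which is the honest
  paired design but differs from fitting once on the whole sample; a
  whole-sample regression is available directly via `fit_logistic()` /
  `forward_stepwise()`.
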