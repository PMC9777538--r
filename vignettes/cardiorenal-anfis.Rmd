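---
title: "Cardiorenal risk modelling with a 27-rule Takagi-Sugeno ANFIS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cardiorenal risk modelling with a 27-rule Takagi-Sugeno ANFIS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cranfis)
```

## The problem

Patients with combined heart and kidney impairment (cardiorenal syndrome)
are monitored through a small set of routine quantities: the natriuretic
peptide NT-proBNP (pg/mL, a marker of cardiac wall stress and volume
overload), serum sodium and potassium (mmol/L), left-ventricular ejection
fraction (EF, %), and an estimated glomerular filtration rate from serum
cystatin C (mL/min/1.73 m^2). The clinical boundaries between "compensated"
and "decompensating" are fuzzy rather than crisp — a potassium of 3.4 versus
3.6 mmol/L is not a categorical change — which motivates a fuzzy-inference
model over these variables rather than threshold rules.

`cranfis` implements that model as a five-layer adaptive neuro-fuzzy
inference system (ANFIS) of Takagi–Sugeno type: NT-proBNP, Na+ and K+ are
the three inputs, and either EF or the cystatin-C GFR is the single output.

## Model

All variables are first mapped to $[0,1]$ by min-max normalization. The
default bounds are frozen at the cohort ranges the model was described on
(NT-proBNP 10–5000 pg/mL, Na+ 123–150 mmol/L, K+ 2.4–7.8 mmol/L, EF
12–75 %, GFR 14–146 mL/min/1.73 m^2), so the normalized clinical
thresholds are reproducible regardless of which sample is in hand:
K+ 3.5 mmol/L maps to 0.20, Na+ 135 mmol/L to 0.44, and GFR
90 mL/min/1.73 m^2 to 0.58 (all half-up at 2 decimals). `fit_minmax()`
refits bounds from data when the frozen defaults are not wanted.

Each input is stratified into *low / normal / high* by three trapezoidal
membership functions arranged as a Ruspini partition: adjacent trapezoids
share linear ramps of width $2s$ (shoulder $s = 0.05$ normalized units by
default) centred on the normalized band edges, so the three memberships
sum to exactly 1 everywhere on $[0,1]$. This guarantees full coverage —
no input can fire zero rules — and makes the normalization layer
well-defined. The default band edges are the published normalized bands
(K+ 0.20–0.60, Na+ 0.44–1.00, NT-proBNP 0.30–0.60); they are stored as
configurable constants rather than derived, because only the K+ and Na+
lower edges coincide exactly with laboratory reference limits mapped
through the frozen ranges (3.5 mmol/L → 0.2037 prints as 0.20; the K+
upper reference 5.5 mmol/L would give 0.57, not the published 0.60, and
the NT-proBNP band does not correspond to the 100/300 pg/mL cutoffs under
these bounds). The discrepancy is documented, not resolved.

The rule base is the full Cartesian product: $3^3 = 27$ first-order
Takagi–Sugeno rules

$$\text{if } x_1 \in A_i \wedge x_2 \in B_j \wedge x_3 \in C_k
  \text{ then } V_l = c_1 x_1 + c_2 x_2 + c_3 x_3,$$

with firing strengths $\omega_l$ (product t-norm by default; minimum
available), normalized strengths $\bar\omega_l = \omega_l / \sum_m
\omega_m$, and output $\hat y = \sum_l \bar\omega_l V_l$. Two readings of
the published consequent notation are possible — crisp inputs or
membership degrees; the standard first-order Takagi–Sugeno reading (crisp
normalized inputs) is implemented. No intercept is carried by default
(the printed rule form has none); `bias = TRUE` adds one.

## Training

Training minimizes the mean square error (MSE) of the normalized output by
full-batch gradient descent, stopping at 1000 epochs or when the training
MSE reaches 0.0005, the published regime. Everything the source text does
not state — split proportions, learning rate, optimizer — takes the
smallest-assumption default: 70/15/15 train/test/check split (floors to
the test and check sets, remainder to train; seed-deterministic shuffle),
learning rate 0.01, plain gradient descent. Two modes are provided:

* `bp`: both the consequent coefficients and (optionally) the trapezoid
  breakpoints descend the gradient. The memberships are piecewise linear,
  so breakpoint derivatives are subgradients; at the non-differentiable
  corners the plateau-side (zero) subgradient is used, and after every
  step the four breakpoints are projected back to a valid trapezoid by
  sort-and-clip to $[0,1]$.
* `hybrid`: given the premises, the consequent subproblem is linear least
  squares and is solved exactly each epoch; premises move by gradient.

The hybrid normal equations carry a small Tikhonov term
($10^{-4}$ of the mean Gram diagonal). This is a numerical-stability
choice, not a modelling one: rules that barely fire in a training set
contribute near-null design columns whose unpenalized coefficients are
arbitrary and can explode off-sample; the penalty pins them near zero
while biasing the well-identified coefficients by orders of magnitude
less than the 0.0005 stopping tolerance (noise-free refits reach
~1e-8 training MSE).

Premise-gradient training is implemented for the product t-norm only;
with the minimum t-norm the premises stay frozen (a classed warning says
so). Divergence (non-finite loss) aborts with learning-rate guidance
rather than returning garbage.

`evaluate_anfis()` reports test and check MSE plus
`relative_check_deviation_pct` $= 100\,|MSE_{check} - MSE_{test}| /
MSE_{test}$. This operationalizes the published remark that checking
"varies in accuracy values of approximately 15%": the original metric is
not defined and the underlying patient data were never deposited, so the
quantity is computed and logged but never asserted against 15%.

## Synthetic cohort

No patient-level data are available, so the package generates cohorts
with the statistical structure of the published 90-subject group
(52 men / 38 women):

* Na+ — truncated normal on [123, 150], calibrated to mean 138, SD 4.12;
* K+ — truncated normal on [2.4, 7.8], mean 4.85, SD 0.88;
* NT-proBNP — truncated lognormal on [10, 5000], targeting mean 1275.77
  and SD 1533.89 (SD > mean forbids a near-symmetric family);
* age — truncated normal on [18, 88], mean 65.98, SD 15.74 (generated but
  unused by the model, mirroring the non-significant age difference in
  the source cohort).

Calibration profiles the mean constraint — for each candidate scale the
location solving the truncated-mean equation is found by bisection — and
then minimizes the relative SD error over the scale, verified in the test
suite against numeric integration of the truncated moments. For Na+, K+
and age both moments match within 0.5%. **The NT-proBNP targets do not:**
the pair (mean 1275.77, SD 1533.89) lies outside the attainable moment
region of any lognormal truncated to [10, 5000] (the family's boundary,
the power-law limit of infinite log-scale, tops out near SD 1390 at that
mean). The calibrator therefore matches the mean exactly, attains the
closest SD (~1385), and emits a classed warning. This is a genuine
property of the printed numbers — the companion evaluation table even
prints a second, mutually inconsistent SD of 252.00 for the same
variable — and is surfaced rather than hidden. The printed cystatin C
row (min 1.73 above max 0.21) is likewise inconsistent and cystatin C is
not generated; the GFR output is generated directly.

Predictors are drawn independently (no covariance structure is
published; a documented simplification). EF and GFR then follow a latent
monotone response on the normalized scale,

$$y = \mathrm{clip}\big(\beta_0 - \beta_1\,\mathrm{bnp} -
\beta_2\,d(\mathrm{na}) - \beta_3\,d(\mathrm{k}) + \varepsilon\big),$$

where $d(\cdot)$ is the distance to the electrolyte stability band,
$\varepsilon \sim N(0, 0.05^2)$ by default, and the EF weights are
$(1, 0.7, 0.25, 0.25)$, GFR $(1, 0.6, 0.2, 0.3)$ (potassium weighted
slightly higher for the renal output). These coefficients are package
plumbing chosen once for realism — high NT-proBNP with low EF/GFR, the
qualitative structure the trained model must recover — and the only
properties asserted about them are monotonicity and a Spearman rank
correlation below −0.3 between NT-proBNP and EF. Outputs are clamped to
the printed ranges. Sex has no effect on any generated variable, and sex
percentages are truncated (not rounded) to two decimals, matching the
published 52/90 → 57.77% convention.

What a green generator test establishes: marginal moments, bounds, sex
composition and a recoverable monotone signal. What it does not: real
covariance between electrolytes and peptide levels, measurement error
structure, or any group-difference statistics of the original cohort —
which is why the published Mann–Whitney p-values are out of scope.

## Risk surfaces and classification

`response_surface()` evaluates the trained model over a normalized grid of
two predictors with the third fixed (default 0.5), reproducing the six
published panel configurations (EF and GFR against each predictor pair)
through the same forward pass as point predictions — no duplicated math.
Classification applies the published normalized thresholds with explicit
boundary conventions, which the source does not state: "below" is strict
(`<`), band membership is inclusive. A predicted normalized EF below 0.5
flags a serious adverse event, a normalized GFR below 0.58 flags renal
failure, and the HFrEF phenotype uses the physical-unit cutoff (predicted
EF < 40%) because the published figure's color scale is not quantitative.
Whether the published 0.5 EF line is a normalized or raw threshold is
ambiguous (normalized over 12–75% it corresponds to 43.5%); the printed
normalized reading is the default and the threshold is configurable.

## Numerical choices

* Half-up rounding (with a $10^{-9}$ tie guard against binary
  representation) for reported 2-dp thresholds; base `round()` ties to
  even and would turn 0.575 into 0.57.
* Degenerate trapezoid edges ($a=b$ or $c=d$) are legal step edges
  evaluating to the plateau side.
* Model JSON serializes numbers at 17 significant digits, so
  `load_model(save_model(m))` predicts bit-identically; cohort CSVs are
  written at full double precision for the same reason.
* An all-zero firing vector raises an explicit "uncovered input" error;
  it is unreachable under the default Ruspini partition but reachable
  with user-supplied membership functions.
* All randomness (generation, splitting) flows through explicit seeds;
  RNG state of the calling session is restored afterwards.

## Worked example

```{r example, eval = FALSE}
co <- generate_cohort(cohort_spec(n = 90, seed = 42))
cfg <- training_config(mode = "hybrid", train_premise = FALSE)
sets <- split_dataset(co, cfg)
fit_ef <- anfis_fit(build_default_model("ef"), sets$train, cfg)
evaluate_anfis(fit_ef$model, sets$test, sets$check)
classify_patient(list(ntprobnp = 2400, na = 131, k = 3.1),
                 fit_ef$model, anfis_fit(build_default_model("epi_cysc"),
                                         sets$train, cfg)$model)
```

## Known limitations

* The synthetic generator emulates printed marginal statistics, not the
  unavailable joint distribution; no clinical claim follows from a green
  test.
* The published "approximately 15%" checking consistency cannot be
  reproduced or even unambiguously defined; it is reported, never
  asserted.
* Premise training under the minimum t-norm is not implemented.
* The CLI config file is JSON (no YAML dependency).
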