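# cranfis

Cardiorenal risk modelling with an adaptive neuro-fuzzy inference system
(ANFIS).

## What it is for

Clinicians monitoring patients with combined heart and kidney impairment
track a handful of routine quantities: NT-proBNP (pg/mL), serum sodium
and potassium (mmol/L), left-ventricular ejection fraction (EF, %), and
cystatin-C based glomerular filtration rate (mL/min/1.73 m^2). The
clinically relevant boundaries between stable and decompensating are
gradual, not crisp, which suits fuzzy inference. `cranfis` provides, for
biostatisticians and clinical modellers:

* a five-layer Takagi–Sugeno ANFIS with three inputs (NT-proBNP, Na+, K+)
  and one output (EF or GFR): trapezoidal fuzzification into
  low/normal/high (a Ruspini partition anchored on clinical reference
  bands), 27 rules (the full 3x3x3 antecedent product), product or min
  t-norm, normalized firing strengths, linear consequents;
* min-max normalization with bounds frozen to published cohort ranges, so
  the normalized risk thresholds (K+ 0.20, Na+ 0.44, GFR 0.58, ...) are
  reproducible;
* training by backpropagation (`bp`, default) or hybrid least
  squares + gradient (`hybrid`), 70/15/15 train/test/check split, the
  published stopping rule (1000 epochs or training MSE <= 0.0005);
* a calibrated synthetic-cohort generator (truncated normal / lognormal
  moment matching against published summary statistics) so the whole
  pipeline runs and is tested without any patient data;
* response-surface exports and risk-band classification
  (serious-adverse-event / at-risk, HFrEF phenotype, renal failure,
  electrolyte stability), plus a CLI (`simulate`, `fit`, `predict`,
  `surface`, `classify`, `report`, `end-to-end`).

The core model, for normalized inputs $x = (x_1, x_2, x_3)$ and rule
$l$ with antecedent memberships $\mu$:

$$\omega_l = \prod_v \mu_{v,l}(x_v), \qquad
  \bar\omega_l = \frac{\omega_l}{\sum_{m=1}^{27}\omega_m}, \qquad
  \hat y = \sum_{l=1}^{27}\bar\omega_l\,(c_{1l}x_1 + c_{2l}x_2 + c_{3l}x_3).$$

## Worked example

```r
library(cranfis)

co <- generate_cohort(cohort_spec(n = 90, seed = 42))  # 52 men, 38 women
summarize_cohort(co)
#> <cohort_summary> 90 subjects
#>  variable      min       max      mean         sd
#>  ntprobnp  10.2462 4827.9693 1416.6428 1493.63134
#>        na 124.0435  145.3452  138.2674    4.10505
#>         k   3.0177    7.2219    4.7646    0.87726
#>        ef  28.8147   75.0000   61.5601   13.29748
#>  epi_cysc  63.1598  146.0000  121.9704   24.26501
#>       age  20.0000   88.0000   63.8778   16.25072
#> sex: male 57.77%, female 42.22%

cfg  <- training_config()            # bp, 1000 epochs, MSE tolerance 5e-4
sets <- split_dataset(co, cfg)       # 64 / 13 / 13
fit_ef  <- anfis_fit(build_default_model("ef"), sets$train, cfg)
fit_epi <- anfis_fit(build_default_model("epi_cysc"), sets$train, cfg)
evaluate_anfis(fit_ef$model, sets$test, sets$check)
#> $test_mse                      0.0384
#> $check_mse                     0.0201
#> $relative_check_deviation_pct  47.8
```

The MSEs are on the normalized-output scale (so 0.02 corresponds to a
root-mean-square EF error of about 0.14 x 63 = 9 EF points on this small
cohort); the check deviation is the package's logged stand-in for the
published "consistency of checking" figure and is never asserted against
it.

```r
classify_patient(list(ntprobnp = 2400, na = 131, k = 3.1),
                 fit_ef$model, fit_epi$model)
#>     ef_norm  ef_pred  epi_norm epi_pred         cardiac_class phenotype
#> 1 0.3018853 31.01878 0.3019084 53.85191 serious_adverse_event     HFrEF
#>     renal_class   k_flag  na_flag bnp_flag
#> 1 renal_failure unstable unstable  in_band
```

A high NT-proBNP with hyponatraemia and hypokalaemia predicts a
normalized EF of 0.30 — below the 0.5 adverse-event line — a physical EF
of 31% (HFrEF, < 40%), and a normalized GFR below the 0.58 renal-failure
threshold; both electrolytes sit outside their stability bands.

```r
batch_report(co, fit_ef$model, fit_epi$model)
#> <risk_report> 90 subjects
#>   cardiac   serious_adverse_event=18, at_risk=72
#>   phenotype HFrEF=12, HFpEF_range=78
#>   renal     renal_failure=21, preserved=69
#>   ...
```

Command-line equivalent of the whole pipeline:

```sh
Rscript -e 'cranfis::cranfis_main()' end-to-end --seed 42 --n 90 --output runs/demo
```

which writes the cohort CSV, both model JSONs, fit histories, six
response-surface grids, the per-patient risk report, and a manifest with
MD5 checksums (byte-identical across runs with the same seed).

## Notes

* The published NT-proBNP summary moments (mean 1275.77 < SD 1533.89 on
  10–5000 pg/mL) are not attainable by any truncated lognormal; the
  calibrator matches the mean exactly, attains the closest SD (~1385),
  and warns. See the methods vignette (`vignettes/cardiorenal-anfis.Rmd`).
* Synthetic cohorts emulate printed marginal statistics plus a monotone
  latent response; they carry no real covariance structure, and no
  clinical conclusion should be drawn from them.
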