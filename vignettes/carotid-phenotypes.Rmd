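---
title: "Bilateral carotid geometry phenotypes: models, choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bilateral carotid geometry phenotypes: models, choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carotidgeom)
```

## The problem

B-mode ultrasound of the common carotid artery (CCA) yields two cheap,
repeatable measurements per side: far-wall intima-media thickness (IMT, mm)
and external (interadventitial) diameter (mm). Each predicts ischemic
stroke on its own, but they plausibly carry different information in
combination: a thick wall inside an enlarged artery suggests outward
remodeling around vulnerable plaque, a thick wall without enlargement
suggests a stable, lumen-narrowing lesion, and an enlarged artery with a
thin wall tracks hypertension-like exposures. Because atherosclerosis is
focal, the right and left CCA frequently disagree, and *bilateral*
abnormality may mark more extensive disease.

`carotidgeom` implements this reasoning as a reproducible pipeline:

1. dichotomize each measure at its sex- and side-specific median —
   "large" means **at or above** the median;
2. classify each side into four geometric patterns (both large / IMT only
   / diameter only / neither large = reference);
3. reduce the 16 ordered right x left pattern pairs to ten non-overlapping
   bilateral phenotypes (symmetric in side), plus six named combined sets;
4. quantify right-left concordance (Cohen's kappa, category-specific
   agreement);
5. treat phenotype membership as a diagnostic test for incident stroke
   (sensitivity, specificity, likelihood ratios with log-method CIs,
   cumulative incidence, relative risk);
6. estimate side-specific hazard ratios with a from-scratch Cox
   proportional-hazards fitter and a change-in-estimate covariate
   retention rule.

Because the motivating cohort's subject-level data are access-restricted,
the package ships a synthetic cohort generator that reproduces the
*statistical structure* the analysis depends on, so every stage is
testable end to end.

## Classification choices

**The tie rule.** "Large" is `>= median`, so a value exactly at the cut is
large. With medians computed from an even-sized continuous sample (the
midpoint of the two central order statistics), ties cannot occur; with
externally supplied medians (e.g. the published 8-cell table from
`reference_medians()`) ties are possible and the `>=` rule governs. For
tie-free data this makes each parameter's "large" group exactly
`ceiling(n/2)` of the stratum.

**Where medians come from.** Default: computed from the analysis sample
*after* exclusions (missing CCA measures first, then prevalent stroke),
which mirrors a median split "from our study sample". Classification
against a supplied median table is a switch
(`classify_cohort(cohort, medians = ...)`,
`run_pipeline(use_reference_medians = TRUE)`), and the manifest records
which source was used.

**The phenotype map.** The 4 x 4 lookup is symmetric by construction, so
`bilateral_phenotype(a, b) == bilateral_phenotype(b, a)` for every pair;
ids partition any classified cohort. The six combined sets are fixed id
unions (`combined_sets()`), and combined counts are literal sums over
constituent ids — the package treats that arithmetic as an invariant and
tests it.

## Concordance

Cohen's unweighted kappa uses the row/column-marginal chance correction
with the common large-sample variance
`p_o(1 - p_o) / (n (1 - p_e)^2)`. The per-category agreement statistic is
**specific (positive) agreement**, `2 n_cc / (row_c + col_c)`: of all
side-classifications landing in category *c*, the fraction whose opposite
side agrees. This choice is an assumption — the motivating analysis
reports a per-category agreement column without defining it — and is
flagged as such in reports. Its CI comes from a seeded subject bootstrap,
implemented as a multinomial redraw of the 16 cell counts (equivalent to
resampling subjects, since the table is a sufficient summary); 2000
resamples by default.

## Diagnostic accuracy

For a positivity definition (a set of phenotype ids) the 2 x 2 table
against incident stroke gives sensitivity, specificity,
`LR+ = sens / (1 - spec)` and `LR- = (1 - sens) / spec`. The LR
confidence intervals use the delta method on the log of a ratio of two
binomial proportions:

$$\mathrm{SE}(\ln LR^{+}) = \sqrt{\frac{1}{tp} - \frac{1}{tp+fn} +
\frac{1}{fp} - \frac{1}{fp+tn}}$$

and symmetrically (`fn`, `tn`) for LR-. This formula choice is validated
by exact reproduction, to printed precision, of a published interval
(women, both-large-bilaterally: +LR 3.10, CI 2.56-3.76) from the published
counts alone. Zero cells trigger a flagged 0.5 continuity correction on
all four cells; the published rows never need it.

**Relative risk** is the direct ratio of cumulative incidences with a
log-delta CI. Note a documented discrepancy: the motivating report prints
phenotype-1-vs-reference relative risks (16.3 for women, 6.4 for men)
that do not equal the direct ratios of its own printed cumulative
incidences (18.6 and 6.7); its computation — possibly person-time based —
is unstated. The direct-ratio definition is implemented and the
difference is left unreconciled rather than reverse-engineered.

A second arithmetic inconsistency in the published counts: the women's
"any large diameter" combined row prints 56 strokes, while its seven
constituent ids sum to 57 (and the women's total of 66 is only consistent
with 57). The package reports the sum; the tests document the
discrepancy.

## Cox estimation

`fit_cox()` maximizes the log partial likelihood by Newton-Raphson with
step-halving. Risk-set sums are prefix sums over subjects sorted by
decreasing time, so one iteration is O(n log n + n p^2). Numerical
choices:

* **Ties**: Breslow by default (the default of the era's mainstream
  survival software), Efron by flag; the two agree exactly on tie-free
  data, and both are cross-checked against an independent reference
  fitter in the test suite (tests only — the implementation is
  self-contained).
* **Convergence**: `max |gradient| < 1e-8` or relative log-likelihood
  change `< 1e-10`, iteration cap 50; the returned gradient norm is part
  of the fit object.
* **Separation**: a coefficient escaping past +/-15 on the log-HR scale
  aborts with an explicit monotone-likelihood error, rather than
  returning a boundary estimate with a meaningless SE. (A 6-subject
  all-events instance in which one group holds every early event is the
  canonical trigger and is pinned in the tests.)
* **Rank**: a rank-deficient design errors naming the collinear columns.
* **Inference**: SEs from the inverse observed information; hazard ratios
  `exp(beta)` with Wald 95% CIs; a zero SE yields a flagged degenerate
  interval.

**Covariate retention** (`select_covariates()`) implements the rule "keep
if p < 0.05 or if removal changes any geometry coefficient by more than
10%": backward elimination dropping the least significant candidate
first, with name order breaking p-value ties for determinism; a drop is
vetoed (the candidate is locked in) when it moves any exposure
coefficient by more than `delta` relative. The change is measured on the
coefficient (log-HR) scale by default with an `"hr"`-scale option, since
the rule's original scale is unstated. Relative change is intrinsically
unstable when an exposure coefficient is near zero (the denominator is
floored at 1e-8); in the intended use the geometry coefficients are
non-trivial. Every decision is logged in an ordered audit table.

## The synthetic cohort generator

The generator's job is to emulate the features the analysis is sensitive
to, with every knob exposed in `cohort_config()`:

* **Arterial measures** are exponentials of a 4-variate Gaussian
  (r_imt, r_dia, l_imt, l_dia). Log-normality gives positivity and right
  skew; more importantly, a median split is invariant to any monotone
  transform, so the Gaussian copula controls all category prevalences
  exactly. The marginal medians are `exp(log_mean)` by construction, with
  per-sex, per-side defaults at the published medians (0.663/8.092 and
  0.676/7.997 mm for men's right/left IMT/diameter; 0.609/7.303 and
  0.603/7.199 for women).
* **Correlation structure** is separable: side factor (correlation
  `rho_between` = 0.35 by default) Kronecker parameter factor
  (`rho_within`), so the cross-side, cross-parameter correlation is the
  product. Positive definiteness reduces to `|rho| < 1` for each factor,
  and violations are reported naming the offending parameters.
* **Calibration** of `rho_within` is closed-form: after a median split,
  P(both large) is the Gaussian orthant mass `1/4 + arcsin(rho)/(2*pi)`,
  so `calibrate_within_correlation(0.32)` returns
  `sin(2*pi*0.07) ≈ 0.4258`, reproducing the observed ~32/18/18/32
  per-side pattern. `rho_between` has no published raw-measure
  counterpart (only categorical agreement is reported), so it is
  calibrated, not identified: 0.35 puts the simulated "neither/neither"
  specific agreement near the published ~46-48% and kappa in the "fair"
  range.
* **Outcomes** are exponential event times with rate
  `baseline_hazard * exp(log_hazard_by_phenotype[id])`, censored by an
  independent Uniform(10, 12)-year administrative time. The phenotype
  used by the hazard is classified against the generator's *true* medians
  (`exp(log_mean)`), so the data-generating mechanism is well-defined
  independent of any sample. The default hazard gradient follows the
  published pooled-sex cumulative-incidence gradient across the ten
  phenotypes (reference ~0.7% over ~11 years at
  `baseline_hazard = 0.0006`/yr); both sexes share the gradient, a
  simplification.
* **Covariates** (age, race, height) are drawn independently of the
  arterial measures by default; the generator makes no attempt to give
  phenotypes the adverse risk-factor profile seen in real cohorts.
* **Reproducibility**: one `set.seed(config$seed)` at the entry of
  `simulate_cohort()`; identical configs give bit-identical cohorts, and
  the pipeline's reports regenerate byte-identically.

**What passing tests therefore show — and don't.** Simulation-based tests
demonstrate that the *estimators* are correct (classification partitions,
prevalences follow the orthant formula, the Cox fitter recovers known
hazard ratios with nominal Wald coverage) under a clean data-generating
process. They cannot show robustness to what the generator omits:
measurement error in IMT/diameter reading, confounding of phenotype by
age and risk factors, non-constant baseline hazards, or cohort sampling
structure. Conclusions about real carotid data rest on the published
counts, which the diagnostics stage reproduces exactly.

## Validation problem sizes

The shipped tests and acceptance script use: the full published count
tables (4014 women / 3262 men) for the diagnostic panel; 12,000-20,000
subject cohorts for calibration checks (binomial 3-SE bands); 200
replicate cohorts of n = 3300 with a true both-large-bilaterally hazard
ratio of 3.7 and ~110 events each for parameter recovery and Wald
coverage; and <= 10-subject instances for brute-force partial-likelihood
cross-checks. These sizes give Monte-Carlo error comfortably inside the
assertion bands while keeping a full run in the tens of seconds.

## Known limitations

* Median cut-points are deliberately unoptimized (as in the motivating
  analysis); the package does not model continuous IMT/diameter effects.
* The per-category agreement definition and its CI are assumptions (see
  above); kappa's CI is the simple asymptotic form, not bias-corrected.
* The Cox module omits time-varying covariates, stratification,
  proportionality diagnostics and competing risks.
* Published side-specific adjusted hazard ratios cannot be reproduced
  without the restricted subject-level data; the package validates the
  estimator by parameter recovery instead.

## Session

```{r}
sessionInfo()
```
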