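---
title: "Symptom-level meta-analysis and SOrT allocation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symptom-level meta-analysis and SOrT allocation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sortmeta)
```

## The scientific problem

Randomised trials comparing antidepressant medication (ADM) with
psychotherapy for major depression are conventionally synthesised on
depression *sum-scores*. Sum-scores, however, average over a heterogeneous
symptom space: two treatments with identical sum-score effects could still
differ on individual symptoms (sleep, guilt, suicidality, ...), and such
differences — if real — could guide which patient should receive which
treatment. `sortmeta` implements the full chain of that idea:

1. estimate per-study, per-symptom treatment effects from ordinal endpoint
   frequency tables;
2. pool them across trials with random-effects meta-analysis, with
   heterogeneity, small-study and moderator diagnostics and
   Benjamini–Hochberg (BH) multiplicity adjustment;
3. combine the pooled symptom weights with a patient's baseline symptom
   profile into a **Symptom-Oriented Therapy (SOrT) score**,
   `SOrT = sum_i m_i * s_i`, positive values indicating an ADM-favouring
   profile;
4. evaluate whether allocating patients by their SOrT score (valence,
   median, or extreme-group splits) is associated with better endpoint
   outcomes.

Because item-level trial data and the validation cohorts this design needs
are not publicly deposited, the package ships first-class synthetic-data
generators with known ground truth; every calibration claim below is a
property of the pipeline *under those generators*, not a claim about any
real dataset.

## Effect metrics

**Proportional odds ratio (primary).** A symptom item is an ordinal variable
with levels `0..L`. For one study the data are a 2 × (L+1) frequency table.
We fit the cumulative-logit proportional-odds model

$$P(Y \le c \mid arm) = \mathrm{logit}^{-1}\!\big(\theta_c - \beta\,
  \mathbf{1}[arm = \mathrm{PSY}]\big),$$

whose single log odds ratio `beta` is the common OR across all cumulative
dichotomisations of the item — an "average OR over all severity steps".
Estimation is maximum likelihood by Fisher scoring with step-halving,
started at the pooled empirical cumulative logits; standard errors come
from the observed-information matrix at the optimum. The ordinal logit
log-likelihood is well behaved in this parametrisation, and the test suite
cross-checks the fit against both `MASS::polr` and an independent
brute-force profile-likelihood grid search (agreement to 1e-4 on hundreds
of random small tables). Severity levels empty in *both* arms are collapsed
before fitting (the estimate is invariant to them). Tables with no variance
after collapsing — one occupied level, an empty arm, or a separated
configuration with a diverging MLE — raise a typed `VarianceError`;
`estimate_effects()` drops such study × symptom cells from that symptom's
pool with a logged notice, which mirrors standard meta-analytic practice.

**Sign convention.** Everywhere in the package a *positive* effect favours
ADM: the psychotherapy arm has higher odds of worse endpoint severity.
Lower endpoint sum-scores are better outcomes.

**Median-split OR (sensitivity).** The item is dichotomised at the median
of the pooled (both-arm) severity distribution, "high" being strictly above
the pooled median level — a deterministic, arm-symmetric tie rule. The 2 × 2
log OR gets the Haldane–Anscombe 0.5 correction on all four cells iff any
cell is zero; an empty margin before correction is a `VarianceError` rather
than a numerically legal but meaningless corrected estimate.

**Standardised mean difference (sum-scores).** Hedges' g with the
small-sample factor `J = 1 - 3/(4(n1+n2-2)-1)` and variance
`J^2 (1/n1 + 1/n2 + g^2/(2(n1+n2-2)))`. The correction can be disabled
(`correct = FALSE`) for sensitivity to the Cohen's d flavour. Completer
(endpoint) arm sizes are used throughout, consistent with the
completer-only analysis design.

**Metric conversion.** Log ORs convert to the SMD scale by
`SMD = ln(OR)/1.81` (the logistic-distribution conversion); the operation
is exactly invertible and the SMD scale — linear and centred at zero — is
what the SOrT weights use.

## Random-effects pooling

Per symptom, estimates are pooled by inverse variance with weights
`w_i = 1/(se_i^2 + tau^2)`. `tau^2` is estimated by REML (default) or the
DerSimonian–Laird closed form; DL is retained because it is hand-checkable
(the test suite pins the classic worked example `y = (0.1, 0.3, 0.5)`,
`se = 0.1`: Q = 8, I² = 75%, tau² = 0.03, pooled = 0.3). The engine behind
the pooling surface is `metafor::rma.uni`; a damped-step retry and a DL
fallback absorb the rare REML non-convergence on simulated collections.
CIs and p-values use normal theory by default — matching the usual software
default — with Knapp–Hartung available via `knha = TRUE` for sensitivity.

Two deliberate definitional choices:

* **I² is Q-based** under both estimators: `I² = max(0, (Q - df)/Q) · 100`
  with `df = k - 1`. (REML software often reports a tau²-based I²; the
  Q-based definition keeps the heterogeneity triple (Q, df, I²) internally
  consistent.)
* **BH is applied per scale** (one family per instrument's symptom set) by
  calling `pool_symptom_effects()` per scale; a joint family is obtained by
  passing the union. BH controls the FDR, not the FWER, and is implemented
  via `stats::p.adjust`.

Small-study asymmetry uses the classical Egger regression of `y_i/se_i` on
`1/se_i`, z-testing the intercept against the standard normal; funnel-plot
coordinates are returned for plotting. Moderator meta-regression (e.g. on
differential dropout, in percentage points of greater ADM dropout) is a
REML mixed-effects model with a Wald z slope test. Dropout itself is pooled
as a per-study 2 × 2 log OR (dropout × arm), oriented so OR < 1 means fewer
psychotherapy dropouts, alongside exact aggregate rates per arm.

## The SOrT metric

`compute_sort()` evaluates `SOrT = sum_i m_i s_i` with `m_i` the pooled
effect on the SMD scale and `s_i` the patient's baseline item scores.
Profiles must be complete: partial-profile scoring has no principled
definition, so missing items are hard errors rather than silently ignored.

With most `m_i` sharing one sign — the empirically typical situation — the
raw score is strongly correlated with overall symptom severity by
construction; it then measures severity as much as treatment preference.
The severity-adjusted variant `SOrT_adj = sum_i m_i s_i / sum_i s_i` is a
convex combination of the weights (bounded by `[min m, max m]`, invariant
to rescaling the profile) and removes that artefact. At `sum_i s_i = 0` the
adjusted score is *undefined* and reported as `NA`, not 0: 0/0 has no
principled value and imputing 0 would bias descriptives toward the centre.

Validation helpers mirror the standard cohort workflow: score descriptives
with the positive-score fraction (the valence-split feasibility
diagnostic), Pearson cross-scale correlation of paired scores, and
per-covariate OLS regressions, unadjusted and adjusted for the baseline
sum-score.

## Allocation evaluation

`loso_weights()` re-pools every symptom excluding the validation study, so
the scored cohort stays independent of its own weights. Splits:

* **valence** — optimal iff the score sign matches the arm (positive →
  ADM); scores exactly 0 are excluded with a logged count rather than
  assigned arbitrarily;
* **median** — optimal iff above the sample median and ADM (or below and
  PSY); exact ties with the median are excluded likewise;
* **extreme groups** — keep the `ceiling(fraction · n)` patients (default
  2/3) farthest from a reference point before splitting. Whether "extreme"
  means far from zero or far from the median is genuinely ambiguous when
  the score distribution is one-sided, so both references are implemented
  (`EXTREME_VALENCE`, `EXTREME_MEDIAN`) and the report carries both; ties
  at the cut are kept in `patient_id` order up to the quota, keeping the
  selection deterministic.

Group outcomes are compared with Welch's t-test (a pooled-variance flag
exists; the unequal-variance default is the safer reading of a "simple
independent samples t test"), plus OLS of endpoint on the optimal
indicator, optionally baseline-adjusted — whose unadjusted coefficient
equals the group mean difference exactly. `run_allocation_pipeline()`
assembles one row per split and, instead of failing, flags infeasible rows:
in particular a valence split on a one-signed score distribution would
merely compare the treatment arms, so it is reported as infeasible with the
positive-score fraction attached.

## Synthetic data: what it emulates and what it does not

`generate_study_collection()` draws, for study *j* and symptom *i*,

$$P(Y \le c \mid arm) = \mathrm{logit}^{-1}\!\big(\theta_{i,c} -
  (\beta_i + u_j)\,\mathbf{1}[arm = \mathrm{PSY}]\big), \qquad
  u_j \sim N(0, \tau^2),$$

then applies independent per-arm Bernoulli dropout; frequency tables and
sum-score summaries come from the same simulated completers, so the two
data products are mutually consistent. Default conditions are the study
setting the package targets: 20 trials, 60–200 randomised per arm, dropout
0.212 (psychotherapy) and 0.261 (ADM) — the aggregate per-arm completer
rates observed across comparable published trials — and right-skewed item
margins (geometric decay 0.55 across levels), the typical post-treatment
shape. Cutpoints are config, not code. Because generation satisfies
proportional odds by construction, the estimator's model is correctly
specified in the base scenario; a `level_shift` option adds a
level-specific departure for stress-testing, since real items need not be
proportional.

`generate_patient_cohort()` draws baseline items from an
exchangeable-correlation latent Gaussian thresholded to
Binomial(`max_level`, `mean/max_level`) margins, assigns treatment
Bernoulli(0.5), and sets

$$endpoint = \max\big(0,\; baseline \cdot response\_mean + \varepsilon -
  \delta\,\mathbf{1}[\text{arm concordant with } \mathrm{sign}(\textstyle\sum_i m_i s_i)]\big),
  \qquad \varepsilon \sim N(0, response\_sd^2),$$

an explicitly linear outcome model with a tunable concordance benefit
`delta` — the ground truth a real-data null result cannot provide. Defaults
(n = 400, correlation 0.3, `response_mean` 0.5, `response_sd` 6) describe a
mid-sized validation cohort. Deliberately **not** simulated: longitudinal
item trajectories, item-level missingness (the design is completer-only),
informative dropout, and non-linear severity–outcome relationships. Passing
calibration tests therefore demonstrates internal statistical correctness,
not robustness to those real-data features.

## Numerical choices and degenerate inputs

* Fisher scoring stops when the NLL change is below `1e-10` (relative) and
  the score norm below `1e-6`; step-halving guards the cutpoint ordering.
  `|beta| > 15` is treated as separation and raises `VarianceError`.
* `metafor` REML gets one damped retry (`stepadj = 0.5`, `maxiter = 1000`)
  then falls back to DL.
* Egger's test refuses designs with all SEs equal (the precision regressor
  would be collinear with the intercept); meta-regression refuses constant
  moderators and k < 3.
* All readers validate hard: negative counts, counts beyond an item's
  declared maximum, duplicate patient ids, out-of-range or missing item
  scores are errors naming the offending row, not warnings.

## Problem sizes used by the calibration studies

The shipped calibration studies (also re-run by `scripts/acceptance.R`)
use: CI coverage — 1000 replicates of 20 trials × 60/arm with
`beta = 0.3`, `tau = 0.1` on a single 0–3 item; null calibration — 2000
replicates of the same design with three items and `beta = 0`; allocation —
1000 cohorts of n = 400 per condition (`delta = 0` and
`delta = 0.5 · response_sd`) scored with sign-balanced weights of
magnitude 0.12. A single simulated item (rather than a full 17-item
instrument) is used where the statistic under study is per-symptom, keeping
replicate counts high where the Monte-Carlo error actually matters.

## Known limitations

* The pOR fit assumes proportional odds; the package generates under it and
  offers a stress option, but provides no automatic non-PO fallback.
* Normal-theory random-effects CIs are slightly liberal at small k; the
  Knapp–Hartung flag exists but is not the default, matching common
  practice.
* BDI-I/BDI-II item aggregation is driven by whatever item mapping the user
  encodes in their scale configuration; no canonical mapping table ships
  with the package.
* SOrT scoring requires complete profiles by design; cohorts with item
  missingness need upstream handling before scoring.
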