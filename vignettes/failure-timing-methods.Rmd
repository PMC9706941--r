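---
title: "Methods: failure-timing analysis for LANPC cohorts"
author: "failtiming package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: failure-timing analysis for LANPC cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

In locoregionally advanced nasopharyngeal carcinoma (LANPC) treated with
induction chemotherapy and intensity-modulated radiotherapy — with or
without concurrent cisplatin — two questions recur:

1. **When is a treatment failure "early"?**  Patients whose locoregional
   recurrence or distant metastasis appears soon after treatment tend to
   die sooner *after* the failure than patients who fail late.  A
   prognosis-based threshold separates the two groups: the candidate
   cut-off that maximises the post-failure survival difference.
2. **When does concurrent cisplatin help?**  A cumulative cisplatin dose
   (CCD) above 200 mg/m2 is the conventional benchmark.  Kaplan–Meier
   curves show *whether* dose groups differ but not *when* the risk
   differs, so the pipeline also estimates covariate-adjusted cumulative
   failure probabilities and their monthly derivatives per dose group.

`failtiming` implements this analysis end to end, plus a calibrated
synthetic-cohort generator so every stage is testable without access to
restricted clinical data.

## Endpoints

All clocks start at treatment initiation, in months.

* **OS** — time to death from any cause.
* **FFS** — time to the first failure (locoregional or distant) or death.
* **LRFFS / DFFS** — time to first locoregional / distant failure;
  patients who die without the failure are **censored at death**.  This is
  the conventional KM/Cox treatment, not a competing-risk estimator; with
  roughly 20% mortality it overstates absolute failure risk somewhat, and
  we document rather than correct this bias (no Fine–Gray model is
  provided by design).
* **Post-failure OS** — OS minus the failure-free interval, defined only
  for patients with the failure under analysis.  For patients with both
  failure types the clock starts at the failure type of the cohort being
  analysed.

## The minimum-P cut-point scan

For a failure cohort of n patients with failure-free interval $x_i$ and
post-failure survival $(s_i, \delta_i)$, each integer-month candidate $c$
splits the cohort into early ($x_i \le c$, matching the clinical phrase
"failure within $c$ months") and late ($x_i > c$).  The two arms'
post-failure survival is compared with the standard log-rank statistic
(hypergeometric variance at ties), and the scan selects

$$\hat c = \arg\min_c \; p_{\text{log-rank}}(c).$$

**Candidate grid.** The scan runs on integer months between the 10th and
90th percentile of the intervals; a candidate is admissible only when both
arms contain at least 10% of the cohort and at least 5 post-failure
deaths.  These rules are our own (grids are rarely reported in applied
work): minimum-P selection is dominated by boundary splits if tiny arms
are allowed, and the admissibility constraints remove exactly those
artifacts.  Both bounds are configurable.

**Multiplicity correction.** The minimum of many correlated P values is
anti-conservative — under the null it rejects far more than 5% of the
time.  The correction simulates the null distribution of the minimum P:

* `"permutation"` (default): permute the intervals $x_i$ against the
  $(s_i, \delta_i)$ pairs.  Under the null of no interval–survival
  association the permutation distribution is exactly exchangeable, which
  is why it is the default.
* `"bootstrap"`: resample pairs with replacement and resample intervals
  independently — kept as an option because resampling-based corrections
  in the applied literature are often described only as "bootstrap".

The corrected P uses the add-one Monte-Carlo estimator
$(1 + \#\{\min P^{(b)} \le \min P^{\text{obs}}\})/(B + 1)$, which cannot
return 0.  The acceptance suite verifies that the corrected test's type-I
error at $\alpha = 0.05$ lies in $[0.03, 0.07]$ under the null while the
raw minimum P rejects more than 10% of the time.

One subtlety matters for exactness: the candidate grid handed to the
correction must be a function of the intervals alone (their multiset is
permutation-invariant).  If the grid is prefiltered using the observed
pairing of deaths to intervals, the observed minimum ranges over more
admissible candidates than each permuted labelling and the corrected P is
biased downwards — we measured the type-I error rising from ≈0.05 to
≈0.075 with such a grid.  The pipeline therefore builds interval-only
grids, and the per-arm death-count admissibility rule is enforced inside
the scan, identically for the observed and every resampled labelling.

**Guarantee-time bias.** Early/late membership is defined by an event
observed during follow-up and treated as fixed at failure time, as is
conventional in this analysis; post-failure clocks start at the failure,
so the comparison is free of the classic immortal-time artefact, but the
selection of *who fails at all* is not modelled.

## Cox models with screening and backward elimination

Multivariable models are built the way the clinical literature usually
reports them: candidate covariates are screened univariably (Wald
P < 0.10), survivors enter a multivariable Cox model, and the largest-P
term is removed iteratively until every retained term has P < 0.05.  Both
thresholds are arguments.  Whether published "P < 0.10 inclusion" rules
use univariable Cox or log-rank screening is usually unstated; we use
univariable Cox so that multi-level factors are screened by the same
block Wald test that later governs their elimination.

The partial likelihood is maximised by damped Newton iteration (step
halving whenever a step would decrease the likelihood) to a gradient norm
of 1e-8.  Ties use the Efron approximation by default — the widely
preferred choice — with Breslow available by flag.  Censored observations
tied with events remain in the risk set for those events (events precede
censorings).  Non-convergence and apparent complete separation are
*flagged* on the fit object, never silently ignored.  No multiplicity
correction is applied across endpoints or tables, matching field
practice; interpret marginal P values accordingly.

## Random survival forest and monthly failure probabilities

The forest follows the standard recipe: each of `n_trees` (default 1000)
trees is grown on a bootstrap resample of the cohort; splits maximise the
two-group log-rank statistic over `mtry` (default $\lceil\sqrt p\rceil$)
randomly chosen covariates with candidate thresholds at observed values;
growth stops when a child would hold fewer than `min_terminal_events`
(default 15) events; terminal nodes store the Nelson–Aalen cumulative
hazard of their in-bag members.  Ties between equally good splits are
broken by the first candidate encountered under the seeded covariate
order, so a fixed seed reproduces the forest exactly.  A single root-only
tree grown without resampling reproduces the cohort Nelson–Aalen
estimator exactly — the oracle the test suite uses for the whole
prediction path.  Predictions average the cumulative hazard over trees
and convert via $F(t) = 1 - \exp(-\bar H(t))$.

**Adjustment.** Published forest-based curves are often described only as
"adjusted for" a covariate list.  We use g-computation / partial
dependence, the standard forest-compatible choice: for each dose group
$g$, set every cohort member's group covariate to $g$, keep their other
covariates, predict each member's $F(t)$, and average.  The default
adjustment set is sex, age group, smoking, family history, T stage and
N stage.

Partial-dependence curves inherit the forest's finite-sample noise: with
a null group covariate at n = 3000 and 1000 trees the group curves
differ by roughly 0.01–0.03 in sup-norm (an independent forest
implementation shows the same magnitude on identical data), because
trees occasionally split on the group's sampling noise and averaging
over trees does not remove what every tree learned from the same
cohort.  Group separations should therefore be read against this noise
floor; the built-in dose effect produces separations several times
larger.

**Monthly probabilities.** The monthly time-specific probability is the
discrete derivative $f(m) = F(m) - F(m-1)$ on the integer-month grid,
smoothed with a centred 3-month moving average (window truncated at the
edges), clipped at zero, and rescaled so that $\sum_m f(m)$ equals
$F(\text{horizon}) - F(0)$ exactly.  First differences of an ensemble
step function are noisy month to month; the 3-month window removes that
jitter without displacing the peak, and is configurable (window 1
disables smoothing, in which case $f$ is exactly the increment sequence).
Conservation is enforced at the horizon; intermediate months trade
exactness for smoothness.

The composite "treatment failure" endpoint used for the failure curves is
the first locoregional or distant failure, with death before failure
treated as censoring.

## The synthetic cohort generator

The generator defines the study conditions under which everything above
is tested.  Per patient it draws:

1. **Covariates**, independently from the published marginal frequencies
   of a 3123-patient LANPC cohort (74.4% male, 54.2% aged 45 or younger,
   97.2% WHO type III, 86.7% T3–4, 52.1% N2–3, 50.8% stage IVa, 57.2%
   EBV DNA at or above 4000 copies/ml, CCD groups 0 / 1–200 / >200 mg/m2 at
   22.67 / 71.41 / 5.92%).  Only marginals are published, so joint
   covariate–dose associations (e.g. younger patients receiving more
   cisplatin) are *not* reproduced — a deliberate simplification that
   matters when interpreting the baseline contingency table, which is
   null by construction here.
2. **Latent times** for locoregional failure, distant failure and
   failure-free death from piecewise-constant proportional hazards with
   an elevated window over the first 48 months (failures in this disease
   concentrate in the first 3–4 years).  Covariate effects are log hazard
   ratios taken from published multivariable estimates, including the key
   treatment effect: CCD > 200 mg/m2 multiplies the distant-failure
   hazard by 0.351 (CCD 1–200 by 0.763) *inside the first 20 months
   only* — the generating change-point structure the scan is asked to
   recover.
3. **Post-failure survival**: after the first failure the death hazard is
   replaced by a residual process whose rate is multiplied by
   $e^{1.1}$ when the failure was early (locoregional failure at or
   before month 14; distant at or before month 20).  The log hazard ratio
   1.1 is the generator's change-point signal size.
4. **Administrative censoring** uniform on 48–96 months, giving a median
   follow-up near the reported 67.5 months.

Baseline hazard scales were calibrated once, against the package's own
deterministic integration oracle (`expected_event_fractions()`), so that
the expected observed event fractions are 13.0% locoregional recurrence,
16.4% distant metastasis and 19.8% death, with 21.7% of locoregional
failures early and 54.4% of distant failures early.  At the default size
the implied 5-year OS / FFS / LRFFS / DFFS are approximately
83 / 70 / 87 / 84%.  The post-failure salvage-treatment label is drawn
independently of outcome: it exists so that cohort tables carry the
column, and it deliberately carries no prognostic signal.

`expected_event_fractions()` integrates the latent model numerically
(cell width 0.25 months, exact piecewise-exponential cell probabilities,
midpoint convolutions for failure-then-death paths; discretisation error
is O(dt)) and is the oracle against which the generator's Monte-Carlo
output is tested.

**What the generator does not emulate.** Real cohorts have correlated
covariates, non-proportional and non-piecewise hazards, informative
censoring, salvage-treatment effects on post-failure survival, and
measurement error in failure dating.  Passing tests therefore demonstrate
that the estimators recover the structures they target under a clean,
fully specified data-generating process — not that any specific clinical
result would replicate.

## Numerical and design choices

* Times are real-valued months; candidate grids are integer months.
  Interval-versus-cutoff comparisons use `<=` ("within c months").
* Exact time equality defines ties; events precede censorings in risk-set
  updates.
* The add-one permutation estimator, integer-month grid and 10–90%
  percentile bounds are the package's choices where the applied
  literature is silent; all are configurable and recorded in the scan
  object.
* Newton iterations for the Cox model stop at gradient norm 1e-8 or 25
  iterations; coefficient magnitudes above 15 flag probable separation.
* Forest hyperparameters beyond the tree count are our defaults
  (log-rank splitting, `mtry` $=\lceil\sqrt p\rceil$, 15 events per
  terminal node), since applied reports rarely state theirs.
* Stage seeds are derived from one master seed by fixed offsets, so any
  stage can be re-run in isolation and a configuration is reproducible
  byte for byte.  Reports serialise months to 6 decimals and
  probabilities to 10.

## Problem sizes used by the test suite

The shipped tests exercise the estimators at sizes chosen to keep the
default suite comfortably inside a normal development cycle while leaving
the statistical claims intact: generator calibration against the
integration oracle uses 400,000 simulated patients (Monte-Carlo SE below
6e-4); change-point recovery uses 100 replicate cohorts of 3123 patients
per endpoint; the null calibration of the corrected minimum P uses 1200
replicate failure cohorts of n = 300 with 500 permutations each; Cox
recovery uses 100 replicates at n = 3000; the forest effect-direction
check uses 50 replicate cohorts with 500-tree forests; and the end-to-end
run uses n = 3000 with 500 trees and 500 resamples, executed twice to
verify byte-level reproducibility.

## Known limitations

* LRFFS/DFFS censor competing deaths; cumulative-incidence-style
  interpretation of those endpoints overstates absolute risk.
* The early/late grouping conditions on failing at all
  (guarantee-time bias at the cohort-selection level).
* Partial-dependence adjustment averages over the *observed* covariate
  distribution; it does not extrapolate to covariate patterns absent
  from the cohort.
* The generator's independence assumptions make the baseline
  contingency tests null by construction; they are pipeline plumbing,
  not a validation target.
* No competing-risk models, frailty terms, time-varying covariates or
  proportional-hazards diagnostics are provided.
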