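---
title: "Weighted cumulative exposure modelling of dispensing claims: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted cumulative exposure modelling of dispensing claims: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Pharmacoepidemiological questions about a medicine are often not "exposed
versus unexposed" but *when, how much, and how recently*. For a drug like
paracetamol taken regularly by elderly patients with chronic obstructive
pulmonary disease (COPD), the hazard of an exacerbation admission may fall
just after starting, rise some weeks into continuous use, and wash out
months after stopping. Classifying exposure as "current use" or "any use in
the last 90 days" cannot express such a profile.

The weighted cumulative exposure (WCE) model replaces the usual scalar
exposure covariate at follow-up day $u$ by a weighted sum of all past daily
doses,

$$\mathrm{WCE}(u) = \sum_{t=1}^{T} w(t)\, X(u - t),$$

where $X(d)$ is the dose (g/day) on day $d$, $t$ is the lag in days, and
$w(t)$ is an unknown *weight function* giving the log-hazard-ratio
contribution of one unit of dose taken $t$ days ago. Beyond the time window
$T$ the weight is zero by assumption. The weight function is estimated from
the data by writing it on a cubic B-spline basis, $w(t) = \sum_j \theta_j
B_j(t)$, so that

$$\mathrm{WCE}(u) = \sum_j \theta_j D_j(u), \qquad
  D_j(u) = \sum_{t=1}^{T} B_j(t)\, X(u-t),$$

and the $D_j(u)$ are ordinary time-varying covariates in a Cox model. The
hazard for subject $i$ in severity stratum $s$ is

$$\lambda_i(u) = \lambda_{0s}(u)\,
  \exp\Big(\textstyle\sum_j \theta_j D_{ij}(u) + \beta' Z_i(u)\Big),$$

with $Z_i(u)$ the fixed baseline covariates (age at entry, sex,
hypertension, congestive heart failure, diabetes, comorbidity count) plus a
daily statin indicator. Once $(\hat\theta, \hat\Sigma)$ are available, the
hazard ratio of *any* dosing pattern $x(t)$ against non-use is
$\exp\{\sum_t \hat w(t) x(t)\}$ with a delta-method interval — this is what
produces dose-by-duration heatmaps and "days since stopping" curves.

# From claims to exposure histories

Dispensing claims record supplies, not ingestion. The package reconstructs a
daily dose series per patient under two rules:

* **Maximum-dose assumption.** Each covered day carries the maximum daily
  dose: 4 g/day for 500 mg tablets (8/day) and 3.99 g/day for 665 mg
  controlled-release tablets (6/day). Supply duration is
  $\lfloor \text{quantity}/\text{tablets per day} \rfloor$, at least one
  day. The tablets-per-day constants are configuration, because the
  conversion from pack size to duration is an analysis choice, so it is
  isolated behind `days_of_supply()`.
* **Supply extension.** A refill dispensed before the current supply runs
  out appends its full duration to the end of the current coverage; a
  refill after a lapse starts new coverage at its own date, leaving the gap
  at dose zero. Covered days take the dose of the script that covers them
  in dispensing order (queue semantics: first dispensed, first consumed).
  This conserves total supplied days under overlap, truncating only at the
  end of follow-up.

Days are half-open intervals: a 12-day supply starting day 0 covers days
0–11. The WCE covariates use a minimum lag of one day — the dose on the
event day itself does not contribute — matching an exposure history that
runs "until the day before" the current day.

# Cohort construction

The eligibility cascade mirrors a new-user design in an entitlement
population: age 45–100 at the study start (1 January 2011), full entitlement
for the prior 12 months, evidence of COPD in the prior 12 months (a
qualifying inhaled-anticholinergic dispensing, ATC `R03BB` excluding
`R03BB01`, or a hospital episode coded J43\*/J440/J441/J448/J449 in *any*
diagnosis position), no paracetamol in the prior 6 months (183 days), not in
residential aged care at the study start, at least one paracetamol
dispensing during the study (to 30 September 2015), and more than one day of
follow-up. Every failed gate is recorded, so exclusion counts reconcile
exactly with the input. Cohort entry is the date of the first in-study
paracetamol dispensing — follow-up cannot begin before exposure is possible,
which removes immortal time.

The outcome is the first post-entry admission with a *primary* J43\*/J44x
code; secondary-position codes qualify a patient for inclusion but never
count as outcomes. Censoring is the earliest of death, residential-care
entry and study end. The severity stratum (separate baseline hazards) is
"high" if the 12 months before study start contain a COPD hospitalization or
systemic glucocorticoid use (`H02AB`).

Comorbidity covariates come from a deliberately small, user-replaceable
ATC-prefix-to-category table (`default_comorbidity_map()`), a stand-in for a
full medication-based comorbidity index: the named indicators (hypertension,
CHF, diabetes) plus a count of the remaining distinct categories, excluding
the named three, the indication itself and statins. The real Rx-Risk
catalogue is much larger; any mapping with columns `atc_prefix`, `category`
can be supplied in `claims_config()`.

# Estimation

The stratified Cox partial likelihood with time-varying covariates is
maximised by Newton–Raphson with step-halving, implemented in the package
(risk sets formed per stratum on the days-since-entry time scale; covariate
values on $(u-1, u]$ are those of exposure day $u-1$). Ties are handled by
the Efron correction by default (Breslow selectable). Convergence is
declared when the maximum absolute score falls below $10^{-8}$ or the
relative change in log partial likelihood below $10^{-10}$; the covariance
is the inverse observed information. The implementation is verified in the
test suite against person-day brute-force expansion, finite differences,
and `survival::coxph` to $10^{-6}$ or better.

Model selection over the lag window and knot count uses
$\mathrm{BIC} = -2\log \mathrm{PL} + p \log(\text{events})$ with $p$ the
total number of free parameters; ties break toward fewer parameters, then
the smaller window. The default candidate grid crosses windows
{30, 60, 75, 90, 180} days with 1–3 interior knots, unconstrained and
right-constrained. Conventional comparators (current dose; mean or
cumulative dose over a 2–90-day window) are fitted in the same machinery so
their BIC values are directly comparable.

**Spline details.** Interior knots are equally spaced on $(0, T)$ (the knot
placement of the original WCE software is not documented in print;
user-supplied knot vectors are accepted). Boundary knots at 0 and $T$ carry
standard multiplicity; the unconstrained basis has $k + 4$ columns and sums
to one at interior lags. The right-constrained variant drops the last *two*
columns, forcing $w(T) = 0$ with a smooth approach — the field's usual
constraint when effects are believed to die out inside the window. Whether
the original analysis of this design constrained the right edge is not
stated in print; both modes are implemented, and the package's own summary
analyses use the constrained fit because the configured truth (and the
reported weight curves in this literature) are essentially zero near the
75-day edge, where the unconstrained basis is poorly identified and
contributes most of the estimation error.

**Proportional hazards.** `schoenfeld_test()` computes per-event Schoenfeld
residuals (tie-adjusted under Efron weighting) and the score test of a
time-varying coefficient $\beta(t) = \beta + \theta g(t)$ using exact
per-event risk-set variances, with Kaplan–Meier, rank or identity time
transforms; it reproduces `survival::cox.zph` on tie-free data to
$10^{-12}$.

# The nested case–control arm

To confirm the weight function with a second design, incidence-density
sampling draws, for each case, two controls uniformly without replacement
from the members still under follow-up and event-free on the case's index
date, matched on sex, age at the index date (±2 years, closed interval) and
first-dispensing date (±30 days). Controls may be reused and may later
become cases; cases with an empty pool are reported, not silently dropped.
Whether the original design sampled from the full eligible pool or
truncated it is not documented; uniform sampling without replacement within
the pool is the package's choice. The conditional logistic likelihood
$\exp(\eta_{\text{case}})/\sum_k \exp(\eta_k)$ per matched set is the
one-case-per-set special case of the grouped partial likelihood, so the
same Newton machinery is reused (verified against `survival::clogit`). WCE
terms are evaluated at the index date from each member's own exposure
history; adjustment covariates are the comorbidity indicators and count in
the 12 months before the index date, any statin use in the 30 days before
it, and log(health services + 1) as a severity proxy (natural log, +1
offset to guard zero — the transform base and offset are not stated in
print).

# The synthetic-claims generator

No real claims can ship with the package, so `simulate_population()`
generates the three claims tables under a fully known process, and every
downstream stage is tested by recovery against that truth:

* **Demographics and baseline.** Ages are drawn from a truncated normal
  (mean 84, sd 7, range 45–100; the age effect is centred at 84 in the
  hazard), 38% female. Every patient receives qualifying COPD evidence
  (85% medication, 16% hospitalization; a 1% trap plants the *excluded*
  `R03BB01` code as the sole evidence to exercise that gate). Comorbidity
  categories are planted as recurring sentinel-ATC dispensings at
  prevalences typical of an elderly COPD population; 30% use glucocorticoids (driving, with baseline
  COPD admissions, a high-severity stratum whose baseline hazard is twice
  the low stratum's); 53% use statins with a monthly refill chain.
* **Paracetamol refill process.** A patient initiates with probability
  0.85 at a uniform date in the first 90% of the study; packs are 96 × 665
  mg CR (67% of patients) or 100 × 500 mg. Refill gaps are a shifted
  geometric around the days of supply, producing both early refills
  (up to 5 days, exercising the extension rule) and lapses (mean extra gap
  6 days). Per-refill persistence is Beta-heterogeneous across patients
  (mean 0.85), and a stopped patient restarts a new episode of use with
  probability 0.45 after a mean 100-day break. These values were chosen to
  reproduce the exposure descriptives reported for the real cohort this
  design emulates — median ≈100 days exposed with a wide interquartile
  range, roughly a quarter of follow-up time exposed, and about
  two-thirds of patients with ≥60 days of use — under ~18–23% outcome
  incidence; they were fixed before the recovery experiments and are not
  tuned to them.
* **Events in discrete time.** On each follow-up day a Bernoulli trial at
  $h(u) = h_0\,m_s \exp\{\theta' D(u) + \beta' Z(u)\}$ decides the outcome
  ($h_0 = 2\times10^{-4}$/day). Daily Bernoulli draws rather than a
  continuous-time algorithm match the day-resolution exposure data and make
  the true hazard ratio of any pattern analytically available
  (`true_pattern_hr()`), which is what the recovery tests compare against.
  Configurations whose implied hazard can exceed 1 are rejected. The first
  event day becomes a primary-position COPD episode; noise admissions
  (osteoarthritis primaries, some with secondary COPD codes) exercise the
  outcome matcher's strictness. Claims stop at death; death and
  residential-care entry censor at configured daily rates.
* **True weight function.** The default truth lies exactly on the 75-day,
  one-knot basis with coefficients (−0.0160, 0.0136, −0.0029, 0.0004,
  −0.0001): negative weights through the first week, a positive phase
  peaking around four weeks, and essentially zero beyond two months. At 4
  g/day this gives a hazard ratio of about 0.80 after 7 days of use and
  about 1.15–1.30 after 30–45 days, the magnitude reported in claims
  studies of this design.

What the generator does *not* emulate: over-the-counter purchasing
(exposure misclassification), dose titration or partial-day dosing,
seasonality, disease progression that feeds back into prescribing, and
reverse causation (initiation triggered by a pre-admission exacerbation).
Passing recovery tests therefore demonstrates that the estimation machinery
is correct under the stated observation model, not that those biases are
absent in real claims.

# Numerical choices and scales

Doses stay in g/day (no normalisation), so $\theta$ carries units of
log-HR per gram-day; the pattern grammar of "4 g daily for 30 days" then
needs no rescaling. Patterns are zero-padded to the window; a stopping lag
at or past the window gives HR exactly 1. Confidence intervals are
normal-theory delta-method at 95% by default. The linear predictor is
shifted by its maximum before exponentiation (the partial likelihood is
shift-invariant, exactly so under Efron ties). Degenerate inputs are
handled explicitly: empty populations produce empty tables; a dispensing
after the end of follow-up is skipped with a note; matched sets reduced to
a single member are dropped from the conditional likelihood.

Problem sizes in the shipped tests and acceptance script are the package's
choices for a desk-scale validation: the headline recovery run uses 2000
patients (~1400 cohort members, ~300 events); replicate calibrations
(pointwise band coverage, null pattern-CI exclusion) use 200 replicates of
500 patients on a study window shortened to end 2013; BIC window selection
uses 50 replicates of 1000 patients. At these sizes the weight function's
mean absolute error stays well under a quarter of the true amplitude and
pointwise 95% bands cover at close to nominal rates.

# Known limitations

* At effect sizes matching the printed hazard ratios of this literature
  (weights below 0.015 log-HR per gram-day), BIC comparisons between lag
  windows and against one-parameter conventional exposure models are
  noise-dominated at desk-scale event counts (150–600 events): the 1-knot
  candidates share a parameter count, so window choice is a pure likelihood
  comparison whose differences are of order 1–3, and the spline's extra
  parameters cost more BIC than the likelihood they buy. The package's own
  calibration suite measures this directly; window/BIC discrimination
  should be expected only with stronger weight functions or much larger
  cohorts, and a reported "best" window at these scales deserves the
  scepticism the selection table's margins make visible.
* The comorbidity map is a documented miniature, not a validated index;
  comorbidity counts are comparable within an analysis but not across
  publications using the full catalogue.
* Weight estimates at lags within ~3 days of zero and of the window edge
  rest on few basis functions; the unconstrained fit's bands there are
  honest but wide. Constraining the right edge assumes effects vanish at
  the window, which should be checked by comparing windows via BIC.
* The NCC arm inherits the matching calipers; in small cohorts strict
  calipers (±2 years, ±30 days) leave many cases unmatched, and estimates
  then carry the selection of matchable cases.
* Discrete daily hazards approximate a continuous-time Cox model; at the
  simulated event rates (≤ a few × 10⁻³/day) the approximation error is
  negligible relative to sampling noise.
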