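---
title: "Detecting low-salinity exposure thresholds for oyster abundance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting low-salinity exposure thresholds for oyster abundance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oysterthresh)
```

## The problem

Eastern oysters (*Crassostrea virginica*) are sessile: when a freshwater
pulse drops estuarine salinity for weeks, they cannot leave. Short forays
below their tolerance are survivable (valves close), but extended runs —
particularly in summer, when high temperature compounds osmotic stress — kill
both recruits (spat, shell height < 25 mm) and adults (≥ 25 mm). Management
questions arrive in the form of thresholds: *at which salinity, and after how
many days of exposure, does abundance collapse?*

"Threshold" hides two distinct operational definitions, and this package
implements both:

1. **A probabilistic crossing.** A hierarchical Bayesian model predicts mean
   abundance as a function of exposure days; the threshold is the day count
   at which the posterior median of predicted abundance falls below a
   *critical abundance*, defined as half the basin's five-year mean, i.e.
   the point at which there is more than 50% probability of being below
   critical.
2. **An abrupt change in the fitted relationship.** A random forest predicts
   abundance from all exposure covariates; the threshold comes from the
   location of the largest change in a partial-dependence curve, converted to
   days-below-a-salinity by a subtraction rule.

The two definitions answer different questions and need not agree; running
both against the same data is the point of the design.

## Exposure covariates

Daily mean salinity per station is binned into 0–1, >1–3, >3–5, >5–7 and
>7–9 psu. For each station, window (summer = May 1–Aug 31, always 123 days;
calendar year = 365/366) and bin, two covariates are computed: total days in
the bin, and the maximum run of consecutive calendar days in the bin. Column
names follow the monitoring convention: `s_d_su3.5` = total summer days in
3–5 psu; `c.d_su3.5` = maximum consecutive summer days. Accumulated
below-level covariates (`s_d_sult5` = total summer days with salinity < 5)
are available on request via `build_exposure_table(below = ...)`.

Numerical conventions, chosen once and documented because the field
convention leaves them open:

* **Bin edges.** Bins are open below, closed above — a day at exactly 5.0 psu
  counts in 3–5 — except 0–1, which is closed at both ends. The bin table is
  an argument, so a different convention is one data frame away.
* **"Below level x"** means strictly `< x`, matching the usual phrasing
  "salinity less than 5". At exact boundary values this differs from the sum
  of bins below x; daily means essentially never sit exactly on an integer
  boundary, but the two counting routes are distinct functions on purpose.
* **Missing days** are never counted and always break a consecutive run.
  This is conservative for run statistics: a gap can only shorten a reported
  run, never lengthen it.
* **Leap years.** Calendar windows use true day counts (366 in 2016, 2020);
  the RF interpretation rule, which mirrors printed arithmetic, uses the
  constants 123 (summer) and 365 (calendar).

## The hierarchical model and its Gibbs sampler

Abundance $A_{ijk}$ (mean oysters per dredge at station $j$, basin $i$, year
$k$, one value per station-season-year) is modeled as

$$A_{ijk} \sim N\!\left(\beta_{ij,0} + \lambda_{k,0} + \sum_m \gamma_m S_m,\ \sigma^2\right)$$

with station intercepts nested in basins,
$\beta_{ij,0} \sim N(\alpha_{i,0}, \sigma_j^2)$, basin intercepts
$\alpha_{i,0} \sim N(\alpha_0, \sigma_i^2)$ around a grand mean, and year
effects $\lambda_{k,0} \sim N(0, \sigma_k^2)$ with a pooled hyper-variance
(the year effects share one variance rather than one per year; with five
years there is no information to do otherwise). Five hierarchy structures are
available: station-in-basin + year, station-in-basin, basin + year, basin,
and year.

Every prior is conjugate — normal for location parameters, inverse-gamma for
variances — so every full conditional is available in closed form and the
sampler is pure Gibbs: no tuning, no acceptance rates. Defaults are flat:
$N(0, 10^6)$ and $\mathrm{IG}(0.001, 0.001)$, all configurable through
`prior_spec()`. Covariates enter on their natural day scale (no
standardization) so a slope is directly "oysters per dredge per day of
exposure"; this is an interpretability choice and costs nothing numerically
at these design scales.

Chain defaults are 3 chains × 20,000 iterations, 5,000 burn-in, thinning 5.
Simulation studies in the tests and the acceptance script use 2 chains of
800–3,000 iterations: at n = 90 observations the slope posterior is
well-mixed within a few hundred iterations, while some hierarchy variances
(three basins' worth of information) mix slowly and can trip the Gelman-Rubin
1.1 limit at those lengths — the fit then carries a warning and a
`converged = FALSE` flag rather than failing, and the slope inference is
unaffected. The degenerate design of a single station with station-level
variance requested is refused outright.

Model comparison follows two instruments: DIC
($\bar D + p_D$, $p_D = \bar D - D(\bar\theta)$, the Spiegelhalter form) for
models sharing a hierarchy, with everything within 2 DIC of the best flagged
co-best; and posterior predictive loss in the squared-error Gelfand–Ghosh
form (sum of squared deviations from posterior-predictive means plus the sum
of predictive variances) across differing hierarchies, where DIC's effective
parameter count is not comparable. Both are deterministic functions of the
saved draws, and the tests pin that property.

Slopes are classified by equal-tailed credible intervals: `negative-95` when
the 95% CI lies below zero, `negative-50` when only the 50% CI does, the
positive mirror images, and `indeterminate` otherwise.

## From fitted model to day threshold

For a negative-classified single-covariate model, `sweep_threshold()` runs
the fitted model over integer day counts 0–123 and reports the first day at
which the posterior median of predicted abundance is below the basin's
critical abundance. Decisions inside that sentence:

* **Prediction** uses the basin-level intercept draw (the distribution the
  station intercepts are drawn from) plus the year effect *averaged over the
  posterior year intercepts*: thresholds are meant to be basin-level
  statements, not single-year ones.
* **"More than 50% probability below critical"** is operationalized as the
  posterior median of the predicted mean crossing the critical value —
  equivalent under continuity of the posterior.
* The sweep grid is integer days, step 1; no extrapolation beyond the window.
* A positive or indeterminate slope is a refusal, not a missing value: the
  question "after how many days does abundance drop below critical" has no
  answer under a non-negative fitted relation. (Positive relations are probed
  further with `fit_quadratic_variant()`, which adds a squared term and asks
  whether DIC improves.)

## The random-forest branch

`fit_rf()` wraps a regression forest (500 trees, p/3 variables per split —
the conventional regression defaults) and computes out-of-bag
$r^2 = 1 - \mathrm{MSE}_{\mathrm{OOB}}/\mathrm{Var}(y)$. Only models with OOB
$r^2 > 0.75$ are interpreted; OOB rather than in-sample is a deliberate
choice (in-sample forest $r^2$ is optimistic enough to make the screen
meaningless). Importance is total node-purity decrease. If the top three
variables sit within 20% relative importance of the leader they are "tightly
grouped" and the lowest salinity bin among them is interpreted — the
rationale being that tightly grouped importances cannot distinguish
correlated exposure variables, and the lowest bin is the mechanistically
limiting one; the 20% is a quantification this package had to choose, and it
is a setting (`cluster_tolerance`), with 0 recovering "always the leader".

Partial dependence is the substitution average: for each grid day the
covariate is overwritten in every training row and predictions averaged. The
changepoint is the grid day maximizing the absolute centered difference of a
width-3 moving average of the curve, ties broken toward the smaller day, with
a configurable floor below which the curve counts as flat (no changepoint).
A manual override channel exists because practitioners often read
changepoints off the plot; injected values flow through the same
interpretation rule.

The interpretation rule itself: an abrupt change after $d$ days in a "safe"
bin (abundance *rising* with days at tolerable salinity) is read as abundance
being limited once days below the bin's lower bound exceed $123 - d$ (or
$365 - d$). When the partial dependence *declines* within the lowest bin
itself, no subtraction applies — the changepoint is the threshold, at
salinity below the bin's upper bound. The pipeline decides between the two
modes from the sign of the smoothed curve at the changepoint.

## The synthetic-data generator

The generator emulates the monitoring design the analysis assumes: six
Louisiana basins (three east, three west, Sabine excluded) with
registry-based baseline salinities, a configurable number of stations per
basin, and daily series over 2016–2020. Each series is baseline + seasonal
sinusoid (amplitude 3 psu, minimum June 15 — emulating early-summer river
pulses) + AR(1) noise ($\phi = 0.8$, innovation SD 1.8, stationary SD ≈ 3,
matching the reported basin-level salinity SDs of roughly 5–8 when combined
with the seasonal cycle), clamped at zero. The AR(1) structure is this
package's choice; per-station autocorrelation is not reported for the source
monitoring data. Low-salinity events overwrite the process with a target
level plus small observation noise, which is how tests plant known exposure
runs; overlapping events are rejected rather than silently merged.

Abundance is drawn from exactly the hierarchical model above, so parameter
recovery is testable against known truth. Negative draws are retained — the
likelihood is an unbounded normal, and truncating the generator would bias
recovery tests against the very model being fitted. Real dredge counts are
non-negative; the CSV reader warns when it meets negative counts. Monthly
replicate records within a season are emitted as identical copies of the
station-year draw (the model's finest unit), so collation averages reproduce
the draw exactly; within-season sampling noise is not emulated.

The canned scenarios fix the study conditions used throughout the tests:
3 basins × 6 stations × 5 years (n = 90), residual SD 5, station-intercept
SD 2, basin intercepts 42/48/45, year effects −2…2, and summer event
durations uniform on 0–90 days so the low-salinity covariates span the
window. `"negative-slope-east"` plants $\gamma = -0.6$ on consecutive summer
days below 1 psu; `"null"` sets all slopes to zero; `"rf-step"` replaces the
linear response with a 30-unit drop once that covariate exceeds 40 days
(residual SD 2).

What passing these tests shows — and does not. The generator reproduces the
*statistical structure* the methods assume: nesting, seasonality,
autocorrelated exposure, planted effects. It does not mimic real hydrology
(no spatial interpolation, no inter-station correlation within a basin, no
zero-inflation of dredge counts, no harvest or disease covariates). Green
tests certify that the machinery recovers what it is pointed at, not that
Louisiana oysters obey a linear day-count model.

## Problem sizes and numerical choices

Simulation studies run at the scale the methods are meant for: n = 90
observations per fit, 20 replicates for coverage and false-positive studies,
2 × 1,500-iteration chains in tests (2 × 2,500 in the acceptance script's
headline fit), 200–1,000 random series for the exposure oracle. The full
pipeline on the smallest fixture completes in well under five minutes on one
CPU. Ties in the changepoint detector are resolved with a $10^{-9}$ relative
tolerance so floating-point jitter cannot flip a tie away from the smaller
day. The master seed fans out to stages through a small deterministic hash,
so stages are independently reproducible and no global RNG state leaks
between them.

## Known limitations

* Stage classification (spat < 25 mm ≤ adult) follows the monitoring
  convention for dredge data; field programs sometimes draw the adult line at
  larger shell heights, and the boundary here is a single documented
  constant.
* The five-year critical abundance is computed over station-year rows, not
  station means of year means; with unbalanced sampling the two differ.
* DIC/PPL are implemented for the normal likelihood only.
* The RF branch inherits partial dependence's blind spot: correlated
  covariates (total vs consecutive days in the same bin are often nearly
  collinear) share importance, which is precisely why the tightly-grouped
  selection rule exists.
* Thresholds are in-window statements (0–123 summer days); nothing is said
  about calendar-scale chronic exposure unless calendar windows are included.
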