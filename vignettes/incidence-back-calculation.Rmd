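---
title: "Back-calculating disease incidence from prevalence and mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Back-calculating disease incidence from prevalence and mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(incback)
```

## The model

`incback` implements the three-state illness–death multistate life table:
a birth cohort moves between *healthy*, *diseased* and *dead*, with two
independent causes of death (the disease and everything else). Four
age-specific transition hazards drive the system, each held constant
within a one-year age interval:

* incidence $i(a)$ — first disease events per disease-free person-year;
* remission $r(a)$ — zero throughout this package's intended use, because
  an *ever-had* prevalence measure admits no return to the healthy state;
* case fatality $f(a)$ — disease deaths per diseased person-year;
* other-cause mortality $m(a)$ — acting equally on both living states.

Writing $S(a)$ and $C(a)$ for the proportions alive and disease-free /
diseased, the system is

$$\frac{dS}{da} = -(i + m)\,S + r\,C, \qquad
  \frac{dC}{da} = i\,S - (r + f + m)\,C,$$

with prevalence among the living $p = C/(S+C)$ and disease-attributable
population mortality $M = f\,p$. Because $m$ acts equally on both states
and the causes are independent, other-cause survival factors out of $p$
multiplicatively: prevalence is invariant to $m$, a property the test
suite asserts on randomised schedules.

Within each one-year interval the $2\times 2$ linear disease submodel is
solved in closed form (real eigenvalues; the divided difference of the
two exponentials is computed through `expm1`, so nearly coincident
eigenvalues — $r = 0$, $i = f$ — need no special-casing for the states).
Death flows are integrated in closed form too, so
$S + C + D_\text{disease} + D_\text{other}$ is conserved to machine
precision, and a `deSolve` numerical integration of the same system is
available as a cross-check (`integrate_cohort(method = "ode")`).

## The inverse problem

The package's central operation runs the model backwards, as consistency
software for burden-of-disease estimation does: given cross-sectional
single-year prevalence of ever-diagnosed disease, remission fixed at
zero, disease-specific population mortality $M(a)$ and all-cause
mortality, `solve_steady_state()` returns the incidence and case-fatality
schedules that reproduce the inputs.

Case fatality comes from the identity $f(a) = M(a)/p(a)$; treating the
death-certificate rate as $M$ is an approximation discussed below. Other-
cause mortality is the all-cause rate minus $M$. Incidence is then solved
sequentially, one age at a time: stepping the cohort from age $a$ with
the fitted hazards, $i(a)$ is the unique non-negative rate landing
exactly on the input prevalence at $a+1$ (the map $i \mapsto p(a+1)$ is
monotone, so a safeguarded Newton iteration inside a bracket converges to
$|\Delta p| < 10^{-15}$). Where the input prevalence falls faster than
zero incidence allows, incidence is floored at 0 and the age flagged;
the convergence flag then reports that the forward-consistency contract
(prevalence reproduced within $10^{-4}$, csmr within $10^{-5}$) is not
met. The top age has no gradient to invert and carries the previous
age's value. At zero remission this construction agrees with the
continuous-time closed form $i = p'/(1-p) + M$ evaluated at interval
midpoints to within discretisation error, which the tests bound at 2%.

## The steady-state assumption and the trend layer

Using one cross-section to stand in for every cohort's history assumes
age-specific rates are static in calendar time. For a disease whose
incidence has fallen for decades this is wrong in a specific direction:
today's prevalence at age $a$ was accumulated under historically higher
incidence, so the steady-state estimate *over-states* current incidence.

`solve_with_trend()` relaxes the assumption the way consistency software
does: every age group changes at the same proportional annual rate
(age-stratified trends are deliberately not supported). The convention is
cohort-time anchored: the cohort observed at age $a$ experienced, at age
$a'$, the index-year hazard scaled by $(1+\tau)^{-\min(a-a',\,H)}$, with
hazards held at the horizon level further back. Matching the
cross-section at age $a$ then determines the index-year $i(a-1)$
sequentially, since all earlier hazards in that cohort's history are
already solved — an $O(A^2)$ sweep that still runs in well under a
second. With both trends zero the trended path performs bitwise the same
arithmetic as the steady-state path.

Two presets ship with the package: the long-run coronary decline
(incidence $-4\%$/yr, case fatality $-1\%$/yr over 28 years) used for the
main trended analysis, and a stronger recent-decade sensitivity setting
($-5\%$/$-4\%$, same horizon — the horizon is not separately documented
for the sensitivity setting, so the main one is reused). A stronger
*case-fatality* decline can raise older-age incidence estimates (a
historically more lethal disease means the surviving prevalent pool
implies more incidence), so "larger trends lower the estimates" is only
asserted at younger ages, where the incidence-trend effect dominates.

## Preprocessing grouped inputs

Survey prevalence arrives in wide age bands; mortality in 5-year bands.
Both are smoothed to single years before solving:

* **Mortality** (`expand_mortality`): natural cubic spline through
  (band midpoint, log rate), exponentiated on the grid. Natural end
  conditions give linear extrapolation in log-rate beyond the outer
  midpoints, avoiding blow-up at the youngest and oldest ages. Zero rates
  are replaced by half the smallest positive rate before the log
  transform (flagged with a warning). Band midpoints use the
  completed-year convention $(a_\text{low}+a_\text{high}+1)/2$; an
  open-ended top band gets its lower bound plus 5 years, since
  survivorship concentrates mass near the bound.
* **Prevalence** (`fit_sigmoid_prevalence`): a 3-parameter logistic
  $L/(1+e^{-k(a-a_0)})$ fitted by weighted least squares
  (Levenberg–Marquardt with box constraints $0 < L \le 1$, $k > 0$;
  multi-start over $a_0 \in \{50, 65, 80\}$). Weights are $1/se^2$ when
  every band reports a positive standard error, equal otherwise. The
  positive-$k$ constraint makes the curve monotone, as ever-had
  prevalence must be when mortality differentials are modest.

The logistic family is a deliberate simplification, and its cost is
measurable: with *noise-free* 10-year band data from the default
synthetic truth, smoothing alone perturbs back-calculated incidence by up
to roughly a tenth locally, because the true prevalence curve is not
exactly logistic. The test suite bounds this at 15% and separately
verifies sub-1% recovery when the survey is emulated at single-year
resolution, isolating the smoothing bias from the solver.

## Uncertainty

`bootstrap_incidence()` propagates survey sampling error with a
parametric bootstrap: band prevalences are drawn from a normal
distribution with the reported standard errors (truncated to $[0,1]$ by
redrawing up to 100 times, then clipping), the sigmoid fit and the solver
are re-run, and each age's interval is the plain percentile interval
(order statistics, no smoothing) of the replicate incidence values.
Mortality and remission are never perturbed; replicates that fail to
converge are excluded and counted, and a run with more than 20% failures
is flagged. The default of 1000 replicates resolves a 95% interval
comfortably; the test suite and the study driver use 200 to stay within
desk-scale budgets. Identical seed and configuration give bit-identical
intervals. Trended bootstrap runs are supported but off by default,
mirroring how uncertainty analyses are typically omitted for trended
runs. Band-level perturbation (before smoothing) was chosen over
perturbing the smoothed curve, since the reported uncertainty attaches to
the bands.

## The registry comparator

`classify_events()` applies the linked-registry case definition: a
qualifying admission is an *emergency* admission with *primary* AMI
diagnosis and a length of stay *strictly greater than one day* for
someone discharged alive; a qualifying death has AMI as the underlying
certificate cause. Any death within 30 days (inclusive, measured from
the admission date) after an admission-based event marks it fatal, on the
assumption it relates to the same event; qualifying records within 30
days of an existing event are absorbed into it; a qualifying death 31 or
more days after the last event opens a new, fatal event. "First" means
first since the registry start: a fixed lookback cannot see earlier
history, so some recurrences are misclassified as first events, and
shortening the lookback can only inflate the first-event count — a
property asserted on simulated histories. `incidence_rates()` converts
first events to rates per 100,000 person-years with normal-approximation
Poisson intervals $rate\,(1 \pm z_{0.975}/\sqrt{n})$ (exact chi-square
limits behind `ci = "exact"`; zero-count bands report the rule-of-three
upper bound). Admission records carry `age_at_admission` because banded
rates need an age for every event — the stand-in for date-of-birth
linkage.

## The synthetic world

`simulate_event_histories()` draws each person's life in continuous time
from birth through the end of the index year: while healthy, first AMI
(calendar-scaled by the incidence trend) competes with other-cause
death; an AMI is immediately fatal with the age-specific 30-day
probability, otherwise it yields an admission record and moves the person
to the diseased state, with mortality at `excess_mult` times the
other-cause hazard and recurrences at `recurrence_mult` times the
first-event hazard. Survivors' eventual deaths carry the AMI-anywhere
certificate flag. At most one transition is drawn per person-interval
(the 30-day fatality is resolved at the event itself); deferring any
further transition to the next interval slightly undercounts same-year
sequences, an approximation accepted for speed.

The default scenario was fixed once, before any acceptance run, to be
magnitude-plausible for England-like first-AMI epidemiology: Gompertz
incidence $6.6\times 10^{-5} e^{0.0626 a}$ (women scaled by 0.45),
matching the rough $10^2 \to 10^3$ per 100,000 rise of measured rates
between the mid-50s and 85+; logistic 30-day case fatality
$\text{logit}^{-1}(-4 + 0.045a)$; Gompertz other-cause mortality
$5\times 10^{-5} e^{0.088 a}$; survivor mortality multiplier 2 and
recurrence multiplier 3; a $-4\%$/yr incidence and $-1\%$/yr
case-fatality decline over a 28-year horizon; registry records from 1998
with index year 2010; 3000 births per single-year cohort and sex
(300,000 persons per sex — large enough for stable band counts, small
enough for a full two-sex study with bootstrap in about half a minute).
The survey emulation allocates 8610 respondents (ages 16+, 10-year
bands) in proportion to population and draws binomial counts; the
vital-statistics emulation tabulates index-year deaths in 5-year bands
over simulated person-years.

`analytic_inputs()` integrates the same transition structure
deterministically, giving the cross-section an infinitely large study
would measure. It distinguishes `csmr_excess` (fatal first events plus
the *excess* mortality of survivors — the ideal model input, under which
the solver recovers the true hazard almost exactly) from
`csmr_anywhere` (additionally counting survivors' baseline deaths, as an
anywhere-on-the-certificate tabulation does — a documented upward
approximation the realistic pipeline inherits). Where prevalence is
exactly zero a disease-attributable rate is not representable as
$f \cdot p$ and is projected to zero.

### What the generator does and does not emulate

It reproduces the features the study design turns on: cohort histories
under secular decline, left-truncated registries, binomial survey noise,
certificate-based mortality, competing risks and recurrences. It does
not attempt real English demography (no migration, no birth-cohort size
variation, no care-home sampling frame — though a self-report
under-report knob exists, off by default), no hospital transfer or coding
noise, and no age-varying trend by default even though the truth supports
one. Passing tests therefore show the *method's* behaviour under known
conditions, not calibration to the real population.

## What the full study shows

Running the whole design — simulate, classify, emulate, smooth, solve,
bootstrap, compare (`run_validation_study()`) — under the default
declining-incidence scenario reproduces the qualitative finding that
motivates the package: the steady-state solver over-estimates measured
first-event rates across the younger and middle age bands with mostly
non-overlapping intervals, while the trend-adjusted run moves the
younger bands close to the registry rates. The acceptance script
(`scripts/acceptance.R`) recomputes these headline quantities from
scratch, along with the analytic checks (sub-1% no-trend recovery;
steady-state versus trend-adjusted mean absolute relative error against
a genuinely trending truth).

## Numerical choices, in one place

* Ages are exact-age grid points; rates attach to the half-open year
  starting at the grid point. Age grids are single-year and consecutive.
* Interval stepping is closed-form; the `ode` method must agree to
  $10^{-8}$ (asserted).
* Interval inversion: safeguarded Newton, bracket expansion by factors of
  4 up to a hazard cap of 50/yr, convergence at $|\Delta p| < 10^{-15}$.
* Display rounding is half-away-from-zero, applied to rates and
  percentage differences only at the reporting layer; machine output
  keeps full precision.
* Bootstrap truncation: redraw up to 100 times, then clip to $[0,1]$.
* 30-day windows are inclusive of day 30; ties between an admission and a
  death on the same day order the admission first.

## Known limitations

* The logistic prevalence family biases back-calculated incidence where
  the true curve departs from it (bounded empirically above); richer
  curve families were deliberately left out of scope.
* The anywhere-on-certificate mortality input overstates
  disease-attributable mortality, inflating incidence mainly at older
  ages where survivor deaths dominate — visible in the synthetic study
  as part of the over-estimation.
* The trend layer applies one proportional change to all ages; when the
  real decline is age-specific this residual mis-specification remains.
* Sampling variation matters at desk scale: band counts of tens of
  events put several percent of Monte-Carlo noise on measured rates,
  which is why directional claims are asserted on bands, not single
  years.
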