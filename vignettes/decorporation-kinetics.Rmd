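---
title: "Modeling whole-body radionuclide decorporation kinetics"
author: "decorpkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling whole-body radionuclide decorporation kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decorpkin)
```

## The problem

After internal contamination with a radionuclide such as ⁶⁵Zn, chelation
therapy (e.g. Zn-DTPA) accelerates excretion. Whole-body counting gives a
single observable per animal and day: the percentage of the reference-time
activity still retained. Two questions drive the analysis of such studies:
how effective is an intervention (a dose–response question answered by
model-free summaries), and what kinetic law governs the decline (a
model-selection question). `decorpkin` implements both layers — summary
metrics, a family of kinetic models with closed-form solutions and
independent numeric oracles, fitting machinery, and a seeded synthetic-data
generator that emulates the three classical experimental settings (single
pre-treatment, pre- plus 24-h post-treatment, and a delayed five-day course
starting on day 12) with seven rats per arm.

## Retention data and model-free summaries

The unit of analysis is a group-level retention series: mean %retention,
SEM and group size per measurement day, always relative to a reference time
where the mean is 100 by construction. SEM is the sample standard deviation
(n − 1 denominator) across animals divided by √n. The reference time is a
*parameter*: delayed-course analyses renormalize mid-study (to day 12 or
13), so `normalize_retention()` and `renormalize_retention()` take it
explicitly.

The area under the retention curve (AURC, %·day) is computed by the
trapezoid rule on the *observed* mean curve — deliberately model-free, with
linear interpolation at window edges so adjacent windows add exactly.
Dose–response relations (AURC or day-2 retention versus chelator dose in
mg/100 g body weight) are ordinary least squares via `dose_response()`.

## The two-compartment model

Blood (amount $C_b$) exchanges with a deep tissue pool ($C_d$), with
first-order urinary elimination from blood:

$$\frac{dC_b}{dt} = -(k_{bd}+k_e)\,C_b + k_{db}\,C_d, \qquad
  \frac{dC_d}{dt} = k_{bd}\,C_b - k_{db}\,C_d,$$

with $C_b(0)=C_0$, $C_d(0)=0$. The blood solution is the biexponential

$$C_b(t) = C_0\frac{k_{db}-\beta}{\alpha-\beta}e^{-\beta t}
         + C_0\frac{k_{db}-\alpha}{\beta-\alpha}e^{-\alpha t}
         = A e^{-\alpha t} + B e^{-\beta t},$$

where $\alpha \ge \beta$ are the eigenvalues of the rate matrix, i.e. the
roots of $\lambda^2-(k_{bd}+k_{db}+k_e)\lambda+k_{db}k_e=0$, and
$A+B=C_0$. `micro_to_macro()`/`macro_to_micro()` convert exactly between
the mechanistic rates and the observable $(A,B,\alpha,\beta)$ form
($k_{db}=(A\beta+B\alpha)/(A+B)$, $k_e=\alpha\beta/k_{db}$,
$k_{bd}=\alpha+\beta-k_{db}-k_e$); the derived elimination half-life is
$t_{1/2}=\ln 2/k_e$. Equations are carried in amounts (equivalently
%retention): the concentration form differs only by the distribution
volume, so no volume parameter exists in the package.

Numerical choices: eigenvalues are ordered fast-first; a relative
discriminant below $10^{-12}$ switches to the confluent (repeated-root)
closed form $C_0(1+(k_{db}-\lambda)t)e^{-\lambda t}$, keeping the solution
continuous in the parameters. `integrate_ode()` (lsoda at $10^{-11}$
tolerances, with cumulative elimination $k_e\int C_b$ as a third state) is
the independent oracle: the test suite checks closed-form agreement to
$10^{-8}$ relative over 1000 random rate sets and mass balance
$C_b+C_d+\text{eliminated}=C_0$ to $10^{-6}$.

### Which observable does whole-body counting see?

Formally the whole-body signal is $C_b+C_d$. With the fast treated rate
set ($k_{bd}=1.77$, $k_{db}=1.21$, $k_e=0.19\ \mathrm{day}^{-1}$),
however, the total has a fast-phase amplitude of only ~4% of $C_0$,
whereas observed treated whole-body curves in this class of experiment
drop steeply on day one (to ~35–40%) — the shape of the *blood* solution,
which is also the form conventionally fitted to whole-body retention data.
Both observables are therefore first-class: `fit_model(...,
observable = "total")` is the default for fitting (mass-balance reading),
`"blood"` is available and is what the pipeline's two-compartment stage
uses (logged in the report), and the synthetic generator states per truth
model which observable it emulates (see below). The package takes no
position on which reading is "correct" for any given dataset; the choice
is explicit everywhere.

## The diffusion model and the square-root law

For late decorporation the package models release from tissues as Fick
diffusion across cell membranes from an "infinite" reservoir held at
$C_{d0}$ into a semi-infinite medium initially at zero:

$$\partial_t C = D\,\partial_x^2 C,\quad C(0,t)=C_{d0},\ C(x,0)=0,\
  C(\infty,t)=0 \;\Rightarrow\; C(x,t)=C_{d0}\,
  \mathrm{erfc}\!\left(\frac{x}{2\sqrt{Dt}}\right),$$

with boundary flux $J(t)=C_{d0}\sqrt{D/(\pi t)}$ and cumulative transfer
$Q(t)=2AC_{d0}\sqrt{Dt/\pi}$ — the square-root law (quadrupling time
doubles the transferred amount). The erfc form is used because it is the
unique similarity solution whose flux integrates exactly to that $Q(t)$.
Empirically the law appears as $\%R(t) = a - b\sqrt t$
(`sqrtlaw` in the registry); $a$ is *not* constrained to 100 because the
law applies to the late window after the first-day drop, and no clipping
at zero is applied — instead the zero-crossing $t^* = (a/b)^2$ is reported
as a validity diagnostic. Only the lumped slope $2AC_{d0}\sqrt{D/\pi}$ is
identifiable from retention data; the mechanistic triple $(D, C_{d0}, A)$
is deliberately not estimated (the `diffusion` registry entry fits the
lumped form).

`pde_oracle()` is the independent check on all of this: Crank–Nicolson
with eight backward-Euler start-up steps (damping the discontinuous
initial condition), a uniform spatial grid on a truncated domain
($L \ge 6\sqrt{D t_{max}}$, violation recorded as a warning), internal
time steps uniform in $\sqrt t$ to resolve the $t^{-1/2}$ flux
singularity, and $Q$ by trapezoidal integration of the one-sided
second-order boundary flux against $\sqrt t$ (the exact integrand is
constant in that variable, so the quadrature error is dominated by the
flux discretization). At `nx = 300` the profile agrees with the erfc form
to 0.34% (where $C>0.01\,C_{d0}$) and numeric $Q$ to well under 1%; the
scheme converges at second order in the grid spacing. These are
oracle-quality settings, chosen for accuracy over speed.

## Fitting

All registered models (`monoexp`, `biexp_macro`, `bicompartment`,
`sqrtlaw`, `diffusion`) share one surface. Models linear in $\sqrt t$ are
solved exactly by OLS. Nonlinear models use Levenberg–Marquardt with box
constraints (rates ≥ 0) and multi-start: the base initialization plus four
multiplicatively jittered restarts (log-normal, 20% scale,
seed-controlled), keeping the best SSE. The base initialization for
biexponential shapes is classical curve stripping (`strip_initialize()`):
the last four points give the slow phase by log-linear regression, the
positive early residuals give the fast phase; residuals below $10^{-8}$ of
the data scale (or an implied $\alpha \le \beta$) trigger a documented
heuristic ($\alpha = 5\beta$) and are flagged in the result. Weights are
`"none"` by default — group means are what is fitted, matching standard
practice for this design — with inverse-SEM² weighting available and
recorded.

Goodness of fit is $R^2 = 1-\mathrm{SSE}/\mathrm{SS_{tot}}$ about the
observed mean, for nonlinear fits too (negative values are allowed and
meaningful); `compare_models()` ranks models by $R^2$ on an identical
window and weights, breaking ties toward fewer parameters. No
information-criterion selection is attempted: with a shared window and
near-equal parameter counts, $R^2$ ordering is the transparent choice for
this design.

Two-phase segmented regression (`fit_two_phase()`) fits two *independent*
OLS lines to log %retention on either side of a breakpoint; candidates are
the midpoints between consecutive sampling days, searched exhaustively
(about ten candidates at daily sampling — a continuous breakpoint search
would add nothing), minimizing pooled SSE with ties broken toward the
earliest candidate (within a $10^{-9}$ relative tolerance, since exact
floating-point ties do not occur). The segments are not constrained to
meet at the breakpoint; natural logs are used throughout.

Default analysis windows mirror standard practice for these designs: full
window 0–10 d and late window 2–10 d for rapid intervention, days 13–23
for the delayed course with the square-root law on 16–23 d. All are
configurable in `run_config()`.

## The synthetic-data generator

No raw per-animal data are publicly deposited for this class of
experiment, so the generator is a first-class module: it encodes the three
designs (doses 0, 3.32 and 5 mg/0.25 mL/100 g b.w.; "30 min before"
encoded as day −0.021; delayed course dosed days 12–16 and measured daily
to day 23; 7 rats; 0.037 MBq per rat). The delayed design includes a
day-12 baseline measurement taken before the first injection, so both
day-12 and day-13 renormalizations are reproducible.

The generative truth is explicit and seeded. Treated rapid arms use the
two-compartment rate set $k_{bd}=1.77$, $k_{db}=1.21$,
$k_e=0.19\ \mathrm{day}^{-1}$ with the blood observable (day-2 retention
≈ 32%). Control arms use the slow transfer rates $k_{bd}=0.14$,
$k_{db}=0.09\ \mathrm{day}^{-1}$ with $k_e = \ln 2/2.8 - k_{bd}$, so the
initial observed log-slope ($k_{bd}+k_e$ under the blood observable)
corresponds to an early half-life of 2.8 days. Delayed arms use the total
(mass-balance) observable, since a delayed intervention acts by draining
the deep pool; treatment is modeled as piecewise-constant multiplicative
factors on $(k_e, k_{db})$ — 15× for one day per administration — chosen
so the first treatment day takes whole-body retention to just under half
(46% noise-free), with the state vector carried continuously across every
switch. Measurement noise is multiplicative log-normal on activity
(counting and biological variability are scale-proportional, and
retention is a ratio of positive activities), $\sigma_{\log}=0.02$ by
default; per-rat streams derive from the master seed by a fixed offset, so
identical configurations give byte-identical CSVs.

What the generator does *not* emulate — and therefore what passing tests
do not show about real data: radioactive decay of ⁶⁵Zn ($t_{1/2}\approx$
244 d) is omitted (over ≤ 23 days it is dominated by biology and mostly
cancels under retention normalization); inter-animal kinetic heterogeneity
beyond measurement noise is off (rats within an arm share one parameter
set); the two treated rapid arms share one rate set, so simulated
dose–response slopes are flatter than those of a real dose-ranging
experiment; and the homogeneous deep pool means the five-day delayed
course keeps draining at a constant modified rate, giving a steeper late
decline than a real, heterogeneously-bound tissue pool would show. The
square-root-law truth option generates the late-window behaviour directly
when that regime is the object of study.

## Problem sizes and verification

The test suite and the acceptance script regenerate everything from code:
1000 random rate sets for the closed-form/ODE comparison, 100–200
replicate groups for the Monte-Carlo recovery and model-contest studies,
`nx = 300` for the diffusion oracle. Noise-free simulate-then-refit
recovers all registered models' parameters to $10^{-4}$ relative (in
practice to near machine precision); with $\sigma_{\log}=0.02$ and $n=7$,
the elimination constant $k_e$ is recovered within 25% of truth in
essentially every replicate. On square-root-truth data with the late
treated-arm shape (≈32% at day 2 falling to ≈10% at day 10), `sqrtlaw`
out-ranks `monoexp` in every one of 200 replicate contests.

## Known limitations

* The two-compartment model is identifiable only when the data contain
  both phases; when the fast amplitude is small relative to noise,
  $k_e$ estimates degrade (the reason the blood/total observable choice
  matters — see above).
* The square-root law is an asymptotic, late-window description; it
  crosses zero at $t^*$ and must not be extrapolated near or beyond it.
* AURC is computed on the observed grid; with daily sampling the
  trapezoid bias is second-order in the spacing but not zero.
* The breakpoint search returns midpoints between sampling days; its
  resolution is half the sampling interval by construction.
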