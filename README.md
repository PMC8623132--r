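# decorpkin

Kinetic analysis of whole-body radionuclide **decorporation** — the removal
of an internally deposited radionuclide (here modeled after ⁶⁵Zn) by
chelation therapy (Zn-DTPA), measured by whole-body counting in small
animals.

The package answers the two questions such studies pose:

* **How effective is an intervention?** Model-free summaries of the
  %retention–time curve: the area under the retention curve (AURC,
  %·day, trapezoid rule), retention at a query day, and ordinary
  least-squares dose–response fits of either metric against chelator dose.
* **What law governs the decline?** A registry of kinetic models fitted by
  (weighted) least squares and compared by R²:
  * `monoexp` — $R(t) = R_0 e^{-kt}$;
  * `bicompartment` — blood ⇄ deep-tissue exchange with urinary
    elimination, $dC_b/dt = -(k_{bd}+k_e)C_b + k_{db}C_d$,
    $dC_d/dt = k_{bd}C_b - k_{db}C_d$, with the closed-form biexponential
    solution $C_b(t) = Ae^{-\alpha t} + Be^{-\beta t}$
    ($\alpha,\beta$ the rate-matrix eigenvalues), exact
    micro ⇄ macro conversion and derived half-lives $t_{1/2}=\ln2/k$;
  * `biexp_macro` — the $(A, B, \alpha, \beta)$ observable form directly;
  * `sqrtlaw` / `diffusion` — the square-root release law
    $\%R(t) = a - b\sqrt{t}$ arising from Fick diffusion out of an
    "infinite" tissue reservoir into a semi-infinite medium
    ($Q(t) = 2AC_{d0}\sqrt{Dt/\pi}$), the model for late, slow
    decorporation.

Around these sit two-phase segmented log-linear regression with exhaustive
breakpoint search (for biphasic curves with an inflection), curve-stripping
initialization, independent numeric oracles (an ODE integrator for the
compartment model, a Crank–Nicolson finite-difference solver for the
diffusion equation), and a seeded synthetic-data generator reproducing the
three classical experiment designs (pre-treatment, pre + 24 h
post-treatment, delayed five-day course; 7 rats per arm).

## Worked example

Simulate the high-dose pre-treatment arm (7 rats, 2% log-normal
measurement noise), normalize, and fit the two-compartment model:

```r
library(decorpkin)

design <- study_designs()$exp2_high
truth  <- default_truth("exp2_high", noise_sigma = 0.02, seed = 42)
sim    <- simulate_group(design, truth)
sim$series
#> <retention_series> group 'exp2_high', 11 points over days 0-10, ref day 0, n = 7
#>        group time_day mean_retention_pct   sem_pct n
#> 1  exp2_high        0          100.00000 0.0000000 7
#> 2  exp2_high        1           37.74062 0.4966684 7
#> 3  exp2_high        2           32.78697 0.4688696 7
#> ...
#> 11 exp2_high       10          17.92454 0.1801053 7

fit_model("bicompartment", sim$series, observable = "blood", seed = 42)
#> <fit_result> model 'bicompartment' on window [0, 10] days
#>   parameters: k_bd = 1.7512, k_db = 1.1991, k_e = 0.19151, c0 = 99.999
#>   R^2 = 0.99990, SSE = 0.5154, converged: TRUE
#>   derived: t_half_e = 3.619, t_half_terminal = 9.257
```

The fitted transfer constants recover the generating values
(k_bd = 1.77, k_db = 1.21, k_e = 0.19 day⁻¹) to within ~1%, and the
derived elimination half-life ln 2 / k_e ≈ 3.6 days. The biphasic shape
and the late-window model contest:

```r
fit_two_phase(sim$series)
#> <segmented_fit> breakpoint at day 1.5 (window [0, 10])
#>   phase1: slope -0.97443 /day, intercept 4.6052, R^2 1.0000 (n = 2)
#>   phase2: slope -0.074676 /day, intercept 3.6259, R^2 0.9976 (n = 9)

compare_models(sim$series, c("sqrtlaw", "monoexp"), window = c(2, 10))
#> <model_comparison> window [2, 10] days
#>  model_id        r2       sse n_params converged
#>   sqrtlaw 0.9983228 0.3383517        2      TRUE
#>   monoexp 0.9970200 0.6011950        2      TRUE
```

The log-retention curve breaks into a fast phase (slope ≈ −0.97/day,
dominated by elimination from blood) and a slow phase (slope ≈ −0.075/day,
the slow eigenvalue β), and on the late window the square-root (diffusion)
law out-fits the mono-exponential — the signature of diffusion-limited
release from tissues.

The full pipeline (normalization, AURC, dose–response across arms, all
fits and comparisons, JSON report + log) is one call:

```r
report <- run_pipeline(run_config(
  arms = c("exp2_control", "exp1_low", "exp2_high"), seed = 1),
  out_dir = "out")
```

A thin command-line wrapper with `simulate` and `analyze` subcommands is
installed at `inst/cli/decorpkin.R`.

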