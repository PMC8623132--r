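Package: decorpkin
Title: Compartmental and Diffusional Kinetics of Whole-Body Radionuclide
    Decorporation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinetic analysis of whole-body radionuclide retention time
    series from chelation (decorporation) studies. Implements the
    mono-exponential, macroscopic biexponential and two-compartment
    (blood/deep tissue) retention models with closed-form solutions,
    micro/macro rate-constant conversion and derived half-lives; a
    semi-infinite-medium Fick diffusion model with its square-root
    release law and a finite-difference oracle; nonlinear least-squares
    fitting with curve-stripping initialization and multi-start;
    segmented two-phase log-linear regression with breakpoint search;
    area-under-the-retention-curve and dose-response summaries; R-squared
    based model comparison; and a seeded generator of per-animal
    synthetic retention data emulating pre-treatment, repeated-dose and
    delayed chelation experiment designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
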