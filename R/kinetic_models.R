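#' Mono-exponential retention parameters
#'
#' @param r0 Initial retention level in percent (> 0).
#' @param k First-order decay rate in day^-1 (>= 0).
#' @return An object of class `mono_exp_params`.
#' @export
mono_exp_params <- function(r0, k) {
  if (r0 <= 0) stop_decorpkin("r0 must be positive", "domain_error")
  if (k < 0) stop_decorpkin("k must be non-negative", "domain_error")
  structure(list(r0 = r0, k = k), class = "mono_exp_params")
}

#' Two-compartment (blood/deep tissue) micro rate constants
#'
#' The model has a central blood compartment exchanging with a deep tissue
#' compartment, with first-order elimination from blood:
#' \deqn{dC_b/dt = -(k_{bd}+k_e) C_b + k_{db} C_d}
#' \deqn{dC_d/dt = k_{bd} C_b - k_{db} C_d}
#' with initial conditions \eqn{C_b(0)=C_0}, \eqn{C_d(0)=0}.  Equations are
#' written in amounts (equivalently percent retention); the concentration
#' form differs only by the distribution volume so no volume is carried.
#'
#' @param k_bd Blood-to-deep transfer rate, day^-1 (>= 0).
#' @param k_db Deep-to-blood transfer rate, day^-1 (>= 0).
#' @param k_e Elimination rate from blood, day^-1 (> 0 for identifiability).
#' @param c0 Initial amount in blood (percent or amount units, > 0).
#' @return An object of class `bicompartment_params`.
#' @export
bicompartment_params <- function(k_bd, k_db, k_e, c0 = 100) {
  if (any(c(k_bd, k_db, k_e) < 0))
    stop_decorpkin("rate constants must be non-negative", "domain_error")
  if (c0 <= 0) stop_decorpkin("c0 must be positive", "domain_error")
  structure(list(k_bd = k_bd, k_db = k_db, k_e = k_e, c0 = c0),
            class = "bicompartment_params")
}

#' Macroscopic biexponential parameters
#'
#' The observable form of the two-compartment blood solution,
#' \eqn{C_b(t) = A e^{-\alpha t} + B e^{-\beta t}} with \eqn{\alpha \ge \beta}
#' (alpha the fast eigenvalue) and \eqn{A + B = C_0}.  The eigenvalues are
#' the roots of \eqn{\lambda^2 - (k_{bd}+k_{db}+k_e)\lambda + k_{db} k_e = 0}.
#'
#' @param coeff_a Coefficient A on the fast exponent (same units as c0).
#' @param coeff_b Coefficient B on the slow exponent.
#' @param alpha Fast eigenvalue, day^-1.
#' @param beta Slow eigenvalue, day^-1; requires `alpha >= beta > 0`.
#' @return An object of class `macro_biexp_params`.
#' @export
macro_biexp_params <- function(coeff_a, coeff_b, alpha, beta) {
  if (beta <= 0 || alpha < beta)
    stop_decorpkin("eigenvalues must satisfy alpha >= beta > 0", "domain_error")
  structure(list(coeff_a = coeff_a, coeff_b = coeff_b,
                 alpha = alpha, beta = beta),
            class = "macro_biexp_params")
}

# Eigenvalues of the two-compartment rate matrix: roots of
# lambda^2 - s*lambda + p = 0 with s = k_bd+k_db+k_e, p = k_db*k_e.
# Returns c(alpha, beta) with alpha >= beta, plus the relative discriminant.
bicompartment_eigen <- function(params) {
  s <- params$k_bd + params$k_db + params$k_e
  p <- params$k_db * params$k_e
  disc <- s^2 - 4 * p
  rel_disc <- if (s > 0) disc / s^2 else 0
  disc <- max(disc, 0)
  root <- sqrt(disc)
  list(alpha = (s + root) / 2, beta = (s - root) / 2, rel_disc = rel_disc)
}

# relative-discriminant tolerance below which the eigenvalues are treated
# as repeated and the confluent closed form is used
.confluent_tol <- 1e-12

#' Evaluate the mono-exponential retention model
#'
#' @param params A [mono_exp_params()].
#' @param t Times in days (>= 0).
#' @return `r0 * exp(-k * t)`.
#' @export
mono_exp <- function(params, t) {
  if (any(t < 0)) stop_decorpkin("t must be non-negative", "domain_error")
  params$r0 * exp(-params$k * t)
}

#' Closed-form blood amount of the two-compartment model
#'
#' Evaluates \eqn{C_b(t) = C_0 (k_{db}-\beta)/(\alpha-\beta) e^{-\beta t} +
#' C_0 (k_{db}-\alpha)/(\beta-\alpha) e^{-\alpha t}}.  When the eigenvalues
#' coincide (relative discriminant below 1e-12) the confluent limit
#' \eqn{C_0 (1 + (k_{db}-\lambda) t) e^{-\lambda t}} is used.
#'
#' @param params A [bicompartment_params()].
#' @param t Times in days (>= 0).
#' @return Amount in blood at each `t`; `C_b(0) = c0`.
#' @export
bicompartment_blood <- function(params, t) {
  if (any(t < 0)) stop_decorpkin("t must be non-negative", "domain_error")
  eg <- bicompartment_eigen(params)
  if (eg$rel_disc < .confluent_tol) {
    lam <- (eg$alpha + eg$beta) / 2
    return(params$c0 * (1 + (params$k_db - lam) * t) * exp(-lam * t))
  }
  a <- eg$alpha; b <- eg$beta
  params$c0 * ((params$k_db - b) / (a - b) * exp(-b * t) +
               (params$k_db - a) / (b - a) * exp(-a * t))
}

#' Closed-form deep-compartment amount of the two-compartment model
#'
#' Evaluates \eqn{C_d(t) = C_0 k_{bd}/(\alpha-\beta) (e^{-\beta t} -
#' e^{-\alpha t})}, with the confluent limit \eqn{C_0 k_{bd} t e^{-\lambda t}}
#' for a repeated eigenvalue; \eqn{C_d(0) = 0}.
#'
#' @inheritParams bicompartment_blood
#' @return Amount in the deep compartment at each `t`.
#' @export
bicompartment_deep <- function(params, t) {
  if (any(t < 0)) stop_decorpkin("t must be non-negative", "domain_error")
  eg <- bicompartment_eigen(params)
  if (eg$rel_disc < .confluent_tol) {
    lam <- (eg$alpha + eg$beta) / 2
    return(params$c0 * params$k_bd * t * exp(-lam * t))
  }
  params$c0 * params$k_bd / (eg$alpha - eg$beta) *
    (exp(-eg$beta * t) - exp(-eg$alpha * t))
}

#' Whole-body (total) retention of the two-compartment model
#'
#' Whole-body counting measures blood and deep compartments together, so
#' the default observable for fitting is `C_b + C_d`.
#'
#' @inheritParams bicompartment_blood
#' @return `bicompartment_blood(params, t) + bicompartment_deep(params, t)`.
#' @export
bicompartment_total <- function(params, t) {
  bicompartment_blood(params, t) + bicompartment_deep(params, t)
}

#' Numeric integration of the two-compartment equations
#'
#' Solves the coupled linear system with `deSolve::lsoda` at tight
#' tolerances, tracking the cumulative eliminated amount
#' \eqn{k_e \int C_b\,dt} as a third state.  Serves as the independent
#' numeric oracle for the closed forms; mass balance
#' `blood + deep + eliminated = c0` holds along the trajectory.
#'
#' @param params A [bicompartment_params()].
#' @param t_grid Increasing times starting at 0.
#' @param rtol,atol Solver tolerances.
#' @return A data.frame with columns `time`, `blood`, `deep`, `eliminated`.
#' @export
integrate_ode <- function(params, t_grid, rtol = 1e-11, atol = 1e-11) {
  if (t_grid[1L] != 0 || any(diff(t_grid) <= 0))
    stop_decorpkin("t_grid must increase from 0", "domain_error")
  deriv <- function(t, y, p) {
    list(c(-(p$k_bd + p$k_e) * y[1L] + p$k_db * y[2L],
           p$k_bd * y[1L] - p$k_db * y[2L],
           p$k_e * y[1L]))
  }
  sol <- deSolve::lsoda(c(blood = params$c0, deep = 0, eliminated = 0),
                        t_grid, deriv, params, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0)
    stop_decorpkin("ODE solver failed to converge", "numeric_error")
  as.data.frame(sol)
}

#' Convert micro rate constants to macro biexponential parameters
#'
#' \eqn{\alpha,\beta} are the eigenvalues of the rate matrix (Vieta:
#' \eqn{\alpha+\beta = k_{bd}+k_{db}+k_e}, \eqn{\alpha\beta = k_{db} k_e});
#' \eqn{A = C_0(k_{db}-\alpha)/(\beta-\alpha)},
#' \eqn{B = C_0(k_{db}-\beta)/(\alpha-\beta)}, so that \eqn{A+B=C_0}.
#'
#' @param params A [bicompartment_params()] with distinct eigenvalues.
#' @return A [macro_biexp_params()].
#' @export
micro_to_macro <- function(params) {
  eg <- bicompartment_eigen(params)
  if (eg$rel_disc < .confluent_tol)
    stop_decorpkin(
      "repeated eigenvalues: no macro biexponential form, use the confluent closed form",
      "repeated_root_error")
  a <- eg$alpha; b <- eg$beta
  macro_biexp_params(
    coeff_a = params$c0 * (params$k_db - a) / (b - a),
    coeff_b = params$c0 * (params$k_db - b) / (a - b),
    alpha = a, beta = b)
}

#' Convert macro biexponential parameters to micro rate constants
#'
#' Inverts [micro_to_macro()]:
#' \eqn{k_{db} = (A\beta + B\alpha)/(A+B)}, \eqn{k_e = \alpha\beta/k_{db}},
#' \eqn{k_{bd} = \alpha+\beta-k_{db}-k_e}, \eqn{C_0 = A+B}.
#'
#' @param params A [macro_biexp_params()] with `coeff_a, coeff_b > 0` and
#'   `alpha > beta > 0`.
#' @return A [bicompartment_params()].
#' @export
macro_to_micro <- function(params) {
  A <- params$coeff_a; B <- params$coeff_b
  if (A <= 0 || B <= 0)
    stop_decorpkin("macro coefficients must be positive", "domain_error")
  if (params$alpha <= params$beta)
    stop_decorpkin("alpha must exceed beta", "domain_error")
  k_db <- (A * params$beta + B * params$alpha) / (A + B)
  k_e <- params$alpha * params$beta / k_db
  k_bd <- params$alpha + params$beta - k_db - k_e
  if (k_bd < -1e-12 * (params$alpha + params$beta))
    stop_decorpkin("macro set implies a negative k_bd: inconsistent macro set",
                   "inconsistent_macro_error")
  bicompartment_params(k_bd = max(k_bd, 0), k_db = k_db, k_e = k_e, c0 = A + B)
}

#' Evaluate the macro biexponential model
#'
#' @param params A [macro_biexp_params()].
#' @param t Times in days (>= 0).
#' @return `coeff_a * exp(-alpha*t) + coeff_b * exp(-beta*t)`.
#' @export
biexp_macro <- function(params, t) {
  if (any(t < 0)) stop_decorpkin("t must be non-negative", "domain_error")
  params$coeff_a * exp(-params$alpha * t) + params$coeff_b * exp(-params$beta * t)
}

#' Half-life of a first-order process
#'
#' @param k Positive first-order rate constant in day^-1.
#' @return `log(2) / k` in days.
#' @examples
#' half_life(0.19)   # elimination half-life ~3.6 days
#' @export
half_life <- function(k) {
  if (any(k <= 0)) stop_decorpkin("k must be positive", "domain_error")
  log(2) / k
}
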