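#' Semi-infinite-medium diffusion parameters
#'
#' Parameters of Fick diffusion from an "infinite" reservoir held at
#' constant concentration `c_d0` into a semi-infinite medium initially at
#' zero, across an interface of area `area`:
#' \deqn{\partial C/\partial t = D\, \partial^2 C/\partial x^2,\quad
#'       C(0,t)=C_{d0},\ C(x,0)=0,\ C(\infty,t)=0.}
#' Only the lumped combination \eqn{2 A C_{d0} \sqrt{D/\pi}} is
#' identifiable from retention data; the individual triple is used for the
#' mechanistic forward model and its oracle.
#'
#' @param d_coeff Diffusion coefficient D, length^2 day^-1 (> 0).
#' @param c_d0 Reservoir boundary concentration (> 0).
#' @param area Interface area A, length^2 (> 0).
#' @return An object of class `diffusion_params`.
#' @export
diffusion_params <- function(d_coeff, c_d0 = 1, area = 1) {
  if (any(c(d_coeff, c_d0, area) <= 0))
    stop_decorpkin("diffusion parameters must all be positive", "domain_error")
  structure(list(d_coeff = d_coeff, c_d0 = c_d0, area = area),
            class = "diffusion_params")
}

#' Empirical square-root retention law parameters
#'
#' The late-phase retention law `%R(t) = intercept - slope * sqrt(t)`.
#' The intercept is not constrained to 100 because the law applies to the
#' late window after the first-day drop.
#'
#' @param intercept Intercept a in percent.
#' @param slope Slope b in percent day^-1/2 (>= 0, so retention is
#'   non-increasing).
#' @return An object of class `sqrt_law_params`.
#' @export
sqrt_law_params <- function(intercept, slope) {
  if (slope < 0)
    stop_decorpkin("slope must be non-negative (retention non-increasing)",
                   "domain_error")
  structure(list(intercept = intercept, slope = slope),
            class = "sqrt_law_params")
}

erfc <- function(z) 2 * pnorm(-z * sqrt(2))

#' Concentration profile of the semi-infinite diffusion solution
#'
#' The similarity solution \eqn{C(x,t) = C_{d0}\,\mathrm{erfc}(x /
#' (2\sqrt{D t}))}, satisfying all three boundary/initial conditions.
#'
#' @param params A [diffusion_params()].
#' @param x Distances from the interface (>= 0).
#' @param t Time in days (> 0, scalar).
#' @return Concentrations at `x`.
#' @export
diffusion_profile <- function(params, x, t) {
  if (any(t <= 0)) stop_decorpkin("t must be positive", "domain_error")
  if (any(x < 0)) stop_decorpkin("x must be non-negative", "domain_error")
  params$c_d0 * erfc(x / (2 * sqrt(params$d_coeff * t)))
}

#' Diffusive flux across the interface
#'
#' \eqn{J(t) = -D\,\partial C/\partial x|_{x=0} = C_{d0}\sqrt{D/(\pi t)}}.
#'
#' @param params A [diffusion_params()].
#' @param t Times in days (> 0).
#' @return Flux at each `t` (concentration x length / day).
#' @export
boundary_flux <- function(params, t) {
  if (any(t <= 0)) stop_decorpkin("t must be positive", "domain_error")
  params$c_d0 * sqrt(params$d_coeff / (pi * t))
}

#' Cumulative amount transferred across the interface
#'
#' \eqn{Q(t) = A \int_0^t J\,dt = 2 A C_{d0} \sqrt{D t / \pi}} — the
#' square-root law: Q is proportional to the square root of time, so
#' quadrupling the time doubles the transferred amount.
#'
#' @param params A [diffusion_params()].
#' @param t Times in days (>= 0).
#' @return Transferred amount at each `t`.
#' @export
cumulative_transfer <- function(params, t) {
  if (any(t < 0)) stop_decorpkin("t must be non-negative", "domain_error")
  2 * params$area * params$c_d0 * sqrt(params$d_coeff * t / pi)
}

#' Evaluate the empirical square-root retention law
#'
#' `%R(t) = a - b * sqrt(t)`.  No clipping at zero is applied: the law's
#' validity window ends before the zero crossing, whose location
#' `t* = (a/b)^2` is reported as a diagnostic by the fitting layer.
#'
#' @param params A [sqrt_law_params()].
#' @param t Times in days (>= 0).
#' @return Percent retention at each `t`.
#' @export
sqrt_retention <- function(params, t) {
  if (any(t < 0)) stop_decorpkin("t must be non-negative", "domain_error")
  params$intercept - params$slope * sqrt(t)
}

# Thomas algorithm for a tridiagonal system with constant bands
# (lower, diag, upper are scalars; d is the RHS vector).
solve_tridiag_const <- function(lower, diag, upper, d) {
  n <- length(d)
  cp <- numeric(n); dp <- numeric(n)
  cp[1L] <- upper / diag
  dp[1L] <- d[1L] / diag
  for (i in 2:n) {
    m <- diag - lower * cp[i - 1L]
    cp[i] <- upper / m
    dp[i] <- (d[i] - lower * dp[i - 1L]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1L):1L) x[i] <- dp[i] - cp[i] * x[i + 1L]
  x
}

#' Finite-difference oracle for the semi-infinite diffusion problem
#'
#' Implicit (Crank-Nicolson with backward-Euler start-up ramp —
#' unconditionally stable) solution of the diffusion equation on a
#' truncated domain `[0, domain_length]` with Dirichlet conditions
#' `C(0) = c_d0`, `C(L) = 0`, on a uniform spatial grid.  Internal time
#' stepping is square-root graded (uniform in `sqrt(t)`) to resolve the
#' initial boundary-layer singularity; the cumulative transfer Q(t) is
#' obtained by trapezoidal integration of the one-sided (second-order)
#' boundary flux against `sqrt(t)`.
#'
#' This is an oracle for the closed forms ([diffusion_profile()],
#' [cumulative_transfer()]); its numerical choices favour accuracy, not
#' speed.
#'
#' @param params A [diffusion_params()].
#' @param domain_length Truncated domain length; should be at least
#'   `6 * sqrt(d_coeff * max(t_grid))`, otherwise a truncation warning is
#'   recorded in the result.
#' @param nx Number of spatial grid points (>= 100).
#' @param t_grid Increasing positive output times.
#' @param nt Number of internal time steps (default `4 * nx`).
#' @return A list with `x` (grid), `profiles` (matrix, one column per
#'   output time), `t_grid`, `q_numeric` (numeric Q at the output times)
#'   and `warnings` (character vector, possibly empty).
#' @export
pde_oracle <- function(params, domain_length, nx, t_grid, nt = 4L * nx) {
  if (nx < 100L) stop_decorpkin("nx must be at least 100", "domain_error")
  if (any(t_grid <= 0) || any(diff(t_grid) <= 0))
    stop_decorpkin("t_grid must be positive and increasing", "domain_error")
  warnings <- character()
  t_max <- max(t_grid)
  if (domain_length < 6 * sqrt(params$d_coeff * t_max))
    warnings <- c(warnings,
      "domain_length < 6*sqrt(D*t_max): truncation may contaminate the solution")

  h <- domain_length / (nx - 1L)
  x <- seq(0, domain_length, length.out = nx)
  D <- params$d_coeff; c0 <- params$c_d0; A <- params$area

  # internal step times uniform in sqrt(t), merged with requested outputs
  s_steps <- seq(0, sqrt(t_max), length.out = nt + 1L)
  t_steps <- sort(unique(c(s_steps^2, t_grid)))
  t_steps <- t_steps[t_steps > 0]

  u <- numeric(nx)           # interior + right boundary; C(0) fixed at c0
  u[1L] <- c0                # Dirichlet left boundary from t > 0
  flux_at <- function(u) -D * (-3 * u[1L] + 4 * u[2L] - u[3L]) / (2 * h)

  profiles <- matrix(NA_real_, nrow = nx, ncol = length(t_grid))
  n_steps <- length(t_steps)
  flux_t <- numeric(n_steps)
  t_prev <- 0
  n_ramp <- 8L  # backward-Euler start-up steps damp the discontinuous IC
  for (j in seq_len(n_steps)) {
    dt <- t_steps[j] - t_prev
    r <- D * dt / h^2
    theta <- if (j <= n_ramp) 1 else 0.5   # 1 = backward Euler, 0.5 = CN
    interior <- 2:(nx - 1L)
    # RHS: explicit part (1-theta) of the Laplacian plus boundary terms
    lap <- u[interior - 1L] - 2 * u[interior] + u[interior + 1L]
    rhs <- u[interior] + (1 - theta) * r * lap
    rhs[1L] <- rhs[1L] + theta * r * c0      # left Dirichlet contribution
    v <- solve_tridiag_const(-theta * r, 1 + 2 * theta * r, -theta * r, rhs)
    u[interior] <- v
    u[1L] <- c0; u[nx] <- 0
    flux_t[j] <- flux_at(u)
    out_idx <- which(t_grid == t_steps[j])
    if (length(out_idx)) profiles[, out_idx] <- u
    t_prev <- t_steps[j]
  }

  # Q(t) = A * int_0^t J dt; substitute s = sqrt(t) so the exact integrand
  # 2 s J(s^2) is constant and the trapezoid rule is essentially exact.
  s_all <- sqrt(t_steps)
  g <- 2 * s_all * flux_t
  q_cum <- c(0, cumsum(diff(s_all) * (head(g, -1L) + tail(g, -1L)) / 2))
  # the first panel [0, s_1] uses the analytic-limit value g(0+) ~ g(s_1)
  q_cum <- q_cum + s_all[1L] * g[1L]
  q_numeric <- A * approx(t_steps, q_cum, xout = t_grid)$y

  list(x = x, profiles = profiles, t_grid = t_grid,
       q_numeric = q_numeric, warnings = warnings)
}
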