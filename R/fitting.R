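# window extraction shared by the fitting operations
window_data <- function(series, window) {
  if (is.null(window)) window <- range(series$times)
  keep <- series$times >= window[1L] & series$times <= window[2L]
  list(t = series$times[keep], y = series$mean_retention[keep],
       sem = series$sem[keep], window = as.numeric(window))
}

#' Coefficient of determination
#'
#' `1 - SSE/SStot` with the total sum of squares taken about the observed
#' mean.  Negative values are allowed (a fit worse than the mean); the
#' value is undefined when the observations have zero variance.
#'
#' @param obs Observed values (length >= 2, not all identical).
#' @param pred Predicted values, same length.
#' @return R-squared (dimensionless, <= 1).
#' @export
r_squared <- function(obs, pred) {
  if (length(obs) != length(pred) || length(obs) < 2L)
    stop_decorpkin("obs and pred must have equal length >= 2", "validation_error")
  sstot <- sum((obs - mean(obs))^2)
  if (sstot == 0)
    stop_decorpkin("R-squared undefined: observations have zero variance",
                   "undefined_r2_error")
  1 - sum((obs - pred)^2) / sstot
}

# Curve stripping (method of residuals) on raw (t, y) vectors: the terminal
# tail gives the slow phase (beta, B); the log of the early residuals
# y - B*exp(-beta*t) gives the fast phase (alpha, A).
strip_initialize_xy <- function(t, y, tail_points = 4L) {
  n <- length(t)
  if (n < 4L)
    stop_decorpkin("curve stripping needs at least 4 points", "validation_error")
  if (any(y <= 0))
    stop_decorpkin("curve stripping needs positive observations", "data_error")
  tail_len <- max(3L, min(tail_points, n - 2L))
  tail_idx <- (n - tail_len + 1L):n
  f_tail <- lm(log(y[tail_idx]) ~ t[tail_idx])
  beta <- max(-unname(coef(f_tail)[2L]), 1e-8)
  B <- exp(unname(coef(f_tail)[1L]))
  early_idx <- setdiff(seq_len(n), tail_idx)
  resid <- y[early_idx] - B * exp(-beta * t[early_idx])
  # residuals indistinguishable from zero mean the data are mono-exponential
  pos <- resid > 1e-8 * max(y)
  method <- "stripped"
  if (sum(pos) >= 2L) {
    f_res <- lm(log(resid[pos]) ~ t[early_idx][pos])
    alpha <- -unname(coef(f_res)[2L])
    A <- exp(unname(coef(f_res)[1L]))
    if (!is.finite(alpha) || alpha <= beta) method <- "heuristic"
  } else method <- "heuristic"
  if (method == "heuristic") {
    alpha <- 5 * beta
    A <- max(y[1L] - B, 0.05 * B)
  }
  out <- macro_biexp_params(coeff_a = A, coeff_b = B, alpha = alpha, beta = beta)
  attr(out, "method") <- method
  out
}

#' Curve-stripping initialization for biexponential fits
#'
#' Method-of-residuals estimate of the macro biexponential parameters: the
#' slow phase (beta, B) from a log-linear fit of the last `tail_points`
#' observations, then the fast phase (alpha, A) from a log-linear fit of
#' the positive early residuals.  When the residuals cannot support a fit
#' (fewer than two positive, or an implied alpha <= beta) a documented
#' heuristic is used instead (`alpha = 5*beta`, `A = y(first) - B`) and the
#' returned object carries `attr(, "method") == "heuristic"`.
#'
#' @param series A [retention_series()].
#' @param window Fitting window `c(t_start, t_end)` (default full range).
#' @param tail_points Number of terminal points for the slow phase
#'   (default 4, never fewer than 3 nor more than n-2).
#' @return A [macro_biexp_params()] with an attribute `method`.
#' @export
strip_initialize <- function(series, window = NULL, tail_points = 4L) {
  d <- window_data(series, window)
  strip_initialize_xy(d$t, d$y, tail_points = tail_points)
}

#' Fit a registered kinetic model to a retention series
#'
#' Least-squares fit of any registered model (see [list_models()]) on a
#' time window.  Models that are linear after transformation (`sqrtlaw`,
#' `diffusion`) are solved exactly by ordinary least squares; nonlinear
#' models use Levenberg-Marquardt with box constraints
#' (`minpack.lm::nls.lm`, rates bounded below by zero) and multi-start:
#' the curve-stripping (or log-linear) initializer plus `n_starts - 1`
#' multiplicatively jittered restarts, seed-controlled, keeping the best
#' sum of squares.
#'
#' @param model_id Registered model identifier.
#' @param series A [retention_series()].
#' @param window Fitting window `c(t_start, t_end)` in days (default: all
#'   observed times).
#' @param init Optional initial parameter object or named vector.
#' @param weights `"none"` (default; group means are fitted unweighted) or
#'   `"inverse-sem"` (weights 1/SEM^2, with zero SEMs replaced by the
#'   smallest positive SEM in the window).
#' @param n_starts Number of multi-start initializations (default 5).
#' @param seed Seed for the jittered restarts.
#' @param observable For `bicompartment` only: `"total"` (default,
#'   whole-body `C_b + C_d` — what whole-body counting measures) or
#'   `"blood"` (`C_b` alone).
#' @param max_iter,ftol Optimizer control.
#' @return A `fit_result` list: `model_id`, `params` (parameter object),
#'   `window`, `r2`, `sse`, `residuals`, `fitted`, `data`, `converged`,
#'   `message`, `n_starts_used`, and `derived` (half-lives
#'   `t_half_e = ln2/k_e` where defined, `t_half_terminal = ln2/terminal
#'   rate`, and the square-root law zero-crossing `t_star = (a/b)^2`).
#' @export
fit_model <- function(model_id, series, window = NULL, init = NULL,
                      weights = c("none", "inverse-sem"),
                      n_starts = 5L, seed = 1L,
                      observable = c("total", "blood"),
                      max_iter = 500L, ftol = 1e-13) {
  weights <- match.arg(weights)
  observable <- match.arg(observable)
  m <- get_model(model_id)
  d <- window_data(series, window)
  if (length(d$t) < m$n_params + 1L)
    stop_decorpkin(sprintf(
      "window holds %d points but model '%s' needs at least %d",
      length(d$t), model_id, m$n_params + 1L), "design_error")

  w <- rep.int(1, length(d$t))
  if (weights == "inverse-sem") {
    sem <- d$sem
    if (any(sem > 0)) sem[sem == 0] <- min(sem[sem > 0]) else sem[] <- 1
    w <- 1 / sem^2
  }
  predict_fun <- if (model_id == "bicompartment" && observable == "blood")
    m$predict_blood else m$predict

  if (isTRUE(m$linear)) {
    v0 <- m$init(d$t, d$y)   # exact OLS solution for the transformed model
    # weighted refinement for the linear-in-sqrt(t) models
    f <- lm(d$y ~ sqrt(d$t), weights = w)
    v0[1L] <- unname(coef(f)[1L]); v0[2L] <- max(-unname(coef(f)[2L]), 0)
    params <- m$from_vector(v0)
    fitted <- predict_fun(params, d$t)
    best <- list(par = v0, fvec = d$y - fitted, converged = TRUE,
                 message = "exact OLS solution", n_used = 1L)
  } else {
    v0 <- if (is.null(init)) m$init(d$t, d$y)
          else if (is.numeric(init)) init else m$to_vector(init)
    lower <- m$lower
    v0 <- pmax(v0, lower + 1e-12)
    resid_fun <- function(v) {
      p <- m$from_vector(pmax(v, lower))
      sqrt(w) * (d$y - predict_fun(p, d$t))
    }
    starts <- list(v0)
    if (n_starts > 1L) {
      jit <- with_local_seed(seed, replicate(n_starts - 1L,
        v0 * exp(rnorm(length(v0), sd = 0.2)), simplify = FALSE))
      starts <- c(starts, jit)
    }
    best <- NULL
    for (s in starts) {
      res <- tryCatch(
        minpack.lm::nls.lm(par = pmax(s, lower + 1e-12), lower = lower,
                           fn = resid_fun,
                           control = minpack.lm::nls.lm.control(
                             maxiter = max_iter, ftol = ftol, ptol = 1e-13)),
        error = function(e) NULL)
      if (is.null(res)) next
      sse_s <- sum(res$fvec^2)
      if (is.null(best) || sse_s < best$sse_w) {
        best <- list(par = res$par, fvec = res$fvec, sse_w = sse_s,
                     converged = res$info %in% 1:4, message = res$message,
                     n_used = length(starts))
      }
    }
    if (is.null(best))
      stop_decorpkin(sprintf("all %d starts failed for model '%s'",
                             length(starts), model_id), "convergence_error")
    params <- m$from_vector(pmax(best$par, m$lower))
  }

  fitted <- predict_fun(params, d$t)
  residuals <- d$y - fitted
  sse <- sum(residuals^2)
  r2 <- tryCatch(r_squared(d$y, fitted), error = function(e) NA_real_)

  derived <- list()
  if (!is.null(params$k_e) && params$k_e > 0)
    derived$t_half_e <- half_life(params$k_e)
  term_rate <- switch(model_id,
    monoexp = params$k,
    biexp_macro = params$beta,
    bicompartment = bicompartment_eigen(params)$beta,
    NULL)
  if (!is.null(term_rate) && term_rate > 0)
    derived$t_half_terminal <- half_life(term_rate)
  if (model_id == "sqrtlaw" && params$slope > 0)
    derived$t_star <- (params$intercept / params$slope)^2
  if (model_id == "diffusion" && params$lumped_slope > 0)
    derived$t_star <- (params$r0 / params$lumped_slope)^2

  structure(list(model_id = model_id, params = params, window = d$window,
                 r2 = r2, sse = sse, residuals = residuals, fitted = fitted,
                 data = data.frame(time = d$t, observed = d$y, weight = w),
                 converged = best$converged, message = best$message,
                 n_starts_used = best$n_used, observable = observable,
                 derived = derived),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  pv <- unlist(x$params[vapply(x$params, is.numeric, logical(1L))])
  cat(sprintf("<fit_result> model '%s' on window [%g, %g] days\n",
              x$model_id, x$window[1L], x$window[2L]))
  cat("  parameters:", paste(sprintf("%s = %.5g", names(pv), pv), collapse = ", "), "\n")
  cat(sprintf("  R^2 = %.5f, SSE = %.5g, converged: %s\n", x$r2, x$sse, x$converged))
  if (length(x$derived))
    cat("  derived:", paste(sprintf("%s = %.4g", names(x$derived),
                                    unlist(x$derived)), collapse = ", "), "\n")
  invisible(x)
}

phase_fit <- function(t, logy) {
  f <- lm(logy ~ t)
  pred <- unname(predict(f))
  r2 <- if (length(logy) > 2L && sum((logy - mean(logy))^2) > 0)
    r_squared(logy, pred) else if (all(abs(logy - pred) < 1e-12)) 1 else NA_real_
  list(slope = unname(coef(f)[2L]), intercept = unname(coef(f)[1L]),
       r2 = r2, sse = sum((logy - pred)^2), n = length(t))
}

#' Two-phase segmented log-linear regression
#'
#' Fits two independent ordinary-least-squares lines to the natural log of
#' mean retention, one on each side of a breakpoint.  Candidate breakpoints
#' are the midpoints between consecutive sampling times (exhaustive search
#' — at the daily sampling density this is a handful of candidates, so no
#' continuous optimization is needed); the breakpoint minimizing the pooled
#' SSE wins, earliest candidate on ties.  The segments are not constrained
#' to meet at the breakpoint.
#'
#' @param series A [retention_series()].
#' @param window Analysis window (default full range).
#' @param min_points_per_phase Minimum points per segment (>= 2, default 2).
#' @return A `segmented_fit` list: `breakpoint`, `phase1`, `phase2` (each
#'   with `slope` (day^-1, of log retention), `intercept`, `r2`, `n`),
#'   `pooled_sse`, and the searched `candidates` with their SSEs.
#' @export
fit_two_phase <- function(series, window = NULL, min_points_per_phase = 2L) {
  if (min_points_per_phase < 2L)
    stop_decorpkin("min_points_per_phase must be at least 2", "validation_error")
  d <- window_data(series, window)
  n <- length(d$t)
  if (n < 2L * min_points_per_phase)
    stop_decorpkin(sprintf(
      "window holds %d points; two phases need at least %d", n,
      2L * min_points_per_phase), "design_error")
  if (any(d$y <= 0))
    stop_decorpkin(sprintf(
      "log transform undefined: non-positive retention at day %g",
      d$t[which(d$y <= 0)[1L]]), "data_error")
  logy <- log(d$y)
  cand_idx <- min_points_per_phase:(n - min_points_per_phase)  # last index of phase 1
  candidates <- (d$t[cand_idx] + d$t[cand_idx + 1L]) / 2
  sse <- vapply(cand_idx, function(i) {
    phase_fit(d$t[1:i], logy[1:i])$sse +
      phase_fit(d$t[(i + 1L):n], logy[(i + 1L):n])$sse
  }, numeric(1L))
  # earliest candidate within round-off of the minimum (flat-SSE tie-break)
  best <- which(sse <= min(sse) * (1 + 1e-9) + 1e-12)[1L]
  i <- cand_idx[best]
  structure(list(
    breakpoint = candidates[best],
    phase1 = phase_fit(d$t[1:i], logy[1:i]),
    phase2 = phase_fit(d$t[(i + 1L):n], logy[(i + 1L):n]),
    pooled_sse = sse[best],
    candidates = data.frame(breakpoint = candidates, pooled_sse = sse),
    window = d$window),
    class = "segmented_fit")
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat(sprintf("<segmented_fit> breakpoint at day %g (window [%g, %g])\n",
              x$breakpoint, x$window[1L], x$window[2L]))
  for (ph in c("phase1", "phase2"))
    cat(sprintf("  %s: slope %.5g /day, intercept %.5g, R^2 %.4f (n = %d)\n",
                ph, x[[ph]]$slope, x[[ph]]$intercept, x[[ph]]$r2, x[[ph]]$n))
  invisible(x)
}

#' Compare registered models on a common window
#'
#' Fits every requested model on the identical window and weights and
#' ranks them by R-squared (descending), breaking ties in favour of fewer
#' parameters.  Individual fit failures yield a partial comparison with
#' the failures listed.
#'
#' @param series A [retention_series()].
#' @param model_ids Character vector of registered model ids.
#' @param window Common fitting window.
#' @param weights,seed Passed to [fit_model()].
#' @return A `model_comparison` list: `entries` (data.frame with model_id,
#'   r2, sse, n_params, converged), `ranking` (model ids best first),
#'   `fits` (named list of `fit_result`s), `failures` (named character).
#' @export
compare_models <- function(series, model_ids, window = NULL,
                           weights = "none", seed = 1L) {
  fits <- list(); failures <- character()
  for (id in model_ids) {
    f <- tryCatch(fit_model(id, series, window = window, weights = weights,
                            seed = seed),
                  error = function(e) conditionMessage(e))
    if (inherits(f, "fit_result")) fits[[id]] <- f else failures[id] <- f
  }
  if (!length(fits))
    stop_decorpkin("every requested model failed to fit", "convergence_error")
  entries <- data.frame(
    model_id = names(fits),
    r2 = vapply(fits, `[[`, numeric(1L), "r2"),
    sse = vapply(fits, `[[`, numeric(1L), "sse"),
    n_params = vapply(names(fits), function(id) get_model(id)$n_params, integer(1L)),
    converged = vapply(fits, `[[`, logical(1L), "converged"),
    row.names = NULL)
  ord <- order(-entries$r2, entries$n_params)
  structure(list(entries = entries[ord, , drop = FALSE],
                 ranking = entries$model_id[ord],
                 fits = fits, failures = failures,
                 window = if (is.null(window)) range(series$times) else window),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> window [%g, %g] days\n",
              x$window[1L], x$window[2L]))
  print(x$entries, row.names = FALSE)
  if (length(x$failures))
    cat("  failed:", paste(names(x$failures), collapse = ", "), "\n")
  invisible(x)
}
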