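# Model registry: every fittable model exposes the same surface —
# predict(params, t), a flat parameter vector representation with bounds,
# and an initializer from data. Used by fit_model()/compare_models().

.registry <- new.env(parent = emptyenv())

register_model <- function(id, entry) assign(id, entry, envir = .registry)

#' List registered kinetic model identifiers
#'
#' @return Character vector of model ids usable in [fit_model()] and
#'   [compare_models()]: `monoexp`, `biexp_macro`, `bicompartment`,
#'   `sqrtlaw`, `diffusion`.
#' @export
list_models <- function() sort(ls(.registry))

get_model <- function(id) {
  if (!exists(id, envir = .registry, inherits = FALSE))
    stop_decorpkin(sprintf("unknown model id '%s' (known: %s)", id,
                           paste(list_models(), collapse = ", ")),
                   "config_error")
  get(id, envir = .registry, inherits = FALSE)
}

#' Predict retention from a registry model
#'
#' @param model_id Registered model identifier (see [list_models()]).
#' @param params The model's parameter object or named vector.
#' @param t Times in days.
#' @return Predicted retention values.
#' @export
predict_model <- function(model_id, params, t) {
  m <- get_model(model_id)
  if (is.numeric(params)) params <- m$from_vector(params)
  m$predict(params, t)
}

# log-linear OLS on a window of (t, y>0); returns c(level, rate)
loglinear_init <- function(t, y) {
  keep <- y > 0
  f <- lm(log(y[keep]) ~ t[keep])
  c(level = exp(unname(coef(f)[1L])), rate = max(-unname(coef(f)[2L]), 1e-6))
}

local({
  register_model("monoexp", list(
    n_params = 2L,
    par_names = c("r0", "k"),
    lower = c(1e-9, 0),
    predict = function(p, t) mono_exp(p, t),
    to_vector = function(p) c(r0 = p$r0, k = p$k),
    from_vector = function(v) mono_exp_params(v[[1L]], v[[2L]]),
    init = function(t, y) {
      ll <- loglinear_init(t, y)
      c(r0 = ll[["level"]], k = ll[["rate"]])
    }))

  register_model("biexp_macro", list(
    n_params = 4L,
    par_names = c("coeff_a", "coeff_b", "alpha", "beta"),
    lower = c(1e-9, 1e-9, 1e-9, 1e-9),
    predict = function(p, t) biexp_macro(p, t),
    to_vector = function(p) c(coeff_a = p$coeff_a, coeff_b = p$coeff_b,
                              alpha = p$alpha, beta = p$beta),
    from_vector = function(v) {
      # keep alpha >= beta by relabelling the two exponential branches
      if (v[[4L]] > v[[3L]]) v <- v[c(2L, 1L, 4L, 3L)]
      macro_biexp_params(v[[1L]], v[[2L]], v[[3L]], v[[4L]])
    },
    init = function(t, y) {
      p <- strip_initialize_xy(t, y)
      c(coeff_a = p$coeff_a, coeff_b = p$coeff_b, alpha = p$alpha, beta = p$beta)
    }))

  register_model("bicompartment", list(
    n_params = 4L,
    par_names = c("k_bd", "k_db", "k_e", "c0"),
    lower = c(0, 1e-9, 1e-9, 1e-9),
    predict = function(p, t) bicompartment_total(p, t),
    predict_blood = function(p, t) bicompartment_blood(p, t),
    to_vector = function(p) c(k_bd = p$k_bd, k_db = p$k_db, k_e = p$k_e, c0 = p$c0),
    from_vector = function(v) bicompartment_params(v[[1L]], v[[2L]], v[[3L]], v[[4L]]),
    init = function(t, y) {
      macro <- strip_initialize_xy(t, y)
      micro <- tryCatch(macro_to_micro(macro), error = function(e) NULL)
      if (is.null(micro)) {
        ll <- loglinear_init(t, y)
        micro <- bicompartment_params(k_bd = ll[["rate"]], k_db = macro$beta,
                                      k_e = ll[["rate"]], c0 = ll[["level"]])
      }
      c(k_bd = micro$k_bd, k_db = micro$k_db, k_e = micro$k_e, c0 = micro$c0)
    }))

  register_model("sqrtlaw", list(
    n_params = 2L,
    par_names = c("intercept", "slope"),
    lower = c(-Inf, 0),
    linear = TRUE,  # exactly solvable by OLS in sqrt(t)
    predict = function(p, t) sqrt_retention(p, t),
    to_vector = function(p) c(intercept = p$intercept, slope = p$slope),
    from_vector = function(v) sqrt_law_params(v[[1L]], v[[2L]]),
    init = function(t, y) {
      f <- lm(y ~ sqrt(t))
      c(intercept = unname(coef(f)[1L]), slope = max(-unname(coef(f)[2L]), 0))
    }))

  # mechanistic Q(t) retention: %R(t) = r0 - m*sqrt(t) with m the lumped
  # slope 2*A*C_d0*sqrt(D/pi)/(initial deep amount)*100; only the lumped
  # slope is identifiable so the fit surface matches sqrtlaw with the
  # mechanistic naming.
  register_model("diffusion", list(
    n_params = 2L,
    par_names = c("r0", "lumped_slope"),
    lower = c(-Inf, 0),
    linear = TRUE,
    predict = function(p, t) p$r0 - p$lumped_slope * sqrt(t),
    to_vector = function(p) c(r0 = p$r0, lumped_slope = p$lumped_slope),
    from_vector = function(v) structure(list(r0 = v[[1L]], lumped_slope = v[[2L]]),
                                        class = "diffusion_lumped_params"),
    init = function(t, y) {
      f <- lm(y ~ sqrt(t))
      c(r0 = unname(coef(f)[1L]), lumped_slope = max(-unname(coef(f)[2L]), 0))
    }))
})
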