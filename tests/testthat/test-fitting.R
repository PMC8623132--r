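test_that("r_squared follows the 1 - SSE/SStot definition", {
  obs <- c(1, 3, 2, 5)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, rep(mean(obs), 4)), 0)
  expect_lt(r_squared(obs, c(5, 1, 4, 0)), 0)   # worse than the mean
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), class = "undefined_r2_error")
  # invariant under a common affine map of obs and pred
  pred <- c(1.2, 2.9, 2.2, 4.6)
  expect_equal(r_squared(obs, pred), r_squared(10 * obs - 3, 10 * pred - 3))
})

test_that("zero-noise fits recover the generating parameters for every model", {
  tt <- 0:10
  # monoexp
  s <- series_from_model(function(t) mono_exp(mono_exp_params(100, 0.3), t), tt)
  f <- fit_model("monoexp", s)
  expect_equal(f$params$k, 0.3, tolerance = 1e-6)
  expect_equal(f$r2, 1, tolerance = 1e-10)

  # biexp_macro
  mac <- micro_to_macro(treated_rates())
  sb <- series_from_model(function(t) biexp_macro(mac, t), tt)
  fb <- fit_model("biexp_macro", sb)
  expect_equal(unlist(fb$params), unlist(mac), tolerance = 1e-4)

  # bicompartment (total observable, its registry default)
  p <- treated_rates()
  st <- series_from_model(function(t) bicompartment_total(p, t), tt)
  ft <- fit_model("bicompartment", st)
  expect_equal(unlist(ft$params), unlist(p), tolerance = 1e-3)

  # bicompartment on the blood observable
  sblood <- series_from_model(function(t) bicompartment_blood(p, t), tt)
  fblood <- fit_model("bicompartment", sblood, observable = "blood")
  expect_equal(unlist(fblood$params), unlist(p), tolerance = 1e-4)
  expect_equal(fblood$derived$t_half_e, log(2) / 0.19, tolerance = 1e-4)

  # sqrtlaw (exact OLS)
  sq <- sqrt_law_params(156, 19.4)
  ss <- retention_series("g", 13:23, sqrt_retention(sq, 13:23),
                         rep(0, 11), 7, ref_time = 12)
  fs <- fit_model("sqrtlaw", ss, window = c(16, 23))
  expect_equal(fs$params$intercept, 156, tolerance = 1e-10)
  expect_equal(fs$params$slope, 19.4, tolerance = 1e-10)
  expect_equal(fs$derived$t_star, (156 / 19.4)^2, tolerance = 1e-8)
})

test_that("fit_model enforces its design preconditions", {
  s <- series_from_model(function(t) mono_exp(mono_exp_params(100, 0.2), t), 0:2)
  expect_error(fit_model("bicompartment", s), class = "design_error")
  expect_error(fit_model("nosuchmodel", s), class = "config_error")
})

test_that("weighted and unweighted fits coincide under equal SEMs", {
  tt <- 0:8
  p <- treated_rates()
  y <- bicompartment_blood(p, tt)
  s <- retention_series("g", tt, y, sem = c(0, rep(2.5, 8)), n = 7, ref_time = 0)
  f0 <- fit_model("monoexp", s, window = c(1, 8), weights = "none")
  f1 <- fit_model("monoexp", s, window = c(1, 8), weights = "inverse-sem")
  expect_equal(unlist(f0$params), unlist(f1$params), tolerance = 1e-6)
})

test_that("curve stripping recovers exact biexponential macro parameters", {
  mac <- macro_biexp_params(60, 40, 2.5, 0.12)
  tt <- 0:10
  s <- retention_series("g", tt, biexp_macro(mac, tt) , rep(0, 11), 7, 0)
  init <- strip_initialize(s, tail_points = 4L)
  expect_equal(init$beta, mac$beta, tolerance = 0.01)
  expect_equal(init$coeff_b, mac$coeff_b, tolerance = 0.02)
  expect_equal(init$alpha, mac$alpha, tolerance = 0.05)
  expect_identical(attr(init, "method"), "stripped")

  # mono-exponential input degenerates to the heuristic branch
  sm <- series_from_model(function(t) mono_exp(mono_exp_params(100, 0.3), t), tt)
  init_m <- strip_initialize(sm)
  expect_identical(attr(init_m, "method"), "heuristic")

  s3 <- series_from_model(function(t) mono_exp(mono_exp_params(100, 0.3), t), 0:2)
  expect_error(strip_initialize(s3), class = "validation_error")
})

test_that("two-phase regression finds a constructed breakpoint and exact slopes", {
  tt <- 1:10
  brk <- 2.5
  y <- ifelse(tt <= brk, 100 * exp(-0.8 * (tt - 1)),
              100 * exp(-0.8 * (brk - 1)) * exp(-0.1 * (tt - brk)))
  s <- retention_series("g", tt, y, rep(0, 10), 7, 1)
  fit <- fit_two_phase(s)
  expect_gt(fit$breakpoint, 2)
  expect_lt(fit$breakpoint, 3)
  expect_equal(fit$phase1$slope, -0.8, tolerance = 1e-6)
  expect_equal(fit$phase2$slope, -0.1, tolerance = 1e-6)
  expect_lt(fit$pooled_sse, 1e-20)
})

test_that("two-phase regression on single-slope data ties and picks the earliest break", {
  tt <- 0:9
  s <- series_from_model(function(t) mono_exp(mono_exp_params(100, 0.25), t), tt)
  fit <- fit_two_phase(s)
  expect_equal(fit$phase1$slope, fit$phase2$slope, tolerance = 1e-8)
  expect_equal(fit$breakpoint, min(fit$candidates$breakpoint))
  # adding a breakpoint never hurts: pooled SSE <= single-line SSE
  single <- lm(log(s$mean_retention) ~ s$times)
  expect_lte(fit$pooled_sse, sum(residuals(single)^2) + 1e-12)
})

test_that("two-phase regression recovers a late break in a delayed design", {
  tt <- 13:23
  brk <- 17
  y <- ifelse(tt <= brk, 100 * exp(-0.35 * (tt - 13)),
              100 * exp(-0.35 * (brk - 13)) * exp(-0.05 * (tt - brk)))
  y <- 100 * y / y[1L]
  s <- retention_series("g", tt, y, rep(0, 11), 7, 13)
  fit <- fit_two_phase(s)
  expect_gt(fit$breakpoint, 16)
  expect_lt(fit$breakpoint, 18)
  expect_error(fit_two_phase(s, min_points_per_phase = 1L),
               class = "validation_error")
})

test_that("two-phase regression rejects non-positive retention with the offending day", {
  s <- retention_series("g", 0:4, c(100, 50, 20, -5, 2) + c(0, 0, 0, 0, 0),
                        rep(0, 5), 7, 0)
  expect_error(fit_two_phase(s), "day 3", class = "data_error")
})

test_that("model comparison ranks by R2 with parameter-count tie-breaks", {
  tt <- 0:10
  s <- series_from_model(function(t) mono_exp(mono_exp_params(100, 0.3), t), tt)
  cmp <- compare_models(s, c("monoexp", "sqrtlaw"), window = c(0, 10))
  expect_equal(cmp$ranking[1L], "monoexp")
  expect_equal(cmp$fits$monoexp$r2, 1, tolerance = 1e-12)

  one <- compare_models(s, "monoexp")
  expect_length(one$ranking, 1L)

  # a model that cannot fit the window yields a partial comparison
  s5 <- series_from_model(function(t) mono_exp(mono_exp_params(100, 0.3), t), 0:3)
  cmp2 <- compare_models(s5, c("monoexp", "bicompartment"))
  expect_true("bicompartment" %in% names(cmp2$failures))
  expect_equal(cmp2$ranking, "monoexp")
})

test_that("sqrt-law truth beats monoexp in the model contest under group noise", {
  # late-window shape of a treated arm: ~32% at day 2 down to ~10% at day 10
  sq <- sqrt_law_params(50, 12.6)
  tt <- 2:10
  wins <- 0L
  reps <- 60L
  for (r in seq_len(reps)) {
    pct <- with_seed_local(1000 + r,
      sapply(1:7, function(i)
        sqrt_retention(sq, tt) * exp(rnorm(length(tt), 0, 0.02))))
    s <- retention_series("g", tt, rowMeans(pct), apply(pct, 1L, sd) / sqrt(7),
                          7, ref_time = 0)
    cmp <- compare_models(s, c("sqrtlaw", "monoexp"), seed = r)
    if (cmp$ranking[1L] == "sqrtlaw") wins <- wins + 1L
  }
  expect_gte(wins / reps, 0.95)
})
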