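test_that("built-in designs encode the three experiment settings", {
  d <- study_designs()
  expect_setequal(names(d),
    c("exp1_control", "exp1_low", "exp2_control", "exp2_high",
      "exp2_high_repeat", "exp3_control", "exp3_delayed"))
  expect_true(all(vapply(d, `[[`, integer(1L), "n_rats") == 7L))
  expect_true(all(vapply(d, `[[`, numeric(1L), "initial_activity") == 0.037))
  expect_equal(d$exp1_low$dose_mg, 3.32)
  expect_equal(d$exp2_high_repeat$dosing_days, c(-0.021, 1))
  expect_equal(d$exp3_delayed$dosing_days, 12:16)
  expect_true(all(13:23 %in% d$exp3_delayed$measurement_days))
  expect_equal(d$exp3_delayed$ref_time, 12)
})

test_that("default truths use the printed rate sets with positive rates", {
  tr <- default_truth("exp2_high")
  expect_equal(tr$base_params$k_bd, 1.77)
  expect_equal(tr$base_params$k_db, 1.21)
  expect_equal(tr$base_params$k_e, 0.19)
  ctrl <- default_truth("exp2_control")
  expect_equal(ctrl$base_params$k_bd, 0.14)
  expect_equal(ctrl$base_params$k_db, 0.09)
  # early observed half-life calibration: k_bd + k_e = ln2 / 2.8
  expect_equal(ctrl$base_params$k_bd + ctrl$base_params$k_e, log(2) / 2.8)
  for (arm in names(study_designs())) {
    p <- default_truth(arm)$base_params
    expect_true(all(unlist(p[c("k_bd", "k_db", "k_e")]) > 0))
  }
  expect_error(default_truth("exp99"), class = "config_error")
})

test_that("noise-free simulation reproduces the model curve exactly and is seeded", {
  d <- experiment_design("mono", 0, numeric(), 0:6)
  tr <- truth_model(mono_exp_params(100, 0.1), noise_sigma = 0)
  r <- simulate_rat(d, tr, 1)
  expect_equal(r$activity, 0.037 * exp(-0.1 * (0:6)), tolerance = 1e-12)

  tr2 <- truth_model(treated_rates(), observable = "blood",
                     noise_sigma = 0.03, seed = 9L)
  a <- simulate_rat(study_designs()$exp2_high, tr2, 3)
  b <- simulate_rat(study_designs()$exp2_high, tr2, 3)
  expect_identical(a$activity, b$activity)
  c <- simulate_rat(study_designs()$exp2_high, tr2, 4)
  expect_false(identical(a$activity, c$activity))
})

test_that("simulated groups write byte-identical CSVs under a fixed seed", {
  d <- study_designs()$exp1_low
  tr <- default_truth("exp1_low", seed = 5L)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_retention_table(simulate_group(d, tr)$rats, f1)
  write_retention_table(simulate_group(d, tr)$rats, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("group SEM is zero without noise and matches theory with noise", {
  d <- study_designs()$exp2_high
  g0 <- simulate_group(d, default_truth("exp2_high", noise_sigma = 0))
  expect_true(all(g0$series$sem == 0))

  one <- experiment_design("solo", 0, numeric(), 0:5, n_rats = 1L)
  g1 <- simulate_group(one, truth_model(mono_exp_params(100, 0.2),
                                        noise_sigma = 0.05, seed = 2L))
  expect_true(all(g1$series$sem == 0))

  # empirical SEM at day 5 across replicates vs the log-normal theory
  sigma <- 0.02
  sems <- vapply(1:150, function(r) {
    g <- simulate_group(d, default_truth("exp2_high", noise_sigma = sigma,
                                         seed = 10000L + r))
    g$series$sem[g$series$times == 5]
  }, numeric(1L))
  ret5 <- bicompartment_blood(treated_rates(), 5)
  theory <- ret5 * sqrt(2) * sigma / sqrt(7)
  expect_lt(abs(mean(sems) - theory) / theory, 0.10)
})

test_that("treatment windows accelerate elimination in the delayed design", {
  d <- study_designs()$exp3_delayed
  ctrl_d <- study_designs()$exp3_control
  drops <- vapply(1:50, function(r) {
    trt <- simulate_group(d, default_truth("exp3_delayed", seed = 300L + r))
    ctl <- simulate_group(ctrl_d, default_truth("exp3_control", seed = 300L + r))
    trt$series$mean_retention[2L] - ctl$series$mean_retention[2L]
  }, numeric(1L))
  expect_true(all(drops < 0))  # treated day-13 retention always below control
  # noise-free first treatment day cuts whole-body retention below half
  g <- simulate_group(d, default_truth("exp3_delayed", noise_sigma = 0))
  expect_lt(g$series$mean_retention[2L], 50)
})

test_that("rapid-arm simulations show the biphasic shape of a treated group", {
  g <- simulate_group(study_designs()$exp2_high,
                      default_truth("exp2_high", noise_sigma = 0))
  s <- g$series
  # sharp first-day drop, then slow decline
  expect_lt(s$mean_retention[s$times == 1], 45)
  late_slope <- diff(log(s$mean_retention[s$times >= 5])) / diff(s$times[s$times >= 5])
  expect_true(all(late_slope > -0.12))
  # control early half-life near the 2.8-day calibration (simulate then refit)
  gc <- simulate_group(study_designs()$exp2_control,
                       default_truth("exp2_control", noise_sigma = 0))
  f <- fit_model("monoexp", gc$series, window = c(0, 2))
  expect_lt(abs(half_life(f$params$k) - 2.8) / 2.8, 0.15)
})

test_that("square-root truth refits exactly at zero noise", {
  sq <- sqrt_law_params(156, 19.4)
  d <- experiment_design("delayed_sqrt", 5, 12:16, 12:23, ref_time = 12)
  tr <- truth_model(sq, noise_sigma = 0)
  g <- simulate_group(d, tr)
  # normalization at day 12 rescales both coefficients by 100 / %R(12)
  scale <- 100 / sqrt_retention(sq, 12)
  f <- fit_model("sqrtlaw", g$series, window = c(16, 23))
  expect_equal(f$params$intercept, 156 * scale, tolerance = 0.05)
  expect_equal(f$params$slope, 19.4 * scale, tolerance = 0.05)
})
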