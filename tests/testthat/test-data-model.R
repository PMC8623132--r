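test_that("per-rat CSV round-trips through read/write and preserves order", {
  path <- tmp_csv(c("group,rat_id,time_day,activity",
                    "ctrl,r1,0,500", "ctrl,r1,1,400", "ctrl,r1,2,320"))
  rats <- read_retention_table(path, "per_rat")
  expect_length(rats, 1L)
  expect_s3_class(rats[[1L]], "rat_series")
  expect_equal(rats[[1L]]$times, c(0, 1, 2))
  expect_equal(rats[[1L]]$activity, c(500, 400, 320))

  out <- tempfile(fileext = ".csv")
  write_retention_table(rats, out)
  again <- read_retention_table(out, "per_rat")
  expect_equal(again[[1L]]$activity, rats[[1L]]$activity)
  expect_equal(again[[1L]]$times, rats[[1L]]$times)
})

test_that("group-level CSV parses with ref_time at the 100% point", {
  path <- tmp_csv(c("group,time_day,mean_retention_pct,sem_pct,n",
                    "a,0,100,0,7", "a,1,80,2,7", "a,2,65,1.5,7"))
  gs <- read_retention_table(path, "group_level")
  expect_equal(gs[["a"]]$ref_time, 0)
  expect_equal(gs[["a"]]$mean_retention, c(100, 80, 65))
})

test_that("malformed tables fail with informative schema/parse/validation errors", {
  missing_col <- tmp_csv(c("group,rat_id,time_day", "a,r1,0"))
  expect_error(read_retention_table(missing_col, "per_rat"),
               class = "schema_error")
  bad_cell <- tmp_csv(c("group,rat_id,time_day,activity",
                        "a,r1,0,500", "a,r1,1,oops"))
  expect_error(read_retention_table(bad_cell, "per_rat"), "row 2",
               class = "parse_error")
  bad_times <- tmp_csv(c("group,rat_id,time_day,activity",
                         "a,r1,1,500", "a,r1,3,400", "a,r1,2,300"))
  expect_error(read_retention_table(bad_times, "per_rat"),
               class = "validation_error")
})

test_that("normalization gives 100/0 at the reference and SD/sqrt(n) SEM", {
  r1 <- rat_series("r1", "g", c(0, 1), c(500, 250))
  s <- normalize_retention(list(r1), 0)
  expect_equal(s$mean_retention, c(100, 50))
  expect_equal(s$sem, c(0, 0))

  # two identical rats: sem 0 everywhere
  r2 <- rat_series("r2", "g", c(0, 1), c(1000, 500))
  s2 <- normalize_retention(list(r1, r2), 0)
  expect_equal(s2$sem, c(0, 0))

  # hand-computed SEM for three distinct rats
  rats <- list(rat_series("a", "g", c(0, 1), c(100, 80)),
               rat_series("b", "g", c(0, 1), c(200, 150)),
               rat_series("c", "g", c(0, 1), c(50, 45)))
  s3 <- normalize_retention(rats, 0)
  pct <- c(80, 75, 90)
  expect_equal(s3$mean_retention[2L], mean(pct))
  expect_equal(s3$sem[2L], sd(pct) / sqrt(3))
})

test_that("normalization is invariant to per-rat rescaling and errors on missing ref", {
  rats <- list(rat_series("a", "g", 0:3, c(100, 70, 50, 40)),
               rat_series("b", "g", 0:3, c(90, 66, 48, 35)))
  scaled <- list(rat_series("a", "g", 0:3, 17 * c(100, 70, 50, 40)),
                 rat_series("b", "g", 0:3, 0.3 * c(90, 66, 48, 35)))
  expect_equal(normalize_retention(rats, 0)$mean_retention,
               normalize_retention(scaled, 0)$mean_retention)
  expect_error(normalize_retention(rats, 0.5), "a, b",
               class = "validation_error")
})

test_that("empirical SEM matches the log-normal noise model at large n", {
  # sigma small: SEM of normalized retention at one point ~ R * sqrt(2) * sigma / sqrt(n)
  # (noise on both the point and the reference measurement)
  sigma <- 0.02
  reps <- 400L
  sems <- vapply(seq_len(reps), function(r) {
    rats <- with_seed_local(r, lapply(1:7, function(i) {
      eps <- rnorm(2, 0, sigma)
      rat_series(paste0("r", i), "g", c(0, 1), 0.037 * c(1, 0.5) * exp(eps))
    }))
    normalize_retention(rats, 0)$sem[2L]
  }, numeric(1L))
  theory <- 50 * sqrt(2) * sigma / sqrt(7)
  expect_lt(abs(mean(sems) - theory) / theory, 0.10)
})

test_that("AURC is the trapezoid integral, additive, and approaches the closed form", {
  flat <- retention_series("g", 0:10, rep(100, 11), rep(0, 11), 7, 0)
  expect_equal(aurc(flat, c(0, 10)), 1000)
  lin <- retention_series("g", 0:10, seq(100, 0, by = -10) + c(0, rep(0, 10)),
                          rep(0, 11), 7, 0)
  expect_equal(aurc(lin, c(0, 10)), 500)
  # additivity with interpolated interior endpoint
  expect_equal(aurc(flat, c(0, 3.7)) + aurc(flat, c(3.7, 10)),
               aurc(flat, c(0, 10)))
  expect_error(aurc(flat, c(0, 12)), class = "range_error")

  # closed-form oracle: integral of 100 e^{-kt} over [0, T] = (100/k)(1-e^{-kT})
  k <- 0.3; T <- 10
  exact <- 100 / k * (1 - exp(-k * T))
  for (h in c(1, 0.1, 0.01)) {
    tt <- seq(0, T, by = h)
    s <- retention_series("g", tt, 100 * exp(-k * tt), rep(0, length(tt)), 7, 0)
    err <- abs(aurc(s, c(0, T)) - exact)
    expect_lt(err, 100 * h^2)  # trapezoid is O(h^2)
  }
})

test_that("dose-response OLS recovers exact collinear inputs with r2 = 1", {
  f <- dose_response(c(0, 1, 2), c(10, 8, 6))
  expect_equal(f$slope, -2)
  expect_equal(f$intercept, 10)
  expect_equal(f$r2, 1)
  # two points always give r2 = 1
  expect_equal(dose_response(c(0, 5), c(578.1, 280.55))$r2, 1)
  expect_error(dose_response(c(2, 2, 2), c(1, 2, 3)),
               class = "degenerate_design_error")

  # noiseless values generated from the dose-response line are recovered exactly
  doses <- c(0, 3.32, 5)
  aurc_line <- -59.51 * doses + 578.1
  fa <- dose_response(doses, aurc_line)
  expect_equal(fa$slope, -59.51, tolerance = 1e-12)
  expect_equal(fa$intercept, 578.1, tolerance = 1e-12)
  expect_equal(fa$r2, 1)
  ret_line <- -8.46 * doses + 73.46
  fr <- dose_response(doses, ret_line)
  expect_equal(fr$slope, -8.46, tolerance = 1e-12)
  expect_equal(fr$intercept, 73.46, tolerance = 1e-12)
})

test_that("series constructors enforce their invariants", {
  expect_error(rat_series("r", "g", c(0, 1), c(1, -2)), class = "validation_error")
  expect_error(rat_series("r", "g", 0, 1), class = "validation_error")
  expect_error(retention_series("g", 0:2, c(100, 90, 80), c(0, -1, 0), 7, 0),
               class = "validation_error")
  expect_error(retention_series("g", 0:2, c(99, 90, 80), c(0, 0, 0), 7, 0),
               class = "validation_error")
})
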