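# shared fixtures, built in code

# the treated and control two-compartment rate sets used throughout
treated_rates <- function() bicompartment_params(k_bd = 1.77, k_db = 1.21,
                                                 k_e = 0.19, c0 = 100)
control_rates <- function() bicompartment_params(k_bd = 0.14, k_db = 0.09,
                                                 k_e = log(2) / 2.8 - 0.14,
                                                 c0 = 100)

# a noiseless retention series from any predict function
series_from_model <- function(predict_fun, times, group = "g", ref = times[1L]) {
  y <- predict_fun(times)
  y <- 100 * y / y[times == ref]
  retention_series(group, times, y, sem = rep(0, length(times)),
                   n = 7L, ref_time = ref)
}

# random valid micro rate sets (well-separated eigenvalues)
random_micro <- function(n, seed = 1) {
  with_seed_local(seed, replicate(n, simplify = FALSE, {
    repeat {
      p <- bicompartment_params(k_bd = runif(1, 0.05, 3),
                                k_db = runif(1, 0.05, 3),
                                k_e = runif(1, 0.05, 2),
                                c0 = runif(1, 50, 150))
      s <- p$k_bd + p$k_db + p$k_e
      if ((s^2 - 4 * p$k_db * p$k_e) / s^2 > 1e-6) break
    }
    p
  }))
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

tmp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
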