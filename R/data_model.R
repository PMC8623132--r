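#' Per-animal whole-body activity series
#'
#' A `rat_series` holds the raw whole-body counting measurements of one
#' animal: strictly increasing measurement times (days since contamination)
#' and the positive activity recorded at each (counts or MBq-equivalent —
#' the unit cancels on normalization).
#'
#' @param rat_id Character label identifying the animal.
#' @param group Character label identifying the experimental arm.
#' @param times Numeric vector of measurement times in days, non-negative
#'   and strictly increasing, length >= 2.
#' @param activity Numeric vector of positive whole-body activities, same
#'   length as `times`.
#' @return An object of class `rat_series`.
#' @examples
#' rat_series("r1", "control", times = 0:3, activity = c(100, 80, 65, 50))
#' @export
rat_series <- function(rat_id, group, times, activity) {
  times <- as.numeric(times)
  activity <- as.numeric(activity)
  if (length(times) < 2L)
    stop_decorpkin("a rat series needs at least 2 time points", "validation_error")
  if (length(activity) != length(times))
    stop_decorpkin("times and activity must have equal length", "validation_error")
  if (anyNA(times) || anyNA(activity))
    stop_decorpkin("times and activity must not contain NA", "validation_error")
  if (any(times < 0))
    stop_decorpkin("times must be non-negative", "validation_error")
  if (any(diff(times) <= 0))
    stop_decorpkin(
      sprintf("times of rat '%s' must be strictly increasing", rat_id),
      "validation_error")
  if (any(activity <= 0))
    stop_decorpkin("activity must be strictly positive", "validation_error")
  structure(
    list(rat_id = as.character(rat_id), group = as.character(group),
         times = times, activity = activity),
    class = "rat_series")
}

#' Group-level percentage retention series
#'
#' A `retention_series` is the universal unit of analysis: mean percentage
#' whole-body retention over time for one arm, with the standard error of
#' the mean (SEM) and the number of animals behind each point.  Retention
#' is always expressed relative to a reference time, where the mean is 100
#' by construction.
#'
#' @param group Character arm label.
#' @param times Numeric measurement times in days, strictly increasing.
#' @param mean_retention Numeric mean retention in percent of the
#'   reference-time activity.
#' @param sem Numeric non-negative SEM in percent (same length).
#' @param n Integer number of animals per point (scalar or vector).
#' @param ref_time The normalization time in days; `mean_retention` must be
#'   exactly 100 there if `ref_time` is among `times`.
#' @return An object of class `retention_series`.
#' @seealso [normalize_retention()]
#' @export
retention_series <- function(group, times, mean_retention, sem, n, ref_time) {
  times <- as.numeric(times)
  mean_retention <- as.numeric(mean_retention)
  sem <- as.numeric(sem)
  len <- length(times)
  if (length(mean_retention) != len || length(sem) != len)
    stop_decorpkin("times, mean_retention and sem lengths must agree",
                   "validation_error")
  if (length(n) == 1L) n <- rep.int(as.integer(n), len)
  if (length(n) != len)
    stop_decorpkin("n must be scalar or match the series length", "validation_error")
  if (any(diff(times) <= 0))
    stop_decorpkin("times must be strictly increasing", "validation_error")
  if (any(sem < 0))
    stop_decorpkin("sem must be non-negative", "validation_error")
  if (any(n < 1L))
    stop_decorpkin("n must be a positive integer", "validation_error")
  at_ref <- which(times == ref_time)
  if (length(at_ref) == 1L && abs(mean_retention[at_ref] - 100) > 1e-9)
    stop_decorpkin("mean retention at the reference time must equal 100",
                   "validation_error")
  structure(
    list(group = as.character(group), times = times,
         mean_retention = mean_retention, sem = sem, n = n,
         ref_time = as.numeric(ref_time)),
    class = "retention_series")
}

#' @export
print.rat_series <- function(x, ...) {
  cat(sprintf("<rat_series> rat '%s' (group '%s'), %d measurements over days %g-%g\n",
              x$rat_id, x$group, length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' @export
print.retention_series <- function(x, ...) {
  cat(sprintf(
    "<retention_series> group '%s', %d points over days %g-%g, ref day %g, n = %s\n",
    x$group, length(x$times), min(x$times), max(x$times), x$ref_time,
    paste(unique(x$n), collapse = "/")))
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.retention_series <- function(x, ...) {
  data.frame(group = x$group, time_day = x$times,
             mean_retention_pct = x$mean_retention, sem_pct = x$sem, n = x$n)
}

#' Read a retention table from delimited text
#'
#' Two CSV schemas are supported (comma-separated, dot decimal, UTF-8,
#' header required):
#' \describe{
#'   \item{`per_rat`}{columns `group,rat_id,time_day,activity`; returns a
#'     list of [rat_series()] (one per `group`:`rat_id`, row order preserved).}
#'   \item{`group_level`}{columns
#'     `group,time_day,mean_retention_pct,sem_pct,n`; returns a list of
#'     [retention_series()] (one per group).  The reference time is taken
#'     as the time where the mean equals 100 (the earliest such time).}
#' }
#'
#' @param path Path to the CSV file.
#' @param schema Either `"per_rat"` or `"group_level"`.
#' @return A named list of `rat_series` or `retention_series` objects.
#' @export
read_retention_table <- function(path, schema = c("per_rat", "group_level")) {
  schema <- match.arg(schema)
  if (!file.exists(path))
    stop_decorpkin(sprintf("file not found: %s", path), "io_error")
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- switch(schema,
    per_rat = c("group", "rat_id", "time_day", "activity"),
    group_level = c("group", "time_day", "mean_retention_pct", "sem_pct", "n"))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop_decorpkin(
      sprintf("schema '%s' requires missing column(s): %s", schema,
              paste(missing_cols, collapse = ", ")),
      "schema_error")
  numeric_cols <- setdiff(required, c("group", "rat_id"))
  for (col in numeric_cols) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & !is.na(df[[col]]))
    if (length(bad))
      stop_decorpkin(
        sprintf("non-numeric value in column '%s' at data row %d", col, bad[1L]),
        "parse_error")
    df[[col]] <- vals
  }
  if (schema == "per_rat") {
    key <- paste(df$group, df$rat_id, sep = ":")
    out <- lapply(split(df, factor(key, levels = unique(key))), function(d)
      rat_series(d$rat_id[1L], d$group[1L], d$time_day, d$activity))
  } else {
    key <- df$group
    out <- lapply(split(df, factor(key, levels = unique(key))), function(d) {
      ref_idx <- which(abs(d$mean_retention_pct - 100) < 1e-9)
      ref <- if (length(ref_idx)) d$time_day[min(ref_idx)] else d$time_day[1L]
      retention_series(d$group[1L], d$time_day, d$mean_retention_pct,
                       d$sem_pct, as.integer(d$n), ref_time = ref)
    })
  }
  out
}

#' Write retention data as delimited text
#'
#' Inverse of [read_retention_table()]; value round-trips within the
#' formatting precision of 15 significant digits.
#'
#' @param x A list of `rat_series` (written with the `per_rat` schema) or a
#'   single/ list of `retention_series` (written with the `group_level` schema).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_retention_table <- function(x, path) {
  if (inherits(x, "rat_series") || inherits(x, "retention_series")) x <- list(x)
  stopifnot(length(x) >= 1L)
  if (inherits(x[[1L]], "rat_series")) {
    df <- do.call(rbind, lapply(x, function(r)
      data.frame(group = r$group, rat_id = r$rat_id, time_day = r$times,
                 activity = r$activity)))
  } else {
    df <- do.call(rbind, lapply(x, as.data.frame))
  }
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(v) signif(v, 15))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Normalize per-animal activity to percentage retention
#'
#' Each animal's activity is expressed as a percentage of its own activity
#' at the reference time; the group mean and SEM (sample standard deviation
#' over the square root of the group size) are then taken across animals at
#' each common time point.  At the reference time the mean is exactly 100
#' and the SEM exactly 0.  The reference time is a parameter because
#' delayed-intervention analyses renormalize mid-study (e.g. to day 12 or
#' 13 rather than to the contamination day).
#'
#' @param raw A list of [rat_series()] from one arm.
#' @param ref_time Normalization time in days; every rat must have a
#'   measurement at exactly this time.
#' @return A [retention_series()] over the times common to all rats at or
#'   after which data exist (the union of times restricted to those present
#'   in every rat).
#' @export
normalize_retention <- function(raw, ref_time) {
  if (inherits(raw, "rat_series")) raw <- list(raw)
  if (!length(raw)) stop_decorpkin("no rat series supplied", "validation_error")
  lacking <- vapply(raw, function(r) !any(r$times == ref_time), logical(1L))
  if (any(lacking))
    stop_decorpkin(
      sprintf("rat(s) %s lack a measurement at reference time %g",
              paste(vapply(raw[lacking], `[[`, "", "rat_id"), collapse = ", "),
              ref_time),
      "validation_error")
  common <- Reduce(intersect, lapply(raw, `[[`, "times"))
  common <- sort(common)
  pct <- vapply(raw, function(r) {
    ref_act <- r$activity[r$times == ref_time]
    100 * r$activity[match(common, r$times)] / ref_act
  }, numeric(length(common)))
  pct <- matrix(pct, nrow = length(common))
  n <- length(raw)
  mean_ret <- rowMeans(pct)
  sem <- if (n > 1L) apply(pct, 1L, sd) / sqrt(n) else rep.int(0, length(common))
  # enforce the exact normalization identities at the reference point
  at_ref <- which(common == ref_time)
  mean_ret[at_ref] <- 100
  sem[at_ref] <- 0
  retention_series(group = raw[[1L]]$group, times = common,
                   mean_retention = mean_ret, sem = sem, n = n,
                   ref_time = ref_time)
}

#' Renormalize a retention series to a new reference time
#'
#' Rescales the mean curve (and SEM proportionally) so the mean equals 100
#' at `ref_time`, optionally dropping points before the new reference.
#'
#' @param series A [retention_series()].
#' @param ref_time New reference time; must be an observed time.
#' @param drop_before Drop points earlier than `ref_time`? Default `TRUE`.
#' @return A [retention_series()].
#' @export
renormalize_retention <- function(series, ref_time, drop_before = TRUE) {
  idx <- which(series$times == ref_time)
  if (length(idx) != 1L)
    stop_decorpkin(sprintf("reference time %g is not an observed time", ref_time),
                   "validation_error")
  keep <- if (drop_before) series$times >= ref_time else rep(TRUE, length(series$times))
  scale <- 100 / series$mean_retention[idx]
  m <- series$mean_retention[keep] * scale
  s <- series$sem[keep] * scale
  m[series$times[keep] == ref_time] <- 100
  s[series$times[keep] == ref_time] <- 0
  retention_series(series$group, series$times[keep], m, s, series$n[keep], ref_time)
}

#' Area under the retention curve (AURC)
#'
#' Model-free trapezoidal integral of the observed mean retention over a
#' time window, in percent-days.  Window endpoints falling between sampling
#' times are handled by linear interpolation, which makes the integral
#' exactly additive over adjacent windows.
#'
#' @param series A [retention_series()].
#' @param window Numeric `c(t_start, t_end)` in days, within the observed
#'   time range; the window must contain at least two distinct curve points.
#' @return The AURC in percent-days (a single number).
#' @export
aurc <- function(series, window = range(series$times)) {
  t0 <- window[1L]; t1 <- window[2L]
  if (t1 < t0) stop_decorpkin("window end precedes window start", "range_error")
  if (t0 < min(series$times) || t1 > max(series$times))
    stop_decorpkin("window lies outside the observed time range", "range_error")
  if (t1 == t0) return(0)
  tt <- sort(unique(c(t0, t1, series$times[series$times > t0 & series$times < t1])))
  yy <- approx(series$times, series$mean_retention, xout = tt)$y
  sum(diff(tt) * (head(yy, -1L) + tail(yy, -1L)) / 2)
}

#' Retention at given query times
#'
#' @param series A [retention_series()].
#' @param at Numeric query times within the observed range (linear
#'   interpolation between sampling points).
#' @return Named numeric vector of percent retention.
#' @export
retention_at <- function(series, at) {
  if (any(at < min(series$times)) || any(at > max(series$times)))
    stop_decorpkin("query time outside the observed time range", "range_error")
  setNames(approx(series$times, series$mean_retention, xout = at)$y,
           paste0("day", at))
}

#' Summary metrics of a retention series
#'
#' @param series A [retention_series()].
#' @param window AURC window (default full observed range).
#' @param at Query times for point retention (default day 2, the customary
#'   early-efficacy readout, clipped to the observed range).
#' @return A list of class `summary_metrics` with elements `aurc` and
#'   `retention_at`.
#' @export
summary_metrics <- function(series, window = range(series$times),
                            at = 2) {
  at <- at[at >= min(series$times) & at <= max(series$times)]
  structure(list(aurc = aurc(series, window),
                 retention_at = if (length(at)) retention_at(series, at) else numeric()),
            class = "summary_metrics")
}

#' Ordinary least-squares dose-response fit
#'
#' Regresses a summary metric (AURC or percent retention at a fixed day)
#' on the chelator dose, returning slope, intercept and R-squared.
#'
#' @param doses Numeric doses (mg per 100 g body weight); at least two
#'   distinct values.
#' @param metrics Numeric response values, one per dose.
#' @return A list of class `dose_response_fit` with `slope`, `intercept`,
#'   `r2` and the input `doses`.
#' @export
dose_response <- function(doses, metrics) {
  if (length(doses) != length(metrics))
    stop_decorpkin("doses and metrics lengths differ", "validation_error")
  if (length(unique(doses)) < 2L)
    stop_decorpkin("dose-response needs at least two distinct doses",
                   "degenerate_design_error")
  fit <- lm(metrics ~ doses)
  pred <- unname(predict(fit))
  r2 <- if (length(doses) == 2L) 1
        else r_squared(metrics, pred)
  structure(list(slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 r2 = r2, doses = doses),
            class = "dose_response_fit")
}
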