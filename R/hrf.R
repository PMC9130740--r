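#' Haemodynamic response timecourse
#'
#' A sampled haemodynamic response (HR) or convolution kernel: values on a
#' regular time grid starting at lag 0, with sampling step `dt` seconds and
#' window `(length - 1) * dt` seconds.
#'
#' @param samples numeric vector of response values (fractional signal
#'   change), one per lag bin starting at lag 0.
#' @param dt sampling step in seconds.
#' @return an object of class `hr_timecourse` with elements `samples`,
#'   `dt`, `window` and `times`.
#' @export
hr_timecourse <- function(samples, dt) {
  stopifnot(is.numeric(samples), length(samples) >= 1L,
            all(is.finite(samples)), is.numeric(dt), dt > 0)
  window <- (length(samples) - 1) * dt
  structure(
    list(samples = as.numeric(samples), dt = dt, window = window,
         times = seq(0, by = dt, length.out = length(samples))),
    class = "hr_timecourse")
}

#' @export
print.hr_timecourse <- function(x, ...) {
  cat(sprintf("<hr_timecourse: %d samples, dt = %.3g s, window = %.3g s>\n",
              length(x$samples), x$dt, x$window))
  invisible(x)
}

# Unnormalized double-gamma shape with a latency stretch: the canonical
# two-gamma difference (response gamma shape `peak_delay`, undershoot gamma
# shape `undershoot_delay`, dispersions 1, undershoot ratio 1/6) evaluated
# on a time axis stretched so the positive peak lands at `time_to_peak`.
double_gamma_shape <- function(t, time_to_peak = 5,
                               peak_delay = 6, undershoot_delay = 16,
                               peak_disp = 1, undershoot_disp = 1,
                               undershoot_ratio = 1 / 6) {
  canonical_peak <- (peak_delay / peak_disp - 1) * peak_disp
  s <- canonical_peak / time_to_peak
  tt <- t * s
  dgamma(tt, shape = peak_delay / peak_disp, scale = peak_disp) -
    undershoot_ratio *
      dgamma(tt, shape = undershoot_delay / undershoot_disp,
             scale = undershoot_disp)
}

#' Canonical double-gamma haemodynamic response function
#'
#' The conventional two-gamma-difference HRF (response gamma with shape 6,
#' undershoot gamma with shape 16, unit dispersions, undershoot ratio 1/6;
#' positive peak near 5 s), sampled on a regular grid and scaled to unit
#' positive extremum. These parameters are the widely used defaults; they
#' are exposed so alternative canonical shapes can be supplied.
#'
#' @param dt sampling step in seconds.
#' @param window kernel duration in seconds; must be at least 24 s so the
#'   undershoot is fully represented.
#' @param peak_delay,undershoot_delay gamma shape parameters (with unit
#'   dispersion these are peak time + 1 in seconds).
#' @param peak_disp,undershoot_disp gamma dispersions.
#' @param undershoot_ratio relative undershoot amplitude.
#' @return an [hr_timecourse] with unit positive extremum.
#' @export
canonical_double_gamma <- function(dt, window = 32,
                                   peak_delay = 6, undershoot_delay = 16,
                                   peak_disp = 1, undershoot_disp = 1,
                                   undershoot_ratio = 1 / 6) {
  stopifnot(dt > 0, window >= 24)
  tt <- seq(0, window, by = dt)
  h <- dgamma(tt, shape = peak_delay / peak_disp, scale = peak_disp) -
    undershoot_ratio *
      dgamma(tt, shape = undershoot_delay / undershoot_disp,
             scale = undershoot_disp)
  hr_timecourse(h / max(h), dt)
}

#' Latency-stretched double-gamma kernel
#'
#' The canonical double-gamma shape with its time axis stretched so the
#' positive peak occurs at `time_to_peak` seconds, scaled to unit extremum
#' magnitude. This is the generative HR family used by the synthetic-data
#' module: it keeps the canonical analysis family while making the
#' time-to-peak a controllable parameter.
#'
#' @param time_to_peak desired peak latency in seconds.
#' @param dt sampling step in seconds.
#' @param window kernel duration in seconds.
#' @param negative if `TRUE`, return the sign-flipped (negative-going)
#'   kernel with extremum -1, as appropriate for NBR regions.
#' @return an [hr_timecourse] with extremum magnitude 1.
#' @export
stretched_double_gamma <- function(time_to_peak, dt, window = 32,
                                   negative = FALSE) {
  stopifnot(time_to_peak > 0, dt > 0, window > time_to_peak)
  tt <- seq(0, window, by = dt)
  h <- double_gamma_shape(tt, time_to_peak = time_to_peak)
  h <- h / max(abs(h))
  if (negative) h <- -h
  hr_timecourse(h, dt)
}

# Resample an hr_timecourse to a new grid by linear interpolation; lags
# outside the original window map to zero.
resample_hr <- function(hr, dt_new, window_new = hr$window) {
  stopifnot(inherits(hr, "hr_timecourse"), dt_new > 0)
  tt <- seq(0, window_new, by = dt_new)
  v <- approx(hr$times, hr$samples, xout = tt, rule = 1)$y
  v[is.na(v)] <- 0
  hr_timecourse(v, dt_new)
}

#' Write / read an HR timecourse as two-column CSV
#'
#' Serializes the response as columns `time_s`, `value`.
#'
#' @param hr an [hr_timecourse].
#' @param path file path.
#' @return `read_hr_csv` returns an [hr_timecourse].
#' @export
write_hr_csv <- function(hr, path) {
  stopifnot(inherits(hr, "hr_timecourse"))
  write.csv(data.frame(time_s = hr$times, value = hr$samples),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hr_csv
#' @export
read_hr_csv <- function(path) {
  d <- read.csv(path)
  stopifnot(all(c("time_s", "value") %in% names(d)), nrow(d) >= 2)
  dt <- d$time_s[2] - d$time_s[1]
  hr_timecourse(d$value, dt)
}
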