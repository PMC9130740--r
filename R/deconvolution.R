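# FIR deconvolution of region haemodynamic responses.
#
# The forward model HR = neural input (*) HRF is inverted without assuming
# a response shape: all events are pooled into one constant-amplitude
# delta train binned at the volume grid, and one response value is
# estimated per post-stimulus lag bin (0, TR, 2 TR, ... up to the window)
# by least squares, with polynomial drift nuisance regressors.

# Build the FIR lag design. Events are assigned to the nearest volume;
# column l holds the train shifted by l volumes.
fir_design <- function(schedule, tr, n_volumes, window = 24,
                       drift_order = 2) {
  stopifnot(inherits(schedule, "event_schedule"), tr > 0,
            window / tr >= 2)
  n_lags <- floor(window / tr) + 1L
  s <- numeric(n_volumes)
  bins <- round(schedule$onsets / tr) + 1L
  bins <- bins[bins >= 1 & bins <= n_volumes]
  for (b in bins) s[b] <- s[b] + 1
  X_lag <- vapply(0:(n_lags - 1L), function(l) {
    c(rep(0, l), s)[seq_len(n_volumes)]
  }, numeric(n_volumes))
  colnames(X_lag) <- sprintf("lag_%d", 0:(n_lags - 1L))
  nuis <- cbind(baseline = rep(1, n_volumes),
                drift_basis(n_volumes, drift_order))
  X <- cbind(X_lag, nuis)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dep <- setdiff(seq_len(n_lags), qx$pivot[seq_len(qx$rank)])
    stop(sprintf(
      "FIR lag design is rank deficient; offending lag bins (s): %s",
      paste(sprintf("%.2f", (dep - 1) * tr), collapse = ", ")))
  }
  list(X_lag = X_lag, nuisance = nuis, X = X, qx = qx,
       n_lags = n_lags, tr = tr,
       lags = (0:(n_lags - 1L)) * tr)
}

#' FIR forward convolution of an event schedule with an HR
#'
#' The discrete forward operator that the FIR deconvolution inverts:
#' events are pooled into a constant-amplitude train binned at the volume
#' grid and convolved with the TR-resolution HR. On noiseless data built
#' with this operator, [deconvolve_hr] recovers the HR to machine
#' precision (the deconvolution-convolution identity).
#'
#' @param schedule an [event_schedule].
#' @param hr an [hr_timecourse] sampled at the TR (`hr$dt == tr`).
#' @param tr repetition time (s).
#' @param n_volumes number of volumes.
#' @return numeric vector of length `n_volumes`.
#' @export
fir_convolve <- function(schedule, hr, tr, n_volumes) {
  stopifnot(inherits(hr, "hr_timecourse"),
            abs(hr$dt - tr) < 1e-9)
  d <- fir_design(schedule, tr, n_volumes, window = hr$window,
                  drift_order = 0)
  drop(d$X_lag %*% hr$samples)
}

#' Estimate a haemodynamic response by FIR deconvolution
#'
#' Least-squares finite-impulse-response estimate of the HR underlying a
#' region-mean BOLD timecourse, given the event timings: one unknown per
#' lag bin 0..floor(window/tr), all events pooled into a single
#' constant-amplitude delta train, with an intercept and polynomial drift
#' as nuisance. Unregularized by default; a ridge penalty is available for
#' ill-conditioned schedules.
#'
#' @param timecourse numeric vector, the ROI mean signal per volume.
#' @param schedule an [event_schedule].
#' @param tr repetition time (s).
#' @param window response window in seconds (default 24 s, comfortably
#'   covering peak latencies up to 18 s and the undershoot).
#' @param drift_order polynomial drift nuisance order.
#' @param ridge ridge penalty on the lag coefficients (0 = plain OLS).
#' @return an [hr_timecourse] sampled at TR resolution, in the units of
#'   the input timecourse.
#' @export
deconvolve_hr <- function(timecourse, schedule, tr, window = 24,
                          drift_order = 2, ridge = 0) {
  stopifnot(is.numeric(timecourse))
  d <- fir_design(schedule, tr, length(timecourse), window = window,
                  drift_order = drift_order)
  if (ridge > 0) {
    p <- ncol(d$X)
    pen <- diag(c(rep(sqrt(ridge), d$n_lags), rep(0, p - d$n_lags)),
                nrow = p)
    coefs <- qr.coef(qr(rbind(d$X, pen)), c(timecourse, numeric(p)))
  } else {
    coefs <- qr.coef(d$qx, timecourse)
  }
  hr_timecourse(coefs[seq_len(d$n_lags)], dt = tr)
}

#' Peak magnitude and time-to-peak of an HR
#'
#' Measured from the maximal absolute signal change: the peak magnitude is
#' the signed sample of largest absolute value and the time-to-peak its
#' lag time. Ties are broken by the earliest bin.
#'
#' @param hr an [hr_timecourse]; must not be identically zero.
#' @return an object of class `hr_metrics`: list with `peak_magnitude`
#'   (signed) and `time_to_peak` (s).
#' @export
hr_metrics <- function(hr) {
  stopifnot(inherits(hr, "hr_timecourse"))
  if (all(hr$samples == 0)) stop("HR is identically zero; no peak defined")
  i <- which.max(abs(hr$samples))
  structure(list(peak_magnitude = hr$samples[i],
                 time_to_peak = hr$times[i]),
            class = "hr_metrics")
}

#' @export
print.hr_metrics <- function(x, ...) {
  cat(sprintf("<hr_metrics: peak %.4g at %.3g s>\n",
              x$peak_magnitude, x$time_to_peak))
  invisible(x)
}

#' Pointwise mean of HR timecourses
#'
#' Averages subject HRs within a group (e.g. a decile) bin by bin. All
#' inputs must share the sampling step and window.
#'
#' @param hrs non-empty list of [hr_timecourse] objects on a common grid.
#' @return an [hr_timecourse].
#' @export
decile_mean_hr <- function(hrs) {
  stopifnot(is.list(hrs), length(hrs) >= 1,
            all(vapply(hrs, inherits, logical(1), "hr_timecourse")))
  dts <- vapply(hrs, `[[`, numeric(1), "dt")
  lens <- vapply(hrs, function(h) length(h$samples), integer(1))
  if (any(abs(dts - dts[1]) > 1e-9) || any(lens != lens[1])) {
    stop("all HRs must share the same sampling step and window")
  }
  m <- rowMeans(vapply(hrs, `[[`, numeric(lens[1]), "samples"))
  hr_timecourse(m, dts[1])
}

#' Normalize an HR to unit extremum magnitude
#'
#' Divides every sample by the maximum absolute amplitude, preserving
#' sign, so the extremum magnitude equals 1. A negative-going (NBR) HR
#' therefore keeps its polarity with extremum -1; when such a kernel is
#' used for GLM convolution, the contrast aligned with the kernel polarity
#' indexes the NBR.
#'
#' @param hr an [hr_timecourse]; must not be identically zero.
#' @return an [hr_timecourse] with extremum magnitude exactly 1.
#' @export
normalize_hr <- function(hr) {
  stopifnot(inherits(hr, "hr_timecourse"))
  m <- max(abs(hr$samples))
  if (m == 0) stop("cannot normalize an identically zero HR")
  hr_timecourse(hr$samples / m, hr$dt)
}
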