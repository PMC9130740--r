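#' Convolve an event schedule with an HR kernel and sample at volume times
#'
#' Builds the event train on a fine 0.01 s grid (each trial a boxcar of its
#' stated duration, constant unit amplitude), convolves it with the kernel
#' resampled to the same grid, and samples the result at volume acquisition
#' times t = volume_index x TR. The regressor is scaled so that an isolated
#' event produces unit extremum deviation, which makes fitted beta-weights
#' directly interpretable as per-event peak fractional signal change.
#'
#' @param schedule an [event_schedule].
#' @param kernel an [hr_timecourse].
#' @param tr repetition time (s).
#' @param n_volumes number of volumes.
#' @param dt fine grid step in seconds; must divide the TR to numerical
#'   precision (0.01 s divides both TR = 1.97 s and the 2 s event grid).
#' @param conditions optional character vector restricting the train to a
#'   subset of condition labels.
#' @return numeric vector of length `n_volumes`.
#' @export
convolve_schedule <- function(schedule, kernel, tr, n_volumes, dt = 0.01,
                              conditions = NULL) {
  stopifnot(inherits(schedule, "event_schedule"),
            inherits(kernel, "hr_timecourse"), tr > 0, dt > 0)
  # tolerate single-precision TR values from NIfTI headers
  if (abs(tr / dt - round(tr / dt)) > 1e-4) {
    stop("fine grid dt must divide the TR exactly")
  }
  keep <- if (is.null(conditions)) rep(TRUE, length(schedule$onsets)) else
    schedule$conditions %in% conditions
  onsets <- schedule$onsets[keep]
  durations <- schedule$durations[keep]
  run_end <- n_volumes * tr
  if (length(onsets) > 0 && any(onsets + durations > run_end + 1e-9)) {
    stop("events extend beyond the end of the acquisition")
  }
  n_fine <- round(max(schedule$run_length, run_end) / dt) + 1L
  if (length(onsets) == 0) return(numeric(n_volumes))

  stim <- numeric(n_fine)
  for (i in seq_along(onsets)) {
    a <- round(onsets[i] / dt) + 1L
    b <- min(n_fine, a + max(1L, round(durations[i] / dt)) - 1L)
    stim[a:b] <- stim[a:b] + 1
  }
  k <- resample_hr(kernel, dt)$samples
  full <- fft_convolve(stim, k)[seq_len(n_fine)]

  # unit-extremum single-event reference response
  nb <- max(1L, round(median(durations) / dt))
  ref <- fft_convolve(c(rep(1, nb), numeric(length(k))), k)
  scale <- 1 / max(abs(ref))

  idx <- round((seq_len(n_volumes) - 1L) * tr / dt) + 1L
  full[idx] * scale
}

#' Build a first-level design matrix
#'
#' One regressor per condition (its delta train convolved with the kernel
#' via [convolve_schedule]), optionally the six demeaned rigid-body motion
#' parameters, then an intercept and polynomial drift nuisance columns.
#' Contrast vectors `pbr` (mean over the condition regressors) and `nbr`
#' (its negation) are attached.
#'
#' @inheritParams convolve_schedule
#' @param motion a [motion_trace] or `NULL`.
#' @param drift_order order of the polynomial drift nuisance (0 for none;
#'   the intercept is always included).
#' @return an object of class `design_matrix`: list with `X` (n_volumes x
#'   n_regressors), `roles` (one of condition/motion/baseline/drift per
#'   column), `contrasts` (named weight vectors) and metadata.
#' @export
build_design_matrix <- function(schedule, kernel, tr, n_volumes,
                                motion = NULL, drift_order = 2, dt = 0.01) {
  conds <- intersect(task_conditions(), unique(schedule$conditions))
  if (length(conds) == 0) conds <- unique(schedule$conditions)
  if (length(conds) == 0) stop("schedule has no events to model")
  cond_cols <- vapply(conds, function(cc) {
    convolve_schedule(schedule, kernel, tr, n_volumes, dt = dt,
                      conditions = cc)
  }, numeric(n_volumes))
  X <- cond_cols
  roles <- rep("condition", length(conds))
  if (!is.null(motion)) {
    stopifnot(inherits(motion, "motion_trace"), nrow(motion) == n_volumes)
    mc <- scale(unclass(motion), center = TRUE, scale = FALSE)
    colnames(mc) <- colnames(motion)
    X <- cbind(X, mc)
    roles <- c(roles, rep("motion", 6))
  }
  X <- cbind(X, baseline = 1)
  roles <- c(roles, "baseline")
  if (drift_order >= 1) {
    X <- cbind(X, drift_basis(n_volumes, drift_order))
    roles <- c(roles, rep("drift", drift_order))
  }
  w <- numeric(ncol(X))
  w[seq_along(conds)] <- 1 / length(conds)
  contrasts <- list(pbr = w, nbr = -w)
  structure(list(X = X, roles = roles, contrasts = contrasts,
                 conditions = conds, tr = tr, n_volumes = n_volumes),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix: %d volumes x %d regressors (%s)>\n",
              nrow(x$X), ncol(x$X),
              paste(sprintf("%d %s", table(x$roles)[unique(x$roles)],
                            unique(x$roles)), collapse = ", ")))
  invisible(x)
}

# Core OLS engine: Y is n_volumes x n_series; returns per-contrast
# estimates, variances, t and Z plus a validity flag per series.
ols_contrast_fit <- function(Y, design) {
  X <- design$X
  n <- nrow(X)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    stop(sprintf("design matrix is rank deficient (rank %d < %d columns)",
                 qx$rank, ncol(X)))
  }
  beta <- qr.coef(qx, Y)
  res <- Y - X %*% beta
  df <- n - ncol(X)
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qx))
  valid <- sigma2 > 1e-24
  out <- lapply(design$contrasts, function(cw) {
    est <- drop(crossprod(cw, beta))
    cvar <- drop(crossprod(cw, xtx_inv %*% cw))
    se <- sqrt(sigma2 * cvar)
    t <- ifelse(valid, est / se, NA_real_)
    list(beta = est, beta_variance = sigma2 * cvar,
         t = t, z = t_to_z(t, df))
  })
  list(contrasts = out, coef = beta, df = df, valid = valid,
       sigma2 = sigma2)
}

#' Fit the first-level GLM
#'
#' Ordinary least squares per voxel (prewhitening is intentionally out of
#' scope; the noise model is handled by drift regressors and acknowledged
#' AR(1) simulation). For each attached contrast c the t statistic is
#' c'beta / sqrt(sigma2 c'(X'X)^-1 c) with df = n_volumes - n_regressors,
#' mapped to a Z statistic by [t_to_z]. Voxels with (numerically) zero
#' residual variance are flagged invalid rather than assigned extreme Z.
#'
#' @param data a [bold_dataset], a numeric matrix (n_volumes x n_series)
#'   or a single numeric timecourse.
#' @param design a [design_matrix].
#' @param mask logical 3-D array selecting voxels (bold input only);
#'   default all voxels.
#' @return an object of class `first_level_result`. For volume input, per
#'   contrast 3-D `beta`, `beta_variance` and `z` arrays (NA outside the
#'   mask / at invalid voxels) plus `df`, `valid` and `mask`. For
#'   matrix/vector input the same fields as vectors.
#' @export
fit_glm <- function(data, design, mask = NULL) {
  stopifnot(inherits(design, "design_matrix"))
  if (inherits(data, "bold_dataset")) {
    d <- dim(data$data)
    stopifnot(d[4] == nrow(design$X))
    if (is.null(mask)) mask <- array(TRUE, dim = d[1:3])
    stopifnot(all(dim(mask) == d[1:3]))
    if (!any(mask)) stop("mask is empty")
    Y <- t(matrix(data$data, nrow = prod(d[1:3]))[which(mask), , drop = FALSE])
    fit <- ols_contrast_fit(Y, design)
    shape <- function(v) {
      a <- array(NA_real_, dim = d[1:3])
      a[which(mask)] <- v
      a
    }
    maps <- lapply(fit$contrasts, function(co) {
      list(beta = shape(co$beta), beta_variance = shape(co$beta_variance),
           z = shape(co$z))
    })
    valid <- array(FALSE, dim = d[1:3])
    valid[which(mask)] <- fit$valid
    structure(list(contrasts = maps, df = fit$df, valid = valid,
                   mask = mask, volumetric = TRUE),
              class = "first_level_result")
  } else {
    Y <- if (is.matrix(data)) data else matrix(data, ncol = 1)
    stopifnot(nrow(Y) == nrow(design$X))
    fit <- ols_contrast_fit(Y, design)
    structure(list(contrasts = fit$contrasts, coef = fit$coef,
                   df = fit$df, valid = fit$valid, volumetric = FALSE),
              class = "first_level_result")
  }
}

#' @export
print.first_level_result <- function(x, ...) {
  cat(sprintf("<first_level_result: contrasts %s, df = %d>\n",
              paste(names(x$contrasts), collapse = ", "), x$df))
  invisible(x)
}

#' Spatially smooth a BOLD dataset
#'
#' Separable Gaussian smoothing applied volume by volume, with the kernel
#' width given as full width at half maximum in millimetres and converted
#' per axis using the voxel dimensions. Reflective boundaries preserve the
#' per-volume total signal. `fwhm = 0` returns the input unchanged.
#'
#' @param bold a [bold_dataset].
#' @param fwhm kernel FWHM in mm.
#' @return a smoothed [bold_dataset].
#' @export
gaussian_smooth <- function(bold, fwhm) {
  stopifnot(inherits(bold, "bold_dataset"), fwhm >= 0)
  if (fwhm == 0) return(bold)
  sigma_vox <- fwhm / (2 * sqrt(2 * log(2))) / bold$voxel_dim
  out <- bold$data
  for (axis in 1:3) {
    if (sigma_vox[axis] <= 0) next
    r <- max(1L, ceiling(3.5 * sigma_vox[axis]))
    k <- exp(-0.5 * ((-r):r / sigma_vox[axis])^2)
    k <- k / sum(k)
    out <- convolve_axis(out, k, axis)
  }
  bold_dataset(out, tr = bold$tr, label_map = bold$label_map,
               voxel_dim = bold$voxel_dim)
}

# 1-D convolution of a 4-D array along a spatial axis with reflective
# (half-sample symmetric) boundary handling.
convolve_axis <- function(a, k, axis) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:4, axis))
  ap <- aperm(a, perm)
  n <- dim(ap)[1]
  m <- matrix(ap, nrow = n)
  r <- (length(k) - 1L) / 2L
  idx <- c(rev(seq_len(min(r, n))), seq_len(n),
           n + 1 - seq_len(min(r, n)))
  # if r > n the reflection wraps; extend by repeated reflection
  while (length(idx) < n + 2 * r) {
    idx <- c(idx[1], idx, idx[length(idx)])
  }
  mp <- m[idx, , drop = FALSE]
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (j in seq_along(k)) {
    out <- out + k[j] * mp[j:(j + n - 1), , drop = FALSE]
  }
  dim(out) <- dim(ap)
  aperm(out, order(perm))
}
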