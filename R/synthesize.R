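#' Toy block atlas
#'
#' A small label volume with one contiguous block per region (cSM1, iSM1,
#' V1, thalamus, PCC) on a background of zeros, standing in for
#' MNI-space anatomical masks at desk scale. Blocks are defined as
#' fractions of a 24 x 24 x 12 reference grid and scale with `grid_shape`.
#' The left/right split puts cSM1 in the left hemisphere (contralateral to
#' a right-hand button press) and iSM1 mirrored on the right.
#'
#' @param grid_shape integer triple of voxel dimensions (each >= 12, 12, 6).
#' @param voxel_dim voxel size in mm (x, y, z); the default mirrors a
#'   3 x 3 x 4.44 mm acquisition.
#' @return an object of class `toy_atlas`: list with `labels` (integer 3-D
#'   array, 0 = background), `region_codes` (named integer vector) and
#'   `voxel_dim`.
#' @export
toy_atlas <- function(grid_shape = c(24, 24, 12), voxel_dim = c(3, 3, 4.44)) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= c(12, 12, 6)))
  ref <- c(24, 24, 12)
  # boxes on the reference grid: xmin,xmax,ymin,ymax,zmin,zmax (1-based)
  boxes <- list(
    cSM1     = c(3, 8, 8, 13, 7, 10),
    iSM1     = c(17, 22, 8, 13, 7, 10),
    V1       = c(9, 16, 19, 24, 3, 6),
    thalamus = c(10, 15, 10, 15, 4, 6),
    PCC      = c(10, 15, 16, 21, 8, 10))
  labels <- array(0L, dim = grid_shape)
  codes <- setNames(seq_along(boxes), names(boxes))
  for (r in names(boxes)) {
    b <- boxes[[r]]
    sc <- function(i, d) max(1L, min(grid_shape[d], round(i * grid_shape[d] / ref[d])))
    xs <- sc(b[1], 1):sc(b[2], 1)
    ys <- sc(b[3], 2):sc(b[4], 2)
    zs <- sc(b[5], 3):sc(b[6], 3)
    labels[xs, ys, zs] <- codes[[r]]
  }
  structure(list(labels = labels, region_codes = codes,
                 voxel_dim = voxel_dim),
            class = "toy_atlas")
}

#' Logical mask for one or more atlas regions
#'
#' @param atlas a [toy_atlas].
#' @param regions character vector of region names; the sensorimotor
#'   cortex mask of the spatial-extent analysis is
#'   `atlas_mask(atlas, c("cSM1", "iSM1"))`.
#' @return logical 3-D array.
#' @export
atlas_mask <- function(atlas, regions) {
  stopifnot(inherits(atlas, "toy_atlas"),
            all(regions %in% names(atlas$region_codes)))
  array(atlas$labels %in% atlas$region_codes[regions],
        dim = dim(atlas$labels))
}

#' 4-D BOLD dataset
#'
#' @param data 4-D numeric array indexed (x, y, z, volume), all finite.
#' @param tr repetition time in seconds.
#' @param label_map integer 3-D array of region labels matching the
#'   spatial dimensions (may be `NULL`).
#' @param voxel_dim voxel size in mm.
#' @return an object of class `bold_dataset`.
#' @export
bold_dataset <- function(data, tr, label_map = NULL,
                         voxel_dim = c(3, 3, 4.44)) {
  stopifnot(is.array(data), length(dim(data)) == 4, tr > 0)
  if (!all(is.finite(data))) stop("BOLD data contain non-finite values")
  if (!is.null(label_map)) {
    stopifnot(all(dim(label_map) == dim(data)[1:3]))
  }
  structure(list(data = data, tr = tr, label_map = label_map,
                 voxel_dim = voxel_dim, n_volumes = dim(data)[4]),
            class = "bold_dataset")
}

#' @export
print.bold_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_dataset: %d x %d x %d voxels, %d volumes, TR = %.3g s>\n",
              d[1], d[2], d[3], d[4], x$tr))
  invisible(x)
}

#' Rigid-body motion trace
#'
#' @param params numeric matrix with one row per volume and six columns:
#'   three translations (mm) then three rotations (radians).
#' @return an object of class `motion_trace` (a matrix).
#' @export
motion_trace <- function(params) {
  params <- as.matrix(params)
  stopifnot(ncol(params) == 6, all(is.finite(params)))
  colnames(params) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")
  structure(params, class = c("motion_trace", "matrix"))
}

#' Synthetic subject specification
#'
#' Bundles everything needed to synthesize one subject reproducibly: age,
#' per-region HR parameters (from the lifespan trajectories by default),
#' noise and drift parameters, and mandatory RNG seeds.
#'
#' @param age age in years, in [18, 88].
#' @param motion_seed,noise_seed integer seeds (mandatory; seeds are
#'   explicit fields, never ambient state).
#' @param decile decile label; defaults to the bin containing `age`.
#' @param region_params data.frame with columns `region`, `amplitude`,
#'   `time_to_peak`; defaults to the trajectory values at `age`.
#' @param noise_sigma AR(1) noise standard deviation as a fraction of
#'   baseline (default 0.01, i.e. temporal SNR of about 100).
#' @param ar1_rho lag-1 autocorrelation of the noise, |rho| < 1.
#' @param drift_coefs polynomial drift coefficients on time scaled to
#'   [-1, 1] (term k multiplies t^k).
#' @param trajectories trajectory table used for the default
#'   `region_params`.
#' @return an object of class `subject_spec`.
#' @export
subject_spec <- function(age, motion_seed, noise_seed,
                         decile = decile_for_age(age),
                         region_params = NULL,
                         noise_sigma = 0.01, ar1_rho = 0.3,
                         drift_coefs = c(0.005, -0.003),
                         trajectories = default_trajectories()) {
  stopifnot(is.numeric(age), age >= 18, age <= 88,
            abs(ar1_rho) < 1, noise_sigma >= 0,
            all(is.finite(drift_coefs)))
  if (is.null(region_params)) {
    regions <- setdiff(trajectories$region, "background")
    region_params <- do.call(rbind, lapply(regions, function(r) {
      p <- hr_from_age(age, r, trajectories)
      data.frame(region = r, amplitude = p$amplitude,
                 time_to_peak = p$time_to_peak, stringsAsFactors = FALSE)
    }))
  }
  stopifnot(all(c("region", "amplitude", "time_to_peak") %in%
                  names(region_params)),
            all(is.finite(region_params$amplitude)),
            all(is.finite(region_params$time_to_peak)))
  amp <- function(r) region_params$amplitude[region_params$region == r]
  for (r in intersect(c("iSM1", "PCC"), region_params$region)) {
    if (amp(r) > 0) stop(sprintf("%s amplitude must be <= 0 (NBR region)", r))
  }
  for (r in intersect(c("cSM1", "V1", "thalamus"), region_params$region)) {
    if (amp(r) < 0) stop(sprintf("%s amplitude must be >= 0 (PBR region)", r))
  }
  structure(list(age = age, decile = decile, region_params = region_params,
                 noise_sigma = noise_sigma, ar1_rho = ar1_rho,
                 drift_coefs = drift_coefs,
                 motion_seed = as.integer(motion_seed),
                 noise_seed = as.integer(noise_seed)),
            class = "subject_spec")
}

# AR(1) series with marginal sd `sigma` and lag-1 correlation `rho`.
ar1_noise <- function(n, sigma, rho) {
  if (sigma == 0) return(numeric(n))
  innov <- rnorm(n, sd = sigma * sqrt(1 - rho^2))
  innov[1] <- rnorm(1, sd = sigma)
  as.numeric(stats::filter(innov, rho, method = "recursive"))
}

# Noiseless fractional task signal of one region at volume times.
region_signal <- function(spec, schedule, region, tr, n_volumes, dt = 0.01) {
  p <- spec$region_params[spec$region_params$region == region, , drop = FALSE]
  if (nrow(p) != 1) stop(sprintf("unknown region '%s' in spec", region))
  if (p$amplitude == 0) return(numeric(n_volumes))
  kernel <- stretched_double_gamma(p$time_to_peak, dt = dt)
  p$amplitude * convolve_schedule(schedule, kernel, tr, n_volumes, dt = dt)
}

#' Synthesize a single region-mean timecourse
#'
#' The forward model for one region: baseline + amplitude x (event train
#' convolved with the unit-extremum region HR, sampled at volume times) +
#' polynomial drift + AR(1) noise. This is the fast path used for
#' region-level cohort studies; [synthesize_subject] applies the same model
#' voxelwise.
#'
#' @param spec a [subject_spec].
#' @param schedule an [event_schedule].
#' @param region region name.
#' @param tr repetition time (s).
#' @param n_volumes number of volumes.
#' @param dt fine convolution grid in seconds (0.01 s: an exact divisor of
#'   both the TR and the event grid).
#' @param noise include AR(1) noise (seeded from `noise_seed` plus the
#'   region's index, so regions are independent but reproducible).
#' @param drift include the polynomial drift.
#' @param baseline baseline signal level (1 makes deviations fractional).
#' @return numeric vector of length `n_volumes`.
#' @export
synthesize_region_timecourse <- function(spec, schedule, region,
                                         tr = 1.97, n_volumes = 261,
                                         dt = 0.01, noise = TRUE,
                                         drift = TRUE, baseline = 1) {
  stopifnot(inherits(spec, "subject_spec"))
  y <- baseline + region_signal(spec, schedule, region, tr, n_volumes, dt)
  if (drift && length(spec$drift_coefs) > 0) {
    y <- y + drop(drift_basis(n_volumes, length(spec$drift_coefs)) %*%
                    spec$drift_coefs)
  }
  if (noise && spec$noise_sigma > 0) {
    ridx <- match(region, default_trajectories()$region, nomatch = 99L)
    y <- y + with_seed(spec$noise_seed + ridx,
                       ar1_noise(n_volumes, spec$noise_sigma, spec$ar1_rho))
  }
  y
}

#' Synthesize a 4-D BOLD dataset and motion trace for one subject
#'
#' Applies the region forward model voxelwise on a toy block atlas: every
#' voxel of a region carries that region's noiseless task signal plus a
#' shared polynomial drift and voxel-independent AR(1) noise; background
#' voxels carry baseline, drift and noise only. The motion trace is a
#' smoothed random walk scaled so its summed framewise displacement
#' follows the observed age trend. Fully reproducible from the spec's
#' seeds.
#'
#' @inheritParams synthesize_region_timecourse
#' @param grid_shape voxel grid dimensions.
#' @param atlas a [toy_atlas]; defaults to `toy_atlas(grid_shape)`.
#' @return a list with `bold` (a [bold_dataset]) and `motion` (a
#'   [motion_trace]).
#' @export
synthesize_subject <- function(spec, schedule, grid_shape = c(24, 24, 12),
                               tr = 1.97, n_volumes = 261, atlas = NULL,
                               dt = 0.01, baseline = 1) {
  stopifnot(inherits(spec, "subject_spec"),
            n_volumes * tr >= schedule$run_length - 1e-9)
  if (is.null(atlas)) atlas <- toy_atlas(grid_shape)
  grid_shape <- dim(atlas$labels)
  nvox <- prod(grid_shape)
  lab <- as.integer(atlas$labels)

  signals <- matrix(0, nrow = n_volumes,
                    ncol = length(atlas$region_codes) + 1L)
  for (r in names(atlas$region_codes)) {
    signals[, atlas$region_codes[[r]] + 1L] <-
      region_signal(spec, schedule, r, tr, n_volumes, dt)
  }
  drift <- if (length(spec$drift_coefs) > 0) {
    drop(drift_basis(n_volumes, length(spec$drift_coefs)) %*% spec$drift_coefs)
  } else numeric(n_volumes)

  # voxels x volumes; fill with region signal + drift, then add noise
  y <- t(signals[, lab + 1L, drop = FALSE]) + baseline +
    matrix(drift, nrow = nvox, ncol = n_volumes, byrow = TRUE)
  if (spec$noise_sigma > 0) {
    y <- y + with_seed(spec$noise_seed, {
      innov <- matrix(rnorm(nvox * n_volumes,
                            sd = spec$noise_sigma * sqrt(1 - spec$ar1_rho^2)),
                      nrow = nvox)
      innov[, 1] <- rnorm(nvox, sd = spec$noise_sigma)
      for (t in 2:n_volumes) {
        innov[, t] <- innov[, t] + spec$ar1_rho * innov[, t - 1]
      }
      innov
    })
  }
  dim(y) <- c(grid_shape, n_volumes)
  list(bold = bold_dataset(y, tr = tr, label_map = atlas$labels,
                           voxel_dim = atlas$voxel_dim),
       motion = generate_motion(spec, n_volumes))
}

#' Generate a subject's motion trace
#'
#' A smoothed Gaussian random walk over the six rigid-body parameters,
#' rescaled so the subject's summed framewise displacement matches an
#' age-dependent target (total FD of about 18.7 + 1.37 x age mm, the line
#' through the observed decile means, with lognormal between-subject
#' scatter). Head motion therefore increases with age in simulated
#' cohorts, as it does in real ageing data.
#'
#' @param spec a [subject_spec] (uses `age` and `motion_seed`).
#' @param n_volumes number of volumes.
#' @param head_radius sphere radius (mm) for the rotation-to-displacement
#'   conversion used when computing the scaling target.
#' @return a [motion_trace].
#' @export
generate_motion <- function(spec, n_volumes, head_radius = 50) {
  stopifnot(inherits(spec, "subject_spec"), n_volumes >= 2)
  with_seed(spec$motion_seed, {
    steps <- cbind(matrix(rnorm(n_volumes * 3), ncol = 3),
                   matrix(rnorm(n_volumes * 3, sd = 0.01), ncol = 3))
    sm <- stats::filter(steps, rep(1 / 5, 5), sides = 2)
    sm[is.na(sm)] <- steps[is.na(sm)]
    walk <- apply(sm, 2, cumsum)
    target <- (18.68 + 1.37 * spec$age) * exp(rnorm(1, 0, 0.25))
    total <- framewise_displacement(motion_trace(walk),
                                    head_radius = head_radius)$total
    if (total > 0) walk <- walk * (target / total)
    motion_trace(walk)
  })
}

#' Simulate a lifespan cohort
#'
#' Draws `n_per_decile` subjects per decile with ages uniform inside each
#' decile's age range, region HR parameters from the lifespan trajectories
#' with multiplicative amplitude jitter (sign-preserving) and additive
#' time-to-peak jitter, and fresh motion/noise seeds. Deterministic given
#' `seed`.
#'
#' @param n_per_decile subjects per decile bin.
#' @param seed integer RNG seed.
#' @param noise_sigma,ar1_rho noise parameters passed to every subject.
#' @param amp_rel_sd relative SD of the between-subject amplitude jitter.
#' @param ttp_sd SD (s) of the between-subject time-to-peak jitter
#'   (truncated to [4, 22] s).
#' @param trajectories trajectory table.
#' @return a list with `manifest` (data.frame: subject_id, age, decile,
#'   motion_seed, noise_seed) and `specs` (list of [subject_spec]).
#' @export
simulate_cohort <- function(n_per_decile = 10, seed,
                            noise_sigma = 0.01, ar1_rho = 0.3,
                            amp_rel_sd = 0.1, ttp_sd = 1.5,
                            trajectories = default_trajectories()) {
  tab <- decile_table()
  with_seed(seed, {
    specs <- list()
    rows <- list()
    sid <- 0L
    for (i in seq_len(nrow(tab))) {
      ages <- runif(n_per_decile, tab$age_min[i], tab$age_max[i])
      for (a in ages) {
        sid <- sid + 1L
        regions <- setdiff(trajectories$region, "background")
        rp <- do.call(rbind, lapply(regions, function(r) {
          p <- hr_from_age(a, r, trajectories)
          amp <- p$amplitude * (1 + rnorm(1, 0, amp_rel_sd))
          # jitter must not flip the response polarity
          if (p$amplitude < 0) amp <- min(amp, 0)
          if (p$amplitude > 0) amp <- max(amp, 0)
          ttp <- min(22, max(4, p$time_to_peak + rnorm(1, 0, ttp_sd)))
          data.frame(region = r, amplitude = amp, time_to_peak = ttp,
                     stringsAsFactors = FALSE)
        }))
        ms <- sample.int(1e8, 1)
        ns <- sample.int(1e8, 1)
        specs[[sid]] <- subject_spec(
          age = a, decile = tab$decile[i], region_params = rp,
          noise_sigma = noise_sigma, ar1_rho = ar1_rho,
          motion_seed = ms, noise_seed = ns)
        rows[[sid]] <- data.frame(
          subject_id = sprintf("sub-%03d", sid), age = a,
          decile = tab$decile[i], motion_seed = ms, noise_seed = ns,
          stringsAsFactors = FALSE)
      }
    }
    list(manifest = do.call(rbind, rows), specs = specs)
  })
}

#' NIfTI, motion and manifest input/output
#'
#' Thin wrappers around RNifti for the 4-D BOLD series and 3-D label map,
#' plus plain-text writers for motion traces (6-column whitespace
#' delimited) and cohort manifests (CSV).
#'
#' @param bold a [bold_dataset].
#' @param atlas a [toy_atlas].
#' @param motion a [motion_trace].
#' @param manifest a cohort manifest data.frame.
#' @param path file path.
#' @name nbr_io
NULL

#' @rdname nbr_io
#' @export
write_bold_nifti <- function(bold, path) {
  stopifnot(inherits(bold, "bold_dataset"))
  img <- RNifti::asNifti(bold$data)
  RNifti::pixdim(img) <- c(bold$voxel_dim, bold$tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname nbr_io
#' @export
read_bold_nifti <- function(path, label_map = NULL) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  bold_dataset(array(as.numeric(img), dim = dim(img)),
               tr = if (length(pd) >= 4) pd[4] else 1,
               label_map = label_map, voxel_dim = pd[1:3])
}

#' @rdname nbr_io
#' @export
write_label_nifti <- function(atlas, path) {
  stopifnot(inherits(atlas, "toy_atlas"))
  img <- RNifti::asNifti(atlas$labels)
  RNifti::pixdim(img) <- atlas$voxel_dim
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname nbr_io
#' @export
write_motion_txt <- function(motion, path) {
  stopifnot(inherits(motion, "motion_trace"))
  write.table(unclass(motion), path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname nbr_io
#' @export
read_motion_txt <- function(path) {
  motion_trace(as.matrix(read.table(path, header = FALSE)))
}

#' @rdname nbr_io
#' @export
write_cohort_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
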