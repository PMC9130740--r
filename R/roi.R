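# Subject-specific ROI construction, spatial-extent statistics, tertile
# splits and framewise displacement.

#' Define a subject-specific cubic ROI around the peak response voxel
#'
#' Locates the extremum of the requested polarity within the anatomical
#' mask (ties broken by lowest linear index) and centres a 3 x 3 x 3 cube
#' (27 voxels) on it, clipping at volume boundaries so a corner peak
#' yields 8 voxels. Only the peak is required to lie inside the mask; the
#' cube may extend beyond it.
#'
#' @param stat_map 3-D numeric array (e.g. a Z map).
#' @param anatomical_mask logical 3-D array, non-empty.
#' @param polarity `"positive"` (peak = maximum, must be > 0) or
#'   `"negative"` (peak = minimum, must be < 0).
#' @param region optional region name stored in the record.
#' @param half_width half edge length of the cube (1 gives 3^3 voxels).
#' @return an object of class `roi_record`: `region`, `peak` (0-based
#'   voxel index triple), `voxels` (1-based linear indices), `dim`,
#'   `n_voxels`, plus `mean_z`, `mean_beta`, `timecourse` slots filled by
#'   [extract_roi_measures].
#' @export
define_subject_roi <- function(stat_map, anatomical_mask,
                               polarity = c("positive", "negative"),
                               region = NULL, half_width = 1) {
  polarity <- match.arg(polarity)
  stopifnot(is.array(stat_map), length(dim(stat_map)) == 3,
            all(dim(anatomical_mask) == dim(stat_map)))
  if (!any(anatomical_mask)) stop("anatomical mask is empty")
  vals <- stat_map
  vals[!anatomical_mask] <- NA
  ok <- if (polarity == "positive") which(vals > 0) else which(vals < 0)
  if (length(ok) == 0) {
    stop(sprintf("no %s voxel inside the mask", polarity))
  }
  target <- if (polarity == "positive") max(vals[ok]) else min(vals[ok])
  peak_lin <- min(ok[vals[ok] == target])
  d <- dim(stat_map)
  p <- arrayInd(peak_lin, d)
  rng <- lapply(1:3, function(i) {
    max(1L, p[i] - half_width):min(d[i], p[i] + half_width)
  })
  g <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  voxels <- g[, 1] + (g[, 2] - 1L) * d[1] + (g[, 3] - 1L) * d[1] * d[2]
  structure(list(region = region, peak = as.integer(p) - 1L,
                 voxels = sort(voxels), dim = d,
                 n_voxels = length(voxels),
                 mean_z = NA_real_, mean_beta = NA_real_,
                 timecourse = NULL),
            class = "roi_record")
}

#' @export
print.roi_record <- function(x, ...) {
  cat(sprintf("<roi_record%s: peak (%s), %d voxels>\n",
              if (is.null(x$region)) "" else paste0(" ", x$region),
              paste(x$peak, collapse = ", "), x$n_voxels))
  invisible(x)
}

#' Extract mean statistics and timecourse for an ROI
#'
#' Fills an [define_subject_roi] record with the arithmetic means of the
#' Z and beta maps over the voxel set and the per-volume spatial mean
#' BOLD timecourse.
#'
#' @param roi an `roi_record`.
#' @param z_map,beta_map 3-D arrays commensurate with the ROI's volume.
#' @param data a [bold_dataset] (optional; required for the timecourse).
#' @return the `roi_record` with `mean_z`, `mean_beta` and (if `data`
#'   given) `timecourse` filled.
#' @export
extract_roi_measures <- function(roi, z_map = NULL, beta_map = NULL,
                                 data = NULL) {
  stopifnot(inherits(roi, "roi_record"))
  if (length(roi$voxels) == 0) stop("ROI voxel set is empty")
  if (!is.null(z_map)) {
    stopifnot(all(dim(z_map) == roi$dim))
    roi$mean_z <- mean(z_map[roi$voxels])
  }
  if (!is.null(beta_map)) {
    stopifnot(all(dim(beta_map) == roi$dim))
    roi$mean_beta <- mean(beta_map[roi$voxels])
  }
  if (!is.null(data)) {
    stopifnot(inherits(data, "bold_dataset"),
              all(dim(data$data)[1:3] == roi$dim))
    m <- matrix(data$data, nrow = prod(roi$dim))
    roi$timecourse <- colMeans(m[roi$voxels, , drop = FALSE])
  }
  roi
}

#' Spatial-extent statistics of PBR and NBR within a mask
#'
#' Counts suprathreshold positive and negative beta-weight voxels inside
#' the mask, thresholding each sign at `threshold_frac` of that sign's own
#' maximum magnitude (the per-sign reading of "5% of the subject's
#' maximum value"; set `per_sign = FALSE` for a single global-magnitude
#' threshold). Counts are converted to proportions of the mask size and
#' their ratio PBR/NBR is formed.
#'
#' @param beta_map 3-D numeric array.
#' @param mask logical 3-D array, non-empty.
#' @param threshold_frac threshold as a fraction of the maximum (default
#'   0.05); 0 counts every strictly-positive / strictly-negative voxel.
#' @param per_sign use per-sign maxima (default) or the global maximum
#'   absolute beta for both thresholds.
#' @return an object of class `extent_metrics`: `pbr_proportion`,
#'   `nbr_proportion`, `ratio` (NA when no NBR voxels survive) and
#'   `ratio_defined`.
#' @export
extent_metrics <- function(beta_map, mask, threshold_frac = 0.05,
                           per_sign = TRUE) {
  stopifnot(all(dim(beta_map) == dim(mask)), threshold_frac >= 0)
  if (!any(mask)) stop("mask is empty")
  vals <- beta_map[mask]
  n_mask <- length(vals)
  pos <- vals[vals > 0]
  neg <- vals[vals < 0]
  if (per_sign) {
    thr_p <- if (length(pos)) threshold_frac * max(pos) else Inf
    thr_n <- if (length(neg)) threshold_frac * max(abs(neg)) else Inf
  } else {
    thr_p <- thr_n <- threshold_frac * max(abs(vals))
  }
  n_pbr <- sum(pos > thr_p)
  n_nbr <- sum(abs(neg) > thr_n)
  pbr_prop <- n_pbr / n_mask
  nbr_prop <- n_nbr / n_mask
  structure(list(pbr_proportion = pbr_prop, nbr_proportion = nbr_prop,
                 ratio = if (nbr_prop > 0) pbr_prop / nbr_prop else NA_real_,
                 ratio_defined = nbr_prop > 0,
                 n_pbr = n_pbr, n_nbr = n_nbr, n_mask = n_mask),
            class = "extent_metrics")
}

#' Split subjects into tertiles by a statistic
#'
#' Ranks subjects by value (ties broken by input order) and partitions
#' them into lower, middle and upper thirds. Each group gets floor(n/3)
#' members; the remainder goes to the middle group first, then the lower
#' group, reproducing the 18/19/18 split of 55 subjects.
#'
#' @param values per-subject statistic, length >= 3.
#' @param ids subject identifiers (default positional indices).
#' @return a list with `lower`, `middle`, `upper`: ids in rank order.
#' @export
tertile_split <- function(values, ids = seq_along(values)) {
  n <- length(values)
  if (n < 3) stop("need at least 3 subjects for a tertile split")
  stopifnot(length(ids) == n)
  ord <- ids[order(values)]
  k <- n %/% 3
  r <- n %% 3
  n_lower <- k + as.integer(r == 2)
  n_middle <- k + as.integer(r >= 1)
  list(lower = ord[seq_len(n_lower)],
       middle = ord[n_lower + seq_len(n_middle)],
       upper = ord[(n_lower + n_middle) + seq_len(n - n_lower - n_middle)])
}

#' Framewise displacement
#'
#' Volume-to-volume head movement: the sum of absolute differences of the
#' three translations plus the three rotations converted to arc length on
#' a sphere (default radius 50 mm). The first volume has FD 0; the total
#' is the sum over volumes, the per-subject summary motion index.
#'
#' @param motion a [motion_trace] (or 6-column matrix) with >= 2 rows.
#' @param head_radius sphere radius in mm for the rotation conversion.
#' @return a list with `fd` (per-volume, mm) and `total` (mm).
#' @export
framewise_displacement <- function(motion, head_radius = 50) {
  m <- as.matrix(unclass(motion))
  if (nrow(m) < 2 || ncol(m) != 6 || !all(is.finite(m))) {
    stop("motion trace must be a finite matrix with >= 2 rows and 6 columns")
  }
  d <- abs(diff(m))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    head_radius * rowSums(d[, 4:6, drop = FALSE])
  fd <- c(0, fd)
  list(fd = fd, total = sum(fd))
}

#' Per-subject ROI and extent summary table
#'
#' Convenience assembler producing one tidy row per subject and region:
#' peak voxel index, mean Z, mean beta, extent proportions and ratio,
#' total FD and (once all subjects are collected) tertile labels.
#'
#' @param subject_id subject identifier.
#' @param roi a filled `roi_record`.
#' @param extent an `extent_metrics` (may be `NULL`).
#' @param fd_total total framewise displacement (may be `NA`).
#' @return a one-row data.frame.
#' @export
roi_summary_row <- function(subject_id, roi, extent = NULL, fd_total = NA) {
  data.frame(
    subject_id = subject_id,
    region = if (is.null(roi$region)) NA_character_ else roi$region,
    peak_x = roi$peak[1], peak_y = roi$peak[2], peak_z = roi$peak[3],
    mean_z = roi$mean_z, mean_beta = roi$mean_beta,
    pbr_proportion = if (is.null(extent)) NA_real_ else extent$pbr_proportion,
    nbr_proportion = if (is.null(extent)) NA_real_ else extent$nbr_proportion,
    pbr_nbr_ratio = if (is.null(extent)) NA_real_ else extent$ratio,
    fd_total = fd_total,
    stringsAsFactors = FALSE)
}
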