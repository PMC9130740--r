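# Second-level maps and cohort statistics.

# Accept a list of equal-dim 3-D arrays or an n_subjects x n_voxels
# matrix; return list(Y = matrix, dims = NULL or spatial dims).
as_subject_matrix <- function(subject_maps) {
  if (is.list(subject_maps)) {
    dims <- dim(subject_maps[[1]])
    stopifnot(all(vapply(subject_maps,
                         function(m) all(dim(m) == dims), logical(1))))
    list(Y = t(vapply(subject_maps, as.numeric,
                      numeric(prod(dims)))), dims = dims)
  } else {
    list(Y = as.matrix(subject_maps), dims = NULL)
  }
}

reshape_map <- function(v, dims) {
  if (is.null(dims)) v else array(v, dim = dims)
}

#' Second-level mean + covariate model
#'
#' Per-voxel OLS of subject beta maps on an intercept and a mean-subtracted
#' covariate (e.g. age). The intercept map is the group mean response; the
#' covariate map shows where the response correlates positively or
#' negatively with the covariate. Both coefficients are returned with
#' their Z statistics (negate for the opposite-sign contrast).
#'
#' @param subject_maps list of 3-D beta arrays (one per subject) or an
#'   n_subjects x n_voxels matrix.
#' @param covariate per-subject values, non-constant, length >= 3.
#' @return an object of class `group_result`: `mean_beta`, `mean_z`,
#'   `covariate_beta`, `covariate_z`, `df`.
#' @export
second_level_mean_covariate <- function(subject_maps, covariate) {
  sm <- as_subject_matrix(subject_maps)
  n <- nrow(sm$Y)
  stopifnot(n >= 3, length(covariate) == n)
  if (var(covariate) == 0) stop("covariate is constant")
  X <- cbind(1, covariate - mean(covariate))
  qx <- qr(X)
  beta <- qr.coef(qx, sm$Y)
  res <- sm$Y - X %*% beta
  df <- n - 2L
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qx))
  z_for <- function(i) {
    se <- sqrt(sigma2 * xtx_inv[i, i])
    t <- ifelse(se > 0, beta[i, ] / se, NA_real_)
    t_to_z(t, df)
  }
  structure(list(mean_beta = reshape_map(beta[1, ], sm$dims),
                 mean_z = reshape_map(z_for(1), sm$dims),
                 covariate_beta = reshape_map(beta[2, ], sm$dims),
                 covariate_z = reshape_map(z_for(2), sm$dims),
                 df = df),
            class = "group_result")
}

#' Voxelwise two-sample difference between decile groups
#'
#' Pooled-variance two-sample t test per voxel (group A minus group B),
#' mapped to Z. Voxels with zero pooled variance are flagged invalid (NA)
#' unless the mean difference is also zero, in which case Z = 0.
#'
#' @param maps_a,maps_b subject maps per group (list of arrays or
#'   subjects x voxels matrices), each with >= 2 subjects.
#' @return a list with `z` (array or vector), `df`, `valid`.
#' @export
pairwise_decile_difference <- function(maps_a, maps_b) {
  a <- as_subject_matrix(maps_a)
  b <- as_subject_matrix(maps_b)
  na <- nrow(a$Y); nb <- nrow(b$Y)
  stopifnot(na >= 2, nb >= 2, ncol(a$Y) == ncol(b$Y))
  ma <- colMeans(a$Y); mb <- colMeans(b$Y)
  ssa <- colSums(sweep(a$Y, 2, ma)^2)
  ssb <- colSums(sweep(b$Y, 2, mb)^2)
  df <- na + nb - 2L
  sp2 <- (ssa + ssb) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  diffm <- ma - mb
  t <- ifelse(se > 0, diffm / se, ifelse(diffm == 0, 0, NA_real_))
  list(z = reshape_map(t_to_z(t, df), a$dims), df = df,
       valid = reshape_map(!is.na(t), a$dims))
}

#' One-way ANOVA across groups
#'
#' Classical between/within sum-of-squares decomposition testing for an
#' effect of group (e.g. decile) on a per-subject statistic.
#'
#' @param groups list of numeric vectors, >= 2 groups of >= 2 values.
#' @return a list with `F`, `df1`, `df2`, `p`.
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, integer(1)) >= 2))
  y <- unlist(groups, use.names = FALSE)
  if (all(y == y[1])) stop("all values identical; ANOVA undefined (0/0)")
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  ot <- oneway.test(y ~ g, var.equal = TRUE)
  list(F = unname(ot$statistic), df1 = unname(ot$parameter[1]),
       df2 = unname(ot$parameter[2]), p = ot$p.value)
}

#' Pairwise post-hoc t tests
#'
#' Welch (unequal-variance) two-sample t test for every pair of groups.
#' p values are reported uncorrected with a Bonferroni column alongside;
#' no correction is ever applied silently.
#'
#' @param groups named or unnamed list of numeric vectors.
#' @return data.frame with columns `group1`, `group2`, `t`, `df`, `p`,
#'   `p_bonferroni`, `flagged` (TRUE where the variance was degenerate and
#'   the test undefined).
#' @export
posthoc_ttests <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group", seq_along(groups))
  pairs <- combn(seq_along(groups), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    ij <- pairs[, j]
    x <- groups[[ij[1]]]; y <- groups[[ij[2]]]
    tt <- tryCatch(t.test(x, y), error = function(e) NULL)
    if (is.null(tt)) {
      data.frame(group1 = nm[ij[1]], group2 = nm[ij[2]],
                 t = NA_real_, df = NA_real_, p = NA_real_,
                 flagged = TRUE, stringsAsFactors = FALSE)
    } else {
      data.frame(group1 = nm[ij[1]], group2 = nm[ij[2]],
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, flagged = FALSE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out[, c("group1", "group2", "t", "df", "p", "p_bonferroni", "flagged")]
}

#' Pearson correlation with significance
#'
#' Product-moment correlation; p from the t transform with n - 2 degrees
#' of freedom.
#'
#' @param x,y numeric vectors, n >= 3, each with positive variance.
#' @return a list with `r`, `p`, `n`.
#' @export
pearson_corr <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (var(x) == 0 || var(y) == 0) stop("zero variance input")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Residualize values on age
#'
#' Returns the residuals of a simple linear regression of `values` on
#' `ages` -- the "age-corrected" statistic used before correlating
#' responses between regions.
#'
#' @param values numeric vector.
#' @param ages numeric vector, non-constant.
#' @return numeric residual vector (orthogonal to `ages`).
#' @export
residualize_on_age <- function(values, ages) {
  stopifnot(length(values) == length(ages), length(values) >= 3)
  if (var(ages) == 0) stop("age is constant; cannot residualize")
  unname(resid(lm(values ~ ages)))
}

#' Incremental-variance (nested regression) F test
#'
#' Compares nested OLS models y ~ base vs y ~ base + added, reporting the
#' added predictor's incremental R-squared and the partial F test --
#' the check that a response statistic explains no variance beyond age.
#'
#' @param y response vector.
#' @param base_predictors matrix (or vector) of base-model predictors.
#' @param added_predictor additional predictor vector.
#' @return a list with `delta_r2`, `F`, `df1`, `df2`, `p`.
#' @export
nested_regression_f <- function(y, base_predictors, added_predictor) {
  base <- as.matrix(base_predictors)
  stopifnot(length(y) == nrow(base),
            length(added_predictor) == length(y),
            length(y) > ncol(base) + 2)
  r0 <- qr(cbind(1, base))$rank
  if (r0 < ncol(base) + 1) stop("base model is rank deficient")
  if (qr(cbind(1, base, added_predictor))$rank == r0) {
    stop("added predictor is collinear with the base model")
  }
  m0 <- lm(y ~ base)
  m1 <- lm(y ~ base + added_predictor)
  a <- anova(m0, m1)
  list(delta_r2 = summary(m1)$r.squared - summary(m0)$r.squared,
       F = a$F[2], df1 = a$Df[2], df2 = m1$df.residual, p = a$`Pr(>F)`[2])
}
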