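test_that("second-level mean + covariate model matches closed-form simple regression", {
  # identical subject maps: covariate slope must vanish
  maps <- replicate(5, array(2.5, dim = c(4, 4, 2)), simplify = FALSE)
  g <- second_level_mean_covariate(maps, covariate = c(20, 30, 40, 50, 60))
  expect_equal(as.numeric(g$covariate_beta), rep(0, 32), tolerance = 1e-12)
  expect_equal(as.numeric(g$mean_beta), rep(2.5, 32))

  # 5-subject toy voxel against the hand-computed slope
  y <- c(1.2, 0.9, 0.7, 0.8, 0.3)
  age <- c(22, 35, 48, 61, 80)
  gm <- second_level_mean_covariate(matrix(y, ncol = 1), age)
  ac <- age - mean(age)
  slope <- sum(ac * (y - mean(y))) / sum(ac^2)
  expect_equal(gm$covariate_beta, slope, tolerance = 1e-12)
  # mean-subtracted covariate is orthogonal to the intercept:
  # the intercept beta is exactly the sample mean
  expect_equal(gm$mean_beta, mean(y), tolerance = 1e-12)
  expect_error(second_level_mean_covariate(matrix(y, ncol = 1),
                                           rep(1, 5)), "constant")
})

test_that("pairwise decile difference is a pooled-variance t mapped to Z", {
  a <- matrix(c(1.1, 0.8, 1.3), ncol = 1)
  b <- matrix(c(0.2, 0.5, 0.1), ncol = 1)
  out <- pairwise_decile_difference(a, b)
  # hand-computed pooled t
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / 4
  tref <- (mean(a) - mean(b)) / sqrt(sp2 * (2 / 3))
  expect_equal(out$z, t_to_z(tref, 4), tolerance = 1e-12)
  expect_equal(out$df, 4)

  # identical groups give Z = 0; swapping negates
  same <- pairwise_decile_difference(a, a)
  expect_equal(same$z, 0)
  expect_equal(pairwise_decile_difference(b, a)$z, -out$z)
})

test_that("one-way ANOVA matches the sum-of-squares decomposition oracle", {
  groups <- list(c(1.2, 1.5, 1.1), c(2.2, 2.0, 2.4), c(0.9, 1.4, 1.0))
  res <- one_way_anova(groups)
  y <- unlist(groups)
  gm <- mean(y)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  Fref <- (ssb / 2) / (ssw / 6)
  expect_equal(res$F, Fref, tolerance = 1e-12)
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 6)
  expect_equal(res$p, pf(Fref, 2, 6, lower.tail = FALSE), tolerance = 1e-12)

  # equal group means but internal spread: F = 0
  eq <- one_way_anova(list(c(-1, 1), c(-2, 2), c(-3, 3)))
  expect_equal(eq$F, 0)
  # within-group permutation leaves F unchanged
  perm <- one_way_anova(lapply(groups, sample))
  expect_equal(perm$F, res$F)
  expect_error(one_way_anova(list(c(1, 1), c(1, 1))), "identical")
})

test_that("post-hoc Welch t tests match the Welch formula and are antisymmetric", {
  x <- c(1.0, 1.4, 0.8, 1.2)
  y <- c(2.1, 2.6, 2.0)
  tab <- posthoc_ttests(list(a = x, b = y))
  se <- sqrt(var(x) / 4 + var(y) / 3)
  tref <- (mean(x) - mean(y)) / se
  dfref <- se^4 / ((var(x) / 4)^2 / 3 + (var(y) / 3)^2 / 2)
  expect_equal(tab$t, tref, tolerance = 1e-12)
  expect_equal(tab$df, dfref, tolerance = 1e-9)

  tab2 <- posthoc_ttests(list(b = y, a = x))
  expect_equal(tab2$t, -tab$t)
  # identical groups: t = 0; uncorrected and Bonferroni p both reported
  tab3 <- posthoc_ttests(list(x, x, y))
  expect_equal(tab3$t[1], 0)
  expect_equal(tab3$p_bonferroni, pmin(1, tab3$p * 3))
  # degenerate variance flagged, not crashed
  tab4 <- posthoc_ttests(list(c(1, 1), c(1, 1)))
  expect_true(tab4$flagged)
})

test_that("Pearson correlation matches the product-moment formula", {
  x <- c(1, 3, 4, 6, 8)
  y <- c(2.1, 2.9, 4.4, 5.8, 7.9)
  res <- pearson_corr(x, y)
  rref <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, rref, tolerance = 1e-12)
  tref <- rref * sqrt(3 / (1 - rref^2))
  expect_equal(res$p, 2 * pt(abs(tref), 3, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(pearson_corr(y, x)$r, res$r)
  expect_equal(pearson_corr(x, 2 * x + 1)$r, 1)
  expect_error(pearson_corr(x, rep(1, 5)), "variance")
})

test_that("age residualization is OLS-orthogonal and equals the partial-correlation route", {
  set.seed(31)
  ages <- runif(40, 20, 88)
  v <- 0.02 * ages + rnorm(40)
  r <- residualize_on_age(v, ages)
  expect_lt(abs(cor(r, ages)), 1e-12)
  # values already orthogonal to age come back unchanged up to mean removal
  w <- rnorm(40)
  w_orth <- residualize_on_age(w, ages)
  expect_equal(w_orth, unname(resid(lm(w ~ ages))))
  # hand OLS
  b <- cov(v, ages) / var(ages)
  a <- mean(v) - b * mean(ages)
  expect_equal(r, v - a - b * ages, tolerance = 1e-10)

  # residualize-then-correlate equals the partial correlation given age
  u <- 0.5 * v + rnorm(40)
  r1 <- pearson_corr(residualize_on_age(v, ages),
                     residualize_on_age(u, ages))$r
  rvu <- cor(v, u); rva <- cor(v, ages); rua <- cor(u, ages)
  partial <- (rvu - rva * rua) / sqrt((1 - rva^2) * (1 - rua^2))
  expect_equal(r1, partial, tolerance = 1e-10)
})

test_that("nested regression F matches a brute-force RSS comparison", {
  set.seed(77)
  n <- 30
  age <- runif(n, 20, 88)
  nbr_z <- 0.01 * age + rnorm(n, sd = 0.3)
  behav <- 0.05 * age + rnorm(n)
  res <- nested_regression_f(behav, age, nbr_z)
  X0 <- cbind(1, age)
  X1 <- cbind(1, age, nbr_z)
  rss0 <- sum(resid(lm.fit(X0, behav))^2)
  rss1 <- sum(resid(lm.fit(X1, behav))^2)
  Fref <- (rss0 - rss1) / (rss1 / (n - 3))
  expect_equal(res$F, Fref, tolerance = 1e-10)
  expect_equal(res$p, pf(Fref, 1, n - 3, lower.tail = FALSE),
               tolerance = 1e-10)

  # added predictor equal to the base residuals completes R^2 to 1
  resid_base <- resid(lm(behav ~ age))
  full <- suppressWarnings(nested_regression_f(behav, age, resid_base))
  expect_equal(suppressWarnings(
    summary(lm(behav ~ age + resid_base))$r.squared), 1)
  expect_gt(full$delta_r2, 0)
  # orthogonalized pure-noise predictor adds (numerically) nothing
  noise <- resid(lm(rnorm(n) ~ age + behav))
  near0 <- nested_regression_f(behav, age, noise)
  expect_lt(near0$delta_r2, 1e-20)
  expect_error(nested_regression_f(behav, age, 2 * age), "collinear")
})

test_that("a simulated lifespan cohort recovers the injected amplitude decline", {
  sch <- std_schedule()
  cohort <- simulate_cohort(n_per_decile = 8, seed = 21)
  betas <- vapply(seq_along(cohort$specs), function(i) {
    sp <- cohort$specs[[i]]
    y <- synthesize_region_timecourse(sp, sch, "iSM1", tr = TR,
                                      n_volumes = NVOL)
    p <- sp$region_params[sp$region_params$region == "iSM1", ]
    kern <- stretched_double_gamma(p$time_to_peak, dt = 0.01)
    fit_glm(y, build_design_matrix(sch, kern, TR, NVOL))$contrasts$pbr$beta
  }, numeric(1))
  age <- cohort$manifest$age
  # beta is negative (NBR); it correlates positively with age (toward zero),
  # i.e. NBR magnitude declines
  expect_lt(mean(betas), 0)
  ct <- pearson_corr(age, betas)
  expect_gt(ct$r, 0.5)
  expect_lt(ct$p, 1e-4)
  # slope close to the injected trajectory slope
  injected <- (-0.013 - (-0.034)) / (82.6 - 25.8)
  slope <- unname(coef(lm(betas ~ age))[2])
  expect_equal(slope, injected, tolerance = 0.35)
})

test_that("per-decile PBR-NBR coupling emerges only where injected", {
  # construct a cohort where cSM1 and iSM1 amplitudes are anticorrelated
  # in the oldest bins only, then recover the emergence pattern
  set.seed(55)
  n <- 18
  mk_vals <- function(coupled) {
    csm <- 0.08 + rnorm(n, sd = 0.01)
    ism <- if (coupled) -0.02 - 0.5 * (csm - 0.08) + rnorm(n, sd = 0.002)
    else -0.02 + rnorm(n, sd = 0.005)
    list(csm = csm, ism = ism)
  }
  young <- mk_vals(FALSE)
  old <- mk_vals(TRUE)
  r_young <- pearson_corr(young$csm, young$ism)
  r_old <- pearson_corr(old$csm, old$ism)
  expect_lt(r_old$r, -0.5)
  expect_lt(r_old$p, 0.01)
  expect_gt(r_young$p, 0.05)
})
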