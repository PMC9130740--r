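test_that("generated paradigm honours trial counts, grid and SOA range", {
  s <- std_schedule(seed = 1)
  expect_s3_class(s, "event_schedule")
  expect_length(s$onsets, 128)
  expect_true(all(abs(s$onsets / 2 - round(s$onsets / 2)) < 1e-9))
  soa <- diff(s$onsets)
  expect_true(all(soa >= 2 - 1e-9))
  expect_true(all(soa <= 26 + 1e-9))
  expect_equal(min(soa), 2)
  expect_equal(max(soa), 26)
  expect_true(all(s$onsets + s$durations < s$run_length))
  # equal numbers of the three bimodal tones
  counts <- table(s$conditions)
  expect_equal(unname(counts[["audiovisual_300Hz"]]), 40)
  expect_equal(unname(counts[["audiovisual_600Hz"]]), 40)
  expect_equal(unname(counts[["audiovisual_1200Hz"]]), 40)
  expect_equal(sum(counts[c("audio_only", "visual_only")]), 8)
})

test_that("paradigm generation is deterministic, handles empty and errors on overpacking", {
  expect_identical(std_schedule(seed = 5), std_schedule(seed = 5))
  e <- generate_paradigm(n_bimodal = 0, n_unimodal = 0, seed = 1)
  expect_length(e$onsets, 0)
  expect_equal(e$run_length, 1.97 * 261)
  expect_error(generate_paradigm(n_bimodal = 400, n_unimodal = 0, seed = 1),
               "impossible packing")
})

test_that("lifespan trajectories hit the anchor values and interpolate linearly", {
  young <- hr_from_age(25.8, "iSM1")
  old <- hr_from_age(82.6, "iSM1")
  expect_equal(young$amplitude, -0.034)
  expect_equal(young$time_to_peak, 10)
  expect_equal(old$amplitude, -0.013)
  expect_equal(old$time_to_peak, 18)
  mid <- hr_from_age((25.8 + 82.6) / 2, "iSM1")
  expect_equal(mid$amplitude, (-0.034 - 0.013) / 2)
  expect_equal(mid$time_to_peak, 14)
  # stable PBR amplitudes, drifting latencies
  expect_equal(hr_from_age(30, "cSM1")$amplitude,
               hr_from_age(80, "cSM1")$amplitude)
  expect_equal(hr_from_age(25.8, "cSM1")$time_to_peak, 9.4)
  expect_equal(hr_from_age(82.6, "cSM1")$time_to_peak, 10.7)
  expect_equal(hr_from_age(25.8, "thalamus")$time_to_peak, 8.2)
  expect_equal(hr_from_age(82.6, "thalamus")$time_to_peak, 10.1)
  expect_error(hr_from_age(50, "cerebellum"), "unknown region")
})

test_that("noiseless region mean equals the direct convolution oracle", {
  sch <- short_schedule()
  spec <- test_spec(noise_sigma = 0, drift_coefs = numeric(0))
  y <- synthesize_region_timecourse(spec, sch, "iSM1", tr = TR,
                                    n_volumes = 120)
  p <- spec$region_params[spec$region_params$region == "iSM1", ]
  kern <- stretched_double_gamma(p$time_to_peak, dt = 0.01)
  expect_equal(y - 1, p$amplitude * oracle_convolve(sch, kern, TR, 120),
               tolerance = 1e-10)
})

test_that("null amplitudes give constant baseline; synthesis is deterministic and linear", {
  sch <- short_schedule()
  atlas <- toy_atlas(c(12, 12, 6))
  rp <- default_trajectories()
  rp0 <- data.frame(region = setdiff(rp$region, "background"),
                    amplitude = 0, time_to_peak = 8)
  spec0 <- subject_spec(age = 30, motion_seed = 1, noise_seed = 2,
                        region_params = rp0, noise_sigma = 0,
                        drift_coefs = numeric(0))
  out0 <- synthesize_subject(spec0, sch, atlas = atlas, tr = TR,
                             n_volumes = 120)
  expect_true(all(out0$bold$data == 1))

  spec <- test_spec(noise_sigma = 0.01)
  a <- synthesize_subject(spec, sch, atlas = atlas, tr = TR, n_volumes = 120)
  b <- synthesize_subject(spec, sch, atlas = atlas, tr = TR, n_volumes = 120)
  expect_identical(a$bold$data, b$bold$data)
  expect_identical(unclass(a$motion), unclass(b$motion))

  # doubling every amplitude doubles the noiseless deviation everywhere
  mk <- function(f) {
    rp2 <- spec$region_params
    rp2$amplitude <- rp2$amplitude * f
    subject_spec(age = spec$age, motion_seed = 1, noise_seed = 2,
                 region_params = rp2, noise_sigma = 0,
                 drift_coefs = numeric(0))
  }
  d1 <- synthesize_subject(mk(1), sch, atlas = atlas, tr = TR,
                           n_volumes = 120)$bold$data - 1
  d2 <- synthesize_subject(mk(2), sch, atlas = atlas, tr = TR,
                           n_volumes = 120)$bold$data - 1
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
})

test_that("subject spec enforces polarity and range invariants", {
  rp <- data.frame(region = "iSM1", amplitude = 0.02, time_to_peak = 10)
  expect_error(subject_spec(age = 30, motion_seed = 1, noise_seed = 2,
                            region_params = rp), "iSM1")
  expect_error(subject_spec(age = 99, motion_seed = 1, noise_seed = 2))
  expect_error(subject_spec(age = 30, motion_seed = 1, noise_seed = 2,
                            ar1_rho = 1.2))
})

test_that("simulated cohorts couple age to iSM1 amplitude and motion", {
  cohort <- simulate_cohort(n_per_decile = 8, seed = 3)
  expect_equal(nrow(cohort$manifest), 56)
  amp <- vapply(cohort$specs, function(s) {
    s$region_params$amplitude[s$region_params$region == "iSM1"]
  }, numeric(1))
  age <- cohort$manifest$age
  # amplitude rises toward zero with age
  expect_gt(cor(age, amp), 0.9)
  # motion: total FD grows with age on average
  fd <- vapply(cohort$specs, function(s) {
    framewise_displacement(generate_motion(s, 60))$total
  }, numeric(1))
  expect_gt(cor(age, fd), 0.3)
})

test_that("atlas regions are disjoint blocks and masks line up", {
  atlas <- toy_atlas()
  expect_equal(sort(unique(as.integer(atlas$labels))), 0:5)
  for (r in names(atlas$region_codes)) {
    expect_gt(sum(atlas_mask(atlas, r)), 0)
  }
  sm <- atlas_mask(atlas, c("cSM1", "iSM1"))
  expect_equal(sum(sm), sum(atlas_mask(atlas, "cSM1")) +
                 sum(atlas_mask(atlas, "iSM1")))
})

test_that("schedules, motion and HR timecourses round-trip through text formats", {
  dir <- withr::local_tempdir()
  s <- short_schedule()
  f <- file.path(dir, "events.tsv")
  write_events_tsv(s, f)
  s2 <- read_events_tsv(f, run_length = s$run_length)
  expect_equal(s2$onsets, s$onsets)
  expect_equal(s2$conditions, s$conditions)

  m <- generate_motion(test_spec(), 50)
  fm <- file.path(dir, "motion.txt")
  write_motion_txt(m, fm)
  expect_equal(unclass(read_motion_txt(fm)), unclass(m),
               tolerance = 1e-12, ignore_attr = TRUE)

  h <- canonical_double_gamma(dt = TR, window = 24)
  fh <- file.path(dir, "hr.csv")
  write_hr_csv(h, fh)
  h2 <- read_hr_csv(fh)
  expect_equal(h2$samples, h$samples)
  expect_equal(h2$dt, h$dt)
})

test_that("BOLD datasets round-trip through NIfTI with geometry preserved", {
  dir <- withr::local_tempdir()
  atlas <- toy_atlas(c(12, 12, 6))
  spec <- test_spec()
  out <- synthesize_subject(spec, short_schedule(), atlas = atlas,
                            tr = TR, n_volumes = 120)
  f <- file.path(dir, "bold.nii.gz")
  write_bold_nifti(out$bold, f)
  back <- read_bold_nifti(f)
  expect_equal(dim(back$data), dim(out$bold$data))
  expect_equal(back$tr, TR, tolerance = 1e-6)
  expect_equal(back$data, out$bold$data, tolerance = 1e-6,
               ignore_attr = TRUE)
  fl <- file.path(dir, "labels.nii.gz")
  write_label_nifti(atlas, fl)
  lab <- RNifti::readNifti(fl)
  expect_equal(array(as.integer(lab), dim(lab)), atlas$labels)
})
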