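# Shared fixtures: small, fast, built in code.

TR <- 1.97
NVOL <- 261

# Full-size study paradigm (cheap to build; reused across files).
std_schedule <- function(seed = 42) {
  generate_paradigm(n_bimodal = 120, n_unimodal = 8, min_soa = 2,
                    max_soa = 26, seed = seed)
}

# A short schedule for toy designs.
short_schedule <- function(n = 20, seed = 7, n_volumes = 120, tr = TR) {
  generate_paradigm(n_bimodal = n, n_unimodal = 0, min_soa = 2,
                    max_soa = 26, seed = seed, tr = tr,
                    n_volumes = n_volumes)
}

test_spec <- function(age = 25.8, noise_sigma = 0.01, ar1_rho = 0.3,
                      drift_coefs = c(0.005, -0.003), seed = 11) {
  subject_spec(age = age, motion_seed = seed, noise_seed = seed + 1,
               noise_sigma = noise_sigma, ar1_rho = ar1_rho,
               drift_coefs = drift_coefs)
}

# Direct convolution-sum oracle: event boxcars convolved with a kernel on
# a fine grid by explicit summation, sampled at volume times, with the
# same unit-extremum single-event scaling convention as the package.
oracle_convolve <- function(schedule, kernel, tr, n_volumes, dt = 0.01) {
  n_fine <- round(max(schedule$run_length, n_volumes * tr) / dt) + 1L
  k <- approx(kernel$times, kernel$samples,
              xout = seq(0, kernel$window, by = dt), rule = 1)$y
  k[is.na(k)] <- 0
  out <- numeric(n_fine + length(k))
  for (i in seq_along(schedule$onsets)) {
    a <- round(schedule$onsets[i] / dt) + 1L
    nb <- max(1L, round(schedule$durations[i] / dt))
    for (b in a:(a + nb - 1L)) {
      idx <- b:(b + length(k) - 1L)
      out[idx] <- out[idx] + k
    }
  }
  nb <- max(1L, round(median(schedule$durations) / dt))
  ref <- numeric(nb + length(k))
  for (b in seq_len(nb)) {
    ref[b:(b + length(k) - 1L)] <- ref[b:(b + length(k) - 1L)] + k
  }
  idx <- round((seq_len(n_volumes) - 1L) * tr / dt) + 1L
  out[idx] / max(abs(ref))
}
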