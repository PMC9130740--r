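# Lifespan trajectories of region haemodynamic responses.

# Decile mean ages anchoring the linear trajectories (youngest and oldest
# age bins of the cohort design).
AGE_YOUNG <- 25.8
AGE_OLD <- 82.6

#' Age-decile definitions
#'
#' The seven equal-width adult age bins (Twenties through Eighties) with
#' the age ranges and mean ages used to anchor the lifespan trajectories.
#'
#' @return a data.frame with columns `decile`, `age_min`, `age_max`,
#'   `mean_age`.
#' @export
decile_table <- function() {
  data.frame(
    decile = c("Twenties", "Thirties", "Forties", "Fifties",
               "Sixties", "Seventies", "Eighties"),
    age_min = c(20, 32, 42, 52, 61, 71, 80),
    age_max = c(29, 38, 48, 58, 68, 78, 88),
    mean_age = c(25.8, 34.7, 44.9, 54.1, 64.2, 73.9, 82.6),
    stringsAsFactors = FALSE)
}

#' Assign an age to its decile bin
#'
#' Ages inside a bin's range map to that bin; ages in the small gaps
#' between bins map to the bin with the nearest mean age.
#'
#' @param age age in years.
#' @return decile label (character).
#' @export
decile_for_age <- function(age) {
  stopifnot(is.numeric(age), all(age >= 18 & age <= 88))
  tab <- decile_table()
  vapply(age, function(a) {
    hit <- which(a >= tab$age_min & a <= tab$age_max)
    if (length(hit) == 1) return(tab$decile[hit])
    tab$decile[which.min(abs(tab$mean_age - a))]
  }, character(1))
}

#' Default lifespan HR trajectories
#'
#' Per-region endpoints of the linear age trajectories of HR amplitude
#' (fractional signal change, signed) and time-to-peak (s), anchored at
#' the mean ages of the youngest (25.8 y) and oldest (82.6 y) deciles.
#' The ipsilateral sensorimotor (iSM1) NBR amplitude shallows from -0.034
#' to -0.013 while its time-to-peak lengthens from 10 s to 18 s; cSM1 and
#' thalamus latencies lengthen modestly (9.4 to 10.7 s and 8.2 to 10.1 s);
#' all PBR amplitudes and the PCC NBR stay constant.
#'
#' @return a data.frame with one row per region: `region`, `amp_young`,
#'   `amp_old`, `ttp_young`, `ttp_old`.
#' @export
default_trajectories <- function() {
  data.frame(
    region = c("cSM1", "iSM1", "V1", "thalamus", "PCC", "background"),
    amp_young = c(0.08, -0.034, 0.10, 0.04, -0.03, 0),
    amp_old   = c(0.08, -0.013, 0.10, 0.04, -0.03, 0),
    ttp_young = c(9.4, 10, 8.8, 8.2, 11, 5),
    ttp_old   = c(10.7, 18, 8.8, 10.1, 11, 5),
    stringsAsFactors = FALSE)
}

#' Region HR parameters at a given age
#'
#' Linearly interpolates (and, beyond the anchor ages, extrapolates) the
#' region's amplitude and time-to-peak trajectories in age. Over the
#' supported range [18, 88] years all amplitudes keep their sign.
#'
#' @param age age in years, in [18, 88].
#' @param region region name, one of `default_trajectories()$region`.
#' @param config trajectory table in the format of
#'   [default_trajectories()].
#' @return a list with `amplitude` (fractional signal change, signed) and
#'   `time_to_peak` (seconds).
#' @export
hr_from_age <- function(age, region, config = default_trajectories()) {
  stopifnot(is.numeric(age), length(age) == 1, age >= 18, age <= 88)
  row <- config[config$region == region, , drop = FALSE]
  if (nrow(row) != 1) {
    stop(sprintf("unknown region '%s'; expected one of: %s", region,
                 paste(config$region, collapse = ", ")))
  }
  f <- (age - AGE_YOUNG) / (AGE_OLD - AGE_YOUNG)
  list(amplitude = row$amp_young + f * (row$amp_old - row$amp_young),
       time_to_peak = row$ttp_young + f * (row$ttp_old - row$ttp_young))
}
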