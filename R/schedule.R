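#' Stimulus condition labels of the sensorimotor task
#'
#' The five modeled conditions: three bimodal audiovisual conditions (one
#' per tone frequency) and two unimodal catch conditions.
#'
#' @export
task_conditions <- function() {
  c("audiovisual_300Hz", "audiovisual_600Hz", "audiovisual_1200Hz",
    "audio_only", "visual_only")
}

#' Event schedule
#'
#' Trial onsets, durations and condition labels defining the neural-input
#' delta train of an event-related run.
#'
#' @param onsets numeric vector of trial onsets in seconds from run start,
#'   strictly increasing.
#' @param durations numeric vector of stimulus durations in seconds
#'   (recycled; default 0.05, the 50 ms delta convention).
#' @param conditions character vector of condition labels, one per trial.
#' @param run_length run duration in seconds; every onset + duration must
#'   fall strictly inside it.
#' @return an object of class `event_schedule`.
#' @export
event_schedule <- function(onsets, durations = 0.05, conditions, run_length) {
  onsets <- as.numeric(onsets)
  n <- length(onsets)
  durations <- rep_len(as.numeric(durations), n)
  conditions <- rep_len(as.character(conditions), n)
  stopifnot(is.numeric(run_length), run_length > 0, all(is.finite(onsets)))
  if (n > 1 && any(diff(onsets) <= 0)) {
    stop("event onsets must be strictly increasing")
  }
  if (n > 0 && (any(onsets < 0) || any(onsets + durations >= run_length))) {
    stop("all onsets + durations must lie inside [0, run_length)")
  }
  structure(list(onsets = onsets, durations = durations,
                 conditions = conditions, run_length = run_length),
            class = "event_schedule")
}

#' @export
print.event_schedule <- function(x, ...) {
  cat(sprintf("<event_schedule: %d trials over %.1f s>\n",
              length(x$onsets), x$run_length))
  if (length(x$onsets) > 1) {
    soa <- diff(x$onsets)
    cat(sprintf("  SOA range %.2f-%.2f s, mean %.2f s\n",
                min(soa), max(soa), mean(soa)))
  }
  invisible(x)
}

#' Number of trials in a schedule
#' @param x an `event_schedule`.
#' @param ... ignored.
#' @export
length.event_schedule <- function(x) length(x$onsets)

#' Generate a rapid event-related paradigm
#'
#' Places trials on a `min_soa`-second grid with pseudo-random null gaps so
#' that observed stimulus onset asynchronies span `[min_soa, max_soa]`,
#' emulating an m-sequence-optimized rapid design (the literal binary
#' m-sequence construction is under-determined and left as future work; a
#' grid-based pseudo-random scheduler constrained to the same SOA range is
#' used instead). Bimodal trials are split equally across the three tone
#' frequencies and unimodal trials across audio-only/visual-only, all in
#' pseudo-random order. Deterministic given `seed`.
#'
#' @param n_bimodal number of bimodal audiovisual trials (study value 120).
#' @param n_unimodal number of unimodal catch trials (study value 8).
#' @param min_soa minimal stimulus onset asynchrony in seconds (also the
#'   placement grid step).
#' @param max_soa maximal SOA in seconds.
#' @param seed integer RNG seed (mandatory).
#' @param tr repetition time in seconds, used for the default run length.
#' @param n_volumes number of volumes, used for the default run length.
#' @param run_length run duration in seconds.
#' @param trial_duration stimulus duration in seconds (50 ms default).
#' @return an [event_schedule].
#' @export
generate_paradigm <- function(n_bimodal = 120, n_unimodal = 8,
                              min_soa = 2, max_soa = 26, seed,
                              tr = 1.97, n_volumes = 261,
                              run_length = tr * n_volumes,
                              trial_duration = 0.05) {
  stopifnot(min_soa > 0, max_soa >= min_soa,
            n_bimodal >= 0, n_unimodal >= 0)
  n <- n_bimodal + n_unimodal
  if (n == 0) {
    return(event_schedule(numeric(0), trial_duration, character(0),
                          run_length))
  }
  max_slots <- floor((run_length - trial_duration - 1e-9) / min_soa)
  if (n > max_slots) {
    stop(sprintf(
      "impossible packing: %d trials need %d grid slots at min SOA %.3g s but the run holds only %d",
      n, n, min_soa, max_slots))
  }
  gap_max <- max(1L, floor(max_soa / min_soa))
  with_seed(seed, {
    # Geometric-flavoured gap distribution gives the short-SOA-dominated
    # mix of a rapid design (mean SOA ~4 s for the study's trial counts).
    gaps <- sample.int(gap_max, n, replace = TRUE, prob = 0.55^seq_len(gap_max))
    if (n >= 3 && gap_max > 1) {
      # guarantee that the observed SOAs span the requested range
      pick <- sample.int(n - 1, 2) + 1L
      gaps[pick[1]] <- 1L
      gaps[pick[2]] <- gap_max
      protected <- pick[2]
    } else {
      protected <- integer(0)
    }
    while (sum(gaps) > max_slots) {
      shrinkable <- setdiff(which(gaps == max(gaps[-protected])), protected)
      if (length(shrinkable) == 0) shrinkable <- which.max(gaps)
      i <- shrinkable[1]
      gaps[i] <- gaps[i] - 1L
    }
    onsets <- cumsum(gaps) * min_soa
    conds <- task_conditions()
    n3 <- n_bimodal %/% 3
    bi <- c(rep(conds[1:3], n3),
            sample(conds[1:3], n_bimodal - 3 * n3))
    uni <- c(rep(conds[4], ceiling(n_unimodal / 2)),
             rep(conds[5], floor(n_unimodal / 2)))
    labels <- sample(c(bi, uni))
    event_schedule(onsets, trial_duration, labels, run_length)
  })
}

#' Read / write BIDS-style events tables
#'
#' Tab-separated with columns `onset`, `duration`, `trial_type`.
#'
#' @param schedule an [event_schedule].
#' @param path file path.
#' @param run_length run duration in seconds (needed when reading, since
#'   the table does not store it).
#' @return `read_events_tsv` returns an [event_schedule].
#' @export
write_events_tsv <- function(schedule, path) {
  stopifnot(inherits(schedule, "event_schedule"))
  write.table(data.frame(onset = schedule$onsets,
                         duration = schedule$durations,
                         trial_type = schedule$conditions),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path, run_length) {
  d <- read.table(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  event_schedule(d$onset, d$duration, d$trial_type, run_length)
}
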