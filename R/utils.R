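# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. Seeds are explicit arguments throughout the package, never
# ambient state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Convert t statistics to Z statistics
#'
#' Maps a t statistic with `df` degrees of freedom through its cumulative
#' distribution and the standard-normal quantile, working in log-probability
#' space so large |t| values do not saturate. The map is monotone and odd.
#'
#' @param t numeric vector of t statistics.
#' @param df degrees of freedom.
#' @return numeric vector of Z statistics.
#' @export
t_to_z <- function(t, df) {
  stopifnot(df > 0)
  z <- numeric(length(t))
  neg <- !is.na(t) & t < 0
  z[neg] <- qnorm(pt(t[neg], df, lower.tail = TRUE, log.p = TRUE),
                  log.p = TRUE)
  z[!neg] <- -qnorm(pt(t[!neg], df, lower.tail = FALSE, log.p = TRUE),
                    log.p = TRUE)
  z[is.na(t)] <- NA_real_
  z
}

# Linear convolution via FFT, zero-padded to a highly composite length so
# the transform stays O(n log n) for any input size.
fft_convolve <- function(x, k) {
  n <- length(x) + length(k) - 1L
  N <- stats::nextn(n, 2L)
  xf <- stats::fft(c(x, numeric(N - length(x))))
  kf <- stats::fft(c(k, numeric(N - length(k))))
  Re(stats::fft(xf * kf, inverse = TRUE))[seq_len(n)] / N
}

# Polynomial drift basis on time scaled to [-1, 1]: columns t, t^2, ..., t^order.
# An intercept is supplied separately by callers.
drift_basis <- function(n_volumes, order) {
  if (order < 1L) return(matrix(numeric(0), nrow = n_volumes, ncol = 0))
  tt <- seq(-1, 1, length.out = n_volumes)
  out <- vapply(seq_len(order), function(k) tt^k, numeric(n_volumes))
  colnames(out) <- paste0("drift_", seq_len(order))
  out
}
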