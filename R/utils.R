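#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rexp rpois rbinom quantile sd var median
#'   ecdf fft mvfft t.test wilcox.test ks.test cor.test kmeans prcomp
#'   p.adjust pt approx qnorm setNames
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Two-sample Kolmogorov-Smirnov distance
#'
#' Maximum absolute difference between the empirical CDFs of two samples,
#' evaluated over the pooled sample points.
#'
#' @param x,y numeric vectors.
#' @return the KS distance, a number in \[0, 1\].
#' @export
ks_distance <- function(x, y) {
  x <- sort(x[is.finite(x)]); y <- sort(y[is.finite(y)])
  if (!length(x) || !length(y)) stop("ks_distance needs nonempty samples")
  pts <- sort(c(x, y))
  fx <- findInterval(pts, x) / length(x)
  fy <- findInterval(pts, y) / length(y)
  max(abs(fx - fy))
}

#' Bonferroni correction
#'
#' Familywise-error control by multiplying each p-value by the number of
#' comparisons, capped at 1: p_adj = min(1, m * p).
#'
#' @param p vector of raw p-values.
#' @param m number of comparisons; defaults to `length(p)`.
#' @export
bonferroni <- function(p, m = length(p)) pmin(1, m * p)

# Centered moving average over an odd window of n samples; edges use the
# available samples only (shrinking window).
moving_average <- function(x, n) {
  if (n <= 1L) return(x)
  if (n %% 2L == 0L) n <- n + 1L
  cs <- cumsum(c(0, x))
  half <- (n - 1L) %/% 2L
  i <- seq_along(x)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, length(x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / n)  # periodic Hann (FFT use)
}

# Deterministic sub-seed derivation so that independent generator stages use
# independent-looking but fully reproducible RNG streams, and so that paired
# conditions share random draws (common random numbers).
sub_seed <- function(seed, offset) {
  (as.integer(seed) * 97L + as.integer(offset) * 10007L) %% 2147483629L
}

# run-length periods of a state vector sampled at `dt` seconds, starting at t0
runs_to_periods <- function(states, dt, t0 = 0) {
  r <- rle(as.character(states))
  ends <- cumsum(r$lengths)
  starts <- c(0L, head(ends, -1L))
  data.frame(start_s = t0 + starts * dt, end_s = t0 + ends * dt,
             state = r$values, stringsAsFactors = FALSE)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
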