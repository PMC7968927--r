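# Signal conditioning shared by all downstream stages: artifact rejection,
# baseline correction, session z-scoring, Butterworth filtering, and
# windowed band-power spectrograms.

#' Construct an electrophysiology channel
#'
#' A single 1-channel time series (LFP, EEG or EMG) with its sample rate and
#' a per-sample artifact mask. All downstream statistics (means, SDs,
#' spectrograms) ignore masked samples.
#'
#' @param samples numeric vector, raw volts or z-units.
#' @param sample_rate sampling rate in Hz (> 0).
#' @param channel one of "LFP", "EEG", "EMG".
#' @param session_id opaque session identifier.
#' @param artifact_mask logical vector, `TRUE` where a sample is an artifact;
#'   defaults to all-`FALSE`.
#' @param zscored logical flag: samples already in session z-units.
#' @return an object of class `ephys_channel`.
#' @export
ephys_channel <- function(samples, sample_rate, channel = c("LFP", "EEG", "EMG"),
                          session_id = "session", artifact_mask = NULL,
                          zscored = FALSE) {
  channel <- match.arg(channel)
  samples <- as.numeric(samples)
  if (!is.numeric(sample_rate) || sample_rate <= 0) stopf("sample_rate must be > 0")
  if (is.null(artifact_mask)) artifact_mask <- rep(FALSE, length(samples))
  if (length(artifact_mask) != length(samples))
    stopf("artifact_mask length (%d) != samples length (%d)",
          length(artifact_mask), length(samples))
  structure(list(samples = samples, sample_rate = sample_rate,
                 channel = channel, session_id = session_id,
                 artifact_mask = as.logical(artifact_mask), zscored = zscored),
            class = "ephys_channel")
}

#' @export
print.ephys_channel <- function(x, ...) {
  cat(sprintf("<ephys_channel %s/%s: %d samples @ %g Hz (%.1f s), %d masked%s>\n",
              x$session_id, x$channel, length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate, sum(x$artifact_mask),
              if (isTRUE(x$zscored)) ", z-scored" else ""))
  invisible(x)
}

duration_s <- function(channel) length(channel$samples) / channel$sample_rate

#' Flag movement artifacts by an SD threshold
#'
#' Samples deviating from the session mean by more than `threshold_sd`
#' standard deviations are flagged in the artifact mask and excluded from all
#' later means and SDs. Mean and SD are computed over the currently unmasked
#' samples of the whole session. A constant signal (SD = 0) flags nothing.
#'
#' @param channel an [ephys_channel].
#' @param threshold_sd rejection threshold in SD units (default 5).
#' @return the channel with an updated `artifact_mask`.
#' @export
remove_artifacts <- function(channel, threshold_sd = 5) {
  x <- channel$samples
  if (length(x) < 2L) stopf("remove_artifacts needs at least 2 samples")
  keep <- !channel$artifact_mask
  mu <- mean(x[keep])
  sg <- sd(x[keep])
  if (is.na(sg) || sg == 0) return(channel)
  bad <- abs(x - mu) > threshold_sd * sg
  channel$artifact_mask <- channel$artifact_mask | bad
  channel
}

#' Remove drifting baseline with a high-pass filter
#'
#' Zero-phase second-order Butterworth high-pass; attenuates DC and drift
#' below `cutoff_hz` so the output is approximately zero-mean.
#'
#' @param channel an [ephys_channel].
#' @param cutoff_hz high-pass cutoff in Hz (default 0.3).
#' @export
highpass_baseline <- function(channel, cutoff_hz = 0.3) {
  if (channel$sample_rate <= 2 * cutoff_hz)
    stopf("cutoff (%g Hz) must be below the Nyquist frequency", cutoff_hz)
  channel$samples <- butter_apply(channel$samples, channel$sample_rate,
                                  "high", 2L, cutoff_hz)
  channel
}

#' Session-pooled z-scoring
#'
#' Pools the unmasked samples of all channels in the group (all recordings of
#' the same session/day for a given channel type), and applies one affine
#' transform so the pooled samples have mean 0 and population SD 1.
#'
#' @param channels a single [ephys_channel] or a list of them (same channel
#'   type across the group).
#' @return the input with samples in z-units (list in, list out).
#' @export
zscore_session <- function(channels) {
  single <- inherits(channels, "ephys_channel")
  if (single) channels <- list(channels)
  types <- vapply(channels, `[[`, "", "channel")
  if (length(unique(types)) != 1L)
    stopf("zscore_session pools one channel type; got: %s",
          paste(unique(types), collapse = ", "))
  pooled <- unlist(lapply(channels, function(ch) ch$samples[!ch$artifact_mask]))
  mu <- mean(pooled)
  sg <- sqrt(mean((pooled - mu)^2))  # population SD
  if (!is.finite(sg) || sg == 0) stopf("pooled SD is zero; cannot z-score")
  out <- lapply(channels, function(ch) {
    ch$samples <- (ch$samples - mu) / sg
    ch$zscored <- TRUE
    ch
  })
  if (single) out[[1L]] else out
}

# one-pass IIR y = filter(b, a, x) with zero initial conditions, via
# C-level convolution + recursive filters (avoids per-call ts overhead)
iir_filter <- function(b, a, x) {
  nb <- length(b)
  v <- stats::filter(c(numeric(nb - 1L), x), b, method = "convolution",
                     sides = 1L)
  v <- as.numeric(v)[nb:(nb - 1L + length(x))]
  if (length(a) > 1L)
    v <- as.numeric(stats::filter(v, -a[-1L] / a[1L], method = "recursive"))
  v / a[1L]
}

# zero-phase (forward-backward) application
filtfilt_ba <- function(b, a, x) {
  y <- iir_filter(b, a, x)
  rev(iir_filter(b, a, rev(y)))
}

butter_apply <- function(x, fs, type, order, cutoff_hz) {
  w <- cutoff_hz / (fs / 2)
  if (any(w >= 1)) stopf("cutoff at or above Nyquist (%g Hz)", fs / 2)
  if (any(w <= 0)) stopf("cutoff must be positive")
  if (order < 1L) stopf("filter order must be >= 1")
  stable <- function(bf) all(Mod(polyroot(rev(bf$a))) < 1 - 1e-9)
  bf <- signal::butter(order, w, type = type)
  if (stable(bf)) return(filtfilt_ba(bf$b, bf$a, x))
  if (type == "pass") {
    # narrow low bands can be numerically unstable as a single design;
    # an equivalent high-pass + low-pass cascade is well conditioned
    hp <- signal::butter(max(2L, order %/% 2L), w[1], type = "high")
    lp <- signal::butter(order, w[2], type = "low")
    if (stable(hp) && stable(lp))
      return(filtfilt_ba(lp$b, lp$a, filtfilt_ba(hp$b, hp$a, x)))
  }
  stopf("unstable Butterworth design (order %d, type %s)", order, type)
}

#' Zero-phase Butterworth filtering
#'
#' Forward-backward (zero-phase) application, so peak and trough timing is
#' preserved for the duration gates downstream.
#'
#' @param channel an [ephys_channel].
#' @param kind "highpass", "lowpass" or "bandpass".
#' @param order filter order (>= 1).
#' @param cutoff_hz one cutoff for high/lowpass, length-2 `c(lo, hi)` for
#'   bandpass, in Hz.
#' @export
butter_filter <- function(channel, kind = c("highpass", "lowpass", "bandpass"),
                          order, cutoff_hz) {
  kind <- match.arg(kind)
  type <- switch(kind, highpass = "high", lowpass = "low", bandpass = "pass")
  if (kind == "bandpass" && length(cutoff_hz) != 2L)
    stopf("bandpass needs cutoff_hz = c(lo, hi)")
  channel$samples <- butter_apply(channel$samples, channel$sample_rate,
                                  type, order, cutoff_hz)
  channel
}

#' Default spectral bands
#'
#' Slow (0.5-4 Hz), theta (6-10 Hz), mid (8-20 Hz) and high-gamma
#' (80-100 Hz); the slow-wave ratio used for scoring is slow/mid.
#' @export
default_bands <- function() {
  list(slow = c(0.5, 4), theta = c(6, 10), mid = c(8, 20),
       high_gamma = c(80, 100))
}

#' Windowed band-power spectrogram
#'
#' Moving-window band powers: a Hann-tapered periodogram per window,
#' integrated over each named band. Frames whose window overlaps masked
#' artifact samples by more than 50% are flagged invalid and dropped from
#' scoring.
#'
#' @param channel an [ephys_channel].
#' @param window_s window length in seconds (default 10).
#' @param step_s step between window centers in seconds (default 5).
#' @param bands named list of `c(lo, hi)` band edges in Hz.
#' @return a `band_spectrogram`: list with `frame_times` (window centers, s),
#'   `powers` (frames x bands matrix), `valid`, `window_s`, `step_s`.
#' @export
band_spectrogram <- function(channel, window_s = 10, step_s = 5,
                             bands = default_bands()) {
  fs <- channel$sample_rate
  if (window_s < step_s) stopf("window_s must be >= step_s")
  hi_edges <- vapply(bands, max, 0)
  if (any(hi_edges > fs / 2)) stopf("band above Nyquist (%g Hz)", fs / 2)
  nwin <- round(window_s * fs)
  nstep <- round(step_s * fs)
  n <- length(channel$samples)
  if (n < nwin) stopf("signal shorter than one window")
  starts <- seq(1L, n - nwin + 1L, by = nstep)
  centers <- (starts - 1L + nwin / 2) / fs
  w <- hann_window(nwin)
  wss <- sum(w^2)
  freqs <- (seq_len(nwin %/% 2L + 1L) - 1L) * fs / nwin

  x <- channel$samples
  x[channel$artifact_mask] <- 0  # masked samples carry no power
  segs <- matrix(0, nrow = nwin, ncol = length(starts))
  for (j in seq_along(starts)) {
    seg <- x[starts[j]:(starts[j] + nwin - 1L)]
    segs[, j] <- (seg - mean(seg)) * w
  }
  X <- mvfft(segs)[seq_along(freqs), , drop = FALSE]
  # one-sided PSD (power per Hz); doubling interior bins
  psd <- (Mod(X)^2) / (fs * wss)
  if (nrow(psd) > 2L) psd[2:(nrow(psd) - 1L), ] <- 2 * psd[2:(nrow(psd) - 1L), ]
  df <- fs / nwin

  powers <- vapply(bands, function(b) {
    sel <- freqs >= b[1] & freqs <= b[2]
    colSums(psd[sel, , drop = FALSE]) * df
  }, numeric(length(starts)))
  powers <- matrix(powers, ncol = length(bands),
                   dimnames = list(NULL, names(bands)))

  mask_frac <- vapply(seq_along(starts), function(j) {
    mean(channel$artifact_mask[starts[j]:(starts[j] + nwin - 1L)])
  }, 0)
  structure(list(frame_times = centers, powers = powers,
                 valid = mask_frac <= 0.5, window_s = window_s,
                 step_s = step_s, bands = bands, sample_rate = fs,
                 zscored = FALSE),
            class = "band_spectrogram")
}

# Total power per frame (for Parseval-type bounds in tests)
frame_total_power <- function(channel, window_s = 10, step_s = 5) {
  fs <- channel$sample_rate
  nwin <- round(window_s * fs)
  nstep <- round(step_s * fs)
  starts <- seq(1L, length(channel$samples) - nwin + 1L, by = nstep)
  vapply(starts, function(s) {
    seg <- channel$samples[s:(s + nwin - 1L)]
    mean((seg - mean(seg))^2)
  }, 0)
}
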