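# Slow-wave detection in NREM sleep: candidate extraction at
# positive-to-negative zero crossings of the 0.1-4 Hz filtered signal,
# UP/DOWN polarity verification via nested high-gamma, and percentile/
# duration classification into slow oscillations vs delta waves.

#' Filter a channel into the slow-wave band
#'
#' The two-filter cascade used for wave detection: zero-phase second-order
#' Butterworth high-pass at 0.1 Hz, then fourth-order low-pass at 4 Hz.
#'
#' @param channel z-scored [ephys_channel].
#' @export
slow_wave_filter <- function(channel) {
  butter_filter(butter_filter(channel, "highpass", 2L, 0.1),
                "lowpass", 4L, 4)
}

#' Detect slow-wave candidates
#'
#' One candidate per positive-to-negative zero crossing inside NREM: the
#' preceding peak is the maximum since the previous negative-to-positive
#' crossing, the following trough the minimum up to the next one.
#'
#' @param filtered z-scored channel filtered by [slow_wave_filter()].
#' @param nrem_periods data frame (start_s, end_s) of NREM periods.
#' @return data frame: zero_cross_time, peak_amp, trough_amp, p2t_duration_ms,
#'   peak_time, trough_time.
#' @export
detect_candidates <- function(filtered, nrem_periods) {
  empty <- data.frame(zero_cross_time = numeric(0), peak_amp = numeric(0),
                      trough_amp = numeric(0), p2t_duration_ms = numeric(0),
                      peak_time = numeric(0), trough_time = numeric(0))
  if (is.null(nrem_periods) || !nrow(nrem_periods)) return(empty)
  x <- filtered$samples
  fs <- filtered$sample_rate
  sgn <- sign(x)
  sgn[sgn == 0] <- 1
  d <- diff(sgn)
  p2n <- which(d < 0)       # crossing between i and i+1
  n2p <- which(d > 0)
  if (!length(p2n)) return(empty)
  t_p2n <- (p2n - 0.5) / fs
  inside <- in_periods(t_p2n, nrem_periods)
  i <- p2n[inside]
  if (!length(i)) return(empty)
  # signal start/end act as implicit flanking crossings
  n2p_ext <- c(0L, n2p, length(x))
  pos <- findInterval(i, n2p_ext)
  a <- n2p_ext[pos]
  b <- n2p_ext[pos + 1L]
  m <- length(i)
  pk_i <- tr_i <- integer(m)
  for (k in seq_len(m)) {
    pk_i[k] <- which.max(x[(a[k] + 1L):i[k]]) + a[k]
    tr_i[k] <- which.min(x[(i[k] + 1L):b[k]]) + i[k]
  }
  data.frame(zero_cross_time = (i - 0.5) / fs, peak_amp = x[pk_i],
             trough_amp = x[tr_i],
             p2t_duration_ms = (tr_i - pk_i) / fs * 1000,
             peak_time = (pk_i - 0.5) / fs, trough_time = (tr_i - 0.5) / fs)
}

#' Verify UP/DOWN polarity with nested high-gamma
#'
#' Gamma oscillations nest in UP states, so candidate troughs (UP) should
#' carry more 80-100 Hz amplitude than candidate peaks (DOWN). If the mean
#' peak high-gamma strictly exceeds the mean trough high-gamma, the signal
#' is inverted and detection re-run.
#'
#' @param raw z-scored (unfiltered) [ephys_channel].
#' @param candidates data frame from [detect_candidates()].
#' @param nrem_periods NREM periods (for the re-run after inversion).
#' @param window_s half-width of the amplitude window around each extremum
#'   (default 0.05 s).
#' @return list(candidates, inverted, peak_gamma, trough_gamma).
#' @export
verify_polarity <- function(raw, candidates, nrem_periods, window_s = 0.05) {
  if (!nrow(candidates)) stopf("verify_polarity needs candidates")
  fs <- raw$sample_rate
  hg <- abs(butter_apply(raw$samples, fs, "pass", 4L,
                         c(80, min(100, 0.95 * fs / 2))))
  amp_at <- function(times) {
    vapply(times, function(t0) {
      i0 <- max(1L, round((t0 - window_s) * fs))
      i1 <- min(length(hg), round((t0 + window_s) * fs))
      mean(hg[i0:i1])
    }, 0)
  }
  pg <- mean(amp_at(candidates$peak_time))
  tg <- mean(amp_at(candidates$trough_time))
  if (pg == 0 && tg == 0) {
    warnf("high-gamma band is all zero; polarity not verified")
    return(list(candidates = candidates, inverted = FALSE,
                peak_gamma = pg, trough_gamma = tg))
  }
  inverted <- pg > tg  # strict: ties leave the signal untouched
  if (inverted) {
    flipped <- raw
    flipped$samples <- -flipped$samples
    candidates <- detect_candidates(slow_wave_filter(flipped), nrem_periods)
  }
  list(candidates = candidates, inverted = inverted,
       peak_gamma = pg, trough_gamma = tg)
}

#' Classify candidates into slow oscillations and delta waves
#'
#' Percentile gates computed within this recording's candidate set (peaks
#' and troughs ranked separately; troughs on signed values, more negative =
#' lower percentile). Slow oscillations: peak > 85th percentile, trough <
#' 40th percentile, peak-to-trough duration 150-500 ms. Delta waves: peak <
#' 85th percentile, trough < 40th percentile, duration > 100 ms. Candidates
#' matching neither rule are discarded.
#'
#' @param candidates data frame from [detect_candidates()].
#' @param recording_id identifier attached to the events.
#' @param peak_pct,trough_pct percentile gates (defaults 0.85, 0.40).
#' @param so_dur_ms,delta_min_dur_ms duration gates in ms.
#' @param min_candidates refuse below this many candidates (percentiles
#'   unstable); default 20.
#' @return data frame of classified events with a `class` column.
#' @export
classify_waves <- function(candidates, recording_id = "rec",
                           peak_pct = 0.85, trough_pct = 0.40,
                           so_dur_ms = c(150, 500), delta_min_dur_ms = 100,
                           min_candidates = 20L) {
  if (nrow(candidates) < min_candidates)
    stopf("only %d candidates (< %d); percentile gates would be unstable",
          nrow(candidates), min_candidates)
  pk_cut <- quantile(candidates$peak_amp, peak_pct, names = FALSE)
  tr_cut <- quantile(candidates$trough_amp, trough_pct, names = FALSE)
  pk <- candidates$peak_amp
  tr <- candidates$trough_amp
  du <- candidates$p2t_duration_ms
  is_so <- pk > pk_cut & tr < tr_cut & du >= so_dur_ms[1] & du <= so_dur_ms[2]
  is_delta <- pk < pk_cut & tr < tr_cut & du > delta_min_dur_ms
  out <- candidates[is_so | is_delta, , drop = FALSE]
  out$class <- ifelse(is_so[is_so | is_delta], "slow_oscillation", "delta_wave")
  out$recording_id <- recording_id
  rownames(out) <- NULL
  out
}

#' Detect and classify slow waves in one recording
#'
#' Full per-recording pipeline: slow-wave-band filtering, candidate
#' detection in NREM, high-gamma polarity verification, and percentile/
#' duration classification.
#'
#' @param channel z-scored LFP or EEG [ephys_channel].
#' @param hyp a [hypnogram].
#' @param recording_id identifier for percentile grouping.
#' @param ... passed to [classify_waves()].
#' @return list(events, candidates, inverted).
#' @export
detect_slow_waves <- function(channel, hyp, recording_id = channel$session_id,
                              ...) {
  nrem <- state_periods(hyp, "NREM")
  cand <- detect_candidates(slow_wave_filter(channel), nrem)
  inverted <- FALSE
  if (nrow(cand)) {
    pol <- verify_polarity(channel, cand, nrem)
    cand <- pol$candidates
    inverted <- pol$inverted
  }
  events <- if (nrow(cand)) classify_waves(cand, recording_id, ...) else cand
  list(events = events, candidates = cand, inverted = inverted)
}

#' k-means separability of the two wave classes
#'
#' k = 2 clustering on the (peak, trough) amplitude plane (unstandardized,
#' squared Euclidean distance), with agreement against the rule-based
#' classes maximized over label permutations.
#'
#' @param events classified events from [classify_waves()].
#' @param seed RNG seed for the restarts.
#' @param nstart k-means restarts (default 10).
#' @return list(cluster, centers, agreement).
#' @export
kmeans_separability <- function(events, seed = 1L, nstart = 10L) {
  if (sum(events$class == "slow_oscillation") < 2L ||
      sum(events$class == "delta_wave") < 2L)
    stopf("need at least 2 events of each class")
  xy <- cbind(events$peak_amp, events$trough_amp)
  if (nrow(unique(xy)) < 2L) stopf("degenerate input: all points identical")
  set.seed(seed)
  km <- kmeans(xy, centers = 2L, nstart = nstart)
  truth <- as.integer(events$class == "slow_oscillation") + 1L
  agree <- max(mean(km$cluster == truth), mean((3L - km$cluster) == truth))
  list(cluster = km$cluster, centers = km$centers, agreement = agree)
}

#' Amplitude statistics between two conditions
#'
#' Peak-minus-trough amplitude distributions per wave class, per-animal mean
#' percent change (CNO - saline)/saline x 100, paired t-tests across
#' animals, and a two-sample KS test on the pooled event-level
#' distributions.
#'
#' @param events_a,events_b classified wave events for conditions A
#'   (reference, e.g. saline) and B (e.g. CNO); must carry an `animal`
#'   column for paired statistics.
#' @return list with per-class entries: pooled distributions, ks, percent
#'   change per animal, paired t.
#' @export
amplitude_stats <- function(events_a, events_b) {
  amp <- function(e) e$peak_amp - e$trough_amp
  out <- list()
  for (cl in c("slow_oscillation", "delta_wave")) {
    a <- events_a[events_a$class == cl, , drop = FALSE]
    b <- events_b[events_b$class == cl, , drop = FALSE]
    if (!nrow(a) || !nrow(b)) next
    ks <- list(distance = ks_distance(amp(a), amp(b)),
               p = suppressWarnings(ks.test(amp(a), amp(b))$p.value))
    res <- list(amp_a = amp(a), amp_b = amp(b), ks = ks)
    if (!is.null(a$animal) && !is.null(b$animal)) {
      ma <- tapply(amp(a), a$animal, mean)
      mb <- tapply(amp(b), b$animal, mean)
      common <- intersect(names(ma), names(mb))
      dropped <- setdiff(union(names(ma), names(mb)), common)
      if (length(dropped))
        message(sprintf("animals missing one condition dropped: %s",
                        paste(dropped, collapse = ", ")))
      pc <- (mb[common] - ma[common]) / ma[common] * 100
      tt <- if (length(common) >= 2L && sd(mb[common] - ma[common]) > 0)
        t.test(mb[common], ma[common], paired = TRUE) else NULL
      res$percent_change <- pc
      res$mean_percent_change <- mean(pc)
      res$paired_t <- tt
    } else {
      res$mean_percent_change <- (mean(amp(b)) - mean(amp(a))) / mean(amp(a)) * 100
    }
    out[[cl]] <- res
  }
  out
}
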