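# Threshold-based sleep-state scoring: 5 s epochs classified from z-scored
# spectral, EMG, and locomotion evidence, then segmented into behavioral
# periods with wake subdivided by locomotion.

#' Construct a hypnogram
#'
#' Ordered, contiguous, non-overlapping behavioral periods tiling the scored
#' interval.
#'
#' @param periods data frame with columns start_s, end_s, state and
#'   optionally substate.
#' @export
hypnogram <- function(periods) {
  if (nrow(periods)) {
    stopifnot(all(c("start_s", "end_s", "state") %in% names(periods)))
    if (is.null(periods$substate)) periods$substate <- "n/a"
    ord <- order(periods$start_s)
    periods <- periods[ord, , drop = FALSE]
    if (any(periods$end_s <= periods$start_s)) stopf("empty or inverted period")
    if (nrow(periods) > 1L &&
        any(abs(periods$start_s[-1] - periods$end_s[-nrow(periods)]) > 1e-9))
      stopf("hypnogram periods must tile the interval without gaps/overlaps")
  } else {
    periods <- data.frame(start_s = numeric(0), end_s = numeric(0),
                          state = character(0), substate = character(0))
  }
  rownames(periods) <- NULL
  class(periods) <- c("hypnogram", "data.frame")
  periods
}

#' Epoch features for sleep scoring
#'
#' One record per 5 s scoring bin: the slow-wave ratio (slow/mid band power)
#' and theta power, each z-scored across the session's valid frames; mean
#' absolute z-scored EMG per bin, z-scored across bins; and a locomotion
#' flag (any movement in the bin).
#'
#' @param spec a [band_spectrogram] of the z-scored LFP (or EEG).
#' @param emg z-scored EMG [ephys_channel].
#' @param locomotion data frame (time_s, speed) covering the session.
#' @return data frame: frame_time, swr_z, theta_z, emg_z, locomotory, valid.
#' @export
epoch_features <- function(spec, emg, locomotion) {
  ft <- spec$frame_times
  pw <- spec$powers
  swr <- pw[, "slow"] / pmax(pw[, "mid"], .Machine$double.eps)
  zf <- function(x, ok) (x - mean(x[ok])) / sd(x[ok])
  ok <- spec$valid & is.finite(swr)
  swr_z <- zf(swr, ok)
  theta_z <- zf(pw[, "theta"], ok)

  bin_of <- function(times) findInterval(times, ft - spec$step_s / 2,
                                         rightmost.closed = FALSE)
  # mean |z EMG| per bin (bins centered on frame times, step_s wide)
  es <- abs(emg$samples)
  es[emg$artifact_mask] <- NA
  et <- (seq_along(es) - 0.5) / emg$sample_rate
  eb <- bin_of(et)
  keep <- eb >= 1L & eb <= length(ft)
  emg_amp <- rep(NA_real_, length(ft))
  agg <- tapply(es[keep], eb[keep], mean, na.rm = TRUE)
  emg_amp[as.integer(names(agg))] <- agg
  emg_ok <- ok & is.finite(emg_amp)
  emg_z <- zf(emg_amp, emg_ok)

  lb <- bin_of(locomotion$time_s)
  keep <- lb >= 1L & lb <= length(ft)
  moved <- tapply(locomotion$speed[keep] > 0, lb[keep], any)
  locomotory <- rep(FALSE, length(ft))
  locomotory[as.integer(names(moved))] <- as.logical(moved)

  data.frame(frame_time = ft, swr_z = swr_z, theta_z = theta_z,
             emg_z = emg_z, locomotory = locomotory,
             valid = ok & is.finite(emg_z))
}

#' Default scoring thresholds
#'
#' NREM: slow-wave ratio > 0.5 SD from the mean, stationary, EMG < 5 SD.
#' REM (only if not NREM): theta > 0.25 SD, stationary, EMG < 0.4 SD.
#' All in SD units of the session's frame distribution.
#' @export
default_thresholds <- function() {
  list(nrem_ratio = 0.5, nrem_emg = 5, rem_theta = 0.25, rem_emg = 0.4)
}

#' Classify 5 s epochs into NREM / REM / wake
#'
#' NREM is evaluated first; REM only for epochs not already NREM; all
#' remaining epochs are wake. Any locomotion in an epoch vetoes both sleep
#' states. Epochs with missing features are marked unscorable.
#'
#' @param features data frame from [epoch_features()].
#' @param thresholds see [default_thresholds()].
#' @return character vector: "NREM", "REM", "wake" or NA (unscorable).
#' @export
classify_epochs <- function(features, thresholds = default_thresholds()) {
  th <- thresholds
  n <- nrow(features)
  out <- rep("wake", n)
  nrem <- features$swr_z > th$nrem_ratio & !features$locomotory &
    features$emg_z < th$nrem_emg
  rem <- !nrem & features$theta_z > th$rem_theta & !features$locomotory &
    features$emg_z < th$rem_emg
  out[which(nrem)] <- "NREM"
  out[which(rem)] <- "REM"
  if (!is.null(features$valid)) out[!features$valid] <- NA
  out[is.na(features$swr_z) | is.na(features$theta_z) | is.na(features$emg_z)] <- NA
  out
}

#' Segment epoch states into behavioral periods
#'
#' Runs of identical state become periods; sleep (NREM or REM) periods
#' shorter than the active minimum are reassigned to wake, then adjacent
#' same-state periods are merged. The longer minimum is used by the
#' sleep/wake transition analyses.
#'
#' @param states epoch-state vector from [classify_epochs()].
#' @param epoch_s epoch length in seconds (default 5).
#' @param min_sleep_s minimum sleep-period duration (default 15 s).
#' @param t0 time of the first epoch's start (default 0).
#' @return a [hypnogram] (without wake substates). Unscorable epochs are
#'   excluded from the scored interval at the edges and treated as wake
#'   inside it.
#' @export
segment_periods <- function(states, epoch_s = 5, min_sleep_s = 15, t0 = 0) {
  if (!length(states)) return(hypnogram(data.frame()))
  states[is.na(states)] <- "wake"
  # the minimum applies to maximal sleep (NREM or REM) runs: a brief REM
  # stretch inside a long NREM period is not a short sleep period
  sw <- ifelse(states %in% c("NREM", "REM"), "sleep", "wake")
  r <- rle(sw)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  short <- which(r$values == "sleep" & r$lengths * epoch_s < min_sleep_s)
  states2 <- states
  for (k in short) states2[starts[k]:ends[k]] <- "wake"
  per <- runs_to_periods(states2, epoch_s, t0 = t0)
  hypnogram(per)
}

#' Subdivide wake periods by locomotion
#'
#' Within each wake period, consecutive locomotory 1 s bins form locomotory
#' sub-periods and consecutive stationary bins form stationary sub-periods.
#' The first `post_locomotion_buffer_s` seconds of a stationary sub-period
#' immediately following a locomotory one are excluded (Ca2+ bursts outlast
#' locomotion), and stationary sub-periods shorter than `min_stationary_s`
#' after buffering are excluded from substate analyses (they remain wake).
#'
#' @param hyp a [hypnogram].
#' @param locomotion data frame (time_s, speed).
#' @param min_stationary_s,post_locomotion_buffer_s seconds.
#' @return a [hypnogram] whose wake periods are split with substate
#'   "locomotory", "stationary" or "excluded".
#' @export
subdivide_wake <- function(hyp, locomotion, min_stationary_s = 15,
                           post_locomotion_buffer_s = 10) {
  if (!nrow(hyp)) return(hyp)
  # any-movement flag per whole second, computed once
  mv_t <- floor(locomotion$time_s[locomotion$speed > 0])
  max_sec <- max(ceiling(hyp$end_s), floor(max(locomotion$time_s)) + 1)
  moved_sec <- logical(max_sec)
  mv_idx <- mv_t[mv_t >= 0 & mv_t < max_sec] + 1L
  moved_sec[mv_idx] <- TRUE
  rows <- list()
  for (i in seq_len(nrow(hyp))) {
    p <- hyp[i, ]
    if (p$state != "wake") {
      p$substate <- "n/a"
      rows[[length(rows) + 1L]] <- p
      next
    }
    secs <- seq(floor(p$start_s), ceiling(p$end_s) - 1)
    moved <- moved_sec[secs + 1L]
    r <- rle(moved)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    prev_loco <- c(FALSE, head(r$values, -1L))
    for (k in seq_along(r$values)) {
      s0 <- max(secs[starts[k]], p$start_s)
      s1 <- min(secs[ends[k]] + 1, p$end_s)
      if (r$values[k]) {
        rows[[length(rows) + 1L]] <- data.frame(
          start_s = s0, end_s = s1, state = "wake", substate = "locomotory")
      } else {
        b0 <- s0
        if (prev_loco[k] && post_locomotion_buffer_s > 0) {
          bcut <- min(s0 + post_locomotion_buffer_s, s1)
          rows[[length(rows) + 1L]] <- data.frame(
            start_s = s0, end_s = bcut, state = "wake", substate = "excluded")
          b0 <- bcut
        }
        if (b0 < s1) {
          sub <- if (s1 - b0 >= min_stationary_s) "stationary" else "excluded"
          rows[[length(rows) + 1L]] <- data.frame(
            start_s = b0, end_s = s1, state = "wake", substate = sub)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[out$end_s > out$start_s, , drop = FALSE]
  hypnogram(out)
}

#' Score a session end to end
#'
#' Artifact rejection, baseline correction and session z-scoring of LFP and
#' EMG; windowed band powers; epoch classification; period segmentation and
#' wake subdivision.
#'
#' @param lfp,emg raw [ephys_channel]s.
#' @param locomotion data frame (time_s, speed).
#' @param thresholds scoring thresholds, see [default_thresholds()].
#' @param min_sleep_s minimum sleep-period duration.
#' @param window_s,step_s spectrogram window/step.
#' @return list: `hypnogram`, `features`, `epoch_states`, `spectrogram`.
#' @export
score_sleep <- function(lfp, emg, locomotion,
                        thresholds = default_thresholds(),
                        min_sleep_s = 15, window_s = 10, step_s = 5) {
  lfp <- zscore_session(highpass_baseline(remove_artifacts(lfp)))
  emg <- zscore_session(highpass_baseline(remove_artifacts(emg)))
  spec <- band_spectrogram(lfp, window_s = window_s, step_s = step_s)
  feats <- epoch_features(spec, emg, locomotion)
  states <- classify_epochs(feats, thresholds)
  hyp <- segment_periods(states, epoch_s = step_s, min_sleep_s = min_sleep_s,
                         t0 = feats$frame_time[1] - step_s / 2)
  hyp <- subdivide_wake(hyp, locomotion)
  list(hypnogram = hyp, features = feats, epoch_states = states,
       spectrogram = spec, lfp_z = lfp, emg_z = emg)
}

# --- hypnogram helpers ------------------------------------------------------

#' Periods of a given state (optionally substate)
#' @param hyp a [hypnogram].
#' @param state state name; "sleep" selects NREM and REM.
#' @param substate optional wake substate filter.
#' @export
state_periods <- function(hyp, state, substate = NULL) {
  sel <- if (identical(state, "sleep")) hyp$state %in% c("NREM", "REM")
         else hyp$state == state
  if (!is.null(substate)) sel <- sel & hyp$substate == substate
  hyp[sel, , drop = FALSE]
}

#' Total time covered by a set of periods
#' @param periods data frame with start_s, end_s.
#' @export
period_time <- function(periods) sum(periods$end_s - periods$start_s)

#' Membership of time points in a set of periods
#' @param times numeric vector (s).
#' @param periods data frame with start_s, end_s.
#' @export
in_periods <- function(times, periods) {
  if (!nrow(periods)) return(rep(FALSE, length(times)))
  out <- rep(FALSE, length(times))
  for (i in seq_len(nrow(periods)))
    out <- out | (times >= periods$start_s[i] & times < periods$end_s[i])
  out
}

#' State at given time points
#' @param hyp a [hypnogram].
#' @param times numeric vector (s).
#' @param use_substate replace wake by its substate where defined.
#' @export
state_at <- function(hyp, times, use_substate = FALSE) {
  idx <- findInterval(times, hyp$start_s)
  ok <- idx >= 1L & times < c(hyp$end_s, Inf)[pmax(idx, 1L)]
  st <- rep(NA_character_, length(times))
  st[ok] <- hyp$state[idx[ok]]
  if (use_substate) {
    sub <- hyp$substate[idx[ok]]
    w <- st[ok] == "wake" & sub %in% c("locomotory", "stationary")
    st[ok][w] <- paste0("wake_", sub[w])
  }
  st
}

#' Epoch-level agreement with ground truth
#'
#' Compares scored epoch states with the generator's per-second truth at the
#' 3-state level (NREM/REM/wake), overall and restricted to epochs at least
#' `stable_margin_s` from a true state transition.
#'
#' @param epoch_states vector from [classify_epochs()].
#' @param frame_times epoch centers (s).
#' @param truth_state_1s truth factor, one state per second.
#' @param epoch_s epoch length (s).
#' @param stable_margin_s margin from the nearest true transition.
#' @return list(overall, stable, n, n_stable).
#' @export
epoch_agreement <- function(epoch_states, frame_times, truth_state_1s,
                            epoch_s = 5, stable_margin_s = 10) {
  t3 <- ifelse(as.character(truth_state_1s) %in%
                 c("wake_stationary", "wake_locomotory"),
               "wake", as.character(truth_state_1s))
  # majority truth state per epoch
  truth_ep <- vapply(frame_times, function(tc) {
    secs <- pmax(1L, floor(tc - epoch_s / 2) + 1L):
      pmin(length(t3), ceiling(tc + epoch_s / 2))
    names(sort(table(t3[secs]), decreasing = TRUE))[1]
  }, "")
  trans <- which(t3[-1] != t3[-length(t3)])  # transition after second `trans`
  dist_to_trans <- vapply(frame_times, function(tc) {
    if (!length(trans)) return(Inf)
    min(abs(tc - trans))
  }, 0)
  ok <- !is.na(epoch_states)
  agree <- epoch_states[ok] == truth_ep[ok]
  stable <- dist_to_trans[ok] >= stable_margin_s
  list(overall = mean(agree), stable = mean(agree[stable]),
       n = sum(ok), n_stable = sum(stable))
}
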