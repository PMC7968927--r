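# Synthetic multimodal session generator.
#
# Emulates a head-fixed recording session: bout-structured sleep/wake with
# state-dependent band power, an NREM slow-wave train with nested high-gamma,
# state-dependent EMG, locomotion bouts, and inhomogeneous-Poisson astrocyte
# Ca2+ events with pre-transition ramps and an SWA-coupled kernel. Everything
# is seeded and ground truth is returned alongside the signals.

STATE_LEVELS <- c("NREM", "REM", "wake_stationary", "wake_locomotory")

#' The 20 event-feature names used by the synthetic generator
#'
#' Stand-ins for the morphology/kinetics outputs of event-based astrocyte
#' Ca2+ detection (area, perimeter, duration, amplitude, propagation, ...).
#' Grouped as spatial (1-8), temporal (9-14), amplitude-related (15-20).
#' @export
aqua_feature_names <- function() {
  c("area_um2", "perimeter_um", "circularity", "prop_dist_um",
    "prop_speed_um_s", "prop_anisotropy", "centroid_shift_um",
    "spatial_footprint_um2",
    "duration_s", "rise_time_s", "decay_time_s", "onset_delay_s",
    "growth_rate_um2_s", "shrink_rate_um2_s",
    "dff_max", "dff_auc", "onset_slope", "offset_slope",
    "snr_db", "peak_sharpness")
}

#' Default per-state event-feature distributions
#'
#' Multivariate-normal mean/covariance per behavioral state for the 20 event
#' features. The correlation structure is a three-factor model
#' (spatial/temporal/amplitude groups), so the leading principal components
#' of generated features are interpretable as spatial, temporal and
#' amplitude axes. Locomotory-wake events are larger and longer; sleep and
#' stationary wake differ by a modest multi-feature shift.
#'
#' @param sleep_wake_shift_sd size (in SD units) of the sleep vs stationary
#'   wake mean difference, spread over all features.
#' @export
default_feature_params <- function(sleep_wake_shift_sd = 0.35) {
  nm <- aqua_feature_names()
  p <- length(nm)
  groups <- rep(1:3, c(8, 6, 6))
  L <- matrix(0, p, 3)
  L[cbind(seq_len(p), groups)] <- 0.8
  R <- L %*% t(L)
  diag(R) <- 1
  sds <- c(55, 18, 0.1, 6, 3, 0.15, 2.5, 60,      # spatial
           1.1, 0.5, 0.9, 0.3, 22, 18,            # temporal
           0.4, 1.5, 1.8, 1.2, 3, 0.25)           # amplitude
  mu0 <- c(120, 48, 0.62, 8, 5, 0.4, 3.5, 140,
           2.8, 1.1, 2.0, 0.6, 45, 38,
           1.1, 3.2, 4.0, 2.8, 12, 0.7)
  # signed direction touching every feature so all leading PCs shift a bit
  dir_sw <- rep(c(1, -1), length.out = p)
  shift_sw <- sleep_wake_shift_sd * sds * dir_sw
  shift_loco <- c(rep(0.9, 8), rep(0.9, 6), rep(0.5, 6)) * sds
  means <- list(
    NREM = mu0 + shift_sw / 2,
    REM = mu0 + shift_sw / 2,
    wake_stationary = mu0 - shift_sw / 2,
    wake_locomotory = mu0 + shift_loco
  )
  list(names = nm, sds = sds, cor = R, means = means)
}

#' Condition-effect presets
#'
#' Multipliers applied when a session is simulated under "CNO".
#' `condition_gi()` mimics Gi-pathway activation: more Ca2+ events, larger
#' delta waves (and slightly larger slow oscillations), unchanged sleep/wake
#' transition structure, plus a sleep-specific shift of event-feature means.
#' `condition_gq()` mimics Gq-pathway activation: a brief event-rate surge
#' followed by near-complete suppression, and slowed transitions (NREM and
#' wake bouts lengthened; REM bouts untouched).
#' @export
condition_gi <- function() {
  list(event_rate = 1.6, delta_amp = 1.2, so_amp = 1.05, transition_rate = 1,
       sleep_feature_shift_sd = 0.5, rate_profile = NULL)
}

#' @rdname condition_gi
#' @export
condition_gq <- function() {
  list(event_rate = 1, delta_amp = 1, so_amp = 1,
       transition_rate = c(NREM = 1 / 2.8, wake = 1 / 2),
       sleep_feature_shift_sd = 0,
       rate_profile = list(early_mult = 2.5, early_window_s = 480,
                           late_mult = 0.03))
}

#' Simulation configuration
#'
#' Defaults define the reference study conditions used throughout the test
#' suite: a 60-min session at 1 kHz with clear state separations. All rates
#' are per minute; powers are relative (pre-z-scoring) variance units.
#'
#' @param session_duration seconds.
#' @param sample_rate_ephys,sample_rate_loco Hz.
#' @param bout_duration_means mean bout length (s) per state. May name a
#'   subset of states (e.g. a single state for a degenerate one-state
#'   session used in calibration experiments).
#' @param state_transition_graph named list: for each state, a named
#'   probability vector over successor states.
#' @param band_power_by_state background noise power per state for the slow,
#'   theta, mid and high-gamma bands. In NREM the slow band is carried by
#'   the wave train, not background noise.
#' @param wave_rates events/min of NREM for slow oscillations and delta
#'   waves; `background_cycle_rate = NULL` fills the remaining NREM time
#'   with low-amplitude background cycles.
#' @param wave_amplitude_params per-class peak/trough amplitude and
#'   peak-to-trough duration distributions.
#' @param gamma_nesting_depth multiplicative 80-100 Hz amplitude ratio in UP
#'   (trough) vs DOWN (peak) half-cycles; > 1.
#' @param emg_amplitude_by_state,ca_rate_by_state per-state EMG amplitude
#'   (z-units) and Ca2+ event rate (events/min).
#' @param transition_ramp fractional event-rate change over the final
#'   `ramp_s` seconds of sleep (positive) and wake (negative).
#' @param swa_coupling_kernel list(amplitude, half_width_s): dip-then-rise
#'   perturbation of measured SWA (z-units) around each event.
#' @param kernel_states states whose events carry the kernel (NULL = all).
#' @param coherence_coupling shared LFP/EEG band component and its
#'   pre-transition amplitude ramp.
#' @param event_locked_shared optional shared tone bursts at event onsets
#'   (for coherence round-trip experiments); NULL disables.
#' @param feature_params see [default_feature_params()].
#' @param condition_effects see [condition_gi()]; applied under "CNO".
#' @param seed integer; fully determines every output.
#' @return a validated `sim_config` object.
#' @export
sim_config <- function(session_duration = 3600,
                       sample_rate_ephys = 1000,
                       sample_rate_loco = 100,
                       bout_duration_means = c(NREM = 110, REM = 60, wake = 190),
                       state_transition_graph = list(
                         NREM = c(REM = 0.25, wake = 0.75),
                         REM = c(wake = 1),
                         wake = c(NREM = 1)),
                       band_power_by_state = list(
                         slow = c(NREM = 0, REM = 0.04, wake_stationary = 0.05,
                                  wake_locomotory = 0.05),
                         theta = c(NREM = 2.0, REM = 2.8, wake_stationary = 0.4,
                                   wake_locomotory = 0.5),
                         mid = c(NREM = 0.25, REM = 0.5, wake_stationary = 1.0,
                                 wake_locomotory = 1.2),
                         high_gamma = c(NREM = 0.03, REM = 0.03,
                                        wake_stationary = 0.08,
                                        wake_locomotory = 0.10)),
                       floor_power = 0.25,
                       wave_rates = c(slow_oscillation = 17, delta = 29),
                       background_cycle_rate = NULL,
                       wave_amplitude_params = list(
                         slow_oscillation = list(peak = c(2.4, 0.15),
                                                 trough = c(-1.6, 0.2),
                                                 p2t_ms = c(300, 40),
                                                 p2t_range_ms = c(180, 460)),
                         delta = list(peak = c(1.15, 0.12),
                                      trough = c(-1.3, 0.15),
                                      p2t_ms = c(280, 45),
                                      p2t_range_ms = c(130, 540)),
                         background = list(peak = c(0.6, 0.08),
                                           trough = c(-0.5, 0.08),
                                           p2t_ms = c(250, 35),
                                           p2t_range_ms = c(150, 420))),
                       gamma_nesting_depth = 3,
                       emg_amplitude_by_state = c(NREM = 0.4, REM = 0.15,
                                                  wake_stationary = 1.5,
                                                  wake_locomotory = 2.5),
                       ca_rate_by_state = c(NREM = 20, REM = 20,
                                            wake_stationary = 40,
                                            wake_locomotory = 80),
                       transition_ramp = c(sleep = 0.5, wake = -0.5),
                       ramp_s = 30,
                       swa_coupling_kernel = list(amplitude = 0.05,
                                                  half_width_s = 2),
                       kernel_states = NULL,
                       coherence_coupling = list(band = c(2, 12),
                                                 base_power = 0.02,
                                                 pre_transition_gain = 3,
                                                 ramp_s = 10),
                       event_locked_shared = NULL,
                       feature_params = default_feature_params(),
                       condition_effects = list(event_rate = 1, delta_amp = 1,
                                                so_amp = 1, transition_rate = 1,
                                                sleep_feature_shift_sd = 0,
                                                rate_profile = NULL),
                       min_bout_s = 10,
                       seed = 1L) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$session_duration < 2 * max(cfg$bout_duration_means))
    stopf("session_duration (%g s) must be at least twice the longest bout mean (%g s)",
          cfg$session_duration, max(cfg$bout_duration_means))
  if (any(cfg$ca_rate_by_state < 0) || any(cfg$wave_rates < 0) ||
      any(cfg$emg_amplitude_by_state < 0))
    stopf("rates and amplitudes must be >= 0")
  if (cfg$gamma_nesting_depth <= 0) stopf("gamma_nesting_depth must be > 0")
  if (any(cfg$bout_duration_means <= 0)) stopf("bout means must be > 0")
  R <- cfg$feature_params$cor
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (!isTRUE(all.equal(R, t(R))) || min(ev) < -1e-8)
    stopf("feature covariance is not symmetric positive semi-definite (min eigenvalue %.3g)",
          min(ev))
  invisible(cfg)
}

# apply condition multipliers to a config; "saline" returns it unchanged
resolve_condition <- function(cfg, condition) {
  if (condition == "saline") return(cfg)
  ce <- cfg$condition_effects
  cfg$ca_rate_by_state <- cfg$ca_rate_by_state * ce$event_rate
  # amplitude multipliers scale the drawn amplitudes (common random numbers
  # across conditions), so the condition effect is exactly multiplicative
  cfg$wave_amp_mult <- c(slow_oscillation = ce$so_amp, delta = ce$delta_amp,
                         background = 1)
  # slower transitions = proportionally longer NREM and wake bouts (REM bouts
  # are left untouched); transition_rate may be one scalar or named per state
  tr <- ce$transition_rate
  for (s in intersect(c("NREM", "wake"), names(cfg$bout_duration_means))) {
    m <- if (length(tr) > 1L) tr[[s]] else tr
    cfg$bout_duration_means[s] <- cfg$bout_duration_means[s] / m
  }
  if (ce$sleep_feature_shift_sd != 0) {
    fp <- cfg$feature_params
    dir <- rep(c(1, -1), length.out = length(fp$sds))
    fp$means$NREM <- fp$means$NREM + ce$sleep_feature_shift_sd * fp$sds * dir
    fp$means$REM <- fp$means$REM + ce$sleep_feature_shift_sd * fp$sds * dir
    cfg$feature_params <- fp
  }
  cfg$rate_profile <- ce$rate_profile
  cfg
}

# truncated normal via inverse-CDF so the RNG draw count is fixed
rtnorm <- function(n, mean, sd, lo, hi) {
  u <- runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Simulate the behavioral state sequence
#'
#' Semi-Markov chain with exponential bout durations truncated below at
#' `min_bout_s`; wake bouts are subdivided into alternating stationary and
#' locomotory segments. Bout durations are generated from unit-exponential
#' draws scaled by the (condition-adjusted) bout means, so paired conditions
#' simulated from the same seed share bout-level randomness.
#'
#' @param config a [sim_config].
#' @param seed RNG seed (defaults to the config seed).
#' @return factor vector of states, one per second, tiling the session.
#' @export
simulate_state_sequence <- function(config, seed = config$seed) {
  dur <- config$session_duration
  means <- config$bout_duration_means
  graph <- config$state_transition_graph
  minb <- config$min_bout_s
  set.seed(sub_seed(seed, 1L))
  states <- character(0)
  lens <- numeric(0)
  cur <- if ("wake" %in% names(means)) "wake" else names(means)[1]
  total <- 0
  while (total < dur) {
    m <- means[[cur]]
    # exponential bout, truncated below at the minimum and above at 4x the
    # mean: very long bouts would push state occupancy into the regime where
    # fixed-SD scoring gates sit inside the majority class
    len <- minb + min(max(m - minb, 1) * rexp(1), 4 * m)
    states <- c(states, cur)
    lens <- c(lens, len)
    total <- total + len
    if (length(means) == 1L) next
    pr <- graph[[cur]]
    pr <- pr[names(pr) %in% names(means)]
    cur <- names(pr)[1 + findInterval(runif(1), cumsum(pr / sum(pr)))]
  }
  lens[length(lens)] <- lens[length(lens)] - (total - dur)
  sec_state <- rep(states, times = pmax(1, round(lens)))
  if (length(sec_state) < dur)
    sec_state <- c(sec_state, rep(states[length(states)], dur - length(sec_state)))
  sec_state <- sec_state[seq_len(dur)]

  # subdivide wake seconds into stationary/locomotory segments
  set.seed(sub_seed(seed, 2L))
  out <- sec_state
  r <- rle(sec_state)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in which(r$values == "wake")) {
    n <- r$lengths[k]
    seg <- character(0)
    loco <- runif(1) < 0.3
    while (length(seg) < n) {
      sl <- if (loco) 5 + rexp(1) * 10 else 10 + rexp(1) * 30
      seg <- c(seg, rep(if (loco) "wake_locomotory" else "wake_stationary",
                        max(1L, round(sl))))
      loco <- !loco
    }
    out[starts[k]:ends[k]] <- seg[seq_len(n)]
  }
  factor(out, levels = STATE_LEVELS)
}

# sleep(=NREM+REM)/wake periods from the 1 s truth states
sleep_wake_periods <- function(state_1s) {
  sw <- ifelse(as.character(state_1s) %in% c("NREM", "REM"), "sleep", "wake")
  runs_to_periods(sw, 1)
}

#' Simulate Ca2+ event onsets
#'
#' Inhomogeneous Poisson process: per-state base rates, a linear fractional
#' ramp over the final `ramp_s` seconds of each sleep and each wake period,
#' and (optionally) a time-dependent condition rate profile.
#'
#' @param config resolved [sim_config].
#' @param state_1s factor of truth states per second.
#' @param seed RNG seed.
#' @return list with `onsets` (s), `state` (state at onset) and `rate_1s`
#'   (events/min per second, the true rate function).
#' @export
simulate_event_onsets <- function(config, state_1s, seed = config$seed) {
  n <- length(state_1s)
  base <- config$ca_rate_by_state[as.character(state_1s)] / 60  # events/s
  ramp_mult <- rep(1, n)
  ramp <- config$transition_ramp
  rs <- config$ramp_s
  per <- sleep_wake_periods(state_1s)
  if (nrow(per) > 1L) {  # final period has no transition after it
    for (i in seq_len(nrow(per) - 1L)) {
      amt <- if (per$state[i] == "sleep") ramp[["sleep"]] else ramp[["wake"]]
      if (amt == 0) next
      idx <- (per$start_s[i] + 1):per$end_s[i]
      tt <- idx - 0.5
      frac <- pmax(0, 1 - (per$end_s[i] - tt) / rs)
      ramp_mult[idx] <- 1 + amt * frac
    }
  }
  prof_mult <- rep(1, n)
  rp <- config$rate_profile
  if (!is.null(rp)) {
    tt <- seq_len(n) - 0.5
    prof_mult <- ifelse(tt < rp$early_window_s, rp$early_mult, rp$late_mult)
  }
  lambda <- pmax(base * ramp_mult * prof_mult, 0)
  set.seed(sub_seed(seed, 3L))
  counts <- rpois(n, lambda)
  onsets <- rep(seq_len(n) - 1L, counts) + runif(sum(counts))
  ord <- order(onsets)
  onsets <- onsets[ord]
  list(onsets = onsets,
       state = as.character(state_1s)[pmin(floor(onsets) + 1L, n)],
       rate_1s = lambda * 60)
}

#' Simulate event feature vectors
#'
#' Draws one 20-feature row per event from the multivariate-normal
#' distribution of the event's behavioral state.
#'
#' @param n_events number of events.
#' @param state_labels character vector of states, length `n_events`.
#' @param feature_params see [default_feature_params()].
#' @param seed RNG seed.
#' @return `n_events` x 20 data frame with the documented feature names.
#' @export
simulate_event_features <- function(n_events, state_labels,
                                    feature_params = default_feature_params(),
                                    seed = 1L) {
  fp <- feature_params
  p <- length(fp$names)
  if (n_events == 0L) {
    m <- as.data.frame(matrix(numeric(0), 0, p))
    names(m) <- fp$names
    return(m)
  }
  if (length(state_labels) != n_events)
    stopf("state_labels must have length n_events")
  missing_st <- setdiff(unique(state_labels), names(fp$means))
  if (length(missing_st))
    stopf("no feature parameters for state(s): %s",
          paste(missing_st, collapse = ", "))
  Sigma <- diag(fp$sds) %*% fp$cor %*% diag(fp$sds)
  out <- matrix(NA_real_, n_events, p)
  set.seed(sub_seed(seed, 4L))
  for (st in unique(state_labels)) {
    idx <- which(state_labels == st)
    out[idx, ] <- MASS::mvrnorm(length(idx), mu = fp$means[[st]], Sigma = Sigma)
  }
  out <- as.data.frame(out)
  names(out) <- fp$names
  out
}

#' Simulate the NREM slow-wave train
#'
#' Fills NREM time with a continuous train of biphasic cycles (positive
#' half-sine peak, then negative half-sine trough): labeled slow-oscillation
#' and delta-wave cycles interleaved with low-amplitude background cycles.
#' Class labels are assigned by stratified randomization within blocks so
#' that short-window slow-wave power is stable, emulating the
#' quasi-stationary depth of consolidated NREM sleep. High-gamma UP-state
#' nesting is returned as a per-sample indicator of negative (UP)
#' half-cycles.
#'
#' @param config resolved [sim_config].
#' @param nrem_mask logical vector at the ephys rate, `TRUE` during NREM.
#' @param seed RNG seed.
#' @param amp_envelope optional per-sample multiplicative amplitude envelope
#'   (the SWA-kernel modulation), same length as `nrem_mask`.
#' @return list: `waves` (truth list of labeled waves: zero-crossing time,
#'   class, peak, trough, p2t duration), `trace` (additive waveform at the
#'   ephys rate), `upstate` (logical, negative half-cycles).
#' @export
simulate_wave_train <- function(config, nrem_mask, seed = config$seed,
                                amp_envelope = NULL) {
  fs <- config$sample_rate_ephys
  n <- length(nrem_mask)
  trace <- numeric(n)
  upstate <- logical(n)
  empty <- data.frame(time_s = numeric(0), class = character(0),
                      peak = numeric(0), trough = numeric(0),
                      duration_ms = numeric(0))
  if (!any(nrem_mask)) stopf("nrem_mask has no NREM samples")
  w <- config$wave_amplitude_params
  rates <- config$wave_rates
  if (all(rates == 0) && is.null(config$background_cycle_rate))
    return(list(waves = empty, trace = trace, upstate = upstate))

  # mean full-cycle durations (two half-cycles of the mean p2t duration)
  cyc_s <- vapply(w, function(p) 2 * p$p2t_ms[1] / 1000, 0)
  duty_wave <- sum(rates * cyc_s[c("slow_oscillation", "delta")]) / 60
  if (duty_wave > 1.02)
    stopf("requested wave rates x durations (%.0f%% duty) exceed NREM occupancy",
          100 * duty_wave)
  r_bg <- config$background_cycle_rate %||%
    ((1 - duty_wave) * 60 / cyc_s[["background"]])
  all_rates <- c(rates, background = r_bg)
  if (sum(all_rates) == 0)
    return(list(waves = empty, trace = trace, upstate = upstate))
  fracs <- all_rates / sum(all_rates)

  per <- runs_to_periods(nrem_mask, 1 / fs)
  per <- per[per$state == "TRUE", , drop = FALSE]
  total_nrem <- sum(per$end_s - per$start_s)
  n_max <- ceiling(total_nrem / min(cyc_s) * 1.1) + 64L

  set.seed(sub_seed(seed, 5L))
  # quota-interleaved class stream: each cycle takes the class with the
  # largest running deficit (random tie-break), so every short window of the
  # train has near-exact class composition and window-to-window slow-wave
  # power is stable, emulating consolidated NREM depth
  cls_names <- names(all_rates)
  deficit <- fracs * 0
  classes <- character(n_max)
  jitter <- matrix(runif(n_max * length(fracs), 0, 1e-6), n_max)
  for (i in seq_len(n_max)) {
    deficit <- deficit + fracs
    pick <- which.max(deficit + jitter[i, ])
    classes[i] <- cls_names[pick]
    deficit[pick] <- deficit[pick] - 1
  }
  draw <- function(cl, what) {
    p <- w[[cl]][[what]]
    k <- sum(classes == cl)
    if (what == "p2t_ms") {
      r <- w[[cl]]$p2t_range_ms
      rtnorm(k, p[1], p[2], r[1], r[2])
    } else if (what == "peak") {
      rtnorm(k, p[1], p[2], 0.05, Inf)
    } else {
      rtnorm(k, p[1], p[2], -Inf, -0.05)
    }
  }
  amp_mult <- config$wave_amp_mult %||%
    c(slow_oscillation = 1, delta = 1, background = 1)
  peaks <- troughs <- durs <- numeric(n_max)
  for (cl in names(all_rates)) {
    idx <- classes == cl
    peaks[idx] <- draw(cl, "peak") * amp_mult[[cl]]
    troughs[idx] <- draw(cl, "trough") * amp_mult[[cl]]
    durs[idx] <- draw(cl, "p2t_ms")
  }

  waves <- vector("list", nrow(per))
  ci <- 1L
  for (pp in seq_len(nrow(per))) {
    t0 <- per$start_s[pp]
    t_end <- per$end_s[pp]
    t <- t0
    rows <- list()
    while (ci <= n_max) {
      d_half <- durs[ci] / 1000
      if (t + 2 * d_half > t_end) break
      i0 <- floor(t * fs) + 1L
      n1 <- max(1L, round(d_half * fs))
      n2 <- n1
      if (i0 + n1 + n2 - 1L > n) break
      ph1 <- (seq_len(n1) - 0.5) / n1
      ph2 <- (seq_len(n2) - 0.5) / n2
      seg <- c(peaks[ci] * sin(pi * ph1), troughs[ci] * sin(pi * ph2))
      sel <- i0:(i0 + n1 + n2 - 1L)
      trace[sel] <- trace[sel] + seg
      upstate[sel[(n1 + 1L):(n1 + n2)]] <- TRUE
      if (classes[ci] != "background") {
        rows[[length(rows) + 1L]] <- data.frame(
          time_s = t + d_half,  # positive-to-negative zero crossing
          class = if (classes[ci] == "slow_oscillation") "slow_oscillation" else "delta_wave",
          peak = peaks[ci], trough = troughs[ci], duration_ms = durs[ci])
      }
      t <- t + 2 * d_half
      ci <- ci + 1L
    }
    waves[[pp]] <- if (length(rows)) do.call(rbind, rows) else empty
  }
  waves <- do.call(rbind, waves)
  rownames(waves) <- NULL
  if (!is.null(amp_envelope)) trace <- trace * amp_envelope
  list(waves = waves, trace = trace, upstate = upstate)
}

# --- band-limited background noise -----------------------------------------

band_noise <- function(n, fs, lo, hi, seed_val, order = 4L) {
  set.seed(seed_val)
  x <- rnorm(n)
  w <- c(lo, min(hi, 0.4995 * fs)) / (fs / 2)
  stable <- function(bf) all(Mod(polyroot(rev(bf$a))) < 1 - 1e-9)
  bf <- signal::butter(order, w, type = "pass")
  x <- if (stable(bf)) iir_filter(bf$b, bf$a, x) else {
    hp <- signal::butter(2L, w[1], type = "high")
    lp <- signal::butter(order, w[2], type = "low")
    iir_filter(lp$b, lp$a, iir_filter(hp$b, hp$a, x))
  }
  x / sd(x)
}

# one-over-f shaped broadband floor on [lo, hi] Hz; kept out of the scored
# bands so tone/noise cross-terms do not inflate band-power variance
floor_noise <- function(n, fs, lo, hi, power, seed_val) {
  set.seed(seed_val)
  x <- rnorm(n)
  X <- fft(x)
  f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs / n
  af <- abs(f)
  shape <- ifelse(af >= lo & af <= hi, 1 / sqrt(pmax(af, lo)), 0)
  y <- Re(fft(X * shape, inverse = TRUE)) / n
  y / sd(y) * sqrt(power)
}

# interpolate a per-second (or coarser) envelope to the sample grid
env_interp <- function(values, grid_times, n, fs) {
  approx(grid_times, values, xout = (seq_len(n) - 0.5) / fs, rule = 2)$y
}

# --- SWA coupling kernel ----------------------------------------------------

# Relative variance of the package's windowed SWA power estimator (0.5 s
# boxcar over squared 0.5-4 Hz noise), measured once by long simulation of
# the estimator on stationary band-limited noise (0.487 at 250 Hz, 0.482 at
# 1 kHz).
SWA_EST_RELVAR <- 0.485

# drive = -1 on [-hw-0.25, 0), +1 on [0, hw+0.25) around each event, built
# on the sample grid; through the 0.5 s moving-average SWA estimator this
# measures as a -1/+1 plateau pair at all 0.25 s lag-grid points in
# [-hw, hw].
kernel_drive_u <- function(onsets, n, fs, half_width_s,
                           edge_ext_s = 0.375, boost = 0.35) {
  u <- numeric(n)
  if (!length(onsets)) return(u)
  d <- numeric(n + 1L)
  hw <- round((half_width_s + edge_ext_s) * fs)
  bo <- round(0.25 * fs)
  i_ev <- pmin(pmax(round(onsets * fs) + 1L, 1L), n)
  add <- function(idx, val) {
    idx <- pmin(pmax(idx, 1L), n + 1L)
    for (j in seq_along(idx)) d[idx[j]] <<- d[idx[j]] + val
  }
  add(i_ev - hw, -1)
  add(i_ev - bo, -boost)
  add(i_ev, 2 * (1 + boost))
  add(i_ev + bo, -boost)
  add(i_ev + hw, -1)
  cumsum(d)[seq_len(n)]
}

# calibration: gain applied to the drive so the measured z-scored SWA
# event-triggered average has the configured amplitude (exact for
# single-state configurations)
# trim factor: residual plateau attenuation of the analytic gain formula,
# measured once by long-run event-triggered-average recovery experiments
KERNEL_GAIN_TRIM <- 1.06

kernel_gain <- function(amplitude, u, relvar = SWA_EST_RELVAR) {
  vu <- var(u)
  denom <- 1 - amplitude^2 * vu * (1 + relvar)
  if (denom < 0.05)
    stopf("SWA coupling kernel too strong/dense to embed (variance budget exhausted)")
  KERNEL_GAIN_TRIM * amplitude * sqrt(relvar / denom)
}

injected_kernel_df <- function(kcfg) {
  lags <- seq(-kcfg$half_width_s, kcfg$half_width_s, by = 0.25)
  data.frame(lag_s = lags, value = kcfg$amplitude * sign(lags))
}

# --- full session -----------------------------------------------------------

#' Simulate a complete multimodal session
#'
#' Generates LFP, EEG and EMG channels, a locomotion trace, a Ca2+ event
#' table and the generating ground truth for one session under a condition.
#' The LFP carries the NREM slow-wave train with nested high-gamma plus
#' state-dependent band noise; the EEG shares the slow-oscillation cycles
#' (but not delta waves) with an independent noise floor, encoding the
#' local-vs-global wave dichotomy; the same seed yields byte-identical
#' outputs, and paired conditions share random draws stage by stage.
#'
#' @param config a [sim_config].
#' @param condition "saline" or "CNO" (condition multipliers applied).
#' @return list with elements `lfp`, `eeg`, `emg` ([ephys_channel]s),
#'   `locomotion` (data frame time_s, speed), `events` (event table:
#'   onset_s + 20 features), `truth` (ground-truth list), `config`,
#'   `condition`.
#' @export
simulate_session <- function(config, condition = c("saline", "CNO")) {
  condition <- match.arg(condition)
  validate_sim_config(config)
  cfg <- resolve_condition(config, condition)
  seed <- cfg$seed
  fs <- cfg$sample_rate_ephys
  dur <- cfg$session_duration
  n <- round(dur * fs)

  state_1s <- simulate_state_sequence(cfg, seed)
  st_chr <- as.character(state_1s)
  ev <- simulate_event_onsets(cfg, state_1s, seed)

  # SWA-kernel drive on a 0.25 s grid, from (optionally state-restricted) events
  kcfg <- cfg$swa_coupling_kernel
  kev <- ev$onsets
  if (!is.null(cfg$kernel_states))
    kev <- kev[ev$state %in% cfg$kernel_states]
  u <- kernel_drive_u(kev, n, fs, kcfg$half_width_s)
  gain <- if (kcfg$amplitude > 0 && length(kev))
    kernel_gain(kcfg$amplitude, u) else 0
  mod <- pmax(1 + gain * u, 0.02)

  nrem_mask <- rep(st_chr == "NREM", each = fs)[seq_len(n)]
  train <- if (any(nrem_mask))
    simulate_wave_train(cfg, nrem_mask, seed, amp_envelope = sqrt(mod))
  else list(waves = data.frame(time_s = numeric(0), class = character(0),
                               peak = numeric(0), trough = numeric(0),
                               duration_ms = numeric(0)),
            trace = numeric(n), upstate = logical(n))

  bp <- cfg$band_power_by_state
  sec_t <- seq_len(length(state_1s)) - 0.5
  pw <- function(band) bp[[band]][st_chr]
  comp <- function(band, lo, hi, off) {
    x <- band_noise(n, fs, lo, hi, sub_seed(seed, off))
    x * env_interp(sqrt(pw(band)), sec_t, n, fs)
  }
  slow_bg <- comp("slow", 0.5, 4, 6L) * sqrt(mod)
  # theta: an amplitude-stable ~7 Hz rhythm (theta is rhythmic, not
  # broadband); a tone has no spectral skirts, so none of it leaks into the
  # 8-20 Hz band and its measured band power carries no estimator chi-noise
  set.seed(sub_seed(seed, 7L))
  th_f <- 7 + 0.8 * moving_average(rnorm(n), round(2 * fs))
  theta <- sqrt(2) * sin(2 * pi * cumsum(th_f) / fs) *
    env_interp(sqrt(pw("theta")), sec_t, n, fs)
  # mid band: broadband noise in wake/REM; in NREM an amplitude-stable
  # spindle-band rhythm, so the slow-wave-ratio denominator does not carry
  # estimator chi-noise inside NREM
  pw_mid <- pw("mid")
  mid <- band_noise(n, fs, 8, 20, sub_seed(seed, 8L)) *
    env_interp(sqrt(ifelse(st_chr == "NREM", 0, pw_mid)), sec_t, n, fs)
  set.seed(sub_seed(seed, 18L))
  f_inst <- 13 + 2 * moving_average(rnorm(n), round(2 * fs))
  tone <- sqrt(2) * sin(2 * pi * cumsum(f_inst) / fs)
  mid <- mid + tone *
    env_interp(sqrt(ifelse(st_chr == "NREM", pw_mid, 0)), sec_t, n, fs)
  g_env <- env_interp(sqrt(pw("high_gamma")), sec_t, n, fs)
  g_env <- g_env * (1 + (cfg$gamma_nesting_depth - 1) * train$upstate)
  gamma <- band_noise(n, fs, 80, min(100, 0.95 * fs / 2), sub_seed(seed, 9L)) * g_env
  lfp_floor <- floor_noise(n, fs, 20, min(70, 0.95 * fs / 2), cfg$floor_power,
                           sub_seed(seed, 10L))

  # shared LFP/EEG component with a pre-transition amplitude ramp
  cc <- cfg$coherence_coupling
  shared <- numeric(n)
  if (!is.null(cc) && cc$base_power > 0) {
    sh_env_1s <- rep(sqrt(cc$base_power), length(state_1s))
    per <- sleep_wake_periods(state_1s)
    if (nrow(per) > 1L) for (i in seq_len(nrow(per) - 1L)) {
      if (per$state[i] != "sleep") next
      idx <- (per$start_s[i] + 1):per$end_s[i]
      frac <- pmax(0, 1 - (per$end_s[i] - (idx - 0.5)) / cc$ramp_s)
      sh_env_1s[idx] <- sh_env_1s[idx] * (1 + (cc$pre_transition_gain - 1) * frac)
    }
    shared <- band_noise(n, fs, cc$band[1], cc$band[2], sub_seed(seed, 11L)) *
      env_interp(sh_env_1s, sec_t, n, fs)
  }
  # optional event-locked shared tone bursts (coherence round-trip tests)
  els <- cfg$event_locked_shared
  if (!is.null(els)) {
    burst_n <- round(els$dur_s * fs)
    tt <- seq_len(burst_n) / fs
    set.seed(sub_seed(seed, 12L))
    for (t0 in ev$onsets) {
      i0 <- floor(t0 * fs) + 1L
      if (i0 + burst_n - 1L > n) next
      ph <- runif(1) * 2 * pi
      sel <- i0:(i0 + burst_n - 1L)
      shared[sel] <- shared[sel] +
        els$amp * sin(2 * pi * els$freq * tt + ph) * sin(pi * tt / els$dur_s)
    }
  }

  # half-sine cycles carry harmonics into the theta band; a 5 Hz low-pass
  # confines the train to the slow band without touching what the 0.1-4 Hz
  # detection cascade sees
  train_lp <- if (any(nrem_mask)) butter_apply(train$trace, fs, "low", 4L, 5)
              else train$trace
  lfp <- train_lp + slow_bg + theta + mid + gamma + lfp_floor + shared

  # EEG: slow oscillations travel, delta waves do not
  eeg_train <- numeric(n)
  if (nrow(train$waves)) {
    so <- train$waves[train$waves$class == "slow_oscillation", , drop = FALSE]
    for (i in seq_len(nrow(so))) {
      d_half <- so$duration_ms[i] / 1000
      n1 <- max(1L, round(d_half * fs))
      i0 <- floor((so$time_s[i] - d_half) * fs) + 1L
      if (i0 < 1L || i0 + 2L * n1 - 1L > n) next
      ph <- (seq_len(n1) - 0.5) / n1
      seg <- c(so$peak[i] * sin(pi * ph), so$trough[i] * sin(pi * ph))
      sel <- i0:(i0 + 2L * n1 - 1L)
      eeg_train[sel] <- eeg_train[sel] + seg
    }
  }
  eeg <- eeg_train +
    band_noise(n, fs, 0.5, 4, sub_seed(seed, 13L)) *
      env_interp(sqrt(pmax(pw("slow"), 0.03)), sec_t, n, fs) +
    comp("mid", 8, 20, 14L) * 0.8 +
    floor_noise(n, fs, 20, min(70, 0.95 * fs / 2), cfg$floor_power,
                sub_seed(seed, 15L)) + shared

  emg <- {
    set.seed(sub_seed(seed, 16L))
    rnorm(n) * env_interp(cfg$emg_amplitude_by_state[st_chr], sec_t, n, fs)
  }

  # locomotion: strictly positive speed in locomotory wake, exact zero elsewhere
  fl <- cfg$sample_rate_loco
  nl <- round(dur * fl)
  set.seed(sub_seed(seed, 17L))
  loco_mask <- rep(st_chr == "wake_locomotory", each = fl)[seq_len(nl)]
  speed <- numeric(nl)
  if (any(loco_mask)) {
    sm <- moving_average(rnorm(nl), round(fl / 2))
    speed[loco_mask] <- pmax(0.5, 4 + 6 * sm[loco_mask])
  }
  locomotion <- data.frame(time_s = (seq_len(nl) - 0.5) / fl, speed = speed)

  feats <- simulate_event_features(length(ev$onsets), ev$state,
                                   cfg$feature_params, seed)
  events <- cbind(data.frame(onset_s = ev$onsets), feats)
  events$session_id <- paste0("sim", seed)
  events$condition <- condition

  sid <- paste0("sim", seed)
  truth <- list(
    state_1s = state_1s,
    periods = runs_to_periods(st_chr, 1),
    waves = train$waves,
    rate_1s = ev$rate_1s,
    event_state = ev$state,
    injected_kernel = injected_kernel_df(kcfg),
    kernel_gain = gain,
    seed = seed
  )
  list(
    lfp = ephys_channel(lfp, fs, "LFP", sid),
    eeg = ephys_channel(eeg, fs, "EEG", sid),
    emg = ephys_channel(emg, fs, "EMG", sid),
    locomotion = locomotion,
    events = events,
    truth = truth,
    config = config,
    condition = condition
  )
}
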