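test_that("the SWA trace tracks slow-band amplitude modulation", {
  fs <- 250
  t <- seq_len(120 * fs) / fs
  # constant-amplitude tone: trace ~ flat zero after z-scoring
  tr <- swa_trace(make_channel(sin(2 * pi * 2 * t), fs, zscored = TRUE))
  mid <- tr$swa[tr$time_s > 5 & tr$time_s < 115]
  expect_lt(sd(mid), 0.35)
  # 10 s on / 10 s off amplitude modulation: trace alternates
  envl <- rep(rep(c(1, 0), each = 10 * fs), 6)
  tr2 <- swa_trace(make_channel(sin(2 * pi * 2 * t) * envl, fs, zscored = TRUE))
  on_idx <- ((floor(tr2$time_s) %/% 10) %% 2) == 0
  expect_gt(mean(tr2$swa[on_idx]), mean(tr2$swa[!on_idx]) + 1)
  expect_error(swa_trace(make_channel(rnorm(5 * fs), fs)), "10 s")
})

test_that("event-triggered averages are exact on constructed traces", {
  swa <- data.frame(time_s = seq(0.125, 300, 0.25), swa = 0)
  attr(swa, "step_s") <- 0.25
  # flat trace: ETA flat at zero
  eta <- event_triggered_swa(swa, c(50, 100, 150))
  expect_true(all(eta$mean == 0))
  expect_true(all(eta$lag_s == -rev(eta$lag_s)))
  # single event: ETA equals the raw segment, SEM undefined
  swa2 <- swa; swa2$swa <- sin(swa2$time_s)
  attr(swa2, "step_s") <- 0.25
  eta1 <- event_triggered_swa(swa2, 100)
  gi <- round((100 - swa2$time_s[1]) / 0.25) + 1
  expect_equal(eta1$mean, swa2$swa[gi + (-20:20)])
  expect_true(all(is.na(eta1$sem)))
  # linearity: adding a constant shifts the ETA by that constant
  swa3 <- swa2; swa3$swa <- swa3$swa + 2
  attr(swa3, "step_s") <- 0.25
  eta3 <- event_triggered_swa(swa3, c(60, 100, 200))
  eta2 <- event_triggered_swa(swa2, c(60, 100, 200))
  expect_equal(eta3$mean, eta2$mean + 2, tolerance = 1e-12)
  # events whose windows exit the session are dropped
  expect_equal(attr(event_triggered_swa(swa2, c(1, 100)), "n_events"), 1L)
  expect_error(event_triggered_swa(swa2, 0.5), "no usable events")
})

test_that("per-event SWA modulation is zero for symmetric traces", {
  swa <- data.frame(time_s = seq(0.125, 200, 0.25), swa = 0)
  t0 <- swa$time_s[400]
  swa$swa <- cos((swa$time_s - t0) * 2)  # symmetric about a grid point
  attr(swa, "step_s") <- 0.25
  m <- swa_modulation(swa, t0)
  expect_lt(abs(m$modulation), 1e-9)
})

test_that("the injected SWA kernel is recovered by the ETA", {
  cfg <- sim_config(
    session_duration = 2400, sample_rate_ephys = 250,
    bout_duration_means = c(wake_stationary = 600),
    ca_rate_by_state = c(NREM = 0, REM = 0, wake_stationary = 12.5,
                         wake_locomotory = 0),
    transition_ramp = c(sleep = 0, wake = 0),
    swa_coupling_kernel = list(amplitude = 0.5, half_width_s = 2),
    coherence_coupling = NULL, seed = 21)
  ests <- mods <- NULL
  for (sd in 21:22) {
    cfg$seed <- sd
    s <- simulate_session(cfg)
    swa <- swa_trace(zscore_session(s$lfp))
    eta <- event_triggered_swa(swa, s$events$onset_s, window_s = 6)
    k <- s$truth$injected_kernel
    ests <- rbind(ests, eta$mean[match(round(k$lag_s, 2), round(eta$lag_s, 2))])
    mods <- c(mods, swa_modulation(swa, s$events$onset_s)$modulation)
  }
  k <- injected <- s$truth$injected_kernel$value
  expect_lt(max(abs(colMeans(ests) - injected)), 0.12)
  expect_lt(abs(mean(mods) - 1), 0.2)
})

test_that("sleep-restricted kernels yield higher sleep modulation", {
  ok <- 0
  for (sd in 1:5) {
    cfg <- test_config(seed = sd + 40, duration = 2400,
                       swa_coupling_kernel = list(amplitude = 0.35,
                                                  half_width_s = 2),
                       kernel_states = c("NREM"))
    s <- simulate_session(cfg)
    swa <- swa_trace(zscore_session(s$lfp))
    st <- ifelse(s$truth$event_state == "NREM", "sleep", "wake")
    m <- swa_modulation(swa, s$events$onset_s, states = st)
    if (!is.null(m$rank_sum) &&
        m$by_state["sleep"] > m$by_state["wake"] &&
        m$rank_sum$p.value < 0.05) ok <- ok + 1
  }
  expect_gte(ok, 4)
})

test_that("Welch coherence is exact for self-coherence and bounded", {
  set.seed(22)
  x <- rnorm(1500); y <- rnorm(1500)
  self <- welch_coherence(x, x, 1000)
  expect_true(all(abs(self$coherence[is.finite(self$coherence)] - 1) < 1e-12))
  co <- welch_coherence(x, y, 1000)
  expect_true(all(co$coherence >= 0 & co$coherence <= 1, na.rm = TRUE))
  # symmetric in channel order
  expect_equal(welch_coherence(y, x, 1000)$coherence, co$coherence,
               tolerance = 1e-12)
  expect_error(welch_coherence(x[1:500], y[1:500], 1000), "shorter")
})

test_that("the null coherence stays below the documented bias ceiling", {
  set.seed(23)
  meds <- replicate(300, median(welch_coherence(rnorm(1500), rnorm(1500),
                                                1000)$coherence, na.rm = TRUE))
  expect_lt(median(meds), COHERENCE_NULL_CEILING)
  expect_equal(median(meds), COHERENCE_NULL_BIAS, tolerance = 0.05)
})

test_that("a shared tone shows up at its frequency bin", {
  set.seed(24)
  fs <- 1000; tt <- (1:1500) / fs
  vals <- replicate(200, {
    ph <- runif(1) * 2 * pi
    s <- sqrt(2) * sin(2 * pi * 7 * tt + ph)
    welch_coherence(s + rnorm(1500), s + rnorm(1500), fs)$coherence[2:20]
  })
  med <- apply(vals, 1, median)
  freqs <- (2:20 - 1) * fs / 1024
  peak_bin <- which.max(med)
  expect_equal(freqs[peak_bin], 7, tolerance = 0.5)
  expect_lt(abs(med[peak_bin] - COHERENCE_SHARED_TONE_REF), 0.15)
  expect_gt(med[peak_bin], med[peak_bin + 3])
})

test_that("random-aligned controls are seeded and respect periods", {
  s <- test_session(seed = 3, duration = 1200)
  lfp <- zscore_session(s$lfp); eeg <- zscore_session(s$eeg)
  r0 <- random_aligned_control(lfp, eeg, 0, nfft = 256L)
  expect_equal(r0$n_events, 0L)
  r1 <- random_aligned_control(lfp, eeg, 20, seed = 5, nfft = 256L)
  r2 <- random_aligned_control(lfp, eeg, 20, seed = 5, nfft = 256L)
  expect_identical(r1$alignment_points, r2$alignment_points)
  nrem <- s$truth$periods[s$truth$periods$state == "NREM", ]
  r3 <- random_aligned_control(lfp, eeg, 30, seed = 6, nfft = 256L,
                               periods = nrem)
  expect_true(all(in_periods(r3$alignment_points, nrem)))
})

test_that("per-frequency comparison applies Bonferroni exactly", {
  expect_equal(bonferroni(0.0005, 50), 0.025)
  expect_equal(bonferroni(0.2, 50), 1)
  p <- runif(20)
  expect_true(all(bonferroni(p) >= p))
  # identical inputs: nothing significant
  m <- matrix(runif(5 * 10), 5)
  cmp <- compare_coherence(m, m, freqs = 1:10)
  expect_false(any(cmp$significant))
  expect_error(compare_coherence(m[1, , drop = FALSE], m[1, , drop = FALSE],
                                 1:10), "2 mice")
})

test_that("event-locked shared bursts produce significant coherence", {
  em <- rm_ <- NULL
  for (m in 1:5) {
    cfg <- test_config(seed = 100 + m, duration = 1200,
                       ca_rate_by_state = c(NREM = 10, REM = 10,
                                            wake_stationary = 10,
                                            wake_locomotory = 10),
                       event_locked_shared = list(freq = 7, amp = 0.6,
                                                  dur_s = 1),
                       coherence_coupling = NULL)
    s <- simulate_session(cfg)
    lfp <- zscore_session(s$lfp); eeg <- zscore_session(s$eeg)
    ev <- event_aligned_coherence(lfp, eeg, s$events$onset_s, nfft = 256L)
    rn <- random_aligned_control(lfp, eeg, ev$n_events, seed = 200 + m,
                                 nfft = 256L)
    em <- rbind(em, ev$median); rm_ <- rbind(rm_, rn$median)
  }
  cmp <- compare_coherence(em, rm_, (0:128) * 250 / 256, max_freq_hz = 20)
  sig <- cmp$freq_hz[cmp$significant]
  expect_true(any(abs(sig - 7) < 1))
})

test_that("transition-proximity bins follow the truncation arithmetic", {
  # a 7 s sleep tail populates the first four bins only
  hyp <- hypnogram(data.frame(start_s = c(0, 7), end_s = c(7, 60),
                              state = c("NREM", "wake"), substate = "n/a"))
  fs <- 250
  set.seed(25)
  ch1 <- make_channel(rnorm(60 * fs), fs, zscored = TRUE)
  ch2 <- make_channel(rnorm(60 * fs), fs, zscored = TRUE)
  onsets <- c(6.8, 5.5, 3.5, 1.5, 0.3)  # tau = -0.2, -1.5, -3.5, -5.5, -6.7
  tb <- transition_binned_coherence(ch1, ch2, onsets, hyp, seed = 1,
                                    nfft = 256L, n_bins = 6L)
  expect_equal(tb$n_event[1:4], c(1, 1, 1, 1))
  expect_equal(tb$n_event[5:6], c(1, 0))  # tau -6.7 in bin 5; bin 6 empty
  expect_equal(tb$lo_s, -c(0.5, 2.5, 4.5, 6.5, 8.5, 10.5))
})

test_that("pre-transition shared-component ramps raise proximal coherence", {
  cfg <- test_config(seed = 31, duration = 7200,
                     ca_rate_by_state = c(NREM = 60, REM = 20,
                                          wake_stationary = 40,
                                          wake_locomotory = 80),
                     coherence_coupling = list(band = c(2, 12),
                                               base_power = 0.05,
                                               pre_transition_gain = 4,
                                               ramp_s = 10))
  s <- cached("coh_ramp_31", simulate_session(cfg))
  lfp <- zscore_session(s$lfp); eeg <- zscore_session(s$eeg)
  hyp <- truth_hypnogram(s)
  nrem <- state_periods(hyp, "NREM")
  on <- s$events$onset_s[in_periods(s$events$onset_s, nrem)]
  tb <- transition_binned_coherence(lfp, eeg, on, hyp, seed = 31,
                                    nfft = 256L, n_bins = 8L)
  pvd <- attr(tb, "proximal_vs_distal")
  expect_gt(mean(tb$mean_event[2:3]), mean(tb$mean_event[7:8], na.rm = TRUE))
  expect_lt(pvd$p.value, 0.05)
  expect_gt(pvd$statistic, 0)
})
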