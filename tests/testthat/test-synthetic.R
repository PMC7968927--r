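test_that("the generator is fully determined by (config, seed, condition)", {
  cfg <- test_config(seed = 7, duration = 600)
  a <- simulate_session(cfg)
  b <- simulate_session(cfg)
  expect_identical(a$events, b$events)
  expect_identical(a$lfp$samples[1:1000], b$lfp$samples[1:1000])
  expect_identical(a$truth$waves, b$truth$waves)
  c2 <- simulate_session(test_config(seed = 8, duration = 600))
  expect_false(identical(a$lfp$samples[1:1000], c2$lfp$samples[1:1000]))
})

test_that("ground-truth states tile the session exactly", {
  for (sd in 1:5) {
    s <- test_session(seed = sd, duration = 900)
    per <- s$truth$periods
    expect_equal(sum(per$end_s - per$start_s), 900)
    expect_equal(per$start_s[-1], per$end_s[-nrow(per)])
    expect_equal(length(s$truth$state_1s), 900)
  }
  # all truth waves lie inside NREM periods
  s <- test_session(seed = 2, duration = 1200)
  nrem <- s$truth$periods[s$truth$periods$state == "NREM", ]
  expect_true(all(in_periods(s$truth$waves$time_s, nrem)))
})

test_that("config validation refuses impossible settings", {
  expect_error(sim_config(session_duration = 100), "twice the longest")
  bad <- default_feature_params()
  bad$cor[1, 2] <- 0.9; bad$cor[2, 1] <- 0.9
  bad$cor[1, 3] <- -0.9; bad$cor[3, 1] <- -0.9
  bad$cor[2, 3] <- -0.9; bad$cor[3, 2] <- -0.9
  expect_error(sim_config(feature_params = bad), "positive semi-definite")
  expect_error(sim_config(ca_rate_by_state = c(NREM = -1, REM = 1,
                                               wake_stationary = 1,
                                               wake_locomotory = 1)),
               ">= 0")
})

test_that("state-dependent slow-wave ratio separates NREM from wake", {
  sc <- scored_session(seed = 3, duration = 1200)
  f <- sc$scoring$features
  truth <- as.character(sc$session$truth$state_1s)
  st <- truth[pmax(1, round(f$frame_time))]
  expect_gt(mean(f$swr_z[st == "NREM"], na.rm = TRUE),
            mean(f$swr_z[st %in% c("wake_stationary", "wake_locomotory")],
                 na.rm = TRUE) + 1)
})

test_that("event rates recover the injected state ordering and null", {
  # injected ordering locomotory > stationary > NREM
  ok <- 0
  for (sd in 1:6) {
    cfg <- test_config(seed = sd, duration = 2400)
    st <- simulate_state_sequence(cfg)
    ev <- simulate_event_onsets(cfg, st)
    occ <- table(st)[c("NREM", "wake_stationary", "wake_locomotory")]
    cnt <- table(factor(ev$state, names(occ)))
    r <- as.numeric(cnt) / as.numeric(occ) * 60
    if (!any(is.na(r)) && r[1] < r[2] && r[2] < r[3]) ok <- ok + 1
  }
  expect_gte(ok, 5)

  # all rates equal, no ramp: state differences are only Poisson noise
  nsig <- 0
  for (sd in 1:10) {
    cfg <- test_config(seed = sd, duration = 2400,
                       ca_rate_by_state = c(NREM = 20, REM = 20,
                                            wake_stationary = 20,
                                            wake_locomotory = 20),
                       transition_ramp = c(sleep = 0, wake = 0))
    st <- simulate_state_sequence(cfg)
    ev <- simulate_event_onsets(cfg, st)
    occ <- table(st)
    keep <- occ > 60
    cnt <- table(factor(ev$state, names(occ)))[keep]
    p <- chisq.test(cnt, p = as.numeric(occ[keep]) / sum(occ[keep]))$p.value
    if (p < 0.01) nsig <- nsig + 1
  }
  expect_lte(nsig, 1)
})

test_that("wave train honors rates, durations and amplitude linearity", {
  cfg <- test_config(seed = 1, duration = 600)
  mask <- rep(TRUE, 600 * 250)

  # zero rates: empty list, zero trace
  cfg0 <- test_config(seed = 1, duration = 600,
                      wave_rates = c(slow_oscillation = 0, delta = 0),
                      background_cycle_rate = 0)
  tr0 <- simulate_wave_train(cfg0, mask)
  expect_equal(nrow(tr0$waves), 0)
  expect_true(all(tr0$trace == 0))

  # degenerate duration distribution: every generated duration equal
  cfgd <- test_config(seed = 2, duration = 600)
  cfgd$wave_amplitude_params$slow_oscillation$p2t_ms <- c(300, 1e-8)
  cfgd$wave_amplitude_params$slow_oscillation$p2t_range_ms <- c(299.9, 300.1)
  trd <- simulate_wave_train(cfgd, mask)
  so <- trd$waves[trd$waves$class == "slow_oscillation", ]
  expect_true(all(abs(so$duration_ms - 300) < 0.2))

  # refusal when requested waves cannot fit in NREM
  cfgov <- test_config(seed = 1, duration = 600,
                       wave_rates = c(slow_oscillation = 120, delta = 120))
  expect_error(simulate_wave_train(cfgov, mask), "occupancy")

  # condition linearity: doubling the delta multiplier doubles truth
  # amplitudes exactly (common random numbers)
  ce <- condition_gi(); ce$delta_amp <- 1.2
  c1 <- test_config(seed = 5, duration = 900, condition_effects = ce)
  ce2 <- ce; ce2$delta_amp <- 2.4
  c2 <- test_config(seed = 5, duration = 900, condition_effects = ce2)
  w1 <- simulate_session(c1, "CNO")$truth$waves
  w2 <- simulate_session(c2, "CNO")$truth$waves
  d1 <- w1[w1$class == "delta_wave", ]; d2 <- w2[w2$class == "delta_wave", ]
  expect_equal(nrow(d1), nrow(d2))
  expect_equal(d2$peak, 2 * d1$peak, tolerance = 1e-12)
  expect_equal(d2$trough, 2 * d1$trough, tolerance = 1e-12)
})

test_that("high-gamma nesting depth is recovered from the generated LFP", {
  s <- test_session(seed = 4, duration = 1200)
  fs <- s$lfp$sample_rate
  hg <- abs(astrosleep:::butter_apply(s$lfp$samples, fs, "pass", 4L, c(80, 100)))
  w <- s$truth$waves
  half <- w$duration_ms / 2000
  amp_at <- function(times) vapply(times, function(t0) {
    i <- max(1, round((t0 - 0.05) * fs)):min(length(hg), round((t0 + 0.05) * fs))
    mean(hg[i])
  }, 0)
  pk <- amp_at(w$time_s - half)   # peak centers (DOWN)
  tr <- amp_at(w$time_s + half)   # trough centers (UP)
  expect_equal(mean(tr) / mean(pk), 3, tolerance = 0.1)
})

test_that("event features have the documented shape and state effects", {
  fp <- default_feature_params()
  m0 <- simulate_event_features(0, character(0), fp)
  expect_equal(dim(m0), c(0L, 20L))
  expect_identical(names(m0), aqua_feature_names())

  expect_error(simulate_event_features(5, rep("moonwalk", 5), fp), "moonwalk")

  # identical distributions: per-feature KS test is null-behaved
  fp2 <- fp
  fp2$means$wake_stationary <- fp2$means$NREM
  nsig <- 0
  for (sd in 1:20) {
    x <- simulate_event_features(200, rep(c("NREM", "wake_stationary"), 100),
                                 fp2, seed = sd)
    j <- sample(20, 1)
    p <- suppressWarnings(ks.test(x[rep(c(TRUE, FALSE), 100), j],
                                  x[rep(c(FALSE, TRUE), 100), j])$p.value)
    if (p < 0.01) nsig <- nsig + 1
  }
  expect_lte(nsig, 2)

  # a 3 SD mean shift in one feature is detected through PCA + KS
  fp3 <- fp
  fp3$means$wake_stationary <- fp3$means$NREM
  fp3$means$wake_stationary[5] <- fp3$means$NREM[5] + 3 * fp3$sds[5]
  hits <- 0
  for (sd in 1:10) {
    st <- rep(c("NREM", "wake_stationary"), 150)
    x <- simulate_event_features(300, st, fp3, seed = sd)
    pc <- feature_pca(x)
    cmp <- pc_state_comparison(pc$scores, st)
    if (any(cmp$p < 0.01)) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("locomotion is nonzero exactly in locomotory wake", {
  s <- test_session(seed = 6, duration = 900)
  st <- as.character(s$truth$state_1s)[pmin(900, floor(s$locomotion$time_s) + 1)]
  moving <- s$locomotion$speed > 0
  expect_true(all(st[moving] == "wake_locomotory"))
  loco_sec <- st == "wake_locomotory"
  if (any(loco_sec)) expect_gt(mean(moving[loco_sec]), 0.95)
})
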