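test_that("rate-SWA correlation behaves on constructed and null inputs", {
  # rate exactly proportional to -SWA: r = -1
  swa <- data.frame(time_s = seq(0.125, 1200, 0.25),
                    swa = rep(seq(2, -2, length.out = 10), each = 480))
  attr(swa, "step_s") <- 0.25
  rates <- seq(4, 40, by = 4)  # events per 120 s bin, integer
  set.seed(99)
  onsets <- unlist(lapply(1:10, function(b)
    sort(runif(rates[b], (b - 1) * 120, b * 120 - 1e-6))))
  res <- rate_swa_correlation(onsets, swa)
  expect_equal(res$r, -1, tolerance = 1e-9)

  # constant rate: flagged, r undefined
  on2 <- seq(0.5, 1199.5, length.out = 10 * 120)
  res2 <- rate_swa_correlation(on2, swa)
  expect_true(res2$flagged || abs(res2$r) < 1)

  # independent events and SWA: |r| small in most seeds
  nbig <- 0
  for (sd in 1:20) {
    set.seed(sd)
    swa_n <- data.frame(time_s = seq(0.125, 7200, 0.25),
                        swa = rnorm(28800))
    attr(swa_n, "step_s") <- 0.25
    on_n <- sort(runif(600, 0, 7200))
    r <- rate_swa_correlation(on_n, swa_n)$r
    if (abs(r) >= 0.3) nbig <- nbig + 1
  }
  expect_lte(nbig, 1)

  expect_error(rate_swa_correlation(1:10, swa[1:400, ]), "3 full bins")
})

test_that("state event rates recover generator rates and the null", {
  s <- test_session(seed = 5, duration = 2400)
  hyp <- truth_hypnogram_sub(s)
  res <- state_event_rates(s$events$onset_s, hyp)
  r <- res$rates
  # generator rates 20 / 40 / 80 per minute within 15%
  expect_equal(unname(r["NREM"]), 20, tolerance = 0.15)
  expect_equal(unname(r["wake_stationary"]), 40, tolerance = 0.15)
  expect_equal(unname(r["wake_locomotory"]), 80, tolerance = 0.15)
  expect_true(r["NREM"] < r["wake_stationary"] &&
                r["wake_stationary"] < r["wake_locomotory"])
  # rank-sum comparisons are returned for each pair
  expect_gte(length(res$tests), 1L)

  # zero events: all rates zero
  r0 <- state_event_rates(numeric(0), hyp)$rates
  expect_true(all(r0 == 0, na.rm = TRUE))
})

test_that("event conservation: per-state counts sum to the total in periods", {
  s <- test_session(seed = 5, duration = 2400)
  hyp <- truth_hypnogram_sub(s)
  res <- state_event_rates(s$events$onset_s, hyp,
                           states = c("NREM", "REM", "wake_stationary",
                                      "wake_locomotory"))
  tot <- sum(vapply(res$per_period, sum, 0) * 0) +
    sum(unlist(lapply(names(res$per_period), function(st) {
      per <- if (st %in% c("NREM", "REM")) state_periods(hyp, st)
             else state_periods(hyp, "wake", sub("wake_", "", st))
      sum(in_periods(s$events$onset_s, per))
    })))
  inside <- sum(in_periods(s$events$onset_s, hyp))
  expect_equal(tot, inside)
})

test_that("transition profiles are normalized and detect the ramp", {
  # single event 1 s before the transition: all mass in the final bin
  hyp <- hypnogram(data.frame(start_s = c(0, 100), end_s = c(100, 200),
                              state = c("NREM", "wake"), substate = "n/a"))
  pr <- transition_profile(99, hyp)
  expect_equal(pr$to_wake$mean, c(0, 0, 0, 0, 0, 1))

  # homogeneous events: flat profile, each 5 s bin has ~ bin/period share
  set.seed(12)
  prs <- replicate(20, {
    on <- sort(runif(150, 0, 100))
    transition_profile(on, hyp)$to_wake$mean
  })
  expect_lt(abs(mean(rowMeans(prs)) - 0.05), 0.005)
  slope <- coef(lm(rowMeans(prs) ~ seq_len(6)))[2]
  expect_lt(abs(slope), 0.005)

  # generator ramp: pre-wake profile slopes upward in most seeds
  ok <- 0
  for (sd in 1:8) {
    cfg <- test_config(seed = sd, duration = 7200)
    st <- simulate_state_sequence(cfg)
    ev <- simulate_event_onsets(cfg, st)
    s_min <- list(truth = list(periods = astrosleep:::runs_to_periods(as.character(st), 1)))
    h <- truth_hypnogram(s_min)
    p <- transition_profile(ev$onsets, h)
    sl <- coef(lm(p$to_wake$mean ~ p$to_wake$lag_s))[2]
    if (sl > 0) ok <- ok + 1
  }
  expect_gte(ok, 7)
})

test_that("tertile change measures last-third enrichment", {
  hyp <- hypnogram(data.frame(start_s = c(0, 90), end_s = c(90, 180),
                              state = c("NREM", "wake"), substate = "n/a"))
  # all events in the final third of sleep: change = count
  on <- seq(61, 89, by = 1)
  tc <- tertile_change(on, hyp)
  expect_equal(tc$sleep$change, length(on))
  # uniform events: change ~ 0 in expectation
  set.seed(13)
  ch <- replicate(200, {
    tertile_change(sort(runif(30, 0, 90)), hyp)$sleep$change
  })
  expect_lt(abs(mean(ch)), 1)
})

test_that("cumulative counts split early and late rates", {
  # constant rate: linear curve, early ~= late
  on <- seq(0.5, 1199.5, by = 2)
  cc <- cumulative_counts(on, 0, 1200, 1200)
  expect_equal(cc$early_rate, cc$late_rate, tolerance = 0.05)
  expect_equal(cc$curve$count[nrow(cc$curve)], length(on))
  fit <- lm(count ~ time_s, cc$curve)
  expect_gt(summary(fit)$r.squared, 0.999)

  # zero events after t0: flat curve
  cc0 <- cumulative_counts(numeric(0), 0, 600, 1200)
  expect_true(all(cc0$curve$count == 0))

  expect_warning(cumulative_counts(on, 600, 1200, 1200), "truncated")
  expect_error(cumulative_counts(on, -5, 100, 1200), "outside")

  # surge-then-suppression: early rate high, late rate low
  s <- cached("gq_small", simulate_session(
    test_config(seed = 9, duration = 2400,
                condition_effects = condition_gq()), "CNO"))
  cc2 <- cumulative_counts(s$events$onset_s, 0, 2400, 2400)
  expect_gt(cc2$early_rate, 10 * cc2$late_rate)
})

test_that("feature PCA matches closed-form eigen fractions", {
  # data constructed to have an exact sample covariance diag(20:1)
  set.seed(14)
  n <- 200; p <- 20
  x <- matrix(rnorm(n * p), n)
  x <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(x)
  white <- sv$u %*% t(sv$v) * sqrt(n - 1)      # exact identity covariance
  lam <- seq(20, 1)
  y <- white %*% diag(sqrt(lam))
  colnames(y) <- aqua_feature_names()
  pc <- feature_pca(y, k = 5, standardize = FALSE)
  expect_equal(pc$variance_explained, lam / sum(lam), tolerance = 1e-8)
  # cumulative variance at k = p is exactly 1
  expect_equal(sum(pc$variance_explained), 1, tolerance = 1e-12)
  # loadings orthonormal
  g <- t(pc$loadings) %*% pc$loadings
  expect_equal(g, diag(5), tolerance = 1e-8, ignore_attr = TRUE)

  # duplication invariance
  pc2 <- feature_pca(rbind(y, y), k = 5, standardize = FALSE)
  expect_equal(abs(pc2$loadings), abs(pc$loadings), tolerance = 1e-8)
  expect_equal(pc2$variance_explained, pc$variance_explained, tolerance = 1e-8)

  # constant column dropped with zero-padded loadings
  y2 <- y; y2[, 3] <- 7
  expect_warning(pc3 <- feature_pca(y2, k = 2), "constant")
  expect_true(all(pc3$loadings[3, ] == 0))

  expect_error(feature_pca(y[1:10, ]), "at least")
})

test_that("equicorrelated features give the known top eigen fraction", {
  # correlation matrix with all off-diagonals rho: eigenvalues
  # 1 + (p-1) rho and (1 - rho) (multiplicity p-1)
  set.seed(15)
  p <- 20; rho <- 0.5; n <- 300
  R <- matrix(rho, p, p); diag(R) <- 1
  x <- matrix(rnorm(n * p), n)
  x <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(x)
  white <- sv$u %*% t(sv$v) * sqrt(n - 1)
  ev <- eigen(R, symmetric = TRUE)
  y <- white %*% (ev$vectors %*% diag(sqrt(ev$values)) %*% t(ev$vectors))
  colnames(y) <- aqua_feature_names()
  pc <- feature_pca(y, k = 1, standardize = TRUE)
  expect_equal(pc$variance_explained[1], (1 + (p - 1) * rho) / p,
               tolerance = 1e-6)
})

test_that("PC state comparisons use exact ECDF distances", {
  set.seed(16)
  sc <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("PC1", "PC2")))
  st <- rep(c("a", "b"), 50)
  same <- pc_state_comparison(rbind(sc, sc),
                              c(rep("a", 100), rep("b", 100)))
  expect_true(all(same$ks_distance == 0))
  # disjoint supports: distance 1
  sc2 <- rbind(sc, sc + 100)
  d <- pc_state_comparison(sc2, c(rep("a", 100), rep("b", 100)))
  expect_true(all(d$ks_distance == 1))
  # matches the brute-force oracle on random samples
  cmp <- pc_state_comparison(sc, st)
  for (j in 1:2) {
    expect_equal(cmp$ks_distance[cmp$pc == paste0("PC", j)],
                 ks_distance_oracle(sc[st == "a", j], sc[st == "b", j]))
  }
  expect_error(pc_state_comparison(sc, rep("a", 100)), ">= 2 states")
})

test_that("condition KS distances localize the CNO effect to sleep", {
  fp <- default_feature_params()
  gen <- function(m, cond, st, n, shift) {
    mu_shift <- if (st == "NREM" && cond == "CNO") shift else 0
    x <- simulate_event_features(
      n, rep(st, n), within(fp, {
        means <- lapply(means, function(v) v + mu_shift * sds)
      }), seed = m * 100 + (cond == "CNO") * 7 + (st == "NREM") * 3)
    x
  }
  ok <- 0
  for (rep_i in 1:5) {
    rows <- list(); meta <- list()
    for (m in 1:6) for (cond in c("saline", "CNO")) for (st in c("NREM", "wake_stationary")) {
      x <- gen(m + rep_i * 10, cond, st, 80, shift = 0.8)
      rows[[length(rows) + 1L]] <- x
      meta[[length(meta) + 1L]] <- data.frame(mouse = rep(m, 80), cond = cond,
                                              st = ifelse(st == "NREM", "NREM", "wake"))
    }
    x <- do.call(rbind, rows); mm <- do.call(rbind, meta)
    pc <- feature_pca(x)
    res <- condition_ks_distance(pc$scores, mm$mouse, mm$cond, mm$st)
    d <- res$distances
    sleep_d <- mean(d$ks_distance[d$state == "NREM"])
    wake_d <- mean(d$ks_distance[d$state == "wake"])
    if (sleep_d > wake_d) ok <- ok + 1
  }
  expect_gte(ok, 4)

  # identical conditions: all distances are small-sample noise, Wilcoxon n.s.
  x0 <- simulate_event_features(400, rep(c("NREM", "wake_stationary"), 200),
                                fp, seed = 3)
  pc0 <- feature_pca(x0)
  st0 <- rep(c("NREM", "wake"), 200)
  res0 <- condition_ks_distance(pc0$scores, rep(1:4, each = 100),
                                rep(rep(c("saline", "CNO"), each = 50), 4), st0)
  expect_true(all(res0$distances$ks_distance < 0.5))

  # single mouse: distances computed, Wilcoxon refused
  res1 <- condition_ks_distance(pc0$scores[1:100, ], rep(1, 100),
                                rep(rep(c("saline", "CNO"), each = 25), 2),
                                st0[1:100])
  expect_true(all(vapply(res1$wilcoxon, is.null, TRUE)))
})
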