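# Shared fixtures: small synthetic sessions are expensive to generate, so
# they are cached per (seed, duration, variant) within one test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

test_config <- function(seed = 1, duration = 1200, fs = 250, ...) {
  sim_config(session_duration = duration, sample_rate_ephys = fs,
             seed = seed, ...)
}

# a default-parameter session at reduced sample rate (all bands of interest
# lie below 100 Hz) for speed
test_session <- function(seed = 1, duration = 1200, condition = "saline", ...) {
  key <- paste("sess", seed, duration, condition,
               paste(deparse(substitute(list(...))), collapse = ""), sep = "_")
  cached(key, simulate_session(test_config(seed, duration, ...), condition))
}

scored_session <- function(seed = 1, duration = 1200, ...) {
  key <- paste("scored", seed, duration, sep = "_")
  cached(key, {
    s <- test_session(seed, duration, ...)
    sc <- score_sleep(s$lfp, s$emg, s$locomotion)
    list(session = s, scoring = sc)
  })
}

# hypnogram built directly from generator truth (for tests that isolate a
# downstream stage from scoring)
truth_hypnogram <- function(session) {
  per <- session$truth$periods
  per$state <- ifelse(per$state %in% c("wake_stationary", "wake_locomotory"),
                      "wake", per$state)
  per$substate <- "n/a"
  r <- rle(per$state)
  ie <- cumsum(r$lengths); is <- ie - r$lengths + 1L
  hypnogram(data.frame(start_s = per$start_s[is], end_s = per$end_s[ie],
                       state = r$values, substate = "n/a"))
}

# truth hypnogram including wake substates
truth_hypnogram_sub <- function(session) {
  per <- session$truth$periods
  out <- data.frame(start_s = per$start_s, end_s = per$end_s,
                    state = ifelse(per$state %in% c("wake_stationary",
                                                    "wake_locomotory"),
                                   "wake", per$state),
                    substate = ifelse(per$state == "wake_stationary", "stationary",
                             ifelse(per$state == "wake_locomotory", "locomotory",
                                    "n/a")))
  hypnogram(out)
}

# brute-force O(n^2) KS distance oracle
ks_distance_oracle <- function(x, y) {
  pts <- c(x, y)
  max(vapply(pts, function(p)
    abs(mean(x <= p) - mean(y <= p)), 0))
}

make_channel <- function(x, fs = 250, channel = "LFP", zscored = FALSE) {
  ephys_channel(x, fs, channel, "test", zscored = zscored)
}
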