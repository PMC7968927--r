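# Astrocyte Ca2+ event statistics: event rate vs SWA and behavioral state,
# pre-transition dynamics, tertile analysis, cumulative counts after
# injection, and the 20-feature PCA with ECDF/KS/Wilcoxon machinery.

#' Event rate vs SWA correlation
#'
#' Divides the session into bins, pairs per-bin event rate with per-bin mean
#' SWA, and reports Pearson's r with a two-sided p-value.
#'
#' @param onsets event onset times (s).
#' @param swa data frame from [swa_trace()].
#' @param bin_s bin width in seconds (default 120).
#' @return list(bins, r, p, flagged).
#' @export
rate_swa_correlation <- function(onsets, swa, bin_s = 120) {
  t_max <- max(swa$time_s)
  edges <- seq(0, t_max, by = bin_s)
  if (length(edges) < 4L) stopf("need at least 3 full bins")
  n_bins <- length(edges) - 1L
  counts <- tabulate(findInterval(onsets, edges,
                                  rightmost.closed = FALSE), n_bins)
  swa_bin <- tapply(swa$swa,
                    factor(findInterval(swa$time_s, edges), levels = seq_len(n_bins)),
                    mean)
  bins <- data.frame(bin_start = edges[-length(edges)],
                     rate = counts / (bin_s / 60),
                     swa = as.numeric(swa_bin))
  bins <- bins[is.finite(bins$swa), , drop = FALSE]
  if (sd(bins$rate) == 0 || sd(bins$swa) == 0)
    return(list(bins = bins, r = NA_real_, p = NA_real_, flagged = TRUE))
  ct <- cor.test(bins$rate, bins$swa)
  list(bins = bins, r = unname(ct$estimate), p = ct$p.value, flagged = FALSE)
}

#' Event rates per behavioral state
#'
#' Rate per state = events with onset inside that state's periods divided by
#' total state time; pairwise two-sided rank-sum tests on per-period rates.
#' REM is reported but excluded from the pairwise tests by default.
#'
#' @param onsets event onset times (s).
#' @param hyp a [hypnogram] with wake substates.
#' @param states states compared (default NREM, stationary and locomotory
#'   wake).
#' @return list(rates (events/min), per_period, tests).
#' @export
state_event_rates <- function(onsets, hyp,
                              states = c("NREM", "wake_stationary",
                                         "wake_locomotory")) {
  pget <- function(st) {
    if (st == "NREM") state_periods(hyp, "NREM")
    else if (st == "REM") state_periods(hyp, "REM")
    else state_periods(hyp, "wake", substate = sub("wake_", "", st))
  }
  per_period <- list()
  rates <- setNames(rep(NA_real_, length(states)), states)
  for (st in states) {
    per <- pget(st)
    if (!nrow(per) || period_time(per) == 0) next
    cnt <- vapply(seq_len(nrow(per)), function(i)
      sum(onsets >= per$start_s[i] & onsets < per$end_s[i]), 0)
    rates[st] <- sum(cnt) / (period_time(per) / 60)
    per_period[[st]] <- cnt / ((per$end_s - per$start_s) / 60)
  }
  tests <- list()
  cmb <- utils::combn(names(per_period), 2, simplify = FALSE)
  for (pair in cmb) {
    a <- per_period[[pair[1]]]; b <- per_period[[pair[2]]]
    if (length(a) >= 2L && length(b) >= 2L)
      tests[[paste(pair, collapse = "|")]] <-
        suppressWarnings(wilcox.test(a, b))
  }
  list(rates = rates, per_period = per_period, tests = tests)
}

#' Event proportion around state transitions
#'
#' For each sleep and each wake period of at least `min_period_s` that ends
#' in a transition, events in the final `lookback_s` are binned; each
#' period's histogram is normalized by the period's total event count, then
#' averaged across periods with SEM. Periods with zero events are excluded.
#'
#' @param onsets event onset times (s).
#' @param hyp a [hypnogram].
#' @param lookback_s window before the transition (default 30).
#' @param bin_s histogram bin (default 5).
#' @param min_period_s minimum period duration (default 30; sleep periods
#'   shorter than this are excluded from this analysis).
#' @return list per transition type ("to_wake", "to_sleep"): data frame
#'   (lag_s, mean, sem, n_periods).
#' @export
transition_profile <- function(onsets, hyp, lookback_s = 30, bin_s = 5,
                               min_period_s = 30) {
  per <- merge_sleep_wake(hyp)
  out <- list()
  for (type in c("to_wake", "to_sleep")) {
    from <- if (type == "to_wake") "sleep" else "wake"
    sel <- which(per$state == from &
                   c(per$state[-1] != from, FALSE) &
                   (per$end_s - per$start_s) >= min_period_s)
    profs <- list()
    for (i in sel) {
      tot <- sum(onsets >= per$start_s[i] & onsets < per$end_s[i])
      if (tot == 0) next
      rel <- onsets[onsets >= per$end_s[i] - lookback_s &
                      onsets < per$end_s[i] &
                      onsets >= per$start_s[i]] - per$end_s[i]
      h <- tabulate(findInterval(rel, seq(-lookback_s, 0, by = bin_s),
                                 rightmost.closed = TRUE),
                    nbins = lookback_s / bin_s)
      profs[[length(profs) + 1L]] <- h / tot
    }
    if (!length(profs)) {
      out[[type]] <- NULL
      next
    }
    m <- do.call(rbind, profs)
    out[[type]] <- data.frame(
      lag_s = seq(-lookback_s + bin_s / 2, -bin_s / 2, by = bin_s),
      mean = colMeans(m),
      sem = apply(m, 2, sd) / sqrt(nrow(m)),
      n_periods = nrow(m))
  }
  out
}

# maximal sleep(NREM+REM)/wake periods of a hypnogram
merge_sleep_wake <- function(hyp) {
  sw <- ifelse(hyp$state %in% c("NREM", "REM"), "sleep", "wake")
  r <- rle(sw)
  ie <- cumsum(r$lengths)
  is <- ie - r$lengths + 1L
  data.frame(start_s = hyp$start_s[is], end_s = hyp$end_s[ie],
             state = r$values)
}

#' Tertile change in event count
#'
#' Each sleep and wake period is split into three equal-duration bins; the
#' change metric is the third-bin count minus the mean of the first two.
#' With an `animal` grouping the metric is averaged per animal and tested
#' with a paired t-test (third bin vs mean of first two) across animals;
#' without one, periods are the paired units.
#'
#' @param onsets event onset times (s).
#' @param hyp a [hypnogram].
#' @param min_period_s minimum period duration (default 15).
#' @param animal optional single animal id for the returned per-period table.
#' @return list per state ("sleep", "wake"): per-period counts, change
#'   metric, paired t-test.
#' @export
tertile_change <- function(onsets, hyp, min_period_s = 15, animal = NULL) {
  per <- merge_sleep_wake(hyp)
  out <- list()
  for (st in c("sleep", "wake")) {
    sel <- which(per$state == st & (per$end_s - per$start_s) >= min_period_s)
    if (!length(sel)) next
    thirds <- t(vapply(sel, function(i) {
      e <- seq(per$start_s[i], per$end_s[i], length.out = 4L)
      vapply(1:3, function(k)
        sum(onsets >= e[k] & onsets < e[k + 1L]), 0)
    }, numeric(3)))
    change <- thirds[, 3] - (thirds[, 1] + thirds[, 2]) / 2
    tt <- if (nrow(thirds) >= 2L && sd(change) > 0)
      t.test(thirds[, 3], (thirds[, 1] + thirds[, 2]) / 2, paired = TRUE)
      else NULL
    out[[st]] <- list(counts = thirds, change = change,
                      mean_change = mean(change), paired_t = tt,
                      n_periods = nrow(thirds), animal = animal)
  }
  out
}

#' Cumulative event counts after injection
#'
#' Cumulative count versus time from `t0_injection`, with separate event
#' rates in the early window (default 8 min) and afterwards.
#'
#' @param onsets event onset times (s).
#' @param t0_injection injection time (s); must lie within the session.
#' @param horizon_s analysis horizon after t0 (truncated to the session with
#'   a warning).
#' @param session_dur_s session duration (s).
#' @param early_window_s early high-activity window (default 480 s).
#' @return list(curve (time_s, count), early_rate, late_rate) in events/min.
#' @export
cumulative_counts <- function(onsets, t0_injection, horizon_s,
                              session_dur_s = max(onsets, t0_injection + horizon_s),
                              early_window_s = 480) {
  if (t0_injection < 0 || t0_injection > session_dur_s)
    stopf("t0_injection outside the session")
  if (t0_injection + horizon_s > session_dur_s) {
    warnf("horizon truncated to session end")
    horizon_s <- session_dur_s - t0_injection
  }
  rel <- onsets[onsets >= t0_injection &
                  onsets < t0_injection + horizon_s] - t0_injection
  tt <- seq(0, horizon_s, by = 1)
  curve <- data.frame(time_s = tt,
                      count = findInterval(tt, sort(rel)))
  ew <- min(early_window_s, horizon_s)
  early_rate <- sum(rel < ew) / (ew / 60)
  late_rate <- if (horizon_s > ew)
    sum(rel >= ew) / ((horizon_s - ew) / 60) else NA_real_
  list(curve = curve, early_rate = early_rate, late_rate = late_rate,
       n = length(rel))
}

#' PCA of the 20 event features
#'
#' Features are z-standardized by default (they carry incommensurate units)
#' before the eigendecomposition. Constant columns are dropped with a
#' warning and their loadings padded with zeros.
#'
#' @param features data frame or matrix of event features (>= 21 rows).
#' @param k number of components to report scores for (default 5).
#' @param standardize z-score columns first (default TRUE).
#' @return list: `loadings` (p x k), `scores` (n x k), `variance_explained`
#'   (fraction per component, all components).
#' @export
feature_pca <- function(features, k = 5L, standardize = TRUE) {
  x <- as.matrix(features)
  if (nrow(x) < ncol(x) + 1L)
    stopf("need at least %d events for a %d-feature PCA", ncol(x) + 1L, ncol(x))
  sds <- apply(x, 2, sd)
  const <- sds == 0
  if (any(const)) {
    warnf("dropping constant feature column(s): %s",
          paste(colnames(x)[const], collapse = ", "))
  }
  xs <- x[, !const, drop = FALSE]
  pc <- prcomp(xs, center = TRUE, scale. = standardize)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(k, ncol(pc$rotation))
  loadings <- matrix(0, ncol(x), k,
                     dimnames = list(colnames(x), paste0("PC", seq_len(k))))
  loadings[!const, ] <- pc$rotation[, seq_len(k), drop = FALSE]
  list(loadings = loadings,
       scores = pc$x[, seq_len(k), drop = FALSE],
       variance_explained = ve,
       k_variance = sum(ve[seq_len(k)]),
       dropped = colnames(x)[const])
}

#' Per-PC ECDF comparison between behavioral states
#'
#' Two-sample KS tests between every pair of states for each principal
#' component score; states with fewer than `min_events` events are excluded.
#'
#' @param scores n x k score matrix from [feature_pca()].
#' @param states character vector of states, one per event.
#' @param min_events minimum events per state (default 10).
#' @return data frame: pc, state_a, state_b, ks_distance, p.
#' @export
pc_state_comparison <- function(scores, states, min_events = 10L) {
  tab <- table(states)
  keep <- names(tab)[tab >= min_events]
  if (length(keep) < 2L) stopf("need >= 2 states with >= %d events", min_events)
  prs <- utils::combn(keep, 2, simplify = FALSE)
  rows <- list()
  for (j in seq_len(ncol(scores))) {
    for (pr in prs) {
      a <- scores[states == pr[1], j]
      b <- scores[states == pr[2], j]
      rows[[length(rows) + 1L]] <- data.frame(
        pc = colnames(scores)[j] %||% paste0("PC", j),
        state_a = pr[1], state_b = pr[2],
        ks_distance = ks_distance(a, b),
        p = suppressWarnings(ks.test(a, b)$p.value))
    }
  }
  do.call(rbind, rows)
}

#' Per-mouse condition KS distances and state comparison
#'
#' For each mouse and each PC: the KS distance between saline and CNO score
#' distributions within each behavioral state; across mice the paired
#' distances are compared between states with a two-sided Wilcoxon
#' signed-rank test. Mice missing any cell of the 2x2 design are dropped.
#'
#' @param scores n x k score matrix.
#' @param mouse,condition,state vectors, one entry per event; condition in
#'   {"saline", "CNO"}; state the behavioral state ("NREM"/"wake", or any
#'   two labels).
#' @param states the two states compared (default NREM vs wake).
#' @return list: `distances` (long data frame), `wilcoxon` (per PC).
#' @export
condition_ks_distance <- function(scores, mouse, condition, state,
                                  states = c("NREM", "wake")) {
  rows <- list()
  for (m in unique(mouse)) {
    cells <- expand.grid(cond = c("saline", "CNO"), st = states,
                         stringsAsFactors = FALSE)
    ns <- vapply(seq_len(nrow(cells)), function(i)
      sum(mouse == m & condition == cells$cond[i] & state == cells$st[i]), 0)
    if (any(ns == 0)) {
      message(sprintf("mouse %s missing a condition/state cell; dropped", m))
      next
    }
    for (st in states) {
      for (j in seq_len(ncol(scores))) {
        a <- scores[mouse == m & condition == "saline" & state == st, j]
        b <- scores[mouse == m & condition == "CNO" & state == st, j]
        rows[[length(rows) + 1L]] <- data.frame(
          mouse = m, state = st,
          pc = colnames(scores)[j] %||% paste0("PC", j),
          ks_distance = ks_distance(a, b))
      }
    }
  }
  if (!length(rows)) stopf("no mouse has a complete 2x2 design")
  d <- do.call(rbind, rows)
  wil <- list()
  for (pc in unique(d$pc)) {
    a <- d$ks_distance[d$pc == pc & d$state == states[1]]
    b <- d$ks_distance[d$pc == pc & d$state == states[2]]
    mice_a <- d$mouse[d$pc == pc & d$state == states[1]]
    mice_b <- d$mouse[d$pc == pc & d$state == states[2]]
    a <- a[order(mice_a)]; b <- b[order(mice_b)]
    wil[[pc]] <- if (length(a) >= 2L)
      suppressWarnings(wilcox.test(a, b, paired = TRUE)) else NULL
  }
  list(distances = d, wilcoxon = wil)
}
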