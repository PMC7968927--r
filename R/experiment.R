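# Condition-level comparisons: state occupancy, transitions, bout
# structure, SWA distributions, and paired per-mouse tests.

#' Summarize one scored session
#'
#' Percent time per state, sleep/wake transition counts, bout statistics,
#' mean SWA in sleep and wake, and the SWA histogram over 5 s bins assigned
#' to their containing state. The analysis interval can be restricted (e.g.
#' to a post-injection suppression epoch).
#'
#' @param hyp a [hypnogram].
#' @param swa data frame from [swa_trace()] (optional).
#' @param onsets event onsets (optional, for the event rate).
#' @param interval optional c(start_s, end_s) restriction.
#' @param mouse_id,condition labels carried into the summary.
#' @param swa_bin_s width of SWA summary bins (default 5).
#' @return a `session_summary` list.
#' @export
summarize_session <- function(hyp, swa = NULL, onsets = NULL,
                              interval = NULL, mouse_id = "m1",
                              condition = "saline", swa_bin_s = 5) {
  if (!nrow(hyp)) stopf("empty hypnogram")
  if (!is.null(interval)) {
    hyp <- clip_hypnogram(hyp, interval[1], interval[2])
    if (!is.null(swa))
      swa <- swa[swa$time_s >= interval[1] & swa$time_s < interval[2], ]
    if (!is.null(onsets))
      onsets <- onsets[onsets >= interval[1] & onsets < interval[2]]
    if (!nrow(hyp)) stopf("empty hypnogram after interval restriction")
  }
  total <- period_time(hyp)
  occ <- vapply(c("NREM", "REM", "wake"), function(s)
    period_time(state_periods(hyp, s)), 0)
  pct <- occ / total * 100
  per <- merge_sleep_wake(hyp)
  s2w <- sum(per$state == "sleep" & c(per$state[-1] == "wake", FALSE))
  w2s <- sum(per$state == "wake" & c(per$state[-1] == "sleep", FALSE))
  bouts <- lapply(c(sleep = "sleep", wake = "wake"), function(s) {
    d <- per$end_s[per$state == s] - per$start_s[per$state == s]
    list(count = length(d), durations = d,
         mean_s = if (length(d)) mean(d) else NA_real_)
  })
  res <- list(mouse_id = mouse_id, condition = condition,
              interval = interval %||% c(hyp$start_s[1], hyp$end_s[nrow(hyp)]),
              percent_time = pct, transitions = c(sleep_to_wake = s2w,
                                                  wake_to_sleep = w2s),
              bouts = bouts, total_s = total)
  if (!is.null(swa)) {
    bin <- floor((swa$time_s - hyp$start_s[1]) / swa_bin_s)
    bin_t <- hyp$start_s[1] + (bin + 0.5) * swa_bin_s
    bin_swa <- tapply(swa$swa, bin, mean)
    bt <- as.numeric(names(bin_swa))
    bt <- hyp$start_s[1] + (bt + 0.5) * swa_bin_s
    st <- state_at(hyp, bt)
    sleepish <- st == "NREM"
    res$swa_sleep_bins <- as.numeric(bin_swa[which(sleepish)])
    res$swa_wake_bins <- as.numeric(bin_swa[which(st == "wake")])
    res$mean_sleep_swa <- mean(res$swa_sleep_bins)
    res$mean_wake_swa <- mean(res$swa_wake_bins)
  }
  if (!is.null(onsets))
    res$event_rate <- length(onsets) / (total / 60)
  class(res) <- "session_summary"
  res
}

clip_hypnogram <- function(hyp, t0, t1) {
  out <- hyp[hyp$end_s > t0 & hyp$start_s < t1, , drop = FALSE]
  if (!nrow(out)) return(hypnogram(data.frame()))
  out$start_s <- pmax(out$start_s, t0)
  out$end_s <- pmin(out$end_s, t1)
  hypnogram(out)
}

#' Bout statistics for one state
#'
#' Bouts are maximal same-state periods ("sleep" merges NREM and REM).
#'
#' @param hyp a [hypnogram].
#' @param state "sleep", "wake", "NREM" or "REM".
#' @return list(count, durations, mean_s, median_s).
#' @export
bout_statistics <- function(hyp, state) {
  per <- if (state %in% c("sleep", "wake")) {
    p <- merge_sleep_wake(hyp)
    p[p$state == state, , drop = FALSE]
  } else state_periods(hyp, state)
  d <- per$end_s - per$start_s
  list(count = length(d), durations = d,
       mean_s = if (length(d)) mean(d) else NA_real_,
       median_s = if (length(d)) median(d) else NA_real_)
}

#' Paired condition comparison of a session metric
#'
#' Two-sided paired t-test across mice on a scalar metric extracted from
#' per-session summaries; unpaired mice are dropped with a message. A
#' zero-variance difference is flagged as degenerate rather than reported
#' as an infinite t statistic.
#'
#' @param summaries list of `session_summary` objects (both conditions).
#' @param metric function mapping a summary to a scalar, or the name of a
#'   top-level numeric field.
#' @param conditions the two condition labels, reference first.
#' @return list: per-mouse deltas, group mean and SD, test, p, n, flag.
#' @export
paired_compare <- function(summaries, metric,
                           conditions = c("saline", "CNO")) {
  f <- if (is.function(metric)) metric else function(s) s[[metric]]
  val <- vapply(summaries, function(s) as.numeric(f(s)), 0)
  mouse <- vapply(summaries, `[[`, "", "mouse_id")
  cond <- vapply(summaries, `[[`, "", "condition")
  a <- val[cond == conditions[1]]; names(a) <- mouse[cond == conditions[1]]
  b <- val[cond == conditions[2]]; names(b) <- mouse[cond == conditions[2]]
  common <- intersect(names(a), names(b))
  dropped <- setdiff(union(names(a), names(b)), common)
  if (length(dropped))
    message("unpaired mice dropped: ", paste(dropped, collapse = ", "))
  if (length(common) < 2L) stopf("need >= 2 complete pairs")
  delta <- b[common] - a[common]
  degenerate <- sd(delta) == 0
  tt <- if (!degenerate) t.test(b[common], a[common], paired = TRUE) else NULL
  list(deltas = delta, mean = mean(delta), sd = sd(delta),
       test = "paired t", statistic = if (degenerate) NA_real_ else unname(tt$statistic),
       p = if (degenerate) NA_real_ else tt$p.value,
       n = length(common), degenerate = degenerate)
}
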