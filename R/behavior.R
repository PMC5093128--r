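#' Critical stop-signal delay
#'
#' Estimates the critical SSD — the delay at which the subject stops
#' successfully on half of the stop trials — as the mean SSD over stop
#' trials after discarding the initial staircase transient. The transient
#' comprises all stop trials before the first staircase reversal (the first
#' change of step direction), with a minimum of 5 stop trials discarded.
#' Because the 1-up/1-down tracker oscillates around the 50% point once
#' converged, the post-transient mean is a robust estimate of that point.
#'
#' @param events An event-log data.frame (see [simulate_subject()]) with at
#'   least 20 stop trials.
#' @return Critical SSD in ms.
#' @export
critical_ssd <- function(events) {
  ssd <- events$ssd_ms[events$trial_type == "stop"]
  n <- length(ssd)
  if (n < 20L) {
    stop("need at least 20 stop trials to estimate the critical SSD",
         call. = FALSE)
  }
  steps <- diff(ssd)
  dir <- sign(steps[steps != 0])
  burn <- 5L
  if (length(dir) >= 2L) {
    rev_pos <- which(dir[-1] != dir[-length(dir)])
    if (length(rev_pos)) {
      nonzero_idx <- which(steps != 0)
      first_reversal <- nonzero_idx[rev_pos[1] + 1L]  # trial of direction change
      burn <- max(burn, first_reversal)
    }
  }
  burn <- min(burn, n - 5L)  # keep at least a handful of trials
  mean(ssd[(burn + 1L):n])
}

#' Stop-signal reaction time (race model)
#'
#' SSRT is the latency of the stopping process under the independent race
#' model: the median go RT (successful go trials) minus the critical SSD.
#'
#' @param events An event-log data.frame with at least 20 successful go
#'   trials and enough stop trials for [critical_ssd()].
#' @return SSRT in ms.
#' @export
ssrt <- function(events) {
  gort <- events$rt_ms[events$outcome == "GS"]
  if (length(gort) < 20L) {
    stop("need at least 20 successful go trials to estimate SSRT",
         call. = FALSE)
  }
  stats::median(gort) - critical_ssd(events)
}

#' Sequential effect: anticipation-driven go slowing
#'
#' Quantifies proactive slowing as the Pearson correlation between the
#' trial-by-trial p(Stop) estimate and go reaction time, over successful go
#' trials. Significance uses the t transform with `n - 2` degrees of
#' freedom (two-sided).
#'
#' @param events An event-log data.frame with a `pstop` column; at least 10
#'   successful go trials required.
#' @return A list with `r`, `p`, `n`, and the t statistic `t`.
#' @export
sequential_effect <- function(events) {
  if (!"pstop" %in% names(events)) {
    stop("'events' must carry a 'pstop' column", call. = FALSE)
  }
  gs <- events$outcome == "GS" & !is.na(events$rt_ms)
  if (sum(gs) < 10L) {
    stop("need at least 10 successful go trials", call. = FALSE)
  }
  pearson_test(events$pstop[gs], events$rt_ms[gs])
}

#' Per-subject behavioral summary
#'
#' Computes the standard stop-signal performance measures from one
#' subject's event log: counts, the go response rate (fraction of go trials
#' with a successful response inside the window), the stop-success rate,
#' median go RT, critical SSD, SSRT, and the sequential effect.
#'
#' @param events A complete event-log data.frame for one subject, with a
#'   `pstop` column.
#' @return A one-row data.frame with columns `n_go`, `n_stop`,
#'   `go_response_rate`, `ss_rate`, `median_gort_ms`, `critical_ssd_ms`,
#'   `ssrt_ms`, `seq_effect_r`, `seq_effect_p`.
#' @export
behavioral_summary <- function(events) {
  go <- events$trial_type == "go"
  n_go <- sum(go)
  n_stop <- sum(!go)
  gs <- events$outcome == "GS"
  cssd <- critical_ssd(events)
  med_gort <- stats::median(events$rt_ms[gs])
  se <- sequential_effect(events)
  data.frame(n_go = n_go, n_stop = n_stop,
             go_response_rate = sum(gs) / n_go,
             ss_rate = sum(events$outcome == "SS") / n_stop,
             median_gort_ms = med_gort,
             critical_ssd_ms = cssd,
             ssrt_ms = med_gort - cssd,
             seq_effect_r = se$r,
             seq_effect_p = se$p)
}
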