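#' Stop-signal task trial schedule
#'
#' Builds the skeleton of one task session: randomized go/stop ordering and
#' trial onsets. Each trial starts with a fixation dot, the go signal
#' appears after a uniformly drawn foreperiod, the response window lasts
#' 1 s, and trials are separated by a fixed inter-trial interval. Onsets
#' accumulate `foreperiod + response window + ITI` so the schedule is a
#' faithful timeline for later BOLD modelling.
#'
#' @param n_trials Number of trials (>= 1).
#' @param stop_fraction Probability that a trial is a stop trial
#'   (default 0.25; each trial drawn independently).
#' @param iti_s Inter-trial interval in seconds (default 2).
#' @param foreperiod_range_s Two-element range (seconds) of the uniform
#'   fixation-to-go foreperiod (default `c(1, 5)`).
#' @param start_s Onset of the first trial's fixation, seconds from session
#'   start (default 0; set to the discarded-volume duration when the
#'   session feeds an fMRI design).
#' @param seed Optional integer seed; the schedule is deterministic given
#'   the seed.
#' @return A data.frame with columns `index`, `trial_type` ("go"/"stop"),
#'   `onset_s` (fixation onset) and `foreperiod_s`.
#' @examples
#' head(sst_schedule(10, seed = 1))
#' @export
sst_schedule <- function(n_trials, stop_fraction = 0.25, iti_s = 2,
                         foreperiod_range_s = c(1, 5), start_s = 0,
                         seed = NULL) {
  n_trials <- as.integer(n_trials)
  if (is.na(n_trials) || n_trials < 1L) {
    stop("'n_trials' must be a positive integer", call. = FALSE)
  }
  if (stop_fraction < 0 || stop_fraction >= 1) {
    stop("'stop_fraction' must be in [0, 1)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  is_stop <- stats::runif(n_trials) < stop_fraction
  foreperiod <- stats::runif(n_trials, foreperiod_range_s[1],
                             foreperiod_range_s[2])
  response_window <- 1
  dur <- foreperiod + response_window + iti_s
  onset <- start_s + c(0, cumsum(dur[-n_trials]))
  data.frame(index = seq_len(n_trials),
             trial_type = ifelse(is_stop, "stop", "go"),
             onset_s = onset,
             foreperiod_s = foreperiod,
             stringsAsFactors = FALSE)
}

#' Staircase state for stop-signal delay tracking
#'
#' @param ssd_ms Current stop-signal delay in ms (default 200, the starting
#'   value of the 1-up/1-down tracker).
#' @param step_ms Staircase step in ms (default 67).
#' @param min_ms,max_ms Clamp bounds for the SSD (defaults 0 and 900 ms;
#'   the response window is 1 s).
#' @return A list of class `"staircase"`.
#' @export
staircase <- function(ssd_ms = 200, step_ms = 67, min_ms = 0, max_ms = 900) {
  if (step_ms <= 0) stop("'step_ms' must be positive", call. = FALSE)
  ssd_ms <- min(max(ssd_ms, min_ms), max_ms)
  structure(list(ssd_ms = ssd_ms, step_ms = step_ms,
                 min_ms = min_ms, max_ms = max_ms),
            class = "staircase")
}

#' One staircase update after a stop trial
#'
#' The 1-up/1-down tracker: the SSD increases by one step after a
#' successful stop (making the next stop harder) and decreases by one step
#' after a failed stop, clamped to the state's bounds. In the long run this
#' drives the stop-success rate to 50%.
#'
#' @param state A [staircase()] object.
#' @param stop_outcome `"SS"` (successful stop) or `"SE"` (stop error).
#' @return The updated staircase state.
#' @examples
#' staircase_step(staircase(200), "SS")$ssd_ms  # 267
#' staircase_step(staircase(200), "SE")$ssd_ms  # 133
#' @export
staircase_step <- function(state, stop_outcome) {
  if (!stop_outcome %in% c("SS", "SE")) {
    stop("'stop_outcome' must be \"SS\" or \"SE\"", call. = FALSE)
  }
  delta <- if (stop_outcome == "SS") state$step_ms else -state$step_ms
  state$ssd_ms <- min(max(state$ssd_ms + delta, state$min_ms), state$max_ms)
  state
}

#' Generative behavioral profile of one simulated subject
#'
#' Bundles the parameters that generate a subject's task behavior under
#' the race model, together with demographic and trait scores used by the
#' group-level analyses.
#'
#' The go process finishes at
#' `go_mu_ms + slowing_coef_ms * (p(Stop) - stop_fraction) +
#'  drift_ms_per_100trials * index / 100 + noise`,
#' floored at 80 ms, where the anticipatory-slowing term implements the
#' sequential effect (subjects slow down when a stop signal is likely) and
#' the drift term a slow within-session RT increase. On stop trials a
#' response is emitted iff the go process finishes before `SSD + SSRT`
#' (independent race).
#'
#' @param subject_id Identifier.
#' @param gender `"M"` or `"F"`.
#' @param age Years.
#' @param NS,HA,RD Trait subscale scores (novelty seeking 0-13, harm
#'   avoidance 0-22, reward dependence 0-9).
#' @param go_mu_ms Mean go finishing time, ms.
#' @param ssrt_true_ms True stop-process duration, ms.
#' @param slowing_coef_ms RT increase per unit p(Stop), ms.
#' @param rt_noise_sd_ms Trial-to-trial Gaussian RT noise SD, ms.
#' @param go_fail_prob Probability a go trial is an error (premature press
#'   or omission, split evenly); must lie in `[0, 0.2]`.
#' @param drift_ms_per_100trials Linear within-session RT drift, ms per 100
#'   trials.
#' @return A list of class `"subject_profile"`.
#' @export
subject_profile <- function(subject_id = "s01", gender = "F", age = 30,
                            NS = 4, HA = 6, RD = 6,
                            go_mu_ms = 620, ssrt_true_ms = 204,
                            slowing_coef_ms = 500, rt_noise_sd_ms = 100,
                            go_fail_prob = 0.022,
                            drift_ms_per_100trials = 6) {
  if (!gender %in% c("M", "F")) stop("'gender' must be \"M\" or \"F\"",
                                     call. = FALSE)
  if (go_mu_ms <= 0 || ssrt_true_ms <= 0 || rt_noise_sd_ms < 0) {
    stop("durations must be positive", call. = FALSE)
  }
  if (go_fail_prob < 0 || go_fail_prob > 0.2) {
    stop("'go_fail_prob' must be in [0, 0.2]", call. = FALSE)
  }
  if (NS < 0 || NS > 13 || HA < 0 || HA > 22 || RD < 0 || RD > 9) {
    stop("trait scores outside subscale ranges", call. = FALSE)
  }
  structure(list(subject_id = subject_id, gender = gender, age = age,
                 NS = NS, HA = HA, RD = RD,
                 go_mu_ms = go_mu_ms, ssrt_true_ms = ssrt_true_ms,
                 slowing_coef_ms = slowing_coef_ms,
                 rt_noise_sd_ms = rt_noise_sd_ms,
                 go_fail_prob = go_fail_prob,
                 drift_ms_per_100trials = drift_ms_per_100trials),
            class = "subject_profile")
}

#' Simulate one subject performing the stop-signal task
#'
#' Runs the race-model subject over a schedule from [sst_schedule()]. On
#' every trial the subject's anticipatory p(Stop) is computed causally with
#' the generating dynamic belief model, and the go finishing time is drawn
#' as described in [subject_profile()]. Go trials end in `GS` (response
#' within the 1 s window) or `GE` (with probability `go_fail_prob`, half
#' premature presses before the go signal and half omissions; finishing
#' times beyond the window are also omissions). On stop trials the go and
#' stop processes race: a response is emitted iff the go process finishes
#' before `SSD + SSRT` and within the window (`SE`, with the finishing time
#' as RT), otherwise the stop succeeds (`SS`). The SSD staircase updates
#' after every stop trial.
#'
#' @param profile A [subject_profile()].
#' @param schedule A schedule data.frame from [sst_schedule()]; a column
#'   `session` is carried through if present.
#' @param dbm_params Generating DBM parameters ([dbm_params()]).
#' @param tracker Initial [staircase()] state.
#' @param stop_fraction Reference stop rate subtracted from p(Stop) in the
#'   slowing term (default 0.25).
#' @param seed Optional integer seed; the event log is deterministic given
#'   the seed.
#' @return A data.frame event log, one row per trial: `index`,
#'   `trial_type`, `onset_s`, `foreperiod_s`, `ssd_ms` (`NA` on go trials),
#'   `rt_ms` (`NA` without a scored response), `outcome`
#'   (`GS`/`GE`/`SS`/`SE`), `premature` (flag within GE), and `pstop` (the
#'   generating model's anticipation).
#' @export
simulate_subject <- function(profile, schedule, dbm_params = NULL,
                             tracker = staircase(), stop_fraction = 0.25,
                             seed = NULL) {
  if (!inherits(profile, "subject_profile")) {
    stop("'profile' must be a subject_profile", call. = FALSE)
  }
  need <- c("index", "trial_type", "onset_s", "foreperiod_s")
  if (!all(need %in% names(schedule))) {
    stop("'schedule' must come from sst_schedule()", call. = FALSE)
  }
  if (is.null(dbm_params)) dbm_params <- dbm_params()
  if (!is.null(seed)) set.seed(seed)

  n <- nrow(schedule)
  is_stop <- schedule$trial_type == "stop"
  state <- dbm_prior(dbm_params)
  pstop <- numeric(n)
  ssd <- rep(NA_real_, n)
  rt <- rep(NA_real_, n)
  outcome <- character(n)
  premature <- rep(FALSE, n)

  for (k in seq_len(n)) {
    pstop[k] <- dbm_pstop(state)
    finish <- profile$go_mu_ms +
      profile$slowing_coef_ms * (pstop[k] - stop_fraction) +
      profile$drift_ms_per_100trials * schedule$index[k] / 100 +
      stats::rnorm(1, 0, profile$rt_noise_sd_ms)
    finish <- max(finish, 80)
    if (is_stop[k]) {
      ssd[k] <- tracker$ssd_ms
      responded <- finish < tracker$ssd_ms + profile$ssrt_true_ms &&
        finish <= 1000
      if (responded) {
        outcome[k] <- "SE"
        rt[k] <- finish
      } else {
        outcome[k] <- "SS"
      }
      tracker <- staircase_step(tracker, outcome[k])
    } else {
      if (stats::runif(1) < profile$go_fail_prob) {
        outcome[k] <- "GE"
        premature[k] <- stats::runif(1) < 0.5
      } else if (finish <= 1000) {
        outcome[k] <- "GS"
        rt[k] <- finish
      } else {
        outcome[k] <- "GE"  # omission: too slow for the window
      }
    }
    state <- dbm_update(state, as.numeric(is_stop[k]))
    state <- dbm_advance(state, dbm_params)
  }

  out <- data.frame(index = schedule$index,
                    trial_type = schedule$trial_type,
                    onset_s = schedule$onset_s,
                    foreperiod_s = schedule$foreperiod_s,
                    ssd_ms = ssd, rt_ms = rt, outcome = outcome,
                    premature = premature, pstop = pstop,
                    stringsAsFactors = FALSE)
  if ("session" %in% names(schedule)) {
    out <- cbind(session = schedule$session, out)
  }
  attr(out, "staircase") <- tracker
  out
}

#' Simulate a multi-session run for one subject
#'
#' Convenience wrapper: builds one schedule per session and stacks the
#' event logs with a `session` column. The SSD staircase carries over from
#' one session to the next (the tracker is not reset, so only the first
#' session shows the initial transient), whereas the belief model and the
#' within-session RT drift restart with each session.
#'
#' @inheritParams simulate_subject
#' @param n_sessions Number of sessions (default 4).
#' @param trials_per_session Trials per session (default 100).
#' @param start_s First-trial fixation onset within each session, seconds.
#' @param seed Integer seed; per-session seeds are derived from it.
#' @return Stacked event-log data.frame with a `session` column.
#' @export
simulate_sessions <- function(profile, n_sessions = 4,
                              trials_per_session = 100,
                              dbm_params = NULL, stop_fraction = 0.25,
                              start_s = 10, seed = 1) {
  set.seed(seed)
  session_seeds <- sample.int(.Machine$integer.max - 1L, n_sessions)
  tracker <- staircase()
  logs <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    sched <- sst_schedule(trials_per_session,
                          stop_fraction = stop_fraction,
                          start_s = start_s, seed = session_seeds[s])
    sched$session <- s
    logs[[s]] <- simulate_subject(profile, sched, dbm_params = dbm_params,
                                  tracker = tracker,
                                  stop_fraction = stop_fraction,
                                  seed = session_seeds[s] %% 1000000L + s)
    tracker <- attr(logs[[s]], "staircase")
    attr(logs[[s]], "staircase") <- NULL
  }
  do.call(rbind, logs)
}
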