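#' Synthetic cohort configuration
#'
#' Default generative parameters for a synthetic stop-signal study cohort.
#' Trait marginals are truncated, rounded normals matching the published
#' summary statistics of a healthy adult cohort (NS 4.1 +/- 2.5 on 0-13,
#' HA 6.5 +/- 4.4 on 0-22 with a gender difference — women 7.44 +/- 4.40,
#' men 5.07 +/- 4.12 — and RD 6.4 +/- 2.4 on 0-9). Behavioral parameters
#' are population distributions for the race-model subject of
#' [subject_profile()]; the anticipatory-slowing mean is calibrated (see
#' [calibrate_cohort()]) so the cohort mean sequential effect matches the
#' canonical 0.33, and `go_fail_prob` maps directly onto the 97.8% go
#' response rate. Four regions of interest carry trait-linked BOLD
#' modulation amplitudes: the anterior pre-SMA, MFG/lOFC and IPL amplitudes
#' decrease with novelty seeking, the thalamus amplitude with harm
#' avoidance; amplitude scales are set so traits explain roughly 6-12% of
#' the between-subject contrast variance.
#'
#' @param n_subjects Cohort size (default 78).
#' @param n_female Number of women (default 48).
#' @param n_sessions,trials_per_session Task structure (default 4 x 100).
#' @param stop_fraction Stop-trial probability (default 0.25).
#' @param traits Trait marginals: list of `c(mean, sd, lo, hi)` for NS and
#'   RD, and per-gender means/SDs for HA.
#' @param age_mean,age_sd,age_range Age distribution (years).
#' @param go_mu_mean,go_mu_sd Population distribution of the subject mean
#'   go finishing time (ms).
#' @param ssrt_mean,ssrt_sd Population distribution of the true SSRT (ms).
#' @param slowing_mean,slowing_sd Population distribution of the
#'   anticipatory slowing coefficient (ms per unit p(Stop)).
#' @param rt_noise_sd Within-subject trial RT noise SD (ms).
#' @param go_fail_prob Go-error probability.
#' @param drift_ms_per_100trials Within-session RT drift (ms/100 trials).
#' @param dbm Generating belief-model parameters ([dbm_params()]).
#' @param rois Named list of ROI models: each has `trait` (`"NS"` or
#'   `"HA"`), `base` (mean modulation amplitude), `slope` (amplitude change
#'   per trait point; negative), `amp_noise_sd` (between-subject amplitude
#'   noise).
#' @param task_amplitude Amplitude of the event (onset) regressor common to
#'   all ROIs.
#' @param bold_noise_sd,bold_ar1 Marginal SD and AR(1) coefficient of the
#'   scanner noise added to each ROI time series.
#' @param tr_s,discard_volumes,start_s Scanning timeline parameters.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_subjects = 78, n_female = 48,
                          n_sessions = 4, trials_per_session = 100,
                          stop_fraction = 0.25,
                          traits = list(
                            NS = c(mean = 4.1, sd = 2.5, lo = 0, hi = 13),
                            HA_female = c(mean = 7.44, sd = 4.40, lo = 0,
                                          hi = 22),
                            HA_male = c(mean = 5.07, sd = 4.12, lo = 0,
                                        hi = 22),
                            RD = c(mean = 6.4, sd = 2.4, lo = 0, hi = 9)),
                          age_mean = 30.2, age_sd = 10.2,
                          age_range = c(18, 60),
                          go_mu_mean = 620, go_mu_sd = 90,
                          ssrt_mean = 204, ssrt_sd = 42,
                          slowing_mean = 500, slowing_sd = 150,
                          rt_noise_sd = 100, go_fail_prob = 0.022,
                          drift_ms_per_100trials = 6,
                          dbm = dbm_params(alpha = 0.8, pm = 0.25,
                                           scale = 4),
                          rois = list(
                            pre_sma = list(trait = "NS", base = 1.0,
                                           slope = -0.10,
                                           amp_noise_sd = 0.5),
                            mfg_lofc = list(trait = "NS", base = 1.0,
                                            slope = -0.10,
                                            amp_noise_sd = 0.5),
                            ipl = list(trait = "NS", base = 1.0,
                                       slope = -0.10, amp_noise_sd = 0.5),
                            thalamus = list(trait = "HA", base = 1.0,
                                            slope = -0.06,
                                            amp_noise_sd = 0.5)),
                          task_amplitude = 1.0,
                          bold_noise_sd = 0.5, bold_ar1 = 0.3,
                          tr_s = 2, discard_volumes = 5L, start_s = 10) {
  if (n_female > n_subjects) {
    stop("'n_female' cannot exceed 'n_subjects'", call. = FALSE)
  }
  for (nm in names(traits)) {
    tr <- traits[[nm]]
    if (tr["mean"] < tr["lo"] || tr["mean"] > tr["hi"]) {
      stop("trait mean outside subscale range for ", nm, call. = FALSE)
    }
    if (tr["sd"] < 0) stop("negative trait SD for ", nm, call. = FALSE)
  }
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  cfg
}

# truncated, rounded normal draw on an integer subscale
draw_trait <- function(n, spec) {
  round(pmin(pmax(stats::rnorm(n, spec["mean"], spec["sd"]), spec["lo"]),
             spec["hi"]))
}

# AR(1) noise with marginal sd, by recursion (stationary start)
ar1_series <- function(n, rho, sd) {
  innov_sd <- sd * sqrt(1 - rho^2)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  if (n > 1) {
    e <- stats::rnorm(n - 1, 0, innov_sd)
    for (t in 2:n) x[t] <- rho * x[t - 1] + e[t - 1]
  }
  x
}

#' Generate a synthetic study cohort
#'
#' Draws a full synthetic study from a [cohort_config()]: trait scores and
#' demographics, per-subject generative behavioral parameters, simulated
#' multi-session event logs (via [simulate_sessions()]), and — optionally —
#' trait-linked ROI BOLD time series built from the first-level design
#' operator itself (signal = design columns x generating amplitudes, so
#' GLM recovery is exact in expectation) plus AR(1) scanner noise. The
#' output is deterministic given `seed`, and a ground-truth record retains
#' every generating quantity for recovery tests.
#'
#' @param config A [cohort_config()].
#' @param seed Master integer seed; all subject-level seeds derive from it.
#' @param include_bold Generate ROI BOLD (default `TRUE`; behavioral-only
#'   cohorts are considerably faster).
#' @param hrf An [hrf_spec()] used to build the generating designs.
#' @return A list of class `"cohort_bundle"`:
#'   \describe{
#'     \item{cohort}{data.frame: subject_id, gender, age, NS, HA, RD and
#'       the generating behavioral parameters.}
#'     \item{events}{named list of per-subject event logs (with the
#'       generating p(Stop) in column `pstop`).}
#'     \item{bold}{named list of per-subject data.frames: `session` plus
#'       one column per ROI (rows are retained volumes), or `NULL`.}
#'     \item{ground_truth}{list: config, master seed, per-subject seeds and
#'       ROI modulation amplitudes.}
#'   }
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1,
                            include_bold = TRUE, hrf = NULL) {
  if (!inherits(config, "cohort_config")) {
    stop("'config' must come from cohort_config()", call. = FALSE)
  }
  set.seed(seed)
  n <- config$n_subjects
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n)
  gender <- c(rep("F", config$n_female), rep("M", n - config$n_female))
  age <- pmin(pmax(stats::rnorm(n, config$age_mean, config$age_sd),
                   config$age_range[1]), config$age_range[2])
  NS <- draw_trait(n, config$traits$NS)
  HA <- numeric(n)
  HA[gender == "F"] <- draw_trait(sum(gender == "F"),
                                  config$traits$HA_female)
  HA[gender == "M"] <- draw_trait(sum(gender == "M"),
                                  config$traits$HA_male)
  RD <- draw_trait(n, config$traits$RD)

  go_mu <- stats::rnorm(n, config$go_mu_mean, config$go_mu_sd)
  ssrt_true <- pmax(stats::rnorm(n, config$ssrt_mean, config$ssrt_sd), 80)
  slowing <- stats::rnorm(n, config$slowing_mean, config$slowing_sd)

  # trait-linked ROI modulation amplitudes
  amplitudes <- lapply(config$rois, function(roi) {
    trait <- if (roi$trait == "NS") NS else HA
    roi$base + roi$slope * trait +
      stats::rnorm(n, 0, roi$amp_noise_sd)
  })

  ids <- sprintf("s%02d", seq_len(n))
  cohort <- data.frame(subject_id = ids, gender = gender, age = age,
                       NS = NS, HA = HA, RD = RD, go_mu_ms = go_mu,
                       ssrt_true_ms = ssrt_true,
                       slowing_coef_ms = slowing,
                       rt_noise_sd_ms = config$rt_noise_sd,
                       go_fail_prob = config$go_fail_prob,
                       drift_ms_per_100trials =
                         config$drift_ms_per_100trials,
                       stringsAsFactors = FALSE)

  if (is.null(hrf)) hrf <- hrf_spec(tr_s = config$tr_s)
  events <- vector("list", n)
  bold <- if (include_bold) vector("list", n) else NULL
  bold_seeds <- sample.int(.Machine$integer.max - 1L, n)

  for (i in seq_len(n)) {
    prof <- subject_profile(subject_id = ids[i], gender = gender[i],
                            age = age[i], NS = NS[i], HA = HA[i],
                            RD = RD[i], go_mu_ms = go_mu[i],
                            ssrt_true_ms = ssrt_true[i],
                            slowing_coef_ms = slowing[i],
                            rt_noise_sd_ms = config$rt_noise_sd,
                            go_fail_prob = config$go_fail_prob,
                            drift_ms_per_100trials =
                              config$drift_ms_per_100trials)
    ev <- simulate_sessions(prof, n_sessions = config$n_sessions,
                            trials_per_session = config$trials_per_session,
                            dbm_params = config$dbm,
                            stop_fraction = config$stop_fraction,
                            start_s = config$start_s,
                            seed = subject_seeds[i])
    events[[i]] <- ev

    if (include_bold) {
      nv <- volumes_needed(ev, tr_s = config$tr_s,
                           discard_volumes = config$discard_volumes)
      des <- build_design(ev, hrf, n_volumes_per_session = nv,
                          discard_volumes = config$discard_volumes)
      set.seed(bold_seeds[i])
      roi_y <- lapply(names(config$rois), function(rn) {
        w <- numeric(ncol(des$X))
        w[grepl("_task$", colnames(des$X))] <- config$task_amplitude
        w[grepl("_gs_pstop$", colnames(des$X))] <- amplitudes[[rn]][i]
        signal <- as.numeric(des$X %*% w)
        noise <- unlist(lapply(des$n_volumes, function(m) {
          ar1_series(m, config$bold_ar1, config$bold_noise_sd)
        }))
        signal + noise
      })
      names(roi_y) <- names(config$rois)
      bold[[i]] <- data.frame(session = des$session, roi_y)
    }
  }
  names(events) <- ids
  if (include_bold) names(bold) <- ids

  structure(list(cohort = cohort, events = events, bold = bold,
                 ground_truth = list(config = config, seed = seed,
                                     subject_seeds = subject_seeds,
                                     bold_seeds = bold_seeds,
                                     amplitudes = amplitudes)),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("Synthetic stop-signal cohort: %d subjects (%d F / %d M)\n",
              nrow(x$cohort), sum(x$cohort$gender == "F"),
              sum(x$cohort$gender == "M")))
  cat(sprintf("  task: %d sessions x %d trials, %.0f%% stop\n",
              x$ground_truth$config$n_sessions,
              x$ground_truth$config$trials_per_session,
              100 * x$ground_truth$config$stop_fraction))
  cat(sprintf("  ROI BOLD: %s\n",
              if (is.null(x$bold)) "not generated"
              else paste(names(x$ground_truth$config$rois),
                         collapse = ", ")))
  invisible(x)
}

# cohort-mean behavioral statistic used by the calibrator
cohort_behavior_means <- function(config, seed, n_subjects = NULL) {
  cfg <- config
  if (!is.null(n_subjects)) cfg$n_subjects <- n_subjects
  if (!is.null(n_subjects)) {
    cfg$n_female <- round(n_subjects * config$n_female /
                            config$n_subjects)
  }
  bundle <- generate_cohort(cfg, seed = seed, include_bold = FALSE)
  summ <- do.call(rbind, lapply(bundle$events, behavioral_summary))
  c(seq_effect = mean(summ$seq_effect_r),
    ss_rate = mean(summ$ss_rate),
    go_response_rate = mean(summ$go_response_rate),
    ssrt = mean(summ$ssrt_ms))
}

#' Calibrate the cohort generator to target behavioral means
#'
#' Adjusts designated free parameters of a [cohort_config()] so that the
#' simulated cohort means match target behavioral statistics:
#' `go_response_rate` maps directly onto `go_fail_prob`
#' (`go_fail_prob = 1 - target`), while `seq_effect` (via `slowing_mean`)
#' and `ss_rate` (via `drift_ms_per_100trials`) are solved by a secant
#' search on simulated cohort means. Targets are matched to `tolerance`;
#' if the search exhausts its iterations the error reports the best
#' achieved values.
#'
#' @param config Starting [cohort_config()].
#' @param targets Named numeric vector; any of `seq_effect`, `ss_rate`,
#'   `go_response_rate`, `ssrt` (the latter is checked, not tuned: the
#'   SSRT estimator is unbiased so `ssrt_mean` already sets it).
#' @param tolerance Acceptable absolute deviation per target (default
#'   0.01).
#' @param n_subjects Cohort size used during search (default 24; smaller
#'   than the full design for speed).
#' @param seed Base seed for the calibration simulations.
#' @param n_seeds Number of independent replicate cohorts averaged per
#'   evaluation of the simulated statistic (default 2; more seeds give a
#'   steadier search target).
#' @param max_iter Secant iterations per free parameter (default 8).
#' @return The calibrated `cohort_config`, with a `calibration` attribute
#'   recording targets, achieved values, and the search trace.
#' @export
calibrate_cohort <- function(config = cohort_config(), targets,
                             tolerance = 0.01, n_subjects = 24, seed = 99,
                             n_seeds = 2, max_iter = 8) {
  targets <- unlist(targets)
  allowed <- c("seq_effect", "ss_rate", "go_response_rate", "ssrt")
  if (!all(names(targets) %in% allowed)) {
    stop("targets must be among: ", paste(allowed, collapse = ", "),
         call. = FALSE)
  }
  trace <- list()

  if ("go_response_rate" %in% names(targets)) {
    config$go_fail_prob <- 1 - targets[["go_response_rate"]]
    trace$go_fail_prob <- config$go_fail_prob
  }

  eval_stat <- function(cfg, target_name) {
    mean(vapply(seq_len(n_seeds), function(k) {
      cohort_behavior_means(cfg, seed = seed + k - 1,
                            n_subjects = n_subjects)[[target_name]]
    }, numeric(1)))
  }

  solve_param <- function(config, param, target_name, lower, upper) {
    stat <- function(value) {
      cfg <- config
      cfg[[param]] <- value
      eval_stat(cfg, target_name)
    }
    x0 <- config[[param]]
    f0 <- stat(x0) - targets[[target_name]]
    hist <- data.frame(value = x0, gap = f0)
    if (abs(f0) <= tolerance) {
      return(list(value = x0, achieved = f0 + targets[[target_name]],
                  trace = hist))
    }
    x1 <- min(max(x0 * 1.25 + 1, lower), upper)
    for (it in seq_len(max_iter)) {
      f1 <- stat(x1) - targets[[target_name]]
      hist <- rbind(hist, data.frame(value = x1, gap = f1))
      if (abs(f1) <= tolerance) {
        return(list(value = x1, achieved = f1 + targets[[target_name]],
                    trace = hist))
      }
      slope <- (f1 - f0) / (x1 - x0)
      x0 <- x1; f0 <- f1
      x1 <- if (is.finite(slope) && abs(slope) > 1e-12)
        min(max(x1 - f1 / slope, lower), upper) else (lower + upper) / 2
    }
    best <- hist[which.min(abs(hist$gap)), ]
    stop(sprintf(
      "calibration of '%s' failed: best %s = %.4g at %s = %.4g (target %.4g)",
      param, target_name, best$gap + targets[[target_name]], param,
      best$value, targets[[target_name]]), call. = FALSE)
  }

  if ("seq_effect" %in% names(targets)) {
    sol <- solve_param(config, "slowing_mean", "seq_effect", 0, 2000)
    config$slowing_mean <- sol$value
    trace$slowing_mean <- sol
  }
  if ("ss_rate" %in% names(targets)) {
    sol <- solve_param(config, "drift_ms_per_100trials", "ss_rate",
                       0, 100)
    config$drift_ms_per_100trials <- sol$value
    trace$drift <- sol
  }

  achieved <- rowMeans(vapply(seq_len(n_seeds), function(k) {
    cohort_behavior_means(config, seed = seed + k - 1,
                          n_subjects = n_subjects)
  }, numeric(4)))
  attr(config, "calibration") <- list(targets = targets,
                                      achieved = achieved,
                                      tolerance = tolerance,
                                      n_subjects = n_subjects,
                                      seed = seed, trace = trace)
  config
}
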