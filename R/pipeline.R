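#' Analysis-side settings for a full study run
#'
#' The analysis-side belief model may deliberately differ from the
#' generating one; both are recorded in the run's provenance.
#'
#' @param dbm Analysis-side [dbm_params()] used to recompute p(Stop) from
#'   the observed go/stop sequence (per session).
#' @param hrf [hrf_spec()] for the first-level designs.
#' @param orthogonalize Serially orthogonalize the parametric modulators
#'   (default `FALSE`).
#' @param bonferroni_alpha Family-wise alpha for the trait-coefficient
#'   summary (default 0.05).
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(dbm = dbm_params(alpha = 0.8, pm = 0.25, scale = 4),
                       hrf = NULL, orthogonalize = FALSE,
                       bonferroni_alpha = 0.05) {
  structure(list(dbm = dbm, hrf = hrf, orthogonalize = orthogonalize,
                 bonferroni_alpha = bonferroni_alpha),
            class = "run_config")
}

# analysis-side p(Stop): recomputed per session, strictly causal
attach_analysis_pstop <- function(events, params) {
  for (s in unique(events$session)) {
    rows <- events$session == s
    events$pstop[rows] <- dbm(events$trial_type[rows],
                              params = params)$pstop
  }
  events
}

#' Run the complete analysis chain on a synthetic study
#'
#' End-to-end pipeline: cohort generation, analysis-side trial-by-trial
#' p(Stop) estimation, per-subject behavioral summaries (go response rate,
#' stop-success rate, critical SSD, SSRT, sequential effect), first-level
#' ROI GLMs with the positive p(Stop)-on-GS contrast, second-level trait
#' regressions per ROI (NS, HA, RD with age and gender covariates), trait
#' gender comparisons, and gender slope comparisons for each ROI's linked
#' trait. Everything is a pure function of `(config, analysis, seed)`.
#'
#' @param config A [cohort_config()] for the generator.
#' @param analysis A [run_config()] with analysis-side settings.
#' @param seed Master seed.
#' @param out_dir Optional directory: event logs, cohort, contrast and
#'   report tables are written there as TSV together with a plain-text
#'   summary and a provenance log.
#' @param include_bold Run the imaging arm (default `TRUE`).
#' @return An object of class `"sst_study"`: list with `behavior` (per
#'   subject), `behavior_means`, `trait_tests`, `contrasts` (subject x ROI
#'   table), `second_level` (list of [trait_regression()] per ROI),
#'   `trait_significance` (Bonferroni summary), `slope_comparisons`,
#'   `provenance`.
#' @export
run_study <- function(config = cohort_config(), analysis = run_config(),
                      seed = 1, out_dir = NULL, include_bold = TRUE) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(analysis, "run_config"))
  bundle <- generate_cohort(config, seed = seed,
                            include_bold = include_bold,
                            hrf = analysis$hrf)
  cohort <- bundle$cohort

  # behavioral arm (analysis-side p(Stop))
  events <- lapply(bundle$events, attach_analysis_pstop, analysis$dbm)
  behavior <- do.call(rbind, lapply(events, behavioral_summary))
  behavior <- cbind(subject_id = cohort$subject_id, behavior,
                    row.names = NULL)
  behavior_means <- c(
    go_response_rate = mean(behavior$go_response_rate),
    ss_rate = mean(behavior$ss_rate),
    median_gort_ms = mean(behavior$median_gort_ms),
    ssrt_ms = mean(behavior$ssrt_ms),
    seq_effect_r = mean(behavior$seq_effect_r),
    n_seq_significant = sum(behavior$seq_effect_p < 0.05))

  # trait summaries and gender comparisons
  f <- cohort$gender == "F"
  trait_tests <- lapply(c(NS = "NS", HA = "HA", RD = "RD"), function(tr) {
    two_sample_t(cohort[[tr]][f], cohort[[tr]][!f])
  })

  contrasts <- NULL; second_level <- NULL
  trait_significance <- NULL; slope_comparisons <- NULL
  if (include_bold) {
    hrf <- if (is.null(analysis$hrf)) hrf_spec(tr_s = config$tr_s)
           else analysis$hrf
    roi_names <- names(config$rois)
    rows <- vector("list", nrow(cohort))
    for (i in seq_len(nrow(cohort))) {
      ev <- events[[i]]
      nv <- volumes_needed(ev, tr_s = config$tr_s,
                           discard_volumes = config$discard_volumes)
      des <- build_design(ev, hrf, n_volumes_per_session = nv,
                          discard_volumes = config$discard_volumes,
                          orthogonalize = analysis$orthogonalize)
      est <- vapply(roi_names, function(rn) {
        fit <- fit_roi_glm(bundle$bold[[i]][[rn]], des)
        con <- roi_contrast(fit, "gs_pstop")
        c(con$estimate, con$t)
      }, numeric(2))
      rows[[i]] <- data.frame(subject_id = cohort$subject_id[i],
                              roi = roi_names, contrast = "gs_pstop_pos",
                              estimate = est[1, ], t = est[2, ],
                              row.names = NULL)
    }
    contrasts <- do.call(rbind, rows)

    second_level <- lapply(roi_names, function(rn) {
      tab <- cohort[, c("subject_id", "gender", "age", "NS", "HA", "RD")]
      tab$contrast <- contrasts$estimate[contrasts$roi == rn]
      trait_regression(tab)
    })
    names(second_level) <- roi_names
    for (rn in roi_names) attr(second_level[[rn]], "dependent") <- rn
    trait_significance <- bonferroni_traits(second_level,
                                            alpha =
                                              analysis$bonferroni_alpha)

    slope_comparisons <- lapply(roi_names, function(rn) {
      tr <- config$rois[[rn]]$trait
      cvals <- contrasts$estimate[contrasts$roi == rn]
      res <- compare_slopes(cohort[[tr]][!f], cvals[!f],
                            cohort[[tr]][f], cvals[f])
      c(roi = rn, trait = tr, res[c("t", "dof", "p", "slope1", "slope2")])
    })
    names(slope_comparisons) <- roi_names
  }

  provenance <- list(seed = seed, generator = config,
                     analysis = analysis,
                     n_subjects = nrow(cohort),
                     timestamp = format(Sys.time(), tz = "UTC"),
                     package_version =
                       as.character(utils::packageVersion("stopbayes")))

  study <- structure(list(behavior = behavior,
                          behavior_means = behavior_means,
                          trait_tests = trait_tests,
                          cohort = cohort,
                          contrasts = contrasts,
                          second_level = second_level,
                          trait_significance = trait_significance,
                          slope_comparisons = slope_comparisons,
                          provenance = provenance),
                     class = "sst_study")
  if (!is.null(out_dir)) write_study(study, bundle, out_dir)
  study
}

# writes the TSV/text report bundle for a finished run
write_study <- function(study, bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "events"), showWarnings = FALSE)
  for (id in names(bundle$events)) {
    ev <- bundle$events[[id]]
    ev <- cbind(subject_id = id, ev)
    write_events_tsv(ev, file.path(out_dir, "events",
                                   paste0(id, "_events.tsv")))
  }
  write_table_tsv(study$cohort, file.path(out_dir, "cohort.tsv"))
  write_table_tsv(study$behavior, file.path(out_dir, "behavior.tsv"))
  if (!is.null(study$contrasts)) {
    write_table_tsv(study$contrasts, file.path(out_dir, "contrasts.tsv"))
    sl <- do.call(rbind, lapply(names(study$second_level), function(rn) {
      cbind(roi = rn, as.data.frame(study$second_level[[rn]]))
    }))
    write_table_tsv(sl, file.path(out_dir, "second_level.tsv"))
  }
  con <- file(file.path(out_dir, "summary.txt"), "w")
  on.exit(close(con))
  sink(con); on.exit(sink(), add = TRUE, after = FALSE)
  print(study)
  cat("\nProvenance\n")
  cat("  seed:", study$provenance$seed, "\n")
  cat("  package version:", study$provenance$package_version, "\n")
  cat("  generated:", study$provenance$timestamp, "\n")
  invisible(out_dir)
}

#' @export
print.sst_study <- function(x, ...) {
  cat("Synthetic stop-signal study analysis\n")
  cat(sprintf("  %d subjects, seed %s\n", x$provenance$n_subjects,
              x$provenance$seed))
  bm <- x$behavior_means
  cat("Behavioral cohort means:\n")
  cat(sprintf("  go response rate %.1f%%, stop-success rate %.1f%%\n",
              100 * bm[["go_response_rate"]], 100 * bm[["ss_rate"]]))
  cat(sprintf("  median GoRT %.0f ms, SSRT %.0f ms\n",
              bm[["median_gort_ms"]], bm[["ssrt_ms"]]))
  cat(sprintf("  sequential effect r = %.3f (significant in %d/%d)\n",
              bm[["seq_effect_r"]], bm[["n_seq_significant"]],
              x$provenance$n_subjects))
  cat("Trait gender comparisons (women - men):\n")
  for (tr in names(x$trait_tests)) {
    tt <- x$trait_tests[[tr]]
    cat(sprintf("  %s: t(%d) = %.3f, p = %.3f, d = %.3f\n", tr, tt$dof,
                tt$t, tt$p, tt$cohens_d))
  }
  if (!is.null(x$second_level)) {
    cat("Second-level trait regressions (contrast: p(Stop) on GS > 0):\n")
    for (rn in names(x$second_level)) {
      rep <- x$second_level[[rn]]
      lead <- rep[rep$predictor %in% c("NS", "HA"), ]
      for (j in seq_len(nrow(lead))) {
        cat(sprintf("  %s ~ %s: beta = %.4f (t = %.2f, p = %.4f)\n", rn,
                    lead$predictor[j], lead$estimate[j], lead$t[j],
                    lead$p[j]))
      }
    }
  }
  invisible(x)
}
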