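# small simulated event log + design used by several fits
glm_fixture <- function(n_sessions = 2, trials_per_session = 80, seed = 301) {
  prof <- subject_profile()
  ev <- simulate_sessions(prof, n_sessions = n_sessions,
                          trials_per_session = trials_per_session,
                          start_s = 10, seed = seed)
  nv <- volumes_needed(ev)
  des <- build_design(ev, hrf_spec(oversampling = 8L),
                      n_volumes_per_session = nv)
  list(events = ev, design = des, n = sum(nv))
}

# AR(1) series with sd 'sd' (marginal), one session
ar1_noise <- function(n, rho, sd) {
  as.numeric(arima.sim(list(ar = rho), n = n, sd = sd * sqrt(1 - rho^2)))
}

test_that("canonical HRF has the expected double-gamma shape", {
  k <- canonical_hrf(hrf_spec())
  peak_t <- k$t[which.max(k$hrf)]
  expect_gte(peak_t, 4)
  expect_lte(peak_t, 7)
  # exactly one sign change after the peak (the undershoot)
  after <- k$hrf[k$t > peak_t]
  flips <- sum(diff(sign(after[after != 0])) != 0)
  expect_equal(flips, 1)
  # derivative of a pulse integrates to ~0 (relative to unit peak)
  dt <- k$t[2] - k$t[1]
  expect_lt(abs(sum(k$deriv) * dt), 1e-3 * max(k$hrf))
})

test_that("a single impulse reproduces the shifted kernel", {
  ev <- data.frame(session = 1, onset_s = 12, outcome = "GS",
                   ssd_ms = NA_real_, pstop = 0.25)
  spec <- hrf_spec(oversampling = 8L)
  des <- suppressWarnings(build_design(ev, spec, n_volumes_per_session = 30))
  k <- canonical_hrf(spec)
  vol_t <- (5 + 0:29) * 2  # retained volume times
  expected <- approx(k$t + 12, k$hrf, xout = vol_t, rule = 2)$y
  expected[vol_t < 12 | vol_t > 12 + 32] <- 0  # outside kernel support
  task <- des$X[, "s1_task"]
  expect_equal(task, expected, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("modulator columns are mean-centered and linear", {
  spec <- hrf_spec(oversampling = 8L)
  # constant p(Stop) over GS trials centers to an all-zero column, which
  # is dropped as degenerate
  ev <- data.frame(session = 1, onset_s = c(12, 30, 52, 70),
                   outcome = "GS", ssd_ms = NA_real_, pstop = 0.3)
  w <- capture_warnings(
    des <- build_design(ev, spec, n_volumes_per_session = 60))
  expect_match(w, "gs_pstop", all = FALSE)
  expect_false("s1_gs_pstop" %in% colnames(des$X))

  # centered weights (+c, 0, -c) -> antisymmetric combination of two
  # shifted kernels (the middle trial carries zero weight)
  ev2 <- data.frame(session = 1, onset_s = c(12, 26, 40), outcome = "GS",
                    ssd_ms = NA_real_, pstop = c(0.4, 0.3, 0.2))
  des2 <- suppressWarnings(build_design(ev2, spec,
                                        n_volumes_per_session = 45))
  one <- function(onset) {
    e <- data.frame(session = 1, onset_s = onset, outcome = "GS",
                    ssd_ms = NA_real_, pstop = 1)
    suppressWarnings(build_design(e, spec,
                                  n_volumes_per_session = 45))$X[, "s1_task"]
  }
  expect_equal(des2$X[, "s1_gs_pstop"], 0.1 * one(12) - 0.1 * one(40),
               tolerance = 1e-10, ignore_attr = TRUE)

  # adding a constant to all modulator values leaves the design unchanged
  ev3 <- ev2
  ev3$pstop <- ev3$pstop + 0.17
  des3 <- suppressWarnings(build_design(ev3, spec,
                                        n_volumes_per_session = 45))
  expect_equal(des2$X, des3$X)

  # onsets outside the retained window are rejected
  bad <- ev2
  bad$onset_s[1] <- 4  # inside the discarded 5 volumes
  expect_error(suppressWarnings(build_design(bad, spec,
                                             n_volumes_per_session = 45)),
               "outside")
})

test_that("design construction is deterministic and flags empty strata", {
  fx <- glm_fixture()
  des2 <- build_design(fx$events, hrf_spec(oversampling = 8L),
                       n_volumes_per_session = volumes_needed(fx$events))
  expect_identical(fx$design$X, des2$X)

  ev <- fx$events[fx$events$session == 1 & fx$events$outcome != "SE", ]
  w <- capture_warnings(
    des_nose <- build_design(ev, hrf_spec(oversampling = 8L),
                             n_volumes_per_session = volumes_needed(ev)))
  expect_length(w, 2)
  expect_match(w, "se_(ssd|pstop)", all = TRUE)
  expect_false(any(grepl("se_ssd|se_pstop", colnames(des_nose$X))))
})

test_that("an exact model fit has zero residual variance and rho 0", {
  fx <- glm_fixture()
  set.seed(361)
  beta <- rnorm(ncol(fx$design$X), 0, 0.5)
  y <- as.numeric(fx$design$X %*% beta)
  fit <- fit_roi_glm(y, fx$design)
  expect_equal(unname(fit$betas[seq_along(beta)]), beta, tolerance = 1e-8)
  expect_lt(fit$sigma2, 1e-16)
  expect_equal(fit$rho, 0)
})

test_that("whitening with rho = 0 reproduces plain OLS exactly", {
  set.seed(371)
  fx <- glm_fixture(n_sessions = 1, trials_per_session = 60, seed = 371)
  y <- rnorm(fx$n) + 0.7 * fx$design$X[, "s1_task"]
  fit0 <- fit_roi_glm(y, fx$design, rho = 0)
  G <- cbind(fx$design$X, fx$design$hp_basis)
  ols <- lm.fit(G, y)
  expect_equal(unname(fit0$betas), unname(ols$coefficients),
               tolerance = 1e-10)
  expect_equal(fit0$rho, 0)
  expect_equal(sum(fit0$residuals^2), sum(ols$residuals^2),
               tolerance = 1e-10)
})

test_that("white-noise data yield a near-zero AR(1) estimate", {
  set.seed(311)
  prof <- subject_profile()
  ev <- simulate_sessions(prof, n_sessions = 1, trials_per_session = 340,
                          start_s = 10, seed = 311)
  nv <- max(volumes_needed(ev), 1000)
  des <- build_design(ev, hrf_spec(oversampling = 8L),
                      n_volumes_per_session = nv)
  fit <- fit_roi_glm(rnorm(nv), des)
  expect_lt(abs(fit$rho), 0.05)
})

test_that("betas and rho are recovered from AR(1) data", {
  set.seed(321)
  fx <- glm_fixture()
  beta <- numeric(ncol(fx$design$X))
  names(beta) <- colnames(fx$design$X)
  beta[grep("_task$", names(beta))] <- 1.2
  beta[grep("_gs_pstop$", names(beta))] <- 0.8
  noise <- unlist(lapply(fx$design$n_volumes,
                         function(n) ar1_noise(n, 0.3, 1)))
  y <- as.numeric(fx$design$X %*% beta) + noise
  fit <- fit_roi_glm(y, fx$design)
  expect_lt(abs(fit$rho - 0.3), 0.05)
  con <- roi_contrast(fit, "gs_pstop")
  expect_lt(abs(con$estimate - 0.8), 2 * con$se)
  con_task <- roi_contrast(fit, "task")
  expect_lt(abs(con_task$estimate - 1.2), 2 * con_task$se)
})

test_that("contrasts negate exactly and vanish with zero weights", {
  set.seed(331)
  fx <- glm_fixture(n_sessions = 1, trials_per_session = 60, seed = 331)
  y <- rnorm(fx$n, 0, 1) + 0.5 * fx$design$X[, "s1_task"]
  fit <- fit_roi_glm(y, fx$design)
  pos <- roi_contrast(fit, "gs_pstop", sign = 1)
  neg <- roi_contrast(fit, "gs_pstop", sign = -1)
  expect_identical(pos$estimate, -neg$estimate)
  expect_identical(pos$t, -neg$t)
  zero <- roi_contrast(fit, numeric(length(fit$betas)))
  expect_identical(zero$estimate, 0)
  expect_identical(zero$t, 0)
})

test_that("drift in the DCT span cannot move contrast estimates", {
  set.seed(341)
  fx <- glm_fixture(n_sessions = 1, trials_per_session = 60, seed = 341)
  y <- rnorm(fx$n) + fx$design$X[, "s1_task"]
  H <- fx$design$hp_basis
  drift <- as.numeric(H %*% rnorm(ncol(H), 0, 5))
  c1 <- roi_contrast(fit_roi_glm(y, fx$design), "gs_pstop")
  c2 <- roi_contrast(fit_roi_glm(y + drift, fx$design), "gs_pstop")
  expect_lt(abs(c1$estimate - c2$estimate),
            1e-8 * max(abs(c1$estimate), 1e-12))
})

test_that("rank-deficient designs are reported with the guilty columns", {
  fx <- glm_fixture(n_sessions = 1, trials_per_session = 60, seed = 351)
  des <- fx$design
  dup <- des$X[, "s1_task", drop = FALSE]
  colnames(dup) <- "s1_task_copy"
  des$X <- cbind(des$X, dup)
  des$column_names <- colnames(des$X)
  expect_error(fit_roi_glm(rnorm(nrow(des$X)), des), "collinear")
})
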