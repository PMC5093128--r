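#' Canonical HRF specification
#'
#' Parameters of the canonical double-gamma hemodynamic response function
#' and of its sampling: a positive gamma peaking around 6 s minus a scaled
#' gamma undershoot around 16 s, sampled over 32 s.
#'
#' @param tr_s Repetition time in seconds (default 2).
#' @param oversampling Microtime resolution: samples per TR used when
#'   convolving event impulses (default 16).
#' @param peak_delay_s,undershoot_delay_s Delays of the response peak and
#'   undershoot (defaults 6 and 16 s).
#' @param peak_disp_s,undershoot_disp_s Dispersions (defaults 1 s).
#' @param p_u_ratio Peak-to-undershoot amplitude ratio (default 6).
#' @param duration_s Kernel support (default 32 s).
#' @param include_derivative Include the temporal-derivative regressor in
#'   designs built from this spec (default `TRUE`).
#' @return A list of class `"hrf_spec"`.
#' @export
hrf_spec <- function(tr_s = 2, oversampling = 16L, peak_delay_s = 6,
                     undershoot_delay_s = 16, peak_disp_s = 1,
                     undershoot_disp_s = 1, p_u_ratio = 6,
                     duration_s = 32, include_derivative = TRUE) {
  if (tr_s <= 0) stop("'tr_s' must be positive", call. = FALSE)
  if (any(c(peak_delay_s, undershoot_delay_s, peak_disp_s,
            undershoot_disp_s) <= 0)) {
    stop("HRF delays and dispersions must be positive", call. = FALSE)
  }
  structure(list(tr_s = tr_s, oversampling = as.integer(oversampling),
                 peak_delay_s = peak_delay_s,
                 undershoot_delay_s = undershoot_delay_s,
                 peak_disp_s = peak_disp_s,
                 undershoot_disp_s = undershoot_disp_s,
                 p_u_ratio = p_u_ratio, duration_s = duration_s,
                 include_derivative = include_derivative),
            class = "hrf_spec")
}

#' Sample the canonical HRF and its temporal derivative
#'
#' @param spec An [hrf_spec()].
#' @return A list with `t` (sample times at `tr_s / oversampling`
#'   resolution over the kernel support), `hrf` (the double-gamma kernel,
#'   scaled to unit peak) and `deriv` (finite-difference temporal
#'   derivative).
#' @export
canonical_hrf <- function(spec = hrf_spec()) {
  dt <- spec$tr_s / spec$oversampling
  t <- seq(0, spec$duration_s, by = dt)
  h <- stats::dgamma(t, shape = spec$peak_delay_s / spec$peak_disp_s,
                     scale = spec$peak_disp_s) -
    stats::dgamma(t, shape = spec$undershoot_delay_s / spec$undershoot_disp_s,
                  scale = spec$undershoot_disp_s) / spec$p_u_ratio
  h <- h / max(h)
  d <- c(diff(h), 0) / dt
  list(t = t, hrf = h, deriv = d)
}

# Convolve unit impulses (or weighted impulses) at event onsets with a
# kernel on the microtime grid, then sample at the retained volume times.
convolve_events <- function(onsets, weights, kernel, dt, n_micro, vol_idx) {
  x <- numeric(n_micro)
  idx <- pmin(pmax(round(onsets / dt) + 1L, 1L), n_micro)
  for (i in seq_along(idx)) {
    x[idx[i]] <- x[idx[i]] + weights[i]
  }
  conv <- stats::convolve(x, rev(kernel), type = "open")[seq_len(n_micro)]
  conv[vol_idx]
}

# Discrete cosine high-pass basis (constant excluded), SPM convention:
# order floor(2 * duration * cutoff_hz).
dct_basis <- function(n, tr_s, cutoff_hz = 1 / 128) {
  order <- floor(2 * n * tr_s * cutoff_hz)
  if (order < 1L) return(matrix(numeric(0), nrow = n, ncol = 0))
  t <- seq_len(n) - 0.5
  sapply(seq_len(order), function(k) cos(pi * k * t / n))
}

#' First-level design matrix for simulated ROI BOLD
#'
#' Builds the session-wise design: one event regressor with unit impulses
#' at every trial's fixation onset convolved with the canonical HRF, its
#' temporal derivative, and five ordered parametric modulators — p(Stop) on
#' successful go (GS) trials, SSD on successful stop (SS) trials, p(Stop)
#' on SS trials, SSD on failed stop (SE) trials, and p(Stop) on SE trials.
#' Modulator values are mean-centered within their session and stratum
#' before convolution, so the modulator columns are orthogonal to constant
#' shifts of the modulator. Sessions are concatenated block-diagonally and
#' each session contributes a constant column. An empty or degenerate
#' stratum (e.g. a session without SE trials, or with a single one, whose
#' centered modulator would be identically zero) drops that column with a
#' warning.
#'
#' The first `discard_volumes` volumes of each session are treated as
#' discarded before the retained data start: the returned rows correspond
#' to retained volumes only, and onsets must fall inside the retained part
#' of the session.
#'
#' Optionally (`orthogonalize = TRUE`) the modulators are serially
#' orthogonalized in the stated order, each column residualized against
#' the event regressor and all earlier modulators within its session; the
#' default leaves them as built, which keeps their interpretation
#' order-independent.
#'
#' @param events Event-log data.frame with columns `session`, `onset_s`
#'   (seconds from session start), `outcome`, `ssd_ms`, `pstop`.
#' @param spec An [hrf_spec()].
#' @param n_volumes_per_session Integer vector (recycled) of retained
#'   volumes per session.
#' @param discard_volumes Volumes discarded at the start of each session
#'   (default 5).
#' @param orthogonalize Serially orthogonalize the modulators (default
#'   `FALSE`).
#' @return A list of class `"sst_design"`: `X` (rows = total retained
#'   volumes), `column_names`, `session` (row labels), `tr_s`, `hp_basis`
#'   (block-diagonal DCT high-pass basis, 1/128 Hz cutoff, applied at fit
#'   time), `n_volumes`, `session_boundaries`.
#' @export
build_design <- function(events, spec = hrf_spec(), n_volumes_per_session,
                         discard_volumes = 5L, orthogonalize = FALSE) {
  if (!all(c("session", "onset_s", "outcome", "pstop") %in% names(events))) {
    stop("'events' must carry session, onset_s, outcome, ssd_ms, pstop",
         call. = FALSE)
  }
  sessions <- sort(unique(events$session))
  n_vol <- rep_len(as.integer(n_volumes_per_session), length(sessions))
  dt <- spec$tr_s / spec$oversampling
  kern <- canonical_hrf(spec)

  blocks <- vector("list", length(sessions))
  col_names <- character(0)
  hp_blocks <- vector("list", length(sessions))
  session_rows <- integer(0)

  for (si in seq_along(sessions)) {
    ev <- events[events$session == sessions[si], ]
    n <- n_vol[si]
    t_start <- discard_volumes * spec$tr_s
    t_end <- (discard_volumes + n) * spec$tr_s
    if (any(ev$onset_s < t_start | ev$onset_s >= t_end)) {
      stop(sprintf("session %s has onsets outside the retained volumes",
                   sessions[si]), call. = FALSE)
    }
    n_micro <- as.integer(ceiling(t_end / dt))
    # volume acquisition times relative to session start
    vol_idx <- round((discard_volumes + seq_len(n) - 1) * spec$tr_s / dt) + 1L

    build_col <- function(onsets, weights, kernel) {
      convolve_events(onsets, weights, kernel, dt, n_micro, vol_idx)
    }

    cols <- list(task = build_col(ev$onset_s, rep(1, nrow(ev)), kern$hrf))
    if (spec$include_derivative) {
      cols$task_deriv <- build_col(ev$onset_s, rep(1, nrow(ev)), kern$deriv)
    }

    strata <- list(
      gs_pstop = list(sel = ev$outcome == "GS", val = ev$pstop),
      ss_ssd   = list(sel = ev$outcome == "SS", val = ev$ssd_ms),
      ss_pstop = list(sel = ev$outcome == "SS", val = ev$pstop),
      se_ssd   = list(sel = ev$outcome == "SE", val = ev$ssd_ms),
      se_pstop = list(sel = ev$outcome == "SE", val = ev$pstop)
    )
    for (nm in names(strata)) {
      sel <- strata[[nm]]$sel
      v <- strata[[nm]]$val[sel]
      # a stratum without variation centers to an all-zero column; with
      # exactly two trials its two centered modulators (+c/-c) are
      # proportional to each other -- both unestimable, so require >= 3
      if (sum(sel) < 3L || max(v) - min(v) == 0) {
        warning(sprintf(
          "session %s: modulator '%s' empty or degenerate; column omitted",
          sessions[si], nm), call. = FALSE)
        next
      }
      v <- v - mean(v)
      cols[[nm]] <- build_col(ev$onset_s[sel], v, kern$hrf)
    }

    if (orthogonalize) {
      mods <- intersect(names(strata), names(cols))
      base <- cbind(cols$task)
      for (nm in mods) {
        fit <- stats::lm.fit(cbind(base, 1), cols[[nm]])
        cols[[nm]] <- fit$residuals
        base <- cbind(base, cols[[nm]])
      }
    }

    cols$const <- rep(1, n)
    blocks[[si]] <- do.call(cbind, cols)
    col_names <- c(col_names,
                   paste0("s", sessions[si], "_", names(cols)))
    hp_blocks[[si]] <- dct_basis(n, spec$tr_s)
    session_rows <- c(session_rows, rep(sessions[si], n))
  }

  # block-diagonal assembly
  total_rows <- sum(n_vol)
  X <- matrix(0, nrow = total_rows, ncol = length(col_names))
  H <- matrix(0, nrow = total_rows,
              ncol = sum(vapply(hp_blocks, ncol, integer(1))))
  r0 <- 0L; c0 <- 0L; h0 <- 0L
  for (si in seq_along(sessions)) {
    nr <- nrow(blocks[[si]]); nc <- ncol(blocks[[si]])
    X[r0 + seq_len(nr), c0 + seq_len(nc)] <- blocks[[si]]
    nh <- ncol(hp_blocks[[si]])
    if (nh > 0) H[r0 + seq_len(nr), h0 + seq_len(nh)] <- hp_blocks[[si]]
    r0 <- r0 + nr; c0 <- c0 + nc; h0 <- h0 + nh
  }
  colnames(X) <- col_names
  structure(list(X = X, column_names = col_names, session = session_rows,
                 tr_s = spec$tr_s, hp_basis = H, n_volumes = n_vol,
                 session_boundaries = cumsum(n_vol)),
            class = "sst_design")
}

#' Retained volumes needed to cover an event log
#'
#' Number of retained volumes per session so that every trial onset plus
#' the HRF tail falls inside the scanned window.
#'
#' @param events Event log with `session` and `onset_s`.
#' @param tr_s Repetition time (s).
#' @param discard_volumes Discarded initial volumes per session.
#' @param tail_s Post-onset coverage (default 33 s, one TR past the kernel).
#' @return Integer vector, one entry per session (sorted by session id).
#' @export
volumes_needed <- function(events, tr_s = 2, discard_volumes = 5L,
                           tail_s = 33) {
  vapply(sort(unique(events$session)), function(s) {
    last <- max(events$onset_s[events$session == s])
    as.integer(ceiling((last + tail_s) / tr_s)) - as.integer(discard_volumes)
  }, integer(1))
}

# Residualize columns against the high-pass basis, per whole matrix
# (the basis is already block-diagonal by session).
hp_filter <- function(M, H) {
  if (ncol(H) == 0) return(M)
  M - H %*% qr.coef(qr(H), M)
}

# AR(1) whitening transform applied block-wise by session: the first
# retained volume of each session is scaled by sqrt(1 - rho^2), later
# volumes become x_t - rho * x_{t-1}. With rho = 0 this is the identity.
ar1_whiten <- function(M, rho, session) {
  M <- as.matrix(M)
  W <- M
  for (s in unique(session)) {
    rows <- which(session == s)
    block <- M[rows, , drop = FALSE]
    out <- block
    out[1, ] <- sqrt(1 - rho^2) * block[1, ]
    if (length(rows) > 1) {
      out[-1, ] <- block[-1, , drop = FALSE] -
        rho * block[-length(rows), , drop = FALSE]
    }
    W[rows, ] <- out
  }
  W
}

# pooled within-session lag-1 "autocovariance ratio" e'Le / e'e
lag1_ratio <- function(e, session) {
  num <- 0; den <- 0
  for (s in unique(session)) {
    v <- e[session == s]
    num <- num + sum(v[-1] * v[-length(v)])
    den <- den + sum(v^2)
  }
  if (den <= 0) return(NA_real_)
  num / den
}

#' Fit a first-level GLM with AR(1) prewhitening
#'
#' Fits one ROI time series against a [build_design()] design with the
#' discrete-cosine high-pass basis (1/128 Hz cutoff) included as nuisance
#' columns, which is equivalent to high-pass filtering data and regressors.
#' Serial autocorrelation is corrected by a first-order autoregressive
#' model: starting from the OLS residual lag-1 autocorrelation, the AR(1)
#' coefficient is refined so that, after whitening data and design and
#' refitting, the residual lag-1 autocorrelation equals its expected value
#' under white noise (which is slightly negative because of the projection
#' onto the residual space — ignoring this projection effect would bias rho
#' downwards). Estimates, their covariance, and the residual variance come
#' from the whitened model; with a fixed `rho = 0` the fit is exactly OLS.
#'
#' @param y Numeric ROI time series, one value per retained volume
#'   (sessions stacked in design order).
#' @param design An [build_design()] object.
#' @param rho Optional fixed AR(1) coefficient (skips estimation);
#'   `NULL` (default) estimates it.
#' @return An object of class `"roi_glm"`: `betas` (design columns, then
#'   high-pass columns), `sigma2`, `rho`, `dof`, `cov_unscaled` (the
#'   whitened `(G'G)^{-1}` over all columns), `residuals` (whitened),
#'   `column_names`, `session`.
#' @export
fit_roi_glm <- function(y, design, rho = NULL) {
  if (!inherits(design, "sst_design")) {
    stop("'design' must come from build_design()", call. = FALSE)
  }
  y <- as.numeric(y)
  X <- design$X
  if (length(y) != nrow(X)) {
    stop("length of 'y' must match the design rows", call. = FALSE)
  }
  H <- design$hp_basis
  hp_names <- if (ncol(H)) paste0("hp", seq_len(ncol(H))) else character(0)
  G <- cbind(X, H)
  all_names <- c(design$column_names, hp_names)
  session <- design$session
  n <- nrow(G); p <- ncol(G)
  if (n - p <= 0) stop("non-positive residual degrees of freedom",
                       call. = FALSE)

  qr0 <- qr(G)
  if (qr0$rank < p) {
    bad <- all_names[qr0$pivot[(qr0$rank + 1):p]]
    stop("design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  # residual lag-1 autocorrelation at a given rho, and its white-noise
  # expectation -tr(L P)/(n - p) from the whitened orthonormal basis
  pass <- function(r) {
    Gw <- ar1_whiten(G, r, session)
    yw <- ar1_whiten(cbind(y), r, session)[, 1]
    qrW <- qr(Gw)
    e <- qr.resid(qrW, yw)
    Q <- qr.Q(qrW)[, seq_len(p), drop = FALSE]
    trLP <- sum(vapply(seq_len(p), function(j) {
      lag1_ratio(Q[, j], session) * sum(Q[, j]^2)
    }, numeric(1)))
    list(qrW = qrW, yw = yw, e = e,
         gap = lag1_ratio(e, session) - (-trLP / (n - p)))
  }

  if (is.null(rho)) {
    e0 <- qr.resid(qr0, y)
    if (sum(e0^2) <= 1e-12 * max(sum(y^2), .Machine$double.xmin)) {
      rho <- 0  # perfect fit leaves no autocorrelation to model
      fit1 <- pass(rho)
    } else {
      rho <- min(max(lag1_ratio(e0, session), -0.95), 0.95)
      fit1 <- pass(rho)
      # secant refinement of rho on the residual-autocorrelation gap
      r_prev <- rho; g_prev <- fit1$gap
      r_cur <- min(max(rho + fit1$gap, -0.95), 0.95)
      for (it in 1:6) {
        if (!is.finite(g_prev) || abs(g_prev) < 1e-4 ||
            abs(r_cur - r_prev) < 1e-8) break
        fit1 <- pass(r_cur)
        rho <- r_cur
        slope <- (fit1$gap - g_prev) / (r_cur - r_prev)
        r_prev <- r_cur; g_prev <- fit1$gap
        step <- if (is.finite(slope) && abs(slope) > 1e-8)
          -fit1$gap / slope else fit1$gap
        r_cur <- min(max(r_cur + step, -0.95), 0.95)
      }
    }
  } else {
    fit1 <- pass(rho)
  }

  qrW <- fit1$qrW
  betas <- qr.coef(qrW, fit1$yw)
  names(betas) <- all_names
  dof <- n - p
  sigma2 <- sum(fit1$e^2) / dof
  R <- qr.R(qrW)
  cov_unscaled <- chol2inv(R)
  if (!identical(qrW$pivot, seq_len(p))) {
    piv <- order(qrW$pivot)
    cov_unscaled <- cov_unscaled[piv, piv]
  }
  dimnames(cov_unscaled) <- list(all_names, all_names)
  structure(list(betas = betas, sigma2 = sigma2, rho = rho, dof = dof,
                 cov_unscaled = cov_unscaled, residuals = fit1$e,
                 column_names = all_names,
                 n_task_columns = ncol(X),
                 session = session),
            class = "roi_glm")
}

#' @export
print.roi_glm <- function(x, ...) {
  cat("First-level ROI GLM (AR(1)-whitened)\n")
  cat(sprintf("  %d volumes, %d regressors, dof = %d\n",
              length(x$session), length(x$betas), x$dof))
  cat(sprintf("  AR(1) rho = %.3f, residual variance = %.4g\n",
              x$rho, x$sigma2))
  invisible(x)
}

#' @export
coef.roi_glm <- function(object, ...) object$betas

#' @export
residuals.roi_glm <- function(object, ...) object$residuals

#' Contrast estimate and t statistic from a fitted ROI GLM
#'
#' Computes `w' beta`, its standard error from the whitened-model
#' covariance, and the t statistic. `weights` may be a full numeric vector
#' over design columns, or the bare name of a regressor (e.g.
#' `"gs_pstop"`), in which case the contrast averages that regressor's
#' column across the sessions that contain it, scaled by `sign`.
#'
#' @param fit A [fit_roi_glm()] object.
#' @param weights Numeric contrast vector or regressor name.
#' @param sign Multiplier applied to a name-built contrast (use `-1` for
#'   the negative contrast; default `+1`).
#' @return A list with `estimate`, `se`, `t`, `dof`.
#' @export
roi_contrast <- function(fit, weights, sign = 1) {
  if (is.character(weights)) {
    stopifnot(length(weights) == 1L)
    hit <- grepl(paste0("^s[^_]+_", weights, "$"), fit$column_names)
    if (!any(hit)) {
      stop("no design column matches '", weights, "'", call. = FALSE)
    }
    w <- numeric(length(fit$column_names))
    w[hit] <- sign / sum(hit)
    weights <- w
  }
  if (length(weights) != length(fit$betas)) {
    stop("'weights' must match the number of design columns",
         call. = FALSE)
  }
  est <- sum(weights * fit$betas)
  v <- fit$sigma2 * drop(t(weights) %*% fit$cov_unscaled %*% weights)
  se <- sqrt(v)
  t <- if (se > 0) est / se else 0
  list(estimate = est, se = se, t = t, dof = fit$dof)
}
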