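#' Dynamic belief model parameters
#'
#' Construct and validate the parameter set of the dynamic belief model
#' (DBM). The DBM assumes the latent stop-trial rate `r` persists from one
#' trial to the next with probability `alpha` and is redrawn from a generic
#' beta prior with probability `1 - alpha`. The beta prior is parameterized
#' by its mean `pm` and concentration `scale`, i.e. shape parameters
#' `a = pm * scale` and `b = (1 - pm) * scale`.
#'
#' @param alpha Belief-persistence probability in `[0, 1]`.
#' @param pm Prior mean stop rate, strictly inside `(0, 1)`.
#' @param scale Positive concentration (sum of beta shape parameters).
#' @param grid_size Number of discretization points for the stop rate
#'   (at least 10; default 100).
#'
#' @return An object of class `"dbm_params"`: a list with elements
#'   `alpha`, `pm`, `scale`, `grid_size`.
#' @examples
#' dbm_params(alpha = 0.8, pm = 0.25, scale = 4)
#' @export
dbm_params <- function(alpha = 0.8, pm = 0.25, scale = 4, grid_size = 100L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1) {
    stop("'alpha' must be a single probability in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(pm) || length(pm) != 1L || is.na(pm) ||
      pm <= 0 || pm >= 1) {
    stop("'pm' must be a single value strictly inside (0, 1)", call. = FALSE)
  }
  if (!is.numeric(scale) || length(scale) != 1L || is.na(scale) || scale <= 0) {
    stop("'scale' must be a single positive value", call. = FALSE)
  }
  grid_size <- as.integer(grid_size)
  if (length(grid_size) != 1L || is.na(grid_size) || grid_size < 10L) {
    stop("'grid_size' must be an integer >= 10", call. = FALSE)
  }
  structure(list(alpha = alpha, pm = pm, scale = scale,
                 grid_size = grid_size),
            class = "dbm_params")
}

# Discretized beta prior over the stop rate: density at midpoints of
# grid_size equal-width bins on (0,1), renormalized. Midpoints avoid the
# endpoint singularities of beta densities with shape < 1.
dbm_prior_mass <- function(params) {
  r <- dbm_r_grid(params$grid_size)
  a <- params$pm * params$scale
  b <- (1 - params$pm) * params$scale
  mass <- stats::dbeta(r, a, b)
  mass / sum(mass)
}

dbm_r_grid <- function(grid_size) {
  (seq_len(grid_size) - 0.5) / grid_size
}

#' Initial belief state of the dynamic belief model
#'
#' Returns the belief state for trial 1: the predictive distribution over
#' the stop rate equals the discretized beta prior (no observations yet),
#' and the posterior is initialized to the same distribution.
#'
#' @param params A [dbm_params()] object.
#' @return A list of class `"dbm_state"` with elements `r_grid`,
#'   `predictive_mass`, `posterior_mass`, `trial_index`, and `prior_mass`
#'   (the fixed generic prior used by the mixture step).
#' @examples
#' st <- dbm_prior(dbm_params(pm = 0.25, scale = 4))
#' sum(st$predictive_mass)  # 1
#' @export
dbm_prior <- function(params) {
  if (!inherits(params, "dbm_params")) {
    params <- do.call(dbm_params, as.list(params))
  }
  pi_mass <- dbm_prior_mass(params)
  structure(list(r_grid = dbm_r_grid(params$grid_size),
                 predictive_mass = pi_mass,
                 posterior_mass = pi_mass,
                 prior_mass = pi_mass,
                 trial_index = 1L),
            class = "dbm_state")
}

#' Bayesian posterior update for one observed trial
#'
#' Updates the belief state with the observed trial category by Bayes'
#' rule: the posterior over the stop rate is proportional to the predictive
#' distribution times the Bernoulli likelihood (`r` for a stop trial,
#' `1 - r` for a go trial).
#'
#' @param state A `"dbm_state"` object.
#' @param outcome Observed trial category: 1 for a stop trial, 0 for go.
#' @return The state with `posterior_mass` replaced by the normalized
#'   posterior.
#' @export
dbm_update <- function(state, outcome) {
  if (!is.numeric(outcome) && !is.logical(outcome)) {
    stop("'outcome' must be 0 (go) or 1 (stop)", call. = FALSE)
  }
  outcome <- as.numeric(outcome)
  if (length(outcome) != 1L || is.na(outcome) || !outcome %in% c(0, 1)) {
    stop("'outcome' must be 0 (go) or 1 (stop)", call. = FALSE)
  }
  lik <- if (outcome == 1) state$r_grid else 1 - state$r_grid
  unnorm <- lik * state$predictive_mass
  total <- sum(unnorm)
  if (!is.finite(total) || total <= 0) {
    stop("posterior mass vanished; belief state is degenerate",
         call. = FALSE)
  }
  state$posterior_mass <- unnorm / total
  state
}

#' Advance the belief state to the next trial
#'
#' Applies the DBM transition: with probability `alpha` the stop rate
#' persists (the posterior carries over), with probability `1 - alpha` it is
#' redrawn from the generic prior. The predictive distribution for the next
#' trial is therefore the mixture
#' `alpha * posterior + (1 - alpha) * prior`.
#'
#' @param state A `"dbm_state"` object (posterior up to date).
#' @param params A [dbm_params()] object.
#' @return The state for the next trial: updated `predictive_mass`,
#'   `trial_index` incremented.
#' @export
dbm_advance <- function(state, params) {
  state$predictive_mass <- params$alpha * state$posterior_mass +
    (1 - params$alpha) * state$prior_mass
  state$trial_index <- state$trial_index + 1L
  state
}

#' Probability of a stop signal from the current belief state
#'
#' p(Stop) for the upcoming trial is the mean of the predictive
#' distribution over the stop rate.
#'
#' @param state A `"dbm_state"` object.
#' @return A single probability.
#' @export
dbm_pstop <- function(state) {
  sum(state$r_grid * state$predictive_mass)
}

# Strictly causal p(Stop) series for a 0/1 category sequence.
dbm_run <- function(categories, params) {
  n <- length(categories)
  state <- dbm_prior(params)
  pstop <- numeric(n)
  for (k in seq_len(n)) {
    pstop[k] <- dbm_pstop(state)
    state <- dbm_update(state, categories[k])
    state <- dbm_advance(state, params)
  }
  pstop
}

check_categories <- function(trial_type) {
  if (is.character(trial_type) || is.factor(trial_type)) {
    trial_type <- as.character(trial_type)
    bad <- !trial_type %in% c("go", "stop")
    if (any(bad)) {
      stop("'trial_type' must be 'go'/'stop' or 0/1", call. = FALSE)
    }
    trial_type <- as.numeric(trial_type == "stop")
  }
  trial_type <- as.numeric(trial_type)
  if (length(trial_type) == 0L) {
    stop("empty trial sequence", call. = FALSE)
  }
  if (anyNA(trial_type) || !all(trial_type %in% c(0, 1))) {
    stop("'trial_type' must be 'go'/'stop' or 0/1", call. = FALSE)
  }
  trial_type
}

#' Fit the dynamic belief model to a trial sequence
#'
#' Runs the dynamic belief model over an observed go/stop sequence,
#' producing the strictly causal trial-by-trial estimate p(Stop) — the
#' probability of an impending stop signal given the history of trials
#' seen so far. p(Stop) on trial `k` is computed *before* observing trial
#' `k`'s category; on trial 1 it equals the prior mean `pm` (up to
#' discretization).
#'
#' If go-trial reaction times are supplied, the sequential effect — the
#' Pearson correlation between p(Stop) and go RT — is computed and stored,
#' together with the least-squares regression of RT on p(Stop) that the
#' `fitted` and `residuals` methods use.
#'
#' @param trial_type Trial categories: a `"go"`/`"stop"` character vector or
#'   a 0/1 vector (1 = stop).
#' @param rt Optional numeric vector of reaction times, aligned with
#'   `trial_type`; entries must be `NA` wherever no valid go response
#'   exists (stop trials, omissions). Units are arbitrary (ms typical).
#' @param alpha,pm,scale,grid_size Model parameters; see [dbm_params()].
#' @param params Alternatively, a ready-made [dbm_params()] object
#'   (overrides the scalar arguments).
#'
#' @return An object of class `"dbm"`: a list with `params`, `categories`,
#'   `pstop` (the p(Stop) series), `rt`, and — when RTs are given —
#'   `seq_effect` (list with Pearson `r`, two-sided `p`, `n`) and `lm_coef`
#'   (intercept and slope of RT on p(Stop)).
#' @examples
#' fit <- dbm(c(0, 0, 1, 0, 0, 0, 1, 0))
#' fitted(fit)  # p(Stop) per trial
#' @seealso [dbm_grid_fit()] for selecting parameters from behavior,
#'   [exp_filter()] for the equivalent causal exponential filter.
#' @export
dbm <- function(trial_type, rt = NULL, alpha = 0.8, pm = 0.25, scale = 4,
                grid_size = 100L, params = NULL) {
  if (is.null(params)) {
    params <- dbm_params(alpha, pm, scale, grid_size)
  }
  categories <- check_categories(trial_type)
  pstop <- dbm_run(categories, params)
  object <- list(params = params, categories = categories,
                 pstop = pstop, rt = NULL, seq_effect = NULL,
                 lm_coef = NULL)
  if (!is.null(rt)) {
    if (length(rt) != length(categories)) {
      stop("'rt' must align with 'trial_type'", call. = FALSE)
    }
    object$rt <- as.numeric(rt)
    ok <- !is.na(object$rt)
    if (sum(ok) >= 3L) {
      se <- pearson_test(pstop[ok], object$rt[ok])
      object$seq_effect <- se
      fit <- stats::lm.fit(cbind(1, pstop[ok]), object$rt[ok])
      object$lm_coef <- c(intercept = fit$coefficients[[1]],
                          slope = fit$coefficients[[2]])
    }
  }
  class(object) <- "dbm"
  object
}

# Pearson correlation with the t transform (n - 2 df), two sided.
pearson_test <- function(x, y) {
  n <- length(x)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  r <- stats::cor(x, y)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  list(r = r, p = p, n = n, t = tt)
}

#' @export
print.dbm <- function(x, ...) {
  cat("Dynamic belief model (stop-signal anticipation)\n")
  cat(sprintf("  parameters: alpha = %.3g, pm = %.3g, scale = %.3g, grid = %d\n",
              x$params$alpha, x$params$pm, x$params$scale,
              x$params$grid_size))
  cat(sprintf("  trials: %d (%d stop, %d go)\n", length(x$categories),
              sum(x$categories == 1), sum(x$categories == 0)))
  cat(sprintf("  p(Stop): mean %.3f, range [%.3f, %.3f]\n",
              mean(x$pstop), min(x$pstop), max(x$pstop)))
  if (!is.null(x$seq_effect)) {
    cat(sprintf("  sequential effect: r = %.3f (p = %.3g, n = %d)\n",
                x$seq_effect$r, x$seq_effect$p, x$seq_effect$n))
  }
  invisible(x)
}

#' @export
summary.dbm <- function(object, ...) {
  out <- list(params = object$params,
              n_trials = length(object$categories),
              n_stop = sum(object$categories == 1),
              stop_fraction = mean(object$categories),
              pstop_mean = mean(object$pstop),
              pstop_sd = stats::sd(object$pstop),
              seq_effect = object$seq_effect)
  class(out) <- "summary.dbm"
  out
}

#' @export
print.summary.dbm <- function(x, ...) {
  cat("Dynamic belief model summary\n")
  cat(sprintf("  alpha = %.3g, pm = %.3g, scale = %.3g\n",
              x$params$alpha, x$params$pm, x$params$scale))
  cat(sprintf("  %d trials, observed stop fraction %.3f\n",
              x$n_trials, x$stop_fraction))
  cat(sprintf("  p(Stop): mean %.3f, sd %.3f\n", x$pstop_mean, x$pstop_sd))
  if (!is.null(x$seq_effect)) {
    cat(sprintf("  sequential effect r = %.3f, p = %.3g (n = %d go RTs)\n",
                x$seq_effect$r, x$seq_effect$p, x$seq_effect$n))
  }
  invisible(x)
}

#' @export
coef.dbm <- function(object, ...) {
  c(alpha = object$params$alpha, pm = object$params$pm,
    scale = object$params$scale)
}

#' @export
fitted.dbm <- function(object, ...) {
  object$pstop
}

#' Predict p(Stop) for a new trial sequence
#'
#' @param object A fitted [dbm()] object.
#' @param newdata New trial categories (`"go"`/`"stop"` or 0/1). If omitted,
#'   the training-sequence p(Stop) series is returned.
#' @param ... Unused.
#' @return A numeric vector of causal p(Stop) values.
#' @export
predict.dbm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    return(object$pstop)
  }
  dbm_run(check_categories(newdata), object$params)
}

#' @export
residuals.dbm <- function(object, ...) {
  if (is.null(object$lm_coef)) {
    stop("no reaction times attached; residuals undefined", call. = FALSE)
  }
  ok <- !is.na(object$rt)
  res <- rep(NA_real_, length(object$rt))
  res[ok] <- object$rt[ok] -
    (object$lm_coef[["intercept"]] + object$lm_coef[["slope"]] *
       object$pstop[ok])
  res
}

#' Simulate go/stop sequences from the generative model
#'
#' Draws trial-category sequences from the DBM's own generative process:
#' the stop rate persists with probability `alpha` or is redrawn from the
#' beta prior, and each trial is a stop trial with probability equal to the
#' current rate.
#'
#' @param object A [dbm()] object (its parameters are used).
#' @param nsim Number of sequences.
#' @param seed Optional integer seed.
#' @param n_trials Length of each simulated sequence; defaults to the
#'   length of the fitted sequence.
#' @param ... Unused.
#' @return A list of 0/1 vectors, one per simulation.
#' @export
simulate.dbm <- function(object, nsim = 1, seed = NULL, n_trials = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_trials)) n_trials <- length(object$categories)
  p <- object$params
  a <- p$pm * p$scale
  b <- (1 - p$pm) * p$scale
  lapply(seq_len(nsim), function(i) {
    s <- integer(n_trials)
    r <- stats::rbeta(1, a, b)
    for (k in seq_len(n_trials)) {
      if (k > 1 && stats::runif(1) >= p$alpha) {
        r <- stats::rbeta(1, a, b)
      }
      s[k] <- as.integer(stats::runif(1) < r)
    }
    s
  })
}

#' Plot the trial-by-trial p(Stop) trace
#'
#' @param x A [dbm()] object.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.dbm <- function(x, ...) {
  graphics::plot(seq_along(x$pstop), x$pstop, type = "l",
                 xlab = "trial", ylab = "p(Stop)", ...)
  stop_idx <- which(x$categories == 1)
  graphics::rug(stop_idx, side = 1)
  graphics::abline(h = x$params$pm, lty = 3)
  invisible(x)
}

#' Causal exponential-filter estimate of the stop rate
#'
#' A causal, exponentially weighted running estimate of the stop-trial
#' rate, used as a comparison oracle for the dynamic belief model (whose
#' mixture update is essentially equivalent to such a filter). The estimate
#' before trial `k` weights past observations by `decay^(age)` and includes
#' the initial guess `init` as one pseudo-observation with the oldest
#' weight:
#' `est_k = (init * decay^(k-1) + sum_j decay^(k-1-j) s_j) /`
#' `(decay^(k-1) + sum_j decay^(k-1-j))`.
#' As `decay` approaches 1 the estimate converges to the cumulative stop
#' fraction.
#'
#' @param trial_type Trial categories (`"go"`/`"stop"` or 0/1).
#' @param decay Exponential decay factor in `(0, 1)`.
#' @param init Initial rate estimate (used on trial 1).
#' @return A numeric vector of causal rate estimates, one per trial.
#' @export
exp_filter <- function(trial_type, decay, init = 0.25) {
  categories <- check_categories(trial_type)
  if (!is.numeric(decay) || length(decay) != 1L || decay <= 0 || decay >= 1) {
    stop("'decay' must be in (0, 1)", call. = FALSE)
  }
  n <- length(categories)
  est <- numeric(n)
  num <- init
  den <- 1
  for (k in seq_len(n)) {
    est[k] <- num / den
    num <- decay * num + categories[k]
    den <- decay * den + 1
  }
  est
}

#' Select DBM parameters from behavior by grid search
#'
#' Chooses, from a candidate grid of parameter sets, the one whose p(Stop)
#' series correlates most strongly (Pearson) with go-trial reaction time.
#' Ties break deterministically to the first candidate in grid order. The
#' returned fit is flagged when the best correlation is not significantly
#' positive, indicating that the RTs carry no detectable anticipation
#' signal at the given sample size.
#'
#' @param trial_type Trial categories (`"go"`/`"stop"` or 0/1).
#' @param rt Reaction times aligned with `trial_type` (`NA` where no valid
#'   go response); at least 20 non-missing values required.
#' @param grid A list of [dbm_params()] objects (or lists coercible to
#'   them).
#' @return The winning [dbm()] fit, with an added `fit` element: list with
#'   `index` (position in the grid), `r`, `p`, and `signal_detected`
#'   (logical: one-sided p < 0.05 for r > 0).
#' @export
dbm_grid_fit <- function(trial_type, rt, grid) {
  categories <- check_categories(trial_type)
  rt <- as.numeric(rt)
  ok <- !is.na(rt)
  if (sum(ok) < 20L) {
    stop("need at least 20 go trials with RT to select parameters",
         call. = FALSE)
  }
  if (stats::sd(rt[ok]) == 0) {
    stop("RT vector has zero variance; correlation undefined",
         call. = FALSE)
  }
  if (!length(grid)) stop("empty parameter grid", call. = FALSE)
  grid <- lapply(grid, function(g) {
    if (inherits(g, "dbm_params")) g else do.call(dbm_params, as.list(g))
  })
  best_r <- -Inf
  best_i <- 1L
  for (i in seq_along(grid)) {
    ps <- dbm_run(categories, grid[[i]])
    r <- if (stats::sd(ps[ok]) == 0) -Inf else stats::cor(ps[ok], rt[ok])
    if (r > best_r + 1e-12) {
      best_r <- r
      best_i <- i
    }
  }
  out <- dbm(categories, rt = rt, params = grid[[best_i]])
  se <- out$seq_effect
  one_sided_p <- stats::pt(se$t, df = se$n - 2, lower.tail = FALSE)
  out$fit <- list(index = best_i, r = se$r, p = se$p,
                  signal_detected = !is.na(one_sided_p) && one_sided_p < 0.05)
  out
}
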