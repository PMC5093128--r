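test_that("discretized beta prior has the requested mean and symmetry", {
  st <- dbm_prior(dbm_params(pm = 0.25, scale = 4))
  expect_equal(sum(st$predictive_mass), 1, tolerance = 1e-12)
  expect_equal(sum(st$r_grid * st$predictive_mass), 0.25, tolerance = 0.005)

  # pm = 0.5, scale = 2 is Beta(1, 1): symmetric about 0.5
  sym <- dbm_prior(dbm_params(pm = 0.5, scale = 2))
  expect_equal(sym$predictive_mass, rev(sym$predictive_mass),
               tolerance = 1e-10)

  # grid refinement leaves the prior mean essentially unchanged
  m100 <- dbm_pstop(dbm_prior(dbm_params(pm = 0.25, scale = 4,
                                         grid_size = 100)))
  m1000 <- dbm_pstop(dbm_prior(dbm_params(pm = 0.25, scale = 4,
                                          grid_size = 1000)))
  expect_lt(abs(m100 - m1000), 0.002)
})

test_that("parameter validation names the offending field", {
  expect_error(dbm_params(alpha = 1.2), "alpha")
  expect_error(dbm_params(pm = 0), "pm")
  expect_error(dbm_params(pm = 1), "pm")
  expect_error(dbm_params(scale = -1), "scale")
  expect_error(dbm_params(grid_size = 5), "grid_size")
})

test_that("Bayes update matches conjugate beta arithmetic", {
  # uniform predictive (Beta(1,1)), one stop -> Beta(2,1), mean 2/3
  st <- dbm_prior(dbm_params(pm = 0.5, scale = 2))
  up <- dbm_update(st, 1)
  expect_equal(sum(up$posterior_mass), 1, tolerance = 1e-12)
  expect_equal(sum(up$r_grid * up$posterior_mass), 2 / 3, tolerance = 0.01)

  # Beta(1,3) predictive, one stop -> Beta(2,3), mean 2/5
  st2 <- dbm_prior(dbm_params(pm = 0.25, scale = 4))
  up2 <- dbm_update(st2, 1)
  expect_equal(sum(up2$r_grid * up2$posterior_mass), 0.4, tolerance = 0.01)

  # a go observation always pulls the mean down
  for (pm in c(0.2, 0.5, 0.8)) {
    s <- dbm_prior(dbm_params(pm = pm, scale = 3))
    g <- dbm_update(s, 0)
    expect_lt(sum(g$r_grid * g$posterior_mass),
              sum(s$r_grid * s$predictive_mass))
  }

  expect_error(dbm_update(st, 2), "outcome")
  expect_error(dbm_update(st, NA), "outcome")
})

test_that("mixture transition degenerates correctly at alpha = 0, 1", {
  params0 <- dbm_params(alpha = 0, pm = 0.3, scale = 5)
  st <- dbm_update(dbm_prior(params0), 1)
  adv <- dbm_advance(st, params0)
  expect_equal(adv$predictive_mass, st$prior_mass, tolerance = 1e-12)

  params1 <- dbm_params(alpha = 1, pm = 0.3, scale = 5)
  adv1 <- dbm_advance(st, params1)
  expect_equal(adv1$predictive_mass, st$posterior_mass, tolerance = 1e-12)

  # posterior equal to the prior is a fixed point of the mixture
  params_half <- dbm_params(alpha = 0.5, pm = 0.3, scale = 5)
  fp <- dbm_prior(params_half)
  adv_fp <- dbm_advance(fp, params_half)
  expect_equal(adv_fp$predictive_mass, fp$prior_mass, tolerance = 1e-12)
  expect_equal(adv_fp$trial_index, 2L)
})

test_that("p(Stop) is the predictive mean", {
  expect_equal(dbm_pstop(dbm_prior(dbm_params(pm = 0.25, scale = 4))),
               0.25, tolerance = 0.005)
  st <- dbm_prior(dbm_params(pm = 0.5, scale = 2))  # uniform
  expect_equal(dbm_pstop(st), 0.5, tolerance = 0.005)
  # discretized Beta(2, 6): pm = 0.25, scale = 8
  st2 <- dbm_prior(dbm_params(pm = 0.25, scale = 8))
  expect_equal(dbm_pstop(st2), discrete_beta_mean(2, 6), tolerance = 1e-10)
  expect_equal(dbm_pstop(st2), 0.25, tolerance = 0.005)
})

test_that("alpha = 0 gives a constant p(Stop) at pm for any sequence", {
  set.seed(11)
  for (i in 1:3) {
    cats <- random_categories(200)
    fit <- dbm(cats, alpha = 0, pm = 0.25, scale = 4)
    expect_true(all(abs(fit$pstop - 0.25) < 0.005))
  }
})

test_that("alpha = 1 reproduces the conjugate beta-Bernoulli closed form", {
  # spec'd small example: sequence (1, 0, 0) -> 0.25, 0.40, 1/3
  fit <- dbm(c(1, 0, 0), alpha = 1, pm = 0.25, scale = 4)
  expect_equal(fit$pstop, c(0.25, 0.40, 1 / 3), tolerance = 0.005)

  set.seed(42)
  for (i in 1:5) {
    cats <- random_categories(500)
    fit <- dbm(cats, alpha = 1, pm = 0.25, scale = 4)
    oracle <- conjugate_pstop(cats, pm = 0.25, scale = 4)
    expect_lt(max(abs(fit$pstop - oracle)), 0.005)
  }
})

test_that("p(Stop) is strictly causal: the future cannot leak backwards", {
  set.seed(7)
  cats <- random_categories(120)
  fit <- dbm(cats)
  k <- 60
  perm <- cats
  perm[k:120] <- sample(perm[k:120])
  fit_perm <- dbm(perm)
  expect_identical(fit$pstop[1:k], fit_perm$pstop[1:k])
})

test_that("a stop raises the next-trial p(Stop) relative to a go", {
  set.seed(3)
  cats <- random_categories(50)
  for (alpha in c(0.2, 0.8, 1)) {
    p_after_stop <- dbm(c(cats, 1, 0), alpha = alpha)$pstop[52]
    p_after_go <- dbm(c(cats, 0, 0), alpha = alpha)$pstop[52]
    expect_gt(p_after_stop, p_after_go)
  }
})

test_that("belief masses stay normalized along a whole sequence", {
  params <- dbm_params(alpha = 0.8, pm = 0.25, scale = 4)
  set.seed(5)
  cats <- random_categories(300)
  state <- dbm_prior(params)
  for (k in seq_along(cats)) {
    expect_lt(abs(sum(state$predictive_mass) - 1), 1e-10)
    state <- dbm_update(state, cats[k])
    expect_lt(abs(sum(state$posterior_mass) - 1), 1e-10)
    state <- dbm_advance(state, params)
  }
})

test_that("doubling the grid leaves p(Stop) essentially unchanged", {
  set.seed(9)
  cats <- random_categories(200)
  p100 <- dbm(cats, grid_size = 100)$pstop
  p200 <- dbm(cats, grid_size = 200)$pstop
  expect_lt(max(abs(p100 - p200)), 0.002)
})

test_that("exponential filter behaves as a running stop-rate estimate", {
  set.seed(13)
  cats <- random_categories(400)
  # decay -> 1: converges to the cumulative stop fraction
  est <- exp_filter(cats, decay = 0.9999, init = 0.25)
  cumfrac <- cumsum(cats) / seq_along(cats)
  expect_lt(abs(est[400] - cumfrac[399]), 0.01)

  # all-go sequence: monotone decay toward 0 from init
  dec <- exp_filter(rep(0, 50), decay = 0.8, init = 0.4)
  expect_equal(dec[1], 0.4)
  expect_true(all(diff(dec) < 0))
  expect_lt(dec[50], 0.01)
})

test_that("DBM is essentially an exponential filter (best-decay r > 0.95)", {
  set.seed(21)
  cats <- random_categories(400)
  for (alpha in c(0.6, 0.8, 0.95)) {
    ps <- dbm(cats, alpha = alpha, pm = 0.25, scale = 4)$pstop
    best <- optimize(function(d) {
      -cor(ps, exp_filter(cats, decay = d, init = 0.25))
    }, interval = c(0.01, 0.999))
    expect_gt(-best$objective, 0.95)
  }
})

test_that("grid search recovers generating parameters from noiseless RT", {
  set.seed(31)
  cats <- random_categories(300)
  grid <- list(
    dbm_params(alpha = 0.5, pm = 0.25, scale = 4),
    dbm_params(alpha = 0.8, pm = 0.25, scale = 4),
    dbm_params(alpha = 0.95, pm = 0.25, scale = 4)
  )
  true_ps <- dbm(cats, params = grid[[2]])$pstop
  rt <- 500 + 300 * true_ps  # exact linear function of p(Stop)
  rt[cats == 1] <- NA
  fit <- dbm_grid_fit(cats, rt, grid)
  expect_identical(fit$fit$index, 2L)
  expect_true(fit$fit$signal_detected)

  # a one-element grid is returned as-is
  fit1 <- dbm_grid_fit(cats, rt, grid[1])
  expect_identical(fit1$fit$index, 1L)
})

test_that("grid search flags pure-noise RT as no detectable signal", {
  set.seed(37)
  grid <- list(dbm_params(alpha = 0.8, pm = 0.25, scale = 4))
  flags <- vapply(1:20, function(i) {
    cats <- random_categories(200)
    rt <- rnorm(length(cats), 500, 50)
    rt[cats == 1] <- NA
    dbm_grid_fit(cats, rt, grid)$fit$signal_detected
  }, logical(1))
  # one-sided 5% test under the null: detections should be rare
  expect_lt(mean(flags), 0.3)
  expect_error(dbm_grid_fit(rep(c(0, 1), 50), rep(500, 100), grid),
               "variance")
})

test_that("dbm methods expose the fit coherently", {
  set.seed(41)
  cats <- random_categories(120)
  rt <- 500 + 200 * dbm(cats)$pstop + rnorm(120, 0, 20)
  rt[cats == 1] <- NA
  fit <- dbm(cats, rt = rt)
  expect_equal(fitted(fit), fit$pstop)
  expect_equal(coef(fit), c(alpha = 0.8, pm = 0.25, scale = 4))
  expect_identical(predict(fit, newdata = cats), fit$pstop)
  res <- residuals(fit)
  expect_true(all(is.na(res[cats == 1])))
  ok <- !is.na(rt)
  expect_lt(abs(mean(res[ok])), 1e-8)  # least-squares residuals center at 0
  expect_output(print(fit), "sequential effect")
  expect_output(print(summary(fit)), "stop fraction")
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_true(all(unlist(sims) %in% c(0L, 1L)))
  sims2 <- simulate(fit, nsim = 2, seed = 1)
  expect_identical(sims, sims2)
})
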