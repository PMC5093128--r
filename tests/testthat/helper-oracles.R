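# Independent oracles used across test files.

# Conjugate beta-Bernoulli posterior-predictive mean: with full persistence
# (alpha = 1) the DBM reduces to standard beta-Bernoulli updating, so
# p(Stop)_k = (pm*scale + #stops before k) / (scale + k - 1).
conjugate_pstop <- function(categories, pm, scale) {
  k <- seq_along(categories)
  stops_before <- c(0, cumsum(categories))[k]
  (pm * scale + stops_before) / (scale + k - 1)
}

# Discretized mean of a Beta(a, b) on the same midpoint grid the package
# uses, computed directly from the density.
discrete_beta_mean <- function(a, b, grid_size = 100) {
  r <- (seq_len(grid_size) - 0.5) / grid_size
  w <- dbeta(r, a, b)
  sum(r * w) / sum(w)
}

# Random go/stop sequence with a given stop fraction.
random_categories <- function(n, stop_fraction = 0.25) {
  as.integer(runif(n) < stop_fraction)
}
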