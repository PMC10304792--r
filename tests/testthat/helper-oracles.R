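# Monte-Carlo oracle for E[max of n standard normal draws].  Uses the
# exact order-statistic sampler: the maximum of n iid standard normals
# equals qnorm(U^(1/n)) in distribution (U^(1/n) ~ Beta(n, 1) is the
# maximum of n uniforms), so each replicate is one draw of the maximum.
mc_expected_max <- function(n, reps = 1e5) {
  mean(qnorm(runif(reps)^(1 / n)))
}

# Brute-force grid search oracle for the inoculum-effect objective
# sum((y - mu - sigma * z)^2), sigma >= 0.  Returns the best objective
# value over a k x k grid covering the stated box.
grid_search_best <- function(z, y, mu_range, sigma_range, k = 200L) {
  mus <- seq(mu_range[1], mu_range[2], length.out = k)
  sigmas <- seq(max(sigma_range[1], 0), sigma_range[2], length.out = k)
  n <- length(y)
  syy <- sum(y^2); sy <- sum(y); sz <- sum(z)
  szz <- sum(z^2); szy <- sum(z * y)
  # RSS expanded so the k x k surface is a single vectorised expression
  obj <- outer(mus, sigmas, function(m, s)
    syy - 2 * m * sy - 2 * s * szy + n * m^2 + 2 * m * s * sz + s^2 * szz)
  min(obj)
}

# Exact-model inoculum observations (no noise) for a given distribution.
exact_inoculum_obs <- function(dist, n = c(1e2, 1e3, 1e4, 1e5)) {
  data.frame(inoculum_cells = n,
             mic_exp_mM = predicted_mic_exp(dist, n))
}

# Random small noisy dataset on the log10 scale.
random_inoculum_obs <- function(mu, sigma, noise_sd = 0.02,
                                n = c(1e2, 1e3, 1e4, 1e5), reps = 2L) {
  nn <- rep(n, reps)
  z <- expected_max_quantile(nn)
  data.frame(inoculum_cells = nn,
             mic_exp_mM = 10^(mu + sigma * z + rnorm(length(nn), 0, noise_sd)))
}
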