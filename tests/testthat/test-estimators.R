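test_that("a flat inoculum response fits a homogeneous population", {
  obs <- data.frame(inoculum_cells = c(1e2, 1e3, 1e4, 1e5),
                    mic_exp_mM = rep(6.5, 4))
  f <- fit_inoculum_effect(obs)
  expect_equal(f$heteroresistance, 0)
  expect_equal(f$ic50_mM, 6.5)
  expect_equal(f$mic_model_mM, 6.5)
  expect_false(f$sigma_clamped)   # slope is exactly 0, not negative
})

test_that("noisy decreasing data clamps the spread to zero with a flag", {
  obs <- data.frame(inoculum_cells = c(1e2, 1e5), mic_exp_mM = c(8, 6))
  f <- fit_inoculum_effect(obs)
  expect_equal(f$heteroresistance, 0)
  expect_true(f$sigma_clamped)
  expect_equal(f$ic50_mM, sqrt(8 * 6), tolerance = 1e-12)  # 10^mean(log10)
})

test_that("two exact points are fit exactly by the closed-form solution", {
  z2 <- expected_max_quantile(1e2)
  z5 <- expected_max_quantile(1e5)
  sigma <- (log10(8) - log10(6)) / (z5 - z2)
  mu <- log10(6) - sigma * z2
  obs <- data.frame(inoculum_cells = c(1e2, 1e5), mic_exp_mM = c(6, 8))
  f <- fit_inoculum_effect(obs)
  expect_equal(f$heteroresistance, sigma, tolerance = 1e-12)
  expect_equal(f$ic50_mM, 10^mu, tolerance = 1e-12)
  expect_equal(f$rss, 0, tolerance = 1e-20)
  # fitted curve passes through both points
  d <- resistance_distribution(f$mu, f$sigma)
  expect_equal(predicted_mic_exp(d, c(1e2, 1e5)), c(6, 8),
               tolerance = 1e-10)
})

test_that("the fit rejects under-determined and invalid inputs", {
  expect_error(fit_inoculum_effect(
    data.frame(inoculum_cells = c(1e4, 1e4), mic_exp_mM = c(6, 7))),
    "under-determined")
  expect_error(fit_inoculum_effect(
    data.frame(inoculum_cells = c(1e2, 1e5), mic_exp_mM = c(6, 8),
               strain_id = c("a", "b"))),
    "single strain")
  expect_error(fit_inoculum_effect(
    data.frame(mic_exp_mM = c(6, 8))), "inoculum_cells")
  expect_warning(
    f <- fit_inoculum_effect(
      data.frame(inoculum_cells = c(1e2, 1e3, 1e5),
                 mic_exp_mM = c(6, 6.5, NA),
                 censored = c(FALSE, FALSE, TRUE))),
    "censored")
  expect_equal(f$n_points, 2L)
})

test_that("rescaling concentrations rescales IC50 and model MIC but not heteroresistance", {
  set.seed(5)
  obs <- random_inoculum_obs(log10(4), 0.07)
  f1 <- fit_inoculum_effect(obs)
  for (k in c(0.5, 3, 10)) {
    obs_k <- transform(obs, mic_exp_mM = mic_exp_mM * k)
    fk <- fit_inoculum_effect(obs_k)
    expect_equal(fk$ic50_mM, k * f1$ic50_mM, tolerance = 1e-10)
    expect_equal(fk$mic_model_mM, k * f1$mic_model_mM, tolerance = 1e-10)
    expect_equal(fk$heteroresistance, f1$heteroresistance,
                 tolerance = 1e-10)
  }
})

test_that("raising the MIC at the largest inoculum never decreases the fitted spread", {
  set.seed(6)
  for (rep in 1:20) {
    obs <- random_inoculum_obs(log10(4), runif(1, 0.02, 0.1))
    f0 <- fit_inoculum_effect(obs)
    top <- obs$inoculum_cells == max(obs$inoculum_cells)
    obs_up <- obs
    obs_up$mic_exp_mM[top] <- obs_up$mic_exp_mM[top] * runif(1, 1.01, 1.5)
    f1 <- fit_inoculum_effect(obs_up)
    expect_gte(f1$heteroresistance, f0$heteroresistance - 1e-12)
  }
})

test_that("the exact solution is never beaten by a brute-force grid search", {
  set.seed(7)
  for (rep in 1:10) {
    obs <- random_inoculum_obs(runif(1, 0.3, 0.8), runif(1, 0, 0.12),
                               noise_sd = 0.05)
    f <- fit_inoculum_effect(obs)
    z <- expected_max_quantile(obs$inoculum_cells)
    y <- log10(obs$mic_exp_mM)
    best <- grid_search_best(z, y, f$mu + c(-0.5, 0.5),
                             c(0, f$sigma * 2 + 0.2))
    expect_lte(f$rss, best + 1e-8)
  }
})

test_that("the linear-normal mode fits on the raw mM scale", {
  # exact plain-normal data: mic = m + s * z(n)
  nn <- c(1e2, 1e3, 1e4, 1e5)
  obs <- data.frame(inoculum_cells = nn,
                    mic_exp_mM = 5 + 0.4 * expected_max_quantile(nn))
  f <- fit_inoculum_effect(obs, scale = "linear")
  expect_equal(f$ic50_mM, 5, tolerance = 1e-10)
  expect_equal(f$heteroresistance, 0.4, tolerance = 1e-10)
  expect_equal(f$mic_model_mM, 5 + 0.4 * qnorm(0.9999), tolerance = 1e-10)
})

test_that("dose-response fitting is a projection on noise-free model data", {
  d <- resistance_distribution(0.6, 0.08)
  cc <- seq(2.5, 8, by = 0.5)
  obs <- data.frame(concentration_mM = cc,
                    percent_survival = 100 * survival_fraction(d, cc))
  f <- fit_dose_response(obs)
  expect_equal(f$mu, 0.6, tolerance = 1e-6)
  expect_equal(f$sigma, 0.08, tolerance = 1e-6)

  # refitting the fit's own predictions returns the same parameters
  obs2 <- data.frame(concentration_mM = cc,
                     percent_survival = 100 * survival_fraction(
                       resistance_distribution(f$mu, f$sigma), cc))
  f2 <- fit_dose_response(obs2)
  expect_equal(f2$mu, f$mu, tolerance = 1e-6)
  expect_equal(f2$sigma, f$sigma, tolerance = 1e-6)

  # the fitted curve crosses 50% at the reported IC50
  expect_equal(100 * survival_fraction(
    resistance_distribution(f$mu, f$sigma), f$ic50_mM), 50,
    tolerance = 1e-9)
})

test_that("dose-response fitting rejects uninformative data and controls", {
  cc <- seq(1, 4, by = 0.5)
  expect_error(fit_dose_response(
    data.frame(concentration_mM = cc, percent_survival = rep(95, 7))),
    "50%")
  expect_error(fit_dose_response(
    data.frame(concentration_mM = cc, percent_survival = rep(2, 7))),
    "50%")
  expect_error(fit_dose_response(
    data.frame(concentration_mM = c(0, 0, 3), percent_survival = c(100, 100, 40))),
    "under-determined")
  # zero-concentration controls are excluded from the residuals: adding a
  # wildly off control row must not change the fit
  d <- resistance_distribution(0.6, 0.08)
  cc <- seq(2.5, 8, by = 0.5)
  obs <- data.frame(concentration_mM = cc,
                    percent_survival = 100 * survival_fraction(d, cc))
  with_ctrl <- rbind(data.frame(concentration_mM = 0, percent_survival = 55),
                     obs)
  f1 <- fit_dose_response(obs)
  f2 <- fit_dose_response(with_ctrl)
  expect_equal(f2$mu, f1$mu, tolerance = 1e-9)
  expect_equal(f2$sigma, f1$sigma, tolerance = 1e-9)
})

test_that("dose-response recovery under binomial plate-count noise", {
  set.seed(8)
  d <- resistance_distribution(0.6, 0.08)
  sig_hat <- replicate(60, {
    obs <- simulate_dose_response(d, inoculum_sizes = c(1e4, 1e2),
                                  concentrations = seq(0, 10, by = 0.5))
    fit_dose_response(obs)$sigma
  })
  expect_lt(abs(mean(sig_hat) / 0.08 - 1), 0.15)
})

test_that("aggregate_fits computes means and standard errors over replicates", {
  mk <- function(mm) {
    obs <- data.frame(inoculum_cells = c(1e2, 1e5),
                      mic_exp_mM = c(6, 6) * mm / 6)
    fit_inoculum_effect(obs)
  }
  fits <- lapply(c(6.0, 6.2, 6.4), mk)   # flat fits: mic_model = level
  agg <- aggregate_fits(fits)
  mm_row <- agg[agg$parameter == "mic_model_mM", ]
  expect_equal(mm_row$mean, 6.2, tolerance = 1e-12)
  expect_equal(mm_row$sem, 0.2 / sqrt(3), tolerance = 1e-9)

  # single fit: SEM reported as 0, flagged
  one <- aggregate_fits(fits[1])
  expect_true(all(one$sem == 0))
  expect_true(attr(one, "single_fit"))

  # identical fits: SEM exactly 0
  same <- aggregate_fits(fits[c(2, 2, 2)])
  expect_true(all(same$sem == 0))

  expect_error(aggregate_fits(list()), "non-empty")
})

test_that("fit_inoculum_replicates fits each biological replicate separately", {
  set.seed(9)
  d <- resistance_distribution(log10(4), 0.07)
  obs <- simulate_mic_exp(d, assay_design(biological_replicates = 3),
                          seed = 1)
  res <- fit_inoculum_replicates(obs)
  expect_length(res$fits, 3L)
  expect_s3_class(res$summary, "data.frame")
  expect_equal(unique(res$summary$k), 3)
})
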