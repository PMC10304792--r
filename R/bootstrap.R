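#' Case-resampling bootstrap for MIC fits
#'
#' Resamples observation rows with replacement, refits the chosen
#' estimator on each resample, and returns 95% percentile intervals for
#' IC50, heteroresistance and model MIC together with a pointwise 95%
#' envelope of predicted curves.  Case resampling (rather than residual
#' resampling) is used because MIC and plate-count data are
#' heteroscedastic.
#'
#' Resamples on which the estimator fails (e.g. a resample that loses all
#' but one inoculum size) are dropped and counted; if more than 20% fail
#' the bootstrap is considered unstable and an error is raised.
#'
#' @param observations Data frame accepted by the chosen fitter.
#' @param fitter `"inoculum"` ([fit_inoculum_effect()]) or
#'   `"dose_response"` ([fit_dose_response()]).
#' @param B Number of bootstrap resamples (>= 100).
#' @param seed Integer seed; the run is fully reproducible given `seed`.
#' @param level Confidence level (default 0.95).
#' @param curve_points Number of abscissa points for the envelope.
#' @param ... Passed on to the fitter (e.g. `scale`, `percentile`).
#' @return An object of class `mic_boot`: list with `fit` (the full-data
#'   fit), `ci` (data frame of percentile intervals), `envelope` (data
#'   frame `x`, `lower`, `upper`; `x` is inoculum size or concentration),
#'   `replicates` (matrix of per-resample parameter estimates), `B`,
#'   `n_failed`, `seed`, `level`.
#' @examples
#' obs <- data.frame(inoculum_cells = rep(c(1e2, 1e3, 1e4, 1e5), 3),
#'                   mic_exp_mM = c(6, 6.5, 7, 7.5, 6.1, 6.4, 7.2, 7.4,
#'                                  5.9, 6.6, 6.9, 7.6))
#' bootstrap_fit(obs, "inoculum", B = 200, seed = 1)$ci
#' @export
bootstrap_fit <- function(observations,
                          fitter = c("inoculum", "dose_response"),
                          B = 1000L, seed, level = 0.95,
                          curve_points = 50L, ...) {
  fitter <- match.arg(fitter)
  if (!is.numeric(B) || B < 100L)
    stop("'B' must be >= 100", call. = FALSE)
  if (missing(seed) || !is.numeric(seed))
    stop("an integer 'seed' is required for reproducibility", call. = FALSE)
  obs <- as.data.frame(observations)
  fit_fun <- switch(fitter,
                    inoculum = fit_inoculum_effect,
                    dose_response = fit_dose_response)
  full_fit <- fit_fun(obs, ...)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))

  n <- nrow(obs)
  params <- c("ic50_mM", "heteroresistance", "mic_model_mM")
  est <- matrix(NA_real_, nrow = B, ncol = 3L,
                dimnames = list(NULL, params))
  mus <- sig <- rep(NA_real_, B)
  idx_mat <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
  for (b in seq_len(B)) {
    res <- tryCatch(
      suppressWarnings(fit_fun(obs[idx_mat[b, ], , drop = FALSE], ...)),
      error = function(e) NULL)
    if (!is.null(res)) {
      est[b, ] <- unlist(res[params])
      mus[b] <- res$mu
      sig[b] <- res$sigma
    }
  }
  ok <- !is.na(est[, 1L])
  n_failed <- sum(!ok)
  if (n_failed > 0.2 * B)
    stop("bootstrap unstable: ", n_failed, " of ", B,
         " resamples failed to fit", call. = FALSE)

  alpha <- (1 - level) / 2
  ci <- t(apply(est[ok, , drop = FALSE], 2L, stats::quantile,
                probs = c(alpha, 1 - alpha), names = FALSE))
  ci <- data.frame(parameter = params, lower = ci[, 1L], upper = ci[, 2L],
                   stringsAsFactors = FALSE)

  envelope <- bootstrap_envelope(fitter, obs, mus[ok], sig[ok],
                                 full_fit, curve_points, alpha)

  structure(list(fit = full_fit, ci = ci, envelope = envelope,
                 replicates = est[ok, , drop = FALSE],
                 B = B, n_failed = n_failed, seed = as.integer(seed),
                 level = level),
            class = "mic_boot")
}

# Pointwise percentile envelope of the fitted curves.
bootstrap_envelope <- function(fitter, obs, mus, sig, full_fit,
                               curve_points, alpha) {
  if (fitter == "inoculum") {
    rng <- range(obs$inoculum_cells)
    x <- 10^seq(log10(rng[1L]), log10(rng[2L]), length.out = curve_points)
    z <- expected_max_quantile(x)
    pred <- outer(mus, rep(1, length(x))) + outer(sig, z)   # log/linear scale
    if (full_fit$scale == "log10") pred <- 10^pred
  } else {
    cc <- obs$concentration_mM[obs$concentration_mM > 0]
    x <- seq(min(cc), max(cc), length.out = curve_points)
    pred <- 100 * stats::pnorm(outer(-mus, log10(x), "+") /
                                 pmax(sig, 1e-12), lower.tail = FALSE)
  }
  qs <- apply(pred, 2L, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  data.frame(x = x, lower = qs[1L, ], upper = qs[2L, ])
}

#' @export
print.mic_boot <- function(x, ...) {
  cat(sprintf("Bootstrap (%d resamples, %d failed, seed %d)\n",
              x$B, x$n_failed, x$seed))
  print(x$fit)
  cat(sprintf("%.0f%% percentile intervals:\n", 100 * x$level))
  print(x$ci, row.names = FALSE)
  invisible(x)
}
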