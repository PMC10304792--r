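#' Fit a lognormal dose-response curve to percent-survival data
#'
#' Fits percent survival against stressor concentration to one minus a
#' cumulative normal distribution on log10 concentration:
#' `survival(c) = 100 * (1 - pnorm((log10(c) - mu)/sigma))`,
#' by least squares over `(mu, sigma >= 0)`.  `10^mu` is the IC50 (the
#' concentration at which the fitted curve crosses 50% survival) and
#' `sigma` the heteroresistance.
#'
#' Zero-concentration rows are normalisation controls (they define the
#' 100% reference in the assay) and are excluded from the residuals.  The
#' optimiser is `stats::nlminb` with a box constraint `sigma >= 0`,
#' started at `mu0 = log10` of the concentration whose observed survival
#' is nearest 50% and `sigma0 = 0.05`, with up to 5 jittered restarts on
#' non-convergence; the best converged solution is returned.
#'
#' @param observations Data frame with columns `concentration_mM` and
#'   `percent_survival` (schema of [read_dose_response_csv()] and
#'   [simulate_dose_response()]); optional `strain_id`, `replicate_id`.
#'   Needs at least 3 non-control points, spanning at least one point
#'   above and one below 50% survival (otherwise the location of the
#'   curve is not identified and an under-determined-fit error is
#'   raised).
#' @param percentile Percentile defining the model MIC (default 0.9999).
#' @return A `mic_fit` object (see [fit_inoculum_effect()]); `rss` is on
#'   the percent-survival scale.
#' @examples
#' d <- resistance_distribution(0.6, 0.08)
#' cc <- seq(2, 8, by = 0.5)
#' obs <- data.frame(concentration_mM = cc,
#'                   percent_survival = 100 * survival_fraction(d, cc))
#' fit_dose_response(obs)
#' @export
fit_dose_response <- function(observations, percentile = 0.9999) {
  obs <- validate_dose_obs(observations)
  ctrl <- obs$concentration_mM == 0
  obs <- obs[!ctrl, , drop = FALSE]
  if (nrow(obs) < 3L)
    stop("under-determined fit: need >= 3 non-control points", call. = FALSE)
  if (all(obs$percent_survival > 50) || all(obs$percent_survival < 50))
    stop("under-determined fit: data must span both sides of 50% survival",
         call. = FALSE)

  lc <- log10(obs$concentration_mM)
  ps <- obs$percent_survival
  objective <- function(par) {
    pred <- 100 * stats::pnorm((lc - par[1L]) / max(par[2L], 1e-12),
                               lower.tail = FALSE)
    sum((ps - pred)^2)
  }

  mu0 <- lc[which.min(abs(ps - 50))]
  starts <- list(c(mu0, 0.05))
  best <- NULL
  for (k in seq_len(6L)) {
    st <- if (k == 1L) starts[[1L]] else
      starts[[1L]] + c(stats::runif(1, -0.1, 0.1), stats::runif(1, 0, 0.1))
    st[2L] <- max(st[2L], 1e-4)
    res <- tryCatch(
      stats::nlminb(st, objective, lower = c(-Inf, 0),
                    control = list(rel.tol = 1e-14, x.tol = 1e-14,
                                   eval.max = 2000L, iter.max = 1000L)),
      error = function(e) NULL)
    ok <- !is.null(res) && res$convergence %in% c(0L, 1L)
    if (!is.null(res) && (is.null(best) || res$objective < best$objective)) {
      res$converged_flag <- ok
      best <- res
    }
    if (ok && k >= 2L) break   # one confirmation restart is enough
  }
  if (is.null(best) || !isTRUE(best$converged_flag))
    stop("dose-response fit failed to converge after restarts",
         " (best objective: ",
         if (is.null(best)) "none" else format(best$objective), ")",
         call. = FALSE)

  mu <- best$par[1L]
  sigma <- max(best$par[2L], 0)
  dist <- resistance_distribution(mu, sigma)
  new_mic_fit(
    ic50_mM = dist$ic50_mM, heteroresistance = sigma,
    mic_model_mM = mic_model(dist, percentile),
    mu = mu, sigma = sigma,
    n_points = length(ps), rss = best$objective,
    converged = TRUE, sigma_clamped = sigma == 0,
    scale = "log10", method = "dose_response", percentile = percentile,
    strain_id = first_or_na(obs$strain_id),
    replicate_id = first_or_na(obs$replicate_id)
  )
}

validate_dose_obs <- function(observations) {
  obs <- as.data.frame(observations)
  required <- c("concentration_mM", "percent_survival")
  missing <- setdiff(required, names(obs))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!is.null(obs$strain_id) && length(unique(obs$strain_id)) > 1L)
    stop("observations must come from a single strain", call. = FALSE)
  if (any(!is.finite(obs$concentration_mM)) || any(obs$concentration_mM < 0))
    stop("'concentration_mM' must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(obs$percent_survival)) || any(obs$percent_survival < 0))
    stop("'percent_survival' must be finite and >= 0", call. = FALSE)
  obs
}
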