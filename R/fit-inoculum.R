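#' Fit the inoculum-effect model to MIC observations
#'
#' Estimates IC50 and heteroresistance from experimental MIC readings
#' taken at two or more inoculum sizes.  The expected MIC of an inoculum
#' of `n` cells is the expected maximum of `n` single-cell resistances,
#' which for a lognormal population is
#' `log10(MIC) = mu + sigma * z(n)` with
#' `z(n) = qnorm((n - pi/8)/(n - pi/4 + 1))` (see
#' [expected_max_quantile()]).  Because the model is linear in
#' `(mu, sigma)` once `z(n)` is computed, the non-linear least-squares
#' problem has an exact solution: ordinary least squares of the
#' (log-scale) MIC on `z(n)`, with the slope constrained to be
#' non-negative.  A negative unconstrained slope (possible on noisy, flat
#' data) is clamped to zero and flagged.
#'
#' @param observations Data frame of inoculum-effect MIC observations with
#'   columns `inoculum_cells` and `mic_exp_mM` (the schema produced by
#'   [read_inoculum_csv()] and [simulate_mic_exp()]); optional columns
#'   `strain_id`, `replicate_id` and `censored`.  All rows must belong to
#'   one strain; rows from several biological replicates are pooled into a
#'   single fit (fit per replicate and combine with [aggregate_fits()] to
#'   follow the one-curve-per-replicate convention).  Censored rows
#'   (MIC not reached on the concentration grid) are dropped with a
#'   warning.
#' @param scale `"log10"` (default): residuals on `log10(MIC)`, i.e. a
#'   lognormal single-cell distribution.  `"linear"`: residuals on raw
#'   mM, i.e. a plain-normal single-cell distribution (provided for
#'   comparison; the lognormal form is the recommended model).
#' @param percentile Percentile defining the model MIC (default 0.9999).
#' @return An object of class `mic_fit`: a list with `ic50_mM`,
#'   `heteroresistance`, `mic_model_mM`, the underlying `mu` and `sigma`
#'   on the fitting scale, `n_points`, `rss` (residual sum of squares on
#'   the fitting scale), `converged`, `sigma_clamped`, `scale`, `method`,
#'   and the strain/replicate labels.
#' @examples
#' obs <- data.frame(inoculum_cells = c(1e2, 1e3, 1e4, 1e5),
#'                   mic_exp_mM     = c(6.0, 6.5, 7.1, 7.5))
#' fit_inoculum_effect(obs)
#' @export
fit_inoculum_effect <- function(observations,
                                scale = c("log10", "linear"),
                                percentile = 0.9999) {
  scale <- match.arg(scale)
  obs <- validate_inoculum_obs(observations)
  if (length(unique(obs$inoculum_cells)) < 2L)
    stop("under-determined fit: need >= 2 distinct inoculum sizes",
         call. = FALSE)

  z <- expected_max_quantile(obs$inoculum_cells)
  y <- if (scale == "log10") log10(obs$mic_exp_mM) else obs$mic_exp_mM

  sol <- constrained_line_fit(z, y)

  if (scale == "log10") {
    dist <- resistance_distribution(sol$intercept, sol$slope)
    ic50 <- dist$ic50_mM
    het <- sol$slope
    mm <- mic_model(dist, percentile)
  } else {
    ic50 <- sol$intercept
    het <- sol$slope
    mm <- sol$intercept + sol$slope * stats::qnorm(percentile)
  }

  new_mic_fit(
    ic50_mM = ic50, heteroresistance = het, mic_model_mM = mm,
    mu = sol$intercept, sigma = sol$slope,
    n_points = length(y), rss = sol$rss,
    converged = TRUE, sigma_clamped = sol$clamped,
    scale = scale, method = "inoculum", percentile = percentile,
    strain_id = first_or_na(obs$strain_id),
    replicate_id = first_or_na(obs$replicate_id)
  )
}

# Exact minimiser of sum((y - mu - sigma * z)^2) subject to sigma >= 0.
# If the unconstrained OLS slope is negative, the constrained optimum lies
# on the boundary sigma = 0 with mu = mean(y).
constrained_line_fit <- function(z, y) {
  zbar <- mean(z); ybar <- mean(y)
  szz <- sum((z - zbar)^2)
  szy <- sum((z - zbar) * (y - ybar))
  slope <- szy / szz
  clamped <- FALSE
  if (slope < 0) {
    slope <- 0
    clamped <- TRUE
  }
  intercept <- ybar - slope * zbar
  rss <- sum((y - intercept - slope * z)^2)
  list(intercept = intercept, slope = slope, rss = rss, clamped = clamped)
}

validate_inoculum_obs <- function(observations) {
  obs <- as.data.frame(observations)
  required <- c("inoculum_cells", "mic_exp_mM")
  missing <- setdiff(required, names(obs))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!is.null(obs$strain_id) && length(unique(obs$strain_id)) > 1L)
    stop("observations must come from a single strain; got: ",
         paste(unique(obs$strain_id), collapse = ", "), call. = FALSE)
  if (!is.null(obs$censored) && any(obs$censored)) {
    warning(sum(obs$censored),
            " censored observation(s) (MIC beyond the concentration grid)",
            " excluded from the fit")
    obs <- obs[!obs$censored, , drop = FALSE]
  }
  if (nrow(obs) == 0L)
    stop("no usable observations", call. = FALSE)
  if (any(!is.finite(obs$inoculum_cells)) || any(obs$inoculum_cells < 1))
    stop("'inoculum_cells' must be finite and >= 1", call. = FALSE)
  if (any(!is.finite(obs$mic_exp_mM)) || any(obs$mic_exp_mM <= 0))
    stop("'mic_exp_mM' must be finite and > 0", call. = FALSE)
  obs
}

first_or_na <- function(x) if (is.null(x) || !length(x)) NA else x[[1L]]

new_mic_fit <- function(...) {
  structure(list(...), class = "mic_fit")
}

#' @export
print.mic_fit <- function(x, ...) {
  cat(sprintf("MIC fit (%s, %s scale)", x$method, x$scale))
  if (!is.na(x$strain_id)) cat(sprintf("  strain %s", x$strain_id))
  if (!is.na(x$replicate_id)) cat(sprintf(" / replicate %s", x$replicate_id))
  cat("\n")
  unit <- if (x$scale == "log10") "" else " mM"
  cat(sprintf("  IC50:             %.4g mM\n", x$ic50_mM))
  cat(sprintf("  heteroresistance: %.4g%s%s\n", x$heteroresistance, unit,
              if (isTRUE(x$sigma_clamped)) "  (clamped to 0)" else ""))
  cat(sprintf("  MIC_MODEL:        %.4g mM (percentile %.4f)\n",
              x$mic_model_mM, x$percentile))
  cat(sprintf("  n = %d, RSS = %.4g, converged: %s\n",
              x$n_points, x$rss, x$converged))
  invisible(x)
}

#' Flatten one or more MIC fits to a data frame
#'
#' One row per fit, with the columns used by the fit-result CSV writers:
#' strain/replicate labels, parameter estimates, residual sum of squares
#' and diagnostic flags.
#'
#' @param x A `mic_fit` object.
#' @param ... Unused.
#' @return A one-row data frame.
#' @export
as.data.frame.mic_fit <- function(x, ...) {
  data.frame(
    strain_id = as.character(x$strain_id),
    replicate_id = as.character(x$replicate_id),
    method = x$method,
    scale = x$scale,
    ic50_mM = x$ic50_mM,
    heteroresistance = x$heteroresistance,
    mic_model_mM = x$mic_model_mM,
    n_points = x$n_points,
    rss = x$rss,
    converged = x$converged,
    sigma_clamped = x$sigma_clamped,
    stringsAsFactors = FALSE
  )
}

#' Fit each biological replicate separately, then summarise
#'
#' Splits inoculum-effect observations by `replicate_id`, fits one curve
#' per biological replicate with [fit_inoculum_effect()], and returns the
#' per-replicate fits together with their [aggregate_fits()] summary
#' (mean and standard error of each parameter across replicates).
#'
#' @inheritParams fit_inoculum_effect
#' @return A list with elements `fits` (list of `mic_fit`) and `summary`
#'   (see [aggregate_fits()]).
#' @export
fit_inoculum_replicates <- function(observations,
                                    scale = c("log10", "linear"),
                                    percentile = 0.9999) {
  scale <- match.arg(scale)
  obs <- as.data.frame(observations)
  if (is.null(obs$replicate_id))
    obs$replicate_id <- 1L
  fits <- lapply(split(obs, obs$replicate_id), fit_inoculum_effect,
                 scale = scale, percentile = percentile)
  list(fits = fits, summary = aggregate_fits(fits))
}
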