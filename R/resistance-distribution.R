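#' Lognormal single-cell resistance distribution
#'
#' Constructs the parametric model underlying all estimators in this
#' package: single-cell resistances (in mM of stressor) are lognormally
#' distributed, i.e. `log10(resistance)` is normal with location
#' `mu_log10` and spread `sigma_log10`.  The median of the distribution,
#' `10^mu_log10`, is the population IC50; `sigma_log10` is the
#' heteroresistance -- the cell-to-cell standard deviation of
#' `log10(resistance)`.
#'
#' `sigma_log10 = 0` is legal and describes a perfectly homogeneous
#' population (no inoculum effect); downstream quantities then collapse to
#' step functions or constants.
#'
#' @param mu_log10 Location of `log10(resistance)`, in `log10(mM)`.
#' @param sigma_log10 Standard deviation of `log10(resistance)`
#'   (dimensionless on the log10 scale).  Must be non-negative.
#' @return An object of class `resistance_distribution` with fields
#'   `mu_log10`, `sigma_log10` and the derived `ic50_mM = 10^mu_log10`.
#' @examples
#' d <- resistance_distribution(mu_log10 = log10(4), sigma_log10 = 0.07)
#' d$ic50_mM
#' mic_model(d)
#' @export
resistance_distribution <- function(mu_log10, sigma_log10) {
  stopifnot(is.numeric(mu_log10), length(mu_log10) == 1L,
            is.numeric(sigma_log10), length(sigma_log10) == 1L)
  if (!is.finite(mu_log10))
    stop("'mu_log10' must be finite", call. = FALSE)
  if (!is.finite(sigma_log10) || sigma_log10 < 0)
    stop("'sigma_log10' must be finite and >= 0", call. = FALSE)
  structure(
    list(mu_log10 = mu_log10,
         sigma_log10 = sigma_log10,
         ic50_mM = 10^mu_log10),
    class = "resistance_distribution"
  )
}

#' @export
print.resistance_distribution <- function(x, ...) {
  cat("Lognormal single-cell resistance distribution\n")
  cat(sprintf("  IC50:             %.4g mM  (mu_log10 = %.4f)\n",
              x$ic50_mM, x$mu_log10))
  cat(sprintf("  heteroresistance: %.4g    (sigma_log10)\n", x$sigma_log10))
  cat(sprintf("  MIC_MODEL:        %.4g mM  (99.99th percentile)\n",
              mic_model(x)))
  invisible(x)
}

#' Expected-maximum quantile for a normal sample of size n
#'
#' Standard-normal quantile `z_n` such that the expected maximum of `n`
#' independent standard-normal draws is approximately `z_n`
#' (Blom/Royston-type approximation):
#' `z_n = qnorm((n - pi/8) / (n - pi/4 + 1))`.
#'
#' This is the quantity that links an inoculum of `n` cells to its
#' expected MIC: the most resistant of `n` cells sits, on average, `z_n`
#' standard deviations above the population median.
#'
#' @param n Cell count(s), `n >= 1` (need not be integer; vectorised).
#' @return Standard-normal quantile(s), dimensionless; strictly increasing
#'   in `n`, with `expected_max_quantile(1) == 0` exactly.
#' @examples
#' expected_max_quantile(1)      # 0
#' expected_max_quantile(1e4)    # ~ 3.84
#' @export
expected_max_quantile <- function(n) {
  if (!is.numeric(n) || length(n) == 0L || any(!is.finite(n)) || any(n < 1))
    stop("'n' must be finite and >= 1", call. = FALSE)
  stats::qnorm((n - pi / 8) / (n - pi / 4 + 1))
}

#' Predicted experimental MIC at a given inoculum size
#'
#' Expected MIC of an inoculum of `n` cells drawn from the resistance
#' distribution: the expected maximum single-cell resistance,
#' `10^(mu_log10 + sigma_log10 * expected_max_quantile(n))`.  At `n = 1`
#' this is exactly the IC50; it is non-decreasing in `n` (the inoculum
#' effect), and constant when `sigma_log10 = 0`.
#'
#' @param dist A [resistance_distribution()].
#' @param n Inoculum size(s) in cells, `n >= 1` (vectorised).
#' @return Concentration(s) in mM.
#' @examples
#' d <- resistance_distribution(0.602, 0.07)
#' predicted_mic_exp(d, c(1e2, 1e4))
#' @export
predicted_mic_exp <- function(dist, n) {
  stopifnot(inherits(dist, "resistance_distribution"))
  10^(dist$mu_log10 + dist$sigma_log10 * expected_max_quantile(n))
}

#' Model MIC: upper percentile of the single-cell resistance distribution
#'
#' The concentration inhibiting a given fraction of single cells; with the
#' default `percentile = 0.9999` this is the conventional "MIC of 10,000
#' cells" summary, `10^(mu_log10 + sigma_log10 * qnorm(0.9999))` (the
#' multiplier `qnorm(0.9999)` is about 3.7190).  Always `>= IC50`, with
#' equality iff `sigma_log10 = 0`.
#'
#' @param dist A [resistance_distribution()].
#' @param percentile Fraction in (0, 1); default `0.9999`.
#' @return Concentration in mM.
#' @export
mic_model <- function(dist, percentile = 0.9999) {
  stopifnot(inherits(dist, "resistance_distribution"))
  if (!is.numeric(percentile) || length(percentile) != 1L ||
      !is.finite(percentile) || percentile <= 0 || percentile >= 1)
    stop("'percentile' must be in (0, 1)", call. = FALSE)
  10^(dist$mu_log10 + dist$sigma_log10 * stats::qnorm(percentile))
}

#' Fraction of single cells surviving a given concentration
#'
#' Upper tail of the single-cell resistance distribution:
#' `1 - pnorm((log10(c) - mu_log10) / sigma_log10)`.  For a degenerate
#' distribution (`sigma_log10 = 0`) this is a step function: 1 below the
#' IC50, 0.5 at exactly the IC50, 0 above it.
#'
#' @param dist A [resistance_distribution()].
#' @param conc_mM Concentration(s) in mM, strictly positive (vectorised).
#' @return Survival fraction(s) in \[0, 1\], non-increasing in `conc_mM`.
#' @examples
#' d <- resistance_distribution(0.6, 0.08)
#' survival_fraction(d, d$ic50_mM)   # 0.5
#' @export
survival_fraction <- function(dist, conc_mM) {
  stopifnot(inherits(dist, "resistance_distribution"))
  if (!is.numeric(conc_mM) || length(conc_mM) == 0L ||
      any(!is.finite(conc_mM)) || any(conc_mM <= 0))
    stop("'conc_mM' must be finite and > 0", call. = FALSE)
  z <- log10(conc_mM) - dist$mu_log10
  if (dist$sigma_log10 == 0) {
    # step-function limit of the normal CDF
    out <- ifelse(z < 0, 1, ifelse(z > 0, 0, 0.5))
  } else {
    out <- stats::pnorm(z / dist$sigma_log10, lower.tail = FALSE)
  }
  out
}
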