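#' Summarise fits across biological replicates
#'
#' Arithmetic mean and standard error of the mean (sample SD / sqrt(k))
#' of IC50, heteroresistance and model MIC over a set of per-replicate
#' fits.  The model MIC is averaged over the per-replicate values, not
#' recomputed from the mean location and mean spread (the two differ
#' because the percentile transform is non-linear).
#'
#' @param fits A list of `mic_fit` objects (at least one).
#' @return A data frame with one row per parameter (`ic50_mM`,
#'   `heteroresistance`, `mic_model_mM`) and columns `mean`, `sem`, `k`.
#'   With a single fit the SEM is reported as 0 and the attribute
#'   `single_fit` is set to `TRUE`.
#' @examples
#' obs <- data.frame(inoculum_cells = c(1e2, 1e5), mic_exp_mM = c(6, 8))
#' f <- fit_inoculum_effect(obs)
#' aggregate_fits(list(f, f, f))
#' @export
aggregate_fits <- function(fits) {
  if (inherits(fits, "mic_fit")) fits <- list(fits)
  if (!is.list(fits) || length(fits) == 0L ||
      !all(vapply(fits, inherits, logical(1), "mic_fit")))
    stop("'fits' must be a non-empty list of mic_fit objects", call. = FALSE)
  k <- length(fits)
  params <- c("ic50_mM", "heteroresistance", "mic_model_mM")
  vals <- vapply(fits, function(f) unlist(f[params]), numeric(3L))
  means <- rowMeans(vals)
  sems <- if (k == 1L) rep(0, 3L) else apply(vals, 1L, stats::sd) / sqrt(k)
  out <- data.frame(parameter = params, mean = unname(means),
                    sem = unname(sems), k = k,
                    stringsAsFactors = FALSE)
  attr(out, "single_fit") <- k == 1L
  out
}
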