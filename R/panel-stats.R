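#' Pearson correlation with one- or two-tailed p-value
#'
#' Wraps [stats::cor.test()] (Pearson; p from the t distribution with
#' n - 2 degrees of freedom) and reports both the two-tailed p-value and
#' the one-tailed p-value in the direction of the observed correlation
#' (`p_two/2`; used when the direction of association is specified in
#' advance, as in regression-based screening).
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, neither constant.
#' @param tail `"two"` (default) or `"one"`: which p-value the `p` field
#'   reports; both are always returned.
#' @return An object of class `cor_result`: list with `r`, `n`,
#'   `p_two_tailed`, `p_one_tailed`, `p`, `tail`.
#' @examples
#' pearson_cor(1:10, (1:10) * 2 + rnorm(10))
#' @export
pearson_cor <- function(x, y, tail = c("two", "one")) {
  tail <- match.arg(tail)
  if (length(x) != length(y))
    stop("'x' and 'y' must have the same length", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L)
    stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate correlation: constant input", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  p_two <- ct$p.value
  structure(list(r = unname(ct$estimate), n = length(x),
                 p_two_tailed = p_two, p_one_tailed = p_two / 2,
                 p = if (tail == "two") p_two else p_two / 2,
                 tail = tail),
            class = "cor_result")
}

#' @export
print.cor_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d), p = %.3g (%s-tailed)\n",
              x$r, x$n, x$p, x$tail))
  invisible(x)
}

#' Welch two-sample t-test
#'
#' Two-sample t-test assuming unequal variances
#' ([stats::t.test()] with `var.equal = FALSE`), the comparison used for
#' species-group contrasts of resistance parameters.
#'
#' @param a,b Numeric vectors, each with at least 2 values.
#' @return List with `t`, `df` (Welch-Satterthwaite), `p_two_tailed`,
#'   `mean_a`, `mean_b`.
#' @examples
#' welch_t(c(1, 2, 3), c(4, 5, 6))
#' @export
welch_t <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_two_tailed = tt$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Sample standard deviation, optionally on the log10 scale
#'
#' Standard deviation with the n - 1 denominator ([stats::sd()]); with
#' `log10_transform = TRUE` values are log10-transformed first (the
#' appropriate scale for comparing dispersion of concentration-valued
#' parameters such as IC50).
#'
#' @param x Numeric vector with at least 2 values.
#' @param log10_transform Transform before computing (default `FALSE`).
#' @return Scalar standard deviation.
#' @export
sample_sd <- function(x, log10_transform = FALSE) {
  x <- x[is.finite(x)]
  if (length(x) < 2L)
    stop("need at least 2 values", call. = FALSE)
  if (log10_transform) {
    if (any(x <= 0))
      stop("log10 transform requires positive values", call. = FALSE)
    x <- log10(x)
  }
  stats::sd(x)
}

#' Cross-strain summary statistics for a resistance panel
#'
#' Computes, for a panel of per-strain parameter estimates, the three
#' pairwise Pearson correlations (heteroresistance-IC50,
#' heteroresistance-model MIC, IC50-model MIC) overall and per species,
#' group means/SDs/SEMs, Welch t-tests between every pair of species, and
#' parameter ranges.  Optionally excludes named strains (outlier
#' re-analysis) and restricts to one species.  Correlations are computed
#' on the untransformed per-strain values (the plotted quantities);
#' species subgroups with fewer than 3 strains are skipped for
#' correlations and fewer than 2 for t-tests, with a notice.
#'
#' @param records Data frame with columns `strain_id`, `species`,
#'   `heteroresistance`, `ic50_mM`, `mic_model_mM` (the schema of
#'   [read_panel_csv()] and [zygo_panel()]).
#' @param exclude Character vector of strain ids to drop (unknown ids are
#'   an error).
#' @param species If non-`NULL`, restrict the report to one species.
#' @param group_by_species Also compute per-species blocks (default
#'   `TRUE`).
#' @param tail Tail convention passed to [pearson_cor()].
#' @return An object of class `panel_report`: list of data frames
#'   `correlations`, `groups`, `welch`, `ranges`, plus `n`, `excluded`,
#'   `notices`.
#' @examples
#' rep <- panel_report(zygo_panel())
#' rep$correlations
#' @export
panel_report <- function(records, exclude = NULL, species = NULL,
                         group_by_species = TRUE,
                         tail = c("two", "one")) {
  tail <- match.arg(tail)
  rec <- as.data.frame(records)
  required <- c("strain_id", "species", "heteroresistance", "ic50_mM",
                "mic_model_mM")
  missing <- setdiff(required, names(rec))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  rec$strain_id <- as.character(rec$strain_id)
  if (!is.null(exclude)) {
    exclude <- as.character(exclude)
    unknown <- setdiff(exclude, rec$strain_id)
    if (length(unknown))
      stop("unknown strain id(s) in 'exclude': ",
           paste(unknown, collapse = ", "), call. = FALSE)
    rec <- rec[!rec$strain_id %in% exclude, , drop = FALSE]
  }
  if (!is.null(species)) {
    if (!species %in% rec$species)
      stop("species not present in panel: ", species, call. = FALSE)
    rec <- rec[rec$species == species, , drop = FALSE]
  }
  if (nrow(rec) < 3L)
    stop("need at least 3 records after exclusion", call. = FALSE)

  pairs <- list(
    c("heteroresistance", "ic50_mM"),
    c("heteroresistance", "mic_model_mM"),
    c("ic50_mM", "mic_model_mM")
  )
  notices <- character(0)

  cor_block <- function(dat, label) {
    out <- lapply(pairs, function(p) {
      res <- tryCatch(pearson_cor(dat[[p[1L]]], dat[[p[2L]]], tail = tail),
                      error = function(e) NULL)
      if (is.null(res))
        data.frame(group = label, var1 = p[1L], var2 = p[2L],
                   n = nrow(dat), r = NA_real_, p_two_tailed = NA_real_,
                   p_one_tailed = NA_real_, stringsAsFactors = FALSE)
      else
        data.frame(group = label, var1 = p[1L], var2 = p[2L],
                   n = res$n, r = res$r, p_two_tailed = res$p_two_tailed,
                   p_one_tailed = res$p_one_tailed,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }

  correlations <- cor_block(rec, "all")
  params <- c("heteroresistance", "ic50_mM", "mic_model_mM")

  groups <- welch <- NULL
  if (group_by_species && is.null(species)) {
    for (sp in sort(unique(rec$species))) {
      sub <- rec[rec$species == sp, , drop = FALSE]
      if (nrow(sub) < 3L) {
        notices <- c(notices, paste0("species '", sp, "' has n = ",
                                     nrow(sub),
                                     " < 3; correlations skipped"))
        next
      }
      correlations <- rbind(correlations, cor_block(sub, sp))
    }
    groups <- do.call(rbind, lapply(sort(unique(rec$species)), function(sp) {
      sub <- rec[rec$species == sp, , drop = FALSE]
      do.call(rbind, lapply(params, function(p) {
        v <- sub[[p]]
        data.frame(species = sp, parameter = p, n = length(v),
                   mean = mean(v),
                   sd = if (length(v) >= 2L) stats::sd(v) else NA_real_,
                   sem = if (length(v) >= 2L)
                     stats::sd(v) / sqrt(length(v)) else NA_real_,
                   stringsAsFactors = FALSE)
      }))
    }))
    spp <- sort(unique(rec$species))
    if (length(spp) >= 2L) {
      combos <- utils::combn(spp, 2L, simplify = FALSE)
      welch <- do.call(rbind, lapply(combos, function(cp) {
        a <- rec[rec$species == cp[1L], , drop = FALSE]
        b <- rec[rec$species == cp[2L], , drop = FALSE]
        if (nrow(a) < 2L || nrow(b) < 2L) {
          notices <<- c(notices,
                        paste0("pair ", cp[1L], " vs ", cp[2L],
                               " below minimum n; t-tests skipped"))
          return(NULL)
        }
        do.call(rbind, lapply(params, function(p) {
          wt <- welch_t(a[[p]], b[[p]])
          data.frame(species_a = cp[1L], species_b = cp[2L],
                     parameter = p, n_a = nrow(a), n_b = nrow(b),
                     mean_a = wt$mean_a, mean_b = wt$mean_b,
                     t = wt$t, df = wt$df, p_two_tailed = wt$p_two_tailed,
                     stringsAsFactors = FALSE)
        }))
      }))
    }
  }

  ranges <- do.call(rbind, lapply(params, function(p) {
    data.frame(parameter = p, min = min(rec[[p]]), max = max(rec[[p]]),
               stringsAsFactors = FALSE)
  }))

  structure(list(correlations = correlations, groups = groups,
                 welch = welch, ranges = ranges, n = nrow(rec),
                 excluded = exclude, species = species, tail = tail,
                 notices = notices),
            class = "panel_report")
}

#' @export
print.panel_report <- function(x, ...) {
  cat(sprintf("Panel report: %d strains", x$n))
  if (length(x$excluded))
    cat(" (excluded: ", paste(x$excluded, collapse = ", "), ")", sep = "")
  if (!is.null(x$species)) cat(" [", x$species, " only]", sep = "")
  cat("\n\nPairwise Pearson correlations:\n")
  print(x$correlations, row.names = FALSE, digits = 3)
  if (!is.null(x$groups)) {
    cat("\nSpecies group summaries:\n")
    print(x$groups, row.names = FALSE, digits = 4)
  }
  if (!is.null(x$welch)) {
    cat("\nWelch t-tests between species:\n")
    print(x$welch, row.names = FALSE, digits = 3)
  }
  cat("\nParameter ranges:\n")
  print(x$ranges, row.names = FALSE, digits = 3)
  for (msg in x$notices) cat("note:", msg, "\n")
  invisible(x)
}
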