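#' Design of a broth microdilution inoculum-effect assay
#'
#' Collects the knobs of the simulated assay: nominal inoculum sizes, the
#' arithmetic concentration grid, replicate structure, Poisson variation
#' of the actual cell number around the nominal inoculum, and the MIC
#' scoring rule.  Defaults mirror a 96-well sorbic acid assay: inocula
#' 10^2 to 10^5 cells/well, concentrations from 0 in 0.125 mM increments
#' up to 20 mM (the stock limit), four technical and six biological
#' replicates.
#'
#' Two scoring rules are provided.  `"any_clear"` records the lowest
#' concentration at which growth is absent in at least one of the
#' technical replicate wells; `"all_clear"` the lowest concentration at
#' which no technical replicate grows.  `"any_clear"` never exceeds
#' `"all_clear"` on the same draws.
#'
#' @param inoculum_sizes Nominal cells per well.
#' @param conc_start,conc_step,conc_max Arithmetic concentration grid (mM).
#' @param technical_replicates Wells per concentration and inoculum.
#' @param biological_replicates Independent cultures.
#' @param poisson_inoculum If `TRUE` (default), the actual cell number in
#'   each well is Poisson-distributed around the nominal inoculum.
#' @param scoring_rule `"any_clear"` (default) or `"all_clear"`.
#' @return An object of class `assay_design`.
#' @export
assay_design <- function(inoculum_sizes = c(1e2, 1e3, 1e4, 1e5),
                         conc_start = 0, conc_step = 0.125, conc_max = 20,
                         technical_replicates = 4L,
                         biological_replicates = 6L,
                         poisson_inoculum = TRUE,
                         scoring_rule = c("any_clear", "all_clear")) {
  scoring_rule <- match.arg(scoring_rule)
  stopifnot(is.numeric(inoculum_sizes), length(inoculum_sizes) >= 1L,
            all(is.finite(inoculum_sizes)), all(inoculum_sizes >= 1),
            conc_step > 0, conc_max > conc_start, conc_start >= 0,
            technical_replicates >= 1L, biological_replicates >= 1L)
  structure(
    list(inoculum_sizes = sort(inoculum_sizes),
         concentration_grid = seq(conc_start, conc_max, by = conc_step),
         technical_replicates = as.integer(technical_replicates),
         biological_replicates = as.integer(biological_replicates),
         poisson_inoculum = isTRUE(poisson_inoculum),
         scoring_rule = scoring_rule),
    class = "assay_design"
  )
}

#' @export
print.assay_design <- function(x, ...) {
  g <- x$concentration_grid
  cat("Inoculum-effect assay design\n")
  cat("  inocula (cells/well):", paste(format(x$inoculum_sizes,
                                              scientific = TRUE),
                                       collapse = ", "), "\n")
  cat(sprintf("  concentrations: %g to %g mM in %g mM steps (%d wells)\n",
              min(g), max(g), g[2L] - g[1L], length(g)))
  cat(sprintf("  replicates: %d technical x %d biological\n",
              x$technical_replicates, x$biological_replicates))
  cat(sprintf("  Poisson inoculum: %s; scoring: %s\n",
              x$poisson_inoculum, x$scoring_rule))
  invisible(x)
}

#' Draw single-cell resistances from a population
#'
#' `n` independent draws from the lognormal resistance distribution:
#' `10^(mu_log10 + sigma_log10 * rnorm(n))`.
#'
#' @param dist A [resistance_distribution()].
#' @param n Number of cells (>= 1).
#' @return Numeric vector of `n` resistances in mM.
#' @export
sample_population <- function(dist, n) {
  stopifnot(inherits(dist, "resistance_distribution"))
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1)
    stop("'n' must be a single value >= 1", call. = FALSE)
  10^(dist$mu_log10 + dist$sigma_log10 * stats::rnorm(as.integer(n)))
}

# P(no growth) for wells of n cells at concentration c:
# Phi((log10 c - mu)/sigma)^n.  c = 0 gives Phi = 0; n = 0 gives 1
# (an empty well never grows).  Vectorised over n and c jointly.
no_growth_prob <- function(dist, n_cells, conc_mM) {
  lc <- suppressWarnings(log10(conc_mM))          # -Inf at c = 0
  if (dist$sigma_log10 == 0) {
    phi <- ifelse(lc < dist$mu_log10, 0,
                  ifelse(lc > dist$mu_log10, 1, 0.5))
  } else {
    phi <- stats::pnorm((lc - dist$mu_log10) / dist$sigma_log10)
  }
  ifelse(n_cells == 0, 1, phi^n_cells)
}

#' Simulate growth/no-growth of a single well
#'
#' A well inoculated with `n_cells` cells grows iff at least one cell's
#' resistance strictly exceeds the well concentration; the growth
#' probability is therefore
#' `1 - pnorm((log10(c) - mu)/sigma)^n_cells`, which is how the outcome
#' is drawn (no per-cell sampling is needed).
#'
#' @param dist A [resistance_distribution()].
#' @param n_cells Cells in the well (>= 0; 0 never grows).
#' @param conc_mM Stressor concentration in mM (>= 0).
#' @return Logical: `TRUE` if the well grows.
#' @export
simulate_well <- function(dist, n_cells, conc_mM) {
  stopifnot(inherits(dist, "resistance_distribution"))
  if (!is.numeric(n_cells) || any(n_cells < 0) || any(!is.finite(n_cells)))
    stop("'n_cells' must be finite and >= 0", call. = FALSE)
  if (!is.numeric(conc_mM) || any(conc_mM < 0) || any(!is.finite(conc_mM)))
    stop("'conc_mM' must be finite and >= 0", call. = FALSE)
  p_ng <- no_growth_prob(dist, n_cells, conc_mM)
  stats::runif(length(p_ng)) >= p_ng
}

#' Simulate a full inoculum-effect MIC assay
#'
#' For every biological replicate and inoculum size, wells are simulated
#' across the whole concentration grid (technical replicates at each
#' concentration, actual cell numbers Poisson-distributed around the
#' nominal inoculum if enabled) and the MIC is scored per the design's
#' rule.  If no concentration on the grid qualifies, the observation is
#' flagged as censored (`mic_exp_mM = NA`); censored rows are excluded by
#' the fitters with a warning.
#'
#' Wells are simulated for the complete grid (no early stopping), so the
#' two scoring rules can be compared on identical draws and the random
#' number stream does not depend on the rule.
#'
#' @param dist A [resistance_distribution()].
#' @param design An [assay_design()].
#' @param strain_id Label stored in the output (default `"sim"`).
#' @param seed Optional integer seed for reproducibility.
#' @return Data frame with columns `strain_id`, `replicate_id`,
#'   `inoculum_cells` (nominal), `mic_exp_mM`, `censored`.
#' @examples
#' d <- resistance_distribution(log10(4), 0.07)
#' head(simulate_mic_exp(d, assay_design(), seed = 1))
#' @export
simulate_mic_exp <- function(dist, design = assay_design(),
                             strain_id = "sim", seed = NULL) {
  stopifnot(inherits(dist, "resistance_distribution"),
            inherits(design, "assay_design"))
  if (!is.null(seed)) set.seed(as.integer(seed))

  grid <- design$concentration_grid
  tail_p <- if (dist$sigma_log10 == 0) {
    as.numeric(max(grid) < dist$ic50_mM)
  } else {
    stats::pnorm((log10(max(grid)) - dist$mu_log10) / dist$sigma_log10,
                 lower.tail = FALSE)
  }
  if (tail_p > 1e-9 * max(design$inoculum_sizes))
    warning("concentration grid may not cover the distribution's upper ",
            "tail; censored observations are likely")

  nconc <- length(grid)
  tech <- design$technical_replicates
  rows <- vector("list",
                 design$biological_replicates * length(design$inoculum_sizes))
  i <- 0L
  for (rep_id in seq_len(design$biological_replicates)) {
    for (n_nom in design$inoculum_sizes) {
      n_act <- if (design$poisson_inoculum)
        stats::rpois(nconc * tech, n_nom) else rep(n_nom, nconc * tech)
      p_ng <- no_growth_prob(dist, n_act, rep(grid, each = tech))
      clear <- matrix(stats::runif(nconc * tech) < p_ng,
                      nrow = tech, ncol = nconc)
      hit <- if (design$scoring_rule == "any_clear")
        colSums(clear) >= 1L else colSums(clear) == tech
      mic <- if (any(hit)) grid[which(hit)[1L]] else NA_real_
      i <- i + 1L
      rows[[i]] <- data.frame(strain_id = strain_id,
                              replicate_id = rep_id,
                              inoculum_cells = n_nom,
                              mic_exp_mM = mic,
                              censored = is.na(mic),
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (all(out$censored))
    stop("simulation design error: concentration grid exhausted for all ",
         "replicates", call. = FALSE)
  out
}

#' Simulate an agar plate-count dose-response assay
#'
#' Cells are plated at each concentration; the colony count is
#' `Binomial(actual cells plated, survival_fraction(dist, c))`, with the
#' actual cell number Poisson-distributed around the nominal inoculum.
#' Percent survival is `100 * CFU(c) / CFU(0)`, each concentration
#' normalised to its replicate's zero-concentration control plate.  Two
#' default inoculum sizes (10^4 and 10^2 cells) give usable counting
#' resolution in different survival ranges.  Replicates whose control
#' plate has zero colonies are dropped with a warning.
#'
#' @param dist A [resistance_distribution()].
#' @param inoculum_sizes Nominal cells plated (default `c(1e4, 1e2)`).
#' @param concentrations Concentration grid in mM; must include 0 (the
#'   normalisation control).
#' @param replicates Biological replicates (default 3).
#' @param poisson_inoculum Poisson-vary the plated cell number (default
#'   `TRUE`).
#' @param strain_id Label stored in the output.
#' @param seed Optional integer seed.
#' @return Data frame with columns `strain_id`, `replicate_id`,
#'   `inoculum_cells`, `concentration_mM`, `cfu`, `cfu_control`,
#'   `percent_survival`.
#' @export
simulate_dose_response <- function(dist,
                                   inoculum_sizes = c(1e4, 1e2),
                                   concentrations = seq(0, 12, by = 0.5),
                                   replicates = 3L,
                                   poisson_inoculum = TRUE,
                                   strain_id = "sim", seed = NULL) {
  stopifnot(inherits(dist, "resistance_distribution"))
  if (!any(concentrations == 0))
    stop("'concentrations' must include 0 (the control plate)",
         call. = FALSE)
  if (any(concentrations < 0))
    stop("'concentrations' must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))

  conc <- sort(unique(concentrations))
  surv <- numeric(length(conc))
  surv[conc == 0] <- 1
  surv[conc > 0] <- survival_fraction(dist, conc[conc > 0])
  rows <- list(); i <- 0L
  for (rep_id in seq_len(replicates)) {
    for (n_nom in inoculum_sizes) {
      n_act <- if (poisson_inoculum)
        stats::rpois(length(conc), n_nom) else rep(n_nom, length(conc))
      cfu <- stats::rbinom(length(conc), n_act, surv)
      cfu0 <- cfu[conc == 0][1L]
      if (cfu0 == 0) {
        warning("replicate ", rep_id, " at inoculum ", n_nom,
                " has zero control CFU; dropped")
        next
      }
      i <- i + 1L
      rows[[i]] <- data.frame(strain_id = strain_id,
                              replicate_id = rep_id,
                              inoculum_cells = n_nom,
                              concentration_mM = conc,
                              cfu = cfu,
                              cfu_control = cfu0,
                              percent_survival = 100 * cfu / cfu0,
                              stringsAsFactors = FALSE)
    }
  }
  if (i == 0L)
    stop("all replicates degenerate (zero control CFU)", call. = FALSE)
  do.call(rbind, rows)
}

#' Generate a full synthetic strain panel with ground truth
#'
#' Runs [simulate_mic_exp()] and [simulate_dose_response()] for every
#' strain in a specification table and returns the pooled observation
#' tables together with the ground-truth parameter table, for end-to-end
#' recovery studies.
#'
#' @param strains Data frame with columns `strain_id`, `species`,
#'   `mu_log10`, `sigma_log10` (one row per strain; ids must be unique).
#' @param design An [assay_design()] for the MIC assay.
#' @param dose_concentrations Concentration grid for the dose-response
#'   simulation (must include 0).
#' @param seed Optional integer seed.
#' @return List with elements `mic` (inoculum-effect observations),
#'   `dose` (dose-response observations) and `truth` (the input table
#'   plus `true_ic50_mM` and `true_mic_model_mM`).
#' @export
generate_panel <- function(strains, design = assay_design(),
                           dose_concentrations = seq(0, 12, by = 0.5),
                           seed = NULL) {
  strains <- as.data.frame(strains)
  required <- c("strain_id", "species", "mu_log10", "sigma_log10")
  missing <- setdiff(required, names(strains))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(strains) < 1L)
    stop("need at least one strain", call. = FALSE)
  if (anyDuplicated(strains$strain_id))
    stop("duplicate strain_id in panel specification", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))

  mic <- list(); dose <- list()
  for (j in seq_len(nrow(strains))) {
    d <- resistance_distribution(strains$mu_log10[j],
                                 strains$sigma_log10[j])
    mic[[j]] <- simulate_mic_exp(d, design,
                                 strain_id = strains$strain_id[j])
    dose[[j]] <- simulate_dose_response(
      d, concentrations = dose_concentrations,
      strain_id = strains$strain_id[j])
  }
  truth <- strains
  truth$true_ic50_mM <- 10^strains$mu_log10
  truth$true_mic_model_mM <- 10^(strains$mu_log10 +
                                   strains$sigma_log10 * stats::qnorm(0.9999))
  list(mic = do.call(rbind, mic), dose = do.call(rbind, dose),
       truth = truth)
}
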