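#' Read and write the package's CSV schemas
#'
#' Plain-CSV (UTF-8, decimal point) readers and writers for the three
#' observation/record tables:
#' \describe{
#'   \item{inoculum observations}{`strain_id, replicate_id,
#'     inoculum_cells, mic_exp_mM` (optional `censored`)}
#'   \item{dose-response observations}{`strain_id, replicate_id,
#'     concentration_mM, percent_survival` -- or `cfu` and `cfu_control`,
#'     from which percent survival is derived}
#'   \item{panel records}{`strain_id, species, heteroresistance,
#'     ic50_mM, mic_model_mM`}
#' }
#' Readers validate the header (a missing required column is an error
#' naming the column), coerce numeric columns with an error naming the
#' first bad row, ignore (but preserve) unknown columns, and skip `#`
#' comment lines.  Writers prepend `#` header comments recording the
#' package version and the resolved configuration, so every output file
#' documents how it was produced; a write-then-read round trip is
#' identity up to float text precision.
#'
#' @param path File path.
#' @param x Data frame to write.
#' @param config Optional named list recorded in the header comments.
#' @return Readers return a validated data frame; writers return `path`
#'   invisibly.
#' @name heterores_io
NULL

read_checked_csv <- function(path, required, numeric_cols) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        colClasses = "character", check.names = TRUE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("schema error in ", basename(path), ": missing required column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (col in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !(df[[col]] %in% c("NA", "")))
    if (length(bad))
      stop("parse error in ", basename(path), ", column '", col,
           "', row ", bad[1L], ": non-numeric value '",
           df[[col]][bad[1L]], "'", call. = FALSE)
    df[[col]] <- v
  }
  df
}

write_with_header <- function(x, path, config = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  version <- as.character(utils::packageVersion("heterores"))
  writeLines(paste0("# heterores ", version), con)
  if (!is.null(config))
    for (nm in names(config))
      writeLines(paste0("# config: ", nm, " = ",
                        paste(format(config[[nm]]), collapse = " ")), con)
  utils::write.table(x, con, sep = ",", row.names = FALSE,
                     quote = FALSE, qmethod = "double")
  invisible(path)
}

#' @rdname heterores_io
#' @export
read_inoculum_csv <- function(path) {
  df <- read_checked_csv(path,
                         required = c("strain_id", "replicate_id",
                                      "inoculum_cells", "mic_exp_mM"),
                         numeric_cols = c("inoculum_cells", "mic_exp_mM"))
  if (!is.null(df$censored)) df$censored <- as.logical(df$censored)
  df
}

#' @rdname heterores_io
#' @export
write_inoculum_csv <- function(x, path, config = NULL) {
  stopifnot(all(c("strain_id", "replicate_id", "inoculum_cells",
                  "mic_exp_mM") %in% names(x)))
  write_with_header(x, path, config)
}

#' @rdname heterores_io
#' @export
read_dose_response_csv <- function(path) {
  df <- read_checked_csv(path,
                         required = c("strain_id", "replicate_id",
                                      "concentration_mM"),
                         numeric_cols = c("concentration_mM",
                                          "percent_survival",
                                          "cfu", "cfu_control"))
  if (is.null(df$percent_survival)) {
    if (is.null(df$cfu) || is.null(df$cfu_control))
      stop("schema error in ", basename(path),
           ": need either 'percent_survival' or both 'cfu' and ",
           "'cfu_control'", call. = FALSE)
    df$percent_survival <- 100 * df$cfu / df$cfu_control
  }
  df
}

#' @rdname heterores_io
#' @export
write_dose_response_csv <- function(x, path, config = NULL) {
  stopifnot(all(c("strain_id", "replicate_id", "concentration_mM",
                  "percent_survival") %in% names(x)))
  write_with_header(x, path, config)
}

#' @rdname heterores_io
#' @export
read_panel_csv <- function(path) {
  read_checked_csv(path,
                   required = c("strain_id", "species", "heteroresistance",
                                "ic50_mM", "mic_model_mM"),
                   numeric_cols = c("heteroresistance", "ic50_mM",
                                    "mic_model_mM"))
}

#' @rdname heterores_io
#' @export
write_panel_csv <- function(x, path, config = NULL) {
  stopifnot(all(c("strain_id", "species", "heteroresistance", "ic50_mM",
                  "mic_model_mM") %in% names(x)))
  write_with_header(x, path, config)
}

#' Bundled Zygosaccharomyces sorbic acid resistance panel
#'
#' The reference panel of 29 food-spoilage Zygosaccharomyces isolates
#' (5 Z. bailii, 17 Z. parabailii, 7 Z. pseudobailii) with their sorbic
#' acid resistance parameters: heteroresistance (SD of log10 single-cell
#' resistance), IC50 (mM) and model MIC (mM), each a mean over
#' per-biological-replicate inoculum-effect fits.
#'
#' @return Data frame with columns `strain_id`, `species`,
#'   `heteroresistance`, `ic50_mM`, `mic_model_mM` (29 rows).
#' @examples
#' table(zygo_panel()$species)
#' @export
zygo_panel <- function() {
  path <- system.file("extdata", "zygosaccharomyces_panel.csv",
                      package = "heterores", mustWork = TRUE)
  read_panel_csv(path)
}
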