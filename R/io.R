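# Readers and writers for the tidy CSV schemas the pipeline consumes, with
# hard validation so malformed inputs fail loudly and name the offending
# rows.

.fail_rows <- function(bad, what, path) {
  stop("invalid ", what, " in '", path, "' at row(s): ",
       paste(utils::head(which(bad), 10), collapse = ", "),
       if (sum(bad) > 10) " ..." else "", call. = FALSE)
}

.parse_iso_date <- function(x) as.Date(as.character(x), format = "%Y-%m-%d")

#' Read and validate a daily SST table
#'
#' Expects columns `zone_id`, `date` (ISO `YYYY-MM-DD`), `sst_c`. Fails on
#' missing columns, unparseable dates or non-finite temperatures; warns on
#' values outside the -5..40 degC sanity range.
#'
#' @param path CSV file path.
#' @return validated data.frame with a `Date` column.
#' @export
read_sst_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("zone_id", "date", "sst_c"), names(x))
  if (length(miss)) stop("'", path, "' is missing columns: ",
                         paste(miss, collapse = ", "))
  d <- .parse_iso_date(x$date)
  if (anyNA(d)) .fail_rows(is.na(d), "ISO date", path)
  x$date <- d
  if (any(!is.finite(x$sst_c))) .fail_rows(!is.finite(x$sst_c), "SST value", path)
  message("read ", nrow(x), " SST rows from '", path, "'")
  .check_sst(x)
}

#' Read and validate an annual canopy table
#'
#' Expects columns `zone_id`, `sub_region`, `survey_year`, `species`,
#' `area_ha`; areas must be finite and nonnegative.
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_canopy_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("zone_id", "sub_region", "survey_year", "species",
                    "area_ha"), names(x))
  if (length(miss)) stop("'", path, "' is missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(!is.finite(x$area_ha) | x$area_ha < 0))
    .fail_rows(!is.finite(x$area_ha) | x$area_ha < 0, "canopy area", path)
  message("read ", nrow(x), " canopy rows from '", path, "'")
  .check_canopy(x)
}

#' Read and validate zone centroid coordinates
#'
#' Expects columns `zone_id`, `x`, `y` in a consistent planar projection.
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_zones_csv <- function(path) {
  z <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("zone_id", "x", "y"), names(z))
  if (length(miss)) stop("'", path, "' is missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(!is.finite(z$x) | !is.finite(z$y)))
    .fail_rows(!is.finite(z$x) | !is.finite(z$y), "coordinate", path)
  if (anyDuplicated(z$zone_id)) stop("duplicate zone_id in '", path, "'")
  message("read ", nrow(z), " zone centroids from '", path, "'")
  z
}

#' Read a zone-to-grid-cell mapping
#'
#' Expects columns `zone_id`, `cell_id` (many zones to one SST cell).
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_zone_cells_csv <- function(path) {
  z <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("zone_id", "cell_id"), names(z))
  if (length(miss)) stop("'", path, "' is missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(z$zone_id)) stop("duplicate zone_id in '", path, "'")
  z
}

#' Read a pre-computed day-of-year climatology
#'
#' Expects columns `day_of_year` (1..365), `clim_c`, optionally `zone_id`.
#'
#' @param path CSV file path.
#' @return validated data.frame usable wherever [build_climatology()]
#'   output is.
#' @export
read_climatology_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("day_of_year", "clim_c"), names(x))
  if (length(miss)) stop("'", path, "' is missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(!(x$day_of_year %in% 1:365)))
    .fail_rows(!(x$day_of_year %in% 1:365), "day_of_year", path)
  if (any(!is.finite(x$clim_c)))
    .fail_rows(!is.finite(x$clim_c), "climatology value", path)
  x
}

#' Write a beta-regression fit record as JSON
#'
#' @param fit a [kelpbeta()] fit.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "kelpbeta"))
  rec <- list(link = fit$link,
              coefficients = as.list(coef(fit)),
              se = as.list(fit$se), z = as.list(fit$z), p = as.list(fit$p),
              loglik = fit$loglik, aic = fit$aic,
              pseudo_r2 = fit$pseudo_r2, n = fit$n,
              converged = fit$converged)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Assemble and validate a pipeline run configuration
#'
#' @param period analysis years (e.g. `2011:2018`; the long record
#'   `1989:2021` for the secondary analysis).
#' @param baseline_years pre-heatwave baseline years; must lie within
#'   `period`.
#' @param onset_year heatwave onset; must lie within `period`.
#' @param reference_years climatology reference years.
#' @param metrics metric columns to use as regression covariates.
#' @param smoothing_halfwidth climatology smoothing half-width (days).
#' @param loss_window years searched for the heatwave loss minimum.
#' @param sub_regions optional subset of sub-regions to analyze.
#' @param seed seed recorded with the run.
#' @return a validated list of class `"kelpwave_config"`.
#' @export
run_config <- function(period = 2011:2018, baseline_years = 2011:2013,
                       onset_year = 2014, reference_years = 1985:1993,
                       metrics = c("warmest_month_mean_sst",
                                   "max_monthly_ssta",
                                   "days_ssta_positive"),
                       smoothing_halfwidth = 15L,
                       loss_window = 2014:2016,
                       sub_regions = NULL, seed = 1L) {
  if (!all(baseline_years %in% period))
    stop("baseline years must lie within the analysis period")
  if (!(onset_year %in% period))
    stop("onset year must lie within the analysis period")
  structure(list(period = period, baseline_years = baseline_years,
                 onset_year = onset_year, reference_years = reference_years,
                 metrics = metrics, smoothing_halfwidth = smoothing_halfwidth,
                 loss_window = loss_window, sub_regions = sub_regions,
                 seed = seed),
            class = "kelpwave_config")
}

#' Load a pipeline configuration from YAML
#'
#' Understands the fields of [run_config()]; year fields may be written as
#' vectors or `"first-last"` ranges.
#'
#' @param path YAML file path.
#' @return a `"kelpwave_config"` object.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  expand <- function(v) {
    if (is.character(v) && length(v) == 1L && grepl("-", v)) {
      parts <- as.integer(strsplit(v, "-")[[1L]])
      return(parts[1L]:parts[2L])
    }
    as.integer(v)
  }
  args <- list()
  for (f in c("period", "baseline_years", "reference_years", "loss_window"))
    if (!is.null(y[[f]])) args[[f]] <- expand(y[[f]])
  for (f in c("onset_year", "smoothing_halfwidth", "seed"))
    if (!is.null(y[[f]])) args[[f]] <- as.integer(y[[f]])
  for (f in c("metrics", "sub_regions"))
    if (!is.null(y[[f]])) args[[f]] <- as.character(y[[f]])
  do.call(run_config, args)
}
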