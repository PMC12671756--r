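# Baseline, loss, recovery and scaling statistics for annual canopy-area
# series. Units are hectares of floating kelp canopy per zone or sub-region
# and year. The pre-heatwave baseline is the 2011-2013 mean +/- sample s.d.

.check_canopy <- function(canopy) {
  stopifnot(is.data.frame(canopy))
  need <- c("zone_id", "survey_year", "species", "area_ha")
  miss <- setdiff(need, names(canopy))
  if (length(miss))
    stop("canopy table is missing columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(canopy$area_ha)) || any(canopy$area_ha < 0))
    stop("canopy areas must be finite and >= 0")
  key <- paste(canopy$zone_id, canopy$survey_year, canopy$species)
  if (anyDuplicated(key))
    stop("duplicate (zone_id, survey_year, species) rows in canopy table")
  canopy
}

#' Pre-heatwave baseline mean and s.d. of canopy area
#'
#' @param areas numeric vector of annual canopy areas (ha).
#' @param years integer years aligned with `areas`; defaults to
#'   `names(areas)`.
#' @param baseline_years years defining the baseline period (default
#'   2011:2013, the pre-heatwave reference).
#' @param unit label used in error messages.
#' @return list with `mean_ha`, `sd_ha` (sample s.d., n-1), `years_used`.
#' @export
baseline_stats <- function(areas, years = NULL, baseline_years = 2011:2013,
                           unit = "unit") {
  if (is.null(years)) years <- as.integer(names(areas))
  stopifnot(length(years) == length(areas))
  keep <- years %in% baseline_years & !is.na(areas)
  if (sum(keep) < 2L)
    stop("fewer than 2 baseline years with data for ", unit)
  list(mean_ha = mean(areas[keep]), sd_ha = sd(areas[keep]),
       years_used = sort(years[keep]))
}

#' Percent difference of canopy area from the baseline mean
#'
#' `100 * (area - baseline mean) / baseline mean`.
#'
#' @param area_ha canopy area(s) in hectares.
#' @param baseline baseline as returned by [baseline_stats()] (any list with
#'   a positive `mean_ha`).
#' @return numeric percent difference(s).
#' @export
percent_of_baseline <- function(area_ha, baseline) {
  m <- baseline$mean_ha
  if (!is.finite(m) || m <= 0) stop("baseline mean must be > 0")
  100 * (area_ha - m) / m
}

#' Fold difference between the lowest and highest canopy area
#'
#' The ratio max/min, conventionally reported to one decimal.
#'
#' @param min_ha,max_ha smallest and largest annual canopy area (ha).
#' @param digits decimals for reporting (default 1); `NULL` for full
#'   precision.
#' @return the ratio `max_ha / min_ha`.
#' @export
fold_difference <- function(min_ha, max_ha, digits = 1) {
  if (any(min_ha <= 0)) stop("fold difference undefined for a zero minimum")
  if (any(max_ha < min_ha)) stop("max_ha must be >= min_ha")
  r <- max_ha / min_ha
  if (is.null(digits)) r else round(r, digits)
}

#' Maximum canopy loss relative to the baseline mean
#'
#' Percent loss from the baseline mean down to the smallest area observed in
#' the loss window: `100 * (mean - min) / mean`, conventionally rounded to
#' the nearest integer percent.
#'
#' @param areas annual canopy areas (ha).
#' @param years years aligned with `areas`; defaults to `names(areas)`.
#' @param baseline list with `mean_ha` (see [baseline_stats()]).
#' @param loss_window years to search for the minimum (default 2014:2016,
#'   the heatwave years).
#' @param digits decimals for reporting (default 0); `NULL` for full
#'   precision.
#' @return percent loss.
#' @export
max_loss <- function(areas, years = NULL, baseline,
                     loss_window = 2014:2016, digits = 0) {
  if (is.null(years)) years <- as.integer(names(areas))
  keep <- years %in% loss_window & !is.na(areas)
  if (!any(keep)) stop("no canopy data within the loss window")
  if (!is.finite(baseline$mean_ha) || baseline$mean_ha <= 0)
    stop("baseline mean must be > 0")
  loss <- 100 * (baseline$mean_ha - min(areas[keep])) / baseline$mean_ha
  if (is.null(digits)) loss else round(loss, digits)
}

#' Decline and recovery year of a canopy series
#'
#' A unit declines in the first year at/after `onset_year` whose area falls
#' below `mean - sd` of the baseline, and recovers in the first later year
#' whose area returns to at least that threshold (one-sided). With
#' `symmetric = TRUE` recovery instead requires `|area - mean| < sd`, i.e.
#' a return into the baseline band.
#'
#' @param areas annual canopy areas (ha).
#' @param years years aligned with `areas`; defaults to `names(areas)`.
#' @param baseline list with `mean_ha` and `sd_ha` (see [baseline_stats()]).
#' @param onset_year first year considered for the decline (default 2014,
#'   the heatwave onset).
#' @param symmetric use the symmetric within-one-s.d. recovery rule.
#' @return list with `decline_year`, `recovery_year` (either `NA` when not
#'   reached) and `threshold_ha`.
#' @export
recovery_year <- function(areas, years = NULL, baseline, onset_year = 2014,
                          symmetric = FALSE) {
  if (is.null(years)) years <- as.integer(names(areas))
  stopifnot(length(years) == length(areas))
  o <- order(years); years <- years[o]; areas <- areas[o]
  thr <- baseline$mean_ha - baseline$sd_ha
  dec <- which(years >= onset_year & !is.na(areas) & areas < thr)
  decline_year <- if (length(dec)) years[dec[1L]] else NA_integer_
  rec_year <- NA_integer_
  if (!is.na(decline_year)) {
    ok <- if (symmetric) {
      abs(areas - baseline$mean_ha) < baseline$sd_ha
    } else {
      areas >= thr
    }
    rec <- which(years > decline_year & !is.na(areas) & ok)
    if (length(rec)) rec_year <- years[rec[1L]]
  }
  list(decline_year = decline_year, recovery_year = rec_year,
       threshold_ha = thr)
}

#' Scale canopy areas to the fraction of the zone maximum
#'
#' Divides each zone-species series by its maximum over the analysis period,
#' giving the regression response as a fraction of maximum observed canopy.
#' Values that land exactly on 0 or 1 are replaced with 0.01 and 0.99 so the
#' response stays strictly inside (0, 1).
#'
#' @param canopy canopy table (`zone_id`, `survey_year`, `species`,
#'   `area_ha`, optionally `sub_region`).
#' @param period years over which the maximum is taken and rows retained
#'   (default: all years present).
#' @return the input rows within `period` with an added `scaled` column.
#' @export
scale_to_max <- function(canopy, period = NULL) {
  canopy <- .check_canopy(canopy)
  if (!is.null(period)) canopy <- canopy[canopy$survey_year %in% period, ,
                                         drop = FALSE]
  if (!nrow(canopy)) stop("no canopy rows in the requested period")
  grp <- interaction(canopy$zone_id, canopy$species, drop = TRUE)
  mx <- ave(canopy$area_ha, grp, FUN = max)
  if (any(mx <= 0)) {
    bad <- unique(canopy$zone_id[mx <= 0])
    stop("cannot scale all-zero series for zone(s): ",
         paste(bad, collapse = ", "))
  }
  s <- canopy$area_ha / mx
  s[s == 0] <- 0.01
  s[s == 1] <- 0.99
  canopy$scaled <- s
  canopy
}

#' Correlation of annual canopy area between two species
#'
#' Pearson correlation over matched zone-year observations of the two
#' species, with the usual two-sided t-test.
#'
#' @param canopy canopy table.
#' @param species two species labels to pair (default giant and bull kelp).
#' @param period years included (default: all).
#' @return an object of class `"htest"` from [cor.test()].
#' @export
species_correlation <- function(canopy,
                                species = c("macrocystis", "nereocystis"),
                                period = NULL) {
  canopy <- .check_canopy(canopy)
  stopifnot(length(species) == 2L)
  if (!is.null(period)) canopy <- canopy[canopy$survey_year %in% period, ,
                                         drop = FALSE]
  a <- canopy[canopy$species == species[1L], c("zone_id", "survey_year", "area_ha")]
  b <- canopy[canopy$species == species[2L], c("zone_id", "survey_year", "area_ha")]
  key_a <- paste(a$zone_id, a$survey_year)
  key_b <- paste(b$zone_id, b$survey_year)
  pos <- match(key_a, key_b)
  keep <- !is.na(pos)
  x <- a$area_ha[keep]; y <- b$area_ha[pos[keep]]
  if (length(x) < 3L) stop("fewer than 3 matched zone-year pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance in one species' areas; correlation undefined")
  cor.test(x, y, method = "pearson")
}

#' Sub-region summary of canopy area, variability and heatwave loss
#'
#' Sums species within sub-region and year, then reports per sub-region the
#' minimum, maximum, fold difference, period mean +/- s.d., baseline mean
#' +/- s.d. and maximum percent loss in the loss window relative to the
#' baseline mean.
#'
#' @param canopy canopy table including a `sub_region` column.
#' @param period analysis years (default 2011:2018).
#' @param baseline_years baseline years (default 2011:2013).
#' @param loss_window years searched for the loss minimum (default
#'   2014:2016).
#' @return data.frame with one row per sub-region.
#' @export
canopy_summary_table <- function(canopy, period = 2011:2018,
                                 baseline_years = 2011:2013,
                                 loss_window = 2014:2016) {
  canopy <- .check_canopy(canopy)
  if (!"sub_region" %in% names(canopy))
    stop("canopy table needs a 'sub_region' column for the summary")
  canopy <- canopy[canopy$survey_year %in% period, , drop = FALSE]
  tot <- aggregate(area_ha ~ sub_region + survey_year, data = canopy, FUN = sum)
  res <- lapply(split(tot, tot$sub_region), function(d) {
    bl <- baseline_stats(d$area_ha, d$survey_year, baseline_years,
                         unit = d$sub_region[1L])
    data.frame(
      sub_region = d$sub_region[1L],
      min_ha = min(d$area_ha), max_ha = max(d$area_ha),
      fold_difference = fold_difference(min(d$area_ha), max(d$area_ha)),
      mean_ha = mean(d$area_ha), sd_ha = sd(d$area_ha),
      baseline_mean_ha = bl$mean_ha, baseline_sd_ha = bl$sd_ha,
      max_loss_pct = max_loss(d$area_ha, d$survey_year, bl, loss_window)
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
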