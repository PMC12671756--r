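# Annual marine-heatwave temperature metrics from daily SST records.
#
# All functions work on tidy per-zone daily series (zone_id, date, sst_c).
# The exposure year attributed to a canopy survey is the September-August
# "water year" ending in the survey year, so the 2014 metrics summarize
# September 2013 through August 2014.

#' Day of year with a 365-day calendar
#'
#' Maps calendar dates to day-of-year 1..365. In leap years February 29 is
#' folded onto day 59 (it shares February 28's climatology slot) and all
#' later days are shifted down by one, so every year has the same 365 slots.
#'
#' @param dates a `Date` vector (or anything coercible with [as.Date()]).
#' @return integer vector in 1..365.
#' @export
day_of_year_365 <- function(dates) {
  dates <- as.Date(dates)
  lt <- as.POSIXlt(dates)
  yd <- lt$yday + 1L
  yr <- lt$year + 1900L
  leap <- (yr %% 4 == 0 & yr %% 100 != 0) | yr %% 400 == 0
  ifelse(leap & yd >= 60L, yd - 1L, yd)
}

.check_sst <- function(sst) {
  stopifnot(is.data.frame(sst))
  need <- c("zone_id", "date", "sst_c")
  miss <- setdiff(need, names(sst))
  if (length(miss))
    stop("SST table is missing columns: ", paste(miss, collapse = ", "))
  sst$date <- as.Date(sst$date)
  if (anyNA(sst$date)) stop("SST table contains unparseable dates")
  if (any(!is.finite(sst$sst_c)))
    stop("SST values must be finite")
  if (any(sst$sst_c < -5 | sst$sst_c > 40))
    warning("SST values outside the sanity range [-5, 40] degC")
  dup <- duplicated(sst[c("zone_id", "date")])
  if (any(dup)) stop("duplicate (zone_id, date) rows in SST table")
  sst[order(sst$zone_id, sst$date), , drop = FALSE]
}

#' Build a day-of-year SST climatology
#'
#' For each zone and each of 365 day-of-year slots, averages all reference-year
#' observations whose day of year falls in a centered circular window of
#' `2 * smoothing_halfwidth + 1` days. With `smoothing_halfwidth = 0` this is
#' the plain day-of-year mean across reference years. A pre-computed
#' climatology table can be supplied downstream instead of using this builder.
#'
#' @param sst data.frame with columns `zone_id`, `date`, `sst_c`.
#' @param reference_years integer vector of years defining the baseline
#'   climate period.
#' @param smoothing_halfwidth half-width in days of the centered smoothing
#'   window (default 15, i.e. a 31-day window, standard practice for daily
#'   SST climatologies).
#' @return data.frame with columns `zone_id`, `day_of_year`, `clim_c`.
#' @export
build_climatology <- function(sst, reference_years, smoothing_halfwidth = 15L) {
  sst <- .check_sst(sst)
  stopifnot(smoothing_halfwidth >= 0)
  h <- as.integer(smoothing_halfwidth)
  yr <- as.POSIXlt(sst$date)$year + 1900L
  ref <- sst[yr %in% reference_years, , drop = FALSE]
  zones <- unique(sst$zone_id)
  out <- vector("list", length(zones))
  # circular window of day-of-year slots for each target day
  idx <- (outer(0:364, -h:h, `+`) %% 365L) + 1L
  for (i in seq_along(zones)) {
    z <- zones[i]
    zr <- ref[ref$zone_id == z, , drop = FALSE]
    if (nrow(zr) == 0L)
      stop("no SST data in reference years for zone '", z, "'")
    doy <- day_of_year_365(zr$date)
    by_doy <- split(zr$sst_c, factor(doy, levels = 1:365))
    # mean() over the pooled window observations (long-double accumulation,
    # so a window of identical values averages to exactly that value)
    clim <- vapply(1:365, function(d) {
      obs <- unlist(by_doy[idx[d, ]], use.names = FALSE)
      if (length(obs)) mean(obs) else NA_real_
    }, numeric(1))
    wcnt <- vapply(1:365, function(d)
      sum(lengths(by_doy[idx[d, ]])), numeric(1))
    expected <- length(reference_years) * (2L * h + 1L)
    if (any(wcnt == 0))
      warning("zone '", z, "': some day-of-year slots have no reference data")
    else if (any(wcnt < 0.5 * expected))
      warning("zone '", z, "': <50% reference coverage for some days of year")
    out[[i]] <- data.frame(zone_id = z, day_of_year = 1:365, clim_c = clim)
  }
  res <- do.call(rbind, out)
  attr(res, "reference_years") <- as.integer(reference_years)
  attr(res, "smoothing_halfwidth") <- h
  res
}

#' Daily SST anomalies against a climatology
#'
#' Subtracts the climatological mean for each observation's day of year:
#' `ssta = sst - clim(day_of_year)`.
#'
#' @param sst data.frame with columns `zone_id`, `date`, `sst_c`.
#' @param clim climatology as returned by [build_climatology()] (columns
#'   `day_of_year`, `clim_c`, and `zone_id` unless a single shared
#'   climatology is meant to apply to every zone).
#' @return the input table with an added `ssta` column.
#' @export
anomaly_series <- function(sst, clim) {
  sst <- .check_sst(sst)
  stopifnot(all(c("day_of_year", "clim_c") %in% names(clim)))
  doy <- day_of_year_365(sst$date)
  if ("zone_id" %in% names(clim)) {
    key <- paste(sst$zone_id, doy)
    ckey <- paste(clim$zone_id, clim$day_of_year)
    pos <- match(key, ckey)
  } else {
    pos <- match(doy, clim$day_of_year)
  }
  if (anyNA(pos))
    stop("climatology does not cover all (zone, day-of-year) pairs present")
  sst$ssta <- sst$sst_c - clim$clim_c[pos]
  sst
}

#' September-August exposure window for a survey year
#'
#' @param survey_year integer survey year.
#' @return list with `survey_year`, `start` (Sep 1 of the previous year) and
#'   `end` (Aug 31 of the survey year).
#' @export
water_year_window <- function(survey_year) {
  survey_year <- as.integer(survey_year)
  list(survey_year = survey_year,
       start = as.Date(sprintf("%d-09-01", survey_year - 1L)),
       end   = as.Date(sprintf("%d-08-31", survey_year)))
}

.months_in_window <- function(survey_year) {
  # ordered Sep (previous year) .. Aug (survey year)
  m <- c(9:12, 1:8)
  y <- c(rep(survey_year - 1L, 4), rep(survey_year, 8))
  sprintf("%d-%02d", y, m)
}

#' Monthly means of a daily series within an exposure window
#'
#' @param dates,values daily observation dates and values for one zone.
#' @param survey_year survey year defining the September-August window.
#' @return data.frame with one row per calendar month Sep..Aug: `month`
#'   (`"YYYY-MM"`), `mean` (NA when the month has no data), `n_days`.
#' @export
monthly_summaries <- function(dates, values, survey_year) {
  dates <- as.Date(dates)
  w <- water_year_window(survey_year)
  keep <- !is.na(values) & dates >= w$start & dates <= w$end
  if (!any(keep))
    stop("no observations in the ", survey_year, " exposure window")
  d <- dates[keep]; v <- values[keep]
  mk <- format(d, "%Y-%m")
  months <- .months_in_window(w$survey_year)
  mean_v <- vapply(months, function(m) {
    x <- v[mk == m]
    if (length(x)) mean(x) else NA_real_
  }, numeric(1))
  n_v <- vapply(months, function(m) sum(mk == m), integer(1))
  data.frame(month = months, mean = unname(mean_v), n_days = unname(n_v))
}

#' Warmest-month mean SST within an exposure window
#'
#' Returns the largest monthly mean SST over the September-August window and
#' the month that attains it; ties go to the earliest month in the window.
#'
#' @inheritParams monthly_summaries
#' @param sst daily SST values.
#' @return list with `month` (`"YYYY-MM"`) and `warmest_month_mean_sst`.
#' @export
metric_warmest_month <- function(dates, sst, survey_year) {
  ms <- monthly_summaries(dates, sst, survey_year)
  if (all(is.na(ms$mean))) stop("no month with data in window")
  i <- which.max(ms$mean)  # first maximum = earliest month on ties
  list(month = ms$month[i], warmest_month_mean_sst = ms$mean[i])
}

#' Maximum monthly mean SST anomaly within an exposure window
#'
#' Monthly means of the daily anomalies are computed for each calendar month
#' of the September-August window; the metric is the maximum across months.
#'
#' @inheritParams monthly_summaries
#' @param ssta daily SST anomaly values.
#' @return numeric scalar (degC).
#' @export
metric_max_monthly_ssta <- function(dates, ssta, survey_year) {
  ms <- monthly_summaries(dates, ssta, survey_year)
  if (all(is.na(ms$mean))) stop("no month with data in window")
  max(ms$mean, na.rm = TRUE)
}

#' Count of days with positive SST anomaly within an exposure window
#'
#' Days with anomaly strictly above zero; missing days are simply not
#' counted.
#'
#' @inheritParams metric_max_monthly_ssta
#' @return integer count.
#' @export
metric_days_positive <- function(dates, ssta, survey_year) {
  dates <- as.Date(dates)
  w <- water_year_window(survey_year)
  keep <- !is.na(ssta) & dates >= w$start & dates <= w$end
  sum(ssta[keep] > 0)
}

#' Annual temperature metrics for every zone and survey year
#'
#' Computes the three exposure metrics (warmest-month mean SST, maximum
#' monthly SST anomaly, days with positive anomaly) over the
#' September-August window preceding each survey. When a `zone_cells`
#' mapping is supplied, metrics are computed once per SST grid cell and
#' every zone mapped to that cell receives identical values.
#'
#' @param sst daily SST table (`zone_id`, `date`, `sst_c`). With a
#'   `zone_cells` mapping the `zone_id` column may hold either zone ids or
#'   cell ids.
#' @param clim climatology table (see [build_climatology()]).
#' @param survey_years integer vector of survey years.
#' @param zone_cells optional data.frame `zone_id`, `cell_id` mapping zones
#'   (many) to SST grid cells (one).
#' @param min_coverage windows with a smaller fraction of days available are
#'   flagged via a message (default 0.8); they are still computed.
#' @return data.frame with columns `zone_id`, `survey_year`, `warmest_month`,
#'   `warmest_month_mean_sst`, `max_monthly_ssta`, `days_ssta_positive`,
#'   `n_days_available`.
#' @export
compute_annual_metrics <- function(sst, clim, survey_years, zone_cells = NULL,
                                   min_coverage = 0.8) {
  an <- anomaly_series(sst, clim)
  series_ids <- unique(an$zone_id)
  rows <- list()
  for (sid in series_ids) {
    zs <- an[an$zone_id == sid, , drop = FALSE]
    if (nrow(zs) == 0L) next
    for (y in survey_years) {
      w <- water_year_window(y)
      n_window <- as.integer(w$end - w$start) + 1L
      res <- tryCatch({
        wm <- metric_warmest_month(zs$date, zs$sst_c, y)
        mssta <- metric_max_monthly_ssta(zs$date, zs$ssta, y)
        ndays <- sum(zs$date >= w$start & zs$date <= w$end &
                       !is.na(zs$sst_c))
        if (ndays < min_coverage * n_window)
          message("zone/cell '", sid, "', year ", y, ": only ", ndays, "/",
                  n_window, " days available")
        data.frame(zone_id = sid, survey_year = y,
                   warmest_month = wm$month,
                   warmest_month_mean_sst = wm$warmest_month_mean_sst,
                   max_monthly_ssta = mssta,
                   days_ssta_positive = metric_days_positive(zs$date, zs$ssta, y),
                   n_days_available = as.integer(ndays))
      }, error = function(e) {
        message("zone/cell '", sid, "', year ", y, ": skipped (",
                conditionMessage(e), ")")
        NULL
      })
      if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    }
  }
  if (!length(rows)) {
    warning("no metric rows could be computed")
    return(data.frame(zone_id = character(), survey_year = integer(),
                      warmest_month = character(),
                      warmest_month_mean_sst = numeric(),
                      max_monthly_ssta = numeric(),
                      days_ssta_positive = integer(),
                      n_days_available = integer()))
  }
  out <- do.call(rbind, rows)
  if (!is.null(zone_cells)) {
    stopifnot(all(c("zone_id", "cell_id") %in% names(zone_cells)))
    keep <- zone_cells$cell_id %in% out$zone_id
    # one block of rows per zone, all copied from its cell
    blocks <- lapply(which(keep), function(i) {
      b <- out[out$zone_id == zone_cells$cell_id[i], , drop = FALSE]
      b$zone_id <- zone_cells$zone_id[i]
      b
    })
    out <- do.call(rbind, blocks)
  }
  rownames(out) <- NULL
  out
}
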