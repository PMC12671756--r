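# Synthetic daily SST and canopy tables with known ground truth. The SST
# generator is a seasonal cosine plus stationary AR(1) noise with boxcar
# heatwave events added on top; the canopy generator draws scaled areas from
# the same beta-regression model the package fits, so parameter recovery can
# be checked end to end.

#' Simulate daily SST series
#'
#' `sst(t) = mean_sst + seasonal_amplitude * cos(2 pi (doy(t) - peak_day) / 365)
#'  + AR(1) noise + sum of active event intensities`. The AR(1) noise has
#' stationary standard deviation `noise_sd` and lag-one correlation
#' `ar1`; events add a constant intensity over `duration_days` starting at
#' `start`. Output is reproducible given `seed`.
#'
#' @param zone_ids character vector of series identifiers (zones or SST
#'   grid cells).
#' @param years calendar years covered (daily from Jan 1 to Dec 31).
#' @param mean_sst,seasonal_amplitude annual mean and seasonal half-range
#'   (degC); either scalars or one value per zone.
#' @param peak_day day of year of the seasonal maximum (default 227,
#'   mid-August).
#' @param ar1 lag-one autocorrelation of the noise, in \[0, 1).
#' @param noise_sd stationary s.d. of the noise (degC).
#' @param events optional data.frame with columns `start` (date),
#'   `duration_days`, `intensity_c` and optionally `zone_id` (events
#'   without a `zone_id` apply to every zone).
#' @param seed RNG seed.
#' @return data.frame `zone_id`, `date`, `sst_c`.
#' @export
simulate_sst <- function(zone_ids = "Z1", years = 2011:2018,
                         mean_sst = 10, seasonal_amplitude = 3,
                         peak_day = 227, ar1 = 0.8, noise_sd = 0.5,
                         events = NULL, seed = 1) {
  stopifnot(noise_sd >= 0, ar1 >= 0, ar1 < 1)
  if (!is.null(events))
    stopifnot(all(c("start", "duration_days", "intensity_c") %in%
                    names(events)), all(events$duration_days >= 1))
  set.seed(seed)
  dates <- seq(as.Date(sprintf("%d-01-01", min(years))),
               as.Date(sprintf("%d-12-31", max(years))), by = "day")
  nd <- length(dates)
  doy <- day_of_year_365(dates)
  mean_sst <- rep_len(mean_sst, length(zone_ids))
  seasonal_amplitude <- rep_len(seasonal_amplitude, length(zone_ids))
  out <- vector("list", length(zone_ids))
  for (i in seq_along(zone_ids)) {
    base <- mean_sst[i] +
      seasonal_amplitude[i] * cos(2 * pi * (doy - peak_day) / 365)
    if (noise_sd > 0) {
      innov <- rnorm(nd, sd = noise_sd * sqrt(1 - ar1^2))
      innov[1L] <- rnorm(1, sd = noise_sd)  # start the chain at stationarity
      noise <- as.numeric(stats::filter(innov, ar1, method = "recursive"))
    } else noise <- numeric(nd)
    sst <- base + noise
    if (!is.null(events)) {
      ev <- events
      if ("zone_id" %in% names(ev))
        ev <- ev[is.na(ev$zone_id) | ev$zone_id == zone_ids[i], , drop = FALSE]
      for (j in seq_len(nrow(ev))) {
        s <- as.Date(ev$start[j])
        act <- dates >= s & dates < s + ev$duration_days[j]
        sst[act] <- sst[act] + ev$intensity_c[j]
      }
    }
    out[[i]] <- data.frame(zone_id = zone_ids[i], date = dates, sst_c = sst)
  }
  do.call(rbind, out)
}

#' Simulate canopy areas from a known beta-regression relationship
#'
#' Standardizes the chosen temperature metric (z-score within `sub_region`
#' when that column is present, otherwise overall), forms
#' `mu = inverse link(beta0 + beta1 * z)` with the Cauchy link, draws the
#' scaled response from `Beta(mu phi, (1 - mu) phi)` and converts it to
#' hectares with a per-zone baseline scale. The generating parameters are
#' returned alongside the table so estimators can be checked against truth.
#'
#' @param metrics annual metrics table from [compute_annual_metrics()]
#'   (optionally with a `sub_region` column).
#' @param metric name of the metric column used as the covariate.
#' @param beta0,beta1 intercept and slope of the mean submodel on the
#'   standardized metric (Cauchy link scale).
#' @param phi beta precision (> 0).
#' @param baseline_ha per-zone canopy scale in hectares (scalar or named by
#'   zone).
#' @param species species label written to the table.
#' @param seed RNG seed.
#' @return list with `canopy` (a canopy table with the true `scaled` draw
#'   retained) and `truth` (generating parameters plus the metric
#'   standardization used).
#' @export
simulate_canopy <- function(metrics, metric = "warmest_month_mean_sst",
                            beta0 = 0.3, beta1 = -0.8, phi = 20,
                            baseline_ha = 100, species = "nereocystis",
                            seed = 1) {
  stopifnot(phi > 0, metric %in% names(metrics))
  set.seed(seed)
  x <- metrics[[metric]]
  if ("sub_region" %in% names(metrics)) {
    mu_x <- ave(x, metrics$sub_region, FUN = mean)
    sd_x <- ave(x, metrics$sub_region, FUN = sd)
  } else {
    mu_x <- mean(x); sd_x <- sd(x)
  }
  sd_x[sd_x == 0] <- 1
  z <- (x - mu_x) / sd_x
  mu <- inverse_cauchy_link(beta0 + beta1 * z)
  scaled <- rbeta(length(mu), mu * phi, (1 - mu) * phi)
  scale_ha <- if (is.null(names(baseline_ha))) {
    rep_len(baseline_ha, nrow(metrics))
  } else baseline_ha[metrics$zone_id]
  canopy <- data.frame(zone_id = metrics$zone_id,
                       survey_year = metrics$survey_year,
                       species = species,
                       area_ha = scaled * scale_ha,
                       scaled = scaled)
  if ("sub_region" %in% names(metrics))
    canopy$sub_region <- metrics$sub_region
  list(canopy = canopy,
       truth = list(beta0 = beta0, beta1 = beta1, phi = phi,
                    metric = metric, center = mu_x, scale = sd_x,
                    mu = mu, seed = seed))
}

#' A miniature synthetic study region
#'
#' Builds a self-contained bundle mimicking the structure of the study:
#' six sub-regions ordered from the open coast inland, each with its own
#' SST grid cell and about ten zones, daily SST for 1989-2021 with a
#' 2014-2016 heatwave block whose intensity and duration escalate inland,
#' and canopy tables generated from a known negative relationship between
#' scaled canopy and the warmest-month metric. Everything is reproducible
#' from `seed`.
#'
#' @param seed RNG seed.
#' @param years calendar years of SST coverage.
#' @param n_zones zones per sub-region.
#' @param beta1 true slope of scaled canopy on the standardized
#'   warmest-month metric (negative: warmer years mean less canopy).
#' @param phi beta precision of the canopy draws.
#' @return list with `sst` (daily SST per cell), `zones` (zone_id,
#'   sub_region, cell_id, x, y), `zone_cells`, `canopy`, `events`,
#'   `reference_years`, `truth`.
#' @export
make_fixture <- function(seed = 42, years = 1989:2021, n_zones = 10,
                         beta1 = -0.8, phi = 50) {
  regions <- c("Open Coast", "Western Strait", "Eastern Strait",
               "Smith & Minor Island AR", "Cypress Island AR",
               "Cherry Point AR")
  cells <- paste0("cell_", seq_along(regions))
  set.seed(seed)
  # heatwave block: onset spring 2014, longer and hotter toward the inland end
  events <- data.frame(
    zone_id = cells,
    start = as.Date("2014-03-01"),
    duration_days = 270 + 150 * (seq_along(regions) - 1L),
    intensity_c = 1.2 + 0.4 * (seq_along(regions) - 1L)
  )
  sst <- simulate_sst(cells, years,
                      mean_sst = 9.5 + 0.4 * (seq_along(regions) - 1L),
                      seasonal_amplitude = 2.5 + 0.3 * (seq_along(regions) - 1L),
                      ar1 = 0.8, noise_sd = 0.4, events = events,
                      seed = seed)
  zones <- do.call(rbind, lapply(seq_along(regions), function(i) {
    data.frame(
      zone_id = sprintf("%s_z%02d", gsub("[^A-Za-z]", "", regions[i]), 1:n_zones),
      sub_region = regions[i], cell_id = cells[i],
      x = i * 50000 + runif(n_zones, 0, 20000),
      y = runif(n_zones, 0, 30000)
    )
  }))
  zone_cells <- zones[, c("zone_id", "cell_id")]
  reference_years <- years[seq_len(min(7L, length(years)))]
  clim <- build_climatology(sst, reference_years)
  metrics <- compute_annual_metrics(sst, clim,
                                    survey_years = 2011:2018,
                                    zone_cells = zone_cells)
  metrics$sub_region <- zones$sub_region[match(metrics$zone_id, zones$zone_id)]
  baseline_ha <- setNames(round(runif(nrow(zones), 20, 120)), zones$zone_id)
  sim <- simulate_canopy(metrics, metric = "warmest_month_mean_sst",
                         beta0 = 0.5, beta1 = beta1, phi = phi,
                         baseline_ha = baseline_ha, seed = seed + 1L)
  canopy <- sim$canopy
  # coast and western strait carry both species; split the combined area
  two_sp <- canopy$sub_region %in% regions[1:2]
  share <- pmin(pmax(rnorm(sum(two_sp), 0.4, 0.05), 0.1), 0.7)
  macro <- canopy[two_sp, , drop = FALSE]
  macro$species <- "macrocystis"
  macro$area_ha <- macro$area_ha * share
  nere <- canopy[two_sp, , drop = FALSE]
  nere$area_ha <- nere$area_ha * (1 - share)
  canopy <- rbind(canopy[!two_sp, , drop = FALSE], macro, nere)
  canopy$scaled <- NULL
  rownames(canopy) <- NULL
  list(sst = sst, zones = zones, zone_cells = zone_cells, canopy = canopy,
       metrics = metrics, events = events,
       reference_years = reference_years, truth = sim$truth)
}
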