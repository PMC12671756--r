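# Climatology, anomalies and the three annual temperature metrics.

make_daily <- function(zone, dates, sst) {
  data.frame(zone_id = zone, date = as.Date(dates), sst_c = sst)
}

test_that("climatology of a constant series is that constant", {
  dates <- seq(as.Date("2010-01-01"), as.Date("2012-12-31"), by = "day")
  sst <- make_daily("A", dates, 10)
  cl <- build_climatology(sst, 2010:2012, smoothing_halfwidth = 15)
  expect_equal(nrow(cl), 365)
  expect_true(all(cl$clim_c == 10))
})

test_that("climatology recovers a periodic cycle and hand averages", {
  dates <- seq(as.Date("2010-01-01"), as.Date("2011-12-31"), by = "day")
  doy <- day_of_year_365(dates)
  cycle <- 10 + 3 * sin(2 * pi * doy / 365)
  cl <- build_climatology(make_daily("A", dates, cycle), 2010:2011,
                          smoothing_halfwidth = 0)
  expect_equal(cl$clim_c, 10 + 3 * sin(2 * pi * (1:365) / 365))

  # two reference years offset by 2 average to the midpoint
  v <- ifelse(format(as.Date(dates), "%Y") == "2010", 8, 10)
  cl2 <- build_climatology(make_daily("A", dates, v), 2010:2011, 0)
  expect_true(all(cl2$clim_c == 9))
})

test_that("climatology errors without reference data and warns on gaps", {
  dates <- seq(as.Date("2010-01-01"), as.Date("2010-12-31"), by = "day")
  sst <- make_daily("A", dates, 10)
  expect_error(build_climatology(sst, 1990:1995), "no SST data")
  # half the days missing triggers the coverage warning
  expect_warning(build_climatology(sst[seq(1, nrow(sst), 4), ], 2010, 0),
                 "no reference data")
})

test_that("anomalies are exact differences and zero against self", {
  s <- event_sst()
  cl <- build_climatology(s, 2010:2012, 0)
  an <- anomaly_series(s, cl)
  in_event <- an$date >= as.Date("2014-06-01") & an$date < as.Date("2014-07-01")
  expect_true(all(an$ssta[!in_event] == 0))
  expect_equal(an$ssta[in_event], rep(2, 30), tolerance = 1e-12)

  # one-off subtraction
  cl1 <- data.frame(day_of_year = 1:365, clim_c = 10)
  one <- make_daily("A", "2014-03-05", 12.5)
  expect_equal(anomaly_series(one, cl1)$ssta, 2.5)
})

test_that("day-of-year folds Feb 29 onto day 59", {
  expect_equal(day_of_year_365(as.Date(c("2012-02-28", "2012-02-29",
                                         "2012-03-01", "2012-12-31"))),
               c(59, 59, 60, 365))
  expect_equal(day_of_year_365(as.Date("2013-12-31")), 365)
})

test_that("monthly summaries average available days and flag gaps", {
  sep <- seq(as.Date("2013-09-01"), as.Date("2013-09-30"), by = "day")
  vals <- rep(c(10, 12), 15)
  ms <- monthly_summaries(sep, vals, 2014)
  expect_equal(ms$mean[ms$month == "2013-09"], 11)
  expect_true(all(is.na(ms$mean[ms$month != "2013-09"])))
  expect_error(monthly_summaries(sep, vals, 2016), "no observations")

  # a fully missing month stays missing while others are computed
  dates <- seq(as.Date("2013-09-01"), as.Date("2014-08-31"), by = "day")
  keep <- format(dates, "%Y-%m") != "2013-10"
  ms2 <- monthly_summaries(dates[keep], rep(7, sum(keep)), 2014)
  expect_true(is.na(ms2$mean[ms2$month == "2013-10"]))
  expect_true(all(ms2$mean[ms2$month != "2013-10"] == 7))
})

test_that("warmest month picks the maximum and breaks ties earliest", {
  dates <- seq(as.Date("2013-09-01"), as.Date("2014-08-31"), by = "day")
  wm <- metric_warmest_month(dates, rep(10, length(dates)), 2014)
  expect_equal(wm$month, "2013-09")
  expect_equal(wm$warmest_month_mean_sst, 10)

  sst <- ifelse(format(dates, "%Y-%m") == "2014-02", 15, 12)
  wm2 <- metric_warmest_month(dates, sst, 2014)
  expect_equal(wm2$month, "2014-02")
  expect_equal(wm2$warmest_month_mean_sst, 15)

  # a seasonal cycle peaking mid-August has August as warmest month
  s <- simulate_sst("A", 2013:2014, noise_sd = 0, peak_day = 227, seed = 1)
  wm3 <- metric_warmest_month(s$date, s$sst_c, 2014)
  expect_equal(wm3$month, "2014-08")
})

test_that("max monthly anomaly and positive-day count follow definitions", {
  dates <- seq(as.Date("2013-09-01"), as.Date("2014-08-31"), by = "day")
  zero <- rep(0, length(dates))
  expect_equal(metric_max_monthly_ssta(dates, zero, 2014), 0)
  expect_equal(metric_days_positive(dates, zero, 2014), 0)  # strict > 0

  ssta <- ifelse(format(dates, "%Y-%m") == "2014-06", 2, 0)
  expect_equal(metric_max_monthly_ssta(dates, ssta, 2014), 2)
  expect_equal(metric_days_positive(dates, ssta, 2014), 30)

  neg <- ifelse(format(dates, "%Y-%m") == "2014-06", -0.5, -1.5)
  expect_equal(metric_max_monthly_ssta(dates, neg, 2014), -0.5)
  expect_equal(metric_days_positive(dates, rep(0.1, length(dates)), 2014),
               365)
})

test_that("metric invariants hold on noisy series", {
  s <- simulate_sst("A", 2010:2015, ar1 = 0.6, noise_sd = 0.7, seed = 8)
  cl <- build_climatology(s, 2010:2012)
  an <- anomaly_series(s, cl)
  for (y in 2013:2015) {
    w <- water_year_window(y)
    inw <- an$date >= w$start & an$date <= w$end
    expect_lte(metric_max_monthly_ssta(an$date, an$ssta, y),
               max(an$ssta[inw]))
    expect_lte(metric_warmest_month(an$date, an$sst_c, y)$warmest_month_mean_sst,
               max(an$sst_c[inw]))
  }
  # positive-day count is invariant to shifting both series and climatology
  s2 <- s; s2$sst_c <- s2$sst_c + 5
  cl2 <- cl; cl2$clim_c <- cl2$clim_c + 5
  an2 <- anomaly_series(s2, cl2)
  expect_equal(metric_days_positive(an2$date, an2$ssta, 2014),
               metric_days_positive(an$date, an$ssta, 2014))
  # determinism
  expect_identical(compute_annual_metrics(s, cl, 2013:2015),
                   compute_annual_metrics(s, cl, 2013:2015))
})

test_that("zones sharing a grid cell receive identical metrics", {
  s <- simulate_sst("cellA", 2010:2015, ar1 = 0.5, noise_sd = 0.5, seed = 2)
  cl <- build_climatology(s, 2010:2012)
  zc <- data.frame(zone_id = c("z1", "z2", "z3"), cell_id = "cellA")
  m <- compute_annual_metrics(s, cl, 2013:2015, zone_cells = zc)
  expect_setequal(unique(m$zone_id), c("z1", "z2", "z3"))
  m1 <- m[m$zone_id == "z1", -1]
  m2 <- m[m$zone_id == "z2", -1]
  rownames(m1) <- rownames(m2) <- NULL
  expect_identical(m1, m2)
})

test_that("per-window metrics table matches hand loops over the oracles", {
  s <- simulate_sst("A", 2010:2016, ar1 = 0.4, noise_sd = 0.6,
                    events = data.frame(start = as.Date("2014-05-01"),
                                        duration_days = 60, intensity_c = 1.5),
                    seed = 4)
  cl <- build_climatology(s, 2010:2012)
  an <- anomaly_series(s, cl)
  m <- compute_annual_metrics(s, cl, 2013:2016)
  for (y in 2013:2016) {
    row <- m[m$survey_year == y, ]
    expect_equal(row$warmest_month_mean_sst,
                 metric_warmest_month(an$date, an$sst_c, y)$warmest_month_mean_sst)
    expect_equal(row$max_monthly_ssta,
                 metric_max_monthly_ssta(an$date, an$ssta, y))
    expect_equal(row$days_ssta_positive,
                 metric_days_positive(an$date, an$ssta, y))
  }
})
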