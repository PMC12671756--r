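# Top-level analysis: temperature metrics -> canopy response statistics ->
# per-sub-region beta regressions for each metric -> diagnostics, with an
# optional directory of tidy CSV outputs.

.stage_msg <- function(stage, t0) {
  message(sprintf("[%s] done in %.2fs", stage,
                  as.numeric(proc.time()[3] - t0)))
}

#' Run the full canopy-vs-temperature analysis
#'
#' Chains the pipeline stages: builds (or accepts) a climatology, computes
#' the three annual temperature metrics per zone, summarizes canopy
#' baselines, losses and recovery per sub-region, scales zone-level canopy
#' to the fraction of maximum, fits a beta regression of scaled canopy on
#' each standardized metric per sub-region (constant precision, plus the
#' varying-precision fit for the misspecification test), and runs the
#' Breusch-Pagan and Moran's I diagnostics. The covariate is z-scored
#' within sub-region before fitting so slopes are comparable across
#' metrics.
#'
#' @param config a [run_config()] list.
#' @param sst daily SST table (or result of [read_sst_csv()]).
#' @param canopy canopy table with `sub_region` column.
#' @param zones optional centroid table (`zone_id`, `x`, `y`) for Moran's I.
#' @param zone_cells optional zone-to-cell mapping.
#' @param climatology optional pre-computed climatology table; built from
#'   `config$reference_years` when absent.
#' @param out_dir optional directory; when given, tidy CSVs (`metrics.csv`,
#'   `summary_table.csv`, `response.csv`, `recovery.csv`, `scaled.csv`,
#'   `regressions.csv`, `diagnostics.csv`) are written there.
#' @return list with elements `metrics`, `summary_table`, `response`,
#'   `recovery`, `scaled`, `regressions` (one row per sub-region x metric),
#'   `moran`, `fits` (the fitted model objects) and `config`.
#' @export
run_pipeline <- function(config, sst, canopy, zones = NULL,
                         zone_cells = NULL, climatology = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "kelpwave_config"))

  t0 <- proc.time()[3]
  if (is.null(climatology))
    climatology <- build_climatology(sst, config$reference_years,
                                     config$smoothing_halfwidth)
  metrics <- compute_annual_metrics(sst, climatology, config$period,
                                    zone_cells = zone_cells)
  .stage_msg("metrics", t0)

  t0 <- proc.time()[3]
  canopy <- .check_canopy(canopy)
  canopy <- canopy[canopy$survey_year %in% config$period, , drop = FALSE]
  if (!is.null(config$sub_regions))
    canopy <- canopy[canopy$sub_region %in% config$sub_regions, , drop = FALSE]
  summary_table <- canopy_summary_table(canopy, config$period,
                                        config$baseline_years,
                                        config$loss_window)
  tot <- aggregate(area_ha ~ sub_region + survey_year, canopy, sum)
  response <- do.call(rbind, lapply(split(tot, tot$sub_region), function(d) {
    bl <- baseline_stats(d$area_ha, d$survey_year, config$baseline_years,
                         unit = d$sub_region[1L])
    data.frame(sub_region = d$sub_region, survey_year = d$survey_year,
               area_ha = d$area_ha,
               pct_of_baseline = percent_of_baseline(d$area_ha, bl))
  }))
  recovery <- do.call(rbind, lapply(split(tot, tot$sub_region), function(d) {
    bl <- baseline_stats(d$area_ha, d$survey_year, config$baseline_years,
                         unit = d$sub_region[1L])
    r <- recovery_year(d$area_ha, d$survey_year, bl, config$onset_year)
    data.frame(sub_region = d$sub_region[1L],
               decline_year = r$decline_year, recovery_year = r$recovery_year,
               threshold_ha = r$threshold_ha)
  }))
  rownames(response) <- rownames(recovery) <- NULL

  # zone-level combined-species series for the regressions
  comb <- aggregate(area_ha ~ zone_id + sub_region + survey_year, canopy, sum)
  comb$species <- "combined"
  scaled <- scale_to_max(comb, config$period)
  .stage_msg("response", t0)

  t0 <- proc.time()[3]
  dat <- merge(scaled, metrics, by = c("zone_id", "survey_year"))
  reg_rows <- list(); fits <- list()
  for (sr in unique(dat$sub_region)) {
    d <- dat[dat$sub_region == sr, , drop = FALSE]
    sub_fits <- list()
    for (m in config$metrics) {
      d$x <- as.numeric(scale(d[[m]]))
      fit <- tryCatch(kelpbeta(scaled ~ x, data = d), error = function(e) NULL)
      if (is.null(fit) || !fit$converged) {
        message("regression skipped for '", sr, "' x ", m,
                " (no converged fit)")
        next
      }
      fitv <- tryCatch(kelpbeta(scaled ~ x | x, data = d),
                       error = function(e) NULL)
      lr_p <- if (!is.null(fitv) && fitv$converged)
        lrtest_precision(fit, fitv)$p.value else NA_real_
      bp_p <- tryCatch(breusch_pagan(scaled ~ x, d)$p.value,
                       error = function(e) NA_real_)
      sub_fits[[m]] <- fit
      reg_rows[[paste(sr, m)]] <- data.frame(
        sub_region = sr, metric = m, n = fit$n,
        slope = unname(coef(fit, "mean")[2L]),
        slope_p = unname(fit$p[2L]),
        pseudo_r2 = fit$pseudo_r2, aic = fit$aic,
        bp_p = bp_p, lr_phi_p = lr_p
      )
    }
    if (length(sub_fits)) {
      cmp <- compare_models(sub_fits)
      for (m in names(sub_fits)) {
        reg_rows[[paste(sr, m)]]$delta_aic <-
          cmp$delta_aic[cmp$model == m]
        reg_rows[[paste(sr, m)]]$co_best <- cmp$co_best[cmp$model == m]
      }
      fits[[sr]] <- sub_fits
    }
  }
  regressions <- if (length(reg_rows)) do.call(rbind, reg_rows) else
    data.frame()
  rownames(regressions) <- NULL
  .stage_msg("regress", t0)

  t0 <- proc.time()[3]
  moran <- NULL
  if (!is.null(zones)) {
    zone_mean <- aggregate(scaled ~ zone_id + sub_region, dat, mean)
    moran <- do.call(rbind, lapply(split(zone_mean, zone_mean$sub_region),
                                   function(zm) {
      if (nrow(zm) < 3L) {
        message("Moran's I skipped for '", zm$sub_region[1L],
                "' (<3 zones)")
        return(NULL)
      }
      co <- zones[match(zm$zone_id, zones$zone_id), , drop = FALSE]
      res <- tryCatch({
        w <- inverse_distance_weights(co)
        morans_i(zm$scaled, w)
      }, error = function(e) {
        message("Moran's I skipped for '", zm$sub_region[1L], "' (",
                conditionMessage(e), ")")
        NULL
      })
      if (is.null(res)) return(NULL)
      data.frame(sub_region = zm$sub_region[1L], n_zones = nrow(zm),
                 moran_i = unname(res$statistic),
                 expectation = unname(res$parameter["expectation"]),
                 p_value = res$p.value)
    }))
    rownames(moran) <- NULL
  }
  .stage_msg("diagnose", t0)

  out <- list(metrics = metrics, summary_table = summary_table,
              response = response, recovery = recovery, scaled = scaled,
              regressions = regressions, moran = moran, fits = fits,
              config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, f) if (!is.null(df) && nrow(df))
      write.csv(df, file.path(out_dir, f), row.names = FALSE)
    wr(metrics, "metrics.csv"); wr(summary_table, "summary_table.csv")
    wr(response, "response.csv"); wr(recovery, "recovery.csv")
    wr(scaled, "scaled.csv"); wr(regressions, "regressions.csv")
    wr(moran, "diagnostics.csv")
  }
  out
}
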