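#' Pipeline configuration
#'
#' Collects every tunable of the analysis in one list. Defaults reproduce
#' the reference settings: scales 1/3/6/9 months, stages S1/S2/S3,
#' significance level 0.05, AR(1) policy "auto" with DW bounds 1.5/2.5,
#' decade periods 1980-1989 / 1990-1999 / 2000-2014, full-record
#' calibration.
#'
#' @param scales SPEI time scales in months.
#' @param stage_scales Scales used for the stage correlation table.
#' @param panel_scale Scale of the covariate entering the panel model.
#' @param panel_stage Stage of the covariate entering the panel model.
#' @param calibration_years Years for the distribution fits (NULL = all).
#' @param ar1 AR(1) policy for [fit_panel()].
#' @param dw_bounds DW bounds for the "auto" policy.
#' @param periods Named list of year vectors for [decade_summary()].
#' @param alpha Significance level for trend and correlation tests.
#' @param seed Integer seed recorded in the manifest.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(scales = c(1, 3, 6, 9), stage_scales = c(1, 3),
                            panel_scale = 3, panel_stage = "S3",
                            calibration_years = NULL,
                            ar1 = "auto", dw_bounds = c(1.5, 2.5),
                            periods = list("1980s" = 1980:1989,
                                           "1990s" = 1990:1999,
                                           "2000s" = 2000:2014),
                            alpha = 0.05, seed = 1L) {
  structure(list(scales = scales, stage_scales = stage_scales,
                 panel_scale = panel_scale, panel_stage = panel_stage,
                 calibration_years = calibration_years, ar1 = ar1,
                 dw_bounds = dw_bounds, periods = periods, alpha = alpha,
                 seed = seed),
            class = "pipeline_config")
}

#' Read / write the long-format interchange CSVs
#'
#' Climate CSV columns: site, latitude, year, month, tmean_c, precip_mm.
#' Yield CSV columns: site, year, yield_t_ha. Readers validate the schema;
#' the climate reader additionally checks for gaps.
#'
#' @param path File path.
#' @return The validated data.frame.
#' @export
read_climate_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("site", "latitude", "year", "month", "tmean_c",
                      "precip_mm"), basename(path))
  validate_climate(df)
  df
}

#' @rdname read_climate_csv
#' @export
read_yield_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("site", "year", "yield_t_ha"), basename(path))
  if (any(!is.finite(df$yield_t_ha)) || any(df$yield_t_ha <= 0)) {
    stop_invalid("%s: yields must be positive and finite", basename(path))
  }
  df
}

#' @rdname read_climate_csv
#' @param df Data.frame to write.
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Sequences the stages over validated input files: multi-scalar SPEI,
#' per-site trend tests of annual mean temperature, annual precipitation
#' and annual-mean 1-month SPEI, the two detrended correlation tables, the
#' quadratic fixed-effects panel fit on the configured stage covariate, the
#' moisture-level response table, and decade summaries. Outputs and a
#' manifest (input/output MD5 checksums, configuration, package version;
#' no timestamps, so identical inputs and config give byte-identical
#' manifests) are written under `out_dir`.
#'
#' @param climate_csv,yield_csv Input file paths.
#' @param out_dir Output directory (created if absent).
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of output paths (the manifest's files).
#' @export
run_pipeline <- function(climate_csv, yield_csv, out_dir,
                         config = pipeline_config()) {
  climate <- read_climate_csv(climate_csv)
  yields <- read_yield_csv(yield_csv)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- list()
  put <- function(df, name) {
    p <- file.path(out_dir, name)
    write_table_csv(df, p)
    paths[[name]] <<- p
  }

  spei <- compute_spei(climate, scales = config$scales,
                       calibration_years = config$calibration_years)
  out_spei <- spei
  out_spei$spei <- round(out_spei$spei, 6)
  put(out_spei, "spei.csv")

  annual <- function(df, col, fun) {
    agg <- stats::aggregate(df[[col]], by = list(site = df$site,
                                                 year = df$year), FUN = fun)
    names(agg)[3] <- "value"
    agg
  }
  trends <- rbind(
    cbind(series = "tmean_annual_c",
          trend_suite(annual(climate, "tmean_c", mean), alpha = config$alpha)),
    cbind(series = "precip_annual_mm",
          trend_suite(annual(climate, "precip_mm", sum), alpha = config$alpha)),
    cbind(series = "spei1_annual_mean",
          trend_suite(annual(spei[spei$scale == 1 & !is.na(spei$spei), ],
                             "spei", mean), alpha = config$alpha))
  )
  put(trends, "trends.csv")

  linkage <- linkage_tables(yields, spei, season_scales = config$scales,
                            stage_scales = config$stage_scales)
  put(linkage$growing_season, "linkage_growing_season.csv")
  put(linkage$stages, "linkage_stages.csv")

  harvest_years <- sort(unique(yields$year))
  cov <- season_covariate(spei, config$panel_stage, harvest_years,
                          config$panel_scale)
  fit <- fit_panel(yields, cov, ar1 = config$ar1,
                   dw_bounds = config$dw_bounds)
  coefs <- data.frame(
    term = c("mean_intercept", "alpha1", "alpha2", "alpha3", "rho",
             "adj_r2", "dw", "n_obs",
             paste0("beta_", names(fit$site_intercepts))),
    value = c(fit$mean_intercept, fit$alpha1, fit$alpha2, fit$alpha3,
              fit$rho, fit$adj_r2, fit$dw, fit$n_obs,
              unname(fit$site_intercepts)),
    stringsAsFactors = FALSE)
  put(coefs, "panel_fit.csv")
  put(response_table(fit), "response_table.csv")
  scalars <- data.frame(
    name = c("optimum_spei", "loss_threshold_low", "loss_threshold_high"),
    value = c(optimum_spei(fit), loss_thresholds(fit)),
    stringsAsFactors = FALSE)
  put(scalars, "derived_scalars.csv")
  put(decade_summary(cov, config$periods, fit), "decade_summary.csv")

  manifest <- data.frame(
    key = c("package_version",
            paste0("input_md5_", basename(c(climate_csv, yield_csv))),
            "config",
            paste0("output_md5_", names(paths))),
    value = c(as.character(utils::packageVersion("wheatmoist")),
              unname(tools::md5sum(c(climate_csv, yield_csv))),
              paste(deparse(unclass(config), control = NULL), collapse = ""),
              unname(tools::md5sum(unlist(paths)))),
    stringsAsFactors = FALSE)
  mp <- file.path(out_dir, "manifest.csv")
  write_table_csv(manifest, mp)
  paths[["manifest.csv"]] <- mp
  invisible(paths)
}
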