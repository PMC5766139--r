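#' Winter-wheat growth stage definitions
#'
#' The growing season runs October through June, labeled by the harvest
#' year: months October-December belong to calendar year harvest_year - 1.
#' Stages: S1 sowing/seedling (Oct-Nov), S2 over-wintering (Dec-Feb),
#' S3 late growth (Apr-Jun), full_season (Oct-Jun, all nine months).
#' March falls in no stage by construction.
#'
#' @return A data.frame (stage, month, year_offset) where year_offset is
#'   the calendar-year offset relative to the harvest year (-1 or 0).
#' @export
stage_definitions <- function() {
  rbind(
    data.frame(stage = "S1", month = c(10L, 11L), year_offset = -1L),
    data.frame(stage = "S2", month = c(12L, 1L, 2L),
               year_offset = c(-1L, 0L, 0L)),
    data.frame(stage = "S3", month = c(4L, 5L, 6L), year_offset = 0L),
    data.frame(stage = "full_season",
               month = c(10L, 11L, 12L, 1L, 2L, 3L, 4L, 5L, 6L),
               year_offset = c(-1L, -1L, -1L, 0L, 0L, 0L, 0L, 0L, 0L))
  )
}

#' Stage-mean SPEI covariate per site and harvest year
#'
#' Averages the k-month SPEI values of the stage's months (e.g. SPEI_3_S3 is
#' the mean of the 3-month SPEI of April, May and June of the harvest year).
#'
#' @param spei SPEI data.frame from [compute_spei()] (site, year, month,
#'   scale, spei).
#' @param stage Stage name from [stage_definitions()] ("S1", "S2", "S3",
#'   "full_season") or a data.frame with columns month, year_offset.
#' @param harvest_years Integer vector of harvest years to assemble.
#' @param scale Time scale k whose SPEI values are averaged.
#' @return A data.frame (site, year, covariate) with year the harvest year.
#' @export
season_covariate <- function(spei, stage, harvest_years, scale) {
  check_columns(spei, c("site", "year", "month", "scale", "spei"),
                "SPEI table")
  if (is.character(stage)) {
    defs <- stage_definitions()
    if (!stage %in% defs$stage) stop_invalid("unknown stage '%s'", stage)
    stage <- defs[defs$stage == stage, c("month", "year_offset")]
  }
  sub <- spei[spei$scale == scale, , drop = FALSE]
  if (!nrow(sub)) stop_invalid("no SPEI values at scale %s", scale)
  key <- paste(sub$site, sub$year, sub$month)
  rows <- list()
  missing <- character(0)
  for (site in unique(sub$site)) {
    for (hy in harvest_years) {
      want <- paste(site, hy + stage$year_offset, stage$month)
      vals <- sub$spei[match(want, key)]
      if (any(is.na(vals))) {
        lost <- want[is.na(vals)]
        missing <- c(missing, paste0(site, "/", hy, " (",
                                     paste(lost, collapse = "; "), ")"))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        site = site, year = hy, covariate = mean(vals),
        stringsAsFactors = FALSE)
    }
  }
  if (length(missing)) {
    stop_invalid("season months missing or undefined for: %s",
                 paste(missing, collapse = ", "))
  }
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

#' First-order differencing
#'
#' Replaces an annual series by successive differences
#' `x_{t+1} - x_t`, removing linear technological or long-term trends
#' before correlation.
#'
#' @param x Numeric series, n >= 2.
#' @return Numeric vector of length n - 1.
#' @export
first_difference <- function(x) {
  if (length(x) < 2) stop_invalid("first difference requires n >= 2")
  diff(x)
}

#' Pearson correlation between detrended series
#'
#' Pearson r with the two-sided p-value from the t distribution on n - 2
#' degrees of freedom, plus significance stars: "**" for p < 0.01, "*" for
#' p < 0.05.
#'
#' @param y,x Equal-length numeric vectors, n >= 4.
#' @return A list: r, p_value, stars, n.
#' @export
correlate <- function(y, x) {
  if (length(y) != length(x)) stop_invalid("series lengths differ")
  if (length(y) < 4) stop_invalid("correlation requires n >= 4")
  if (stats::sd(y) == 0 || stats::sd(x) == 0) {
    stop_invalid("undefined correlation: zero-variance input")
  }
  ct <- stats::cor.test(y, x, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  p <- ct$p.value
  list(r = r, p_value = p, stars = p_stars(p), n = length(y))
}

p_stars <- function(p) {
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
}

#' Detrended yield-SPEI correlation tables
#'
#' Builds the two linkage tables of the analysis: growing-season mean SPEI
#' at scales 1/3/6/9 versus detrended yield, and stage means (S1, S2, S3)
#' at scales 1 and 3 versus detrended yield. Both yield and covariate are
#' detrended by first differences over the common harvest years.
#'
#' @param yields Data.frame (site, year, yield_t_ha).
#' @param spei SPEI data.frame from [compute_spei()] containing all needed
#'   scales.
#' @param season_scales Scales for the growing-season table (default
#'   1, 3, 6, 9).
#' @param stage_scales Scales for the stage table (default 1, 3).
#' @param stages Stage names for the stage table (default S1, S2, S3).
#' @return A list with data.frames `growing_season` and `stages`, long
#'   format (site, covariate, r, p_value, stars, n).
#' @export
linkage_tables <- function(yields, spei, season_scales = c(1, 3, 6, 9),
                           stage_scales = c(1, 3),
                           stages = c("S1", "S2", "S3")) {
  check_columns(yields, c("site", "year", "yield_t_ha"), "yield panel")
  one <- function(scale, stage, label) {
    years_avail <- covariate_years(spei, stage, scale)
    rows <- list()
    for (site in unique(yields$site)) {
      ysub <- yields[yields$site == site, , drop = FALSE]
      common <- sort(intersect(ysub$year, years_avail))
      if (length(common) < 5) {
        stop_invalid("site %s, %s: only %d overlapping seasons (need >= 5)",
                     site, label, length(common))
      }
      cov <- season_covariate(spei[spei$site == site, , drop = FALSE],
                              stage, common, scale)
      y <- ysub$yield_t_ha[match(common, ysub$year)]
      s <- cov$covariate[match(common, cov$year)]
      res <- correlate(first_difference(y), first_difference(s))
      rows[[length(rows) + 1L]] <- data.frame(
        site = site, covariate = label, r = res$r, p_value = res$p_value,
        stars = res$stars, n = res$n, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }
  season <- do.call(rbind, lapply(season_scales, function(k) {
    one(k, "full_season", sprintf("SPEI_%d", k))
  }))
  stage_tab <- do.call(rbind, lapply(stage_scales, function(k) {
    do.call(rbind, lapply(stages, function(st) {
      one(k, st, sprintf("SPEI_%d_%s", k, st))
    }))
  }))
  row.names(season) <- row.names(stage_tab) <- NULL
  list(growing_season = season, stages = stage_tab)
}

# harvest years whose every stage month has a defined SPEI value at `scale`
# for every site present in `spei`
covariate_years <- function(spei, stage, scale) {
  if (is.character(stage)) {
    defs <- stage_definitions()
    stage <- defs[defs$stage == stage, c("month", "year_offset")]
  }
  sub <- spei[spei$scale == scale & !is.na(spei$spei), , drop = FALSE]
  if (!nrow(sub)) return(integer(0))
  years <- sort(unique(sub$year - min(stage$year_offset)))
  key <- paste(sub$site, sub$year, sub$month)
  ok <- vapply(years, function(hy) {
    all(vapply(unique(sub$site), function(site) {
      all(paste(site, hy + stage$year_offset, stage$month) %in% key)
    }, logical(1)))
  }, logical(1))
  years[ok]
}
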