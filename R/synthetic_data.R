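#' Describe a synthetic meteorological site
#'
#' A site specification drives the climate generator: a sinusoidal seasonal
#' temperature cycle around a site mean, a linear warming trend, Gaussian
#' month-to-month temperature noise, and gamma-distributed monthly
#' precipitation whose monthly means sum to the site's annual total.
#'
#' @param name Site identifier (unique within a site list).
#' @param latitude Latitude in decimal degrees north, in \[-90, 90\].
#' @param mean_annual_temp Long-term annual mean temperature, degrees C.
#' @param annual_precip Long-term annual precipitation total, mm (> 0).
#' @param warming_slope Linear temperature trend, degrees C per year.
#' @param temp_seasonal_amplitude Half peak-to-trough seasonal temperature
#'   swing, degrees C (>= 0). The cycle peaks in July (Northern Hemisphere).
#' @param temp_noise_sd Standard deviation of monthly temperature noise,
#'   degrees C.
#' @param precip_shape Gamma shape parameter for monthly precipitation
#'   (> 0); smaller values give more skewed, drizzle-or-deluge months.
#' @return A list of class `site_spec`.
#' @export
site_spec <- function(name, latitude, mean_annual_temp, annual_precip,
                      warming_slope = 0, temp_seasonal_amplitude = 12,
                      temp_noise_sd = 0.8, precip_shape = 1.2) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_invalid("site name must be a non-empty string")
  }
  if (!is.finite(latitude) || latitude < -90 || latitude > 90) {
    stop_invalid("latitude must lie in [-90, 90] (got %s)", latitude)
  }
  if (!is.finite(annual_precip) || annual_precip <= 0) {
    stop_invalid("annual_precip must be positive")
  }
  if (!is.finite(precip_shape) || precip_shape <= 0) {
    stop_invalid("precip_shape must be positive")
  }
  if (!is.finite(temp_seasonal_amplitude) || temp_seasonal_amplitude < 0) {
    stop_invalid("temp_seasonal_amplitude must be >= 0")
  }
  if (!is.finite(temp_noise_sd) || temp_noise_sd < 0) {
    stop_invalid("temp_noise_sd must be >= 0")
  }
  structure(list(name = name, latitude = latitude,
                 mean_annual_temp = mean_annual_temp,
                 annual_precip = annual_precip,
                 warming_slope = warming_slope,
                 temp_seasonal_amplitude = temp_seasonal_amplitude,
                 temp_noise_sd = temp_noise_sd,
                 precip_shape = precip_shape),
            class = "site_spec")
}

#' Default ten-site network emulating the Jiangsu station layout
#'
#' Ten sites spanning latitudes 31-35 degrees N with a north(dry, cool) to
#' south(wet, warm) gradient: site annual means interpolate 13-16 degrees C
#' and 724-1210 mm along latitude, and warming slopes interpolate
#' 0.04-0.07 degrees C/yr (weakest in the north, strongest in the south).
#'
#' @return A list of [site_spec()] objects.
#' @export
default_sites <- function() {
  names <- c("Ganyu", "Xuzhou", "Xuyi", "Dongtai", "Gaoyou",
             "Yangzhou", "Nantong", "Nanjing", "Liyang", "Wujiang")
  lat <- c(34.500, 34.167, 32.583, 32.517, 32.483,
           32.250, 32.050, 32.000, 31.267, 31.083)
  frac <- (max(lat) - lat) / (max(lat) - min(lat))  # 0 at north, 1 at south
  mapply(function(nm, la, fr) {
    site_spec(name = nm, latitude = la,
              mean_annual_temp = 13 + 3 * fr,
              annual_precip = 724 + (1210 - 724) * fr,
              warming_slope = 0.04 + 0.03 * fr)
  }, names, lat, frac, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

# Monthly climatological precipitation weights (sum to 1), peaking in the
# June-August monsoon with a secondary spring contribution.
monthly_precip_weights <- function() {
  c(0.04, 0.05, 0.06, 0.07, 0.09, 0.13, 0.16, 0.14, 0.08, 0.07, 0.06, 0.05)
}

#' Generate a monthly climate panel
#'
#' Temperature at site i, year y, month m is
#' `mean_annual_temp + A * cos(2*pi*(m - 7)/12) + slope * (y - start_year) + e`
#' with `e ~ N(0, temp_noise_sd^2)`, so the seasonal cycle peaks in July.
#' Monthly precipitation is drawn from a gamma distribution with the site's
#' shape parameter and a monthly mean equal to the climatological weight for
#' that month times the site's annual total, so expected annual precipitation
#' equals `annual_precip`.
#'
#' @param sites List of [site_spec()] objects with unique names.
#' @param start_year First calendar year of the record.
#' @param n_years Number of years (>= 2).
#' @param seed Integer seed; the panel is bit-reproducible given
#'   (sites, start_year, n_years, seed).
#' @return A data.frame with columns site, latitude, year, month, tmean_c,
#'   precip_mm: one row per (site, year, month), months strictly consecutive.
#' @export
generate_climate <- function(sites, start_year, n_years, seed) {
  if (inherits(sites, "site_spec")) sites <- list(sites)
  if (!length(sites)) stop_invalid("at least one site is required")
  if (!is.numeric(n_years) || n_years < 2) {
    stop_invalid("n_years must be at least 2")
  }
  nms <- vapply(sites, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop_invalid("duplicate site names: %s",
                                       paste(unique(nms[duplicated(nms)]),
                                             collapse = ", "))
  n_years <- as.integer(n_years)
  years <- start_year + seq_len(n_years) - 1L
  months <- 1:12
  weights <- monthly_precip_weights()
  with_seed(seed, {
    panels <- lapply(sites, function(s) {
      grid <- expand.grid(month = months, year = years,
                          KEEP.OUT.ATTRS = FALSE)
      seasonal <- s$temp_seasonal_amplitude * cos(2 * pi * (grid$month - 7) / 12)
      trend <- s$warming_slope * (grid$year - start_year)
      noise <- stats::rnorm(nrow(grid), 0, s$temp_noise_sd)
      tmean <- s$mean_annual_temp + seasonal + trend + noise
      mu <- weights[grid$month] * s$annual_precip
      precip <- stats::rgamma(nrow(grid), shape = s$precip_shape,
                              scale = mu / s$precip_shape)
      data.frame(site = s$name, latitude = s$latitude,
                 year = grid$year, month = grid$month,
                 tmean_c = tmean, precip_mm = precip,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, panels)
  })
}

#' Parameters of the quadratic fixed-effects yield model
#'
#' The data-generating model for annual yields is
#' `Y_{i,t} = beta_i + alpha1 * s_{i,t} + alpha2 * s_{i,t}^2 + alpha3 * t + u_{i,t}`
#' with AR(1) errors `u_{i,t} = rho * u_{i,t-1} + eps_{i,t}`,
#' `eps ~ N(0, error_sd^2)`, independent across sites, and `u` initialized
#' from its stationary distribution `N(0, error_sd^2 / (1 - rho^2))`.
#'
#' @param site_intercepts Named numeric vector of site intercepts beta_i, t/ha.
#' @param alpha1 Linear moisture coefficient, t/ha per SPEI unit.
#' @param alpha2 Quadratic moisture coefficient, t/ha per squared SPEI unit.
#' @param alpha3 Linear technology-trend coefficient, t/ha per year.
#' @param rho AR(1) coefficient, |rho| < 1.
#' @param error_sd Innovation standard deviation, t/ha (>= 0).
#' @return A list of class `panel_params`.
#' @export
panel_params <- function(site_intercepts, alpha1, alpha2, alpha3,
                         rho = 0, error_sd = 0) {
  if (is.null(names(site_intercepts)) || any(!nzchar(names(site_intercepts)))) {
    stop_invalid("site_intercepts must be a named vector")
  }
  if (!is.finite(rho) || abs(rho) >= 1) stop_invalid("|rho| must be < 1")
  if (!is.finite(error_sd) || error_sd < 0) stop_invalid("error_sd must be >= 0")
  structure(list(site_intercepts = site_intercepts, alpha1 = alpha1,
                 alpha2 = alpha2, alpha3 = alpha3, rho = rho,
                 error_sd = error_sd),
            class = "panel_params")
}

#' Default yield-model parameters (reported estimation regime)
#'
#' Coefficients in the regime of the reference estimation for the ten default
#' sites: alpha1 = -0.1592, alpha2 = -0.1297, alpha3 = 0.0626 (t/ha units),
#' rho = 0.39, and site intercepts equal to the 3.3376 t/ha mean intercept
#' plus per-site deviations. The innovation sd (0.25 t/ha) is a synthetic
#' choice, not an estimate.
#'
#' @return A `panel_params` object for the ten [default_sites()].
#' @export
default_panel_params <- function() {
  dev <- c(Ganyu = 0.2166, Xuzhou = 0.3275, Xuyi = -0.1691,
           Dongtai = 0.5424, Gaoyou = 0.7057, Yangzhou = 0.2799,
           Nantong = -0.0369, Nanjing = -0.6264, Liyang = -0.7786,
           Wujiang = -0.4612)
  panel_params(site_intercepts = 3.3376 + dev,
               alpha1 = -0.1592, alpha2 = -0.1297, alpha3 = 0.0626,
               rho = 0.39, error_sd = 0.25)
}

#' Simulate annual yields from the quadratic fixed-effects model
#'
#' @param covariate Data.frame with columns site, year and a moisture
#'   covariate column (default name `covariate`): one finite value per
#'   (site, year) cell for every site named in `params$site_intercepts`.
#' @param params A [panel_params()] object.
#' @param seed Integer seed.
#' @param covariate_col Name of the covariate column.
#' @return A data.frame (site, year, yield_t_ha), one row per input cell.
#'   The time index t used in the trend term is 1, 2, ... over the sorted
#'   distinct years.
#' @export
generate_yields <- function(covariate, params, seed,
                            covariate_col = "covariate") {
  stopifnot(inherits(params, "panel_params"))
  check_columns(covariate, c("site", "year", covariate_col), "covariate table")
  s <- covariate[[covariate_col]]
  if (any(!is.finite(s))) {
    bad <- covariate[!is.finite(s), c("site", "year")]
    stop_invalid("missing covariate value(s), e.g. site %s year %s",
                 bad$site[1], bad$year[1])
  }
  sites <- names(params$site_intercepts)
  if (!all(covariate$site %in% sites)) {
    stop_invalid("covariate contains sites without an intercept: %s",
                 paste(setdiff(unique(covariate$site), sites), collapse = ", "))
  }
  years <- sort(unique(covariate$year))
  tindex <- match(covariate$year, years)
  ord <- order(match(covariate$site, sites), covariate$year)
  covariate <- covariate[ord, , drop = FALSE]
  s <- s[ord]
  tindex <- tindex[ord]
  with_seed(seed, {
    u <- numeric(nrow(covariate))
    for (site in unique(covariate$site)) {
      idx <- which(covariate$site == site)
      n <- length(idx)
      if (params$error_sd == 0) {
        u[idx] <- 0
        next
      }
      stat_sd <- params$error_sd / sqrt(1 - params$rho^2)
      e <- stats::rnorm(n, 0, params$error_sd)
      ui <- numeric(n)
      ui[1] <- stats::rnorm(1, 0, stat_sd)
      if (n > 1) {
        for (t in 2:n) ui[t] <- params$rho * ui[t - 1] + e[t]
      }
      u[idx] <- ui
    }
    beta <- params$site_intercepts[covariate$site]
    yield <- beta + params$alpha1 * s + params$alpha2 * s^2 +
      params$alpha3 * tindex + u
    data.frame(site = covariate$site, year = covariate$year,
               yield_t_ha = as.numeric(yield),
               stringsAsFactors = FALSE, row.names = NULL)
  })
}

#' Simulate a stationary AR(1) error path
#'
#' Utility used to check the error process itself: draws n values of
#' `u_t = rho * u_{t-1} + eps_t` initialized from the stationary law.
#'
#' @param n Number of draws.
#' @param rho AR(1) coefficient, |rho| < 1.
#' @param sd Innovation standard deviation.
#' @param seed Integer seed.
#' @return Numeric vector of length n.
#' @export
simulate_ar1 <- function(n, rho, sd, seed) {
  if (abs(rho) >= 1) stop_invalid("|rho| must be < 1")
  with_seed(seed, {
    u <- numeric(n)
    u[1] <- stats::rnorm(1, 0, sd / sqrt(1 - rho^2))
    if (n > 1) {
      e <- stats::rnorm(n - 1, 0, sd)
      for (t in 2:n) u[t] <- rho * u[t - 1] + e[t - 1]
    }
    u
  })
}
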