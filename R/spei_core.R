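#' Thornthwaite potential evapotranspiration
#'
#' Monthly PET (mm) from monthly mean temperature and latitude, after
#' Thornthwaite (1948). The annual heat index I is computed from the
#' per-calendar-month climatological mean temperatures over the record
#' (negative means clamped to zero): `I = sum((T_m / 5)^1.514)`. The
#' exponent is `a = 6.75e-7 I^3 - 7.71e-5 I^2 + 1.792e-2 I + 0.49239`.
#' Uncorrected PET is 0 for T <= 0 C, `16 (10 T / I)^a` for 0 < T < 26.5 C,
#' and the high-temperature polynomial `-415.85 + 32.24 T - 0.43 T^2` for
#' T >= 26.5 C. Each month is scaled by `(N / 12) (NDM / 30)` where N is the
#' daylength (hours) at the month's mid-day from solar declination and NDM
#' the days in the month (non-leap calendar).
#'
#' @param tmean Numeric vector of monthly mean temperatures, degrees C, in
#'   strict time order; at least 12 values.
#' @param latitude Latitude in decimal degrees, \[-90, 90\].
#' @param months Calendar month (1-12) of each value; defaults to a cycle
#'   starting in January.
#' @return Numeric vector of PET in mm/month, same length as `tmean`.
#' @export
thornthwaite_pet <- function(tmean, latitude, months = NULL) {
  if (length(tmean) < 12) {
    stop_invalid("at least 12 monthly temperatures are required (annual heat index undefined)")
  }
  if (any(!is.finite(tmean))) stop_invalid("temperatures must be finite")
  if (!is.finite(latitude) || abs(latitude) > 90) {
    stop_invalid("latitude must lie in [-90, 90]")
  }
  if (is.null(months)) {
    months <- rep_len(1:12, length(tmean))
  }
  if (length(months) != length(tmean) || any(!(months %in% 1:12))) {
    stop_invalid("months must align with tmean and lie in 1..12")
  }
  # climatological monthly normals -> annual heat index
  normals <- vapply(1:12, function(m) {
    v <- tmean[months == m]
    if (!length(v)) 0 else mean(v)
  }, numeric(1))
  Tm <- pmax(normals, 0)
  I <- sum((Tm / 5)^1.514)
  a <- 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239

  pet0 <- numeric(length(tmean))
  warm <- is.finite(tmean) & tmean > 0 & tmean < 26.5
  hot <- tmean >= 26.5
  if (I > 0) {
    pet0[warm] <- 16 * (10 * tmean[warm] / I)^a
  }
  pet0[hot] <- -415.85 + 32.24 * tmean[hot] - 0.43 * tmean[hot]^2

  K <- daylength_hours(latitude, months) / 12 * DAYS_PER_MONTH[months] / 30
  pmax(pet0 * K, 0)
}

# Mean daylength (hours) at the mid-day of each calendar month, from solar
# declination; latitudes inside the polar circles are clamped to 0/24 h.
daylength_hours <- function(latitude, months) {
  mid <- cumsum(DAYS_PER_MONTH) - DAYS_PER_MONTH / 2
  J <- mid[months]
  delta <- 0.4093 * sin(2 * pi * J / 365 - 1.405)
  phi <- latitude * pi / 180
  x <- pmin(pmax(-tan(phi) * tan(delta), -1), 1)
  24 / pi * acos(x)
}

#' Climatic water balance
#'
#' Monthly difference `D_i = P_i - PET_i` between precipitation and
#' potential evapotranspiration, order preserved.
#'
#' @param precip Monthly precipitation, mm.
#' @param pet Monthly PET, mm; same length as `precip`.
#' @return Numeric vector D in mm.
#' @export
water_balance <- function(precip, pet) {
  if (length(precip) != length(pet)) {
    stop_invalid("precip and pet must have equal length (%d vs %d)",
                 length(precip), length(pet))
  }
  precip - pet
}

#' Trailing k-month aggregation of the water balance
#'
#' The k-month aggregated value at month m is the sum of D over months
#' m-k+1, ..., m. The first k-1 positions are undefined (NA).
#'
#' @param d Water-balance series in strict time order.
#' @param k Time scale in months (>= 1, <= length of the series).
#' @return Numeric vector with an NA prefix of length k-1.
#' @export
aggregate_balance <- function(d, k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1) {
    stop_invalid("scale k must be a single integer >= 1")
  }
  k <- as.integer(k)
  if (k > length(d)) stop_invalid("scale k exceeds the series length")
  as.numeric(stats::filter(d, rep(1, k), sides = 1))
}

#' Fit a three-parameter log-logistic distribution by L-moments
#'
#' Fits the distribution with density
#' `f(x) = (beta/alpha) ((x - gamma)/alpha)^(beta-1) (1 + ((x - gamma)/alpha)^beta)^(-2)`
#' by unbiased probability-weighted moments (PWMs). With `w_s` the unbiased
#' estimate of `E[X (1 - F(X))^s]`, the parameters are
#' `beta = (2 w1 - w0) / (6 w1 - w0 - 6 w2)`,
#' `alpha = (w0 - 2 w1) beta / (G1 G2)` and `gamma = w0 - alpha G1 G2`,
#' where `G1 G2 = gamma(1 + 1/beta) * gamma(1 - 1/beta)`.
#'
#' The log-logistic has positive L-skewness only; a sample with negative
#' L-skewness (which a long climate record occasionally produces for some
#' calendar month) is fitted after reflection (`-x`), the mirror member of
#' the same generalized-logistic family, and flagged `reflected = TRUE`;
#' [ploglogistic()] and [qloglogistic()] undo the reflection transparently.
#'
#' @param x Numeric sample (>= 10 finite values).
#' @param allow_reflection Fall back to the reflected fit when the shape
#'   estimate is inadmissible (default TRUE).
#' @return List of class `loglogistic_params`: alpha (scale > 0),
#'   beta (shape > 0), gamma (origin), reflected (logical).
#' @export
fit_loglogistic <- function(x, allow_reflection = TRUE) {
  x <- x[is.finite(x)]
  if (length(x) < 10) {
    stop_invalid("at least 10 finite samples are required (got %d)", length(x))
  }
  if (diff(range(x)) == 0) {
    stop_invalid("degenerate sample: all values identical")
  }
  n <- length(x)
  xs <- sort(x)
  j <- seq_len(n)
  # unbiased PWMs of E[X (1-F)^s]: descending weights on the ascending sort
  w0 <- mean(xs)
  w1 <- sum(xs * (n - j) / (n - 1)) / n
  w2 <- sum(xs * (n - j) * (n - j - 1) / ((n - 1) * (n - 2))) / n

  beta <- (2 * w1 - w0) / (6 * w1 - w0 - 6 * w2)
  if (!is.finite(beta) || beta <= 1) {
    if (allow_reflection) {
      f <- fit_loglogistic(-x, allow_reflection = FALSE)
      f$reflected <- TRUE
      return(f)
    }
    stop_invalid("log-logistic fit failed: shape estimate %.4f not > 1", beta)
  }
  gg <- gamma(1 + 1 / beta) * gamma(1 - 1 / beta)
  alpha <- (w0 - 2 * w1) * beta / gg
  gamma_ <- w0 - alpha * gg
  if (!is.finite(alpha) || alpha <= 0) {
    stop_invalid("log-logistic fit failed: non-positive scale")
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma_,
                 reflected = FALSE),
            class = "loglogistic_params")
}

#' Log-logistic cumulative distribution function
#'
#' `F(x) = (1 + (alpha / (x - gamma))^beta)^(-1)` for x > gamma, 0 otherwise.
#'
#' @param x Quantiles.
#' @param params A `loglogistic_params` object.
#' @return Probabilities in \[0, 1\].
#' @export
ploglogistic <- function(x, params) {
  if (isTRUE(params$reflected)) {
    flipped <- params
    flipped$reflected <- FALSE
    return(1 - ploglogistic(-x, flipped))
  }
  p <- numeric(length(x))
  above <- x > params$gamma
  p[above] <- 1 / (1 + (params$alpha / (x[above] - params$gamma))^params$beta)
  p
}

#' Log-logistic quantile function
#'
#' Inverse of [ploglogistic()]: `x = gamma + alpha (u / (1 - u))^(1/beta)`.
#'
#' @param u Probabilities in (0, 1).
#' @param params A `loglogistic_params` object.
#' @return Quantiles.
#' @export
qloglogistic <- function(u, params) {
  stopifnot(all(u > 0 & u < 1))
  if (isTRUE(params$reflected)) {
    flipped <- params
    flipped$reflected <- FALSE
    return(-qloglogistic(1 - u, flipped))
  }
  params$gamma + params$alpha * (u / (1 - u))^(1 / params$beta)
}

# standardization constants of the rational normal-quantile approximation
STD_CONST <- c(C0 = 2.515517, C1 = 0.802853, C2 = 0.010328,
               d1 = 1.432788, d2 = 0.189269, d3 = 0.001308)

#' Standardize an exceedance probability to an SPEI value
#'
#' Maps `P = 1 - F(x)` to a standard-normal-like deviate with the classical
#' rational approximation: for P <= 0.5, `W = sqrt(-2 ln P)` and
#' `SPEI = W - (C0 + C1 W + C2 W^2) / (1 + d1 W + d2 W^2 + d3 W^3)`;
#' for P > 0.5 the same formula is applied to 1 - P and the sign flipped.
#' Small P (rare wet excess) maps to large positive SPEI.
#'
#' @param p_exceed Exceedance probabilities, strictly inside (0, 1).
#' @return SPEI values (dimensionless).
#' @export
standardize_spei <- function(p_exceed) {
  if (any(!is.finite(p_exceed)) || any(p_exceed <= 0) || any(p_exceed >= 1)) {
    stop_invalid("exceedance probabilities must lie strictly in (0, 1)")
  }
  k <- STD_CONST
  flip <- p_exceed > 0.5
  p <- ifelse(flip, 1 - p_exceed, p_exceed)
  w <- sqrt(-2 * log(p))
  z <- w - (k["C0"] + k["C1"] * w + k["C2"] * w^2) /
    (1 + k["d1"] * w + k["d2"] * w^2 + k["d3"] * w^3)
  unname(ifelse(flip, -z, z))
}

#' Classify an SPEI value into a moisture level
#'
#' Seven levels tiling the real line, closed on the drought side:
#' extreme drought (<= -2), moderate drought (-2, -1\], slight drought
#' (-1, -0.5\], normal (-0.5, 0.5), slight wetting \[0.5, 1), moderate
#' wetting \[1, 2), extreme wetting (>= 2).
#'
#' @param spei Finite SPEI values.
#' @return Ordered factor of moisture levels (dry to wet).
#' @export
classify_spei <- function(spei) {
  if (any(!is.finite(spei))) stop_invalid("SPEI values must be finite")
  lv <- moisture_levels()
  idx <- ifelse(spei <= -2, 1L,
         ifelse(spei <= -1, 2L,
         ifelse(spei <= -0.5, 3L,
         ifelse(spei < 0.5, 4L,
         ifelse(spei < 1, 5L,
         ifelse(spei < 2, 6L, 7L))))))
  factor(lv[idx], levels = lv, ordered = TRUE)
}

#' Moisture level labels, dry to wet
#' @return Character vector of the seven level names.
#' @export
moisture_levels <- function() {
  c("extreme drought", "moderate drought", "slight drought", "normal",
    "slight wetting", "moderate wetting", "extreme wetting")
}

#' Compute multi-scalar SPEI for a climate panel
#'
#' For each site and time scale k: Thornthwaite PET from temperature and
#' latitude, monthly water balance D = P - PET, trailing k-month sums, a
#' separate log-logistic L-moment fit per calendar month over the
#' calibration years, and inverse-normal standardization of the exceedance
#' probability. Aggregated values at or below the fitted origin are clamped
#' to cumulative probability 1e-6 (symmetrically 1 - 1e-6 above), so
#' extreme tails saturate rather than fail.
#'
#' @param panel Climate data.frame (site, latitude, year, month, tmean_c,
#'   precip_mm), complete and strictly consecutive per site.
#' @param scales Integer vector of time scales in months.
#' @param calibration_years Optional integer vector of years used for the
#'   distribution fits; defaults to all years in the panel.
#' @return A data.frame (site, year, month, scale, spei, level) with the
#'   first k-1 months per site NA at scale k, and the per-(site, scale,
#'   calendar month) fitted parameters in `attr(, "params")`.
#' @export
compute_spei <- function(panel, scales = c(1, 3, 6, 9),
                         calibration_years = NULL) {
  check_columns(panel, c("site", "latitude", "year", "month",
                         "tmean_c", "precip_mm"), "climate panel")
  validate_climate(panel)
  out <- list()
  par_rows <- list()
  for (site in unique(panel$site)) {
    sub <- panel[panel$site == site, , drop = FALSE]
    sub <- sub[order(sub$year, sub$month), , drop = FALSE]
    pet <- thornthwaite_pet(sub$tmean_c, sub$latitude[1], sub$month)
    d <- water_balance(sub$precip_mm, pet)
    calib <- if (is.null(calibration_years)) unique(sub$year) else calibration_years
    for (k in scales) {
      agg <- aggregate_balance(d, k)
      spei <- rep(NA_real_, length(agg))
      for (m in 1:12) {
        sel <- which(sub$month == m & !is.na(agg))
        fit_sel <- sel[sub$year[sel] %in% calib]
        if (length(fit_sel) < 10) {
          stop_invalid("site %s month %d scale %d: only %d calibration values (need >= 10)",
                       site, m, k, length(fit_sel))
        }
        fit <- fit_loglogistic(agg[fit_sel])
        cdf <- ploglogistic(agg[sel], fit)
        cdf <- pmin(pmax(cdf, 1e-6), 1 - 1e-6)
        spei[sel] <- standardize_spei(1 - cdf)
        par_rows[[length(par_rows) + 1L]] <-
          data.frame(site = site, scale = k, calendar_month = m,
                     alpha = fit$alpha, beta = fit$beta, gamma = fit$gamma,
                     reflected = fit$reflected, stringsAsFactors = FALSE)
      }
      lvl <- rep(NA_character_, length(spei))
      lvl[!is.na(spei)] <- as.character(classify_spei(spei[!is.na(spei)]))
      out[[length(out) + 1L]] <-
        data.frame(site = site, year = sub$year, month = sub$month,
                   scale = k, spei = spei, level = lvl,
                   stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  attr(res, "params") <- do.call(rbind, par_rows)
  res
}

#' Validate a climate panel for completeness
#'
#' Checks the schema and that every site's (year, month) sequence is
#' strictly consecutive with no gaps or duplicates and finite values.
#'
#' @param panel Climate data.frame.
#' @return Invisibly, the panel; errors name the offending site and month.
#' @export
validate_climate <- function(panel) {
  check_columns(panel, c("site", "year", "month", "tmean_c", "precip_mm"),
                "climate panel")
  if (any(!is.finite(panel$tmean_c)) || any(!is.finite(panel$precip_mm))) {
    stop_invalid("climate panel contains non-finite values")
  }
  if (any(panel$precip_mm < 0)) stop_invalid("negative precipitation found")
  for (site in unique(panel$site)) {
    sub <- panel[panel$site == site, , drop = FALSE]
    sub <- sub[order(sub$year, sub$month), , drop = FALSE]
    idx <- sub$year * 12L + sub$month
    if (anyDuplicated(idx)) {
      d <- sub[duplicated(idx), ]
      stop_invalid("site %s: duplicate record for %d-%02d",
                   site, d$year[1], d$month[1])
    }
    gaps <- which(diff(idx) != 1L)
    if (length(gaps)) {
      y <- idx[gaps[1]] + 1L
      stop_invalid("site %s: missing month %d-%02d",
                   site, (y - 1L) %/% 12L, (y - 1L) %% 12L + 1L)
    }
  }
  invisible(panel)
}
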