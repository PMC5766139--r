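#' Fit the quadratic fixed-effects yield-response panel model
#'
#' Estimates `Y_{i,t} = beta_i + alpha1 s_{i,t} + alpha2 s_{i,t}^2 +
#' alpha3 t + u_{i,t}` by least squares with site dummies (LSDV), where s is
#' the moisture covariate (typically the stage-mean 3-month SPEI of the late
#' growth stage) and t = 1, 2, ... indexes the sorted panel years. The
#' Durbin-Watson statistic of the within-site-ordered OLS residuals is always
#' computed; when it falls outside `dw_bounds` (policy "auto") or when
#' forced ("on"), AR(1) errors are handled by iterated Cochrane-Orcutt:
#' rho is estimated from the pooled within-site regression of residuals on
#' their site-lagged values through the origin, all columns including the
#' dummies are quasi-differenced (first observation per site dropped), the
#' model refit, and the cycle repeated until |delta rho| < 1e-6 or 50
#' iterations.
#'
#' @param yields Data.frame (site, year, yield_t_ha).
#' @param covariate Data.frame (site, year, covariate); cells present in
#'   only one input are dropped with a message.
#' @param ar1 AR(1) policy: "auto" (apply when DW flags autocorrelation),
#'   "on", or "off".
#' @param dw_bounds Length-2 numeric; "auto" applies AR(1) when the DW
#'   statistic leaves \[dw_bounds\[1\], dw_bounds\[2\]\].
#' @param covariate_col Name of the covariate column.
#' @return A list of class `panel_fit`: site_intercepts (named, t/ha),
#'   mean_intercept, alpha1, alpha2, alpha3, rho, adj_r2, dw, n_obs,
#'   n_dropped, ar1_applied, iterations.
#' @export
fit_panel <- function(yields, covariate, ar1 = c("auto", "on", "off"),
                      dw_bounds = c(1.5, 2.5), covariate_col = "covariate") {
  ar1 <- match.arg(ar1)
  check_columns(yields, c("site", "year", "yield_t_ha"), "yield panel")
  check_columns(covariate, c("site", "year", covariate_col), "covariate table")
  m <- merge(yields, covariate[, c("site", "year", covariate_col)],
             by = c("site", "year"))
  n_dropped <- (nrow(yields) - nrow(m)) + (nrow(covariate) - nrow(m))
  if (n_dropped > 0) {
    message(sprintf("fit_panel: dropped %d unmatched site-year cell(s)",
                    n_dropped))
  }
  sites <- sort(unique(m$site))
  if (length(sites) < 2) stop_invalid("panel needs >= 2 sites")
  per_site <- table(m$site)
  if (any(per_site < 5)) {
    stop_invalid("every site needs >= 5 years (worst: %d)", min(per_site))
  }
  years <- sort(unique(m$year))
  m <- m[order(match(m$site, sites), m$year), , drop = FALSE]
  t_idx <- match(m$year, years)
  s <- m[[covariate_col]]
  if (any(!is.finite(s)) || any(!is.finite(m$yield_t_ha))) {
    stop_invalid("non-finite yield or covariate values")
  }

  D <- stats::model.matrix(~ 0 + factor(m$site, levels = sites))
  colnames(D) <- sites
  X <- cbind(D, s = s, s2 = s^2, t = t_idx)
  y <- m$yield_t_ha
  if (qr(X)$rank < ncol(X)) {
    stop_invalid("estimation error: rank-deficient design (constant covariate?)")
  }

  ols <- stats::lm.fit(X, y)
  beta <- ols$coefficients
  e <- as.numeric(y - X %*% beta)
  dw <- durbin_watson(e, m$site)

  apply_ar1 <- switch(ar1, on = TRUE, off = FALSE,
                      auto = (dw < dw_bounds[1] || dw > dw_bounds[2]))
  rho <- 0
  iterations <- 0L
  site_of <- m$site
  lag_pairs <- function() {
    # index pairs (t, t-1) within each site, rows already site/time ordered
    keep <- c(FALSE, site_of[-1] == site_of[-length(site_of)])
    list(cur = which(keep), prev = which(keep) - 1L)
  }
  lp <- lag_pairs()
  if (apply_ar1) {
    repeat {
      iterations <- iterations + 1L
      rho_new <- sum(e[lp$cur] * e[lp$prev]) / sum(e[lp$prev]^2)
      if (!is.finite(rho_new)) stop_invalid("AR(1) estimation failed")
      rho_new <- max(min(rho_new, 0.999), -0.999)
      ys <- y[lp$cur] - rho_new * y[lp$prev]
      Xs <- X[lp$cur, , drop = FALSE] - rho_new * X[lp$prev, , drop = FALSE]
      fit <- stats::lm.fit(Xs, ys)
      beta <- fit$coefficients
      e <- as.numeric(y - X %*% beta)
      if (abs(rho_new - rho) < 1e-6 || iterations >= 50L) {
        rho <- rho_new
        break
      }
      rho <- rho_new
    }
    final_res <- as.numeric(ys - Xs %*% beta)
    final_y <- ys
    p <- ncol(Xs)
  } else {
    final_res <- e
    final_y <- y
    p <- ncol(X)
  }
  nn <- length(final_y)
  tss <- sum((final_y - mean(final_y))^2)
  r2 <- 1 - sum(final_res^2) / tss
  adj_r2 <- 1 - (1 - r2) * (nn - 1) / (nn - p)

  intercepts <- beta[sites]
  structure(list(site_intercepts = intercepts,
                 mean_intercept = mean(intercepts),
                 alpha1 = unname(beta["s"]), alpha2 = unname(beta["s2"]),
                 alpha3 = unname(beta["t"]), rho = rho, adj_r2 = adj_r2,
                 dw = dw, n_obs = nrow(m), n_dropped = n_dropped,
                 ar1_applied = apply_ar1, iterations = iterations),
            class = "panel_fit")
}

#' @export
print.panel_fit <- function(x, ...) {
  cat("Fixed-effects quadratic moisture-response panel fit\n")
  cat(sprintf("  alpha1 (SPEI)    %9.4f t/ha\n", x$alpha1))
  cat(sprintf("  alpha2 (SPEI^2)  %9.4f t/ha\n", x$alpha2))
  cat(sprintf("  alpha3 (trend)   %9.4f t/ha per year\n", x$alpha3))
  cat(sprintf("  mean intercept   %9.4f t/ha over %d sites\n",
              x$mean_intercept, length(x$site_intercepts)))
  cat(sprintf("  AR(1) rho        %9.4f (%s, %d iteration(s))\n", x$rho,
              if (x$ar1_applied) "applied" else "not applied", x$iterations))
  cat(sprintf("  DW (OLS resid)   %9.4f   adj R2 %6.4f   n %d\n",
              x$dw, x$adj_r2, x$n_obs))
  invisible(x)
}

#' Durbin-Watson statistic over within-site residual sequences
#'
#' `dw = sum (e_t - e_{t-1})^2 / sum e_t^2` with the successive differences
#' taken only within each site's time-ordered residual sequence.
#'
#' @param residuals Numeric residuals, time-ordered within site.
#' @param sites Site label per residual (groups the sequences).
#' @return The DW statistic in \[0, 4\].
#' @export
durbin_watson <- function(residuals, sites = rep(1L, length(residuals))) {
  if (length(residuals) != length(sites)) {
    stop_invalid("residuals and sites must align")
  }
  keep <- c(FALSE, sites[-1] == sites[-length(sites)])
  if (!any(keep)) {
    stop_invalid("Durbin-Watson needs at least one site with >= 2 residuals")
  }
  cur <- which(keep)
  sum((residuals[cur] - residuals[cur - 1L])^2) / sum(residuals^2)
}

resolve_coefs <- function(fit) {
  if (inherits(fit, "panel_fit") || is.list(fit)) {
    list(alpha1 = fit$alpha1, alpha2 = fit$alpha2)
  } else {
    stop_invalid("fit must be a panel_fit or a list with alpha1 and alpha2")
  }
}

#' Yield response to a moisture level, relative to SPEI = 0
#'
#' `response(s) = 1000 (alpha1 s + alpha2 s^2)` in kg/ha; zero at s = 0 by
#' construction. With both coefficients negative the response is a concave
#' parabola: wet excess (s > 0) costs more yield than an equal-magnitude
#' drought.
#'
#' @param s SPEI value(s), finite.
#' @param fit A `panel_fit` or any list with elements alpha1 and alpha2
#'   (t/ha units).
#' @return Yield response(s) in kg/ha.
#' @export
yield_response <- function(s, fit) {
  if (any(!is.finite(s))) stop_invalid("SPEI values must be finite")
  cf <- resolve_coefs(fit)
  1000 * (cf$alpha1 * s + cf$alpha2 * s^2)
}

#' Optimum moisture level implied by the fitted parabola
#'
#' The vertex `-alpha1 / (2 alpha2)` of the concave quadratic response.
#'
#' @param fit A `panel_fit` or list with alpha1, alpha2; alpha2 must be
#'   negative.
#' @return The SPEI value maximizing the response.
#' @export
optimum_spei <- function(fit) {
  cf <- resolve_coefs(fit)
  if (!is.finite(cf$alpha2) || cf$alpha2 >= 0) {
    stop_invalid("no interior optimum: alpha2 must be negative")
  }
  -cf$alpha1 / (2 * cf$alpha2)
}

#' Moisture thresholds of yield loss
#'
#' The two roots of `alpha1 s + alpha2 s^2 = 0`, i.e. 0 and
#' `-alpha1 / alpha2`, sorted ascending. Between them the response is
#' positive; outside, moisture costs yield.
#'
#' @param fit A `panel_fit` or list with alpha1, alpha2; alpha2 must be
#'   negative (a zero quadratic term leaves a single root and is reported
#'   as an error).
#' @return Sorted numeric vector of the two root SPEI values.
#' @export
loss_thresholds <- function(fit) {
  cf <- resolve_coefs(fit)
  if (!is.finite(cf$alpha2) || cf$alpha2 == 0) {
    stop_invalid("degenerate response: alpha2 = 0 leaves the single root 0")
  }
  if (cf$alpha2 > 0) stop_invalid("response is convex: alpha2 must be negative")
  sort(c(0, -cf$alpha1 / cf$alpha2))
}

#' Moisture-level yield-response table
#'
#' Evaluates the fitted response at the endpoints of the seven moisture-level
#' SPEI intervals (closed on the drought side). `response_lo`/`response_hi`
#' bound the endpoint-evaluated responses as printed in the reference table
#' (-Inf for the two unbounded levels); `response_max` additionally accounts
#' for the parabola vertex when it falls inside an interval.
#'
#' @param fit A `panel_fit` or list with alpha1, alpha2 (alpha2 < 0).
#' @return A data.frame (level, spei_lo, spei_hi, response_lo, response_hi,
#'   response_max), ordered dry to wet.
#' @export
response_table <- function(fit) {
  cf <- resolve_coefs(fit)
  if (!is.finite(cf$alpha2) || cf$alpha2 >= 0) {
    stop_invalid("response table requires alpha2 < 0")
  }
  lv <- moisture_levels()
  lo <- c(-Inf, -2, -1, -0.5, 0.5, 1, 2)
  hi <- c(-2, -1, -0.5, 0.5, 1, 2, Inf)
  r_at <- function(s) {
    out <- rep(-Inf, length(s))
    out[is.finite(s)] <- yield_response(s[is.finite(s)], cf)
    out
  }
  rlo <- r_at(lo)
  rhi <- r_at(hi)
  vertex <- optimum_spei(cf)
  rmax <- pmax(rlo, rhi)
  inside <- vertex > lo & vertex < hi
  rmax[inside] <- yield_response(vertex, cf)
  data.frame(level = lv,
             spei_lo = lo, spei_hi = hi,
             response_lo = pmin(rlo, rhi),
             response_hi = pmax(rlo, rhi),
             response_max = rmax,
             stringsAsFactors = FALSE)
}

#' Period means of a site-year series, with optional yield responses
#'
#' Averages a per-(site, year) value (typically the SPEI_3_S3 covariate)
#' over all site-years in each period; when a fit is supplied, also
#' evaluates the yield response at each period mean.
#'
#' @param values Data.frame (site, year, value-column).
#' @param periods Named list of non-overlapping integer year vectors, e.g.
#'   `list("1980s" = 1980:1989, "1990s" = 1990:1999, "2000s" = 2000:2014)`.
#' @param fit Optional `panel_fit` (or alpha1/alpha2 list) for responses.
#' @param value_col Name of the value column (default "covariate").
#' @return A data.frame (period, mean, n, and response_kg_ha when fit is
#'   given).
#' @export
decade_summary <- function(values, periods, fit = NULL,
                           value_col = "covariate") {
  check_columns(values, c("site", "year", value_col), "value table")
  if (is.null(names(periods)) || any(!nzchar(names(periods)))) {
    stop_invalid("periods must be a named list")
  }
  all_years <- unlist(periods)
  if (anyDuplicated(all_years)) stop_invalid("periods overlap")
  rows <- lapply(names(periods), function(pn) {
    sel <- values$year %in% periods[[pn]]
    if (!any(sel)) stop_invalid("period %s matches no site-years", pn)
    data.frame(period = pn, mean = mean(values[[value_col]][sel]),
               n = sum(sel), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(fit)) {
    out$response_kg_ha <- yield_response(out$mean, fit)
  }
  row.names(out) <- NULL
  out
}
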