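#' Mann-Kendall trend test with tie correction
#'
#' Computes `S = sum_{k<j} sgn(x_j - x_k)`, its tie-corrected variance
#' `Var(S) = (n (n-1) (2n+5) - sum_i e_i (e_i-1) (2 e_i+5)) / 18` with `e_i`
#' the extent of each group of tied values, the continuity-corrected normal
#' deviate `Z = (S - 1)/sqrt(Var(S))` for S > 0 (0 for S = 0,
#' `(S + 1)/sqrt(Var(S))` for S < 0) and the two-sided p-value. The normal
#' approximation is standard for n > 10; 4 <= n <= 10 is allowed but the
#' result is flagged.
#'
#' @param x Numeric series in time order, n >= 4, finite.
#' @param alpha Two-sided significance level (default 0.05).
#' @return A list of class `trend_result`: S, var_S, Z, p_value, slope
#'   (Sen's), direction ("up"/"down"/"none"), significant, n, alpha,
#'   small_sample.
#' @export
mann_kendall <- function(x, alpha = 0.05) {
  n <- length(x)
  if (n < 4) stop_invalid("Mann-Kendall requires n >= 4 (got %d)", n)
  if (any(!is.finite(x))) stop_invalid("series must be finite")
  d <- outer(x, x, "-")
  S <- sum(sign(d[lower.tri(d)]))  # rows j > cols k: x_j - x_k
  e <- tabulate(match(x, unique(x)))
  var_S <- (n * (n - 1) * (2 * n + 5) - sum(e * (e - 1) * (2 * e + 5))) / 18
  Z <- if (S > 0) (S - 1) / sqrt(var_S) else if (S < 0) (S + 1) / sqrt(var_S) else 0
  p <- 2 * stats::pnorm(-abs(Z))
  significant <- abs(Z) >= stats::qnorm(1 - alpha / 2)
  direction <- if (Z > 0) "up" else if (Z < 0) "down" else "none"
  structure(list(S = S, var_S = var_S, Z = Z, p_value = p,
                 slope = sens_slope(x), direction = direction,
                 significant = significant, n = n, alpha = alpha,
                 small_sample = n <= 10),
            class = "trend_result")
}

#' Sen's slope estimator
#'
#' The median of all n(n-1)/2 pairwise slopes `(x_j - x_k)/(j - k)` for
#' j > k; for an even count the midpoint of the two central values.
#'
#' @param x Numeric series in time order, n >= 2.
#' @return Slope in series units per time step.
#' @export
sens_slope <- function(x) {
  n <- length(x)
  if (n < 2) stop_invalid("Sen's slope requires n >= 2")
  if (any(!is.finite(x))) stop_invalid("series must be finite")
  t <- seq_len(n)
  num <- outer(x, x, "-")
  den <- outer(t, t, "-")
  stats::median(num[lower.tri(num)] / den[lower.tri(den)])
}

#' Trend tests for a collection of per-site series
#'
#' Applies [mann_kendall()] (which includes Sen's slope) identically to one
#' series per site; suitable for annual temperature, precipitation or SPEI
#' summaries.
#'
#' @param df Long data.frame with site, time and value columns.
#' @param value_col,site_col,time_col Column names (defaults "value",
#'   "site", "year").
#' @param alpha Significance level.
#' @return A data.frame with one row per site: S, var_S, Z, p_value, slope,
#'   direction, significant, n.
#' @export
trend_suite <- function(df, value_col = "value", site_col = "site",
                        time_col = "year", alpha = 0.05) {
  check_columns(df, c(site_col, time_col, value_col), "trend input")
  if (!nrow(df)) stop_invalid("empty series collection")
  sites <- unique(df[[site_col]])
  rows <- lapply(sites, function(s) {
    sub <- df[df[[site_col]] == s, , drop = FALSE]
    sub <- sub[order(sub[[time_col]]), , drop = FALSE]
    r <- mann_kendall(sub[[value_col]], alpha = alpha)
    data.frame(site = s, S = r$S, var_S = r$var_S, Z = r$Z,
               p_value = r$p_value, slope = r$slope,
               direction = r$direction, significant = r$significant,
               n = r$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}
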