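# independent brute-force oracles and small fixture builders

# naive O(n^2) pair enumeration of the Mann-Kendall statistic and its
# tie-corrected variance
mk_brute <- function(x) {
  n <- length(x)
  S <- 0
  for (k in 1:(n - 1)) {
    for (j in (k + 1):n) S <- S + sign(x[j] - x[k])
  }
  e <- as.vector(table(x))
  var_S <- (n * (n - 1) * (2 * n + 5) - sum(e * (e - 1) * (2 * e + 5))) / 18
  list(S = S, var_S = var_S)
}

# explicit enumeration of all pairwise slopes
slope_brute <- function(x) {
  n <- length(x)
  s <- c()
  for (k in 1:(n - 1)) {
    for (j in (k + 1):n) s <- c(s, (x[j] - x[k]) / (j - k))
  }
  median(s)
}

# naive windowed sums for the k-month aggregation
agg_brute <- function(d, k) {
  n <- length(d)
  out <- rep(NA_real_, n)
  for (m in k:n) {
    acc <- 0
    for (i in (m - k + 1):m) acc <- acc + d[i]
    out[m] <- acc
  }
  out
}

# two small sites, enough years for every downstream stage
tiny_sites <- function(n = 2) {
  specs <- list(
    site_spec("north", 34.5, 13, 800, warming_slope = 0.05),
    site_spec("south", 31.1, 16, 1200, warming_slope = 0.06),
    site_spec("mid", 32.5, 14.5, 1000, warming_slope = 0.05)
  )
  specs[seq_len(n)]
}

tiny_climate <- function(n_sites = 2, n_years = 36, seed = 7,
                         start_year = 1979) {
  generate_climate(tiny_sites(n_sites), start_year, n_years, seed)
}

# SPEI + S3 covariate + simulated yields for panel tests
tiny_panel_data <- function(seed = 11, rho = 0, error_sd = 0,
                            alpha1 = -0.1592, alpha2 = -0.1297,
                            alpha3 = 0.0626) {
  clim <- tiny_climate(2, 36, seed = 5)
  sp <- compute_spei(clim, scales = 3)
  cov <- season_covariate(sp, "S3", 1980:2014, 3)
  pars <- panel_params(c(north = 3.4, south = 3.0), alpha1, alpha2, alpha3,
                       rho = rho, error_sd = error_sd)
  yields <- generate_yields(cov, pars, seed = seed)
  list(cov = cov, yields = yields, pars = pars)
}
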