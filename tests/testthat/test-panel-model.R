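table5 <- list(alpha1 = -0.1592, alpha2 = -0.1297)

test_that("noise-free data are recovered exactly by LSDV", {
  d <- tiny_panel_data(rho = 0, error_sd = 0)
  fit <- fit_panel(d$yields, d$cov, ar1 = "off")
  expect_equal(fit$alpha1, -0.1592, tolerance = 1e-9)
  expect_equal(fit$alpha2, -0.1297, tolerance = 1e-9)
  expect_equal(fit$alpha3, 0.0626, tolerance = 1e-9)
  expect_equal(unname(fit$site_intercepts),
               unname(d$pars$site_intercepts[names(fit$site_intercepts)]),
               tolerance = 1e-9)
  expect_equal(fit$mean_intercept, mean(d$pars$site_intercepts),
               tolerance = 1e-9)
  expect_false(fit$ar1_applied)
})

test_that("estimates match a pencil-and-paper normal-equations solution", {
  # two sites, five years, no trend term collinearity issues
  cov <- data.frame(site = rep(c("a", "b"), each = 5),
                    year = rep(2001:2005, 2),
                    covariate = c(-1, 0, 1, 2, -2, 0.5, -0.5, 1.5, -1.5, 1))
  set.seed(8)
  y <- 3 + 0.2 * (cov$site == "b") - 0.3 * cov$covariate -
    0.1 * cov$covariate^2 + 0.05 * rep(1:5, 2) + rnorm(10, 0, 0.05)
  yields <- data.frame(site = cov$site, year = cov$year, yield_t_ha = y)
  fit <- fit_panel(yields, cov, ar1 = "off")
  X <- cbind(a = as.numeric(cov$site == "a"),
             b = as.numeric(cov$site == "b"),
             s = cov$covariate, s2 = cov$covariate^2, t = rep(1:5, 2))
  beta <- solve(t(X) %*% X, t(X) %*% y)  # normal equations oracle
  expect_equal(unname(fit$site_intercepts), beta[1:2, 1], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(fit$alpha1, unname(beta[3, 1]), tolerance = 1e-9)
  expect_equal(fit$alpha2, unname(beta[4, 1]), tolerance = 1e-9)
  expect_equal(fit$alpha3, unname(beta[5, 1]), tolerance = 1e-9)
})

test_that("a constant covariate is a named estimation error", {
  d <- tiny_panel_data()
  d$cov$covariate <- 1
  expect_error(fit_panel(d$yields, d$cov), "rank-deficient")
})

test_that("Durbin-Watson behaves as theory predicts", {
  # perfectly alternating residuals approach 4
  n <- 40
  alt <- rep(c(0.5, -0.5), n / 2)
  expect_equal(durbin_watson(alt), 4 * (n - 1) / n)
  # i.i.d. residuals give about 2; persistent residuals well below 1
  set.seed(19)
  expect_equal(durbin_watson(rnorm(5000)), 2, tolerance = 0.1)
  expect_lt(durbin_watson(simulate_ar1(3000, 0.9, 1, seed = 2)), 1)
  # differences are confined within sites
  e <- c(1, 1.1, 50, 50.1)
  sites <- c("a", "a", "b", "b")
  within <- ((1.1 - 1)^2 + (50.1 - 50)^2) / sum(e^2)
  expect_equal(durbin_watson(e, sites), within)
  expect_error(durbin_watson(c(1, 2), c("a", "b")), "at least one site")
})

test_that("AR(1) errors are absorbed and rho recovered", {
  d <- tiny_panel_data(rho = 0.39, error_sd = 0.2, seed = 30)
  fit <- fit_panel(d$yields, d$cov, ar1 = "auto")
  expect_true(fit$ar1_applied)
  expect_lt(abs(fit$rho - 0.39), 0.25)   # single replicate, loose
  expect_lt(abs(fit$alpha1 + 0.1592), 0.1)
  expect_lt(abs(fit$alpha2 + 0.1297), 0.1)
  expect_true(fit$dw < 1.5 || fit$dw > 2.5)
})

test_that("shifting all yields moves intercepts only", {
  d <- tiny_panel_data(rho = 0, error_sd = 0.1, seed = 44)
  f1 <- fit_panel(d$yields, d$cov, ar1 = "off")
  shifted <- d$yields
  shifted$yield_t_ha <- shifted$yield_t_ha + 5
  f2 <- fit_panel(shifted, d$cov, ar1 = "off")
  expect_equal(f2$site_intercepts, f1$site_intercepts + 5, tolerance = 1e-9)
  expect_equal(f2$alpha1, f1$alpha1, tolerance = 1e-9)
  expect_equal(f2$alpha2, f1$alpha2, tolerance = 1e-9)
  expect_equal(f2$alpha3, f1$alpha3, tolerance = 1e-9)
})

test_that("yield response reproduces the reference response surface", {
  expect_equal(round(yield_response(2, table5), 1), -837.2)
  expect_equal(round(yield_response(-1, table5), 1), 29.5)
  expect_equal(yield_response(0, table5), 0)
  expect_equal(round(yield_response(-2, table5), 1), -200.4)
})

test_that("optimum and loss thresholds are the parabola vertex and roots", {
  expect_equal(round(optimum_spei(table5), 2), -0.61)
  expect_equal(optimum_spei(list(alpha1 = 0, alpha2 = -1)), 0)
  th <- loss_thresholds(table5)
  expect_equal(round(th, 2), c(-1.23, 0))
  expect_equal(yield_response(th, table5), c(0, 0), tolerance = 1e-9)
  # vertex property: response decreases away from the optimum
  opt <- optimum_spei(table5)
  for (eps in c(0.01, 0.1, 0.5, 1)) {
    expect_lt(yield_response(opt + eps, table5),
              yield_response(opt, table5))
    expect_lt(yield_response(opt - eps, table5),
              yield_response(opt, table5))
  }
  # thresholds bracket the optimum; response positive strictly between,
  # negative outside
  expect_true(th[1] < opt && opt < th[2])
  grid_in <- seq(th[1] + 1e-6, th[2] - 1e-6, length.out = 100)
  grid_out <- c(seq(-4, th[1] - 1e-6, length.out = 50),
                seq(th[2] + 1e-6, 4, length.out = 50))
  expect_true(all(yield_response(grid_in, table5) > 0))
  expect_true(all(yield_response(grid_out, table5) < 0))
  expect_error(optimum_spei(list(alpha1 = 1, alpha2 = 0.5)), "optimum")
  expect_error(loss_thresholds(list(alpha1 = 1, alpha2 = 0)), "degenerate")
})

test_that("the response table reproduces the reference intervals", {
  tab <- response_table(table5)
  expect_equal(tab$level, moisture_levels())
  pick <- function(lv) tab[tab$level == lv, ]
  sw <- pick("slight wetting")
  expect_equal(round(c(sw$response_lo, sw$response_hi), 1), c(-288.9, -112.0))
  nm <- pick("normal")
  expect_equal(round(c(nm$response_lo, nm$response_hi), 1), c(-112.0, 47.2))
  ed <- pick("extreme drought")
  expect_equal(round(ed$response_hi, 1), -200.4)
  expect_equal(ed$response_lo, -Inf)
  ew <- pick("extreme wetting")
  expect_equal(round(ew$response_hi, 1), -837.2)
  # vertex-aware maximum only differs where the optimum lies inside
  sd_ <- pick("slight drought")
  expect_equal(sd_$response_max,
               yield_response(optimum_spei(table5), table5))
  expect_gt(sd_$response_max, sd_$response_hi)
  expect_equal(nm$response_max, nm$response_hi)
})

test_that("wet excess always costs more than equal drought", {
  L <- seq(0.01, 4, by = 0.01)
  expect_true(all(abs(yield_response(L, table5)) >
                  abs(yield_response(-L, table5))))
})

test_that("decade summaries average site-years and map through the response", {
  vals <- expand.grid(site = c("a", "b"), year = 1980:2014)
  vals$covariate <- 0.5
  ds <- decade_summary(vals, list(p1 = 1980:1989, p2 = 1990:1999,
                                  p3 = 2000:2014))
  expect_equal(ds$mean, rep(0.5, 3))
  expect_equal(ds$n, c(20, 20, 30))

  # reference decade means map to the printed responses
  m <- data.frame(site = "a", year = c(1985, 1995, 2005),
                  covariate = c(0.0422, 0.3225, -0.3772))
  ds2 <- decade_summary(m, list(`1980s` = 1980:1989, `1990s` = 1990:1999,
                                `2000s` = 2000:2014), fit = table5)
  expect_equal(round(ds2$response_kg_ha, 2), c(-6.95, -64.83, 41.60))

  expect_error(decade_summary(vals, list(a = 1980:1990, b = 1990:1999)),
               "overlap")
  expect_error(decade_summary(vals, list(a = 1900:1910)), "matches no")
})

test_that("parameter recovery is unbiased under the reference regime", {
  clim <- tiny_climate(2, 36, seed = 5)
  sp <- compute_spei(clim, scales = 3)
  cov <- season_covariate(sp, "S3", 1980:2014, 3)
  pars <- panel_params(c(north = 3.4, south = 3.0),
                       -0.1592, -0.1297, 0.0626, rho = 0.39, error_sd = 0.25)
  est <- vapply(1:100, function(i) {
    y <- generate_yields(cov, pars, seed = 2000 + i)
    f <- fit_panel(y, cov, ar1 = "on")
    c(f$alpha1, f$alpha2, f$alpha3)
  }, numeric(3))
  mc_se <- apply(est, 1, sd) / sqrt(ncol(est))
  expect_lt(abs(mean(est[1, ]) + 0.1592), 2 * mc_se[1] + 0.01)
  expect_lt(abs(mean(est[2, ]) + 0.1297), 2 * mc_se[2] + 0.01)
  expect_lt(abs(mean(est[3, ]) - 0.0626), 2 * mc_se[3] + 0.005)
})
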