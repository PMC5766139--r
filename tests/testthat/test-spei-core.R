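test_that("Thornthwaite PET follows the hand-computed reference", {
  # freezing cutoff
  t_cold <- c(rep(0, 6), rep(-5, 6))
  expect_equal(thornthwaite_pet(t_cold, 40), rep(0, 12))

  # constant 20 C at the equator: independent step-by-step evaluation
  pet <- thornthwaite_pet(rep(20, 12), 0)
  I <- 12 * (20 / 5)^1.514
  a <- 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239
  base <- 16 * (10 * 20 / I)^a
  ndm <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  expect_equal(pet, base * ndm / 30, tolerance = 1e-10)  # N = 12 h at lat 0

  # hemisphere daylength symmetry
  t_year <- 15 + 10 * cos(2 * pi * (1:12 - 7) / 12)
  north <- thornthwaite_pet(t_year, 35)
  south <- thornthwaite_pet(t_year, -35)
  expect_gt(north[7], south[7])
  expect_gt(south[12], north[12])

  expect_error(thornthwaite_pet(rep(10, 5), 35), "12 month")
  expect_error(thornthwaite_pet(rep(10, 12), 100), "latitude")
})

test_that("water balance is the elementwise P - PET difference", {
  expect_equal(water_balance(50, 30), 20)
  expect_equal(water_balance(0, 80), -80)
  expect_equal(water_balance(c(10, 20), c(10, 20)), c(0, 0))
  expect_error(water_balance(1:3, 1:2), "equal length")
})

test_that("k-month aggregation matches the naive windowed sum", {
  expect_equal(aggregate_balance(c(1, 2, 3, 4), 1), c(1, 2, 3, 4))
  expect_equal(aggregate_balance(c(1, 2, 3, 4), 3), c(NA, NA, 6, 9))
  set.seed(10)
  d <- rnorm(60)
  for (k in c(1, 3, 6, 9, 12)) {
    expect_equal(aggregate_balance(d, k), agg_brute(d, k))
  }
  expect_error(aggregate_balance(d, 0), "k must be")
  expect_error(aggregate_balance(d, 61), "exceeds")
})

test_that("log-logistic L-moment fit recovers known parameters", {
  tru <- structure(list(alpha = 50, beta = 3, gamma = 10, reflected = FALSE),
                   class = "loglogistic_params")
  set.seed(42)
  x <- qloglogistic(runif(10000), tru)
  f <- fit_loglogistic(x)
  expect_lt(abs(f$alpha - 50) / 50, 0.10)
  expect_lt(abs(f$beta - 3) / 3, 0.10)
  expect_lt(abs(f$gamma - 10) / abs(50 + 10), 0.10)

  # fitted median lies between the sample 40th and 60th percentiles
  med <- qloglogistic(0.5, f)
  q <- quantile(x, c(0.4, 0.6))
  expect_gt(med, q[1])
  expect_lt(med, q[2])

  expect_error(fit_loglogistic(rnorm(5)), "at least 10")
  expect_error(fit_loglogistic(rep(3, 20)), "degenerate")
})

test_that("negatively skewed samples are fitted through reflection", {
  tru <- structure(list(alpha = 50, beta = 3, gamma = 10, reflected = FALSE),
                   class = "loglogistic_params")
  set.seed(9)
  x <- -qloglogistic(runif(500), tru)  # mirror image: negative L-skew
  f <- fit_loglogistic(x)
  expect_true(f$reflected)
  expect_gt(f$beta, 1)
  # CDF round-trips through the quantile function
  u <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  expect_equal(ploglogistic(qloglogistic(u, f), f), u, tolerance = 1e-10)
  # and is increasing on the data range
  g <- seq(min(x), max(x), length.out = 50)
  expect_true(all(diff(ploglogistic(g, f)) >= 0))
})

test_that("standardization matches an independent normal-quantile oracle", {
  p <- seq(0.001, 0.999, by = 0.0005)
  expect_lt(max(abs(standardize_spei(p) - qnorm(1 - p))), 4.5e-4)
  expect_lt(abs(standardize_spei(0.5)), 1e-3)
  expect_equal(standardize_spei(0.025), 1.95996, tolerance = 4.5e-4)
  expect_equal(standardize_spei(0.975), -standardize_spei(0.025))
  # strictly decreasing in the exceedance probability
  expect_true(all(diff(standardize_spei(p)) < 0))
  expect_error(standardize_spei(0), "strictly in")
  expect_error(standardize_spei(1), "strictly in")
})

test_that("moisture classification uses the documented interval scheme", {
  expect_equal(as.character(classify_spei(-2.0)), "extreme drought")
  expect_equal(as.character(classify_spei(0.0)), "normal")
  expect_equal(as.character(classify_spei(1.0)), "moderate wetting")
  x <- c(-2.5, -2, -1.5, -1, -0.7, -0.5, -0.49, 0.49, 0.5, 0.99, 1, 1.99, 2, 3)
  got <- as.character(classify_spei(x))
  expect_equal(got, c("extreme drought", "extreme drought",
                      "moderate drought", "moderate drought",
                      "slight drought", "slight drought",
                      "normal", "normal",
                      "slight wetting", "slight wetting",
                      "moderate wetting", "moderate wetting",
                      "extreme wetting", "extreme wetting"))
  expect_error(classify_spei(NA_real_), "finite")
})

test_that("compute_spei standardizes every calendar month on a long record", {
  clim <- tiny_climate(2, 36, seed = 7)
  sp <- compute_spei(clim, scales = c(1, 3))
  for (k in c(1, 3)) {
    sub <- sp[sp$scale == k & !is.na(sp$spei), ]
    stats <- aggregate(spei ~ site + month, data = sub,
                       FUN = function(v) c(m = mean(v), s = sd(v)))
    expect_true(all(abs(stats$spei[, "m"]) <= 0.05))
    expect_true(all(stats$spei[, "s"] >= 0.9 & stats$spei[, "s"] <= 1.1))
    # undefined prefix of length k - 1 per site
    for (site in unique(sp$site)) {
      s2 <- sp[sp$scale == k & sp$site == site, ]
      s2 <- s2[order(s2$year, s2$month), ]
      expect_equal(sum(is.na(s2$spei)), k - 1)
      if (k > 1) expect_true(all(is.na(s2$spei[seq_len(k - 1)])))
    }
  }
})

test_that("within a calendar month, wetter aggregated balance means higher SPEI", {
  clim <- tiny_climate(1, 36, seed = 12)
  sub <- clim[order(clim$year, clim$month), ]
  pet <- thornthwaite_pet(sub$tmean_c, sub$latitude[1], sub$month)
  d <- water_balance(sub$precip_mm, pet)
  agg <- aggregate_balance(d, 3)
  sp <- compute_spei(clim, scales = 3)
  sp <- sp[order(sp$year, sp$month), ]
  for (m in c(1, 6, 10)) {
    idx <- which(sub$month == m & !is.na(agg))
    expect_equal(order(agg[idx]), order(sp$spei[idx]))
    # wettest month of the aggregated record attains the maximal SPEI
    expect_equal(which.max(agg[idx]), which.max(sp$spei[idx]))
  }
})

test_that("SPEI per site is unaffected by other sites in the panel", {
  clim <- tiny_climate(2, 36, seed = 7)
  both <- compute_spei(clim, scales = 1)
  alone <- compute_spei(clim[clim$site == "north", ], scales = 1)
  expect_equal(both$spei[both$site == "north"], alone$spei)
})

test_that("gappy or duplicated climate records are rejected by name", {
  clim <- tiny_climate(1, 3, seed = 1)
  gap <- clim[-14, ]  # drop Feb of year 2
  expect_error(compute_spei(gap, scales = 1), "missing month")
  expect_error(validate_climate(rbind(clim, clim[5, ])), "duplicate")
})
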