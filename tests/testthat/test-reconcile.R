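test_that("wealth-relative temptation reproduces the published table values", {
  # b = D|C / (C|C * w); w = 1 wealthy, 0.4 poor
  expect_equal(round(wealth_relative_temptation(1.2, 1.1, 1), 2), 1.09)
  expect_equal(round(wealth_relative_temptation(1.6, 1.1, 1), 2), 1.45)
  expect_equal(wealth_relative_temptation(2.2, 1.1, 1), 2.0)
  expect_equal(round(wealth_relative_temptation(1.2, 1.1, 0.4), 1), 2.7)
  expect_equal(wealth_relative_temptation(1.2, 1.1, 0.4), 1.2 / 0.44)
  expect_error(wealth_relative_temptation(1.2, 0, 1), "positive")
})

test_that("temptation is scale-free in the payoffs", {
  set.seed(50)
  for (k in runif(10, 0.1, 10)) {
    expect_equal(wealth_relative_temptation(k * 2.2, k * 1.1, 0.4),
                 wealth_relative_temptation(2.2, 1.1, 0.4))
  }
})

test_that("GDP-normalised temptation behaves like a day's-wage ratio", {
  expect_equal(normalized_temptation(3750, stake = 15, divisor = 250), 2)
  expect_equal(normalized_temptation(3750, stake = 0), 1)  # no temptation
  # strictly decreasing in wealth basis, increasing in stake
  b <- normalized_temptation(c(2000, 5000, 20000, 50000), stake = 15)
  expect_true(all(diff(b) < 0))
  b2 <- normalized_temptation(10000, stake = c(0, 5, 15, 50))
  expect_true(all(diff(b2) > 0))
  expect_error(normalized_temptation(-1, 15), "positive")
})

test_that("density prediction interpolates linearly and clamps at the ends", {
  crv <- temptation_curve(c(1.0, 1.2, 2.0), c(0.95, 0.85, 0.2), "toy")
  expect_equal(predict_density(crv, 1.2), 0.85)        # knot
  expect_equal(predict_density(crv, 1.1), 0.90)        # midpoint
  expect_equal(predict_density(crv, 0.5), 0.95)        # clamp low
  expect_equal(predict_density(crv, 3.0), 0.2)         # clamp high
  expect_error(temptation_curve(1, 0.5), "at least 2")
  expect_error(temptation_curve(c(1, 1), c(0.9, 0.8)), "strictly increasing")
  expect_error(temptation_curve(c(1, 2), c(0.9, 1.2)), "\\[0, 1\\]")

  # monotone non-increasing whenever the curve is
  set.seed(51)
  for (rep in 1:10) {
    d <- sort(runif(5), decreasing = TRUE)
    crv2 <- temptation_curve(sort(runif(5, 1, 2)), d)
    x <- seq(0.8, 2.4, by = 0.05)
    expect_true(all(diff(predict_density(crv2, x)) <= 1e-12))
  }
})

test_that("correlation pipeline recovers perfect and inverted relations", {
  crv <- temptation_curve(seq(1, 2, 0.25), c(0.95, 0.8, 0.6, 0.4, 0.2))
  countries <- country_records(data.frame(
    name = paste0("c", 1:5),
    wealth_basis_usd = c(3800, 6000, 10000, 20000, 38000),
    stake_usd = 15, divisor = 250,
    observed_fraction = 0.5))
  pred <- predict_density(crv, normalized_temptation(countries))
  countries$observed_fraction <- pred        # identical
  expect_equal(correlate_predictions(crv, countries)$r, 1.0)
  countries$observed_fraction <- 0.5 - (pred - mean(pred))  # negated, centred
  rec <- correlate_predictions(crv, countries)
  expect_equal(rec$r, -1.0)
  # Pearson r is invariant to affine rescaling of the observations
  countries$observed_fraction <- pmin(1, pmax(0, 0.1 + 0.5 * pred))
  expect_equal(correlate_predictions(crv, countries)$r, 1.0)

  countries$observed_fraction <- 0.4
  expect_error(correlate_predictions(crv, countries), "zero variance")
  expect_error(correlate_predictions(crv, countries[1:2, ]), "at least 3")
})

test_that("country tables are validated field by field", {
  good <- data.frame(name = "x", wealth_basis_usd = 1000, stake_usd = 15,
                     divisor = 250, observed_fraction = 0.5)
  expect_s3_class(country_records(good), "farmers_countries")
  bad <- good; bad$divisor <- 100
  expect_error(country_records(bad), "divisor")
  expect_silent(country_records(bad, strict_divisor = FALSE))
  bad2 <- good; bad2$observed_fraction <- 1.5
  expect_error(country_records(bad2), "observed_fraction")
  expect_error(country_records(good[, -2]), "missing columns")
})

test_that("synthetic fixture supports offline pipeline validation", {
  fx <- generate_curve_fixture(seed = 7, noise_sd = 0, displacement = -0.1)
  rec <- correlate_predictions(fx$curve, fx$countries)
  expect_equal(rec$r, 1.0)
  expect_equal(rec$displacement, -0.1)
  # published-style range: day's-wage temptation across countries
  b <- normalized_temptation(fx$countries)
  expect_true(all(b > 1 & b < 2))

  fx2 <- generate_curve_fixture(seed = 7, noise_sd = 0, displacement = -0.1)
  expect_identical(fx, fx2)

  # noise degrades the correlation in expectation
  mean_r <- function(noise) {
    mean(vapply(1:25, function(s) {
      f <- generate_curve_fixture(seed = s, noise_sd = noise)
      correlate_predictions(f$curve, f$countries)$r
    }, numeric(1)))
  }
  r_low <- mean_r(0.02); r_mid <- mean_r(0.1); r_high <- mean_r(0.4)
  expect_gt(r_low, r_mid)
  expect_gt(r_mid, r_high)
})

test_that("curves round-trip through CSV and feed the multi-curve table", {
  crv <- temptation_curve(c(1, 1.5, 2), c(0.9, 0.5, 0.2), "roundtrip")
  f <- withr::local_tempfile(fileext = ".csv")
  write_curve(crv, f)
  back <- read_curve(f, name = "roundtrip")
  expect_equal(back$b, crv$b)
  expect_equal(back$density, crv$density)

  fx <- generate_curve_fixture(seed = 3)
  tab <- reconcile_curves(list(crv, fx$curve), fx$countries)
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$r >= -1 & tab$r <= 1))
})
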