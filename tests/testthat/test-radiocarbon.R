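test_that("birth year is exact integer arithmetic on both date formats", {
  expect_identical(birth_year("2017-02-09", 59), 1958L)
  expect_identical(birth_year("02/09/2017", 59), 1958L)
  expect_identical(birth_year("1980-08-21", 14), 1966L)
  expect_identical(birth_year(2005, 0), 2005L)
  expect_error(birth_year(2005, -1), ">= 0")
  expect_error(birth_year("9 Feb 2017", 1), "unparseable")
})

test_that("core-sample audit recomputes years and flags inconsistencies", {
  path <- system.file("extdata", "warsaw_core_d14c.csv", package = "warsawlh")
  cs <- read_core_samples(path)
  expect_equal(nrow(cs), 14)
  get <- function(id, col) cs[cs$sample_id == id, col]
  expect_equal(get("WRG-0675", "year_of_formation"), 1958L)
  expect_equal(get("WRG-17-SPO", "year_of_formation"), 1963L)
  expect_equal(get("WRG-1", "year_of_formation"), 1966L)
  # rows whose printed year contradicts the caption rule are flagged, and
  # the printed value is preserved, not overwritten
  expect_setequal(cs$sample_id[cs$year_mismatch],
                  c("WRG-0022", "WRG-1465", "WRG-7"))
  expect_equal(get("WRG-0022", "printed_year"), 2008L)
  expect_equal(get("WRG-0022", "year_of_formation"), 2004L)
  # "NM" and "--" parse as missing
  expect_true(is.na(get("WRG-0675", "d13c")))
  expect_true(is.na(get("WRG-3201", "oto_mass_mg")))
})

test_that("loess reproduces a global quadratic exactly", {
  x <- seq(1950, 2010, length.out = 60)
  y <- 3 + 0.5 * (x - 1980) + 0.02 * (x - 1980)^2
  fit <- fit_loess(data.frame(year = x, d14c = y), span = 0.2)
  qs <- c(1955.3, 1967.1, 1980, 1999.9, 2008.2)
  expect_equal(predict(fit, qs), 3 + 0.5 * (qs - 1980) + 0.02 * (qs - 1980)^2,
               tolerance = 1e-8)
})

test_that("loess equals the brute-force local regression oracle", {
  set.seed(11)
  for (n in c(30, 50)) {
    x <- sort(runif(n, 1945, 2015))
    y <- sin(x / 7) * 60 + rnorm(n, 0, 6)
    span <- 0.3
    fit <- fit_loess(data.frame(year = x, d14c = y), span = span)
    qs <- runif(20, min(x) + 1, max(x) - 1)
    expect_equal(predict(fit, qs),
                 vapply(qs, loess_oracle, numeric(1), xs = x, ys = y,
                        span = span),
                 tolerance = 1e-8)
  }
})

test_that("loess tracks the bomb-curve mean through the rise", {
  cfg <- bomb_curve_config(seed = 21)
  fit <- fit_loess(generate_reference_series(cfg))
  rise <- seq(cfg$rise_start_year, cfg$peak_year, by = 1)
  expect_true(all(abs(predict(fit, rise) - bomb_curve_mean(cfg, rise)) <
                    2 * cfg$noise_sd))
})

test_that("loess rejects extrapolation and too-small windows", {
  ref <- generate_reference_series(bomb_curve_config(seed = 1))
  fit <- fit_loess(ref)
  expect_error(predict(fit, 1900), "extrapolation")
  expect_error(fit_loess(ref[1:12, ], span = 0.2), "too few points")
  expect_error(fit_loess(ref[1:5, ]), ">= 10")
})

test_that("Bonferroni band reduces to the pointwise CI at m = 1 and widens with m", {
  fit <- fit_loess(generate_reference_series(bomb_curve_config(seed = 2)))
  yrs <- c(1960, 1970, 1990)
  b1 <- predict_with_bonferroni_ci(fit, yrs, m = 1)
  p <- predict(fit, yrs, se = TRUE)
  expect_equal(b1$hi - b1$mean, qt(0.975, p$df) * p$se)
  b14 <- predict_with_bonferroni_ci(fit, yrs, m = 14)
  expect_true(all(b14$hi > b1$hi) && all(b14$lo < b1$lo))
  expect_true(all(b14$lo <= b14$mean & b14$mean <= b14$hi))
  expect_error(predict_with_bonferroni_ci(fit, yrs, m = 0), "m must be")
})

test_that("simultaneous coverage of the Bonferroni band is at least nominal", {
  # the band is an interval for the smooth: the multiplicity correction
  # must give >= 95% simultaneous coverage of the estimator's own mean at
  # all 14 query years (coverage of the true generator curve additionally
  # loses a little to smoothing bias where curvature is strong, a
  # documented loess property)
  cfg <- bomb_curve_config(seed = NULL)
  yrs <- seq(1962, 2005, length.out = 14)
  set.seed(300)
  fits <- los <- his <- matrix(NA_real_, 500, 14)
  for (i in 1:500) {
    cfg$seed <- 1000L + i
    band <- predict_with_bonferroni_ci(
      fit_loess(generate_reference_series(cfg)), yrs, m = 14)
    fits[i, ] <- band$mean; los[i, ] <- band$lo; his[i, ] <- band$hi
  }
  efit <- colMeans(fits)
  cover <- vapply(1:500, function(i)
    all(los[i, ] <= efit & efit <= his[i, ]), logical(1))
  expect_gte(mean(cover), 0.95)
  # and coverage of the true generator mean stays close to nominal
  truth <- bomb_curve_mean(cfg, yrs)
  cover_truth <- vapply(1:500, function(i)
    all(los[i, ] <= truth & truth <= his[i, ]), logical(1))
  expect_gte(mean(cover_truth), 0.90)
})

test_that("residual test accepts on-curve samples and flags pre-bomb ones", {
  cfg <- bomb_curve_config(seed = 5)
  fit <- fit_loess(generate_reference_series(cfg))
  yrs <- seq(1962, 2000, length.out = 10)
  samples <- data.frame(year_of_formation = c(yrs, 1940),
                        d14c = c(predict(fit, yrs), -55))
  rt <- residual_test(fit, samples)
  expect_true(rt$consistent)          # zero residuals
  expect_equal(rt$mean_zero_p, 1)
  expect_equal(rt$n, 10)
  expect_equal(nrow(rt$excluded), 1)  # 1940 predates the reference series
  expect_error(residual_test(fit, samples[11, , drop = FALSE]),
               "insufficient")
})

test_that("SSR profile is zero at no shift for on-curve rise samples", {
  fit <- fit_loess(generate_reference_series(bomb_curve_config(seed = 6)))
  yrs <- seq(1961, 1973, by = 1)
  samples <- data.frame(year_of_formation = yrs, d14c = predict(fit, yrs))
  prof <- ssr_bias_profile(fit, samples)
  expect_equal(prof$ssr_d14c[prof$shift == 0], 0, tolerance = 1e-12)
  expect_true(all(prof$ssr_d14c[prof$shift != 0] > 0))
  expect_true(all(prof$ssr_d14c >= 0))
  expect_identical(attr(prof, "best_shift"), 0L)
  # birth-year mode: inverse prediction recovers the years on the rise
  expect_equal(prof$ssr_birth_year[prof$shift == 0], 0, tolerance = 1e-4)
})

test_that("inverse prediction flags values below the pre-bomb plateau", {
  fit <- fit_loess(generate_reference_series(bomb_curve_config(seed = 6)))
  samples <- data.frame(year_of_formation = c(1965, 1950),
                        d14c = c(predict(fit, 1965), -200))
  prof <- ssr_bias_profile(fit, samples)
  expect_equal(attr(prof, "n_inverse_flagged"), 1L)
})
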