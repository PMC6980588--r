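test_that("VBGF mean length: root, asymptote, and a spot value", {
  gp <- true_params()
  expect_equal(vbgf_mean_length(gp, gp[["t0"]]), 1)   # floored at 1 mm
  expect_equal(vbgf_mean_length(gp, 500), 1533, tolerance = 1e-6)
  expect_equal(vbgf_mean_length(gp, 10),
               1533 * (1 - exp(-0.14 * (10 - 1.82))))  # 1045.26 mm
  expect_error(vbgf_mean_length(gp, 0), "> 0")
})

test_that("logistic selectivity: midpoint, saturation, monotonicity", {
  gp <- true_params()
  expect_equal(logistic_selectivity(gp, 812), 0.5)
  expect_equal(logistic_selectivity(gp, 812 + 78.8), 1 / (1 + exp(-1)))
  expect_equal(logistic_selectivity(gp, 1e6), 1)
  l <- seq(0, 2500, by = 10)
  expect_true(all(diff(logistic_selectivity(gp, l)) > 0))
})

test_that("growth_params validates its domain", {
  expect_error(growth_params(1533, 0.14, 1.82, 0.17, 812, 78.8, 0.066, -0.1),
               "positive")
  expect_error(growth_params(1533, 0.14, 1.82, 1.2, 812, 78.8, 0.066, 0.34),
               "cv_len")
})

test_that("composition grid normalises and respects smoothing", {
  grid <- catch_composition(true_params())
  expect_equal(sum(grid), 1, tolerance = 1e-12)
  expect_true(all(grid > 0))  # every cell keeps at least eps mass
  expect_equal(dim(grid), c(65L, 50L))
})

test_that("with saturated selectivity the age marginal is geometric in Z", {
  gp <- growth_params(1533, 0.14, 1.82, 0.17, 0.001, 0.001, 0.066, 0.34)
  grid <- catch_composition(gp)
  z <- 0.066 + 0.34
  expected <- exp(-z * (0:64))
  expected <- expected / sum(expected)
  expect_equal(rowSums(grid), expected, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("with F = 0 and saturated selectivity mean length tracks the VBGF", {
  gp <- growth_params(1533, 0.14, 1.82, 0.17, 0.001, 0.001, 0.066, 1e-9)
  grid <- catch_composition(gp)
  ml <- as.vector(grid %*% attr(grid, "bin_mid")) / rowSums(grid)
  mu <- vbgf_mean_length(gp, 1:65)
  expect_true(all(abs(ml[5:50] - mu[5:50]) / mu[5:50] < 0.005))
})

test_that("size-selective fishing depresses mean length at older ages", {
  gp <- true_params()
  nofish <- growth_params(1533, 0.14, 1.82, 0.17, 812, 78.8, 0.066, 1e-9)
  gridF <- catch_composition(gp)
  grid0 <- catch_composition(nofish)
  mids <- attr(gridF, "bin_mid")
  mlF <- as.vector(gridF %*% mids) / rowSums(gridF)
  ml0 <- as.vector(grid0 %*% mids) / rowSums(grid0)
  expect_true(all(mlF[20:60] <= ml0[20:60] + 1e-9))
  expect_lt(mlF[40], ml0[40])  # strictly below once F has acted for decades
})

test_that("survivorship declines with age for every growth group", {
  gp <- true_params()
  grid <- catch_composition(gp)
  # age marginal of catch beyond full selection must decay
  pa <- rowSums(grid)
  expect_true(all(diff(pa[15:65]) < 0))
})

test_that("log-likelihood equals a brute-force per-observation sum", {
  gp <- true_params()
  obs <- simulate_catch(gp, 100, seed = 23)
  grid <- catch_composition(gp)
  brute <- sum(vapply(seq_len(nrow(obs)), function(i) {
    a <- obs$age_years[i]
    b <- min(max(ceiling(obs$tl_mm[i] / 50), 1), 50)
    log(grid[a, b])
  }, numeric(1)))
  expect_equal(log_likelihood(gp, obs), brute, tolerance = 1e-12)
  # permutation invariance
  expect_equal(log_likelihood(gp, obs[sample(nrow(obs)), ]),
               log_likelihood(gp, obs))
  # single observation equals its cell log-probability
  one <- data.frame(age_years = 10, tl_mm = 1030)
  expect_equal(log_likelihood(gp, one), log(grid[10, 21]))
  expect_error(log_likelihood(gp, data.frame(age_years = 99, tl_mm = 500)),
               "outside grid")
})

test_that("log-prior matches an independent log-normal density sum", {
  priors <- growth_priors()
  at_median <- do.call(growth_params, as.list(setNames(priors$median,
                                                       priors$parameter)))
  expect_equal(log_prior(at_median, priors),
               sum(-log(priors$log_sd * sqrt(2 * pi))))
  gp <- true_params()
  oracle <- sum(-0.5 * ((log(unclass(gp)) - log(priors$median)) /
                          priors$log_sd)^2 -
                  log(priors$log_sd * sqrt(2 * pi)))
  expect_equal(log_prior(gp, priors), oracle, tolerance = 1e-10)
  bad <- unclass(gp); bad["k"] <- -1
  expect_identical(log_prior(bad, priors), -Inf)
})

test_that("simulate_catch is reproducible and honours grid frequencies", {
  gp <- true_params()
  s1 <- simulate_catch(gp, 500, seed = 77)
  expect_identical(s1, simulate_catch(gp, 500, seed = 77))
  # size-at-age envelope at old ages spans roughly linf +/- a third
  big <- simulate_catch(gp, 50000, seed = 78)
  old <- big$tl_mm[big$age_years > 20]
  expect_gt(max(old), 1533 + 300)
  expect_lt(min(old), 1533 - 300)
  expect_lt(max(old), 1533 + 700)
})

test_that("Hewitt-Hoenig longevity M and mortality summaries", {
  expect_equal(hewitt_hoenig_m(61), 0.069)
  expect_equal(hewitt_hoenig_m(4.22), 1)
  expect_equal(hewitt_hoenig_m(42.2), 0.1)
  expect_error(hewitt_hoenig_m(0), "> 0")
  ms <- mortality_summary(0.34, 0.066)
  expect_equal(ms$z, 0.406)
  expect_equal(mortality_summary(0, 0.1)$f_to_m, 0)
  expect_equal(mortality_summary(0.1, 0.1)$f_to_m_reported, 1.0)
  expect_error(mortality_summary(0.3, 0), "undefined")
})

test_that("least-squares VBGF recovers noiseless data exactly", {
  gp <- true_params()
  age <- 1:40
  obs <- data.frame(age_years = age,
                    tl_mm = 1533 * (1 - exp(-0.14 * (age - 1.82))))
  fit <- fit_vbgf_least_squares(obs)
  expect_true(fit$converged)
  expect_equal(fit$linf, 1533, tolerance = 1e-6)
  expect_equal(fit$k, 0.14, tolerance = 1e-6)
  expect_equal(fit$t0, 1.82, tolerance = 1e-5)
  expect_error(fit_vbgf_least_squares(data.frame(age_years = rep(3, 9),
                                                 tl_mm = 1:9)), "distinct")
})

test_that("least-squares VBGF is structurally biased on selective catch data", {
  # fitting the raw catch ignores gear selectivity (which inflates mean
  # length at young ages) and size-selective mortality (which depresses it
  # at old ages), so plain least squares cannot recover the true curve
  obs <- simulate_catch(true_params(), 1338, seed = 41)
  fit <- fit_vbgf_least_squares(obs)
  expect_true(fit$converged)
  expect_lt(fit$linf, 0.95 * 1533)  # asymptotic length pulled well below truth
  expect_lt(fit$t0, 1.82)           # age intercept pulled below truth
  expect_gt(fit$k, 0.14)            # growth coefficient compensates upward
})
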