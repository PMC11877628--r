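test_that("gaussian fit reproduces sample moments and flags degeneracy", {
  f0 <- fit_gamma_distribution(c(0, 0, 0, 0))
  expect_equal(f0$mu, 0)
  expect_equal(f0$sigma, 0)
  expect_true(f0$degenerate)
  f1 <- fit_gamma_distribution(c(-1, 1))
  expect_equal(f1$mu, 0)
  expect_equal(f1$sigma, sqrt(2))
  set.seed(101)
  draws <- rnorm(1e4, 0.2, 0.05)
  f2 <- fit_gamma_distribution(draws)
  expect_lt(abs(f2$mu - 0.2), 3 * 0.05 / sqrt(1e4))
  expect_error(fit_gamma_distribution(0.3), "at least two")
})

test_that("the counting cutoff is the one-sided 95% quantile of the fit", {
  f <- structure(list(mu = 0, sigma = 1, n = 100, degenerate = FALSE),
                 class = "gamma_fit")
  expect_equal(counting_cutoff(f), qnorm(0.95))
  expect_equal(counting_cutoff(f), 1.6449, tolerance = 1e-4)
  f2 <- structure(list(mu = 0.1, sigma = 0.05, n = 100, degenerate = FALSE),
                  class = "gamma_fit")
  expect_equal(counting_cutoff(f2), 0.1 + qnorm(0.95) * 0.05)
  expect_equal(counting_cutoff(f2), 0.18224, tolerance = 1e-4)
  f3 <- structure(list(mu = 0, sigma = 0, n = 10, degenerate = TRUE),
                  class = "gamma_fit")
  expect_error(counting_cutoff(f3), "degenerate")
})

test_that("five percent of a large reference sample lies above its own cutoff", {
  set.seed(2024)
  g <- rnorm(15000, 0.45, 0.1)
  cut <- counting_cutoff(fit_gamma_distribution(g))
  frac <- mean(g > cut)
  se <- sqrt(0.05 * 0.95 / 15000)
  expect_lt(abs(frac - 0.05), 3 * se)
})

test_that("delta-NP% matches its arithmetic definition", {
  set.seed(7)
  g <- rnorm(2000, 0.4, 0.1)
  self <- delta_np_percent(g, g, 0.55)
  expect_equal(self$delta_np_percent, 0)
  # shuffling rows changes nothing
  expect_equal(delta_np_percent(sample(g), g, 0.55)$delta_np_percent, 0)
  # the printed example: 1500 vs 750 exceedances out of 15000 each -> 5%
  samp <- c(rep(1, 1500), rep(-1, 13500))
  ref <- c(rep(1, 750), rep(-1, 14250))
  expect_equal(delta_np_percent(samp, ref, 0)$delta_np_percent, 5.0)
  expect_error(delta_np_percent(numeric(0), g, 0.5), "both groups")
})

test_that("monte-carlo delta-NP% matches the closed-form normal tail", {
  # reference N(mu, sigma), sample N(mu + delta, sigma):
  # E[delta-NP%] = 100 * (1 - pnorm(qnorm(0.95) - delta/sigma) - 0.05)
  mu <- 0.45
  sigma <- 0.1
  delta <- sigma  # one-sigma shift
  closed <- 100 * (1 - pnorm(qnorm(0.95) - 1) - 0.05)
  expect_equal(closed, 20.95, tolerance = 1e-3)
  set.seed(88)
  n <- 20000
  ref <- rnorm(n, mu, sigma)
  samp <- rnorm(n, mu + delta, sigma)
  cut <- counting_cutoff(fit_gamma_distribution(ref))
  mc <- delta_np_percent(samp, ref, cut)$delta_np_percent
  se <- 100 * sqrt(2 * 0.26 * 0.74 / n)  # conservative binomial bound
  expect_lt(abs(mc - closed), 3 * se)
})

test_that("standard curve recovers an exact line", {
  pts <- data.frame(concentration = 10^c(-1, 0, 1, 2),
                    delta_np = 2 * c(-1, 0, 1, 2) + 1)
  fit <- standard_curve(pts)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$sigma_int, 0, tolerance = 1e-10)
  expect_error(standard_curve(pts[1:2, ]), "three distinct")
  expect_error(standard_curve(transform(pts, concentration = concentration - 1)),
               "> 0")
})

test_that("slope and intercept are recovered within their fit intervals", {
  set.seed(55)
  x <- c(-1, -0.2, 0.6, 1.4, 2.2, 3)
  pts <- do.call(rbind, lapply(x, function(xi) {
    data.frame(concentration = 10^xi,
               delta_np = 2 * xi + 1 + rnorm(6, 0, 0.1))
  }))
  fit <- standard_curve(pts)
  ci <- confint(fit$model)
  expect_gte(2, ci[2, 1]); expect_lte(2, ci[2, 2])
  expect_gte(1, ci[1, 1]); expect_lte(1, ci[1, 2])
  expect_gt(fit$r_squared, 0.99)
})

test_that("LOD and LOQ follow the 3.3/10 sigma-over-slope formulas", {
  fit <- structure(list(slope = 3.3, intercept = 0, sigma_int = 1,
                        r_squared = 1, df = 1, x_transform = "identity",
                        means = data.frame(concentration = 1:3,
                                           mean_delta_np = 1:3)),
                   class = "calibration_fit")
  lim <- lod_loq(fit)
  expect_equal(lim$lod, 1.0)
  expect_equal(lim$loq, 10 / 3.3)
  # dilution factor scales both linearly
  fit10 <- fit
  fit10$df <- 10
  lim10 <- lod_loq(fit10)
  expect_equal(lim10$lod, 10 * lim$lod)
  expect_equal(lim10$loq, 10 * lim$loq)
  # the LOQ/LOD ratio is structural
  expect_equal(lim$loq / lim$lod, 10 / 3.3)
  fit$sigma_int <- 2
  expect_equal(lod_loq(fit)$lod, 2.0)
  fit$slope <- -1
  expect_error(lod_loq(fit), "slope must be > 0")
  # log10 fits also report back-transformed concentrations
  fit_log <- structure(list(slope = 5, intercept = 10, sigma_int = 0.5,
                            r_squared = 1, df = 1, x_transform = "log10",
                            means = data.frame(concentration = 1:3,
                                               mean_delta_np = 1:3)),
                       class = "calibration_fit")
  lim_log <- lod_loq(fit_log)
  expect_equal(lim_log$lod_back_transformed, 10^lim_log$lod)
  expect_equal(lim_log$loq_back_transformed, 10^lim_log$loq)
})

test_that("quantification inverts the calibration and reports recovery", {
  pts <- data.frame(concentration = 10^c(-1, 0, 1, 2),
                    delta_np = 2 * c(-1, 0, 1, 2) + 1)
  fit <- standard_curve(pts)
  # round-trip through a point prediction
  y <- fit$intercept + fit$slope * 1  # log10(c) = 1
  q <- quantify(y, fit, expected = 10)
  expect_equal(q$concentration, 10, tolerance = 1e-9)
  expect_equal(q$recovery_percent, 100, tolerance = 1e-9)
  q2 <- quantify(y, fit, expected = 10 / 0.96)
  expect_equal(q2$recovery_percent, 96, tolerance = 1e-6)
  expect_false(q$extrapolated)
  expect_warning(quantify(100, fit), "extrapolation")
})

test_that("expected delta-NP% is monotone in concentration and zero at zero", {
  conc <- c(0, 0.1, 0.63, 4, 25, 160, 1000)
  e <- expected_delta_np(conc)
  expect_equal(e[1], 0)
  expect_true(all(diff(e) >= 0))
  expect_true(all(e >= 0))
})
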