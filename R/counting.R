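#' Gaussian fit of a per-spot gamma sample
#'
#' Maximum-likelihood Normal fit: sample mean and sample standard deviation
#' (n - 1 denominator). The per-spot gamma values of a homogeneous particle
#' population are well described by a single Gaussian, which is what the
#' counting cutoff is derived from.
#'
#' @param gammas Numeric vector of per-spot gamma values (n >= 2).
#' @return An object of class `gamma_fit`: `mu`, `sigma`, `n`, `degenerate`
#'   (TRUE when sigma is zero).
#' @export
fit_gamma_distribution <- function(gammas) {
  gammas <- as.numeric(gammas[is.finite(gammas)])
  if (length(gammas) < 2L) {
    stop("need at least two gamma values to fit a distribution",
         call. = FALSE)
  }
  mu <- mean(gammas)
  sigma <- stats::sd(gammas)
  structure(
    list(mu = mu, sigma = sigma, n = length(gammas),
         degenerate = sigma == 0),
    class = "gamma_fit"
  )
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat(sprintf("<gamma_fit> mu %.4f, sigma %.4f, n %d%s\n", x$mu, x$sigma,
              x$n, if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Digital counting cutoff from the negative-control fit
#'
#' The cutoff marking the upper tail of the reference (negative-control)
#' gamma distribution: `mu + z * sigma` with `z` the one-sided Normal
#' quantile at `level` (1.6449 at the default 95%), so 5% of the fitted
#' reference distribution lies above the cutoff.
#'
#' @param fit A [fit_gamma_distribution()] result for the reference group.
#' @param level One-sided confidence level (default 0.95).
#' @return The cutoff gamma value.
#' @export
counting_cutoff <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "gamma_fit"))
  if (fit$sigma <= 0) {
    stop("degenerate reference distribution (sigma = 0); no cutoff exists",
         call. = FALSE)
  }
  fit$mu + stats::qnorm(level) * fit$sigma
}

#' Digital counting statistic delta-NP%
#'
#' Counts, in the sample and the reference group, the spots whose gamma
#' strictly exceeds the cutoff, and reports the difference of the two count
#' rates in percent:
#' `delta_NP% = 100 * (NP_sample / n_sample - NP_reference / n_reference)`.
#' Using rates rather than raw counts makes unequal group sizes comparable.
#'
#' @param sample_gammas,reference_gammas Numeric gamma vectors (non-empty).
#' @param cutoff Cutoff derived from the reference fit
#'   ([counting_cutoff()]).
#' @return An object of class `counting_result`: `cutoff`, `np_ref`,
#'   `np_sample`, `n_ref`, `n_sample`, `delta_np_percent`.
#' @export
delta_np_percent <- function(sample_gammas, reference_gammas, cutoff) {
  sample_gammas <- as.numeric(sample_gammas[is.finite(sample_gammas)])
  reference_gammas <- as.numeric(reference_gammas[is.finite(reference_gammas)])
  if (length(sample_gammas) == 0L || length(reference_gammas) == 0L) {
    stop("both groups must contain gamma values", call. = FALSE)
  }
  np_s <- sum(sample_gammas > cutoff)
  np_r <- sum(reference_gammas > cutoff)
  structure(
    list(cutoff = cutoff, np_ref = np_r, np_sample = np_s,
         n_ref = length(reference_gammas), n_sample = length(sample_gammas),
         delta_np_percent = 100 * (np_s / length(sample_gammas) -
                                     np_r / length(reference_gammas))),
    class = "counting_result"
  )
}

#' @export
print.counting_result <- function(x, ...) {
  cat(sprintf(
    "<counting_result> cutoff %.4f: %d/%d sample vs %d/%d reference above; delta-NP%% = %.3f\n",
    x$cutoff, x$np_sample, x$n_sample, x$np_ref, x$n_ref,
    x$delta_np_percent))
  invisible(x)
}

#' Fit the standard curve of delta-NP% against concentration
#'
#' Ordinary least squares of the replicate-mean delta-NP% on
#' log10(concentration) (the calibration range spans four decades, so the
#' log axis is the default; set `log10_x = FALSE` for a linear axis).
#' Per-concentration replicate standard deviations are retained for
#' reporting.
#'
#' @param points Data frame with columns `concentration` (pg/mL, > 0) and
#'   `delta_np` (%), one row per replicate.
#' @param df Dilution factor of the sample matrix (1 for water, 10 for
#'   diluted plasma/serum); enters only the LOD/LOQ formulas.
#' @param log10_x Regress on log10(concentration) (default) or on the
#'   linear concentration.
#' @return An object of class `calibration_fit`: `slope`, `intercept`,
#'   `sigma_int` (standard error of the intercept), `r_squared`, `df`,
#'   `x_transform`, `means` (per-concentration summary) and the fitted
#'   `model`.
#' @export
standard_curve <- function(points, df = 1, log10_x = TRUE) {
  if (!all(c("concentration", "delta_np") %in% names(points))) {
    stop("points needs 'concentration' and 'delta_np' columns", call. = FALSE)
  }
  conc <- unique(points$concentration)
  if (length(conc) < 3L) {
    stop("need at least three distinct concentrations", call. = FALSE)
  }
  if (log10_x && any(points$concentration <= 0)) {
    stop("concentrations must be > 0 for the log10 transform", call. = FALSE)
  }
  if (df < 1) stop("dilution factor must be >= 1", call. = FALSE)
  agg <- stats::aggregate(delta_np ~ concentration, data = points,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                              n = length(v)))
  means <- data.frame(concentration = agg$concentration,
                      mean_delta_np = agg$delta_np[, "mean"],
                      sd_delta_np = agg$delta_np[, "sd"],
                      n = agg$delta_np[, "n"])
  x <- if (log10_x) log10(means$concentration) else means$concentration
  fit <- stats::lm(means$mean_delta_np ~ x)
  sm <- summary(fit)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         sigma_int = unname(sm$coefficients["(Intercept)", "Std. Error"]),
         r_squared = sm$r.squared,
         df = df,
         x_transform = if (log10_x) "log10" else "identity",
         means = means,
         model = fit),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "<calibration_fit> delta-NP%% = %.4g + %.4g * %s(c); R^2 = %.4f, sigma_int = %.4g, DF = %g\n",
    x$intercept, x$slope,
    if (x$x_transform == "log10") "log10" else "", x$r_squared, x$sigma_int,
    x$df))
  invisible(x)
}

#' Limits of detection and quantification from a calibration fit
#'
#' `LOD = DF * 3.3 * sigma_int / S` and `LOQ = DF * 10 * sigma_int / S`,
#' where `S` is the slope, `sigma_int` the standard deviation of the
#' intercept and `DF` the dilution factor. The formulas are applied on the
#' fit's own x scale; when the fit used log10(concentration) the
#' back-transformed values `10^LOD` / `10^LOQ` are reported alongside, since
#' the literature applies the formula on either scale.
#'
#' @param fit A [standard_curve()] result with positive slope.
#' @return List with `lod`, `loq` (fit scale) and, for log10 fits,
#'   `lod_back_transformed`, `loq_back_transformed` (concentration units).
#' @export
lod_loq <- function(fit) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (!is.finite(fit$slope) || fit$slope <= 0) {
    stop("invalid calibration: slope must be > 0", call. = FALSE)
  }
  lod <- fit$df * 3.3 * fit$sigma_int / fit$slope
  loq <- fit$df * 10 * fit$sigma_int / fit$slope
  out <- list(lod = lod, loq = loq)
  if (fit$x_transform == "log10") {
    out$lod_back_transformed <- 10^lod
    out$loq_back_transformed <- 10^loq
  }
  out
}

#' Quantify a measurement against the calibration
#'
#' Inverts the standard curve: `x = (delta_np - intercept)/slope`, back-
#' transformed to a concentration when the fit used log10(concentration).
#' When the expected concentration is supplied, the recovery rate
#' `100 * measured/expected` is reported (80-120% is the conventional
#' acceptance window).
#'
#' @param delta_np Measured delta-NP% value(s).
#' @param fit A [standard_curve()] result.
#' @param expected Optional expected concentration(s), same units as the
#'   calibration.
#' @return Data frame with `delta_np`, `concentration`, `extrapolated`
#'   (TRUE when `delta_np` lies outside the calibrated response range) and,
#'   when `expected` is given, `expected` and `recovery_percent`.
#' @export
quantify <- function(delta_np, fit, expected = NULL) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (fit$slope == 0) stop("invalid calibration: zero slope", call. = FALSE)
  x <- (delta_np - fit$intercept) / fit$slope
  conc <- if (fit$x_transform == "log10") 10^x else x
  rng <- range(fit$means$mean_delta_np)
  out <- data.frame(delta_np = delta_np, concentration = conc,
                    extrapolated = delta_np < rng[1] | delta_np > rng[2])
  if (any(out$extrapolated)) {
    warning("delta_np outside the calibrated range; result is an extrapolation",
            call. = FALSE)
  }
  if (!is.null(expected)) {
    out$expected <- expected
    out$recovery_percent <- 100 * conc / expected
  }
  out
}

#' Expected delta-NP% of the simulator, noiseless
#'
#' Closed-form (quadrature) expectation of the counting statistic under the
#' simulator's population model, without imaging noise: integrates the
#' ground-truth gamma of the bound and unbound shell states over the
#' truncated-Normal diameter distribution and evaluates
#' `100 * p(c) * (P[gamma_bound > cutoff] - P[gamma_base > cutoff])`.
#' Useful as a deterministic reference for the dose-response trend.
#'
#' @param concentration Analyte concentration(s) in pg/mL.
#' @param pop A [population_config()].
#' @param binding A [binding_model()].
#' @param bands A [band_set()].
#' @param cutoff Optional gamma cutoff; defaults to the Gaussian-fit cutoff
#'   of the noiseless negative-control population.
#' @param constants Material table for the core.
#' @return Numeric vector of expected delta-NP% values.
#' @export
expected_delta_np <- function(concentration, pop = population_config(),
                              binding = binding_model(),
                              bands = nonadjacent_bands(), cutoff = NULL,
                              constants = gold_johnson_christy()) {
  lut <- .band_lut(pop, bands, constants)
  # truncated-normal diameter weights on the LUT grid
  d <- lut$diam
  lo <- pop$mean_diameter - 3 * pop$sd_diameter
  hi <- pop$mean_diameter + 3 * pop$sd_diameter
  w <- stats::dnorm(d, pop$mean_diameter, pop$sd_diameter)
  w[d < lo | d > hi] <- 0
  w <- w / sum(w)
  g_base <- (lut$base[, "r"] - lut$base[, "g"]) /
    (lut$base[, "r"] + lut$base[, "g"])
  g_bound <- (lut$bound[, "r"] - lut$bound[, "g"]) /
    (lut$bound[, "r"] + lut$bound[, "g"])
  if (is.null(cutoff)) {
    mu <- sum(w * g_base)
    sigma <- sqrt(sum(w * (g_base - mu)^2))
    cutoff <- mu + stats::qnorm(0.95) * sigma
  }
  tail_base <- sum(w * (g_base > cutoff))
  tail_bound <- sum(w * (g_bound > cutoff))
  p <- bound_probability(binding, concentration)
  100 * p * (tail_bound - tail_base)
}
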