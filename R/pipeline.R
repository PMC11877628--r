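#' Assemble a full run configuration
#'
#' One nested configuration object covering every stage of the pipeline:
#' optics (particle and material), instrument (bands), simulation
#' (population, binding, imaging), detection, and counting (confidence
#' level, dilution factor). Every run writes its resolved configuration and
#' a content hash next to its outputs, so two runs with equal hashes are
#' identical.
#'
#' @param pop A [population_config()].
#' @param binding A [binding_model()].
#' @param img An [imaging_config()].
#' @param bands A [band_set()].
#' @param detection A [detection_params()].
#' @param level One-sided confidence level of the counting cutoff.
#' @param df Dilution factor for LOD/LOQ (1 water, 10 plasma/serum).
#' @return An object of class `run_config`.
#' @export
run_config <- function(pop = population_config(), binding = binding_model(),
                       img = imaging_config(), bands = nonadjacent_bands(),
                       detection = detection_params(), level = 0.95,
                       df = 1) {
  structure(
    list(pop = pop, binding = binding, img = img, bands = bands,
         detection = detection, level = level, df = df),
    class = "run_config"
  )
}

# polynomial rolling hash (mod 2^31 - 1) over the serialized object;
# a compact deterministic content fingerprint
.config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 17
  for (b in bytes) {
    h <- (h * 131 + b) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

.config_json <- function(config) {
  list(
    population = unclass(config$pop),
    binding = unclass(config$binding),
    imaging = unclass(config$img),
    bands = list(g_band = config$bands$g_band, r_band = config$bands$r_band),
    detection = config$detection[
      !vapply(config$detection, is.null, logical(1))],
    level = config$level,
    df = config$df,
    hash = .config_hash(unclass(config))
  )
}

#' Simulate datasets for a list of concentrations
#'
#' One subdirectory per concentration (named `conc_<value>`), each holding
#' the two channel stacks, the ground-truth table and a manifest; the
#' resolved configuration is written to `config.json` in `out_dir`.
#'
#' @param config A [run_config()].
#' @param concentrations Numeric vector of concentrations in pg/mL (0 is
#'   the negative control).
#' @param out_dir Output directory (created if missing).
#' @param n_spots Spots per condition.
#' @param seed Base integer seed; condition `i` uses `seed + 10 * i`.
#' @return Character vector of dataset directories, invisibly.
#' @export
run_simulate <- function(config, concentrations, out_dir, n_spots = 15000,
                         seed = 1L) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop(sprintf("cannot create output directory: %s", out_dir),
         call. = FALSE)
  }
  jsonlite::write_json(.config_json(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  dirs <- character(length(concentrations))
  for (i in seq_along(concentrations)) {
    d <- file.path(out_dir, paste0("conc_", format(concentrations[i],
                                                   trim = TRUE)))
    generate_dataset(concentrations[i], n_spots = n_spots, pop = config$pop,
                     binding = config$binding, img = config$img,
                     bands = config$bands, seed = seed + 10L * i,
                     out_dir = d)
    dirs[i] <- d
  }
  invisible(dirs)
}

#' Analyse one or more simulated dataset directories
#'
#' Calibrates the oversize threshold once (aggregate-free negative-control
#' render under the same configuration) when the configured `max_area` is
#' `NULL`, then runs [analyze_dataset()] on each directory.
#'
#' @param dirs Dataset directories.
#' @param config A [run_config()].
#' @param seed Seed for the area-threshold calibration render.
#' @return Named list of `spot_analysis` objects, invisibly.
#' @export
run_analyze <- function(dirs, config, seed = 99L) {
  stopifnot(inherits(config, "run_config"))
  params <- config$detection
  if (is.null(params$max_area)) {
    params$max_area <- calibrate_max_area(config$pop, config$img,
                                          config$bands, params, seed = seed)
  }
  out <- lapply(dirs, function(d) {
    if (!dir.exists(d)) stop(sprintf("dataset directory not found: %s", d),
                             call. = FALSE)
    analyze_dataset(d, params)
  })
  names(out) <- basename(dirs)
  invisible(out)
}

#' Calibrate from per-condition spot tables
#'
#' Fits the negative-control gamma distribution, places the counting
#' cutoff, computes delta-NP% for every non-reference condition, fits the
#' standard curve on log10(concentration), and derives LOD/LOQ. The
#' negative control (concentration 0) is mandatory: the method is
#' self-referenced against it.
#'
#' @param gamma_tables Named list: names are concentrations in pg/mL
#'   (as written by `format()`, e.g. `"0"`, `"0.1"`), values are numeric
#'   gamma vectors or data frames with a `gamma` column.
#' @param config A [run_config()] (supplies `level` and `df`).
#' @param out_file Optional path for the JSON report.
#' @return List of class `calibration_report`: `fit_nc`, `cutoff`,
#'   `conditions` (per-condition counting results), `curve`, `lod_loq`.
#' @export
run_calibrate <- function(gamma_tables, config = run_config(),
                          out_file = NULL) {
  gv <- lapply(gamma_tables, function(x) {
    if (is.data.frame(x)) x$gamma else as.numeric(x)
  })
  conc <- suppressWarnings(as.numeric(names(gv)))
  if (any(is.na(conc))) {
    stop("gamma_tables must be named by numeric concentrations",
         call. = FALSE)
  }
  if (!any(conc == 0)) {
    stop("a negative control (concentration 0) is required: the counting cutoff is self-referenced",
         call. = FALSE)
  }
  if (sum(conc > 0) < 3L) {
    stop("need at least three non-zero concentrations plus the negative control",
         call. = FALSE)
  }
  nc <- unlist(gv[conc == 0], use.names = FALSE)
  fit_nc <- fit_gamma_distribution(nc)
  cutoff <- counting_cutoff(fit_nc, config$level)
  idx <- which(conc > 0)
  conditions <- lapply(idx, function(i) delta_np_percent(gv[[i]], nc, cutoff))
  names(conditions) <- names(gv)[idx]
  points <- data.frame(
    concentration = conc[idx],
    delta_np = vapply(conditions, function(x) x$delta_np_percent, numeric(1))
  )
  curve <- standard_curve(points, df = config$df)
  limits <- lod_loq(curve)
  report <- structure(
    list(fit_nc = fit_nc, cutoff = cutoff, conditions = conditions,
         curve = curve, lod_loq = limits),
    class = "calibration_report"
  )
  if (!is.null(out_file)) {
    jsonlite::write_json(
      list(
        negative_control = list(mu = fit_nc$mu, sigma = fit_nc$sigma,
                                n = fit_nc$n),
        cutoff = cutoff,
        delta_np_percent = lapply(conditions, function(x) {
          list(delta_np_percent = x$delta_np_percent,
               np_sample = x$np_sample, n_sample = x$n_sample,
               np_ref = x$np_ref, n_ref = x$n_ref)
        }),
        curve = list(slope = curve$slope, intercept = curve$intercept,
                     sigma_int = curve$sigma_int,
                     r_squared = curve$r_squared,
                     x_transform = curve$x_transform, df = curve$df),
        lod_loq = limits,
        config_hash = .config_hash(unclass(config))
      ),
      out_file, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  report
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("<calibration_report> cutoff %.4f (NC mu %.4f, sigma %.4f, n %d)\n",
              x$cutoff, x$fit_nc$mu, x$fit_nc$sigma, x$fit_nc$n))
  for (nm in names(x$conditions)) {
    cat(sprintf("  %s pg/mL: delta-NP%% = %.3f\n", nm,
                x$conditions[[nm]]$delta_np_percent))
  }
  cat(sprintf("  slope %.4g, intercept %.4g, R^2 %.4f\n",
              x$curve$slope, x$curve$intercept, x$curve$r_squared))
  cat(sprintf("  LOD %.4g, LOQ %.4g (fit scale, DF = %g)\n",
              x$lod_loq$lod, x$lod_loq$loq, x$curve$df))
  invisible(x)
}

#' Simulate and analyse one condition in memory
#'
#' Convenience wrapper for computational experiments: generates a dataset at
#' one concentration (without touching disk), runs spot detection and
#' photometry, and returns the per-spot gamma table. The oversize threshold
#' must already be resolved in `config$detection$max_area` (see
#' [calibrate_max_area()]).
#'
#' @param concentration Analyte concentration in pg/mL.
#' @param n_spots Minimum number of non-aggregate spots to simulate.
#' @param config A [run_config()] with a resolved `max_area`.
#' @param seed Integer seed.
#' @return The `spot_analysis` object; its `spots$gamma` column is the
#'   measured gamma sample of the condition.
#' @export
simulate_and_analyze <- function(concentration, n_spots = 15000,
                                 config = run_config(), seed = 1L) {
  if (is.null(config$detection$max_area)) {
    stop("config$detection$max_area must be calibrated first", call. = FALSE)
  }
  ds <- generate_dataset(concentration, n_spots = n_spots, pop = config$pop,
                         binding = config$binding, img = config$img,
                         bands = config$bands, seed = seed)
  analyze_frames(ds$frames$r, ds$frames$g, config$detection)
}

#' Run the full pipeline: simulate, analyse, calibrate
#'
#' @param config A [run_config()].
#' @param concentrations Non-zero concentrations (pg/mL); the negative
#'   control (0) is added automatically.
#' @param out_dir Output directory.
#' @param n_spots Spots per condition.
#' @param seed Base integer seed.
#' @return The `calibration_report`, invisibly; all artifacts (stacks, spot
#'   tables, summaries, `report.json`) are written under `out_dir`.
#' @export
run_pipeline <- function(config, concentrations, out_dir, n_spots = 15000,
                         seed = 1L) {
  conc_all <- c(0, sort(concentrations[concentrations > 0]))
  dirs <- run_simulate(config, conc_all, out_dir, n_spots = n_spots,
                       seed = seed)
  analyses <- run_analyze(dirs, config, seed = seed + 991L)
  gammas <- lapply(analyses, function(a) a$spots$gamma)
  names(gammas) <- vapply(conc_all, function(x) format(x, trim = TRUE),
                          character(1))
  report <- run_calibrate(gammas, config,
                          out_file = file.path(out_dir, "report.json"))
  invisible(report)
}
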