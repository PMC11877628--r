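#' Nanoparticle population description
#'
#' The particle population the simulator draws from: core diameters are
#' Normal(`mean_diameter`, `sd_diameter`) truncated to +/- 3 SD (matching the
#' nominal 80 +/- 9 nm colloid), a small fraction of particles are aggregates
#' (doublets), and every particle wears a protein shell of `base_shell`
#' (capture antibody + PEG, 1.67 nm) that grows to `bound_shell` (1.77 nm)
#' when an analyte molecule is captured.
#'
#' @param mean_diameter,sd_diameter Core diameter distribution (nm).
#' @param aggregate_fraction Fraction of drawn particles that are doublets.
#' @param base_shell,bound_shell Shell thicknesses (nm) of the unbound and
#'   bound states; `bound_shell >= base_shell`.
#' @param shell_index,medium_index Refractive indices of shell and medium.
#' @return An object of class `population_config`.
#' @export
population_config <- function(mean_diameter = 80, sd_diameter = 9,
                              aggregate_fraction = 0.02,
                              base_shell = 1.67, bound_shell = 1.77,
                              shell_index = 1.45, medium_index = 1.333) {
  if (sd_diameter < 0) stop("sd_diameter must be >= 0", call. = FALSE)
  if (aggregate_fraction < 0 || aggregate_fraction > 1) {
    stop("aggregate_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (bound_shell < base_shell) {
    stop("bound_shell must be >= base_shell", call. = FALSE)
  }
  structure(
    list(mean_diameter = mean_diameter, sd_diameter = sd_diameter,
         aggregate_fraction = aggregate_fraction,
         base_shell = base_shell, bound_shell = bound_shell,
         shell_index = shell_index, medium_index = medium_index),
    class = "population_config"
  )
}

#' Analyte binding model
#'
#' Per-particle occupancy probability at analyte concentration `c`:
#' `p = c^h / (c^h + kd^h)` (Langmuir isotherm for `hill = 1`). A particle
#' that captures analyte carries the `bound_shell` thickness, otherwise the
#' `base_shell`.
#'
#' @param kd Concentration at half occupancy, in pg/mL.
#' @param hill Hill coefficient (dimensionless).
#' @return An object of class `binding_model`.
#' @export
binding_model <- function(kd = 1, hill = 1) {
  if (kd <= 0) stop("kd must be > 0", call. = FALSE)
  structure(list(kd = kd, hill = hill), class = "binding_model")
}

#' Occupancy probability of the binding model
#'
#' @param model A [binding_model()].
#' @param concentration Analyte concentration(s) in pg/mL (>= 0).
#' @return Bound probability in `[0, 1]` per concentration.
#' @export
bound_probability <- function(model, concentration) {
  stopifnot(inherits(model, "binding_model"))
  concentration <- as.numeric(concentration)
  if (any(concentration < 0)) {
    stop("concentration must be >= 0", call. = FALSE)
  }
  ifelse(concentration == 0, 0,
         concentration^model$hill /
           (concentration^model$hill + model$kd^model$hill))
}

#' Imaging and camera configuration for the simulator
#'
#' @param frame_shape Frame size in pixels, `c(rows, cols)`.
#' @param psf_sigma Gaussian point-spread-function sigma in pixels (>= 0.5).
#' @param photons_per_unit_cross_section Conversion from band-integrated
#'   scattering cross-section (nm^2 x nm of bandwidth) to expected detected
#'   photons per spot and channel. The default (0.1) gives the dimmest
#'   particle of the default population (53 nm) a few thousand photons per
#'   spot, so the per-spot gamma measurement error (< 0.03 even for the
#'   dimmest spots) stays small against the size-dispersion gamma spread of
#'   the 80 +/- 9 nm population (about 0.10).
#' @param background_level Constant background in counts per pixel.
#' @param read_noise_sd Gaussian read noise SD in counts.
#' @param spots_per_frame Number of particles placed per frame.
#' @return An object of class `imaging_config`.
#' @export
imaging_config <- function(frame_shape = c(256, 256), psf_sigma = 1.4,
                           photons_per_unit_cross_section = 0.1,
                           background_level = 100, read_noise_sd = 2,
                           spots_per_frame = 50) {
  if (psf_sigma < 0.5) stop("psf_sigma must be >= 0.5 px", call. = FALSE)
  if (any(frame_shape < 32)) stop("frame_shape must be >= 32 px", call. = FALSE)
  if (photons_per_unit_cross_section <= 0 || background_level < 0 ||
      read_noise_sd < 0 || spots_per_frame < 1) {
    stop("invalid imaging configuration", call. = FALSE)
  }
  structure(
    list(frame_shape = as.integer(frame_shape), psf_sigma = psf_sigma,
         photons_per_unit_cross_section = photons_per_unit_cross_section,
         background_level = background_level, read_noise_sd = read_noise_sd,
         spots_per_frame = as.integer(spots_per_frame)),
    class = "imaging_config"
  )
}

#' Draw a particle sample from the population
#'
#' @param n Number of particles (> 0).
#' @param pop A [population_config()].
#' @param seed Integer seed; the sample is reproducible bit-for-bit under a
#'   fixed seed (R's default Mersenne-Twister generator).
#' @return A data frame with columns `id`, `diameter` (nm), `is_aggregate`.
#' @export
sample_particles <- function(n, pop = population_config(), seed = 1L) {
  stopifnot(inherits(pop, "population_config"))
  n <- as.integer(n)
  if (n <= 0) stop("n must be > 0", call. = FALSE)
  set.seed(as.integer(seed))
  if (pop$sd_diameter == 0) {
    d <- rep(pop$mean_diameter, n)
  } else {
    lo <- pop$mean_diameter - 3 * pop$sd_diameter
    hi <- pop$mean_diameter + 3 * pop$sd_diameter
    d <- stats::rnorm(n, pop$mean_diameter, pop$sd_diameter)
    bad <- which(d < lo | d > hi)
    while (length(bad) > 0L) {
      d[bad] <- stats::rnorm(length(bad), pop$mean_diameter, pop$sd_diameter)
      bad <- bad[d[bad] < lo | d[bad] > hi]
    }
  }
  agg <- if (pop$aggregate_fraction > 0) {
    stats::runif(n) < pop$aggregate_fraction
  } else {
    rep(FALSE, n)
  }
  data.frame(id = seq_len(n), diameter = d, is_aggregate = agg)
}

#' Assign shell thicknesses by stochastic analyte binding
#'
#' Each particle captures analyte with probability given by the binding
#' model at `concentration` and receives the `bound_shell` thickness;
#' unbound particles keep the `base_shell`.
#'
#' @param particles Data frame from [sample_particles()].
#' @param concentration Analyte concentration in pg/mL (>= 0).
#' @param model A [binding_model()].
#' @param pop A [population_config()] supplying the two shell states.
#' @param seed Integer seed.
#' @return `particles` with added columns `bound` (logical), `shell` (nm).
#' @export
bind_analyte <- function(particles, concentration, model = binding_model(),
                         pop = population_config(), seed = 1L) {
  p <- bound_probability(model, concentration)
  set.seed(as.integer(seed))
  bound <- stats::runif(nrow(particles)) < p
  particles$bound <- bound
  particles$shell <- ifelse(bound, pop$bound_shell, pop$base_shell)
  particles
}

# ---- per-particle band photon lookup -------------------------------------

# Band intensities as a function of diameter are smooth; evaluating the Mie
# series on a 0.5 nm diameter grid and interpolating keeps dataset
# generation fast without visible loss of accuracy (<1e-5 relative).
.lut_key <- function(pop, bands, grid_range) {
  paste(format(c(unlist(bands[c("g_band", "r_band")]), pop$base_shell,
                 pop$bound_shell, pop$shell_index, pop$medium_index,
                 grid_range), digits = 12), collapse = "|")
}

.band_lut <- function(pop, bands, constants = gold_johnson_christy()) {
  d_lo <- max(2, pop$mean_diameter - 3 * pop$sd_diameter - 1)
  d_hi <- pop$mean_diameter + 3 * pop$sd_diameter + 1
  key <- .lut_key(pop, bands, c(d_lo, d_hi))
  cached <- .nanochrome_cache$lut[[key]]
  if (!is.null(cached)) return(cached)
  diam <- seq(d_lo, d_hi, by = 0.5)
  wl_g <- seq(bands$g_band[1], bands$g_band[2], by = 1)
  wl_r <- seq(bands$r_band[1], bands$r_band[2], by = 1)
  eval_one <- function(d, shell) {
    m <- particle_model(d, shell, shell_index = pop$shell_index,
                        medium_index = pop$medium_index)
    vg <- coated_sphere_cross_section(m, wl_g, constants)
    vr <- coated_sphere_cross_section(m, wl_r, constants)
    c(g = sum(diff(wl_g) * (vg[-1] + vg[-length(vg)]) / 2),
      r = sum(diff(wl_r) * (vr[-1] + vr[-length(vr)]) / 2))
  }
  tab_base <- t(vapply(diam, eval_one, numeric(2), shell = pop$base_shell))
  tab_bound <- t(vapply(diam, eval_one, numeric(2), shell = pop$bound_shell))
  lut <- list(diam = diam, base = tab_base, bound = tab_bound)
  if (is.null(.nanochrome_cache$lut)) .nanochrome_cache$lut <- list()
  .nanochrome_cache$lut[[key]] <- lut
  lut
}

#' Ground-truth band intensities and gamma for a particle table
#'
#' Computes, for every particle, the Mie band integrals over the G- and
#' R-bands (via a cached fine diameter grid) and the resulting true contrast
#' `gamma`. Aggregates are doublets and scatter twice the single-particle
#' intensity in each band (their gamma is unchanged).
#'
#' @param particles Data frame with `diameter`, `shell` and `is_aggregate`
#'   columns (see [bind_analyte()]).
#' @param pop A [population_config()].
#' @param bands A [band_set()].
#' @param constants Material table for the core.
#' @return `particles` with added columns `r_int`, `g_int` (band-integrated
#'   cross-sections, nm^2 x nm) and `gamma_true`.
#' @export
particle_band_signal <- function(particles, pop = population_config(),
                                 bands = nonadjacent_bands(),
                                 constants = gold_johnson_christy()) {
  lut <- .band_lut(pop, bands, constants)
  interp <- function(tab, d) {
    cbind(g = stats::spline(lut$diam, tab[, "g"], xout = d)$y,
          r = stats::spline(lut$diam, tab[, "r"], xout = d)$y)
  }
  d <- pmin(pmax(particles$diameter, min(lut$diam)), max(lut$diam))
  base <- interp(lut$base, d)
  bound <- interp(lut$bound, d)
  use_bound <- particles$shell >= (pop$base_shell + pop$bound_shell) / 2
  g <- ifelse(use_bound, bound[, "g"], base[, "g"])
  r <- ifelse(use_bound, bound[, "r"], base[, "r"])
  mult <- ifelse(particles$is_aggregate, 2, 1)
  particles$g_int <- g * mult
  particles$r_int <- r * mult
  particles$gamma_true <- (r - g) / (r + g)
  particles
}

# ---- frame rendering ------------------------------------------------------

# pixel-integrated 2-D Gaussian patch: product of 1-D normal CDF differences.
# Returns the index ranges and the patch so the caller can add it in place
# (avoids copying the whole frame for every spot).
.spot_patch <- function(shape, row, col, photons, sigma) {
  half <- ceiling(5 * sigma)
  rows <- max(1L, floor(row) - half):min(shape[1], floor(row) + half + 1L)
  cols <- max(1L, floor(col) - half):min(shape[2], floor(col) + half + 1L)
  fr <- stats::pnorm(rows + 0.5, row, sigma) - stats::pnorm(rows - 0.5, row, sigma)
  fc <- stats::pnorm(cols + 0.5, col, sigma) - stats::pnorm(cols - 0.5, col, sigma)
  list(rows = rows, cols = cols, patch = photons * (fr %o% fc))
}

# rejection-sample positions with a minimum pairwise separation
.sample_positions <- function(n, shape, margin, min_sep) {
  rows <- numeric(n)
  cols <- numeric(n)
  placed <- 0L
  tries <- 0L
  max_tries <- 2000L * n
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("spot count infeasible for frame size at the requested separation",
           call. = FALSE)
    }
    r <- stats::runif(1, 1 + margin, shape[1] - margin)
    cc <- stats::runif(1, 1 + margin, shape[2] - margin)
    if (placed > 0L) {
      d2 <- (rows[seq_len(placed)] - r)^2 + (cols[seq_len(placed)] - cc)^2
      if (min(d2) < min_sep^2) next
    }
    placed <- placed + 1L
    rows[placed] <- r
    cols[placed] <- cc
  }
  cbind(row = rows, col = cols)
}

#' Render two-channel dark-field frames for a particle table
#'
#' Draws each particle as a diffraction-limited (Gaussian) spot into an R
#' and a G frame. The expected photon count of a spot in a channel is
#' `photons_per_unit_cross_section` times the particle's band-integrated
#' cross-section in that channel. Aggregates are rendered as two overlapping
#' Gaussians (2 PSF sigma apart) each carrying the full single-particle
#' intensity, so they appear roughly twice as large and twice as bright.
#' With `noise = TRUE`, per-pixel Poisson shot noise is applied to spot plus
#' background photons, Gaussian read noise is added, and frames are rounded
#' and clipped to the 16-bit camera range.
#'
#' @param particles Output of [particle_band_signal()] (any data frame with
#'   `r_int`, `g_int`, `is_aggregate`).
#' @param img An [imaging_config()].
#' @param seed Integer seed (positions and noise).
#' @param noise Apply shot/read noise and quantisation.
#' @return A list of class `rendered_frames`: `r` and `g` (lists of numeric
#'   matrices) and `truth` (ground-truth data frame with frame, position,
#'   diameter, shell, aggregate flag and true gamma).
#' @export
render_frames <- function(particles, img = imaging_config(), seed = 1L,
                          noise = TRUE) {
  stopifnot(inherits(img, "imaging_config"))
  need <- c("r_int", "g_int", "is_aggregate")
  if (!all(need %in% names(particles))) {
    stop("particles must carry band signals; see particle_band_signal()",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  n <- nrow(particles)
  n_frames <- ceiling(n / img$spots_per_frame)
  scale <- img$photons_per_unit_cross_section
  sigma <- img$psf_sigma
  margin <- 12  # keeps every spot fully inside the measurement annulus
  shape <- img$frame_shape
  r_stack <- vector("list", n_frames)
  g_stack <- vector("list", n_frames)
  truth <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    idx <- ((f - 1L) * img$spots_per_frame + 1L):min(f * img$spots_per_frame, n)
    pf <- particles[idx, , drop = FALSE]
    pos <- .sample_positions(nrow(pf), shape, margin, 4 * sigma)
    rf <- matrix(0, shape[1], shape[2])
    gf <- matrix(0, shape[1], shape[2])
    for (i in seq_len(nrow(pf))) {
      r_ph <- scale * pf$r_int[i]
      g_ph <- scale * pf$g_int[i]
      if (pf$is_aggregate[i]) {
        theta <- stats::runif(1, 0, 2 * pi)
        off <- sigma * c(cos(theta), sin(theta))
        centres <- rbind(pos[i, ] + off, pos[i, ] - off)
        weights <- c(0.5, 0.5)
      } else {
        centres <- pos[i, , drop = FALSE]
        weights <- 1
      }
      for (k in seq_along(weights)) {
        pr <- .spot_patch(shape, centres[k, 1], centres[k, 2],
                          weights[k], sigma)
        rf[pr$rows, pr$cols] <- rf[pr$rows, pr$cols] + r_ph * pr$patch
        gf[pr$rows, pr$cols] <- gf[pr$rows, pr$cols] + g_ph * pr$patch
      }
    }
    rf <- rf + img$background_level
    gf <- gf + img$background_level
    if (noise) {
      rf <- matrix(stats::rpois(length(rf), rf), shape[1], shape[2])
      gf <- matrix(stats::rpois(length(gf), gf), shape[1], shape[2])
      if (img$read_noise_sd > 0) {
        rf <- rf + matrix(stats::rnorm(length(rf), 0, img$read_noise_sd),
                          shape[1], shape[2])
        gf <- gf + matrix(stats::rnorm(length(gf), 0, img$read_noise_sd),
                          shape[1], shape[2])
      }
      rf <- pmin(pmax(round(rf), 0), 65535)
      gf <- pmin(pmax(round(gf), 0), 65535)
    }
    r_stack[[f]] <- rf
    g_stack[[f]] <- gf
    tf <- pf
    tf$frame <- f
    tf$row <- pos[, 1]
    tf$col <- pos[, 2]
    truth[[f]] <- tf
  }
  structure(
    list(r = r_stack, g = g_stack, truth = do.call(rbind, truth)),
    class = "rendered_frames"
  )
}

#' Generate a complete ground-truthed dataset for one condition
#'
#' Samples enough particles that at least `n_spots` non-aggregate spots are
#' present, assigns shells by analyte binding at `concentration`, computes
#' ground-truth band signals and renders the two-channel frame stack. When
#' `out_dir` is given, writes `r_channel.tif` and `g_channel.tif` (16-bit
#' multi-page TIFF), `ground_truth.csv` and a `manifest.json` recording the
#' seed and all configuration values.
#'
#' @param concentration Analyte concentration in pg/mL (0 = negative
#'   control).
#' @param n_spots Minimum number of non-aggregate spots (default 15000, the
#'   per-condition statistics of the assay).
#' @param pop A [population_config()].
#' @param binding A [binding_model()].
#' @param img An [imaging_config()].
#' @param bands A [band_set()].
#' @param seed Integer seed.
#' @param out_dir Optional output directory.
#' @param noise Apply camera noise (see [render_frames()]).
#' @param constants Material table for the core.
#' @return Invisibly, a list with `frames` (a `rendered_frames` object),
#'   `truth`, and `manifest`.
#' @export
generate_dataset <- function(concentration, n_spots = 15000,
                             pop = population_config(),
                             binding = binding_model(),
                             img = imaging_config(),
                             bands = nonadjacent_bands(),
                             seed = 1L, out_dir = NULL, noise = TRUE,
                             constants = gold_johnson_christy()) {
  if (n_spots <= 0) stop("n_spots must be > 0", call. = FALSE)
  seed <- as.integer(seed)
  n_total <- ceiling(n_spots / max(1 - pop$aggregate_fraction, 1e-6))
  repeat {
    particles <- sample_particles(n_total, pop, seed = seed)
    if (sum(!particles$is_aggregate) >= n_spots) break
    n_total <- ceiling(n_total * 1.05) + 10
  }
  particles <- bind_analyte(particles, concentration, binding, pop,
                            seed = seed + 1L)
  particles <- particle_band_signal(particles, pop, bands, constants)
  frames <- render_frames(particles, img, seed = seed + 2L, noise = noise)
  manifest <- list(
    package = "nanochrome",
    concentration_pg_ml = concentration,
    n_spots_requested = n_spots,
    n_particles = nrow(particles),
    n_frames = length(frames$r),
    seed = seed,
    noise = noise,
    population = unclass(pop),
    binding = unclass(binding),
    imaging = unclass(img),
    bands = list(g_band = bands$g_band, r_band = bands$r_band)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_stack(frames$r, file.path(out_dir, "r_channel.tif"))
    write_stack(frames$g, file.path(out_dir, "g_channel.tif"))
    utils::write.csv(frames$truth, file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(frames = frames, truth = frames$truth, manifest = manifest))
}

#' Write/read a 16-bit multi-page TIFF stack
#'
#' Frames are numeric matrices in camera counts (0-65535); values are stored
#' as 16-bit unsigned samples.
#'
#' @param frames List of numeric matrices.
#' @param path TIFF file path.
#' @return `write_stack()` returns `path` invisibly; `read_stack()` returns
#'   a list of numeric matrices in counts.
#' @export
write_stack <- function(frames, path) {
  tiff::writeTIFF(lapply(frames, function(m) pmin(pmax(m, 0), 65535) / 65535),
                  path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("channel stack not found: %s", path), call. = FALSE)
  }
  frames <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(frames)) frames <- list(frames)
  lapply(frames, function(m) round(m * 65535))
}
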