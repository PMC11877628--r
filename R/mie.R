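#' Concentric core-shell particle for Mie calculations
#'
#' Describes the object whose scattering is computed throughout the package:
#' a spherical gold core of diameter `core_diameter` wearing a concentric
#' dielectric (protein) shell of thickness `shell_thickness`, immersed in a
#' non-absorbing medium. A shell thickness of zero reduces the model to a
#' bare homogeneous sphere.
#'
#' @param core_diameter Gold core diameter in nanometres (> 0).
#' @param shell_thickness Protein shell thickness in nanometres (>= 0). The
#'   assay operates between 1.67 nm (capture antibody + PEG layer) and
#'   1.77 nm (after analyte capture).
#' @param shell_index Real refractive index of the shell; 1.45 is typical
#'   for adsorbed protein/PEG layers.
#' @param medium_index Real refractive index of the surrounding medium;
#'   1.333 for water.
#' @return An object of class `particle_model`.
#' @export
particle_model <- function(core_diameter = 80, shell_thickness = 0,
                           shell_index = 1.45, medium_index = 1.333) {
  if (!is.numeric(core_diameter) || length(core_diameter) != 1L ||
      !is.finite(core_diameter) || core_diameter <= 0) {
    stop("core_diameter must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(shell_thickness) || length(shell_thickness) != 1L ||
      !is.finite(shell_thickness) || shell_thickness < 0) {
    stop("shell_thickness must be a single number >= 0", call. = FALSE)
  }
  if (shell_index < 1 || medium_index < 1) {
    stop("refractive indices must be >= 1", call. = FALSE)
  }
  structure(
    list(core_diameter = core_diameter, shell_thickness = shell_thickness,
         shell_index = shell_index, medium_index = medium_index),
    class = "particle_model"
  )
}

#' @export
print.particle_model <- function(x, ...) {
  cat(sprintf(
    "<particle_model> core %.4g nm + shell %.4g nm (n_shell %.3f, n_med %.3f)\n",
    x$core_diameter, x$shell_thickness, x$shell_index, x$medium_index))
  invisible(x)
}

# Riccati-Bessel functions psi_n(z) = z j_n(z), chi_n(z) = -z y_n(z) and their
# derivatives for orders 0..nmax at a complex argument. j_n is generated by
# downward recurrence (stable for the growing solution), y_n upward.
.riccati_bessel <- function(nmax, z) {
  z <- as.complex(z)
  if (Mod(z) == 0) stop("Riccati-Bessel argument must be nonzero", call. = FALSE)
  nex <- nmax + 15L + as.integer(ceiling(Mod(z)))
  j <- rep(0 + 0i, nex + 2L)            # j[n + 1] holds j_n
  j[nex + 1L] <- 1e-30 + 0i
  for (n in nex:1L) {
    j[n] <- (2 * n + 1) / z * j[n + 1L] - j[n + 2L]
  }
  j <- j * (sin(z) / z) / j[1L]
  y <- rep(0 + 0i, nmax + 2L)           # y[n + 1] holds y_n
  y[1L] <- -cos(z) / z
  y[2L] <- -cos(z) / z^2 - sin(z) / z
  if (nmax >= 1L) {
    for (n in 1:nmax) y[n + 2L] <- (2 * n + 1) / z * y[n + 1L] - y[n]
  }
  idx <- seq_len(nmax + 1L)
  ord <- idx - 1L
  psi <- z * j[idx]
  chi <- -z * y[idx]
  # f'_n = f_{n-1} - n f_n / z holds for both psi and chi
  dpsi <- c(cos(z), psi[-(nmax + 1L)] - ord[-1L] * psi[-1L] / z)
  dchi <- c(-sin(z), chi[-(nmax + 1L)] - ord[-1L] * chi[-1L] / z)
  list(psi = psi, chi = chi, dpsi = dpsi, dchi = dchi)
}

# Scattering cross-section (nm^2) of the coated sphere at one wavelength.
.coated_csca_single <- function(model, wavelength, constants) {
  m_core <- refractive_index(constants, wavelength)
  n_med <- model$medium_index
  k <- 2 * pi * n_med / wavelength
  x <- k * model$core_diameter / 2
  bare <- model$shell_thickness == 0
  y <- if (bare) x else k * (model$core_diameter / 2 + model$shell_thickness)
  m1 <- m_core / n_med
  m2 <- if (bare) m1 else complex(real = model$shell_index / n_med)
  nmax <- as.integer(ceiling(y + 4 * y^(1 / 3) + 2))
  ord <- 1:nmax

  ry <- .riccati_bessel(nmax, y)
  rm2y <- .riccati_bessel(nmax, m2 * y)
  if (bare) {
    An <- Bn <- rep(0 + 0i, nmax + 1L)
  } else {
    rm1x <- .riccati_bessel(nmax, m1 * x)
    rm2x <- .riccati_bessel(nmax, m2 * x)
    An <- (m2 * rm2x$psi * rm1x$dpsi - m1 * rm2x$dpsi * rm1x$psi) /
          (m2 * rm2x$chi * rm1x$dpsi - m1 * rm2x$dchi * rm1x$psi)
    Bn <- (m2 * rm1x$psi * rm2x$dpsi - m1 * rm2x$psi * rm1x$dpsi) /
          (m2 * rm2x$dchi * rm1x$psi - m1 * rm1x$dpsi * rm2x$chi)
  }
  xi <- ry$psi - 1i * ry$chi
  dxi <- ry$dpsi - 1i * ry$dchi
  fa <- rm2y$dpsi - An * rm2y$dchi
  ga <- rm2y$psi - An * rm2y$chi
  fb <- rm2y$dpsi - Bn * rm2y$dchi
  gb <- rm2y$psi - Bn * rm2y$chi
  a <- (ry$psi * fa - m2 * ry$dpsi * ga) / (xi * fa - m2 * dxi * ga)
  b <- (m2 * ry$psi * fb - ry$dpsi * gb) / (m2 * xi * fb - dxi * gb)
  a <- a[-1L]
  b <- b[-1L]
  csca <- (2 * pi / k^2) * sum((2 * ord + 1) * (Mod(a)^2 + Mod(b)^2))
  if (!is.finite(csca) || csca < 0) {
    stop(sprintf(
      "Mie series did not converge (d = %g nm, shell = %g nm, lambda = %g nm)",
      model$core_diameter, model$shell_thickness, wavelength), call. = FALSE)
  }
  csca
}

#' Coated-sphere Mie scattering cross-section
#'
#' Scattering cross-section of a concentric gold-core / dielectric-shell
#' sphere in a non-absorbing medium, from the coated-sphere Mie series
#' (Bohren & Huffman). The series is truncated at
#' `nmax = y + 4 y^(1/3) + 2` where `y` is the outer size parameter. With
#' `shell_thickness = 0` the result is the homogeneous-sphere cross-section
#' of the bare core.
#'
#' @param model A [particle_model()].
#' @param wavelength Vacuum wavelength(s) in nanometres; must lie within the
#'   range of `constants`.
#' @param constants Material table for the core; defaults to
#'   [gold_johnson_christy()].
#' @return Numeric vector of scattering cross-sections in nm^2 (>= 0).
#' @export
coated_sphere_cross_section <- function(model, wavelength,
                                        constants = gold_johnson_christy()) {
  stopifnot(inherits(model, "particle_model"))
  vapply(as.numeric(wavelength),
         function(wl) .coated_csca_single(model, wl, constants),
         numeric(1))
}

#' Scattering spectrum of a particle on a wavelength grid
#'
#' Evaluates [coated_sphere_cross_section()] on an ascending wavelength grid
#' (1 nm steps over 400-800 nm by default, which resolves the 7 nm-wide
#' green detection band).
#'
#' @inheritParams coated_sphere_cross_section
#' @param grid Ascending wavelength grid in nanometres.
#' @return An object of class `spectrum`: a list with numeric `wavelength`
#'   and `value` (cross-section, nm^2) of equal length.
#' @export
scattering_spectrum <- function(model, grid = seq(400, 800, by = 1),
                                constants = gold_johnson_christy()) {
  grid <- as.numeric(grid)
  if (length(grid) == 0L) stop("empty wavelength grid", call. = FALSE)
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  }
  new_spectrum(grid, coated_sphere_cross_section(model, grid, constants))
}

#' Construct a spectrum object
#'
#' @param wavelength Ascending numeric vector in nanometres.
#' @param value Non-negative values (scattering cross-section in nm^2, or any
#'   non-negative spectral quantity) of the same length.
#' @return An object of class `spectrum`.
#' @export
new_spectrum <- function(wavelength, value) {
  wavelength <- as.numeric(wavelength)
  value <- as.numeric(value)
  if (length(wavelength) != length(value)) {
    stop("wavelength and value must have the same length", call. = FALSE)
  }
  if (length(wavelength) > 1L && is.unsorted(wavelength, strictly = TRUE)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(value)) || any(value < 0)) {
    stop("spectrum values must be finite and >= 0", call. = FALSE)
  }
  structure(list(wavelength = wavelength, value = value), class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, %.1f-%.1f nm, max %.4g at %.1f nm\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              max(x$value), x$wavelength[which.max(x$value)]))
  invisible(x)
}

#' @export
as.data.frame.spectrum <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelength, sigma_sca_nm2 = x$value)
}

#' Write a spectrum to a two-column CSV
#'
#' @param spectrum A `spectrum` object.
#' @param path Output file path.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  utils::write.csv(as.data.frame(spectrum), path, row.names = FALSE)
  invisible(path)
}

#' Peak wavelength of a spectrum
#'
#' Wavelength of the global maximum, with ties broken toward the shorter
#' wavelength. When the maximum is an interior grid point, a parabola through
#' the three points around it refines the estimate to sub-grid resolution
#' (disable with `refine = FALSE`).
#'
#' @param spectrum A `spectrum` object.
#' @param refine Apply parabolic refinement around the discrete maximum.
#' @return Peak wavelength in nanometres.
#' @export
peak_wavelength <- function(spectrum, refine = TRUE) {
  stopifnot(inherits(spectrum, "spectrum"))
  v <- spectrum$value
  wl <- spectrum$wavelength
  if (length(v) == 0L) stop("empty spectrum", call. = FALSE)
  if (all(v == 0)) {
    stop("degenerate all-zero spectrum has no peak", call. = FALSE)
  }
  i <- which.max(v)  # which.max already breaks ties toward the first element
  if (!refine || i == 1L || i == length(v)) {
    return(wl[i])
  }
  # quadratic through (wl[i-1..i+1], v[i-1..i+1]); vertex offset in grid units
  y1 <- v[i - 1L]; y2 <- v[i]; y3 <- v[i + 1L]
  denom <- y1 - 2 * y2 + y3
  if (denom == 0) return(wl[i])
  delta <- 0.5 * (y1 - y3) / denom
  delta <- max(-0.5, min(0.5, delta))
  # assume locally uniform grid spacing around the maximum
  h <- (wl[i + 1L] - wl[i - 1L]) / 2
  wl[i] + delta * h
}
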