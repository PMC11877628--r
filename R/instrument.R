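#' Dual-band readout definition
#'
#' The two wavelength windows that reach the green and red camera channels.
#' The default nonadjacent configuration places the G-band at 545-552 nm
#' (just blue of the 560 nm plasmon peak of an 80 nm gold sphere in water)
#' and the R-band at 590-622 nm (covering the long-wavelength half-maximum
#' flank, where a binding-induced red shift changes the intensity most).
#'
#' @param g_band Length-2 numeric `c(lo, hi)` in nanometres.
#' @param r_band Length-2 numeric `c(lo, hi)` in nanometres; must start at or
#'   above the top of the G-band (the bands may not overlap).
#' @return An object of class `band_set`.
#' @export
band_set <- function(g_band = c(545, 552), r_band = c(590, 622)) {
  g_band <- as.numeric(g_band)
  r_band <- as.numeric(r_band)
  if (length(g_band) != 2L || length(r_band) != 2L) {
    stop("each band must be a length-2 numeric interval", call. = FALSE)
  }
  if (g_band[1] >= g_band[2] || r_band[1] >= r_band[2]) {
    stop("band intervals must satisfy lo < hi", call. = FALSE)
  }
  if (g_band[2] > r_band[1]) {
    stop("bands must not overlap (g_band.hi <= r_band.lo)", call. = FALSE)
  }
  structure(list(g_band = g_band, r_band = r_band), class = "band_set")
}

#' @rdname band_set
#' @export
nonadjacent_bands <- function() band_set(c(545, 552), c(590, 622))

#' @rdname band_set
#' @details `adjacent_bands()` returns the comparison configuration of the
#'   earlier dual-view instrument: two touching 20 nm bands centred on the
#'   560 nm plasmon peak (G 540-560 nm, R 560-580 nm).
#' @export
adjacent_bands <- function() band_set(c(540, 560), c(560, 580))

#' @export
print.band_set <- function(x, ...) {
  cat(sprintf("<band_set> G [%g, %g] nm, R [%g, %g] nm\n",
              x$g_band[1], x$g_band[2], x$r_band[1], x$r_band[2]))
  invisible(x)
}

#' Ideal filter stack of the imaging path
#'
#' Models the excitation/emission filter combination as a product of ideal
#' top-hat responses: a multiband bandpass filter (a set of disjoint pass
#' intervals), a long-pass filter, and a notch filter. The defaults are the
#' printed specifications of the physical stack: MBPF pass bands
#' 417-433.5, 466.5-492.5, 525.5-552, 590-622 and 666.5-721 nm, a 525 nm
#' long-pass and a 532 nm notch (10 nm wide).
#'
#' @param multiband_pass List of length-2 numeric intervals (nm), disjoint
#'   and ascending.
#' @param longpass_cutoff Wavelengths below this are blocked (nm).
#' @param notch_center,notch_width Centre and full width of the blocked
#'   notch (nm).
#' @return An object of class `filter_stack`.
#' @export
filter_stack <- function(multiband_pass = list(c(417, 433.5), c(466.5, 492.5),
                                               c(525.5, 552), c(590, 622),
                                               c(666.5, 721)),
                         longpass_cutoff = 525,
                         notch_center = 532, notch_width = 10) {
  edges <- unlist(multiband_pass)
  if (any(diff(edges) <= 0)) {
    stop("multiband_pass intervals must be disjoint and ascending",
         call. = FALSE)
  }
  structure(
    list(multiband_pass = multiband_pass, longpass_cutoff = longpass_cutoff,
         notch_center = notch_center, notch_width = notch_width),
    class = "filter_stack"
  )
}

#' Transmission of the ideal filter stack
#'
#' @param wavelength Numeric vector of wavelengths (nm).
#' @param stack A [filter_stack()].
#' @return 0/1 transmission per wavelength: 1 inside an MBPF interval, above
#'   the long-pass cutoff and outside the notch; 0 otherwise.
#' @export
filter_transmission <- function(wavelength, stack = filter_stack()) {
  stopifnot(inherits(stack, "filter_stack"))
  wavelength <- as.numeric(wavelength)
  inside_mbpf <- Reduce(`|`, lapply(stack$multiband_pass, function(iv) {
    wavelength >= iv[1] & wavelength <= iv[2]
  }))
  in_notch <- abs(wavelength - stack$notch_center) <= stack$notch_width / 2
  as.numeric(inside_mbpf & wavelength >= stack$longpass_cutoff & !in_notch)
}

# trapezoidal integral of a tabulated spectrum over [lo, hi], with linearly
# interpolated endpoint values when the band edges fall between grid points
.band_integral <- function(wavelength, value, lo, hi, weight = NULL) {
  if (lo < wavelength[1] || hi > wavelength[length(wavelength)]) {
    stop(sprintf(
      "band [%g, %g] nm lies outside the spectrum support [%g, %g] nm",
      lo, hi, wavelength[1], wavelength[length(wavelength)]), call. = FALSE)
  }
  inner <- wavelength > lo & wavelength < hi
  wl <- c(lo, wavelength[inner], hi)
  v <- c(stats::approx(wavelength, value, xout = lo)$y,
         value[inner],
         stats::approx(wavelength, value, xout = hi)$y)
  if (!is.null(weight)) v <- v * weight(wl)
  sum(diff(wl) * (v[-1L] + v[-length(v)]) / 2)
}

#' Band-integrated detected intensities
#'
#' Integrates a scattering spectrum over the R- and G-bands (trapezoidal
#' rule) to obtain the two detected intensities `r_scat` and `g_scat` of a
#' particle. With the default uniform source weighting the result is the
#' plain band integral of the scattering cross-section, which is what all
#' design calculations in this package use; a wavelength-dependent source
#' weight (e.g. a lamp emission profile) can be supplied for simulations.
#'
#' @param spectrum A `spectrum` object covering both bands.
#' @param bands A [band_set()].
#' @param source_weight Either `NULL` (uniform weight 1), a function of
#'   wavelength, or a `spectrum` object interpolated linearly.
#' @return An object of class `band_intensities`: list with `r_scat` and
#'   `g_scat` (arbitrary linear units, >= 0).
#' @export
band_intensities <- function(spectrum, bands = nonadjacent_bands(),
                             source_weight = NULL) {
  stopifnot(inherits(spectrum, "spectrum"), inherits(bands, "band_set"))
  wfun <- NULL
  if (inherits(source_weight, "spectrum")) {
    sw <- source_weight
    wfun <- function(wl) stats::approx(sw$wavelength, sw$value, xout = wl)$y
  } else if (is.function(source_weight)) {
    wfun <- source_weight
  } else if (!is.null(source_weight)) {
    stop("source_weight must be NULL, a function, or a spectrum",
         call. = FALSE)
  }
  g <- .band_integral(spectrum$wavelength, spectrum$value,
                      bands$g_band[1], bands$g_band[2], wfun)
  r <- .band_integral(spectrum$wavelength, spectrum$value,
                      bands$r_band[1], bands$r_band[2], wfun)
  structure(list(r_scat = r, g_scat = g), class = "band_intensities")
}

#' Spectral chromatic image contrast
#'
#' The per-particle contrast `gamma = (R_scat - G_scat)/(R_scat + G_scat)`.
#' The sum in the denominator normalises out the overall brightness of the
#' particle, so gamma responds to the spectral shape (the plasmon position)
#' rather than to the particle's total scattering power. gamma lies in
#' `[-1, 1]` and increases when scattering shifts toward the red band.
#'
#' @param intensities A `band_intensities` object, or a numeric `r_scat`
#'   value when `g_scat` is given.
#' @param g_scat Optional numeric G intensity when `intensities` is numeric.
#' @return gamma, dimensionless in `[-1, 1]`.
#' @export
gamma_contrast <- function(intensities, g_scat = NULL) {
  if (inherits(intensities, "band_intensities")) {
    r <- intensities$r_scat
    g <- intensities$g_scat
  } else {
    r <- as.numeric(intensities)
    g <- as.numeric(g_scat)
  }
  if (any(r < 0) || any(g < 0)) {
    stop("band intensities must be >= 0", call. = FALSE)
  }
  s <- r + g
  if (any(s <= 0)) {
    stop("undefined contrast: r_scat + g_scat must be > 0", call. = FALSE)
  }
  (r - g) / s
}

#' Surface sensitivity of a band configuration
#'
#' Gamma change per nanometre of dielectric shell: the finite difference
#' `S_s = (gamma(shell = delta_t) - gamma(shell = 0)) / delta_t`, with both
#' gammas computed from Mie spectra integrated over the given bands. This is
#' the figure of merit used to compare band configurations.
#'
#' @param model A [particle_model()]; its `shell_thickness` is ignored.
#' @param bands A [band_set()].
#' @param delta_t Shell thickness in nanometres (> 0) at which to evaluate.
#' @param constants Material table for the core.
#' @param grid Wavelength grid for the underlying spectra.
#' @return An object of class `sensitivity_result`: list with `s_s` (1/nm),
#'   `band_set`, `delta_t`, and the two gammas.
#' @export
surface_sensitivity <- function(model, bands = nonadjacent_bands(),
                                delta_t = 1.77,
                                constants = gold_johnson_christy(),
                                grid = seq(400, 800, by = 1)) {
  if (!is.numeric(delta_t) || length(delta_t) != 1L || delta_t <= 0) {
    stop("delta_t must be a single positive thickness", call. = FALSE)
  }
  g0 <- .model_gamma(model, 0, bands, constants, grid)
  g1 <- .model_gamma(model, delta_t, bands, constants, grid)
  structure(
    list(s_s = (g1 - g0) / delta_t, band_set = bands, delta_t = delta_t,
         gamma_bare = g0, gamma_coated = g1),
    class = "sensitivity_result"
  )
}

.model_gamma <- function(model, shell, bands, constants, grid) {
  m <- particle_model(model$core_diameter, shell,
                      shell_index = model$shell_index,
                      medium_index = model$medium_index)
  gamma_contrast(band_intensities(scattering_spectrum(m, grid, constants),
                                  bands))
}

#' Compare a nonadjacent with an adjacent band configuration
#'
#' Evaluates two figures of merit for the choice of detection bands:
#' the ratio of surface sensitivities `S_s` (each a gamma change per nm of
#' shell, evaluated at `shell = t2` against the bare particle), and the
#' percent enhancement of the incremental gamma signal between two shell
#' states `t1 -> t2` (the analyte-binding step: antibody/PEG layer at
#' 1.67 nm growing to 1.77 nm on analyte capture),
#' `100 * ((dgamma_nonadjacent / dgamma_adjacent) - 1)`.
#'
#' @param model A [particle_model()]; its `shell_thickness` is ignored.
#' @param nonadjacent,adjacent The two [band_set()]s to compare.
#' @param t1,t2 Shell thicknesses in nm with `0 < t1 < t2`.
#' @param constants Material table for the core.
#' @param grid Wavelength grid for the underlying spectra.
#' @return List with `sensitivity_ratio` (fold), `enhancement_percent` (%),
#'   and the underlying sensitivities and gammas.
#' @export
configuration_comparison <- function(model,
                                     nonadjacent = nonadjacent_bands(),
                                     adjacent = adjacent_bands(),
                                     t1 = 1.67, t2 = 1.77,
                                     constants = gold_johnson_christy(),
                                     grid = seq(400, 800, by = 1)) {
  if (!(t1 > 0 && t2 > t1)) stop("need 0 < t1 < t2", call. = FALSE)
  s_non <- surface_sensitivity(model, nonadjacent, t2, constants, grid)
  s_adj <- surface_sensitivity(model, adjacent, t2, constants, grid)
  if (s_adj$s_s == 0) {
    stop("adjacent configuration has zero sensitivity; ratio undefined",
         call. = FALSE)
  }
  g_non_t1 <- .model_gamma(model, t1, nonadjacent, constants, grid)
  g_adj_t1 <- .model_gamma(model, t1, adjacent, constants, grid)
  d_non <- s_non$gamma_coated - g_non_t1
  d_adj <- s_adj$gamma_coated - g_adj_t1
  if (d_adj == 0) {
    stop("adjacent configuration shows no incremental signal; enhancement undefined",
         call. = FALSE)
  }
  list(
    sensitivity_ratio = s_non$s_s / s_adj$s_s,
    enhancement_percent = 100 * (d_non / d_adj - 1),
    s_s_nonadjacent = s_non$s_s,
    s_s_adjacent = s_adj$s_s,
    dgamma_nonadjacent = d_non,
    dgamma_adjacent = d_adj
  )
}
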