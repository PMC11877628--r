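#' Tabulated complex optical constants of a material
#'
#' Bundles a wavelength grid with the complex refractive index `n + ik`
#' measured at each wavelength. Values between table rows are obtained by
#' linear interpolation of the real and imaginary parts separately.
#'
#' @param wavelength Numeric vector of wavelengths in nanometres, strictly
#'   increasing.
#' @param n Real part of the refractive index at each wavelength.
#' @param k Imaginary part (extinction coefficient) at each wavelength;
#'   must be non-negative.
#' @return An object of class `optical_constants`.
#' @seealso [gold_johnson_christy()], [refractive_index()]
#' @export
optical_constants <- function(wavelength, n, k) {
  wavelength <- as.numeric(wavelength)
  n <- as.numeric(n)
  k <- as.numeric(k)
  if (length(wavelength) < 2L) {
    stop("at least two table rows are required", call. = FALSE)
  }
  if (length(n) != length(wavelength) || length(k) != length(wavelength)) {
    stop("wavelength, n and k must have the same length", call. = FALSE)
  }
  if (any(!is.finite(wavelength)) || any(diff(wavelength) <= 0)) {
    stop("wavelengths must be finite and strictly increasing", call. = FALSE)
  }
  if (any(k < 0)) {
    stop("the imaginary part of the refractive index must be >= 0",
         call. = FALSE)
  }
  structure(
    list(wavelength = wavelength, n = n, k = k),
    class = "optical_constants"
  )
}

#' @export
print.optical_constants <- function(x, ...) {
  cat(sprintf("<optical_constants> %d rows, %.1f-%.1f nm\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength)))
  invisible(x)
}

# cache for the packaged gold table
.nanochrome_cache <- new.env(parent = emptyenv())

#' Gold optical constants of Johnson & Christy (1972)
#'
#' Returns the packaged table of the complex refractive index of evaporated
#' gold films measured by Johnson & Christy (1972), the de facto standard
#' dataset for noble-metal nanoparticle optics. The table spans roughly
#' 188-1937 nm and comfortably covers the 400-800 nm window used throughout
#' this package.
#'
#' @return An [optical_constants()] object.
#' @references Johnson, P. B. & Christy, R. W. (1972). Optical constants of
#'   the noble metals. Physical Review B, 6(12), 4370-4379.
#' @export
gold_johnson_christy <- function() {
  if (is.null(.nanochrome_cache$gold)) {
    path <- system.file("extdata", "gold_johnson_christy_1972.csv",
                        package = "nanochrome", mustWork = TRUE)
    tab <- utils::read.csv(path)
    .nanochrome_cache$gold <- optical_constants(tab$wavelength_nm, tab$n, tab$k)
  }
  .nanochrome_cache$gold
}

#' Interpolate the complex refractive index at given wavelengths
#'
#' Linear interpolation of the real and imaginary parts between the
#' bracketing rows of the table. Querying outside the tabulated range is an
#' error rather than an extrapolation.
#'
#' @param constants An [optical_constants()] object.
#' @param wavelength Numeric vector of query wavelengths in nanometres.
#' @return Complex vector `n + ik`, one value per query wavelength.
#' @export
refractive_index <- function(constants, wavelength) {
  stopifnot(inherits(constants, "optical_constants"))
  wavelength <- as.numeric(wavelength)
  rng <- range(constants$wavelength)
  if (any(!is.finite(wavelength)) ||
      any(wavelength < rng[1]) || any(wavelength > rng[2])) {
    stop(sprintf(
      "wavelength outside the tabulated range [%.1f, %.1f] nm",
      rng[1], rng[2]), call. = FALSE)
  }
  re <- stats::approx(constants$wavelength, constants$n, xout = wavelength)$y
  im <- stats::approx(constants$wavelength, constants$k, xout = wavelength)$y
  complex(real = re, imaginary = im)
}
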