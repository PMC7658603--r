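#' Wavelength-resolved optical properties of a medium
#'
#' Bundles the four bulk optical properties of a turbid medium -- absorption
#' coefficient \eqn{\mu_a} (mm^-1), scattering coefficient \eqn{\mu_s}
#' (mm^-1), scattering anisotropy \eqn{g} (mean cosine of the single-scatter
#' deflection angle) and refractive index \eqn{n} -- tabulated on an
#' ascending wavelength grid covering 350-900 nm. Lookups between grid nodes
#' are linear; lookups outside the grid clamp to the nearest end.
#'
#' @param wavelength numeric, strictly ascending grid in nm.
#' @param mu_a absorption coefficient per wavelength, mm^-1, >= 0.
#' @param mu_s scattering coefficient per wavelength, mm^-1, >= 0.
#' @param g anisotropy per wavelength, in \[-1, 1\].
#' @param n refractive index per wavelength, >= 1.
#' @return An object of class `optical_properties`.
#' @examples
#' op <- optical_properties(c(400, 700), mu_a = c(0.1, 0.02),
#'                          mu_s = c(20, 10), g = c(0.9, 0.9), n = c(1.4, 1.4))
#' op_lookup(op, 550)
#' @export
optical_properties <- function(wavelength, mu_a, mu_s, g, n) {
  wavelength <- as.numeric(wavelength)
  if (length(wavelength) < 1L || any(diff(wavelength) <= 0))
    stop("wavelength grid must be non-empty and strictly ascending")
  len <- length(wavelength)
  chk <- function(x, nm) {
    x <- as.numeric(x)
    if (length(x) == 1L) x <- rep(x, len)
    if (length(x) != len) stop(sprintf("'%s' must match the wavelength grid length", nm))
    if (any(!is.finite(x))) stop(sprintf("'%s' contains non-finite values", nm))
    x
  }
  mu_a <- chk(mu_a, "mu_a"); mu_s <- chk(mu_s, "mu_s")
  g <- chk(g, "g"); n <- chk(n, "n")
  if (any(mu_a < 0)) stop("mu_a must be >= 0")
  if (any(mu_s < 0)) stop("mu_s must be >= 0")
  if (any(g < -1 | g > 1)) stop("g must lie in [-1, 1]")
  if (any(n < 1)) stop("n must be >= 1")
  structure(list(wavelength = wavelength, mu_a = mu_a, mu_s = mu_s,
                 g = g, n = n),
            class = "optical_properties")
}

#' Interpolate optical properties at a wavelength
#'
#' Linear interpolation on the tabulated grid, clamped at the grid ends.
#' At grid nodes the tabulated values are returned exactly.
#'
#' @param op an [optical_properties()] object.
#' @param wavelength numeric vector of query wavelengths (nm).
#' @return A data.frame with columns `wavelength`, `mu_a`, `mu_s`, `g`, `n`.
#' @export
op_lookup <- function(op, wavelength) {
  stopifnot(inherits(op, "optical_properties"))
  wl <- pmin(pmax(wavelength, op$wavelength[1]),
             op$wavelength[length(op$wavelength)])
  itp <- function(v) {
    if (length(op$wavelength) == 1L) rep(v, length(wl))
    else approx(op$wavelength, v, xout = wl, rule = 2)$y
  }
  data.frame(wavelength = wavelength, mu_a = itp(op$mu_a),
             mu_s = itp(op$mu_s), g = itp(op$g), n = itp(op$n))
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf("<optical_properties> %d wavelengths, %g-%g nm\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength)))
  cat(sprintf("  mu_a: %.4g-%.4g mm^-1, mu_s: %.4g-%.4g mm^-1, g: %.3g-%.3g, n: %.3g-%.3g\n",
              min(x$mu_a), max(x$mu_a), min(x$mu_s), max(x$mu_s),
              min(x$g), max(x$g), min(x$n), max(x$n)))
  invisible(x)
}

#' Transport-reduced scattering coefficient
#'
#' \eqn{\mu_s' = \mu_s (1 - g)}: the scattering coefficient rescaled to the
#' equivalent isotropic-scattering rate, the quantity that governs diffuse
#' light transport.
#'
#' @param mu_s scattering coefficient, mm^-1, >= 0.
#' @param g anisotropy, in \[-1, 1\].
#' @return Reduced scattering coefficient in mm^-1.
#' @examples
#' reduced_scattering(10, 0.9) # 1.0
#' @export
reduced_scattering <- function(mu_s, g) {
  if (any(mu_s < 0)) stop("mu_s must be >= 0")
  if (any(g < -1 | g > 1)) stop("g must lie in [-1, 1]")
  mu_s * (1 - g)
}

#' Effective attenuation coefficient of diffusion theory
#'
#' \eqn{\mu_{eff} = \sqrt{3 \mu_a (\mu_a + \mu_s')}}, the asymptotic decay
#' rate of diffuse fluence deep in a turbid medium. This is the coefficient
#' that sets how rapidly both an external excitation beam and any outbound
#' luminescence are attenuated with depth.
#'
#' @param mu_a absorption coefficient, mm^-1, >= 0.
#' @param mu_s_prime reduced scattering coefficient, mm^-1, >= 0.
#' @return Effective attenuation coefficient in mm^-1.
#' @examples
#' effective_attenuation(0.01, 1.0)
#' @export
effective_attenuation <- function(mu_a, mu_s_prime) {
  if (any(mu_a < 0) || any(mu_s_prime < 0))
    stop("mu_a and mu_s_prime must be >= 0")
  sqrt(3 * mu_a * (mu_a + mu_s_prime))
}

#' Effective attenuation spectrum of an optical_properties object
#' @param op an [optical_properties()] object.
#' @param wavelength query wavelengths (nm); defaults to the tabulated grid.
#' @return numeric vector of mu_eff (mm^-1).
#' @export
op_mu_eff <- function(op, wavelength = op$wavelength) {
  p <- op_lookup(op, wavelength)
  effective_attenuation(p$mu_a, reduced_scattering(p$mu_s, p$g))
}
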