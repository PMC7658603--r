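#' Beam specification
#'
#' Describes an excitation source: a megavoltage photon beam (6MV/18MV), a
#' megavoltage electron beam (6MeV/18MeV), or a monochromatic optical beam
#' (wavelength in nm). Radiation beams act as volumetric Cherenkov sources
#' sampled from their depth-dose curve; optical beams are collimated square
#' fields of downward photons at the tissue surface.
#'
#' @param modality "photon-beam", "electron-beam" or "optical".
#' @param energy "6MV"/"18MV" (photon), "6MeV"/"18MeV" (electron), or a
#'   numeric wavelength in nm (optical).
#' @param field_shape "square" or "sheet".
#' @param field_mm field dimensions at the source plane (mm), scalar or
#'   length 2 (x, y).
#' @param ssd_mm source-to-surface distance (mm).
#' @param divergence_deg divergence half-angle applied from each field edge
#'   (degrees, >= 0).
#' @param penumbra_sigma_mm Gaussian lateral blur of the Cherenkov origins,
#'   emulating secondary-particle spread; defaults to 0 for photon beams and
#'   1 mm for electron beams (electrons scatter more, widening the penumbra).
#' @return An object of class `beam_spec`.
#' @examples
#' beam_spec("photon-beam", "6MV")                 # the default 1 cm square field
#' beam_spec("optical", 630, field_mm = 10)        # 630 nm epi-illumination
#' @export
beam_spec <- function(modality = c("photon-beam", "electron-beam", "optical"),
                      energy = "6MV", field_shape = c("square", "sheet"),
                      field_mm = 10, ssd_mm = 900, divergence_deg = 0.97,
                      penumbra_sigma_mm = NULL) {
  modality <- match.arg(modality)
  field_shape <- match.arg(field_shape)
  field_mm <- rep(as.numeric(field_mm), length.out = 2L)
  if (any(field_mm <= 0)) stop("field dimensions must be > 0")
  if (divergence_deg < 0) stop("divergence must be >= 0")
  if (modality == "optical") {
    wl <- suppressWarnings(as.numeric(energy))
    if (!is.finite(wl) || wl < .wl_min || wl > .wl_max)
      stop("optical beams need a numeric wavelength in [350, 900] nm")
    energy <- wl
  } else {
    allowed <- if (modality == "photon-beam") c("6MV", "18MV") else c("6MeV", "18MeV")
    energy <- match.arg(as.character(energy), allowed)
  }
  if (is.null(penumbra_sigma_mm))
    penumbra_sigma_mm <- if (modality == "electron-beam") 1 else 0
  structure(list(modality = modality, energy = energy,
                 field_shape = field_shape, field_mm = field_mm,
                 ssd_mm = as.numeric(ssd_mm),
                 divergence_deg = as.numeric(divergence_deg),
                 penumbra_sigma_mm = as.numeric(penumbra_sigma_mm)),
            class = "beam_spec")
}

#' @export
print.beam_spec <- function(x, ...) {
  cat(sprintf("<beam_spec> %s %s, %s %g x %g mm, SSD %g mm, divergence %g deg\n",
              x$modality, as.character(x$energy), x$field_shape,
              x$field_mm[1], x$field_mm[2], x$ssd_mm, x$divergence_deg))
  invisible(x)
}

#' Cherenkov kinetic-energy threshold for electrons
#'
#' An electron emits Cherenkov light when its speed exceeds the phase
#' velocity of light in the medium, i.e. beta * n > 1. The kinetic-energy
#' threshold is \eqn{m_e c^2 (1/\sqrt{1 - 1/n^2} - 1)} with
#' \eqn{m_e c^2 = 511} keV; for tissue-like n = 1.4 this is about 220 keV.
#'
#' @param n refractive index (> 1).
#' @return Threshold kinetic energy in keV.
#' @examples
#' cherenkov_threshold_energy(1.4)  # ~219 keV
#' @export
cherenkov_threshold_energy <- function(n) {
  if (any(n <= 1))
    stop("no Cherenkov emission is possible for n <= 1")
  511 * (1 / sqrt(1 - 1 / n^2) - 1)
}

#' Analytic percentage depth-dose model
#'
#' Relative dose versus depth in tissue, max-normalized, used as the depth
#' density of Cherenkov photon origins (Cherenkov emission is proportional
#' to deposited dose). Photon beams use a build-up times exponential-falloff
#' form \eqn{D(z) = (1 - e^{-\beta z}) e^{-\alpha z}} with \eqn{\beta}
#' solved so the maximum sits at the clinical depth of maximum dose
#' (15 mm for 6 MV, 35 mm for 18 MV). Electron beams use a Gaussian-peaked
#' form that falls to ~0 beyond the practical range
#' (~ energy(MeV)/2 cm).
#'
#' @param energy "6MV", "18MV", "6MeV" or "18MeV".
#' @param params optional named list overriding the stored parameterization:
#'   photon beams `list(alpha, dmax_mm)`; electron beams
#'   `list(zpeak_mm, sigma_mm, range_mm)`.
#' @return An object of class `pdd_model` with a `dose(z)` closure.
#' @examples
#' pdd <- pdd_model("6MV")
#' z <- seq(0, 50, by = 0.1)
#' z[which.max(dose_at_depth(pdd, z))]  # 15 mm
#' @export
pdd_model <- function(energy = c("6MV", "18MV", "6MeV", "18MeV"), params = NULL) {
  energy <- match.arg(energy)
  defaults <- list(
    "6MV"   = list(type = "photon", alpha = 0.0046, dmax_mm = 15),
    "18MV"  = list(type = "photon", alpha = 0.0035, dmax_mm = 35),
    "6MeV"  = list(type = "electron", zpeak_mm = 13, sigma_mm = 7, range_mm = 30),
    "18MeV" = list(type = "electron", zpeak_mm = 35, sigma_mm = 22, range_mm = 90))
  p <- defaults[[energy]]
  if (!is.null(params)) p[names(params)] <- params
  if (p$type == "photon") {
    alpha <- p$alpha; dmax <- p$dmax_mm
    # beta with argmax(D) = dmax: beta solves ln((alpha+beta)/alpha)/beta = dmax
    beta <- uniroot(function(b) log((alpha + b) / alpha) / b - dmax,
                    c(1e-4, 10), tol = 1e-12)$root
    raw <- function(z) (1 - exp(-beta * z)) * exp(-alpha * z)
    peak <- raw(dmax)
    dosefun <- function(z) raw(z) / peak
    p$beta <- beta
  } else {
    zp <- p$zpeak_mm; sg <- p$sigma_mm; rng <- p$range_mm
    dosefun <- function(z) {
      d <- exp(-((z - zp)^2) / (2 * sg^2))
      # truncate beyond the practical range (sharp electron falloff)
      d[z > rng] <- d[z > rng] * exp(-((z[z > rng] - rng) / (0.05 * rng))^2)
      d
    }
    peak <- max(dosefun(seq(0, rng, by = 0.01)))
    dfun0 <- dosefun
    dosefun <- function(z) dfun0(z) / peak
  }
  structure(list(energy = energy, params = p, dose = dosefun),
            class = "pdd_model")
}

#' @export
print.pdd_model <- function(x, ...) {
  z <- seq(0, 50, by = 0.1)
  cat(sprintf("<pdd_model> %s (%s), argmax %.1f mm\n", x$energy,
              x$params$type, z[which.max(x$dose(z))]))
  invisible(x)
}

#' Relative dose at depth
#'
#' @param pdd a [pdd_model()].
#' @param z depth below the surface (mm, >= 0).
#' @return Relative dose in \[0, 1\] (max-normalized).
#' @export
dose_at_depth <- function(pdd, z) {
  stopifnot(inherits(pdd, "pdd_model"))
  if (any(z < 0)) stop("depth must be >= 0")
  pmax(pdd$dose(z), 0)
}

#' Sample Cherenkov wavelengths from the 1/lambda^2 law
#'
#' The Frank-Tamm spectral density of Cherenkov emission is proportional to
#' \eqn{\lambda^{-2}}. Inverse-CDF sampling on \[lambda_min, lambda_max\]
#' gives \eqn{\lambda = 1 / (1/\lambda_{min} - u (1/\lambda_{min} -
#' 1/\lambda_{max}))}.
#'
#' @param u uniform(0,1) variates.
#' @param lambda_min,lambda_max band limits in nm (default 350-900).
#' @return Wavelengths in nm.
#' @examples
#' mean(sample_cherenkov_wavelength(runif(1e5)))  # ~541 nm
#' @export
sample_cherenkov_wavelength <- function(u, lambda_min = .wl_min,
                                        lambda_max = .wl_max) {
  if (!(lambda_min > 0 && lambda_max > lambda_min))
    stop("need 0 < lambda_min < lambda_max")
  if (any(u < 0 | u > 1)) stop("u must lie in [0, 1]")
  1 / (1 / lambda_min - u * (1 / lambda_min - 1 / lambda_max))
}

#' Field footprint at the tissue surface
#'
#' Each side of the divergent field grows by `2 * SSD * tan(half-angle)`
#' between the source plane and the surface; a 1 cm source at 0.9 m with a
#' 0.97 degree half-angle reaches ~4 cm at the surface.
#'
#' @param beam a [beam_spec()].
#' @return Numeric length-2: footprint (mm) in x and y at the surface.
#' @export
field_footprint <- function(beam) {
  stopifnot(inherits(beam, "beam_spec"))
  beam$field_mm + 2 * beam$ssd_mm * tan(beam$divergence_deg * pi / 180)
}

#' Relative Cherenkov yield of a radiation beam
#'
#' Calibration constants, not derived quantities: electron beams produce
#' ~100x more Cherenkov light than the matched photon beam, and an 18 MV
#' photon beam produces ~2.5x more than 6 MV. Yields are expressed relative
#' to the 6 MV photon beam.
#'
#' @param beam a [beam_spec()] with radiation modality.
#' @return Dimensionless yield relative to 6 MV.
#' @examples
#' relative_yield(beam_spec("electron-beam", "6MeV")) /
#'   relative_yield(beam_spec("photon-beam", "6MV"))   # 100
#' @export
relative_yield <- function(beam) {
  stopifnot(inherits(beam, "beam_spec"))
  if (beam$modality == "optical")
    stop("relative Cherenkov yield is not applicable to optical beams")
  tab <- c("6MV" = 1, "18MV" = 2.5, "6MeV" = 100, "18MeV" = 250)
  unname(tab[as.character(beam$energy)])
}

#' Cherenkov photons per beam primary (absolute-scale anchor)
#'
#' Places the relative yields on an approximate absolute scale so that
#' radiation and optical sources can be compared at equal primary budgets.
#' The Frank-Tamm count over 350-900 nm is
#' \eqn{2\pi\alpha (1/\lambda_1 - 1/\lambda_2) \sin^2\theta_c} photons per
#' unit track length (~39 photons/mm at n = 1.4 for beta ~ 1); multiplied by
#' an assumed mean secondary-electron track length above the 220 keV
#' threshold per 6 MV primary photon within the 5 cm volume
#' (`track_mm`, default 0.9 mm: ~20% interaction probability times a ~4.5 mm
#' above-threshold electron path). Other beams scale by [relative_yield()].
#'
#' @param beam a [beam_spec()] with radiation modality.
#' @param n refractive index used for the Cherenkov angle (default 1.4).
#' @param track_mm mean above-threshold secondary-electron track length per
#'   6 MV primary (mm).
#' @return Expected Cherenkov photons (350-900 nm) per primary.
#' @export
cherenkov_photons_per_primary <- function(beam, n = 1.4, track_mm = 0.9) {
  per_mm <- 2 * pi / 137.036 * (1 / .wl_min - 1 / .wl_max) * 1e6 *
    (1 - 1 / n^2)  # nm^-1 -> mm^-1
  per_mm * track_mm * relative_yield(beam)
}

#' Sample Cherenkov source photons for a radiation beam
#'
#' Draws `count` Cherenkov photon-packet origins: depth by inverse-CDF
#' sampling proportional to the beam's depth-dose curve on a fine grid,
#' lateral position uniform over the divergence-scaled footprint at that
#' depth plus an optional Gaussian penumbra, emission direction isotropic,
#' wavelength from the 1/lambda^2 law, weight 1.
#'
#' @param beam a [beam_spec()] (radiation modality).
#' @param pdd a [pdd_model()]; default derived from `beam$energy`.
#' @param count number of packets (> 0).
#' @param depth_max_mm maximum sampling depth (default 50 mm).
#' @param dz_mm depth-grid resolution for the inverse CDF (default 0.1 mm).
#' @return data.frame of class `source_samples`: `x, y, z, ux, uy, uz,
#'   wavelength, weight`.
#' @export
sample_source_positions <- function(beam, pdd = NULL, count,
                                    depth_max_mm = 50, dz_mm = 0.1) {
  stopifnot(inherits(beam, "beam_spec"), count > 0)
  if (beam$modality == "optical")
    return(sample_optical_source(beam, count))
  if (is.null(pdd)) pdd <- pdd_model(as.character(beam$energy))
  zg <- seq(0, depth_max_mm, by = dz_mm)
  dens <- dose_at_depth(pdd, zg)
  cdf <- cumsum(dens); cdf <- cdf / cdf[length(cdf)]
  # strictly increasing CDF for inverse interpolation
  keep <- c(TRUE, diff(cdf) > 0)
  z <- approx(cdf[keep], zg[keep], xout = runif(count), rule = 2)$y
  foot0 <- field_footprint(beam)
  grow <- 2 * tan(beam$divergence_deg * pi / 180)
  fx <- foot0[1] + grow * z
  fy <- foot0[2] + grow * z
  x <- (runif(count) - 0.5) * fx
  y <- (runif(count) - 0.5) * fy
  if (beam$penumbra_sigma_mm > 0) {
    x <- x + rnorm(count, 0, beam$penumbra_sigma_mm)
    y <- y + rnorm(count, 0, beam$penumbra_sigma_mm)
  }
  # isotropic emission directions
  cost <- 2 * runif(count) - 1
  sint <- sqrt(pmax(0, 1 - cost^2))
  phi <- 2 * pi * runif(count)
  wl <- sample_cherenkov_wavelength(runif(count))
  structure(data.frame(x = x, y = y, z = z,
                       ux = sint * cos(phi), uy = sint * sin(phi), uz = cost,
                       wavelength = wl, weight = 1),
            class = c("source_samples", "data.frame"))
}

# Optical beams deliver monochromatic downward photons at the surface,
# spread over the divergence-expanded footprint (same source geometry as
# the radiation beams: for the default 1 cm field at 0.9 m with 0.97 deg
# divergence the illuminated area is ~4 cm x 4 cm). The <1.3 deg ray tilt
# is neglected.
#' @importFrom stats rnorm uniroot
#' @noRd
sample_optical_source <- function(beam, count) {
  foot <- field_footprint(beam)
  x <- (runif(count) - 0.5) * foot[1]
  y <- (runif(count) - 0.5) * foot[2]
  structure(data.frame(x = x, y = y, z = 1e-6,
                       ux = 0, uy = 0, uz = 1,
                       wavelength = as.numeric(beam$energy), weight = 1),
            class = c("source_samples", "data.frame"))
}
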