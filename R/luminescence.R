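#' Luminescent reporter compound
#'
#' A fluorophore/phosphor described by a peak-normalized absorption spectrum
#' `ma(lambda)`, an emission spectrum (used as a probability density for
#' emission-wavelength sampling) and a luminescence quantum yield.
#'
#' @param name compound name.
#' @param absorption list(wavelength, value): non-negative spectrum; it is
#'   peak-normalized on construction.
#' @param emission list(wavelength, value): non-negative spectrum; it is
#'   normalized to integrate to 1 on construction.
#' @param quantum_yield emitted-per-absorbed probability in \[0, 1\].
#' @return An object of class `fluorophore`.
#' @export
fluorophore <- function(name, absorption, emission, quantum_yield) {
  stopifnot(is.list(absorption), is.list(emission),
            quantum_yield >= 0, quantum_yield <= 1)
  chk <- function(sp, nm) {
    wl <- as.numeric(sp$wavelength); v <- as.numeric(sp$value)
    if (length(wl) != length(v) || any(diff(wl) <= 0) || any(v < 0))
      stop(sprintf("'%s' spectrum must have ascending wavelengths and values >= 0", nm))
    list(wavelength = wl, value = v)
  }
  ab <- chk(absorption, "absorption"); em <- chk(emission, "emission")
  if (max(ab$value) > 0) ab$value <- ab$value / max(ab$value)
  tot <- if (length(em$wavelength) > 1)
    sum(diff(em$wavelength) * (head(em$value, -1) + em$value[-1]) / 2)
  else sum(em$value)
  if (tot > 0) em$value <- em$value / tot
  structure(list(name = name, absorption = ab, emission = em,
                 quantum_yield = quantum_yield,
                 kappa = NULL, background_mu_a = NULL),
            class = "fluorophore")
}

#' @export
print.fluorophore <- function(x, ...) {
  pk <- x$absorption$wavelength[which.max(x$absorption$value)]
  em <- x$emission$wavelength[which.max(x$emission$value)]
  cat(sprintf("<fluorophore> %s: absorption peak %g nm, emission peak %g nm, QY %.3g\n",
              x$name, pk, em, x$quantum_yield))
  invisible(x)
}

#' Peak-normalized absorption at given wavelengths (0 outside support)
#' @param fl a [fluorophore()].
#' @param wavelength nm.
#' @return numeric vector.
#' @export
fl_absorption <- function(fl, wavelength) {
  a <- fl$absorption
  out <- approx(a$wavelength, a$value, xout = wavelength, rule = 1)$y
  out[is.na(out)] <- 0
  out
}

#' Emission density at given wavelengths (0 outside support)
#' @param fl a [fluorophore()].
#' @param wavelength nm.
#' @return numeric vector.
#' @export
fl_emission <- function(fl, wavelength) {
  e <- fl$emission
  out <- approx(e$wavelength, e$value, xout = wavelength, rule = 1)$y
  out[is.na(out)] <- 0
  out
}

#' Default oxygen-probe-like fluorophore
#'
#' A two-Gaussian absorption model with bands at 430 nm (Soret-like, unit
#' amplitude, sigma 22 nm) and 630 nm (Q-band-like, amplitude 0.55, sigma
#' 28 nm) and a single-Gaussian emission at 770 nm (sigma 20 nm), emulating
#' a Pt-porphyrin oxygen-sensing phosphor. The default quantum yield 0.07
#' is typical of Pt-porphyrin dendrimers; escape-fraction ratios are
#' insensitive to it.
#'
#' @param quantum_yield override the default quantum yield.
#' @return A [fluorophore()].
#' @export
ptg4_like_fluorophore <- function(quantum_yield = 0.07) {
  wl <- seq(.wl_min, .wl_max, by = 1)
  ab <- exp(-((wl - 430) / 22)^2 / 2) + 0.55 * exp(-((wl - 630) / 28)^2 / 2)
  em <- exp(-((wl - 770) / 20)^2 / 2)
  fluorophore("PtG4-like (synthetic)",
              absorption = list(wavelength = wl, value = ab),
              emission = list(wavelength = wl, value = em),
              quantum_yield = quantum_yield)
}

#' Fraction of an absorption event attributed to the fluorophore
#'
#' Partition of absorbed weight between the fluorophore and background
#' chromophores: \eqn{f(\lambda) = \kappa m_a(\lambda) / (\kappa
#' m_a(\lambda) + b(\lambda))}, monotone in the concentration scale kappa.
#'
#' @param wavelength nm.
#' @param fl a [fluorophore()].
#' @param kappa concentration scale (mm^-1 per unit normalized absorbance);
#'   default `fl$kappa` as set by [build_layered_model()].
#' @param background background absorption b(lambda) in mm^-1: scalar,
#'   vector matched to `wavelength`, or default `fl$background_mu_a`.
#' @return Probability in \[0, 1\].
#' @export
excitation_fraction <- function(wavelength, fl, kappa = NULL, background = NULL) {
  kappa <- kappa %||% fl$kappa
  if (is.null(kappa)) stop("kappa is not set; supply it or use build_layered_model()")
  if (is.null(background)) {
    bg <- fl$background_mu_a
    if (is.null(bg)) stop("background absorption is not set")
    background <- approx(bg$wavelength, bg$mu_a, xout = wavelength, rule = 2)$y
  }
  fa <- kappa * fl_absorption(fl, wavelength)
  den <- fa + background
  ifelse(den > 0, fa / den, 0)
}

#' Convert an inclusion absorption event to a luminescence packet
#'
#' With probability `excitation_fraction(wavelength) * quantum_yield`, an
#' absorption event at `position` yields a new isotropic packet whose
#' wavelength is drawn from the emission density. This is the analog
#' (probabilistic) form; the transport kernel uses the
#' expectation-equivalent weighted form.
#'
#' @param position numeric length-3 (mm), inside the inclusion.
#' @param wavelength excitation wavelength (nm).
#' @param fl a [fluorophore()].
#' @param weight weight carried by the absorbed packet (default 1).
#' @param kappa,background see [excitation_fraction()].
#' @return `NULL` (no emission) or a one-row `source_samples` data.frame
#'   with the emission packet.
#' @export
emit_luminescence <- function(position, wavelength, fl, weight = 1,
                              kappa = NULL, background = NULL) {
  p_em <- excitation_fraction(wavelength, fl, kappa, background) * fl$quantum_yield
  if (runif(1) >= p_em) return(NULL)
  emg <- seq(.wl_min, .wl_max, by = 1)
  pdf <- fl_emission(fl, emg)
  wl_em <- if (sum(pdf) > 0) sample(emg, 1, prob = pdf) else emg[which.max(pdf)]
  cost <- 2 * runif(1) - 1
  sint <- sqrt(max(0, 1 - cost^2)); phi <- 2 * pi * runif(1)
  structure(data.frame(x = position[1], y = position[2], z = position[3],
                       ux = sint * cos(phi), uy = sint * sin(phi), uz = cost,
                       wavelength = wl_em, weight = weight),
            class = c("source_samples", "data.frame"))
}

#' Luminescence escape fractions
#'
#' From a transport tally with luminescence bookkeeping, the fraction of
#' generated emission weight that crossed the inclusion boundary outward and
#' the fraction that reached the top tissue surface. The nesting
#' surface <= exited <= generated always holds.
#'
#' @param tally a `tally_set` from [run_transport()], or a list with
#'   `generated_weight`, `exited_weight`, `surface_weight` (as in
#'   `tally$lum`).
#' @return list with `exited_fraction`, `surface_fraction`, and the three
#'   raw weights.
#' @export
escape_report <- function(tally) {
  lum <- if (inherits(tally, "tally_set")) tally$lum else tally
  g <- lum$generated_weight
  if (!is.finite(g) || g <= 0)
    stop("no luminescence was generated; escape fractions are undefined")
  list(exited_fraction = lum$exited_weight / g,
       surface_fraction = lum$surface_weight / g,
       generated_weight = g, exited_weight = lum$exited_weight,
       surface_weight = lum$surface_weight)
}
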