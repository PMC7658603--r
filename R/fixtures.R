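#' Synthetic chromophore absorption spectra
#'
#' Analytic stand-ins for the dominant tissue chromophores, used to build
#' the synthetic layer property tables. They are not literature spectra:
#' magnitudes and band positions are chosen to be typical of tissue optics
#' (blood with a strong Soret-like band near 418 nm and a Q-band near
#' 555 nm, a red/NIR floor; melanin as a power law; a weak NIR water-like
#' rise), which is what reproduces the qualitative blood-layer absorption
#' spikes and the red-transmissive window.
#'
#' @param wavelength nm.
#' @return Absorption coefficient in mm^-1 (for whole blood / melanized
#'   epidermis at unit concentration fraction).
#' @name synthetic_chromophores
NULL

#' @rdname synthetic_chromophores
#' @export
mu_a_blood_synthetic <- function(wavelength) {
  115 * exp(-((wavelength - 418) / 22)^2 / 2) +
    23 * exp(-((wavelength - 555) / 28)^2 / 2) +
    0.45 + 0.4 * exp(-((wavelength - 890) / 90)^2 / 2)
}

#' @rdname synthetic_chromophores
#' @export
mu_a_melanin_synthetic <- function(wavelength) {
  1.7 * (wavelength / 550)^-3
}

#' @rdname synthetic_chromophores
#' @export
mu_a_baseline_synthetic <- function(wavelength) {
  0.012 + 0.01 * exp(-((wavelength - 970) / 120)^2 / 2)
}

# layer recipe for the synthetic seven-layer skin + adipose + muscle stack:
# thickness (mm), blood fraction, melanin factor, mus' at 500 nm (mm^-1),
# scatter power, g, n
.seven_layer_recipe <- data.frame(
  layer = c("stratum_corneum", "epidermis", "papillary_dermis",
            "upper_blood_net_dermis", "reticular_dermis",
            "deep_blood_net_dermis", "lower_dermis", "adipose", "muscle"),
  thickness_mm = c(0.02, 0.08, 0.15, 0.10, 0.80, 0.30, 0.05, 5.0, 43.5),
  blood = c(0, 0, 0.04, 0.30, 0.04, 0.25, 0.05, 0.01, 0.03),
  melanin = c(0.05, 1.0, 0, 0, 0, 0, 0, 0, 0),
  musp500 = c(6.0, 4.0, 3.0, 3.0, 2.5, 2.5, 2.3, 1.3, 0.95),
  spower = c(1.2, 1.3, 1.3, 1.3, 1.3, 1.3, 1.3, 0.55, 0.95),
  g = c(0.86, 0.85, 0.87, 0.90, 0.87, 0.90, 0.87, 0.90, 0.90),
  n = c(1.50, 1.40, 1.39, 1.39, 1.39, 1.38, 1.38, 1.44, 1.37),
  stringsAsFactors = FALSE)

#' Write a synthetic tissue layer property table
#'
#' Generates the CSV layer-property dialect consumed by
#' [build_layered_model()] for one of three presets:
#' \describe{
#'   \item{seven-layer-skin-default}{seven skin sublayers (stratum corneum
#'     through lower dermis, including two blood-network plexus layers whose
#'     effective attenuation at the 770 nm emission band is at least twice
#'     that of the adjacent dermis) over 5 mm adipose and muscle to 50 mm
#'     total depth.}
#'   \item{homogeneous-test}{a single 50 mm layer with depth-constant,
#'     wavelength-flat properties (mu_a 0.01, mu_s 10, g 0.9, n 1.4).}
#'   \item{transparent-test}{a single 50 mm layer with mu_a = mu_s = 0.}
#' }
#' The seven-layer spectra are synthetic analytic constructions (see
#' [synthetic_chromophores]), not the literature values of any specific
#' skin-optics report.
#'
#' @param preset one of the three preset names.
#' @param path output CSV path; default a tempfile.
#' @param wl_step wavelength grid step in nm (default 10).
#' @return `path`, invisibly.
#' @export
make_tissue_table <- function(preset = c("seven-layer-skin-default",
                                         "homogeneous-test",
                                         "transparent-test"),
                              path = tempfile(fileext = ".csv"),
                              wl_step = 10) {
  preset <- match.arg(preset)
  wl <- seq(.wl_min, .wl_max, by = wl_step)
  if (preset == "seven-layer-skin-default") {
    rec <- .seven_layer_recipe
    rows <- lapply(seq_len(nrow(rec)), function(i) {
      r <- rec[i, ]
      mu_a <- mu_a_baseline_synthetic(wl) + r$blood * mu_a_blood_synthetic(wl) +
        r$melanin * mu_a_melanin_synthetic(wl)
      musp <- r$musp500 * (wl / 500)^(-r$spower)
      data.frame(layer = r$layer, thickness_mm = r$thickness_mm,
                 wavelength_nm = wl, mu_a_mm = round(mu_a, 6),
                 mu_s_mm = round(musp / (1 - r$g), 6), g = r$g, n = r$n)
    })
    tab <- do.call(rbind, rows)
  } else {
    v <- if (preset == "homogeneous-test") c(0.01, 10) else c(0, 0)
    tab <- data.frame(layer = "bulk", thickness_mm = 50, wavelength_nm = wl,
                      mu_a_mm = v[1], mu_s_mm = v[2], g = 0.9, n = 1.4)
  }
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate a synthetic Gaussian-band compound database
#'
#' Writes a compound index plus two-column spectrum files in the
#' [parse_compound_db()] dialect. Each compound has a single Gaussian
#' absorption band with center, width, and quantum yield drawn under the
#' seed, so every fixture is byte-reproducible. A sidecar CSV stores each
#' compound's overlap score against a supplied reference spectrum computed
#' by independent fine-grid (0.1 nm) trapezoidal quadrature -- an oracle
#' that never calls the package's own scorer.
#'
#' @param n_compounds number of compounds (>= 1).
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param center_range,width_range band-center and band-sigma ranges (nm).
#' @param qy_range quantum-yield range.
#' @param reference_spectrum optional [spectrum()] for the sidecar oracle;
#'   default the d = 0 analytic Cherenkov spectrum (pure 1/lambda^2).
#' @param bounds analysis band for the oracle integral (nm).
#' @return list with `index` (path), `oracle` (path to sidecar CSV), and
#'   `table` (the generation parameters).
#' @export
make_compound_db <- function(n_compounds = 20, dir = tempfile("compounds"),
                             seed = 1, center_range = c(380, 820),
                             width_range = c(10, 40), qy_range = c(0.05, 0.95),
                             reference_spectrum = NULL, bounds = c(350, 850)) {
  stopifnot(n_compounds >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  classes <- c("coumarin", "porphyrin", "xanthene", "cyanine", "acridine")
  par <- data.frame(
    name = sprintf("compound_%02d", seq_len(n_compounds)),
    class = classes[(seq_len(n_compounds) - 1L) %% length(classes) + 1L],
    center = runif(n_compounds, center_range[1], center_range[2]),
    width = runif(n_compounds, width_range[1], width_range[2]),
    qy = round(runif(n_compounds, qy_range[1], qy_range[2]), 3))
  wl <- seq(.wl_min, .wl_max, by = 1)
  idx_lines <- character(n_compounds)
  for (i in seq_len(n_compounds)) {
    ab <- exp(-((wl - par$center[i]) / par$width[i])^2 / 2)
    abs_file <- sprintf("%s_abs.txt", par$name[i])
    writeLines(c("# wavelength_nm value",
                 sprintf("%g %.8f", wl, ab)),
               file.path(dir, abs_file))
    em <- exp(-((wl - (par$center[i] + 40)) / par$width[i])^2 / 2)
    em_file <- sprintf("%s_em.txt", par$name[i])
    writeLines(c("# wavelength_nm value",
                 sprintf("%g %.8f", wl, em)),
               file.path(dir, em_file))
    idx_lines[i] <- sprintf("%s | %s | %.3f | %s | %s", par$name[i],
                            par$class[i], par$qy[i], abs_file, em_file)
  }
  index <- file.path(dir, "index.txt")
  writeLines(idx_lines, index)
  # sidecar oracle: fine-quadrature overlap integrals, independent of the
  # package scorer (trapezoid at 0.1 nm on closed-form band shapes)
  if (is.null(reference_spectrum))
    reference_spectrum <- make_analytic_cherenkov_spectrum(0, "transparent-test")
  fine <- seq(bounds[1], bounds[2], by = 0.1)
  iref <- approx(reference_spectrum$wavelength, reference_spectrum$value,
                 xout = fine, rule = 2)$y
  oracle_score <- vapply(seq_len(n_compounds), function(i) {
    ab <- exp(-((fine - par$center[i]) / par$width[i])^2 / 2)
    par$qy[i] * sum((head(iref * ab, -1) + (iref * ab)[-1]) / 2 * diff(fine))
  }, numeric(1))
  oracle <- data.frame(name = par$name, class = par$class, qy = par$qy,
                       center = par$center, width = par$width,
                       oracle_score = oracle_score)
  oracle <- oracle[order(-oracle$oracle_score, oracle$name), ]
  oracle$oracle_rank <- seq_len(nrow(oracle))
  oracle_path <- file.path(dir, "oracle.csv")
  write.csv(oracle, oracle_path, row.names = FALSE)
  list(index = index, oracle = oracle_path, table = par)
}

#' Analytic in-tissue Cherenkov spectrum stand-in
#'
#' \eqn{I(\lambda) = \lambda^{-2} \exp(-\int_0^d \mu_{eff}(\lambda, z) dz)}
#' on a 1 nm grid over 350-900 nm: the Frank-Tamm spectral density filtered
#' by the depth-integrated effective attenuation of the overlying layers.
#' Tissue acts as a long-pass filter, so the spectral mode shifts red with
#' increasing depth.
#'
#' @param d depth in mm (>= 0).
#' @param preset tissue preset name (see [make_tissue_table()]) or a
#'   [layered_tissue()].
#' @return A [spectrum()].
#' @examples
#' s0 <- make_analytic_cherenkov_spectrum(0, "transparent-test")
#' # pure 1/lambda^2: I(350)/I(700) = 4
#' @export
make_analytic_cherenkov_spectrum <- function(d, preset = "seven-layer-skin-default") {
  stopifnot(d >= 0)
  wl <- seq(.wl_min, .wl_max, by = 1)
  tis <- if (inherits(preset, "layered_tissue")) preset
         else build_layered_model(make_tissue_table(preset))
  tau <- rep(0, length(wl))  # depth-integrated mu_eff over [0, d]
  if (d > 0) {
    z0 <- 0
    for (ly in tis$layers) {
      if (z0 >= d) break
      seg <- min(ly$thickness_mm, d - z0)
      tau <- tau + seg * op_mu_eff(ly$properties, wl)
      z0 <- z0 + seg
    }
  }
  spectrum(wl, wl^-2 * exp(-tau))
}

#' Constructed event sets with known analytic structure
#'
#' Deterministic (seeded) samples used to exercise the profile-analysis
#' operators against closed-form expectations:
#' \describe{
#'   \item{gaussian-lateral}{x ~ Normal(0, sigma_mm), z uniform on
#'     \[0, depth_mm\]: slab FWHM = 2.3548 sigma at every depth.}
#'   \item{depth-widening}{x ~ Normal(0, sigma0_mm + slope * zc) with zc the
#'     center of the event's 1 mm depth slab, so each slab is exactly
#'     Gaussian and the recovered slab FWHM grows linearly with
#'     d(FWHM)/dz = 2.3548 * slope.}
#'   \item{surface-cloud}{x, y ~ Normal(0, sigma_mm), z = 0 with unit
#'     weights: surface histogram with known second moment.}
#' }
#'
#' @param kind fixture kind.
#' @param n number of events.
#' @param seed integer seed.
#' @param sigma_mm,sigma0_mm,slope,depth_mm shape parameters (see above).
#' @return data.frame with `x`, `y`, `z`, `weight`.
#' @export
make_event_fixture <- function(kind = c("gaussian-lateral", "depth-widening",
                                        "surface-cloud"),
                               n = 1e5, seed = 1, sigma_mm = 2,
                               sigma0_mm = 1, slope = 0.2, depth_mm = 10) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind == "gaussian-lateral") {
    z <- runif(n, 0, depth_mm)
    data.frame(x = rnorm(n, 0, sigma_mm), y = rnorm(n, 0, sigma_mm),
               z = z, weight = 1)
  } else if (kind == "depth-widening") {
    z <- runif(n, 0, depth_mm)
    zc <- floor(z) + 0.5
    data.frame(x = rnorm(n, 0, sigma0_mm + slope * zc),
               y = rnorm(n, 0, sigma0_mm + slope * zc), z = z, weight = 1)
  } else {
    data.frame(x = rnorm(n, 0, sigma_mm), y = rnorm(n, 0, sigma_mm),
               z = 0, weight = 1)
  }
}
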