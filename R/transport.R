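#' Sample an exponential free path
#'
#' Standard inversion sampling of the photon free path in a medium with
#' total interaction coefficient `mu_t`: \eqn{s = -\ln(u)/\mu_t}.
#'
#' @param u uniform(0,1\] variates.
#' @param mu_t total attenuation coefficient (mm^-1, > 0).
#' @return Step lengths in mm.
#' @examples
#' sample_step(exp(-1), 1)  # 1 mm
#' @export
sample_step <- function(u, mu_t) {
  if (any(mu_t <= 0)) stop("mu_t must be > 0")
  if (any(u <= 0 | u > 1)) stop("u must lie in (0, 1]")
  -log(u) / mu_t
}

#' Henyey-Greenstein scattering of a direction vector
#'
#' Samples a deflection cosine from the Henyey-Greenstein phase function
#' (isotropic when g = 0; mean deflection cosine equals g) with uniform
#' azimuth, and rotates the direction accordingly. Vectorized reference
#' implementation matching the compiled transport kernel.
#'
#' @param direction unit 3-vector, or an n x 3 matrix of unit rows.
#' @param g anisotropy in (-1, 1).
#' @param u1,u2 uniform variates (deflection, azimuth); default freshly drawn.
#' @return Matrix (n x 3) of unit direction vectors.
#' @export
hg_scatter <- function(direction, g, u1 = NULL, u2 = NULL) {
  d <- if (is.matrix(direction)) direction else matrix(direction, ncol = 3)
  n <- nrow(d)
  if (abs(g) >= 1) stop("g must lie in (-1, 1)")
  if (is.null(u1)) u1 <- runif(n)
  if (is.null(u2)) u2 <- runif(n)
  if (abs(g) < 1e-6) {
    cost <- 2 * u1 - 1
  } else {
    tmp <- (1 - g^2) / (1 - g + 2 * g * u1)
    cost <- pmin(1, pmax(-1, (1 + g^2 - tmp^2) / (2 * g)))
  }
  sint <- sqrt(pmax(0, 1 - cost^2))
  phi <- 2 * pi * u2
  cosp <- cos(phi); sinp <- sin(phi)
  ux <- d[, 1]; uy <- d[, 2]; uz <- d[, 3]
  out <- matrix(0, n, 3)
  vert <- abs(uz) > 0.99999
  if (any(vert)) {
    s <- sign(uz[vert]); s[s == 0] <- 1
    out[vert, ] <- cbind(sint[vert] * cosp[vert], sint[vert] * sinp[vert],
                         cost[vert] * s)
  }
  if (any(!vert)) {
    i <- !vert
    den <- sqrt(1 - uz[i]^2)
    nux <- sint[i] * (ux[i] * uz[i] * cosp[i] - uy[i] * sinp[i]) / den + ux[i] * cost[i]
    nuy <- sint[i] * (uy[i] * uz[i] * cosp[i] + ux[i] * sinp[i]) / den + uy[i] * cost[i]
    nuz <- -sint[i] * cosp[i] * den + uz[i] * cost[i]
    nrm <- sqrt(nux^2 + nuy^2 + nuz^2)
    out[i, ] <- cbind(nux / nrm, nuy / nrm, nuz / nrm)
  }
  out
}

#' Unpolarized Fresnel reflectance
#'
#' Average of the s- and p-polarized Fresnel power reflectances at a planar
#' index mismatch; returns 1 beyond the critical angle (total internal
#' reflection).
#'
#' @param n1 index on the incident side (>= 1).
#' @param n2 index on the far side (>= 1).
#' @param cos_incidence cosine of the incidence angle, in (0, 1\].
#' @return Reflection probability in \[0, 1\].
#' @examples
#' fresnel_reflectance(1, 1.4, 1)  # ~0.0278 at normal incidence
#' @export
fresnel_reflectance <- function(n1, n2, cos_incidence) {
  stopifnot(all(n1 >= 1), all(n2 >= 1),
            all(cos_incidence > 0), all(cos_incidence <= 1))
  s2 <- (n1 / n2)^2 * (1 - cos_incidence^2)
  out <- rep(1, length(s2))
  ok <- s2 < 1
  if (any(ok)) {
    cost <- sqrt(1 - s2[ok]); cosi <- cos_incidence[ok]
    rs <- ((n1 * cosi - n2 * cost) / (n1 * cosi + n2 * cost))^2
    rp <- ((n1 * cost - n2 * cosi) / (n1 * cost + n2 * cosi))^2
    out[ok] <- (rs + rp) / 2
  }
  out[abs(n1 - n2) < 1e-12] <- 0
  out
}

#' Transport configuration
#'
#' @param w_roulette Russian-roulette weight threshold (default 1e-4).
#' @param roulette_survival survival probability when rouletted (default 0.1;
#'   survivors are boosted by its reciprocal).
#' @param nz_fluence number of z-voxels for the pathlength fluence estimator
#'   over the volume depth; the default 5000 gives the 10 um resolution of
#'   the scoring grid. Set 0 to disable fluence scoring.
#' @param spectral_bin_nm width of the spectral tally bins (default 10 nm
#'   over 350-900 nm).
#' @param record_surface keep per-event surface detections (position,
#'   wavelength, weight)?
#' @param max_steps abort threshold for pathological packets.
#' @return list of class `transport_config`.
#' @export
transport_config <- function(w_roulette = 1e-4, roulette_survival = 0.1,
                             nz_fluence = 5000, spectral_bin_nm = 10,
                             record_surface = TRUE, max_steps = 1e6) {
  structure(list(w_roulette = w_roulette, roulette_survival = roulette_survival,
                 nz_fluence = as.integer(nz_fluence),
                 spectral_bin_nm = spectral_bin_nm,
                 record_surface = isTRUE(record_surface), max_steps = max_steps),
            class = "transport_config")
}

# Pack a layered_tissue into the flat arrays the C++ kernel consumes.
# All media are resampled onto a shared 5 nm wavelength grid.
#' @noRd
.pack_model <- function(tissue) {
  wl <- seq(.wl_min, .wl_max, by = 5)
  media <- lapply(tissue$layers, `[[`, "properties")
  has_sphere <- !is.null(tissue$inclusion)
  if (has_sphere) media <- c(media, list(tissue$inclusion$properties))
  M <- length(media)
  getm <- function(field) vapply(media, function(op) op_lookup(op, wl)[[field]],
                                 numeric(length(wl)))
  fluor_on <- FALSE
  exc <- rep(0, length(wl)); em_wl <- c(.wl_min, .wl_max); em_cdf <- c(0, 1)
  if (has_sphere && !is.null(tissue$inclusion$fluorophore)) {
    fl <- tissue$inclusion$fluorophore
    if (!is.null(fl$kappa)) {
      mua_inc <- op_lookup(tissue$inclusion$properties, wl)$mu_a
      ma <- fl_absorption(fl, wl)
      exc <- ifelse(mua_inc > 0, fl$kappa * ma / mua_inc, 0) * fl$quantum_yield
      fluor_on <- any(exc > 0)
    }
    emg <- seq(.wl_min, .wl_max, by = 1)
    pdf <- fl_emission(fl, emg)
    if (sum(pdf) > 0) {
      cdf <- cumsum(pdf) / sum(pdf)
      keep <- c(TRUE, diff(cdf) > 0)
      em_wl <- emg[keep]; em_cdf <- cdf[keep]
      em_cdf[1] <- 0; em_cdf[length(em_cdf)] <- 1
    }
  }
  list(layer_z = tissue$boundaries_mm, wl = wl,
       mua = getm("mu_a"), mus = getm("mu_s"), g = getm("g"), n = getm("n"),
       half = tissue$lateral_mm / 2,
       has_sphere = has_sphere,
       sphere = if (has_sphere)
         c(tissue$inclusion$center, tissue$inclusion$diameter_mm / 2)
       else numeric(4),
       sphere_med = if (has_sphere) M - 1L else -1L,
       fluor_on = fluor_on, exc = exc, em_wl = em_wl, em_cdf = em_cdf)
}

#' Run Monte Carlo transport of source photon packets
#'
#' Traces every packet through the tissue, with implicit-capture absorption,
#' Henyey-Greenstein scattering, Fresnel boundaries, and (when the tissue
#' carries a fluorophore-bearing inclusion) single-generation luminescence
#' conversion of absorption deposits inside the inclusion. Side and bottom
#' boundaries absorb; the top surface detects transmitted packets.
#'
#' @param sources a `source_samples` data.frame (see
#'   [sample_source_positions()]) with columns `x, y, z, ux, uy, uz,
#'   wavelength, weight`.
#' @param tissue a [layered_tissue()].
#' @param config a [transport_config()].
#' @param batches number of batches the source list is split into; each batch
#'   is traced with its own RNG substream and the tallies merged.
#' @param seed optional integer; when given, batch `i` is seeded
#'   `seed + i - 1` so runs are bit-reproducible.
#' @return A `tally_set` (see [merge_tallies()]), with elements `summary`
#'   (weight ledger per provenance), `fluence` (z profile), spectral tallies,
#'   luminescence tallies and `surface_events`.
#' @export
run_transport <- function(sources, tissue, config = transport_config(),
                          batches = 1L, seed = NULL) {
  stopifnot(is.data.frame(sources), nrow(sources) >= 1L,
            inherits(tissue, "layered_tissue"),
            inherits(config, "transport_config"))
  pk <- .pack_model(tissue)
  nb <- as.integer((.wl_max - .wl_min) / config$spectral_bin_nm)
  src <- as.matrix(sources[, c("x", "y", "z", "ux", "uy", "uz",
                               "wavelength", "weight")])
  idx <- split(seq_len(nrow(src)),
               rep(seq_len(batches), each = ceiling(nrow(src) / batches),
                   length.out = nrow(src)))
  out <- NULL
  for (i in seq_along(idx)) {
    if (!is.null(seed)) set.seed(seed + i - 1L)
    raw <- .mc_trace_cpp(src[idx[[i]], , drop = FALSE],
                         pk$layer_z, pk$wl, pk$mua, pk$mus, pk$g, pk$n,
                         pk$half[1], pk$half[2],
                         pk$has_sphere, pk$sphere, pk$sphere_med,
                         tissue$n_ambient,
                         pk$fluor_on, pk$exc, pk$em_wl, pk$em_cdf,
                         config$w_roulette, config$roulette_survival,
                         config$nz_fluence,
                         c(.wl_min, config$spectral_bin_nm, nb),
                         config$record_surface, config$max_steps)
    tl <- .as_tally(raw, tissue, config)
    out <- if (is.null(out)) tl else merge_tallies(out, tl)
  }
  out$n_sources <- nrow(src)
  out
}

#' @noRd
.as_tally <- function(raw, tissue, config) {
  nb <- length(raw$spec_in_tumor)
  wl_centers <- .wl_min + (seq_len(nb) - 0.5) * config$spectral_bin_nm
  nz <- nrow(raw$fluence)
  structure(list(
    summary = raw$summary,
    fluence = raw$fluence,
    z_centers = if (nz > 0) (seq_len(nz) - 0.5) * tissue$depth_mm / nz else numeric(0),
    wl_centers = wl_centers,
    spec_in_tumor = raw$spec_in_tumor,
    spec_exit_tumor = raw$spec_exit_tumor,
    spec_surface_excitation = raw$spec_surface_excitation,
    spec_surface_luminescence = raw$spec_surface_luminescence,
    lum = list(generated_weight = raw$lum_generated_weight,
               generated_count = raw$lum_generated_count,
               exited_weight = raw$lum_exited_weight,
               surface_weight = raw$summary["top", "luminescence"],
               excitation_hist = raw$exc_hist,
               emission_hist = raw$em_hist),
    surface_events = as.data.frame(raw$surface_events),
    n_aborted = raw$n_aborted,
    n_sources = NA_integer_),
    class = "tally_set")
}

#' Merge two transport tallies
#'
#' Summation of all accumulators and concatenation of surface events; the
#' merge is associative and order-independent for every count.
#'
#' @param a,b `tally_set` objects from [run_transport()].
#' @return Merged `tally_set`.
#' @export
merge_tallies <- function(a, b) {
  stopifnot(inherits(a, "tally_set"), inherits(b, "tally_set"))
  out <- a
  for (f in c("summary", "fluence", "spec_in_tumor", "spec_exit_tumor",
              "spec_surface_excitation", "spec_surface_luminescence"))
    out[[f]] <- a[[f]] + b[[f]]
  for (f in c("generated_weight", "generated_count", "exited_weight",
              "surface_weight"))
    out$lum[[f]] <- a$lum[[f]] + b$lum[[f]]
  out$lum$excitation_hist <- a$lum$excitation_hist + b$lum$excitation_hist
  out$lum$emission_hist <- a$lum$emission_hist + b$lum$emission_hist
  out$surface_events <- rbind(a$surface_events, b$surface_events)
  out$n_aborted <- a$n_aborted + b$n_aborted
  ns <- c(a$n_sources, b$n_sources)
  out$n_sources <- if (all(is.na(ns))) NA_integer_ else sum(ns, na.rm = TRUE)
  out
}

#' @export
print.tally_set <- function(x, ...) {
  cat("<tally_set>\n")
  print(round(x$summary, 4))
  if (x$lum$generated_count > 0)
    cat(sprintf("  luminescence: generated %.4g (n=%d), exited %.4g, surface %.4g\n",
                x$lum$generated_weight, as.integer(x$lum$generated_count),
                x$lum$exited_weight, x$lum$surface_weight))
  cat(sprintf("  surface events recorded: %d\n", nrow(x$surface_events)))
  invisible(x)
}

#' Write a transport tally to CSV files
#'
#' Exports the depth fluence profile (`fluence.csv`), the spectral tallies
#' per detector class (`spectra.csv`, 10 nm bins: generated-in/exiting the
#' inclusion, surface arrivals per provenance, luminescence excitation and
#' emission histograms), the weight ledger (`summary.csv`) and the
#' per-event surface detections (`surface_events.csv`).
#'
#' @param tally a `tally_set`.
#' @param outdir output directory (created if needed).
#' @return vector of written paths, invisibly.
#' @export
write_tally <- function(tally, outdir) {
  stopifnot(inherits(tally, "tally_set"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(summary = file.path(outdir, "summary.csv"),
             spectra = file.path(outdir, "spectra.csv"),
             surface = file.path(outdir, "surface_events.csv"))
  write.csv(data.frame(quantity = rownames(tally$summary), tally$summary,
                       row.names = NULL), paths["summary"], row.names = FALSE)
  write.csv(data.frame(wavelength = tally$wl_centers,
                       in_tumor = tally$spec_in_tumor,
                       exit_tumor = tally$spec_exit_tumor,
                       surface_excitation = tally$spec_surface_excitation,
                       surface_luminescence = tally$spec_surface_luminescence,
                       lum_excitation = tally$lum$excitation_hist,
                       lum_emission = tally$lum$emission_hist),
            paths["spectra"], row.names = FALSE)
  write.csv(tally$surface_events, paths["surface"], row.names = FALSE)
  if (nrow(tally$fluence) > 0) {
    paths["fluence"] <- file.path(outdir, "fluence.csv")
    write.csv(data.frame(depth = tally$z_centers,
                         excitation = tally$fluence[, 1],
                         luminescence = tally$fluence[, 2]),
              paths["fluence"], row.names = FALSE)
  }
  invisible(paths)
}

#' Weight-conservation check of a tally
#'
#' Launched weight must equal absorbed + surface + side/bottom + net
#' roulette adjustment, per provenance.
#'
#' @param tally a `tally_set`.
#' @return Named numeric: maximum relative imbalance per provenance.
#' @export
weight_balance <- function(tally) {
  s <- tally$summary
  launched <- s["launched", ]
  acc <- s["absorbed", ] + s["top", ] + s["side_bottom", ] + s["roulette_net", ]
  ifelse(launched > 0, abs(launched - acc) / launched, 0)
}
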