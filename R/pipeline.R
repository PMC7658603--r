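#' @noRd
.parse_source_label <- function(label) {
  lab <- as.character(label)
  if (grepl("MV$", lab)) return(beam_spec("photon-beam", lab))
  if (grepl("MeV$", lab)) return(beam_spec("electron-beam", lab))
  wl <- suppressWarnings(as.numeric(sub("nm$", "", lab)))
  if (is.finite(wl))
    return(beam_spec("optical", wl, field_mm = 10, ssd_mm = 900,
                     divergence_deg = 0.97))
  stop("unrecognized source label: ", lab)
}

#' Sheet-beam lateral-spread experiment
#'
#' Emulates delivery of a thin sheet (2.5 mm x 10 mm, the minimum
#' multileaf-collimator leaf width) of megavoltage photons or electrons from
#' 0.2 m above the tissue: Cherenkov photon origins are sampled from each
#' beam's depth-dose curve with the modality's penumbra blur, transported,
#' and the lateral spread summarized as FWHM per millimetre of depth.
#' Electron beams carry ~100x the Cherenkov weight of photon beams and a
#' wider penumbra.
#'
#' @param energies beam energy labels, e.g. `c("6MV", "6MeV")`.
#' @param events Cherenkov packets sampled per beam.
#' @param tissue a [layered_tissue()]; default the synthetic seven-layer
#'   stack without inclusion.
#' @param seed integer seed (reports are bit-reproducible given the seed).
#' @param transport also transport the packets and tally fluence/surface?
#'   (FWHM analysis itself runs on the emission origins.)
#' @param config [transport_config()] for the transport stage.
#' @param fwhm_on "origins" (default) or "final" (surface exit positions).
#' @return `run_report` with per-beam `origins`, `fwhm` tables, relative
#'   yields, and (if transported) tallies.
#' @export
run_sheet_experiment <- function(energies = c("6MV", "6MeV"), events = 1e5,
                                 tissue = NULL, seed = 1, transport = TRUE,
                                 config = transport_config(nz_fluence = 500),
                                 fwhm_on = c("origins", "final")) {
  fwhm_on <- match.arg(fwhm_on)
  if (is.null(tissue)) tissue <- build_layered_model()
  runs <- list()
  for (en in energies) {
    modality <- if (grepl("MeV$", en)) "electron-beam" else "photon-beam"
    beam <- beam_spec(modality, en, field_shape = "sheet",
                      field_mm = c(2.5, 10), ssd_mm = 200, divergence_deg = 0)
    set.seed(seed)
    src <- sample_source_positions(beam, count = events,
                                   depth_max_mm = tissue$depth_mm)
    src$weight <- relative_yield(beam)
    tl <- NULL
    if (transport)
      tl <- run_transport(src, tissue, config, seed = seed + 1e4)
    ev <- if (fwhm_on == "origins") src else {
      se <- tl$surface_events
      data.frame(x = se$x, z = 0, weight = se$weight)
    }
    fw <- fwhm_by_depth(ev, slab_mm = 1, bin_mm = 0.1,
                        z_range = if (fwhm_on == "origins") c(0, 30) else NULL)
    runs[[en]] <- list(beam = beam, origins = src, fwhm = fw, tally = tl,
                       relative_yield = relative_yield(beam))
  }
  structure(list(experiment = "sheet", runs = runs,
                 meta = list(seed = seed, events = events)),
            class = "run_report")
}

#' Inclusion depth-sensitivity experiment
#'
#' For each excitation source and each inclusion depth: builds the
#' multilayer model with the luminescent sphere's top at that depth,
#' generates the excitation field (Cherenkov origins sampled from the
#' beam's depth-dose curve, or a collimated optical surface beam),
#' transports it with luminescence conversion inside the inclusion, and
#' tallies luminescence generated / exited / reaching the surface. Surface
#' signals are expressed per beam primary, with radiation beams scaled by
#' [cherenkov_photons_per_primary()] so different modalities can be
#' compared at equal primary budgets.
#'
#' @param sources excitation labels among "430nm", "630nm", "6MV", "18MV".
#' @param depths_mm inclusion top depths (mm, within \[0, 10\]).
#' @param events transported packets per (source, depth) run.
#' @param primaries beam primaries each run represents (default `events`).
#' @param tissue_table property table path or layer list for
#'   [build_layered_model()]; default the shipped synthetic table.
#' @param fluorophore inclusion contrast agent.
#' @param seed integer seed.
#' @param config [transport_config()]; fluence scoring is disabled by
#'   default here for speed.
#' @param batches transport batches per run.
#' @return `run_report` with one element per (source, depth) carrying the
#'   tally and escape report, plus a `sensitivity` data.frame of relative
#'   surface luminescence per primary versus depth for each source.
#' @export
run_inclusion_experiment <- function(sources = c("6MV", "630nm"),
                                     depths_mm = c(1, 3, 5, 7, 9),
                                     events = 1e5, primaries = events,
                                     tissue_table = NULL,
                                     fluorophore = ptg4_like_fluorophore(),
                                     seed = 1,
                                     config = transport_config(nz_fluence = 0),
                                     batches = 1L) {
  if (any(depths_mm < 0 | depths_mm > 10))
    stop("inclusion depths must lie within [0, 10] mm")
  runs <- list(); sens <- NULL
  for (slab in sources) {
    beam <- .parse_source_label(slab)
    for (d in depths_mm) {
      tis <- build_layered_model(tissue_table, inclusion_depth_mm = d,
                                 fluorophore = fluorophore)
      set.seed(seed + round(1000 * d))
      src <- sample_source_positions(beam, count = events,
                                     depth_max_mm = tis$depth_mm)
      per_primary <- 1 / events
      if (beam$modality == "optical") {
        # specular entry loss at the air/tissue interface
        n1 <- op_lookup(tis$layers[[1]]$properties, src$wavelength[1])$n
        src$weight <- src$weight * (1 - fresnel_reflectance(1, n1, 1))
      } else {
        per_primary <- cherenkov_photons_per_primary(beam) / events
      }
      tl <- run_transport(src, tis, config, batches = batches,
                          seed = seed + round(1000 * d) + 7L)
      esc <- if (tl$lum$generated_weight > 0) escape_report(tl) else NULL
      key <- sprintf("%s@%gmm", slab, d)
      runs[[key]] <- list(source = slab, depth_mm = d, tally = tl,
                          escape = esc,
                          surface_per_primary = tl$lum$surface_weight * per_primary)
      sens <- rbind(sens, data.frame(source = slab, depth_mm = d,
                                     surface_per_primary =
                                       tl$lum$surface_weight * per_primary,
                                     generated = tl$lum$generated_weight,
                                     exited = tl$lum$exited_weight,
                                     surface = tl$lum$surface_weight,
                                     packets = tl$lum$generated_count))
    }
  }
  structure(list(experiment = "inclusion", runs = runs, sensitivity = sens,
                 meta = list(seed = seed, events = events,
                             primaries = primaries, sources = sources,
                             depths_mm = depths_mm)),
            class = "run_report")
}

#' Depth-sensitivity summary of an inclusion experiment
#'
#' Applies [depth_sensitivity()] to each source's surface-signal-versus-
#' depth curve from [run_inclusion_experiment()].
#'
#' @param report an inclusion `run_report`.
#' @param threshold relative-signal threshold (mandatory; see
#'   [depth_sensitivity()]).
#' @return data.frame with `source`, `depth_mm`, `saturated`.
#' @export
sensitivity_summary <- function(report, threshold) {
  stopifnot(inherits(report, "run_report"), report$experiment == "inclusion")
  s <- report$sensitivity
  out <- lapply(split(s, s$source), function(g) {
    g <- g[order(g$depth_mm), ]
    ds <- depth_sensitivity(g$depth_mm, g$surface_per_primary, threshold)
    data.frame(source = g$source[1], depth_mm = ds$depth_mm,
               saturated = ds$saturated)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Compound-ranking experiment
#'
#' Ranks a compound database against an in-tissue Cherenkov spectrum: either
#' the analytic stand-in at a stated depth, or a spectral tally from a prior
#' inclusion run (the in-tumor detector).
#'
#' @param index_path compound index file ([parse_compound_db()] dialect).
#' @param cherenkov one of: a [spectrum()], a `tally_set` (its in-tumor
#'   spectral tally is used), or a depth in mm (analytic stand-in on the
#'   default tissue preset).
#' @param outdir optional output directory for the ranking CSV + metadata.
#' @param ... passed to [rank_compounds()].
#' @return `run_report` with the `ranking_result`.
#' @export
run_ranking <- function(index_path, cherenkov = 5, outdir = NULL, ...) {
  db <- parse_compound_db(index_path)
  if (inherits(cherenkov, "spectrum")) {
    ich <- cherenkov; prov <- "user-supplied spectrum"
  } else if (inherits(cherenkov, "tally_set")) {
    ich <- spectrum(cherenkov$wl_centers, cherenkov$spec_in_tumor)
    prov <- "transport in-tumor spectral tally"
  } else {
    ich <- make_analytic_cherenkov_spectrum(as.numeric(cherenkov))
    prov <- sprintf("analytic 1/lambda^2 x exp(-mu_eff d), d = %g mm",
                    as.numeric(cherenkov))
  }
  rk <- rank_compounds(db, ich, ...)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_ranking(rk, file.path(outdir, "ranking.csv"), provenance = prov)
  }
  structure(list(experiment = "ranking", ranking = rk,
                 meta = list(provenance = prov, n_records = length(db))),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> experiment: %s\n", x$experiment))
  if (x$experiment == "sheet") {
    for (nm in names(x$runs)) {
      fw <- x$runs[[nm]]$fwhm
      cat(sprintf("  %s (relative yield %g): mean FWHM %.2f mm over %d slabs\n",
                  nm, x$runs[[nm]]$relative_yield,
                  mean(fw$fwhm, na.rm = TRUE), nrow(fw)))
    }
  } else if (x$experiment == "inclusion") {
    print(x$sensitivity, digits = 4)
  } else if (x$experiment == "ranking") {
    print(x$ranking)
  }
  invisible(x)
}

#' Write the tables of a run report to CSV
#'
#' @param report a `run_report`.
#' @param outdir output directory (created if needed).
#' @return vector of written paths, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, nm) {
    p <- file.path(outdir, nm); write.csv(df, p, row.names = FALSE); p
  }
  if (report$experiment == "sheet") {
    for (nm in names(report$runs))
      paths <- c(paths, wr(report$runs[[nm]]$fwhm,
                           sprintf("fwhm_%s.csv", nm)))
  } else if (report$experiment == "inclusion") {
    paths <- c(paths, wr(report$sensitivity, "sensitivity.csv"))
  } else if (report$experiment == "ranking") {
    paths <- c(paths, wr(as.data.frame(report$ranking), "ranking.csv"))
  }
  invisible(paths)
}
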