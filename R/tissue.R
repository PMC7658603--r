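#' A single tissue slab layer
#'
#' @param name layer name.
#' @param thickness_mm layer thickness in mm, > 0.
#' @param properties an [optical_properties()] object.
#' @param blood_network logical; `TRUE` for the highly absorbing blood-plexus
#'   sublayers of the dermis.
#' @return An object of class `tissue_layer`.
#' @export
tissue_layer <- function(name, thickness_mm, properties, blood_network = FALSE) {
  stopifnot(is.character(name), length(name) == 1L,
            inherits(properties, "optical_properties"))
  if (!is.finite(thickness_mm) || thickness_mm <= 0)
    stop("layer thickness must be > 0")
  structure(list(name = name, thickness_mm = as.numeric(thickness_mm),
                 properties = properties,
                 blood_network = isTRUE(blood_network)),
            class = "tissue_layer")
}

#' Spherical luminescent inclusion
#'
#' A tumour-simulating sphere embedded in the slab stack. Coordinates are
#' right-handed with z increasing downward from the tissue surface (z = 0);
#' the top of the sphere sits at depth `center[3] - diameter/2`.
#'
#' @param center numeric length-3 (mm); `center[3]` is depth below surface.
#' @param diameter_mm sphere diameter (mm), > 0; the default 10 mm matches a
#'   1 cm tumour inclusion.
#' @param properties an [optical_properties()] object for the inclusion bulk.
#' @param fluorophore optional [fluorophore()] providing the luminescent
#'   contrast (absorption bands, emission band, quantum yield).
#' @return An object of class `spherical_inclusion`.
#' @export
spherical_inclusion <- function(center, diameter_mm = 10, properties,
                                fluorophore = NULL) {
  center <- as.numeric(center)
  stopifnot(length(center) == 3L, inherits(properties, "optical_properties"))
  if (!is.finite(diameter_mm) || diameter_mm <= 0)
    stop("inclusion diameter must be > 0")
  if (center[3] - diameter_mm / 2 < 0)
    stop("inclusion extends above the tissue surface")
  if (!is.null(fluorophore)) stopifnot(inherits(fluorophore, "fluorophore"))
  structure(list(center = center, diameter_mm = diameter_mm,
                 properties = properties, fluorophore = fluorophore),
            class = "spherical_inclusion")
}

#' Layered tissue volume
#'
#' An ordered stack of slab layers (surface downward), a lateral extent, and
#' an optional spherical inclusion. Ambient medium above the surface is air
#' unless stated otherwise.
#'
#' @param layers list of [tissue_layer()] objects, surface first.
#' @param lateral_mm lateral extent (mm), either scalar (square) or length 2;
#'   default 100 x 100 mm.
#' @param inclusion optional [spherical_inclusion()].
#' @param n_ambient refractive index above the surface (default 1, air).
#' @return An object of class `layered_tissue`.
#' @export
layered_tissue <- function(layers, lateral_mm = c(100, 100), inclusion = NULL,
                           n_ambient = 1) {
  stopifnot(is.list(layers), length(layers) >= 1L,
            all(vapply(layers, inherits, logical(1), "tissue_layer")))
  lateral_mm <- rep(as.numeric(lateral_mm), length.out = 2L)
  if (any(lateral_mm <= 0)) stop("lateral extent must be > 0")
  thick <- vapply(layers, `[[`, numeric(1), "thickness_mm")
  depth <- sum(thick)
  if (!is.null(inclusion)) {
    stopifnot(inherits(inclusion, "spherical_inclusion"))
    r <- inclusion$diameter_mm / 2
    ctr <- inclusion$center
    if (ctr[3] + r > depth)
      stop("inclusion extends below the bottom of the tissue volume")
    if (any(abs(ctr[1:2]) + r > lateral_mm / 2))
      stop("inclusion extends outside the lateral extent")
  }
  structure(list(layers = layers, lateral_mm = lateral_mm,
                 depth_mm = depth, boundaries_mm = c(0, cumsum(thick)),
                 inclusion = inclusion, n_ambient = n_ambient),
            class = "layered_tissue")
}

#' @export
print.layered_tissue <- function(x, ...) {
  cat(sprintf("<layered_tissue> %d layers, %.3g x %.3g mm lateral, %.3g mm deep\n",
              length(x$layers), x$lateral_mm[1], x$lateral_mm[2], x$depth_mm))
  for (ly in x$layers)
    cat(sprintf("  %-18s %7.3f mm%s\n", ly$name, ly$thickness_mm,
                if (ly$blood_network) "  [blood network]" else ""))
  if (!is.null(x$inclusion))
    cat(sprintf("  inclusion: %g mm sphere, top depth %.3g mm%s\n",
                x$inclusion$diameter_mm,
                x$inclusion$center[3] - x$inclusion$diameter_mm / 2,
                if (is.null(x$inclusion$fluorophore)) "" else
                  paste0(" (", x$inclusion$fluorophore$name, ")")))
  invisible(x)
}

#' Read a layer property table
#'
#' Parses the delimited-text tissue dialect: columns `layer`, `thickness_mm`,
#' `wavelength_nm`, `mu_a_mm`, `mu_s_mm`, `g`, `n`, one row per
#' (layer, wavelength). Layer order follows first appearance (surface first).
#'
#' @param path path to a CSV file.
#' @return list of [tissue_layer()] objects.
#' @export
read_property_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("layer", "thickness_mm", "wavelength_nm", "mu_a_mm", "mu_s_mm", "g", "n")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("property table is missing columns: ", paste(miss, collapse = ", "))
  layer_names <- unique(tab$layer)
  lapply(layer_names, function(nm) {
    sub <- tab[tab$layer == nm, , drop = FALSE]
    sub <- sub[order(sub$wavelength_nm), , drop = FALSE]
    if (min(sub$wavelength_nm) > .wl_min || max(sub$wavelength_nm) < .wl_max)
      stop(sprintf("layer '%s' does not cover %d-%d nm", nm, .wl_min, .wl_max))
    th <- unique(sub$thickness_mm)
    if (length(th) != 1L)
      stop(sprintf("layer '%s' has inconsistent thickness entries", nm))
    blood <- grepl("blood", nm, ignore.case = TRUE)
    tissue_layer(nm, th,
                 optical_properties(sub$wavelength_nm, sub$mu_a_mm,
                                    sub$mu_s_mm, sub$g, sub$n),
                 blood_network = blood)
  })
}

#' Build the default multilayer tissue model
#'
#' Assembles the 10 cm x 10 cm x 5 cm tissue volume from a layer property
#' table (seven-layer skin stack over adipose and muscle by default) and
#' optionally embeds the 1 cm luminescent sphere with its top at the
#' requested depth below the surface, centred laterally. The inclusion's
#' scattering, anisotropy and refractive index are copied from the deepest
#' (muscle) layer; its absorption is the sum of a background spectrum (a
#' configurable fraction of muscle absorption) and the fluorophore
#' contribution `kappa * ma(lambda)`, so the fraction of absorbed light
#' taken by the fluorophore is exactly [excitation_fraction()].
#'
#' @param property_table path to a CSV in the [read_property_table()] dialect,
#'   or a list of [tissue_layer()]s. Default: the synthetic seven-layer table
#'   shipped with the package.
#' @param inclusion_depth_mm depth from the tissue surface to the top of the
#'   inclusion (mm, in \[0, 10\]), or `NULL` for no inclusion.
#' @param fluorophore [fluorophore()] assigned to the inclusion
#'   (default [ptg4_like_fluorophore()]).
#' @param inclusion_diameter_mm sphere diameter, default 10 mm.
#' @param background_fraction inclusion background absorption as a fraction
#'   of muscle absorption (default 0.5).
#' @param kappa fluorophore concentration scale (mm^-1 per unit normalized
#'   absorbance). Default `NULL`: chosen so the fluorophore captures 50% of
#'   inclusion absorption at 630 nm.
#' @return A [layered_tissue()] object.
#' @examples
#' tis <- build_layered_model(inclusion_depth_mm = 5)
#' tis
#' @export
build_layered_model <- function(property_table = NULL, inclusion_depth_mm = NULL,
                                fluorophore = ptg4_like_fluorophore(),
                                inclusion_diameter_mm = 10,
                                background_fraction = 0.5, kappa = NULL) {
  if (is.null(property_table))
    property_table <- system.file("extdata", "tissue_sevenlayer_synthetic.csv",
                                  package = "celsim", mustWork = TRUE)
  layers <- if (is.character(property_table)) read_property_table(property_table)
            else property_table
  inclusion <- NULL
  if (!is.null(inclusion_depth_mm)) {
    if (!is.finite(inclusion_depth_mm) || inclusion_depth_mm < 0)
      stop("inclusion depth must be >= 0 mm")
    depth_total <- sum(vapply(layers, `[[`, numeric(1), "thickness_mm"))
    if (inclusion_depth_mm + inclusion_diameter_mm > depth_total)
      stop("inclusion would extend below the tissue volume")
    base <- layers[[length(layers)]]$properties
    wl <- base$wavelength
    bg <- background_fraction * base$mu_a
    ma <- fl_absorption(fluorophore, wl)
    if (is.null(kappa)) {
      ma630 <- fl_absorption(fluorophore, 630)
      if (ma630 <= 0) stop("cannot auto-scale kappa: fluorophore does not absorb at 630 nm")
      bg630 <- approx(wl, bg, xout = 630, rule = 2)$y
      kappa <- bg630 / ma630
    }
    props <- optical_properties(wl, mu_a = bg + kappa * ma,
                                mu_s = base$mu_s, g = base$g, n = base$n)
    fluorophore$kappa <- kappa
    fluorophore$background_mu_a <- list(wavelength = wl, mu_a = bg)
    inclusion <- spherical_inclusion(
      center = c(0, 0, inclusion_depth_mm + inclusion_diameter_mm / 2),
      diameter_mm = inclusion_diameter_mm, properties = props,
      fluorophore = fluorophore)
  }
  layered_tissue(layers, lateral_mm = c(100, 100), inclusion = inclusion)
}

#' Look up the medium at a point
#'
#' Maps an in-volume position to exactly one medium: the inclusion when the
#' point is strictly inside the sphere, otherwise the containing layer.
#' Properties are linearly interpolated at the requested wavelength.
#'
#' @param tissue a [layered_tissue()].
#' @param position numeric length-3 (mm), z downward from the surface.
#' @param wavelength nm.
#' @return list with `medium` ("inclusion" or the layer name) and interpolated
#'   `mu_a`, `mu_s`, `g`, `n`.
#' @export
medium_at <- function(tissue, position, wavelength) {
  stopifnot(inherits(tissue, "layered_tissue"), length(position) == 3L)
  p <- as.numeric(position)
  half <- tissue$lateral_mm / 2
  if (p[3] < 0 || p[3] > tissue$depth_mm ||
      abs(p[1]) > half[1] || abs(p[2]) > half[2])
    stop("position is outside the tissue volume", call. = FALSE)
  inc <- tissue$inclusion
  if (!is.null(inc) &&
      sum((p - inc$center)^2) < (inc$diameter_mm / 2)^2) {
    props <- op_lookup(inc$properties, wavelength)
    return(c(list(medium = "inclusion"), as.list(props[1, -1])))
  }
  idx <- findInterval(p[3], tissue$boundaries_mm, rightmost.closed = TRUE)
  idx <- min(max(idx, 1L), length(tissue$layers))
  ly <- tissue$layers[[idx]]
  props <- op_lookup(ly$properties, wavelength)
  c(list(medium = ly$name), as.list(props[1, -1]))
}
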