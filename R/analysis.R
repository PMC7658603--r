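#' Full width at half maximum of a binned lateral profile
#'
#' Width between the two outermost half-maximum crossings, located by linear
#' interpolation between bin centers. Invariant under uniform rescaling of
#' the counts and translation of the profile. Profiles whose ends do not
#' fall below half maximum are flagged `boundary_truncated`.
#'
#' @param centers bin centers (mm, ascending, uniform).
#' @param counts non-negative counts/weights per bin.
#' @param smooth_window optional odd moving-average window applied before
#'   crossing detection (default 0 = off).
#' @return list with `fwhm` (mm), `left`, `right` crossing positions, and
#'   logical `boundary_truncated`.
#' @examples
#' x <- seq(-10, 10, by = 0.1)
#' fwhm(x, exp(-x^2 / (2 * 2^2)))$fwhm  # ~4.71 = 2 sqrt(2 ln 2) * 2
#' @export
fwhm <- function(centers, counts, smooth_window = 0) {
  stopifnot(length(centers) == length(counts), all(counts >= -1e-12))
  if (smooth_window > 1) {
    # zero-padded moving average: histograms are zero outside their range,
    # so padding (not truncation) is the correct boundary treatment
    k <- smooth_window %/% 2
    padded <- c(rep(0, k), counts, rep(0, k))
    sm <- as.numeric(stats::filter(padded, rep(1 / smooth_window, smooth_window),
                                   sides = 2))
    counts <- sm[(k + 1):(k + length(counts))]
  }
  mx <- max(counts)
  if (!is.finite(mx) || mx <= 0)
    stop("profile has no positive maximum; FWHM is undefined")
  if (length(centers) == 1L)
    return(list(fwhm = NA_real_, left = centers, right = centers,
                boundary_truncated = TRUE))
  half <- mx / 2
  above <- counts >= half
  idx <- which(above)
  bw <- centers[2] - centers[1]
  if (length(idx) == 1L)  # single bin above half maximum: degenerate width
    return(list(fwhm = bw, left = centers[idx] - bw / 2,
                right = centers[idx] + bw / 2, boundary_truncated = FALSE))
  i1 <- idx[1]; i2 <- idx[length(idx)]
  trunc_l <- i1 == 1L; trunc_r <- i2 == length(centers)
  left <- if (trunc_l) centers[1] else {
    f <- (half - counts[i1 - 1]) / (counts[i1] - counts[i1 - 1])
    centers[i1 - 1] + f * bw
  }
  right <- if (trunc_r) centers[length(centers)] else {
    f <- (half - counts[i2 + 1]) / (counts[i2] - counts[i2 + 1])
    centers[i2 + 1] - f * bw
  }
  list(fwhm = right - left, left = left, right = right,
       boundary_truncated = trunc_l || trunc_r)
}

#' FWHM of the lateral spread per 1 mm depth slab
#'
#' Bins events into depth slabs, histograms each slab's lateral (x)
#' positions, and reports the slab FWHM -- the beam-penumbra metric as a
#' function of depth. Slabs with no events are omitted.
#'
#' @param events data.frame with columns `x` and `z` (mm); weights in an
#'   optional `weight` column.
#' @param slab_mm depth slab thickness (default 1 mm).
#' @param bin_mm lateral histogram bin width (default 0.1 mm).
#' @param z_range depth range analysed (default full range of the events).
#' @param smooth_window passed to [fwhm()].
#' @return data.frame with `depth` (slab center, mm), `fwhm` (mm), `n`
#'   (events in slab), `boundary_truncated`.
#' @export
fwhm_by_depth <- function(events, slab_mm = 1, bin_mm = 0.1, z_range = NULL,
                          smooth_window = 0) {
  stopifnot(all(c("x", "z") %in% names(events)))
  w <- events$weight %||% rep(1, nrow(events))
  if (is.null(z_range)) z_range <- c(floor(min(events$z)), ceiling(max(events$z)))
  edges <- seq(z_range[1], z_range[2], by = slab_mm)
  if (length(edges) < 2L) stop("z_range spans no complete slab")
  xr <- range(events$x)
  pad <- bin_mm * (1 + max(0, smooth_window))
  xedges <- seq(floor(xr[1] / bin_mm) * bin_mm - pad,
                ceiling(xr[2] / bin_mm) * bin_mm + pad, by = bin_mm)
  xc <- head(xedges, -1) + bin_mm / 2
  out <- lapply(seq_len(length(edges) - 1L), function(i) {
    in_slab <- events$z >= edges[i] & events$z < edges[i + 1]
    if (!any(in_slab)) return(NULL)
    h <- .whist(events$x[in_slab], w[in_slab], xedges)
    fw <- fwhm(xc, h, smooth_window = smooth_window)
    data.frame(depth = (edges[i] + edges[i + 1]) / 2, fwhm = fw$fwhm,
               n = sum(in_slab), boundary_truncated = fw$boundary_truncated)
  })
  do.call(rbind, out)
}

#' @noRd
.whist <- function(x, w, edges) {
  bin <- findInterval(x, edges, rightmost.closed = TRUE)
  ok <- bin >= 1 & bin <= length(edges) - 1
  as.numeric(tapply(w[ok], factor(bin[ok], levels = seq_len(length(edges) - 1)),
                    sum, default = 0))
}

#' Depth profile from a fluence grid or event depths
#'
#' For a `tally_set`, returns the laterally integrated fluence versus depth
#' (from the pathlength voxel estimator); for a data.frame of events with a
#' `z` column, a weighted depth histogram.
#'
#' @param x a `tally_set` or an events data.frame.
#' @param provenance for tallies: "excitation" or "luminescence".
#' @param bin_mm bin width for event input (default 0.1 mm).
#' @param normalize divide by the maximum value?
#' @return data.frame of class `depth_profile` with `depth` (mm) and `value`.
#' @export
depth_profile <- function(x, provenance = "excitation", bin_mm = 0.1,
                          normalize = FALSE) {
  if (inherits(x, "tally_set")) {
    if (nrow(x$fluence) == 0) stop("tally has no fluence grid (nz_fluence = 0)")
    col <- match.arg(provenance, c("excitation", "luminescence"))
    v <- x$fluence[, if (col == "excitation") 1 else 2]
    out <- data.frame(depth = x$z_centers, value = v)
  } else {
    stopifnot("z" %in% names(x))
    w <- x$weight %||% rep(1, nrow(x))
    edges <- seq(0, ceiling(max(x$z) / bin_mm) * bin_mm + bin_mm, by = bin_mm)
    out <- data.frame(depth = head(edges, -1) + bin_mm / 2,
                      value = .whist(x$z, w, edges))
  }
  if (normalize && max(out$value) > 0) out$value <- out$value / max(out$value)
  class(out) <- c("depth_profile", "data.frame")
  out
}

#' 2D surface histogram of escaping photons
#'
#' Weight-summed histogram of surface detections on the tissue surface
#' plane. Total histogram weight equals the summed event weight.
#'
#' @param events data.frame with `x`, `y` (mm) and optional `weight`.
#' @param bin_mm bin width (default 1 mm).
#' @param extent_mm half-extent of the histogram (default covers the events).
#' @return list with `x`, `y` (bin centers) and matrix `counts`.
#' @export
surface_histogram <- function(events, bin_mm = 1, extent_mm = NULL) {
  w <- events$weight %||% rep(1, nrow(events))
  if (is.null(extent_mm))
    extent_mm <- if (nrow(events)) max(abs(c(events$x, events$y))) + bin_mm else bin_mm
  edges <- seq(-extent_mm, extent_mm, by = bin_mm)
  nb <- length(edges) - 1L
  ctr <- head(edges, -1) + bin_mm / 2
  counts <- matrix(0, nb, nb)
  if (nrow(events)) {
    bx <- findInterval(events$x, edges, rightmost.closed = TRUE)
    by <- findInterval(events$y, edges, rightmost.closed = TRUE)
    ok <- bx >= 1 & bx <= nb & by >= 1 & by <= nb
    for (i in which(ok)) counts[bx[i], by[i]] <- counts[bx[i], by[i]] + w[i]
  }
  list(x = ctr, y = ctr, counts = counts)
}

#' Write a 2D histogram as a plain-text grayscale PGM image
#'
#' @param hist2d output of [surface_histogram()].
#' @param path output file (.pgm, ASCII "P2" dialect).
#' @param gamma display gamma applied to the normalized counts.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(hist2d, path, gamma = 0.5) {
  m <- hist2d$counts
  mx <- max(m)
  g <- if (mx > 0) round(255 * (m / mx)^gamma) else m
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(nrow(g), ncol(g)), "255"), con)
  write(t(g)[, seq_len(nrow(g))], file = con, ncolumns = nrow(g))
  invisible(path)
}

#' Depth sensitivity of a surface-signal-versus-depth curve
#'
#' First depth (linear interpolation) at which the relative surface signal
#' falls below `threshold` times its shallowest-depth value. The threshold
#' is an explicit, mandatory parameter: the source study never defines its
#' criterion numerically, so only the parameterized crossing -- and above
#' all the ordering across excitation sources -- is meaningful.
#'
#' @param depth sampled inclusion depths (mm, ascending, >= 3 points).
#' @param signal surface signal at each depth; must be positive at the
#'   shallowest depth.
#' @param threshold fraction of the shallow-depth signal (in (0, 1)).
#' @return list with `depth_mm` and logical `saturated` (curve never
#'   crossed; deepest sampled depth returned).
#' @examples
#' d <- 0:10
#' depth_sensitivity(d, exp(-d / 3), exp(-1))$depth_mm  # 3
#' @export
depth_sensitivity <- function(depth, signal, threshold) {
  stopifnot(length(depth) >= 3, length(signal) == length(depth),
            threshold > 0, threshold < 1, all(diff(depth) > 0))
  if (signal[1] <= 0) stop("signal must be positive at the shallowest depth")
  rel <- signal / signal[1]
  below <- which(rel < threshold)
  if (!length(below))
    return(list(depth_mm = depth[length(depth)], saturated = TRUE))
  i <- below[1]
  if (i == 1L) return(list(depth_mm = depth[1], saturated = FALSE))
  f <- (rel[i - 1] - threshold) / (rel[i - 1] - rel[i])
  list(depth_mm = depth[i - 1] + f * (depth[i] - depth[i - 1]),
       saturated = FALSE)
}
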