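#' Parse a compound spectra database index
#'
#' Reads the pipe-delimited index dialect: one record per line,
#' `name | class | quantum_yield | absorption_file | emission_file`
#' (empty field = absent; spectrum paths are resolved relative to the index
#' file). Records lacking a resolvable absorption spectrum or a quantum
#' yield are retained but flagged ineligible. Malformed lines produce
#' per-line warnings, never a fatal error.
#'
#' @param index_path path to the index file (UTF-8 text).
#' @return list of `compound_record` objects, each with `name`, `class`,
#'   `quantum_yield` (NA allowed), `absorption` / `emission` spectra
#'   (`NULL` when absent) and `eligible_data` (spectrum + QY present).
#' @export
parse_compound_db <- function(index_path) {
  lines <- readLines(index_path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  base <- dirname(index_path)
  out <- list()
  for (i in seq_along(lines)) {
    parts <- trimws(strsplit(lines[i], "|", fixed = TRUE)[[1]])
    if (length(parts) < 4L) {
      warning(sprintf("index line %d is malformed; skipped: %s", i,
                      substr(lines[i], 1, 60)))
      next
    }
    length(parts) <- 5L
    qy <- suppressWarnings(as.numeric(parts[3]))
    read_sp <- function(ref) {
      if (is.na(ref) || !nzchar(ref)) return(NULL)
      p <- file.path(base, ref)
      if (!file.exists(p)) return(NULL)
      tryCatch(read_spectrum(p), error = function(e) NULL)
    }
    ab <- read_sp(parts[4]); em <- read_sp(parts[5])
    rec <- structure(list(name = parts[1], class = parts[2],
                          quantum_yield = qy, absorption = ab, emission = em,
                          eligible_data = !is.null(ab) && is.finite(qy)),
                     class = "compound_record")
    out[[length(out) + 1L]] <- rec
  }
  out
}

#' Read a two-column spectrum file
#'
#' Whitespace- or comma-delimited `wavelength_nm value` pairs; lines
#' starting with `#` are comments. Wavelengths must be strictly ascending
#' and values non-negative.
#'
#' @param path file path.
#' @return list of class `spectrum` with `wavelength` and `value`.
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(gsub(",", " ", lines), "\\s+")
  mat <- vapply(parts, function(p) as.numeric(p[1:2]), numeric(2))
  spectrum(mat[1, ], mat[2, ])
}

#' Construct a spectrum
#' @param wavelength nm, strictly ascending.
#' @param value non-negative values (arbitrary units).
#' @return list of class `spectrum`.
#' @export
spectrum <- function(wavelength, value) {
  wavelength <- as.numeric(wavelength); value <- as.numeric(value)
  if (any(!is.finite(wavelength)) || any(!is.finite(value)))
    stop("spectrum contains non-numeric entries")
  if (length(wavelength) != length(value) || any(diff(wavelength) <= 0))
    stop("spectrum wavelengths must be strictly ascending")
  if (any(value < 0)) stop("spectrum values must be >= 0")
  structure(list(wavelength = wavelength, value = value), class = "spectrum")
}

#' Compound eligibility for ranking
#'
#' A compound enters the ranking iff its absorption spectrum has support
#' intersecting the analysis band (350-850 nm by default) and a quantum
#' yield is reported.
#'
#' @param record a `compound_record`.
#' @param bounds analysis band (nm), default c(350, 850).
#' @return logical.
#' @export
compound_eligible <- function(record, bounds = c(350, 850)) {
  if (!record$eligible_data) return(FALSE)
  ab <- record$absorption
  pos <- ab$wavelength[ab$value > 0]
  length(pos) > 0 && max(pos) >= bounds[1] && min(pos) <= bounds[2]
}

#' Resample a spectrum onto a target wavelength grid
#'
#' Linear interpolation; zero outside the source support. A single-point
#' spectrum is assigned to its nearest target bin.
#'
#' @param sp a [spectrum()].
#' @param target_grid nm, ascending.
#' @return A [spectrum()] on `target_grid`.
#' @export
resample_to <- function(sp, target_grid) {
  stopifnot(inherits(sp, "spectrum"), length(sp$wavelength) >= 1L)
  if (length(sp$wavelength) == 1L) {
    v <- rep(0, length(target_grid))
    v[which.min(abs(target_grid - sp$wavelength))] <- sp$value
    return(spectrum(target_grid, v))
  }
  v <- approx(sp$wavelength, sp$value, xout = target_grid, rule = 1)$y
  v[is.na(v)] <- 0
  spectrum(target_grid, v)
}

#' Spectral-overlap score of one compound
#'
#' \eqn{S_j = \phi_{QY} \sum_i I_{Ch,tissue}(\lambda_i) m_{a,j}(\lambda_i)}
#' over grid points inside the analysis band: the expected luminescent
#' signal under the in-tissue Cherenkov spectrum, up to a common constant.
#'
#' @param cherenkov_spectrum a [spectrum()].
#' @param absorption a [spectrum()] on the same wavelength grid.
#' @param qy quantum yield in \[0, 1\].
#' @param bounds analysis band (nm), default c(350, 850).
#' @return scalar score.
#' @export
score_compound <- function(cherenkov_spectrum, absorption, qy,
                           bounds = c(350, 850)) {
  stopifnot(inherits(cherenkov_spectrum, "spectrum"),
            inherits(absorption, "spectrum"))
  if (length(cherenkov_spectrum$wavelength) != length(absorption$wavelength) ||
      any(abs(cherenkov_spectrum$wavelength - absorption$wavelength) > 1e-9))
    stop("spectra must share one wavelength grid; resample first")
  in_band <- cherenkov_spectrum$wavelength >= bounds[1] &
    cherenkov_spectrum$wavelength <= bounds[2]
  qy * sum(cherenkov_spectrum$value[in_band] * absorption$value[in_band])
}

#' Rank compounds by Cherenkov-excitation overlap
#'
#' Scores every eligible compound against the supplied in-tissue Cherenkov
#' spectrum (each absorption spectrum resampled to the Cherenkov grid and,
#' by default, peak-normalized so heterogeneous units cannot drive the
#' ranking), sorts descending, and normalizes to the top score. Ties break
#' by name.
#'
#' @param db list of `compound_record`s from [parse_compound_db()].
#' @param cherenkov_spectrum a [spectrum()]: either a transport spectral
#'   tally or the analytic stand-in from
#'   [make_analytic_cherenkov_spectrum()].
#' @param bounds analysis band (nm), default c(350, 850).
#' @param peak_normalize peak-normalize each absorption spectrum before
#'   scoring (default TRUE); set FALSE to use raw reported units.
#' @param detector_response optional [spectrum()] multiplied into the
#'   Cherenkov spectrum (camera quantum-efficiency hook).
#' @return data.frame of class `ranking_result`: `name`, `class`, `score`,
#'   `normalized`, `rank`, with attribute `meta` recording bounds and modes.
#' @export
rank_compounds <- function(db, cherenkov_spectrum, bounds = c(350, 850),
                           peak_normalize = TRUE, detector_response = NULL) {
  elig <- Filter(function(r) compound_eligible(r, bounds), db)
  if (!length(elig))
    stop("no eligible compounds (absorption support in band + quantum yield)")
  ich <- cherenkov_spectrum
  if (!is.null(detector_response)) {
    dr <- resample_to(detector_response, ich$wavelength)
    ich <- spectrum(ich$wavelength, ich$value * dr$value)
  }
  rows <- lapply(elig, function(r) {
    ab <- resample_to(r$absorption, ich$wavelength)
    if (peak_normalize && max(ab$value) > 0)
      ab <- spectrum(ab$wavelength, ab$value / max(ab$value))
    data.frame(name = r$name, class = r$class,
               score = score_compound(ich, ab, r$quantum_yield, bounds))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$name), , drop = FALSE]
  mx <- out$score[1]
  out$normalized <- if (mx > 0) out$score / mx else out$score
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "meta") <- list(bounds = bounds, peak_normalize = peak_normalize,
                            detector_response = !is.null(detector_response))
  class(out) <- c("ranking_result", "data.frame")
  out
}

#' @export
print.ranking_result <- function(x, n = 10, ...) {
  cat(sprintf("<ranking_result> %d eligible compounds (band %g-%g nm)\n",
              nrow(x), attr(x, "meta")$bounds[1], attr(x, "meta")$bounds[2]))
  print.data.frame(head(x, n), digits = 4)
  if (nrow(x) > n) cat(sprintf("  ... %d more\n", nrow(x) - n))
  invisible(x)
}

#' Write ranking results to CSV + JSON metadata
#'
#' @param ranking a `ranking_result`.
#' @param path CSV output path; a `.meta.json` sidecar records the analysis
#'   band, normalization mode and spectrum provenance.
#' @param provenance free-text description of the Cherenkov spectrum used.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path, provenance = "unspecified") {
  write.csv(as.data.frame(ranking), path, row.names = FALSE)
  meta <- c(attr(ranking, "meta"), list(provenance = provenance))
  json <- sprintf(
    '{"bounds": [%g, %g], "peak_normalize": %s, "detector_response": %s, "provenance": "%s"}',
    meta$bounds[1], meta$bounds[2],
    tolower(meta$peak_normalize), tolower(meta$detector_response),
    provenance)
  writeLines(json, sub("\\.csv$", ".meta.json", path))
  invisible(path)
}
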