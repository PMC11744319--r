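# Spectral data model and algebra: wavelength grids, sampled spectra,
# resampling, filter stacking and two-column CSV I/O.

SPECTRUM_KINDS <- c("irradiance", "reflectance", "transmittance", "sensitivity")

#' Wavelength grid
#'
#' A regularly spaced wavelength grid in nanometres. The package default,
#' 300-750 nm at 1 nm, spans the full stomatopod spectral sensitivity range
#' from deep UV to far red; all spectra are resampled onto one session grid
#' before any quantum-catch integration.
#'
#' @param start,stop Grid limits in nm, `start < stop`.
#' @param step Grid increment in nm, positive. `stop` must lie on the grid.
#' @return Numeric vector of wavelengths with class `"wl_grid"`.
#' @examples
#' g <- wl_grid()
#' range(g)
#' @export
wl_grid <- function(start = 300, stop = 750, step = 1) {
  if (!is.numeric(start) || !is.numeric(stop) || !is.numeric(step)) {
    stop("grid parameters must be numeric")
  }
  if (start >= stop) stop("grid start must be < stop")
  if (step <= 0) stop("grid step must be > 0")
  wl <- seq(start, stop, by = step)
  if (abs(wl[length(wl)] - stop) > 1e-9) {
    stop("stop is not reachable from start in whole steps")
  }
  structure(wl, class = "wl_grid")
}

#' Default session grid
#'
#' @return The 300-750 nm, 1-nm [wl_grid()].
#' @export
default_grid <- function() wl_grid(300, 750, 1)

same_grid <- function(a, b) {
  length(a) == length(b) && max(abs(as.numeric(a) - as.numeric(b))) < 1e-9
}

#' Sampled spectrum
#'
#' A spectrum is a non-negative sampled function of wavelength tagged with its
#' physical kind. Reflectance and transmittance values are expected in [0, 1];
#' out-of-range values (measurement noise) are clipped with a warning.
#' Irradiance values are treated throughout as photon-number distributions
#' (quantal units): the quantum-catch integral requires photon counts, and any
#' energy-to-quanta conversion is left to the caller.
#'
#' @param wl Wavelengths (nm), strictly increasing; usually a [wl_grid()].
#' @param value Numeric values, one per wavelength.
#' @param kind One of `"irradiance"`, `"reflectance"`, `"transmittance"`,
#'   `"sensitivity"`.
#' @param units Free-text unit label.
#' @return Object of class `"spectrum"`: a list with elements `wl`, `value`,
#'   `kind`, `units`.
#' @examples
#' s <- spectrum(wl_grid(400, 500, 1), rep(1, 101), "reflectance")
#' @export
spectrum <- function(wl, value, kind, units = "") {
  kind <- match.arg(kind, SPECTRUM_KINDS)
  wl <- as.numeric(wl)
  value <- as.numeric(value)
  if (length(wl) != length(value)) {
    stop("wavelength and value vectors differ in length")
  }
  if (any(diff(wl) <= 0)) stop("wavelengths must be strictly increasing")
  if (anyNA(value)) stop("spectrum values contain NA")
  if (any(value < 0)) {
    if (kind %in% c("reflectance", "transmittance")) {
      warning("negative ", kind, " values clipped to 0")
      value <- pmax(value, 0)
    } else {
      stop(kind, " values must be non-negative")
    }
  }
  if (kind %in% c("reflectance", "transmittance") && any(value > 1)) {
    warning(kind, " values > 1 clipped to 1")
    value <- pmin(value, 1)
  }
  structure(list(wl = wl, value = value, kind = kind, units = units),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s, %d points, %g-%g nm, values %.4g-%.4g>\n",
              x$kind, length(x$wl), min(x$wl), max(x$wl),
              min(x$value), max(x$value)))
  invisible(x)
}

is_spectrum <- function(x) inherits(x, "spectrum")

#' Resample a spectrum onto a wavelength grid
#'
#' Linear interpolation inside the source range, zero fill outside it.
#' Measured spectra carry no information beyond their measured range, so the
#' conservative extrapolation is zero.
#'
#' @param s A [spectrum()].
#' @param grid Target [wl_grid()] (or numeric wavelength vector).
#' @return A spectrum on `grid`, same kind.
#' @export
resample <- function(s, grid) {
  stopifnot(is_spectrum(s))
  if (length(s$wl) < 2) stop("cannot interpolate a single-point spectrum")
  wl <- as.numeric(grid)
  v <- stats::approx(s$wl, s$value, xout = wl, method = "linear",
                     yleft = 0, yright = 0)$y
  spectrum(wl, v, s$kind, s$units)
}

#' Read a two-column spectral table
#'
#' Reads a comma-delimited file with columns (wavelength nm, value), an
#' optional single header line, and resamples onto the session grid. The
#' source wavelength range is recorded in the `"source_range"` attribute.
#'
#' @param path File path.
#' @param kind Spectrum kind (see [spectrum()]).
#' @param grid Session grid; default [default_grid()].
#' @return A [spectrum()] on `grid`.
#' @export
read_spectrum <- function(path, kind, grid = default_grid()) {
  kind <- match.arg(kind, SPECTRUM_KINDS)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty spectrum file: ", path)
  parse_row <- function(ln) suppressWarnings(as.numeric(strsplit(ln, ",")[[1]]))
  first <- parse_row(lines[1])
  data_lines <- lines
  offset <- 0L
  if (anyNA(first)) {          # tolerate one header line
    data_lines <- lines[-1]
    offset <- 1L
    if (length(data_lines) == 0) stop("no data rows in ", path)
  }
  rows <- lapply(data_lines, parse_row)
  bad <- which(vapply(rows, function(r) length(r) < 2 || anyNA(r[1:2]), TRUE))
  if (length(bad)) {
    stop("non-numeric spectral row at line ", bad[1] + offset, " of ", path)
  }
  wl <- vapply(rows, `[`, 0, 1)
  val <- vapply(rows, `[`, 0, 2)
  if (any(wl < 200 | wl > 900)) {
    stop("wavelengths outside 200-900 nm in ", path)
  }
  if (any(diff(wl) <= 0)) stop("wavelengths not strictly increasing in ", path)
  s <- resample(spectrum(wl, val, kind), grid)
  attr(s, "source_range") <- range(wl)
  s
}

#' Write a spectrum as a two-column CSV
#'
#' Writes `wavelength_nm,value` with a header, six significant digits, so
#' that a write/read round trip recovers values within 1e-5 relative error.
#'
#' @param s A [spectrum()].
#' @param path Output path.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(is_spectrum(s))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("wavelength_nm,value", con)
  writeLines(sprintf("%g,%.6g", s$wl, s$value), con)
  invisible(path)
}

#' Filter specification
#'
#' A physical filter: a per-layer transmittance spectrum and a layer count.
#' Stacked identical layers attenuate multiplicatively (Beer-Lambert), so the
#' effective transmittance is the per-layer curve raised to the layer count —
#' this is how the double-layered tent filters of the dim-illumination
#' experiment are represented.
#'
#' @param name Filter name.
#' @param transmittance A transmittance [spectrum()].
#' @param layers Positive integer layer count.
#' @return Object of class `"filter_spec"`.
#' @export
filter_spec <- function(name, transmittance, layers = 1L) {
  stopifnot(is_spectrum(transmittance))
  if (transmittance$kind != "transmittance") {
    stop("filter_spec needs a transmittance spectrum")
  }
  layers <- as.integer(layers)
  if (is.na(layers) || layers < 1L) stop("layers must be a positive integer")
  structure(list(name = name, transmittance = transmittance, layers = layers),
            class = "filter_spec")
}

#' Combine stacked filters into one transmittance spectrum
#'
#' Pointwise product of each filter's per-layer transmittance raised to its
#' layer count. An empty list yields the identity (unit) filter.
#'
#' @param filters List of [filter_spec()] objects on a common grid.
#' @param grid Grid used for the identity filter when `filters` is empty;
#'   defaults to the grid of the first filter.
#' @return A transmittance [spectrum()].
#' @export
combine_filters <- function(filters, grid = default_grid()) {
  if (length(filters) == 0) {
    wl <- as.numeric(grid)
    return(spectrum(wl, rep(1, length(wl)), "transmittance"))
  }
  stopifnot(all(vapply(filters, inherits, TRUE, "filter_spec")))
  wl <- filters[[1]]$transmittance$wl
  for (f in filters) {
    if (!same_grid(f$transmittance$wl, wl)) {
      stop("filters are on different grids; resample() them first")
    }
  }
  v <- rep(1, length(wl))
  for (f in filters) v <- v * f$transmittance$value^f$layers
  spectrum(wl, v, "transmittance")
}

#' Apply a filter to an illuminant
#'
#' @param illuminant An irradiance [spectrum()].
#' @param filt A transmittance [spectrum()] or [filter_spec()] on the same grid.
#' @return The filtered irradiance spectrum.
#' @export
apply_illuminant_filter <- function(illuminant, filt) {
  stopifnot(is_spectrum(illuminant))
  if (inherits(filt, "filter_spec")) filt <- effective_transmittance(filt)
  stopifnot(is_spectrum(filt))
  if (illuminant$kind != "irradiance") stop("illuminant must have kind 'irradiance'")
  if (filt$kind != "transmittance") stop("filter must have kind 'transmittance'")
  if (!same_grid(illuminant$wl, filt$wl)) {
    stop("grids differ; resample() the filter onto the illuminant grid first")
  }
  spectrum(illuminant$wl, illuminant$value * filt$value, "irradiance",
           illuminant$units)
}

#' Effective transmittance of a (possibly multi-layer) filter
#'
#' @param filt A [filter_spec()].
#' @return Transmittance [spectrum()] equal to the per-layer curve raised to
#'   the layer count.
#' @export
effective_transmittance <- function(filt) {
  stopifnot(inherits(filt, "filter_spec"))
  t <- filt$transmittance
  spectrum(t$wl, t$value^filt$layers, "transmittance", t$units)
}
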