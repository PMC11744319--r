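# Synthetic spectral fixtures emulating the grey-card experiment's stimuli
# and illuminations: a shallow-water daylight irradiance, band-pass colour
# filters with the stated passbands, neutral-density attenuators (with an
# optional long-wavelength leak), and the stimulus reflectances built from
# them. All deterministic; no measured spectra are shipped.

#' Synthetic shallow-water daylight irradiance
#'
#' A smooth, strictly positive, broad photon irradiance with a blue-green
#' peak, modelled as a log-normal hump in wavelength: shallow reef water
#' transmits best around 450-550 nm and attenuates both UV and red. Unit
#' peak; deterministic.
#'
#' @param grid Wavelength grid.
#' @param peak Peak wavelength (nm), default 490.
#' @param width Log-scale width, default 0.28 (broader = flatter spectrum).
#' @return An irradiance [spectrum()], photons, relative units.
#' @export
make_illuminant_daylight <- function(grid = default_grid(), peak = 490,
                                     width = 0.28) {
  wl <- as.numeric(grid)
  v <- exp(-0.5 * (log(wl / peak) / width)^2)
  spectrum(wl, v / max(v), "irradiance", "photons, relative")
}

#' Band-pass filter with soft logistic edges
#'
#' Transmittance is the product of two logistic edges. The `softness`
#' parameter is the edge width in nm: transmittance is at least 0.9 one
#' softness-width inside the passband (about 0.88 at exactly one width, 0.95
#' at 1.5 widths) and at most 0.01 three widths outside it. Use
#' `high = Inf` for a long-pass filter.
#'
#' @param low,high Passband edges (nm), `low < high`; `high` may be `Inf`.
#' @param softness Edge width (nm), positive; default 10.
#' @param grid Wavelength grid.
#' @param name Filter name.
#' @param layers Layer count, default 1.
#' @return A [filter_spec()].
#' @export
make_bandpass_filter <- function(low, high, softness = 10,
                                 grid = default_grid(),
                                 name = sprintf("band_%g_%g", low, high),
                                 layers = 1L) {
  if (softness <= 0) stop("edge softness must be positive")
  if (low >= high) stop("low edge must be below high edge")
  wl <- as.numeric(grid)
  # logistic scale softness/2: at 3 softness outside, plogis(-6) < 0.01
  t <- stats::plogis((wl - low) / (softness / 2))
  if (is.finite(high)) t <- t * stats::plogis((high - wl) / (softness / 2))
  filter_spec(name, spectrum(wl, t, "transmittance"), layers)
}

#' Neutral-density filter
#'
#' Spectrally flat attenuation of transmittance `10^(-OD)`. With
#' `red_leak = TRUE` the transmittance rises smoothly above 680 nm toward a
#' leak ceiling, emulating the real ND gels' failure to attenuate far-red
#' light — the reason the red group's dim-light (ND tent) test had to be
#' abandoned in the original experiment.
#'
#' @param od Optical density, non-negative.
#' @param red_leak Add the long-wavelength leak? Default `FALSE`.
#' @param grid Wavelength grid.
#' @param leak_ceiling Transmittance the leak approaches, default 0.7.
#' @param leak_edge,leak_softness Leak onset (nm) and width, defaults 680 / 10.
#' @param layers Layer count, default 1.
#' @return A [filter_spec()].
#' @export
make_nd_filter <- function(od, red_leak = FALSE, grid = default_grid(),
                           leak_ceiling = 0.7, leak_edge = 680,
                           leak_softness = 10, layers = 1L) {
  if (od < 0) stop("optical density must be >= 0")
  wl <- as.numeric(grid)
  t <- rep(10^(-od), length(wl))
  if (red_leak) {
    rise <- stats::plogis((wl - leak_edge) / leak_softness)
    t <- t + (pmax(leak_ceiling, t) - t) * rise
  }
  filter_spec(sprintf("nd_%g%s", od, if (red_leak) "_leak" else ""),
              spectrum(wl, t, "transmittance"), layers)
}

# Stated passbands: stimulus (cable-tie) filters and illumination tents.
STIMULUS_PASSBANDS <- list(blue = c(360, 550), green = c(500, 560),
                           red = c(610, Inf))
TENT_PASSBANDS <- list(blue = c(360, 590), green = c(450, 600),
                       red = c(590, Inf))
GREY_ODS <- c(0.15, 0.3, 0.6, 0.9)

#' Coloured tent filter
#'
#' The illumination-changing filter draped over the behavioural chamber:
#' blue passes about 360-590 nm, green 450-600 nm, red everything above
#' 590 nm. `layers = 2` gives the dim double-layered tents of the second
#' experiment.
#'
#' @param colour `"blue"`, `"green"` or `"red"`.
#' @param layers Layer count.
#' @param grid Wavelength grid.
#' @return A [filter_spec()].
#' @export
make_tent_filter <- function(colour = c("blue", "green", "red"), layers = 1L,
                             grid = default_grid()) {
  colour <- match.arg(colour)
  pb <- TENT_PASSBANDS[[colour]]
  make_bandpass_filter(pb[1], pb[2], grid = grid,
                       name = paste0("tent_", colour), layers = layers)
}

#' Stimulus reflectance
#'
#' Colour targets are a flat white base (reflectance 0.9) seen through the
#' corresponding stimulus band-pass filter (blue 360-550 nm, green
#' 500-560 nm, red above 610 nm); grey distractors are the white base
#' attenuated by a flat ND filter.
#'
#' @param kind `"blue"`, `"green"`, `"red"`, or a grey: either a numeric OD
#'   or a string like `"grey_0.15"`.
#' @param grid Wavelength grid.
#' @param base White-base reflectance, default 0.9.
#' @param red_leak Apply the ND long-wavelength leak to greys? Default `FALSE`.
#' @return A reflectance [spectrum()].
#' @export
make_reflectance <- function(kind, grid = default_grid(), base = 0.9,
                             red_leak = FALSE) {
  wl <- as.numeric(grid)
  white <- rep(base, length(wl))
  if (is.numeric(kind)) kind <- paste0("grey_", kind)
  if (kind %in% names(STIMULUS_PASSBANDS)) {
    pb <- STIMULUS_PASSBANDS[[kind]]
    f <- make_bandpass_filter(pb[1], pb[2], grid = grid)
    return(spectrum(wl, white * effective_transmittance(f)$value, "reflectance"))
  }
  if (grepl("^grey_", kind)) {
    od <- suppressWarnings(as.numeric(sub("^grey_", "", kind)))
    if (is.na(od)) stop("unparseable grey kind: ", kind)
    f <- make_nd_filter(od, red_leak = red_leak, grid = grid)
    return(spectrum(wl, white * effective_transmittance(f)$value, "reflectance"))
  }
  stop("unknown reflectance kind: ", kind)
}

#' Write the packaged spectral fixture library
#'
#' Writes the synthetic daylight, tent and stimulus filters, and stimulus
#' reflectances as two-column CSVs under
#' `dir/{illuminants,filters,reflectances}/`.
#'
#' @param dir Output directory (created if needed).
#' @param grid Wavelength grid.
#' @return Invisibly, the paths written.
#' @export
write_fixture_library <- function(dir, grid = default_grid()) {
  paths <- character(0)
  put <- function(sub, name, s) {
    d <- file.path(dir, sub)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    p <- file.path(d, paste0(name, ".csv"))
    write_spectrum(s, p)
    paths <<- c(paths, p)
  }
  put("illuminants", "daylight", make_illuminant_daylight(grid))
  for (col in c("blue", "green", "red")) {
    put("filters", paste0("tent_", col),
        effective_transmittance(make_tent_filter(col, grid = grid)))
    put("reflectances", col, make_reflectance(col, grid))
  }
  for (od in GREY_ODS) {
    put("filters", sprintf("nd_%g", od),
        effective_transmittance(make_nd_filter(od, grid = grid)))
    put("reflectances", sprintf("grey_%g", od),
        make_reflectance(od, grid))
  }
  invisible(paths)
}
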