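# Quantum catches and the two competing readouts of the 12-channel retina:
# per-row log-opponent activity profiles / contrast differences (the
# multi-dichromatic model) and whole-array activation patterns (the binning
# or "barcode" model).

#' Quantum catch of one receptor
#'
#' The photon signal a receptor absorbs from a stimulus under an illuminant:
#' the integral over wavelength of sensitivity x reflectance x photon
#' irradiance, evaluated by the trapezoid rule on the common grid. Linear in
#' the illuminant and non-negative.
#'
#' @param sensitivity,reflectance,illuminant [spectrum()] objects on one grid.
#' @return Non-negative scalar catch (arbitrary common units).
#' @export
quantum_catch <- function(sensitivity, reflectance, illuminant) {
  stopifnot(is_spectrum(sensitivity), is_spectrum(reflectance),
            is_spectrum(illuminant))
  wl <- sensitivity$wl
  if (!same_grid(wl, reflectance$wl) || !same_grid(wl, illuminant$wl)) {
    stop("spectra are on different grids; resample() first")
  }
  y <- sensitivity$value * reflectance$value * illuminant$value
  n <- length(wl)
  sum(diff(wl) * (y[-1] + y[-n]) / 2)
}

#' Catch table for all 12 channels
#'
#' @param retina A [build_retina()] model.
#' @param reflectance Stimulus reflectance [spectrum()] on the retina grid.
#' @param illuminant Irradiance [spectrum()] on the retina grid.
#' @param stimulus,illuminant_id Identifiers carried in the result.
#' @return A `catch_table`: tibble with columns `channel`, `row`, `tier`,
#'   `value`, plus attributes `stimulus`, `illuminant` and `normalization`
#'   (`"raw"` here).
#' @export
catch_table <- function(retina, reflectance, illuminant,
                        stimulus = "stimulus", illuminant_id = "illuminant") {
  stopifnot(inherits(retina, "retina_model"))
  vals <- vapply(retina$channels, function(ch) {
    quantum_catch(ch$sensitivity, reflectance, illuminant)
  }, 0)
  tb <- tibble::tibble(
    channel = unname(vapply(retina$channels, `[[`, "", "label")),
    row = unname(vapply(retina$channels, `[[`, 0L, "row")),
    tier = unname(vapply(retina$channels, `[[`, "", "tier")),
    value = unname(vals)
  )
  attr(tb, "stimulus") <- stimulus
  attr(tb, "illuminant") <- illuminant_id
  attr(tb, "normalization") <- "raw"
  class(tb) <- c("catch_table", class(tb))
  tb
}

is_normalized <- function(catches) !identical(attr(catches, "normalization"), "raw")

#' Normalise catch tables to a reference entry
#'
#' Divides every catch in every table by one reference catch, following the
#' figure convention of reporting all photon catches relative to the highest
#' value observed — typically channel R2P viewing the ND 0.15 grey under
#' natural light. The reference entry of the reference table becomes exactly 1.
#'
#' @param tables A single `catch_table` or a list of them.
#' @param reference List or character vector `(channel, stimulus, illuminant)`
#'   naming the reference entry, which must exist with a positive catch.
#' @return Table(s) of the same shape, normalised, with the reference recorded
#'   in the `"normalization"` attribute.
#' @export
normalize_catches <- function(tables, reference) {
  single <- inherits(tables, "catch_table")
  if (single) tables <- list(tables)
  reference <- as.list(reference)
  names(reference) <- c("channel", "stimulus", "illuminant")
  ref_val <- NA_real_
  for (tb in tables) {
    if (identical(attr(tb, "stimulus"), reference$stimulus) &&
        identical(attr(tb, "illuminant"), reference$illuminant)) {
      hit <- tb$value[tb$channel == reference$channel]
      if (length(hit) == 1) ref_val <- hit
    }
  }
  if (is.na(ref_val)) stop("reference entry not found among the tables")
  if (ref_val <= 0) stop("reference catch must be > 0")
  out <- lapply(tables, function(tb) {
    tb$value <- tb$value / ref_val
    attr(tb, "normalization") <- reference
    tb
  })
  if (single) out[[1]] else out
}

#' Per-row activity profile
#'
#' The opponent readout of one stimulus: for each midband row, the
#' interneuron output is modelled as the difference of the natural logs of
#' the distal- and proximal-tier quantum catches,
#' `A_n = ln(Q_distal) - ln(Q_proximal)`. Rows where either catch falls at or
#' below the log floor (numerically zero under narrowband illumination) are
#' reported `NA` — undefined, not an error.
#'
#' An alternative normalized-opponency form,
#' `(Q_distal - Q_proximal) / (Q_distal + Q_proximal)`, is available behind
#' the `form` switch; unlike the log form it is not invariant to whether the
#' catches were normalised first.
#'
#' @param retina The [build_retina()] model supplying the opponent pairs.
#' @param catches A `catch_table` for one (stimulus, illuminant) pair.
#' @param log_floor Catches at or below this fraction of the table's scale
#'   (the normalisation reference if normalised, else the table maximum) are
#'   treated as undefined. Default 1e-12.
#' @param form `"log_ratio"` (default) or `"normalized"`.
#' @return Object of class `"activity_profile"`: list with `A` (named numeric,
#'   rows "1".."4", `NA` where undefined), `stimulus`, `illuminant`.
#' @export
activity_profile <- function(retina, catches, log_floor = 1e-12,
                             form = c("log_ratio", "normalized")) {
  stopifnot(inherits(retina, "retina_model"), inherits(catches, "catch_table"))
  form <- match.arg(form)
  scale <- if (is_normalized(catches)) 1 else max(catches$value)
  floor_abs <- log_floor * max(scale, .Machine$double.xmin)
  A <- stats::setNames(rep(NA_real_, 4), as.character(1:4))
  for (r in names(retina$pairs)) {
    pr <- retina$pairs[[r]]
    qd <- catches$value[catches$channel == pr["distal"]]
    qp <- catches$value[catches$channel == pr["proximal"]]
    if (length(qd) != 1 || length(qp) != 1) {
      stop("catch table does not cover the row ", r, " opponent pair")
    }
    if (qd > floor_abs && qp > floor_abs) {
      A[r] <- if (form == "log_ratio") log(qd) - log(qp) else
        (qd - qp) / (qd + qp)
    }
  }
  structure(list(A = A,
                 stimulus = attr(catches, "stimulus"),
                 illuminant = attr(catches, "illuminant")),
            class = "activity_profile")
}

#' Contrast difference between two stimuli
#'
#' Per row, the difference of the two stimuli's activity profiles under the
#' same illuminant: `CD_n = A_n(X) - A_n(Y)`. Undefined rows propagate as
#' `NA`. Comparing profiles computed under different illuminants is an error:
#' a contrast is defined for two stimuli seen in the same light.
#'
#' @param profile_x,profile_y [activity_profile()] objects, same illuminant.
#' @return Object of class `"contrast_table"`: list with `cd` and `abs_cd`
#'   (named per row), `stimulus_pair`, `illuminant`.
#' @export
contrast_difference <- function(profile_x, profile_y) {
  stopifnot(inherits(profile_x, "activity_profile"),
            inherits(profile_y, "activity_profile"))
  if (!identical(profile_x$illuminant, profile_y$illuminant)) {
    stop("activity profiles computed under different illuminants")
  }
  cd <- profile_x$A - profile_y$A
  structure(list(cd = cd, abs_cd = abs(cd),
                 stimulus_pair = c(profile_x$stimulus, profile_y$stimulus),
                 illuminant = profile_x$illuminant),
            class = "contrast_table")
}

#' Active rows under an illumination
#'
#' A row is considered effectively activated only when both of its opponent
#' channels catch an appreciable photon signal: narrowband coloured tents can
#' silence rows whose sensitivities lie outside the transmitted band, and the
#' contrast such rows report is unavailable to the animal. The criterion is a
#' threshold on the normalised catch (relative to the experiment's reference
#' entry), so the table must be normalised first.
#'
#' @param catches A normalised `catch_table`.
#' @param retina The [build_retina()] model supplying opponent pairs.
#' @param threshold Normalised-catch threshold, default 0.05.
#' @return Integer vector of active rows (subset of 1:4).
#' @export
row_activation <- function(catches, retina, threshold = 0.05) {
  stopifnot(inherits(catches, "catch_table"), inherits(retina, "retina_model"))
  if (!is_normalized(catches)) {
    stop("row_activation needs a normalised catch table; see normalize_catches()")
  }
  active <- integer(0)
  for (r in names(retina$pairs)) {
    pr <- retina$pairs[[r]]
    qd <- catches$value[catches$channel == pr["distal"]]
    qp <- catches$value[catches$channel == pr["proximal"]]
    if (qd > threshold && qp > threshold) active <- c(active, as.integer(r))
  }
  active
}

#' Binning (barcode) activation pattern
#'
#' The competing readout: the channel-ordered catch vector rescaled to unit
#' maximum, with the dominant channel (the argmax) determining the encoded
#' colour. Scale-invariant by construction, so intensity alone carries no
#' signal — flat greys of any optical density produce identical patterns.
#'
#' @param catches A `catch_table` (raw or normalised).
#' @param include_R8 Include the R8 channels in the pattern? Default `FALSE`.
#' @return Named numeric pattern vector with attributes `dominant` (channel
#'   label, lowest channel index on ties), `tie` (logical) and `undefined`
#'   (`TRUE` for an all-zero catch vector, in which case the pattern is all
#'   zero).
#' @export
binning_pattern <- function(catches, include_R8 = FALSE) {
  stopifnot(inherits(catches, "catch_table"))
  keep <- if (include_R8) rep(TRUE, nrow(catches)) else catches$tier != "R8"
  v <- stats::setNames(catches$value[keep], catches$channel[keep])
  m <- max(v)
  if (m <= 0) {
    return(structure(v, dominant = NA_character_, tie = FALSE, undefined = TRUE))
  }
  p <- v / m
  top <- which(p >= 1 - 1e-12)
  structure(p, dominant = names(p)[top[1]], tie = length(top) > 1,
            undefined = FALSE)
}

#' Compare two binning patterns
#'
#' Distance is the maximum absolute channelwise difference; patterns further
#' apart than the tolerance are called discriminable. Under the pure binning
#' hypothesis a colour is indistinguishable from any grey whose activation
#' pattern falls within tolerance.
#'
#' @param p1,p2 Pattern vectors from [binning_pattern()], equal length.
#' @param tolerance Discrimination tolerance, default 0.1.
#' @return List with `discriminable` (logical) and `distance`.
#' @export
binning_discriminable <- function(p1, p2, tolerance = 0.1) {
  if (length(p1) != length(p2)) stop("patterns differ in length")
  d <- max(abs(as.numeric(p1) - as.numeric(p2)))
  list(discriminable = d > tolerance, distance = d)
}

#' Tidy export of a catch table
#'
#' @param catches A `catch_table`.
#' @return Tibble with columns `channel,row,tier,stimulus,illuminant,value`.
#' @export
catch_table_tidy <- function(catches) {
  stopifnot(inherits(catches, "catch_table"))
  tibble::tibble(channel = catches$channel, row = catches$row,
                 tier = catches$tier,
                 stimulus = attr(catches, "stimulus"),
                 illuminant = attr(catches, "illuminant"),
                 value = catches$value)
}
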