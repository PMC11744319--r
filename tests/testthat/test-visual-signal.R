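# Quantum catches, activity profiles, contrast differences, row activation
# and the binning-pattern comparator.

test_that("quantum catch integrates by the trapezoid rule and is linear", {
  g <- wl_grid(400, 500, 1)
  one <- flat_spectrum(1, "sensitivity", g)
  oneR <- flat_spectrum(1, "reflectance", g)
  oneI <- flat_spectrum(1, "irradiance", g)
  expect_equal(quantum_catch(one, oneR, oneI), 100)
  twoI <- spectrum(as.numeric(g), rep(2, 101), "irradiance")
  expect_equal(quantum_catch(one, oneR, twoI),
               2 * quantum_catch(one, oneR, oneI))
  expect_error(quantum_catch(one, oneR,
                             flat_spectrum(1, "irradiance", wl_grid(300, 750, 1))),
               "grids")
})

test_that("trapezoid catch matches a 100x finer Riemann oracle on a smooth
           fixture within 1e-6 relative", {
  g <- default_grid()
  wl <- as.numeric(g)
  S <- spectrum(wl, exp(-0.5 * ((wl - 500) / 30)^2), "sensitivity")
  got <- quantum_catch(S, flat_spectrum(1, "reflectance", g),
                       flat_spectrum(1, "irradiance", g))
  # independent oracle: midpoint Riemann sum at 0.01 nm on the closed form
  fine <- seq(300 + 0.005, 750 - 0.005, by = 0.01)
  oracle <- sum(exp(-0.5 * ((fine - 500) / 30)^2)) * 0.01
  expect_equal(got, oracle, tolerance = 1e-6)
})

test_that("catch tables count 12 channels and annihilate with disjoint or
           zero light", {
  ret <- test_retina()
  g <- default_grid()
  day <- make_illuminant_daylight(g)
  tb <- catch_table(ret, make_reflectance(0.15, g), day, "grey_0.15", "natural")
  expect_equal(nrow(tb), 12)
  expect_true(all(tb$value >= 0))
  dark <- spectrum(as.numeric(g), rep(0, 451), "irradiance")
  tb0 <- catch_table(ret, make_reflectance(0.15, g), dark, "grey", "dark")
  expect_true(all(tb0$value == 0))
  # narrowband red light cannot reach a short-wavelength channel
  redlight <- apply_illuminant_filter(
    day, effective_transmittance(make_bandpass_filter(610, Inf, grid = g)))
  tbr <- catch_table(ret, flat_spectrum(0.9, "reflectance", g), redlight,
                     "white", "red_only")
  expect_lt(tbr$value[tbr$channel == "R8.1"] / max(tbr$value), 1e-9)
})

test_that("normalisation sets the reference to 1, preserves ratios, and is
           idempotent", {
  ret <- test_retina()
  g <- default_grid()
  day <- make_illuminant_daylight(g)
  tabs <- list(
    catch_table(ret, make_reflectance(0.15, g), day, "grey_0.15", "natural"),
    catch_table(ret, make_reflectance("blue", g), day, "blue", "natural"))
  ref <- list("R2P", "grey_0.15", "natural")
  nn <- normalize_catches(tabs, ref)
  expect_equal(nn[[1]]$value[nn[[1]]$channel == "R2P"], 1)
  expect_equal(nn[[2]]$value / nn[[2]]$value[1],
               tabs[[2]]$value / tabs[[2]]$value[1])
  again <- normalize_catches(nn, ref)
  expect_equal(again[[2]]$value, nn[[2]]$value)
  expect_error(normalize_catches(tabs, list("R2P", "nope", "natural")),
               "not found")
})

test_that("activity profiles are log-ratios of opponent catches", {
  ret <- test_retina()
  fake <- function(vals) {
    tb <- tibble::tibble(
      channel = names(vals),
      row = rep(1:4, each = 3),
      tier = rep(c("R8", "distal", "proximal"), 4),
      value = unname(vals))
    attr(tb, "stimulus") <- "s"; attr(tb, "illuminant") <- "i"
    attr(tb, "normalization") <- list("x", "y", "z")
    class(tb) <- c("catch_table", class(tb))
    tb
  }
  labs <- vapply(ret$channels, `[[`, "", "label")
  v <- stats::setNames(rep(1, 12), labs)
  prof <- activity_profile(ret, fake(v))
  expect_equal(unname(prof$A), rep(0, 4))          # equal catches
  v["R1D"] <- exp(1)
  expect_equal(activity_profile(ret, fake(v))$A[["1"]], 1)   # ln e
  v["R1D"] <- 2; v["R1P"] <- 1
  expect_equal(activity_profile(ret, fake(v))$A[["1"]], log(2))
  # catches at the log floor are undefined, not -Inf
  v["R3D"] <- 0
  prof3 <- activity_profile(ret, fake(v))
  expect_true(is.na(prof3$A[["3"]]))
  expect_false(anyNA(prof3$A[c("1", "2", "4")]))
  # the alternative normalized-opponency form: (Qd - Qp) / (Qd + Qp)
  v["R3D"] <- 1; v["R1D"] <- 3; v["R1P"] <- 1
  pn <- activity_profile(ret, fake(v), form = "normalized")
  expect_equal(pn$A[["1"]], 0.5)
  expect_equal(pn$A[["2"]], 0)
})

test_that("contrast differences are antisymmetric, zero on self, and NA on
           undefined rows; illuminant mismatch is an error", {
  w <- test_world()
  ret <- test_retina()
  pb <- w$profiles[["blue|tent_blue"]]
  pg <- w$profiles[["grey_0.3|tent_blue"]]
  cd <- contrast_difference(pb, pg)
  cd_rev <- contrast_difference(pg, pb)
  expect_equal(cd$cd, -cd_rev$cd)
  expect_equal(cd$abs_cd, cd_rev$abs_cd)
  self <- contrast_difference(pb, pb)
  expect_true(all(self$cd[!is.na(self$cd)] == 0))
  expect_error(contrast_difference(pb, w$profiles[["grey_0.3|natural"]]),
               "illuminants")
})

test_that("flat greys of any optical density are exact metamers: zero CD and
           zero binning distance under any illuminant", {
  w <- test_world()
  for (il in c("natural", "tent_blue", "tent_green", "tent_red")) {
    p15 <- w$profiles[[paste0("grey_0.15|", il)]]
    p9 <- w$profiles[[paste0("grey_0.9|", il)]]
    cd <- contrast_difference(p15, p9)
    expect_equal(max(abs(cd$cd), na.rm = TRUE), 0, tolerance = 1e-10)
    b <- binning_discriminable(
      binning_pattern(w$tables[[paste0("grey_0.15|", il)]]),
      binning_pattern(w$tables[[paste0("grey_0.9|", il)]]))
    expect_equal(b$distance, 0, tolerance = 1e-12)
    expect_false(b$discriminable)
  }
  # while a non-flat reflectance does produce contrast
  cd_col <- contrast_difference(w$profiles[["blue|natural"]],
                                w$profiles[["grey_0.15|natural"]])
  expect_gt(max(cd_col$abs_cd, na.rm = TRUE), 0.1)
})

test_that("activity profiles, CDs and binning patterns are invariant to
           illuminant intensity scaling", {
  ret <- test_retina()
  g <- default_grid()
  day <- make_illuminant_daylight(g)
  bright <- spectrum(day$wl, day$value * 37.5, "irradiance")
  for (refl in list(make_reflectance("green", g), make_reflectance(0.6, g))) {
    t1 <- catch_table(ret, refl, day, "s", "dim")
    t2 <- catch_table(ret, refl, bright, "s", "bright")
    n1 <- normalize_catches(t1, list("R2P", "s", "dim"))
    n2 <- normalize_catches(t2, list("R2P", "s", "bright"))
    expect_equal(activity_profile(ret, n1)$A, activity_profile(ret, n2)$A,
                 tolerance = 1e-12)
    expect_equal(as.numeric(binning_pattern(t1)),
                 as.numeric(binning_pattern(t2)), tolerance = 1e-12)
  }
})

test_that("row activation requires a normalised table and gates on both
           opponent channels", {
  w <- test_world()
  ret <- test_retina()
  g <- default_grid()
  raw <- catch_table(ret, make_reflectance(0.15, g),
                     make_illuminant_daylight(g), "grey_0.15", "natural")
  expect_error(row_activation(raw, ret), "normalised")
  # full daylight on a grey: every row active; threshold 0 keeps any
  # strictly positive row
  nat <- w$tables[["grey_0.15|natural"]]
  expect_equal(row_activation(nat, ret), 1:4)
  expect_equal(row_activation(nat, ret, threshold = 0), 1:4)
  # under the red tent the default retina loses its short-wavelength rows
  # but keeps at least one long-wavelength row
  redgrey <- w$tables[["grey_0.15|tent_red"]]
  act <- row_activation(redgrey, ret)
  expect_true(length(act) >= 1 && length(act) <= 3)
  expect_false(1 %in% act)
  expect_true(3 %in% act)
})

test_that("binning patterns rescale to unit max, pick the dominant channel,
           and are scale invariant", {
  w <- test_world()
  tb <- w$tables[["green|natural"]]
  p <- binning_pattern(tb)
  expect_equal(max(p), 1)
  expect_equal(attr(p, "dominant"), tb$channel[tb$tier != "R8"][which.max(
    tb$value[tb$tier != "R8"])])
  tb2 <- tb
  tb2$value <- tb2$value * 5.5
  expect_equal(as.numeric(binning_pattern(tb2)), as.numeric(p))
  # all-zero catches give an undefined pattern
  tb0 <- tb
  tb0$value <- 0
  expect_true(attr(binning_pattern(tb0), "undefined"))
  # disjoint dominance is maximally discriminable
  d <- binning_discriminable(c(1, 0, 0), c(0, 1, 0), tolerance = 0.5)
  expect_true(d$discriminable)
  expect_equal(d$distance, 1)
  expect_error(binning_discriminable(c(1, 0), c(1, 0, 0)), "length")
})
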