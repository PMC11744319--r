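# Synthetic fixtures (illuminant, filters, reflectances) and the behavioural
# simulator: chooser, scheduling constraints, staged experiment.

test_that("synthetic daylight is positive, broad and blue-green peaked", {
  day <- make_illuminant_daylight()
  expect_true(all(day$value > 0))
  expect_equal(max(day$value), 1)
  peak_wl <- day$wl[which.max(day$value)]
  expect_gte(peak_wl, 450)
  expect_lte(peak_wl, 550)
  expect_equal(make_illuminant_daylight()$value, day$value)  # deterministic
})

test_that("band-pass fixtures respect the stated passbands: >= 90% inside,
           <= 1% outside", {
  g <- default_grid()
  wl <- as.numeric(g)
  bands <- list(  # stimulus filters and tent filters, stated edges
    list(c(360, 550)), list(c(500, 560)), list(c(610, Inf)),
    list(c(360, 590)), list(c(450, 600)), list(c(590, Inf)))
  soft <- 10
  for (b in bands) {
    pb <- b[[1]]
    t <- effective_transmittance(make_bandpass_filter(pb[1], pb[2], soft,
                                                      grid = g))
    deep_lo <- pb[1] + 1.5 * soft
    deep_hi <- if (is.finite(pb[2])) pb[2] - 1.5 * soft else max(wl)
    inside <- t$value[wl >= deep_lo & wl <= deep_hi]
    expect_gte(min(inside), 0.9)
    outside <- t$value[wl <= pb[1] - 3 * soft |
                         (is.finite(pb[2]) & wl >= pb[2] + 3 * soft)]
    expect_lte(max(outside), 0.01)
  }
  expect_error(make_bandpass_filter(400, 500, softness = 0), "softness")
  expect_error(make_bandpass_filter(500, 400), "edge")
})

test_that("ND filters obey the optical-density law and stack additively", {
  g <- default_grid()
  nd3 <- effective_transmittance(make_nd_filter(0.3, grid = g))
  expect_equal(unique(nd3$value), 10^(-0.3))
  expect_equal(unique(round(nd3$value, 4)), 0.5012)
  # two OD-0.3 layers equal one OD-0.6 filter pointwise
  two <- combine_filters(list(make_nd_filter(0.3, grid = g),
                              make_nd_filter(0.3, grid = g)))
  one <- effective_transmittance(make_nd_filter(0.6, grid = g))
  expect_equal(two$value, one$value, tolerance = 1e-12)
  expect_equal(unique(effective_transmittance(
    make_nd_filter(0, grid = g))$value), 1)
  # the far-red leak rises above 680 nm only
  leak <- effective_transmittance(make_nd_filter(0.9, red_leak = TRUE,
                                                 grid = g))
  wl <- as.numeric(g)
  expect_equal(leak$value[wl == 500], 10^(-0.9), tolerance = 1e-3)
  expect_gt(leak$value[wl == 730], 0.5)
})

test_that("double tents equal single tents squared pointwise", {
  g <- default_grid()
  for (col in c("blue", "green", "red")) {
    single <- effective_transmittance(make_tent_filter(col, 1, g))
    double <- effective_transmittance(make_tent_filter(col, 2, g))
    expect_equal(double$value, single$value^2, tolerance = 1e-12)
  }
})

test_that("stimulus reflectances follow their construction", {
  g <- default_grid()
  wl <- as.numeric(g)
  grey <- make_reflectance(0.15, g)
  expect_equal(unique(grey$value), 0.9 * 10^(-0.15))
  blue <- make_reflectance("blue", g)
  expect_lte(blue$value[wl == 650], 0.01 * 0.9)
  red <- make_reflectance("red", g)
  expect_lte(red$value[wl == 450], 0.01 * 0.9)
  expect_error(make_reflectance("magenta", g), "unknown")
})

test_that("the null chooser is uniform and the sharp chooser picks the
           best-scoring stimulus", {
  null <- chooser_params(beta = 0, lapse = 0, no_choice = 0)
  p <- choice_probabilities(c(a = -0.5, b = 0, c = -0.2), null)
  expect_equal(unname(p[1:3]), rep(1 / 3, 3))
  sharp <- chooser_params(beta = 200, lapse = 0.02, no_choice = 0.05)
  p2 <- choice_probabilities(c(a = -0.5, b = 0, c = -0.2), sharp)
  expect_equal(unname(p2["b"]), (1 - 0.05) * ((1 - 0.02) + 0.02 / 3),
               tolerance = 1e-6)
  # spectrally identical stimuli tie regardless of beta
  p3 <- choice_probabilities(c(a = -0.3, b = -0.3, c = -0.3), sharp)
  expect_equal(unname(p3[1:3]), rep((1 - 0.05) / 3, 3))
  expect_error(chooser_params(lapse = 0.7, no_choice = 0.5), "lapse")
})

test_that("similarity scores are zero for the target under the training light
           and negative for distractors", {
  w <- test_world()
  expect_equal(stimulus_similarity(w, "green", "natural", "green"), 0)
  expect_lt(stimulus_similarity(w, "green", "natural", "grey_0.3"), 0)
  expect_error(stimulus_similarity(w, "green", "natural", "cyan"), "unknown")
})

test_that("testing schedules satisfy the pseudo-randomisation constraints", {
  sched <- schedule_trials(5, n_days = 12, coloured = "tent_green", seed = 7)
  for (ind in unique(sched$individual)) {
    s <- sched[sched$individual == ind, ]
    testing <- s[!s$reinforcement, ]
    # (i) target position never occupies one slot more than twice in a row
    runs <- rle(testing$target_pos)
    expect_lte(max(runs$lengths), 2)
    # (ii) no immediate triple repeat of a distractor combination
    expect_lte(max(rle(testing$combination)$lengths), 2)
    # (iii) day 1 all natural; later days one natural + two coloured
    expect_true(all(testing$illumination[testing$day == 1] == "natural"))
    for (d in 2:12) {
      ill <- testing$illumination[testing$day == d]
      expect_equal(sum(ill == "natural"), 1)
      expect_equal(sum(ill == "tent_green"), 2)
    }
    # (iv) a flagged reinforcement trial after every six testing trials:
    # every 7th record in the interleaved sequence
    expect_equal(which(s$reinforcement), seq(7, nrow(s), by = 7))
  }
  expect_error(schedule_trials(2, seed = 1, positions = "left"),
               "two positions")
  expect_error(schedule_trials(2), "seed")
})

test_that("simulated experiments are reproducible and respect stage rules", {
  w <- test_world()
  des <- experiment_design(groups = c(green = 3, red = 3), testing_days = 4)
  d1 <- simulate_experiment(des, chooser_params(), seed = 99, world = w)
  d2 <- simulate_experiment(des, chooser_params(), seed = 99, world = w)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  expect_identical(attr(d1, "fates"), attr(d2, "fates"))
  expect_true(all(c("priming", "training", "testing") %in% d1$stage))
  # a sharp low-lapse chooser promotes most individuals to testing
  fates <- attr(d1, "fates")
  expect_gte(sum(fates$fate == "included"), 4)
  # reinforcement trials occur only in testing and carry the flag
  expect_true(all(d1$stage[d1$reinforcement] == "testing"))
})

test_that("a null chooser is removed at training with positive probability", {
  w <- test_world()
  des <- experiment_design(groups = c(red = 6), testing_days = 2)
  null_chooser <- chooser_params(beta = 0, lapse = 0, no_choice = 0)
  ds <- simulate_experiment(des, null_chooser, seed = 3, world = w)
  fates <- attr(ds, "fates")
  expect_gte(sum(fates$fate == "removed_training"), 1)
})
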