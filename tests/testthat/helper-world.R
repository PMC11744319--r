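# Shared fixtures. The grey-card world (all catch tables and profiles) takes
# a few seconds to build, so it is constructed once per test run.

.cache <- new.env(parent = emptyenv())

test_world <- function() {
  if (is.null(.cache$world)) .cache$world <- grey_card_world()
  .cache$world
}

test_retina <- function() {
  if (is.null(.cache$retina)) .cache$retina <- build_retina()
  .cache$retina
}

flat_spectrum <- function(value, kind = "reflectance", grid = default_grid()) {
  wl <- as.numeric(grid)
  spectrum(wl, rep(value, length(wl)), kind)
}

random_spectrum <- function(kind = "transmittance", grid = default_grid()) {
  wl <- as.numeric(grid)
  spectrum(wl, runif(length(wl)), kind)
}

# Logistic choice data with individual random intercepts: the independent
# simulation oracle for the mixed-model parameter-recovery checks.
simulate_glmm_dataset <- function(n_ind, n_trials, beta_tent, sd_ind = 0.5,
                                  intercept = 1) {
  ind <- rep(sprintf("i%02d", seq_len(n_ind)), each = n_trials)
  b <- rep(stats::rnorm(n_ind, 0, sd_ind), each = n_trials)
  tent <- rep(rep(c(0, 1), length.out = n_trials), n_ind)
  eta <- intercept + beta_tent * tent + b
  tibble::tibble(
    individual = ind, group = "green", stage = "testing", day = 1,
    trial = rep(seq_len(n_trials), n_ind),
    illumination = ifelse(tent == 1, "tent", "natural"),
    combination = "0.15/0.9", target_pos = "left",
    choice_pos = "left",
    correct = stats::runif(length(eta)) < stats::plogis(eta),
    reinforcement = FALSE)
}
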