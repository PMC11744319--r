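# Simulation of the three-choice grey-card experiment: a precomputed
# "world" of stimuli, illuminants and opponent signals; a contrast-driven
# probabilistic chooser; pseudo-randomised trial scheduling; and the staged
# priming -> training -> testing protocol.

POSITIONS <- c("left", "middle", "right")
COMBINATIONS <- c("0.15/0.3", "0.15/0.6", "0.15/0.9",
                  "0.3/0.6", "0.3/0.9", "0.6/0.9")

#' Chooser parameters
#'
#' The probabilistic decision rule of a simulated animal. Choice follows a
#' Luce/softmax rule over stimulus similarity scores with sensitivity `beta`,
#' mixed with a lapse probability (uniform random choice) and a no-choice
#' probability (the 5-minute timeout). The default `beta = 2*log(6)` is a
#' calibration constant, not a measured value: it makes a stimulus set in
#' which both distractors differ from the target by one row of |CD| = 0.5
#' yield 75% correct choices, the success plateau observed in well-trained
#' animals.
#'
#' @param beta Non-negative softmax sensitivity.
#' @param lapse Probability of a uniform random choice.
#' @param no_choice Probability of making no choice; `lapse + no_choice <= 1`.
#' @param participation Probability of participating in a priming trial.
#' @return Object of class `"chooser_params"`.
#' @export
chooser_params <- function(beta = 2 * log(6), lapse = 0.02, no_choice = 0.05,
                           participation = 0.9) {
  if (beta < 0) stop("beta must be non-negative")
  if (lapse < 0 || no_choice < 0 || lapse + no_choice > 1) {
    stop("need lapse >= 0, no_choice >= 0 and lapse + no_choice <= 1")
  }
  if (participation < 0 || participation > 1) stop("participation must be in [0,1]")
  structure(list(beta = beta, lapse = lapse, no_choice = no_choice,
                 participation = participation), class = "chooser_params")
}

#' Build the grey-card experiment world
#'
#' Precomputes everything the chooser needs: the synthetic daylight and tent
#' illuminants, stimulus reflectances, quantum catches for every
#' (stimulus, illuminant) pair normalised to the R2P / ND 0.15 grey / natural
#' light reference, activity profiles, active rows, and each colour group's
#' learned target signature (the target's activity profile under the natural
#' training light, held fixed during testing — memory without any colour
#' constancy assumption).
#'
#' @param retina A [build_retina()] model.
#' @param grid Session grid.
#' @param tent_layers Layer counts for the coloured tents to include
#'   (1 = bright tents, 2 = the dim double tents). Default `c(1, 2)`.
#' @param nd_tent_ods ND tent optical densities, default `c(0.3, 0.6, 0.9)`.
#' @param nd_red_leak Model the far-red leak of the ND tents? Default `TRUE`,
#'   as in the physical filters.
#' @param activation_threshold Normalised-catch threshold for
#'   [row_activation()].
#' @return Object of class `"gc_world"` with a score lookup used by
#'   [simulate_choice()].
#' @export
grey_card_world <- function(retina = build_retina(), grid = default_grid(),
                            tent_layers = c(1, 2),
                            nd_tent_ods = c(0.3, 0.6, 0.9),
                            nd_red_leak = TRUE,
                            activation_threshold = 0.05) {
  day <- make_illuminant_daylight(grid)
  illums <- list(natural = day)
  for (col in c("blue", "green", "red")) {
    for (ly in tent_layers) {
      nm <- if (ly == 1) paste0("tent_", col) else
        sprintf("tent_%s_x%d", col, ly)
      illums[[nm]] <- apply_illuminant_filter(
        day, make_tent_filter(col, layers = ly, grid = grid))
    }
  }
  for (od in nd_tent_ods) {
    illums[[sprintf("nd_tent_%g", od)]] <- apply_illuminant_filter(
      day, make_nd_filter(od, red_leak = nd_red_leak, grid = grid))
  }

  stim_kinds <- c("blue", "green", "red", sprintf("grey_%g", GREY_ODS))
  stimuli <- lapply(stats::setNames(stim_kinds, stim_kinds), function(k) {
    if (grepl("^grey_", k)) {
      make_reflectance(as.numeric(sub("grey_", "", k)), grid)
    } else make_reflectance(k, grid)
  })

  tables <- list()
  for (il in names(illums)) {
    for (st in stim_kinds) {
      tables[[paste(st, il, sep = "|")]] <-
        catch_table(retina, stimuli[[st]], illums[[il]], st, il)
    }
  }
  tables <- normalize_catches(tables, list("R2P", "grey_0.15", "natural"))

  profiles <- lapply(tables, function(tb) activity_profile(retina, tb))
  active <- lapply(tables, function(tb)
    row_activation(tb, retina, activation_threshold))

  signatures <- lapply(stats::setNames(c("blue", "green", "red"),
                                       c("blue", "green", "red")),
                       function(col) profiles[[paste(col, "natural", sep = "|")]])

  structure(list(retina = retina, grid = as.numeric(grid), illuminants = illums,
                 stimuli = stimuli, tables = tables, profiles = profiles,
                 active = active, signatures = signatures),
            class = "gc_world")
}

#' Similarity of a stimulus to a group's learned target
#'
#' The negative of the maximum absolute per-row contrast difference, over the
#' stimulus's active rows, between the stimulus viewed under the test
#' illumination and the target's remembered appearance under natural light.
#' `NA` when no row is both active and defined — the chromatic signal is lost
#' and the chooser falls back to a uniform guess.
#'
#' @param world A [grey_card_world()].
#' @param group Target colour, `"blue"`, `"green"` or `"red"`.
#' @param illumination Illuminant name in the world (e.g. `"tent_blue"`).
#' @param stimulus Stimulus kind (e.g. `"grey_0.3"`).
#' @return Scalar score (<= 0) or `NA`.
#' @export
stimulus_similarity <- function(world, group, illumination, stimulus) {
  stopifnot(inherits(world, "gc_world"))
  key <- paste(stimulus, illumination, sep = "|")
  if (is.null(world$profiles[[key]])) stop("unknown stimulus/illumination: ", key)
  prof <- world$profiles[[key]]
  sig <- world$signatures[[group]]
  if (is.null(sig)) stop("unknown group: ", group)
  rows <- as.character(world$active[[key]])
  d <- abs(prof$A[rows] - sig$A[rows])
  d <- d[!is.na(d)]
  if (length(d) == 0) return(NA_real_)
  -max(d)
}

#' Softmax choice probabilities
#'
#' Luce-rule probabilities over similarity scores, mixed with the lapse and
#' no-choice rates. Any `NA` score means the chromatic signal is unavailable
#' for that stimulus set and the whole choice collapses to a uniform guess.
#'
#' @param scores Numeric similarity scores, one per position.
#' @param chooser A [chooser_params()].
#' @return Named probability vector over `c(positions, "none")`, summing to 1.
#' @export
choice_probabilities <- function(scores, chooser) {
  stopifnot(inherits(chooser, "chooser_params"))
  k <- length(scores)
  if (anyNA(scores)) {
    p <- rep(1 / k, k)
  } else {
    z <- chooser$beta * (scores - max(scores))
    p <- exp(z) / sum(exp(z))
  }
  probs <- (1 - chooser$no_choice) * ((1 - chooser$lapse) * p + chooser$lapse / k)
  stats::setNames(c(probs, chooser$no_choice),
                  c(names(scores) %||% paste0("opt", seq_len(k)), "none"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate choices for one stimulus presentation
#'
#' Draws `n` independent choices for a presented stimulus set under one
#' illumination, using the contrast-driven chooser. Deterministic given the
#' RNG state.
#'
#' @param world A [grey_card_world()].
#' @param group Target colour group.
#' @param illumination Illuminant name.
#' @param stimuli Named character vector mapping positions (default left,
#'   middle, right) to stimulus kinds; exactly one entry should be the
#'   group's target for a standard trial.
#' @param chooser A [chooser_params()].
#' @param n Number of independent draws.
#' @return Character vector of chosen positions, `"none"` for no-choice.
#' @export
simulate_choice <- function(world, group, illumination, stimuli,
                            chooser = chooser_params(), n = 1) {
  scores <- vapply(stimuli, function(st)
    stimulus_similarity(world, group, illumination, st), 0)
  probs <- choice_probabilities(scores, chooser)
  sample(names(probs), n, replace = TRUE, prob = probs)
}

draw_position_sequence <- function(n, positions = POSITIONS) {
  # no value may occupy the same slot more than twice in a row
  if (length(positions) < 2) stop("need at least two positions")
  out <- character(n)
  for (i in seq_len(n)) {
    cand <- positions
    if (i >= 3 && out[i - 1] == out[i - 2]) cand <- setdiff(cand, out[i - 1])
    out[i] <- cand[sample.int(length(cand), 1)]
  }
  out
}

draw_combination_sequence <- function(n, combos = COMBINATIONS) {
  if (length(combos) < 2) stop("need at least two combinations")
  out <- character(n)
  for (i in seq_len(n)) {
    cand <- combos
    if (i >= 3 && out[i - 1] == out[i - 2]) cand <- setdiff(cand, out[i - 1])
    out[i] <- cand[sample.int(length(cand), 1)]
  }
  out
}

#' Pseudo-randomised testing schedule
#'
#' Generates trial templates for the testing stage: three testing trials per
#' day (all under natural light on day 1; from day 2, one natural-light and
#' two coloured-illumination trials in random order per day), target
#' positions and distractor combinations pseudo-randomised so that no value
#' repeats more than twice consecutively, and one flagged reinforcement trial
#' inserted after every six testing trials.
#'
#' @param n_individuals Number of individuals to schedule.
#' @param n_days Testing days per individual.
#' @param coloured Character vector of coloured-illumination condition names
#'   to rotate through (e.g. `"tent_blue"`).
#' @param seed Integer seed (required: schedules are part of the simulated
#'   dataset's provenance).
#' @param positions Available positions, default left/middle/right.
#' @return Tibble of trial templates with columns `individual`, `day`,
#'   `trial`, `illumination`, `combination`, `target_pos`, `reinforcement`.
#' @export
schedule_trials <- function(n_individuals, n_days = 12,
                            coloured = "tent_blue", seed,
                            positions = POSITIONS) {
  if (missing(seed)) stop("schedule_trials requires a seed")
  if (length(positions) < 2) stop("need at least two positions")
  set.seed(seed)
  out <- vector("list", n_individuals)
  for (ind in seq_len(n_individuals)) {
    illum <- character(0)
    for (d in seq_len(n_days)) {
      if (d == 1) {
        illum <- c(illum, rep("natural", 3))
      } else {
        cols <- rep(coloured, length.out = 2)
        illum <- c(illum, sample(c("natural", cols[1], cols[2])))
      }
    }
    n <- length(illum)
    pos <- draw_position_sequence(n, positions)
    comb <- draw_combination_sequence(n)
    tmpl <- tibble::tibble(
      individual = ind, day = rep(seq_len(n_days), each = 3),
      trial = seq_len(n), illumination = illum, combination = comb,
      target_pos = pos, reinforcement = FALSE)
    # one reinforcement trial (natural light, training procedure) after
    # every six testing trials
    n_re <- n %/% 6
    if (n_re > 0) {
      re_pos <- draw_position_sequence(n_re, positions)
      re_comb <- draw_combination_sequence(n_re)
      re <- tibble::tibble(
        individual = ind, day = (seq_len(n_re) * 6 - 1) %/% 3 + 1,
        trial = seq_len(n_re) * 6L, illumination = "natural",
        combination = re_comb, target_pos = re_pos, reinforcement = TRUE)
      tmpl <- dplyr::arrange(dplyr::bind_rows(tmpl, re), trial, reinforcement)
    }
    tmpl$trial <- seq_len(nrow(tmpl))
    out[[ind]] <- tmpl
  }
  dplyr::bind_rows(out)
}

combo_stimuli <- function(group, combination, target_pos,
                          positions = POSITIONS) {
  ods <- strsplit(combination, "/")[[1]]
  distr <- paste0("grey_", ods)
  st <- stats::setNames(character(length(positions)), positions)
  st[target_pos] <- group
  st[setdiff(positions, target_pos)] <- sample(distr)
  st
}

#' Experiment design
#'
#' @param groups Named integer vector: individuals entering priming per
#'   colour group, default 8 each.
#' @param coloured_conditions Named list mapping group to its coloured
#'   testing conditions (default the single-layer tent of its own colour).
#' @param priming_days,max_training_days,testing_days Stage durations (days,
#'   3 trials per day); defaults 3 / 5 / 12 within the reported ranges.
#' @return A list with class `"gc_design"`.
#' @export
experiment_design <- function(groups = c(blue = 8, green = 8, red = 8),
                              coloured_conditions = NULL,
                              priming_days = 3, max_training_days = 5,
                              testing_days = 12) {
  if (is.null(coloured_conditions)) {
    coloured_conditions <- lapply(stats::setNames(names(groups), names(groups)),
                                  function(g) paste0("tent_", g))
  }
  structure(list(groups = groups, coloured_conditions = coloured_conditions,
                 priming_days = priming_days,
                 max_training_days = max_training_days,
                 testing_days = testing_days),
            class = "gc_design")
}

ind_seed <- function(seed, idx) {
  (as.integer(seed) %% 100000L) * 20011L + idx * 7919L
}

#' Simulate the full grey-card experiment
#'
#' Runs priming, training and testing for every individual, applying the
#' stage-progression rules of [inclusion_filter()]: priming promotes at an
#' 80% participation rate over the last five trials and removes below 50%;
#' training promotes above an 80% success rate over the last six trials and
#' removes below 30%; after testing, individuals whose natural-light success
#' rate is not above 50% are flagged excluded from analysis. Reinforcement
#' trials are simulated and flagged; they never enter any statistic.
#'
#' @param design An [experiment_design()].
#' @param chooser A [chooser_params()].
#' @param seed Integer master seed; per-individual substreams are derived
#'   from it, so the full dataset is reproducible from `design` + `seed`.
#' @param world A [grey_card_world()]; built with defaults when omitted.
#' @return A `choice_dataset`: tibble with columns `individual`, `group`,
#'   `stage`, `day`, `trial`, `illumination`, `combination`, `target_pos`,
#'   `choice_pos`, `correct`, `reinforcement`, plus a `"fates"` attribute
#'   (per-individual stage outcomes) and a `"seed"` attribute.
#' @export
simulate_experiment <- function(design = experiment_design(),
                                chooser = chooser_params(), seed,
                                world = NULL) {
  stopifnot(inherits(design, "gc_design"))
  if (missing(seed)) stop("simulate_experiment requires a seed")
  if (is.null(world)) world <- grey_card_world()
  records <- list()
  fates <- list()
  idx <- 0L
  for (group in names(design$groups)) {
    for (i in seq_len(design$groups[[group]])) {
      idx <- idx + 1L
      id <- sprintf("%s_%02d", group, i)
      set.seed(ind_seed(seed, idx))
      res <- simulate_individual(id, group, design, chooser, world)
      records[[id]] <- res$records
      fates[[id]] <- tibble::tibble(individual = id, group = group,
                                    fate = res$fate)
    }
  }
  out <- dplyr::bind_rows(records)
  attr(out, "fates") <- dplyr::bind_rows(fates)
  attr(out, "seed") <- seed
  class(out) <- c("choice_dataset", class(out))
  out
}

simulate_individual <- function(id, group, design, chooser, world) {
  rec <- list()
  add <- function(stage, day, trial, illumination, combination, target_pos,
                  choice_pos, correct, reinforcement = FALSE) {
    rec[[length(rec) + 1L]] <<- tibble::tibble(
      individual = id, group = group, stage = stage, day = day, trial = trial,
      illumination = illumination, combination = combination,
      target_pos = target_pos, choice_pos = choice_pos, correct = correct,
      reinforcement = reinforcement)
  }

  # --- priming: single target cable tie, participation only -----------------
  part <- logical(0)
  fate <- "removed_priming"
  for (t in seq_len(design$priming_days * 3)) {
    p <- stats::runif(1) < chooser$participation
    part <- c(part, p)
    add("priming", (t - 1) %/% 3 + 1, t, "natural", NA_character_,
        sample(POSITIONS, 1), if (p) "target" else "none", NA)
    dec <- inclusion_filter(part, "priming")
    if (dec == "promote") { fate <- "primed"; break }
    if (dec == "remove") break
  }
  if (fate != "primed") {
    return(list(records = dplyr::bind_rows(rec), fate = "removed_priming"))
  }

  # --- training: natural light, three-choice trials -------------------------
  succ <- logical(0)
  fate <- "not_promoted"
  pos <- draw_position_sequence(design$max_training_days * 3)
  comb <- draw_combination_sequence(design$max_training_days * 3)
  for (t in seq_along(pos)) {
    st <- combo_stimuli(group, comb[t], pos[t])
    ch <- simulate_choice(world, group, "natural", st, chooser)
    correct <- !is.na(ch) && ch != "none" && ch == pos[t]
    add("training", (t - 1) %/% 3 + 1, t, "natural", comb[t], pos[t], ch,
        if (ch == "none") NA else correct)
    if (ch != "none") succ <- c(succ, correct)
    dec <- inclusion_filter(succ, "training")
    if (dec == "promote") { fate <- "trained"; break }
    if (dec == "remove") { fate <- "removed_training"; break }
  }
  if (fate != "trained") {
    return(list(records = dplyr::bind_rows(rec), fate = fate))
  }

  # --- testing: natural + coloured illumination schedule --------------------
  sched <- schedule_trials(1, design$testing_days,
                           design$coloured_conditions[[group]],
                           seed = sample.int(2^31 - 1, 1))
  for (k in seq_len(nrow(sched))) {
    s <- sched[k, ]
    st <- combo_stimuli(group, s$combination, s$target_pos)
    ch <- simulate_choice(world, group, s$illumination, st, chooser)
    correct <- if (ch == "none") NA else ch == s$target_pos
    add("testing", s$day, s$trial, s$illumination, s$combination,
        s$target_pos, ch, correct, s$reinforcement)
  }
  recs <- dplyr::bind_rows(rec)
  nat <- recs[recs$stage == "testing" & !recs$reinforcement &
                recs$illumination == "natural" & !is.na(recs$correct), ]
  dec <- inclusion_filter(nat$correct, "testing")
  list(records = recs,
       fate = if (dec == "include") "included" else "excluded_testing")
}
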