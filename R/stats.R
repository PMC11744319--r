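# Choice statistics for the grey-card experiment: success rates, the
# stage-progression and inclusion rules, chi-square goodness of fit against
# the one-in-three random expectation, and the binomial logit mixed model.

#' Chi-square goodness of fit against random three-alternative choice
#'
#' Pearson goodness of fit of observed (correct, incorrect) counts against
#' the random-choice expectation for one target among three options:
#' expected correct = n/3, expected incorrect = 2n/3. One degree of freedom,
#' upper-tail p, no continuity correction.
#'
#' @param n_correct,n_total Counts, `0 <= n_correct <= n_total`, `n_total >= 1`.
#' @return List with `statistic`, `p_value`, `df`.
#' @examples
#' chi_square_random_choice(8, 20)
#' @export
chi_square_random_choice <- function(n_correct, n_total) {
  if (n_total < 1 || n_correct < 0 || n_correct > n_total) {
    stop("need 0 <= n_correct <= n_total and n_total >= 1")
  }
  obs <- c(n_correct, n_total - n_correct)
  ht <- suppressWarnings(
    stats::chisq.test(obs, p = c(1 / 3, 2 / 3), correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       df = unname(ht$parameter))
}

round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

analysable <- function(dataset) {
  d <- dataset[!dataset$reinforcement & !is.na(dataset$correct) &
                 dataset$choice_pos != "none", ]
  d
}

#' Success rate of a subset of trials
#'
#' Percentage of correct first choices among qualifying trials.
#' Reinforcement trials and no-choice trials never enter the denominator.
#' Zero qualifying trials yield an explicit empty summary (`NA` rate), not 0%.
#'
#' @param dataset A `choice_dataset` (see [simulate_experiment()]) or any
#'   data frame with the same columns.
#' @param group,illumination,stage Optional filters (`NULL` = keep all);
#'   `stage` defaults to `"testing"`.
#' @param individuals Optional character vector restricting to given
#'   individual ids (e.g. the included set from the inclusion ledger).
#' @return One-row tibble: `group`, `condition`, `n_individuals`, `n_trials`,
#'   `n_correct`, `success_rate` (percent, two decimals, half-up),
#'   `chi_square`, `p_value`.
#' @export
success_rate <- function(dataset, group = NULL, illumination = NULL,
                         stage = "testing", individuals = NULL) {
  d <- analysable(dataset)
  if (!is.null(stage)) d <- d[d$stage %in% stage, ]
  if (!is.null(group)) d <- d[d$group %in% group, ]
  if (!is.null(illumination)) d <- d[d$illumination %in% illumination, ]
  if (!is.null(individuals)) d <- d[d$individual %in% individuals, ]
  lab_group <- if (is.null(group)) "all" else paste(group, collapse = "+")
  lab_cond <- if (is.null(illumination)) "all" else
    paste(illumination, collapse = "+")
  if (nrow(d) == 0) {
    return(tibble::tibble(group = lab_group, condition = lab_cond,
                          n_individuals = 0L, n_trials = 0L, n_correct = 0L,
                          success_rate = NA_real_, chi_square = NA_real_,
                          p_value = NA_real_))
  }
  n <- nrow(d)
  k <- sum(d$correct)
  gof <- chi_square_random_choice(k, n)
  tibble::tibble(group = lab_group, condition = lab_cond,
                 n_individuals = length(unique(d$individual)),
                 n_trials = n, n_correct = k,
                 success_rate = round_half_up(100 * k / n),
                 chi_square = gof$statistic, p_value = gof$p_value)
}

#' Stage-progression and inclusion decisions
#'
#' Pure functions of an individual's trial history, encoding the protocol's
#' decision rules:
#' \describe{
#'   \item{priming}{`promote` at >= 80% participation over the last
#'     `window = 5` consecutive trials; `remove` below 50% overall;
#'     otherwise `continue`.}
#'   \item{training}{evaluated once `min_trials = 9` choices are on record:
#'     `promote` above 80% success over the last `window = 6` consecutive
#'     trials, `remove` below 30% overall success, `continue` between 30 and
#'     80%.}
#'   \item{testing}{`include` in the analysis only when the natural-light
#'     success rate is strictly above 50%; otherwise `exclude` (the animal
#'     is judged to have failed to retain the association).}
#' }
#' Histories shorter than the decision window return `continue`
#' (insufficient evidence).
#'
#' @param history Logical vector, ordered in time: participation (priming),
#'   correctness (training), or natural-light correctness (testing),
#'   excluding reinforcement and no-choice trials.
#' @param stage `"priming"`, `"training"` or `"testing"`.
#' @param window Consecutive-trial window; defaults 5 (priming) / 6 (training).
#' @param min_trials Minimum training history before any decision, default 9.
#' @return `"promote"`, `"continue"` or `"remove"` for priming/training;
#'   `"include"` or `"exclude"` for testing.
#' @export
inclusion_filter <- function(history, stage = c("priming", "training", "testing"),
                             window = NULL, min_trials = 9) {
  stage <- match.arg(stage)
  history <- as.logical(history)
  n <- length(history)
  if (stage == "priming") {
    window <- window %||% 5
    if (n < window) return("continue")
    if (mean(utils::tail(history, window)) >= 0.8) return("promote")
    if (mean(history) < 0.5) return("remove")
    return("continue")
  }
  if (stage == "training") {
    window <- window %||% 6
    if (n < max(window, min_trials)) return("continue")
    if (mean(utils::tail(history, window)) > 0.8) return("promote")
    if (mean(history) < 0.3) return("remove")
    return("continue")
  }
  # testing
  if (n == 0) return("exclude")
  if (mean(history) > 0.5) "include" else "exclude"
}

#' Binomial logit mixed model of choice outcomes
#'
#' Fits the choice regression of the analysis stage: correct/incorrect as a
#' binomial outcome with logit link, fixed effects for illumination
#' condition, distractor combination and choice position, and a random
#' intercept per individual (multiple tests per animal). Delegates the fit to
#' `lme4::glmer()` behind this contract. Reinforcement and no-choice trials
#' are excluded.
#'
#' @param dataset A `choice_dataset` (testing-stage records are used).
#' @param fixed Character vector of fixed-effect columns; default
#'   `c("illumination", "combination", "choice_pos")`.
#' @param random Grouping column for the random intercept, default
#'   `"individual"`.
#' @return Object of class `"choice_model_fit"`: list with `coefficients`
#'   (tibble: term, estimate, std_error, z, p_value), `ranef_var`, `logLik`,
#'   `converged`, `n_obs`, `n_individuals` and the underlying `fit`.
#' @export
fit_choice_model <- function(dataset,
                             fixed = c("illumination", "combination",
                                       "choice_pos"),
                             random = "individual") {
  d <- analysable(dataset)
  d <- d[d$stage == "testing", , drop = FALSE]
  if (nrow(d) == 0) stop("no analysable testing trials")
  n_ind <- length(unique(d[[random]]))
  if (n_ind < 2) {
    stop("random intercept unidentifiable with a single individual")
  }
  # drop constant fixed effects (e.g. one illumination only)
  fixed <- fixed[vapply(fixed, function(f) length(unique(d[[f]])) > 1, TRUE)]
  rhs <- paste(c(if (length(fixed)) fixed else "1",
                 sprintf("(1 | %s)", random)), collapse = " + ")
  form <- stats::as.formula(paste("correct ~", rhs))
  fit <- lme4::glmer(form, data = d, family = stats::binomial("logit"))
  msgs <- fit@optinfo$conv$lme4$messages
  co <- summary(fit)$coefficients
  separated <- any(abs(co[, "Estimate"]) > 15) || any(co[, "Std. Error"] > 50)
  structure(list(
    coefficients = tibble::tibble(term = rownames(co),
                                  estimate = co[, "Estimate"],
                                  std_error = co[, "Std. Error"],
                                  z = co[, "z value"],
                                  p_value = co[, "Pr(>|z|)"]),
    ranef_var = unname(lme4::VarCorr(fit)[[random]][1, 1]),
    logLik = as.numeric(stats::logLik(fit)),
    converged = is.null(msgs) && !separated,
    separation_suspected = separated,
    messages = msgs %||% character(0),
    n_obs = nrow(d), n_individuals = n_ind, fit = fit),
    class = "choice_model_fit")
}

#' @export
print.choice_model_fit <- function(x, ...) {
  cat(sprintf("<choice_model_fit: %d obs, %d individuals, converged: %s>\n",
              x$n_obs, x$n_individuals, x$converged))
  print(x$coefficients)
  invisible(x)
}

#' Summarise a simulated or recorded experiment
#'
#' Produces the analysis surfaces of the study: per group x illumination
#' success rates with their chi-square tests (restricted to included
#' individuals), an inclusion ledger (entered / primed / trained / included
#' counts and the trainability percentage = included / entered), and, when
#' identifiable, the mixed-model fit per group.
#'
#' @param dataset A `choice_dataset` from [simulate_experiment()].
#' @param fit_models Fit per-group choice models? Default `TRUE`.
#' @return List of class `"gc_report"`: `group_summaries`,
#'   `inclusion_ledger`, `model_fits` (possibly empty list).
#' @export
summarize_experiment <- function(dataset, fit_models = TRUE) {
  fates <- attr(dataset, "fates")
  if (is.null(fates)) stop("dataset carries no per-individual fates")
  groups <- unique(fates$group)

  ledger <- dplyr::bind_rows(lapply(groups, function(g) {
    f <- fates[fates$group == g, ]
    entered <- nrow(f)
    included <- sum(f$fate == "included")
    tibble::tibble(
      group = g, n_entered = entered,
      n_primed = sum(!f$fate %in% "removed_priming"),
      n_trained = sum(f$fate %in% c("included", "excluded_testing")),
      n_included = included,
      n_excluded_testing = sum(f$fate == "excluded_testing"),
      trainability = round_half_up(100 * included / entered))
  }))

  summaries <- list()
  fits <- list()
  for (g in groups) {
    inc <- fates$individual[fates$group == g & fates$fate == "included"]
    conds <- unique(dataset$illumination[dataset$group == g &
                                           dataset$stage == "testing"])
    for (cond in conds) {
      summaries[[paste(g, cond)]] <-
        success_rate(dataset, group = g, illumination = cond,
                     individuals = inc)
    }
    if (fit_models && length(inc) >= 2) {
      fits[[g]] <- tryCatch(
        fit_choice_model(dataset[dataset$group == g &
                                   dataset$individual %in% inc, ]),
        error = function(e) e$message)
    }
  }
  structure(list(group_summaries = dplyr::bind_rows(summaries),
                 inclusion_ledger = ledger, model_fits = fits),
            class = "gc_report")
}

#' Write a report to CSV + JSON
#'
#' @param report A [summarize_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "gc_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "group_summaries.csv")
  p2 <- file.path(dir, "inclusion_ledger.csv")
  p3 <- file.path(dir, "model_fits.json")
  utils::write.csv(report$group_summaries, p1, row.names = FALSE)
  utils::write.csv(report$inclusion_ledger, p2, row.names = FALSE)
  fits <- lapply(report$model_fits, function(f) {
    if (is.character(f)) return(list(error = f))
    list(coefficients = f$coefficients, ranef_var = f$ranef_var,
         logLik = f$logLik, converged = f$converged)
  })
  jsonlite::write_json(fits, p3, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2, p3))
}
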