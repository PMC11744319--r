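# End-to-end orchestration: a single serialisable configuration drives
# fixture generation, catch/contrast tables, the behavioural simulation and
# the statistical report, written as CSV/JSON with a manifest.

#' Default run configuration
#'
#' A fully serialisable description of one end-to-end run; a run is
#' reproducible from the configuration plus its seed alone.
#'
#' @param seed Integer seed.
#' @param groups Individuals entering priming per colour group.
#' @param grid_start,grid_stop,grid_step Session grid (nm).
#' @param activation_threshold Normalised-catch threshold for row activation.
#' @param high_cd Annotation threshold for "high" contrast, default 0.5.
#' @param chooser List of [chooser_params()] arguments.
#' @param testing_days Testing-stage length in days.
#' @return A named list of class `"run_config"`.
#' @export
run_config <- function(seed = 1L, groups = c(blue = 8, green = 8, red = 8),
                       grid_start = 300, grid_stop = 750, grid_step = 1,
                       activation_threshold = 0.05, high_cd = 0.5,
                       chooser = list(), testing_days = 12) {
  structure(list(seed = as.integer(seed), groups = groups,
                 grid_start = grid_start, grid_stop = grid_stop,
                 grid_step = grid_step,
                 activation_threshold = activation_threshold,
                 high_cd = high_cd, chooser = chooser,
                 testing_days = testing_days),
            class = "run_config")
}

#' Validate a run configuration
#'
#' Schema and cross-field checks. Findings are returned, never thrown:
#' non-standard optical densities or thresholds are warnings (the pipeline is
#' extensible), whereas inconsistent grids or empty group lists are errors.
#'
#' @param config A [run_config()] (or plain list with the same fields).
#' @return Tibble with columns `level` (`"error"`/`"warning"`) and `message`;
#'   zero rows when the configuration is clean.
#' @export
validate_config <- function(config) {
  findings <- list()
  note <- function(level, message) {
    findings[[length(findings) + 1L]] <<-
      tibble::tibble(level = level, message = message)
  }
  if (is.null(config$grid_start) || is.null(config$grid_stop) ||
      config$grid_start >= config$grid_stop) {
    note("error", "grid start must be below grid stop")
  }
  if (!is.null(config$grid_step) && config$grid_step <= 0) {
    note("error", "grid step must be positive")
  }
  if (is.null(config$groups) || length(config$groups) == 0) {
    note("error", "groups list is empty")
  } else if (any(config$groups < 1)) {
    note("error", "every group needs at least one individual")
  }
  thr <- config$activation_threshold
  if (!is.null(thr) && (thr < 0 || thr > 1)) {
    note("error", "activation threshold must be in [0, 1]")
  }
  if (!is.null(config$extra_ods)) {
    odd <- setdiff(config$extra_ods, GREY_ODS)
    if (length(odd)) {
      note("warning", paste("non-standard optical density:",
                            paste(odd, collapse = ", ")))
    }
  }
  if (length(findings) == 0) {
    return(tibble::tibble(level = character(0), message = character(0)))
  }
  dplyr::bind_rows(findings)
}

#' Run the whole pipeline
#'
#' Executes fixtures -> catches/contrasts -> simulation -> analysis and
#' writes every table under `out_dir`: the spectral fixture library,
#' normalised catch tables and per-row contrast differences for each colour
#' group under natural light and its own tent (the figure-style surfaces),
#' the simulated trial records, the statistical report, and a manifest
#' recording the seed and configuration. Identical configuration + seed give
#' identical outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return Invisibly, `out_dir`.
#' @export
run_all <- function(config = run_config(), out_dir) {
  fnd <- validate_config(config)
  if (any(fnd$level == "error")) {
    stop("invalid configuration: ", paste(fnd$message[fnd$level == "error"],
                                          collapse = "; "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- wl_grid(config$grid_start, config$grid_stop, config$grid_step)

  write_fixture_library(file.path(out_dir, "spectra"), grid)

  retina <- build_retina(grid = grid)
  world <- grey_card_world(retina, grid,
                           activation_threshold = config$activation_threshold)

  catches <- dplyr::bind_rows(lapply(world$tables, catch_table_tidy))
  utils::write.csv(catches, file.path(out_dir, "catch_tables.csv"),
                   row.names = FALSE)

  cd_rows <- list()
  for (group in c("blue", "green", "red")) {
    for (il in c("natural", paste0("tent_", group))) {
      pt <- world$profiles[[paste(group, il, sep = "|")]]
      for (od in GREY_ODS) {
        gk <- sprintf("grey_%g", od)
        cdt <- contrast_difference(pt, world$profiles[[paste(gk, il, sep = "|")]])
        act <- intersect(world$active[[paste(group, il, sep = "|")]],
                         world$active[[paste(gk, il, sep = "|")]])
        cd_rows[[paste(group, il, gk)]] <- tibble::tibble(
          group = group, illumination = il, distractor = gk, row = 1:4,
          cd = unname(cdt$cd), abs_cd = unname(cdt$abs_cd),
          active = 1:4 %in% act,
          high = !is.na(cdt$abs_cd) & cdt$abs_cd > config$high_cd)
      }
    }
  }
  utils::write.csv(dplyr::bind_rows(cd_rows),
                   file.path(out_dir, "contrast_differences.csv"),
                   row.names = FALSE)

  design <- experiment_design(groups = config$groups,
                              testing_days = config$testing_days)
  chooser <- do.call(chooser_params, config$chooser)
  trials <- simulate_experiment(design, chooser, seed = config$seed,
                                world = world)
  utils::write.csv(trials, file.path(out_dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(attr(trials, "fates"), file.path(out_dir, "fates.csv"),
                   row.names = FALSE)

  report <- summarize_experiment(trials)
  write_report(report, file.path(out_dir, "report"))

  manifest <- list(
    package = "stomaspec",
    seed = config$seed,
    config = unclass(config),
    normalization_reference = list(channel = "R2P", stimulus = "grey_0.15",
                                   illuminant = "natural"),
    config_hash = sum(utf8ToInt(paste(deparse(unclass(config)),
                                      collapse = ""))),
    r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
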