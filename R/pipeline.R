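#' Run configuration for the analysis pipeline
#'
#' Every analysis decision of the pipeline — cutoffs, ratio mode, FPM
#' counting unit, test directions, outcome grids, required recall days —
#' surfaces here as a named, serialisable setting with its documented
#' default, so an alternative reading of any convention is one config change
#' away.
#'
#' @param composition,recalls,hematology Input CSV paths (may be `NULL` when
#'   the run simulates its own cohort).
#' @param cutoffs [fpm_cutoffs()].
#' @param counting_mode FPM counting unit, `"instances"` (default) or
#'   `"unique_foods"`.
#' @param directions Named map of variable to `"enhancer"`/`"inhibitor"`.
#' @param grids Named list of [outcome_grid()]s.
#' @param required_days Minimum recall days per participant.
#' @param sim [sim_config()] used by [fpm_simulate()].
#' @return A list of class `fpm_run_config`.
#' @export
run_config <- function(composition = NULL, recalls = NULL, hematology = NULL,
                       cutoffs = fpm_cutoffs(),
                       counting_mode = c("instances", "unique_foods"),
                       directions = DEFAULT_DIRECTIONS,
                       grids = default_outcome_grids(),
                       required_days = 3,
                       sim = sim_config()) {
  counting_mode <- match.arg(counting_mode)
  stopifnot(inherits(cutoffs, "fpm_cutoffs"))
  if (!all(sort(names(directions)) == sort(FPM_VARIABLES)) ||
      !all(directions %in% c("enhancer", "inhibitor"))) {
    abort("directions must map iron, ascorbic, phytate, ratio to enhancer/inhibitor",
          class = "fpmiron_invalid_config")
  }
  structure(
    list(composition = composition, recalls = recalls, hematology = hematology,
         cutoffs = cutoffs, counting_mode = counting_mode,
         directions = directions, grids = grids,
         required_days = required_days, sim = sim),
    class = "fpm_run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Reads a key-value YAML file holding any subset of the [run_config()]
#' settings; unspecified keys keep their defaults, unknown keys are an
#' error. Nested blocks: `cutoffs` (`iron`, `ascorbic`, `phytate`, `ratio`,
#' `ratio_mode`), `grids` (`<outcome>: {start, stop, step}`), `sim` (any
#' [sim_config()] argument), `directions` (`<variable>: enhancer|inhibitor`).
#'
#' @param path YAML file path.
#' @return An `fpm_run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("composition", "recalls", "hematology", "cutoffs",
             "counting_mode", "directions", "grids", "required_days", "sim")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "fpmiron_invalid_config")
  }
  args <- raw[intersect(names(raw), c("composition", "recalls", "hematology",
                                      "counting_mode", "required_days"))]
  if (!is.null(raw$cutoffs)) {
    args$cutoffs <- do.call(fpm_cutoffs, raw$cutoffs)
  }
  if (!is.null(raw$directions)) {
    d <- DEFAULT_DIRECTIONS
    d[names(raw$directions)] <- unlist(raw$directions)
    args$directions <- d
  }
  if (!is.null(raw$grids)) {
    g <- default_outcome_grids()
    for (nm in names(raw$grids)) {
      g[[nm]] <- do.call(outcome_grid, c(list(outcome = nm), raw$grids[[nm]]))
    }
    args$grids <- g
  }
  if (!is.null(raw$sim)) {
    sim_args <- raw$sim
    if (!is.null(sim_args$p_high)) sim_args$p_high <- unlist(sim_args$p_high)
    if (!is.null(sim_args$beta)) sim_args$beta <- unlist(sim_args$beta)
    args$sim <- do.call(sim_config, sim_args)
  }
  do.call(run_config, args)
}

strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else x
}

provenance_block <- function(config, seed, counts) {
  cfg <- strip_classes(config)
  list(
    package = "fpmiron",
    package_version = as.character(packageVersion("fpmiron")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    config = cfg,
    row_counts = counts
  )
}

write_provenance <- function(out_dir, stage, config, seed, counts) {
  path <- file.path(out_dir, paste0(stage, "_provenance.json"))
  jsonlite::write_json(provenance_block(config, seed, counts), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Simulate a cohort to disk
#'
#' Generates a synthetic cohort under `config$sim` (optionally overriding
#' its seed) and writes the three input CSVs plus ground truth and a
#' provenance block into `out_dir`.
#'
#' @param config An [run_config()].
#' @param out_dir Output directory.
#' @param seed Optional seed overriding `config$sim$seed`.
#' @return Invisibly, the named vector of written paths.
#' @export
fpm_simulate <- function(config = run_config(), out_dir, seed = NULL) {
  stopifnot(inherits(config, "fpm_run_config"))
  sim <- config$sim
  if (!is.null(seed)) {
    sim$seed <- seed
    validate_sim_config(sim)
  }
  cohort <- generate_cohort(sim, quiet = TRUE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- write_cohort(cohort, out_dir)
  prov <- write_provenance(out_dir, "simulate", config, sim$seed, list(
    foods = nrow(cohort$foods),
    recall_items = nrow(cohort$recalls),
    participants = nrow(cohort$panels)
  ))
  invisible(c(paths, provenance = prov))
}

#' Score a cohort into per-participant profiles
#'
#' Loads the composition and recall CSVs named in the config, builds the
#' MIE and FPM profiles, and writes `profiles.csv` plus a provenance block.
#'
#' @param config An [run_config()] with `composition` and `recalls` paths
#'   set.
#' @param out_dir Output directory.
#' @return The profile tibble, invisibly.
#' @export
fpm_score <- function(config, out_dir) {
  stopifnot(inherits(config, "fpm_run_config"))
  if (is.null(config$composition) || is.null(config$recalls)) {
    abort("config must name composition and recalls CSVs",
          class = "fpmiron_invalid_config")
  }
  foods <- read_composition(config$composition)
  items <- read_recalls(config$recalls)
  n_before <- dplyr::n_distinct(items$participant_id)
  profiles <- build_profiles(items, foods, cutoffs = config$cutoffs,
                             required_days = config$required_days,
                             counting_mode = config$counting_mode)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  readr::write_csv(profiles, file.path(out_dir, "profiles.csv"))
  write_provenance(out_dir, "score", config, NA, list(
    participants_in = n_before,
    participants_retained = nrow(profiles),
    recall_items = nrow(items)
  ))
  invisible(profiles)
}

#' Compare assessment methods on a scored cohort
#'
#' Loads profiles and hematology panels, runs [compare_methods()], and
#' writes the accuracy summary (`comparison.csv`, one row per outcome x
#' variable x method), the tidy ROC points (`roc_points.csv`) and optional
#' per-outcome ROC figures.
#'
#' @param config An [run_config()] with `hematology` set.
#' @param profiles Profile tibble or path to a `profiles.csv`.
#' @param out_dir Output directory.
#' @param plots Also render `roc_<outcome>.pdf` figures.
#' @return The `fpm_comparison`, invisibly.
#' @export
fpm_compare <- function(config, profiles, out_dir, plots = FALSE) {
  stopifnot(inherits(config, "fpm_run_config"))
  if (is.null(config$hematology)) {
    abort("config must name the hematology CSV", class = "fpmiron_invalid_config")
  }
  if (is.character(profiles)) {
    profiles <- readr::read_csv(profiles, col_types = readr::cols(
      participant_id = readr::col_character(), .default = readr::col_double()))
  }
  panels <- read_hematology(config$hematology)
  comparison <- compare_methods(profiles, panels, grids = config$grids,
                                directions = config$directions, quiet = TRUE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  readr::write_csv(comparison$summary, file.path(out_dir, "comparison.csv"))
  readr::write_csv(comparison$roc, file.path(out_dir, "roc_points.csv"))
  if (plots) {
    for (oc in unique(comparison$roc$outcome)) {
      ggplot2::ggsave(file.path(out_dir, paste0("roc_", oc, ".pdf")),
                      plot_roc(comparison, oc), width = 7, height = 6)
    }
  }
  write_provenance(out_dir, "compare", config, NA, list(
    participants = nrow(profiles),
    summary_rows = nrow(comparison$summary),
    roc_points = nrow(comparison$roc)
  ))
  invisible(comparison)
}
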