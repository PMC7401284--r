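#' Simulation configuration for synthetic cohorts
#'
#' Bundles every knob of the cohort generator. Defaults emulate a small
#' premenopausal-women meal-challenge cohort: 27 participants with three 24 h
#' recalls each, about 9.6 +/- 2.8 foods per day, hemoglobin 13.1 +/- 1.0
#' g/dL, ferritin 30.3 +/- 15.1, acute absorption 14.4 +/- 26.0% (clamped to
#' \[0, 100\]), and a food supply whose high-density fractions put cohort FPM
#' densities and mean intakes in the range such recall studies report.
#'
#' The diet-biomarker link is linear-Gaussian: each biomarker equals
#' `baseline + sum_v beta_v * z_v + sd * e` with `z_v` the participant's
#' standard-normal latent preference for variable `v` and `e` standard
#' normal noise. Effect sizes `beta` are in absolute outcome units per
#' latent-SD, so with all `beta = 0` the biomarkers are independent of diet
#' and their marginals equal the configured baseline/SD exactly; with noise
#' 0 a biomarker is a deterministic increasing function of the
#' beta-weighted diet score. The marginal SD for nonzero effects is
#' `sqrt(sd^2 + sum_v beta_v^2)`.
#'
#' @param n_participants,n_days Cohort dimensions.
#' @param seed Integer seed; the same seed reproduces the cohort bitwise.
#'   Internal stages use `seed + 0..3`, so seeds should stay below
#'   `2^31 - 4`.
#' @param n_foods_in_table Number of foods in the generated composition
#'   table.
#' @param foods_per_day_mean,foods_per_day_sd Items per participant-day,
#'   drawn from a rounded normal truncated below at 1.
#' @param portion_meanlog,portion_sdlog Log-normal portion size (g).
#' @param p_high Named fractions of high-density foods for `iron`,
#'   `ascorbic`, `phytate` (the ratio class emerges from the iron and
#'   phytate contents).
#' @param content Named list of per-nutrient log-normal content parameters
#'   (`meanlog_high`, `sdlog_high`, `meanlog_low`, `sdlog_low`, mg/100 g);
#'   each class is truncated to its side of the cutoff so the cutoffs
#'   separate the mixture components exactly.
#' @param pref_sd Scale of the latent preference in the food-sampling
#'   weights `exp(pref_sd * sum_v z_v * is_high_v(food))`.
#' @param beta Named effect sizes (outcome units per latent-SD, applied to
#'   every biomarker) for `iron`, `ascorbic`, `phytate`, `ratio`.
#' @param hemoglobin_mean,hemoglobin_sd,ferritin_mean,ferritin_sd,absorption_mean,absorption_sd
#'   Biomarker marginal parameters.
#' @param cutoffs [fpm_cutoffs()] used both for generating the mixture and
#'   downstream.
#' @return A list of class `fpm_sim_config`.
#' @export
sim_config <- function(n_participants = 27,
                       n_days = 3,
                       seed = 20200628,
                       n_foods_in_table = 120,
                       foods_per_day_mean = 9.6,
                       foods_per_day_sd = 2.8,
                       portion_meanlog = log(120),
                       portion_sdlog = 0.5,
                       p_high = c(iron = 0.50, ascorbic = 0.07, phytate = 0.20),
                       content = default_content_params(),
                       pref_sd = 1,
                       beta = c(iron = 0.5, ascorbic = 0.25,
                                phytate = -0.25, ratio = -0.4),
                       hemoglobin_mean = 13.1, hemoglobin_sd = 1.0,
                       ferritin_mean = 30.3, ferritin_sd = 15.1,
                       absorption_mean = 14.4, absorption_sd = 26.0,
                       cutoffs = fpm_cutoffs()) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  structure(cfg, class = "fpm_sim_config")
}

#' @rdname sim_config
#' @export
default_content_params <- function() {
  list(
    iron = list(meanlog_high = log(1.5), sdlog_high = 0.7,
                meanlog_low = log(0.2), sdlog_low = 0.6),
    ascorbic = list(meanlog_high = log(30), sdlog_high = 0.5,
                    meanlog_low = log(1.2), sdlog_low = 1.2),
    phytate = list(meanlog_high = log(175), sdlog_high = 0.6,
                   meanlog_low = log(3), sdlog_low = 1.5)
  )
}

validate_sim_config <- function(cfg, call = rlang::caller_env()) {
  bad <- function(msg) abort(paste0("invalid simulation config: ", msg),
                             class = "fpmiron_invalid_config", call = call)
  if (!is.numeric(cfg$n_participants) || cfg$n_participants < 1) bad("n_participants")
  if (!is.numeric(cfg$n_days) || cfg$n_days < 1) bad("n_days")
  if (!is.numeric(cfg$seed) || !is.finite(cfg$seed) ||
      cfg$seed != round(cfg$seed) || abs(cfg$seed) >= 2^31 - 4) bad("seed")
  if (cfg$n_foods_in_table < 2) bad("n_foods_in_table must be >= 2")
  sds <- c(cfg$foods_per_day_sd, cfg$portion_sdlog, cfg$hemoglobin_sd,
           cfg$ferritin_sd, cfg$absorption_sd, cfg$pref_sd)
  if (any(!is.finite(sds)) || any(sds < 0)) bad("all sds must be >= 0")
  if (cfg$foods_per_day_mean < 1) bad("foods_per_day_mean must be >= 1")
  if (!all(c("iron", "ascorbic", "phytate") %in% names(cfg$p_high)) ||
      any(cfg$p_high < 0) || any(cfg$p_high > 1)) {
    bad("p_high must give fractions in [0,1] for iron, ascorbic, phytate")
  }
  if (!all(FPM_VARIABLES %in% names(cfg$beta))) {
    bad("beta must name iron, ascorbic, phytate, ratio")
  }
  if (!inherits(cfg$cutoffs, "fpm_cutoffs")) bad("cutoffs")
  invisible(cfg)
}

# Log-normal draw truncated to one side of a cutoff (rejection sampling;
# the default parameters put most mass on the right side already).
rlnorm_side <- function(n, meanlog, sdlog, cutoff, side) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    draw <- rlnorm(length(need), meanlog, sdlog)
    ok <- if (side == "high") draw > cutoff else draw <= cutoff
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Generate a synthetic food composition table
#'
#' Each nutrient content is drawn from a two-component log-normal mixture:
#' with probability `p_high` the food is a high-density food (content
#' truncated above the cutoff), otherwise low (truncated at or below it).
#' The realised high fractions, including the emergent phytate:iron ratio
#' class, are reported.
#'
#' @param config An [sim_config()].
#' @param quiet Suppress the realised-fraction report.
#' @return A composition tibble in the [read_composition()] dialect.
#' @export
generate_composition <- function(config, quiet = FALSE) {
  validate_sim_config(config)
  withr::with_seed(config$seed, {
    n <- config$n_foods_in_table
    cut <- config$cutoffs
    draw_nutrient <- function(nutrient, cutoff) {
      p <- config$p_high[[nutrient]]
      par <- config$content[[nutrient]]
      is_high <- stats::runif(n) < p
      x <- numeric(n)
      x[is_high] <- rlnorm_side(sum(is_high), par$meanlog_high,
                                par$sdlog_high, cutoff, "high")
      x[!is_high] <- rlnorm_side(sum(!is_high), par$meanlog_low,
                                 par$sdlog_low, cutoff, "low")
      x
    }
    foods <- tibble::tibble(
      food_id = sprintf("F%04d", seq_len(n)),
      name = sprintf("synthetic food %d", seq_len(n)),
      iron_mg_per_100g = draw_nutrient("iron", cut$iron),
      ascorbic_mg_per_100g = draw_nutrient("ascorbic", cut$ascorbic),
      phytate_mg_per_100g = draw_nutrient("phytate", cut$phytate)
    )
    if (!quiet) {
      labels <- categorize_foods(foods, cut)
      fr <- vapply(FPM_VARIABLES, function(v) mean(labels[[v]] == "high"),
                   numeric(1))
      inform(sprintf(
        "composition table: realised high fractions iron %.2f, ascorbic %.2f, phytate %.2f, ratio %.2f",
        fr["iron"], fr["ascorbic"], fr["phytate"], fr["ratio"]))
    }
    foods
  })
}

#' Latent diet preference scores
#'
#' One independent standard-normal score per participant and variable; a
#' participant's scores tilt their food sampling toward (positive) or away
#' from (negative) high-density foods for that variable, and drive the
#' biomarkers through the configured effect sizes. Retained as ground truth
#' for parameter-recovery tests.
#'
#' @param config An [sim_config()].
#' @return Tibble: `participant_id`, `z_iron`, `z_ascorbic`, `z_phytate`,
#'   `z_ratio`.
#' @export
generate_latent <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed + 1L, {
    n <- config$n_participants
    tibble::tibble(
      participant_id = sprintf("P%04d", seq_len(n)),
      z_iron = rnorm(n), z_ascorbic = rnorm(n),
      z_phytate = rnorm(n), z_ratio = rnorm(n)
    )
  })
}

#' Generate item-level recall records
#'
#' For every participant-day an item count is drawn from a rounded normal
#' truncated below at 1, then foods are sampled with replacement with
#' weights `exp(pref_sd * sum_v z_v * is_high_v(food))` and log-normal
#' portion sizes. The latent scores are the ground-truth diet signal of
#' which the FPM density is the noisy observable.
#'
#' @param config An [sim_config()].
#' @param foods Composition tibble (typically [generate_composition()]).
#' @param latent Latent score tibble; drawn via [generate_latent()] when
#'   `NULL`.
#' @return Recall item tibble in the [read_recalls()] dialect.
#' @export
generate_recalls <- function(config, foods, latent = NULL) {
  validate_sim_config(config)
  validate_composition(foods)
  latent <- latent %||% generate_latent(config)
  labels <- categorize_foods(foods, config$cutoffs)
  high <- as.matrix(labels[FPM_VARIABLES] == "high") * 1  # foods x variables
  zmat <- as.matrix(latent[paste0("z_", FPM_VARIABLES)])  # participants x variables
  log_w <- config$pref_sd * zmat %*% t(high)              # participants x foods

  withr::with_seed(config$seed + 2L, {
    per_day <- tidyr::expand_grid(
      pid_row = seq_len(config$n_participants),
      day_index = seq_len(config$n_days)
    )
    n_items <- pmax(1L, as.integer(round(
      rnorm(nrow(per_day), config$foods_per_day_mean, config$foods_per_day_sd))))
    rows <- purrr::pmap(
      list(per_day$pid_row, per_day$day_index, n_items),
      function(pid_row, day_index, k) {
        w <- exp(log_w[pid_row, ])
        idx <- sample.int(nrow(foods), k, replace = TRUE, prob = w)
        tibble::tibble(
          participant_id = latent$participant_id[pid_row],
          day_index = as.integer(day_index),
          food_id = foods$food_id[idx],
          grams_consumed = rlnorm(k, config$portion_meanlog, config$portion_sdlog)
        )
      })
    dplyr::bind_rows(rows)
  })
}

#' Generate hematology panels from latent diet scores
#'
#' Linear-Gaussian outcome model (see [sim_config()]): each biomarker is its
#' baseline plus the beta-weighted sum of the participant's standardised
#' latent scores plus Gaussian noise at the configured SD; ferritin is
#' clamped at 0 and absorption to \[0, 100\].
#'
#' @param config An [sim_config()].
#' @param latent Latent score tibble from [generate_latent()].
#' @return Hematology tibble in the [read_hematology()] dialect.
#' @export
generate_hematology <- function(config, latent) {
  validate_sim_config(config)
  beta <- config$beta[FPM_VARIABLES]
  zmat <- as.matrix(latent[paste0("z_", FPM_VARIABLES)])
  signal <- as.numeric(zmat %*% beta)
  n <- nrow(latent)
  withr::with_seed(config$seed + 3L, {
    draw <- function(mean, sd) mean + signal + sd * rnorm(n)
    tibble::tibble(
      participant_id = latent$participant_id,
      hemoglobin_g_dl = pmax(draw(config$hemoglobin_mean, config$hemoglobin_sd), 0.1),
      ferritin_ng_dl = pmax(draw(config$ferritin_mean, config$ferritin_sd), 0),
      absorption_pct = pmin(pmax(draw(config$absorption_mean, config$absorption_sd), 0), 100)
    )
  })
}

#' Generate a complete synthetic cohort
#'
#' Composes the composition, latent-score, recall and hematology generators
#' into one reproducible cohort object.
#'
#' @param config An [sim_config()].
#' @param quiet Suppress generator reports.
#' @return A list of class `fpm_cohort`: `foods`, `recalls`, `panels`,
#'   `latent` (ground truth), `config`.
#' @examples
#' cohort <- generate_cohort(sim_config(n_participants = 8, seed = 1), quiet = TRUE)
#' nrow(cohort$panels)
#' @export
generate_cohort <- function(config = sim_config(), quiet = FALSE) {
  validate_sim_config(config)
  foods <- generate_composition(config, quiet = quiet)
  latent <- generate_latent(config)
  recalls <- generate_recalls(config, foods, latent)
  panels <- generate_hematology(config, latent)
  structure(
    list(foods = foods, recalls = recalls, panels = panels,
         latent = latent, config = config),
    class = "fpm_cohort"
  )
}

#' Write a synthetic cohort to CSV files
#'
#' Writes `composition.csv`, `recalls.csv`, `hematology.csv`, `latent.csv`
#' and a `metadata.json` provenance block (config echo including the seed,
#' package version, row counts) into a directory.
#'
#' @param cohort An `fpm_cohort` from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fpm_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    composition = file.path(dir, "composition.csv"),
    recalls = file.path(dir, "recalls.csv"),
    hematology = file.path(dir, "hematology.csv"),
    latent = file.path(dir, "latent.csv"),
    metadata = file.path(dir, "metadata.json")
  )
  readr::write_csv(cohort$foods, paths["composition"])
  readr::write_csv(cohort$recalls, paths["recalls"])
  readr::write_csv(cohort$panels, paths["hematology"])
  readr::write_csv(cohort$latent, paths["latent"])
  cfg <- strip_classes(cohort$config)
  jsonlite::write_json(
    list(
      generator = "fpmiron::generate_cohort",
      package_version = as.character(packageVersion("fpmiron")),
      seed = cohort$config$seed,
      config = cfg,
      n_foods = nrow(cohort$foods),
      n_recall_items = nrow(cohort$recalls),
      n_participants = nrow(cohort$panels)
    ),
    paths["metadata"], auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}
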