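#' Read item-level 24 h recall records
#'
#' Reads a recall CSV with header
#' `participant_id,day_index,food_id,grams_consumed`, one row per eaten item
#' — a simplified stand-in for item-level ASA24-style exports. Every
#' `grams_consumed` must be finite and strictly positive and every
#' `day_index` a positive integer.
#'
#' @param path Path to the CSV file.
#' @return A tibble of recall items.
#' @export
read_recalls <- function(path) {
  items <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      day_index = readr::col_integer(),
      food_id = readr::col_character(),
      grams_consumed = readr::col_double()
    )
  )
  validate_recalls(items)
  items
}

validate_recalls <- function(items, call = rlang::caller_env()) {
  required <- c("participant_id", "day_index", "food_id", "grams_consumed")
  missing_cols <- setdiff(required, names(items))
  if (length(missing_cols) > 0) {
    abort(paste0("recall table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "fpmiron_parse_error", call = call)
  }
  bad <- which(!is.finite(items$grams_consumed) | items$grams_consumed <= 0)
  if (length(bad) > 0) {
    abort(sprintf("grams_consumed must be finite and > 0; bad row(s): %s",
                  paste(bad, collapse = ", ")),
          class = "fpmiron_parse_error", call = call)
  }
  bad_day <- which(!is.finite(items$day_index) | items$day_index < 1 |
                     items$day_index != round(items$day_index))
  if (length(bad_day) > 0) {
    abort(sprintf("day_index must be an integer >= 1; bad row(s): %s",
                  paste(bad_day, collapse = ", ")),
          class = "fpmiron_parse_error", call = call)
  }
  invisible(items)
}

# Fail loudly when a recall references a food absent from the composition
# table: a silently dropped item would bias every intake below.
check_food_ids <- function(items, foods, call = rlang::caller_env()) {
  unknown <- setdiff(unique(items$food_id), foods$food_id)
  if (length(unknown) > 0) {
    days <- items |>
      dplyr::filter(.data$food_id %in% unknown) |>
      dplyr::distinct(.data$food_id, .data$day_index)
    abort(paste0(
      "recall item(s) reference food_id(s) absent from the composition table: ",
      paste(sprintf("%s (day %d)", days$food_id, days$day_index), collapse = ", ")
    ), class = "fpmiron_unresolved_food", call = call)
  }
  invisible(items)
}

#' Per-day nutrient totals from recall items
#'
#' Sums iron, ascorbic acid and phytate (mg) over all items of each
#' participant-day: each item contributes
#' `grams_consumed * content_per_100g / 100`. Days present in the recall
#' table but with no items cannot occur (the table is item-level); an empty
#' input yields an empty result with a warning.
#'
#' @param items Recall item tibble ([read_recalls()]).
#' @param foods Composition tibble ([read_composition()]).
#' @return A tibble with one row per `participant_id` x `day_index`:
#'   `iron_mg`, `ascorbic_mg`, `phytate_mg`, `n_items`.
#' @examples
#' foods <- tibble::tibble(
#'   food_id = "a", name = "x", iron_mg_per_100g = 0.35,
#'   ascorbic_mg_per_100g = 0, phytate_mg_per_100g = 0
#' )
#' items <- tibble::tibble(
#'   participant_id = "p1", day_index = 1L, food_id = "a", grams_consumed = 200
#' )
#' daily_intake(items, foods) # 0.70 mg iron
#' @export
daily_intake <- function(items, foods) {
  validate_recalls(items)
  validate_composition(foods)
  if (nrow(items) == 0) {
    warn("no recall items: returning empty intake table")
    return(tibble::tibble(
      participant_id = character(), day_index = integer(),
      iron_mg = numeric(), ascorbic_mg = numeric(), phytate_mg = numeric(),
      n_items = integer()
    ))
  }
  check_food_ids(items, foods)
  items |>
    dplyr::inner_join(foods, by = "food_id") |>
    dplyr::group_by(.data$participant_id, .data$day_index) |>
    dplyr::summarise(
      iron_mg = sum(.data$grams_consumed * .data$iron_mg_per_100g / 100),
      ascorbic_mg = sum(.data$grams_consumed * .data$ascorbic_mg_per_100g / 100),
      phytate_mg = sum(.data$grams_consumed * .data$phytate_mg_per_100g / 100),
      n_items = dplyr::n(),
      .groups = "drop"
    )
}

#' Phytate:iron ratio of mean intakes
#'
#' The participant-level ratio of average phytate to average iron intake.
#' Unlike the per-food ratio, a zero mean iron intake is an error here — a
#' participant who ate for several days cannot have consumed literally no
#' iron, so a zero denominator signals a data problem rather than a
#' boundary case.
#'
#' @param mean_phytate_mg,mean_iron_mg Mean daily intakes (mg/day).
#' @inheritParams food_ratio
#' @return Dimensionless ratio (vectorised).
#' @examples
#' participant_ratio(669.6, 14.7, "molar") # 3.854
#' participant_ratio(669.6, 14.7, "mass")  # 45.55
#' @export
participant_ratio <- function(mean_phytate_mg, mean_iron_mg,
                              mode = c("molar", "mass")) {
  mode <- match.arg(mode)
  if (any(!is.finite(mean_phytate_mg)) || any(!is.finite(mean_iron_mg)) ||
      any(mean_phytate_mg < 0) || any(mean_iron_mg < 0)) {
    abort("mean intakes must be finite and non-negative",
          class = "fpmiron_invalid_input")
  }
  if (any(mean_iron_mg == 0)) {
    abort("phytate:iron ratio undefined for zero mean iron intake",
          class = "fpmiron_undefined_ratio")
  }
  if (mode == "molar") {
    (mean_phytate_mg / MW_PHYTATE) / (mean_iron_mg / MW_IRON)
  } else {
    mean_phytate_mg / mean_iron_mg
  }
}

#' Food-pattern-modeling nutrient density for one participant
#'
#' The FPM score of a diet for one variable is the fraction of consumed
#' foods labeled "high" for that variable: portions and frequencies are
#' deliberately ignored. `counting_mode = "instances"` (default) counts
#' every eaten item across all recall days; `"unique_foods"` deduplicates by
#' `food_id` first, scoring the participant's food inventory instead of
#' their consumption stream.
#'
#' @param items Recall items for a single participant (all days).
#' @param foods Composition tibble.
#' @param cutoffs [fpm_cutoffs()].
#' @param counting_mode `"instances"` or `"unique_foods"`.
#' @return Named numeric vector of densities in \[0, 1\], one per variable.
#' @examples
#' foods <- tibble::tibble(
#'   food_id = c("hi", "lo"), name = c("beef", "rice"),
#'   iron_mg_per_100g = c(2.6, 0.2), ascorbic_mg_per_100g = 0,
#'   phytate_mg_per_100g = 0
#' )
#' items <- tibble::tibble(
#'   participant_id = "p", day_index = c(1L, 1L, 2L, 2L),
#'   food_id = c("hi", "lo", "hi", "lo"), grams_consumed = 100
#' )
#' fpm_density(items, foods)["iron"] # 0.5
#' @export
fpm_density <- function(items, foods, cutoffs = fpm_cutoffs(),
                        counting_mode = c("instances", "unique_foods")) {
  counting_mode <- match.arg(counting_mode)
  validate_recalls(items)
  if (nrow(items) == 0) {
    abort("cannot compute a food-pattern density from zero foods",
          class = "fpmiron_invalid_input")
  }
  if (dplyr::n_distinct(items$participant_id) != 1L) {
    abort("fpm_density() expects items for a single participant",
          class = "fpmiron_invalid_input")
  }
  check_food_ids(items, foods)
  labels <- categorize_foods(foods, cutoffs)
  counted <- if (counting_mode == "unique_foods") {
    dplyr::distinct(items, .data$food_id)
  } else {
    items["food_id"]
  }
  eaten <- dplyr::inner_join(counted, labels, by = "food_id")
  vapply(FPM_VARIABLES, function(v) mean(eaten[[v]] == "high"), numeric(1))
}

#' Build per-participant assessment profiles
#'
#' Turns an item-level recall table into the two competing variable sets per
#' participant: mean dietary intake estimates (MIE; mg/day for iron,
#' ascorbic acid, phytate, plus the ratio of mean phytate to mean iron) and
#' food-pattern-modeling densities (FPM; fraction of consumed foods with
#' high density per variable). Participants with fewer than `required_days`
#' distinct recall days are excluded, mirroring the usual completeness
#' filter for multi-day recall studies; exclusions are reported via a
#' message.
#'
#' @param items Recall item tibble for the whole cohort.
#' @param foods Composition tibble.
#' @param cutoffs [fpm_cutoffs()]; its `ratio_mode` also governs the MIE
#'   ratio so both methods share one convention.
#' @param required_days Minimum number of distinct recall days (default 3).
#' @param counting_mode Passed to the FPM score; see [fpm_density()].
#' @return A tibble with one row per retained participant:
#'   `participant_id`, `n_days`, `n_foods_total`, `mie_iron_mg_day`,
#'   `mie_ascorbic_mg_day`, `mie_phytate_mg_day`, `mie_ratio`, `fpm_iron`,
#'   `fpm_ascorbic`, `fpm_phytate`, `fpm_ratio`.
#' @export
build_profiles <- function(items, foods, cutoffs = fpm_cutoffs(),
                           required_days = 3,
                           counting_mode = c("instances", "unique_foods")) {
  counting_mode <- match.arg(counting_mode)
  validate_recalls(items)
  validate_composition(foods)
  if (nrow(items) == 0) {
    abort("empty recall table", class = "fpmiron_empty_cohort")
  }
  check_food_ids(items, foods)

  days_per_pid <- items |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(n_days = dplyr::n_distinct(.data$day_index), .groups = "drop")
  keep <- days_per_pid$participant_id[days_per_pid$n_days >= required_days]
  n_excluded <- nrow(days_per_pid) - length(keep)
  if (n_excluded > 0) {
    inform(sprintf(
      "excluded %d of %d participant(s) with fewer than %d recall days",
      n_excluded, nrow(days_per_pid), required_days))
  }
  if (length(keep) == 0) {
    abort("no participants remain after the required-day filter",
          class = "fpmiron_empty_cohort")
  }
  items <- dplyr::filter(items, .data$participant_id %in% keep)

  daily <- daily_intake(items, foods)
  mie <- daily |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n_days = dplyr::n(),
      mie_iron_mg_day = mean(.data$iron_mg),
      mie_ascorbic_mg_day = mean(.data$ascorbic_mg),
      mie_phytate_mg_day = mean(.data$phytate_mg),
      n_foods_total = sum(.data$n_items),
      .groups = "drop"
    ) |>
    dplyr::mutate(mie_ratio = participant_ratio(
      .data$mie_phytate_mg_day, .data$mie_iron_mg_day, cutoffs$ratio_mode))

  labels <- categorize_foods(foods, cutoffs)
  counted <- if (counting_mode == "unique_foods") {
    dplyr::distinct(items, .data$participant_id, .data$food_id)
  } else {
    items[c("participant_id", "food_id")]
  }
  fpm <- counted |>
    dplyr::inner_join(labels, by = "food_id") |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      fpm_iron = mean(.data$iron == "high"),
      fpm_ascorbic = mean(.data$ascorbic == "high"),
      fpm_phytate = mean(.data$phytate == "high"),
      fpm_ratio = mean(.data$ratio == "high"),
      .groups = "drop"
    )

  mie |>
    dplyr::inner_join(fpm, by = "participant_id") |>
    dplyr::select(
      "participant_id", "n_days", "n_foods_total",
      "mie_iron_mg_day", "mie_ascorbic_mg_day", "mie_phytate_mg_day",
      "mie_ratio", "fpm_iron", "fpm_ascorbic", "fpm_phytate", "fpm_ratio"
    ) |>
    dplyr::arrange(.data$participant_id)
}
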