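#' Nutrient-density cutoffs for food pattern modeling
#'
#' Builds the cutoff table that splits every food into "high" or "low"
#' nutrient density per variable. The defaults are the conventional
#' iron-bioavailability literature values: iron 0.35 mg/100 g, ascorbic acid
#' 24 mg/100 g, phytate 50 mg/100 g, and phytate:iron ratio 1. A food is
#' "high" when its value strictly exceeds the cutoff; a value equal to the
#' cutoff is "low".
#'
#' @param iron Iron cutoff, mg per 100 g.
#' @param ascorbic Ascorbic acid cutoff, mg per 100 g.
#' @param phytate Phytate cutoff, mg per 100 g.
#' @param ratio Phytate:iron ratio cutoff (dimensionless).
#' @param ratio_mode `"molar"` (default) or `"mass"`. Molar divides each mass
#'   by the molecular weight (phytic acid 660.04 g/mol, Fe 55.845 g/mol)
#'   before taking the ratio; mass is the raw mg/mg ratio. The molar
#'   convention is the one under which a ratio of 1 marks the onset of
#'   absorption inhibition.
#'
#' @return A list of class `fpm_cutoffs` with fields `iron`, `ascorbic`,
#'   `phytate`, `ratio`, `ratio_mode`.
#' @examples
#' fpm_cutoffs()
#' fpm_cutoffs(ratio_mode = "mass")
#' @export
fpm_cutoffs <- function(iron = 0.35, ascorbic = 24, phytate = 50, ratio = 1,
                        ratio_mode = c("molar", "mass")) {
  ratio_mode <- match.arg(ratio_mode)
  vals <- c(iron = iron, ascorbic = ascorbic, phytate = phytate, ratio = ratio)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    abort("all cutoffs must be finite and > 0", class = "fpmiron_invalid_input")
  }
  structure(
    list(iron = iron, ascorbic = ascorbic, phytate = phytate, ratio = ratio,
         ratio_mode = ratio_mode),
    class = "fpm_cutoffs"
  )
}

#' @export
print.fpm_cutoffs <- function(x, ...) {
  cat("<fpm_cutoffs>",
      sprintf("  iron    > %.3g mg/100 g", x$iron),
      sprintf("  ascorbic> %.3g mg/100 g", x$ascorbic),
      sprintf("  phytate > %.3g mg/100 g", x$phytate),
      sprintf("  ratio   > %.3g (%s)", x$ratio, x$ratio_mode),
      sep = "\n")
  invisible(x)
}

#' Phytate:iron ratio of a food or intake
#'
#' Vectorised ratio of phytate to iron, per 100 g of food or per day of
#' intake. In molar mode each mass is divided by its molecular weight first.
#' A zero-iron food with positive phytate is maximally inhibitory and maps to
#' `Inf`; a food with neither phytate nor iron maps to 0.
#'
#' @param phytate_mg,iron_mg Non-negative phytate and iron masses (mg).
#' @param mode `"molar"` or `"mass"`.
#' @return Numeric vector of dimensionless ratios.
#' @examples
#' food_ratio(660.04, 55.845, "molar") # 1: one mmol of each
#' food_ratio(50, 25, "mass")          # 2
#' food_ratio(100, 0)                  # Inf: inhibitor with no iron
#' @export
food_ratio <- function(phytate_mg, iron_mg, mode = c("molar", "mass")) {
  mode <- match.arg(mode)
  if (any(!is.finite(phytate_mg)) || any(!is.finite(iron_mg)) ||
      any(phytate_mg < 0) || any(iron_mg < 0)) {
    abort("phytate and iron must be finite and non-negative",
          class = "fpmiron_invalid_input")
  }
  num <- if (mode == "molar") phytate_mg / MW_PHYTATE else phytate_mg
  den <- if (mode == "molar") iron_mg / MW_IRON else iron_mg
  out <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
  as.numeric(out)
}

#' Classify foods as high or low nutrient density
#'
#' Labels every food "high" or "low" for each of the four variables (iron,
#' ascorbic acid, phytate, phytate:iron ratio) against a cutoff table. The
#' boundary belongs to "low": a food is "high" only when it strictly exceeds
#' the cutoff. Labels depend only on per-100 g content, never on portions.
#'
#' @param foods A composition tibble as returned by [read_composition()] (or
#'   any tibble with columns `food_id`, `iron_mg_per_100g`,
#'   `ascorbic_mg_per_100g`, `phytate_mg_per_100g`).
#' @param cutoffs An [fpm_cutoffs()] object.
#' @return A tibble with `food_id` and character columns `iron`, `ascorbic`,
#'   `phytate`, `ratio`, each `"high"` or `"low"`.
#' @examples
#' foods <- tibble::tibble(
#'   food_id = "a", name = "spinach",
#'   iron_mg_per_100g = 2.7, ascorbic_mg_per_100g = 28, phytate_mg_per_100g = 60
#' )
#' categorize_foods(foods, fpm_cutoffs())
#' @export
categorize_foods <- function(foods, cutoffs = fpm_cutoffs()) {
  stopifnot(inherits(cutoffs, "fpm_cutoffs"))
  validate_composition(foods)
  ratio <- food_ratio(foods$phytate_mg_per_100g, foods$iron_mg_per_100g,
                      cutoffs$ratio_mode)
  lab <- function(x, cut) ifelse(x > cut, "high", "low")
  tibble::tibble(
    food_id = foods$food_id,
    iron = lab(foods$iron_mg_per_100g, cutoffs$iron),
    ascorbic = lab(foods$ascorbic_mg_per_100g, cutoffs$ascorbic),
    phytate = lab(foods$phytate_mg_per_100g, cutoffs$phytate),
    ratio = lab(ratio, cutoffs$ratio)
  )
}

#' @rdname categorize_foods
#' @param food A single-row composition tibble (or one-food list with the
#'   same fields).
#' @return `categorize_food()` returns a named character vector with one
#'   `"high"`/`"low"` label per variable.
#' @export
categorize_food <- function(food, cutoffs = fpm_cutoffs()) {
  food <- tibble::as_tibble(food[c("food_id", "name", "iron_mg_per_100g",
                                   "ascorbic_mg_per_100g", "phytate_mg_per_100g")])
  if (nrow(food) != 1L) {
    abort("categorize_food() expects exactly one food", class = "fpmiron_invalid_input")
  }
  labs <- categorize_foods(food, cutoffs)
  unlist(labs[1, FPM_VARIABLES])
}

# Shared validation for composition tables; row numbers in messages refer to
# data rows (header excluded).
validate_composition <- function(foods, call = rlang::caller_env()) {
  required <- c("food_id", "iron_mg_per_100g", "ascorbic_mg_per_100g",
                "phytate_mg_per_100g")
  missing_cols <- setdiff(required, names(foods))
  if (length(missing_cols) > 0) {
    abort(paste0("composition table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "fpmiron_parse_error", call = call)
  }
  dup <- unique(foods$food_id[duplicated(foods$food_id)])
  if (length(dup) > 0) {
    abort(paste0("duplicate food_id in composition table: ",
                 paste(dup, collapse = ", ")),
          class = "fpmiron_parse_error", call = call)
  }
  for (col in required[-1]) {
    x <- foods[[col]]
    bad <- which(!is.finite(x) | x < 0)
    if (length(bad) > 0) {
      abort(sprintf("invalid %s (negative, missing or non-finite) at row(s) %s",
                    col, paste(bad, collapse = ", ")),
            class = "fpmiron_parse_error", call = call)
    }
  }
  invisible(foods)
}

#' Read a food composition table
#'
#' Reads a per-100 g food composition CSV with header
#' `food_id,name,iron_mg_per_100g,ascorbic_mg_per_100g,phytate_mg_per_100g`
#' and validates it: all nutrient contents must be finite and non-negative
#' and `food_id` must be unique. Malformed rows fail loudly, naming the
#' offending id or row, because a silently dropped or zeroed food would bias
#' every downstream density and ratio.
#'
#' @param path Path to the CSV file.
#' @return A tibble of validated food records.
#' @export
read_composition <- function(path) {
  foods <- readr::read_csv(
    path,
    col_types = readr::cols(
      food_id = readr::col_character(),
      name = readr::col_character(),
      iron_mg_per_100g = readr::col_double(),
      ascorbic_mg_per_100g = readr::col_double(),
      phytate_mg_per_100g = readr::col_double()
    )
  )
  validate_composition(foods)
  foods
}
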