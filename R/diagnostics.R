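#' Read per-participant hematology panels
#'
#' Reads a CSV with header
#' `participant_id,hemoglobin_g_dl,ferritin_ng_dl,absorption_pct` holding the
#' three iron-status outcomes: hemoglobin (g/dL), serum ferritin (units
#' treated as an opaque label) and acute iron absorption (% of a test-meal
#' dose).
#'
#' @param path Path to the CSV file.
#' @return A tibble of validated panels.
#' @export
read_hematology <- function(path) {
  panels <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      hemoglobin_g_dl = readr::col_double(),
      ferritin_ng_dl = readr::col_double(),
      absorption_pct = readr::col_double()
    )
  )
  validate_panels(panels)
  panels
}

validate_panels <- function(panels, call = rlang::caller_env()) {
  required <- c("participant_id", "hemoglobin_g_dl", "ferritin_ng_dl",
                "absorption_pct")
  missing_cols <- setdiff(required, names(panels))
  if (length(missing_cols) > 0) {
    abort(paste0("hematology table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "fpmiron_parse_error", call = call)
  }
  if (any(duplicated(panels$participant_id))) {
    abort("duplicate participant_id in hematology table",
          class = "fpmiron_parse_error", call = call)
  }
  ok <- is.finite(panels$hemoglobin_g_dl) & panels$hemoglobin_g_dl > 0 &
    is.finite(panels$ferritin_ng_dl) & panels$ferritin_ng_dl >= 0 &
    is.finite(panels$absorption_pct) & panels$absorption_pct >= 0 &
    panels$absorption_pct <= 100
  if (!all(ok)) {
    abort(sprintf("invalid hematology values at row(s): %s",
                  paste(which(!ok), collapse = ", ")),
          class = "fpmiron_parse_error", call = call)
  }
  invisible(panels)
}

#' Biomarker cutoff grids for ROC construction
#'
#' An evenly spaced grid of candidate dichotomisation points spanning the
#' nadir-to-peak range of a biomarker. Defaults per outcome: hemoglobin
#' 11.0-14.0 g/dL in 0.5 steps (7 cutoffs), ferritin 5-55 in steps of 5
#' (11 cutoffs), acute absorption 0-50% in steps of 5 (11 cutoffs).
#'
#' @param outcome `"hemoglobin"`, `"ferritin"` or `"absorption"`.
#' @param start,stop,step Grid parameters in outcome units; `NULL` uses the
#'   per-outcome default.
#' @return An object of class `fpm_outcome_grid` with fields `outcome`,
#'   `start`, `stop`, `step` and the realised `cutoffs` vector.
#' @examples
#' outcome_grid("hemoglobin")$cutoffs # 11.0 11.5 ... 14.0
#' @export
outcome_grid <- function(outcome = c("hemoglobin", "ferritin", "absorption"),
                         start = NULL, stop = NULL, step = NULL) {
  outcome <- match.arg(outcome)
  defaults <- list(
    hemoglobin = c(11, 14, 0.5),
    ferritin = c(5, 55, 5),
    absorption = c(0, 50, 5)
  )[[outcome]]
  start <- start %||% defaults[1]
  stop <- stop %||% defaults[2]
  step <- step %||% defaults[3]
  if (!is.finite(step) || step <= 0 || !is.finite(start) || !is.finite(stop) ||
      start >= stop) {
    abort("grid requires step > 0 and start < stop",
          class = "fpmiron_invalid_input")
  }
  structure(
    list(outcome = outcome, start = start, stop = stop, step = step,
         cutoffs = seq(start, stop, by = step)),
    class = "fpm_outcome_grid"
  )
}

#' @rdname outcome_grid
#' @return `default_outcome_grids()` returns the named list of the three
#'   default grids.
#' @export
default_outcome_grids <- function() {
  list(
    hemoglobin = outcome_grid("hemoglobin"),
    ferritin = outcome_grid("ferritin"),
    absorption = outcome_grid("absorption")
  )
}

#' Quartile thresholds of a dietary variable
#'
#' The 25th, 50th and 75th percentile of the cohort's values, computed by
#' linear interpolation between closest ranks (the inclusive convention,
#' `quantile(type = 7)`). These three boundaries are the candidate test
#' thresholds swept in the ROC construction. Fewer than four values cannot
#' define quartiles and raise an error; an all-equal input is returned with
#' a `degenerate` flag.
#'
#' @param values Numeric vector, one value per participant.
#' @return A list with `q25`, `q50`, `q75` and logical `degenerate`.
#' @examples
#' quartile_thresholds(1:8) # q25 = 2.75, q50 = 4.5, q75 = 6.25
#' @export
quartile_thresholds <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 4) {
    abort("quartile thresholds need at least 4 values",
          class = "fpmiron_invalid_input")
  }
  if (any(!is.finite(values))) {
    abort("quartile thresholds need finite values",
          class = "fpmiron_invalid_input")
  }
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  list(q25 = q[1], q50 = q[2], q75 = q[3],
       degenerate = length(unique(values)) == 1L)
}

#' Dichotomise a dietary test value
#'
#' Converts a continuous dietary variable into a positive/negative test call
#' for predicting the iron-replete outcome. Enhancer variables (iron,
#' ascorbic acid) are positive strictly above the threshold; inhibitor
#' variables (phytate, phytate:iron ratio) are positive strictly below it.
#' A value exactly at the threshold is negative under either direction.
#'
#' @param value Numeric vector of dietary values.
#' @param threshold Single numeric threshold.
#' @param direction `"enhancer"` or `"inhibitor"`.
#' @return Logical vector: `TRUE` = test positive.
#' @export
dichotomize_test <- function(value, threshold, direction = c("enhancer", "inhibitor")) {
  direction <- match.arg(direction)
  if (any(!is.finite(value)) || !is.finite(threshold)) {
    abort("values and threshold must be finite", class = "fpmiron_invalid_input")
  }
  if (direction == "enhancer") value > threshold else value < threshold
}

#' Cross-tabulate test calls against outcome status
#'
#' @param test_pos,outcome_pos Equal-length logical vectors (`TRUE` =
#'   positive).
#' @return A list of class `fpm_confusion` with counts `tp`, `fp`, `fn`,
#'   `tn` (test x outcome).
#' @export
confusion_table <- function(test_pos, outcome_pos) {
  if (length(test_pos) != length(outcome_pos)) {
    abort("test and outcome label vectors differ in length",
          class = "fpmiron_invalid_input")
  }
  if (length(test_pos) == 0) {
    abort("cannot tabulate an empty cohort", class = "fpmiron_invalid_input")
  }
  if (anyNA(test_pos) || anyNA(outcome_pos)) {
    abort("labels must not contain NA", class = "fpmiron_invalid_input")
  }
  structure(
    list(
      tp = sum(test_pos & outcome_pos),
      fp = sum(test_pos & !outcome_pos),
      fn = sum(!test_pos & outcome_pos),
      tn = sum(!test_pos & !outcome_pos)
    ),
    class = "fpm_confusion"
  )
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The two-sided p-value by full hypergeometric enumeration: with margins
#' fixed, sum the probabilities of every table whose hypergeometric
#' probability does not exceed that of the observed table (ties included up
#' to a relative tolerance of 1e-7, the convention of
#' [stats::fisher.test()]). Implemented directly and vectorised so that
#' whole cutoff-by-threshold grids of tables are tested in one call.
#'
#' @param tp,fp,fn,tn Non-negative integer cell counts (vectorised).
#' @return Numeric vector of two-sided p-values in (0, 1].
#' @examples
#' fisher_exact_2x2(5, 5, 5, 5)   # 1: the most probable table
#' fisher_exact_2x2(3, 1, 1, 3)   # 34/70
#' @export
fisher_exact_2x2 <- function(tp, fp, fn, tn) {
  n <- length(tp)
  stopifnot(length(fp) == n, length(fn) == n, length(tn) == n)
  cells <- cbind(tp, fp, fn, tn)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells))) {
    abort("cell counts must be non-negative integers",
          class = "fpmiron_invalid_input")
  }
  vapply(seq_len(n), function(i) {
    a <- tp[i]; b <- fp[i]; c_ <- fn[i]; d <- tn[i]
    N <- a + b + c_ + d
    if (N == 0) {
      abort("cannot test an empty table", class = "fpmiron_invalid_input")
    }
    r1 <- a + b          # test-positive margin (draws)
    c1 <- a + c_         # outcome-positive margin (successes)
    lo <- max(0, r1 - (N - c1))
    hi <- min(r1, c1)
    d_all <- dhyper(lo:hi, c1, N - c1, r1)
    p <- sum(d_all[d_all <= d_all[a - lo + 1] * (1 + 1e-7)])
    min(p, 1)
  }, numeric(1))
}

#' Diagnostic accuracy metrics of a confusion table
#'
#' Sensitivity, specificity, positive and negative predictive value, the
#' positive likelihood ratio and the two-sided Fisher exact p-value. Any
#' metric with a zero denominator is `NA` (undefined) rather than forced to
#' a number; `lr_plus` is `NA` when specificity is 1.
#'
#' @param ct An `fpm_confusion` table from [confusion_table()], or a list
#'   with fields `tp`, `fp`, `fn`, `tn`.
#' @return A one-row tibble: `tp`, `fp`, `fn`, `tn`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `lr_plus`, `fisher_p` (fractions, not
#'   percentages).
#' @export
diagnostic_metrics <- function(ct) {
  tp <- ct$tp; fp <- ct$fp; fn <- ct$fn; tn <- ct$tn
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  lr_plus <- if (!is.na(sens) && !is.na(spec) && spec < 1) sens / (1 - spec) else NA_real_
  tibble::tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = sens,
    specificity = spec,
    ppv = safe_div(tp, tp + fp),
    npv = safe_div(tn, tn + fn),
    lr_plus = lr_plus,
    fisher_p = fisher_exact_2x2(tp, fp, fn, tn)
  )
}

# Resolve a (variable, method) pair to its profile column.
profile_column <- function(variable, method) {
  variable <- match.arg(variable, FPM_VARIABLES)
  method <- match.arg(method, c("MIE", "FPM"))
  if (method == "FPM") {
    paste0("fpm_", variable)
  } else {
    c(iron = "mie_iron_mg_day", ascorbic = "mie_ascorbic_mg_day",
      phytate = "mie_phytate_mg_day", ratio = "mie_ratio")[[variable]]
  }
}

outcome_column <- function(outcome) {
  c(hemoglobin = "hemoglobin_g_dl", ferritin = "ferritin_ng_dl",
    absorption = "absorption_pct")[[match.arg(outcome, c("hemoglobin", "ferritin", "absorption"))]]
}

#' ROC cell grid for one variable, method and outcome
#'
#' Sweeps every biomarker cutoff in the outcome grid against the three
#' cohort quartile thresholds of the dietary variable, producing one 2x2
#' confusion table and metric set per (cutoff, threshold) cell. Outcome
#' positivity is biomarker >= cutoff (iron sufficient); test positivity
#' follows `direction` (see [dichotomize_test()]). Cells in which either
#' dichotomy is one-sided (an empty 2x2 margin) carry no diagnostic
#' information and are flagged `degenerate`; they are excluded from
#' summaries and paired tests, and each exclusion is reported.
#'
#' @param profiles Profile tibble from [build_profiles()].
#' @param panels Hematology tibble from [read_hematology()].
#' @param variable `"iron"`, `"ascorbic"`, `"phytate"` or `"ratio"`.
#' @param method `"MIE"` or `"FPM"`.
#' @param outcome `"hemoglobin"`, `"ferritin"` or `"absorption"`.
#' @param grid An [outcome_grid()]; defaults to the outcome's default grid.
#' @param direction Test-positivity direction; defaults to the variable's
#'   conventional role (enhancers positive above, inhibitors below).
#' @param quiet Suppress the degenerate-cell report.
#' @return A tibble with one row per cell: `outcome_cutoff`,
#'   `threshold_rank` (`"q25"`, `"q50"`, `"q75"`), `threshold`, the 2x2
#'   counts, all metrics and the `degenerate` flag.
#' @export
roc_grid <- function(profiles, panels, variable, method, outcome,
                     grid = NULL, direction = NULL, quiet = FALSE) {
  variable <- match.arg(variable, FPM_VARIABLES)
  method <- match.arg(method, c("MIE", "FPM"))
  outcome <- match.arg(outcome, c("hemoglobin", "ferritin", "absorption"))
  grid <- grid %||% outcome_grid(outcome)
  stopifnot(inherits(grid, "fpm_outcome_grid"))
  direction <- direction %||% DEFAULT_DIRECTIONS[[variable]]
  direction <- match.arg(direction, c("enhancer", "inhibitor"))

  joined <- dplyr::inner_join(profiles, panels, by = "participant_id")
  if (nrow(joined) == 0) {
    abort("profiles and hematology panels share no participant_id",
          class = "fpmiron_invalid_input")
  }
  test_values <- joined[[profile_column(variable, method)]]
  outcome_values <- joined[[outcome_column(outcome)]]
  thr <- quartile_thresholds(test_values)

  cells_for <- function(cutoff, rank_name) {
    threshold <- thr[[rank_name]]
    test_pos <- dichotomize_test(test_values, threshold, direction)
    outcome_pos <- outcome_values >= cutoff
    ct <- confusion_table(test_pos, outcome_pos)
    m <- diagnostic_metrics(ct)
    degenerate <- (ct$tp + ct$fn == 0) || (ct$fp + ct$tn == 0) ||
      (ct$tp + ct$fp == 0) || (ct$fn + ct$tn == 0)
    dplyr::bind_cols(
      tibble::tibble(outcome_cutoff = cutoff, threshold_rank = rank_name,
                     threshold = threshold),
      m,
      tibble::tibble(degenerate = degenerate)
    )
  }

  cells <- tidyr::expand_grid(cutoff = grid$cutoffs,
                              rank = c("q25", "q50", "q75")) |>
    purrr::pmap(\(cutoff, rank) cells_for(cutoff, rank)) |>
    dplyr::bind_rows()

  if (!quiet && any(cells$degenerate)) {
    deg <- cells[cells$degenerate, ]
    inform(c(
      sprintf("%s/%s vs %s: %d degenerate cell(s) excluded from summaries:",
              method, variable, outcome, nrow(deg)),
      sprintf("  cutoff %g, threshold %s", deg$outcome_cutoff, deg$threshold_rank)
    ))
  }
  cells
}

#' Summarise a cell grid into one accuracy row
#'
#' The unweighted mean of each metric over the retained (non-degenerate)
#' cells, reported as percentages. Cells where a metric is individually
#' undefined are dropped from that metric's mean only; the drop count is
#' reported.
#'
#' @param cells A cell tibble from [roc_grid()].
#' @param quiet Suppress the undefined-metric report.
#' @return A one-row tibble: `sensitivity`, `specificity`, `ppv`, `npv`
#'   (percent), `n_cells` retained.
#' @export
summarize_cells <- function(cells, quiet = FALSE) {
  kept <- cells[!cells$degenerate, ]
  if (nrow(kept) == 0) {
    abort("no non-degenerate cells to summarise", class = "fpmiron_degenerate")
  }
  mean_pct <- function(metric) {
    x <- kept[[metric]]
    n_undef <- sum(is.na(x))
    if (n_undef > 0 && !quiet) {
      inform(sprintf("%d cell(s) with undefined %s dropped from its mean",
                     n_undef, metric))
    }
    100 * mean(x, na.rm = TRUE)
  }
  tibble::tibble(
    sensitivity = mean_pct("sensitivity"),
    specificity = mean_pct("specificity"),
    ppv = mean_pct("ppv"),
    npv = mean_pct("npv"),
    n_cells = nrow(kept)
  )
}

#' Paired comparison of two methods' cell grids
#'
#' Matches the MIE and FPM cell grids 1:1 on (outcome cutoff, quartile
#' threshold rank), keeps pairs where both cells are non-degenerate and the
#' metric is defined for both, and runs a two-sided paired Student t-test on
#' the per-cell sensitivities and, separately, specificities. An all-zero or
#' otherwise zero-variance difference vector has no t distribution; it is
#' reported as p = 1 with a `degenerate` flag so that comparison reports
#' always complete.
#'
#' @param cells_mie,cells_fpm Cell tibbles from [roc_grid()] for the same
#'   variable and outcome.
#' @return A list: `p_sensitivity`, `p_specificity`,
#'   `degenerate_sensitivity`, `degenerate_specificity`, `n_pairs_sensitivity`,
#'   `n_pairs_specificity`.
#' @export
paired_compare <- function(cells_mie, cells_fpm) {
  merged <- dplyr::inner_join(
    cells_mie, cells_fpm,
    by = c("outcome_cutoff", "threshold_rank"),
    suffix = c("_mie", "_fpm")
  )
  one_metric <- function(metric) {
    x <- merged[[paste0(metric, "_mie")]]
    y <- merged[[paste0(metric, "_fpm")]]
    ok <- !merged$degenerate_mie & !merged$degenerate_fpm & !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 2) {
      abort(sprintf("paired test needs at least 2 complete pairs for %s", metric),
            class = "fpmiron_invalid_input")
    }
    d <- x - y
    if (isTRUE(all.equal(stats::var(d), 0)) || stats::var(d) == 0) {
      list(p = 1.0, degenerate = TRUE, n = length(d))
    } else {
      list(p = t.test(x, y, paired = TRUE)$p.value, degenerate = FALSE,
           n = length(d))
    }
  }
  sens <- one_metric("sensitivity")
  spec <- one_metric("specificity")
  list(
    p_sensitivity = sens$p, p_specificity = spec$p,
    degenerate_sensitivity = sens$degenerate,
    degenerate_specificity = spec$degenerate,
    n_pairs_sensitivity = sens$n, n_pairs_specificity = spec$n
  )
}

#' Full MIE-versus-FPM diagnostic accuracy comparison
#'
#' Runs the whole protocol: for every outcome (hemoglobin, ferritin, acute
#' absorption) and every dietary variable (iron, ascorbic acid, phytate,
#' phytate:iron ratio), builds the ROC cell grid for both assessment
#' methods, summarises each method's mean accuracy over retained cells, and
#' compares the two methods by paired t-tests on per-cell sensitivity and
#' specificity.
#'
#' @param profiles Profile tibble from [build_profiles()].
#' @param panels Hematology tibble.
#' @param grids Named list of [outcome_grid()]s (default
#'   [default_outcome_grids()]).
#' @param directions Named character vector mapping each variable to
#'   `"enhancer"` or `"inhibitor"`.
#' @param quiet Suppress degenerate-cell reports.
#' @return A list of class `fpm_comparison`:
#' \describe{
#'   \item{summary}{24-row tibble (3 outcomes x 4 variables x 2 methods):
#'     `outcome`, `variable`, `method`, `sensitivity`, `specificity`, `ppv`,
#'     `npv` (percent), `n_cells`, `p_sensitivity`, `p_specificity`.}
#'   \item{roc}{Tidy ROC plotting points for every retained cell:
#'     `outcome`, `variable`, `method`, `outcome_cutoff`, `threshold_rank`,
#'     `fpr`, `tpr`.}
#'   \item{cells}{The full cell grids, all metrics and flags.}
#' }
#' @export
compare_methods <- function(profiles, panels, grids = default_outcome_grids(),
                            directions = DEFAULT_DIRECTIONS, quiet = FALSE) {
  validate_panels(panels)
  combos <- tidyr::expand_grid(
    outcome = names(grids),
    variable = FPM_VARIABLES
  )
  results <- purrr::pmap(combos, function(outcome, variable) {
    cells <- lapply(c(MIE = "MIE", FPM = "FPM"), function(m) {
      roc_grid(profiles, panels, variable, m, outcome,
               grid = grids[[outcome]],
               direction = directions[[variable]], quiet = quiet)
    })
    pc <- paired_compare(cells$MIE, cells$FPM)
    summary <- dplyr::bind_rows(.id = "method", lapply(cells, summarize_cells, quiet = quiet)) |>
      dplyr::mutate(outcome = outcome, variable = variable,
                    p_sensitivity = pc$p_sensitivity,
                    p_specificity = pc$p_specificity, .before = 1)
    roc <- dplyr::bind_rows(.id = "method", lapply(cells, function(cc) {
      kept <- cc[!cc$degenerate, ]
      tibble::tibble(outcome_cutoff = kept$outcome_cutoff,
                     threshold_rank = kept$threshold_rank,
                     fpr = 1 - kept$specificity, tpr = kept$sensitivity)
    })) |>
      dplyr::mutate(outcome = outcome, variable = variable, .before = 1)
    cells <- dplyr::bind_rows(.id = "method", cells) |>
      dplyr::mutate(outcome = outcome, variable = variable, .before = 1)
    list(summary = summary, roc = roc, cells = cells)
  })
  summary <- dplyr::bind_rows(lapply(results, `[[`, "summary")) |>
    dplyr::select("outcome", "variable", "method", "sensitivity",
                  "specificity", "ppv", "npv", "n_cells",
                  "p_sensitivity", "p_specificity")
  structure(
    list(
      summary = summary,
      roc = dplyr::bind_rows(lapply(results, `[[`, "roc")),
      cells = dplyr::bind_rows(lapply(results, `[[`, "cells"))
    ),
    class = "fpm_comparison"
  )
}

#' @export
print.fpm_comparison <- function(x, ...) {
  cat("<fpm_comparison>: MIE vs FPM diagnostic accuracy\n")
  print(x$summary, n = Inf)
  invisible(x)
}

#' Plot ROC point clouds for one outcome
#'
#' Scatter of (1 - specificity, sensitivity) for every retained grid cell,
#' one panel per dietary variable, coloured by assessment method.
#'
#' @param comparison An `fpm_comparison` from [compare_methods()].
#' @param outcome Which outcome's panels to draw.
#' @return A ggplot object.
#' @export
plot_roc <- function(comparison, outcome = c("hemoglobin", "ferritin", "absorption")) {
  outcome <- match.arg(outcome)
  dat <- dplyr::filter(comparison$roc, .data$outcome == !!outcome)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                    colour = .data$method)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~variable) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = paste("ROC cells:", outcome)) +
    ggplot2::theme_minimal()
}
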