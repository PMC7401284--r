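test_that("quartile thresholds use linear interpolation between closest ranks", {
  q <- quartile_thresholds(1:8)
  expect_equal(q$q25, 2.75)
  expect_equal(q$q50, 4.5)
  expect_equal(q$q75, 6.25)
  expect_false(q$degenerate)
  expect_equal(quartile_thresholds(c(0.1, 0.2, 0.3, 0.4))$q50, 0.25)
  deg <- quartile_thresholds(rep(2, 5))
  expect_true(deg$degenerate)
  expect_equal(deg$q25, 2)
  expect_error(quartile_thresholds(1:3), class = "fpmiron_invalid_input")
})

test_that("test dichotomisation respects direction and the tie-is-negative rule", {
  expect_true(dichotomize_test(0.5, 0.47, "enhancer"))
  expect_true(dichotomize_test(0.8, 2.9, "inhibitor"))
  expect_false(dichotomize_test(0.47, 0.47, "enhancer"))
  expect_false(dichotomize_test(0.47, 0.47, "inhibitor"))
  expect_false(dichotomize_test(0.3, 0.47, "enhancer"))
  expect_false(dichotomize_test(3.0, 2.9, "inhibitor"))
})

test_that("confusion table partitions the cohort", {
  ct <- confusion_table(rep(TRUE, 10), rep(TRUE, 10))
  expect_equal(unclass(ct)[c("tp", "fp", "fn", "tn")],
               list(tp = 10, fp = 0, fn = 0, tn = 0))
  ct2 <- confusion_table(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(unclass(ct2)[c("tp", "fp", "fn", "tn")],
               list(tp = 1, fp = 1, fn = 1, tn = 1))
  expect_error(confusion_table(logical(0), logical(0)),
               class = "fpmiron_invalid_input")
  expect_error(confusion_table(c(TRUE, FALSE), TRUE),
               class = "fpmiron_invalid_input")
})

test_that("metrics follow their defining ratios, flagging zero denominators", {
  m <- diagnostic_metrics(list(tp = 8, fp = 4, fn = 2, tn = 6))
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.6)
  expect_equal(m$ppv, 8 / 12)
  expect_equal(m$npv, 0.75)
  expect_equal(m$lr_plus, 0.8 / 0.4)

  no_pos <- diagnostic_metrics(list(tp = 0, fp = 3, fn = 0, tn = 7))
  expect_true(is.na(no_pos$sensitivity))
  perfect <- diagnostic_metrics(list(tp = 5, fp = 0, fn = 0, tn = 5))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$ppv, 1)
  expect_equal(perfect$npv, 1)
  expect_true(is.na(perfect$lr_plus))  # spec = 1
})

test_that("Fisher exact p equals hypergeometric enumeration and fisher.test", {
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1.0)
  expect_equal(fisher_exact_2x2(10, 0, 0, 10), 2 / choose(20, 10))
  expect_equal(fisher_exact_2x2(3, 1, 1, 3), 34 / 70, tolerance = 1e-12)
  # against R's own implementation on random tables
  withr::with_seed(99, {
    for (i in 1:50) {
      cells <- as.integer(stats::rpois(4, 4))
      if (sum(cells) == 0) cells[1] <- 1L
      tab <- matrix(cells, 2, 2)
      expect_equal(fisher_exact_2x2(cells[1], cells[3], cells[2], cells[4]),
                   stats::fisher.test(tab)$p.value, tolerance = 1e-10)
    }
  })
  expect_error(fisher_exact_2x2(0, 0, 0, 0), class = "fpmiron_invalid_input")
  expect_error(fisher_exact_2x2(1.5, 0, 0, 1), class = "fpmiron_invalid_input")
})

test_that("ROC grids have one cell per cutoff x quartile and flag degeneracy", {
  withr::with_seed(31, {
    profiles <- tibble::tibble(
      participant_id = sprintf("p%02d", 1:20),
      n_days = 3L, n_foods_total = 30L,
      mie_iron_mg_day = stats::runif(20, 5, 25),
      mie_ascorbic_mg_day = stats::runif(20, 20, 150),
      mie_phytate_mg_day = stats::runif(20, 200, 1200),
      mie_ratio = stats::runif(20, 1, 8),
      fpm_iron = stats::runif(20), fpm_ascorbic = stats::runif(20),
      fpm_phytate = stats::runif(20), fpm_ratio = stats::runif(20)
    )
    panels <- tibble::tibble(
      participant_id = profiles$participant_id,
      hemoglobin_g_dl = rnorm(20, 13.1, 1),
      ferritin_ng_dl = pmax(rnorm(20, 30, 15), 0),
      absorption_pct = pmin(pmax(rnorm(20, 15, 20), 0), 100)
    )
  })
  hb <- roc_grid(profiles, panels, "iron", "MIE", "hemoglobin", quiet = TRUE)
  expect_equal(nrow(hb), 7 * 3)
  fe <- roc_grid(profiles, panels, "iron", "MIE", "ferritin", quiet = TRUE)
  expect_equal(nrow(fe), 11 * 3)
  ab <- roc_grid(profiles, panels, "iron", "FPM", "absorption", quiet = TRUE)
  expect_equal(nrow(ab), 11 * 3)

  # cohort squeezed between two grid points: cutoffs outside the observed
  # range split nobody (an empty outcome margin) and are degenerate-flagged;
  # the interior cutoff is retained
  narrow_panels <- panels
  narrow_panels$hemoglobin_g_dl <- stats::runif(20, 13.2, 13.8)
  cells <- roc_grid(profiles, narrow_panels, "iron", "MIE", "hemoglobin",
                    quiet = TRUE)
  expect_true(all(cells$degenerate[cells$outcome_cutoff <= 13]))
  expect_true(all(cells$degenerate[cells$outcome_cutoff >= 14]))
  expect_false(any(cells$degenerate[cells$outcome_cutoff == 13.5]))

  # grid metrics equal the brute-force recount in every cell
  thr <- quartile_thresholds(profiles$mie_iron_mg_day)
  for (i in seq_len(nrow(hb))) {
    manual <- oracle_metrics(
      profiles$mie_iron_mg_day > thr[[hb$threshold_rank[i]]],
      panels$hemoglobin_g_dl >= hb$outcome_cutoff[i]
    )
    expect_identical(hb$tp[i], as.integer(manual$tp))
    expect_equal(hb$sensitivity[i], manual$sensitivity)
    expect_equal(hb$specificity[i], manual$specificity)
  }
})

test_that("ppv/npv obey Bayes' identity and ROC sensitivity is threshold-monotone", {
  withr::with_seed(67, {
    profiles_values <- stats::runif(30, 0, 1)
    outcome_values <- rnorm(30, 13, 1)
  })
  thr <- quartile_thresholds(profiles_values)
  for (cutoff in seq(11, 14, 0.5)) {
    sens_by_thr <- c()
    for (rank in c("q75", "q50", "q25")) {
      test_pos <- dichotomize_test(profiles_values, thr[[rank]], "enhancer")
      outcome_pos <- outcome_values >= cutoff
      m <- diagnostic_metrics(confusion_table(test_pos, outcome_pos))
      prev <- mean(outcome_pos)
      if (!anyNA(c(m$sensitivity, m$specificity, m$ppv)) && prev > 0 && prev < 1) {
        bayes_ppv <- m$sensitivity * prev /
          (m$sensitivity * prev + (1 - m$specificity) * (1 - prev))
        expect_equal(m$ppv, bayes_ppv)
      }
      if (!is.na(m$sensitivity)) sens_by_thr <- c(sens_by_thr, m$sensitivity)
    }
    # lowering an enhancer threshold (q75 -> q25) never lowers sensitivity
    expect_true(all(diff(sens_by_thr) >= 0))
  }
})

test_that("paired comparison handles degenerate and textbook difference vectors", {
  base <- tidyr::expand_grid(outcome_cutoff = seq(11, 14, 0.5),
                             threshold_rank = c("q25", "q50", "q75"))
  mk <- function(sens, spec) {
    dplyr::mutate(base, sensitivity = sens, specificity = spec,
                  degenerate = FALSE)
  }
  withr::with_seed(3, {
    s <- stats::runif(nrow(base), 0.2, 0.8)
    sp <- stats::runif(nrow(base), 0.2, 0.8)
  })
  # identical grids: all-zero differences
  pc <- paired_compare(mk(s, sp), mk(s, sp))
  expect_equal(pc$p_sensitivity, 1.0)
  expect_true(pc$degenerate_sensitivity)
  # constant nonzero difference: still zero variance
  pc2 <- paired_compare(mk(s, sp), mk(s - 0.1, sp))
  expect_equal(pc2$p_sensitivity, 1.0)
  expect_true(pc2$degenerate_sensitivity)
  expect_true(pc2$degenerate_specificity)  # identical specificities

  # six-cell hand-computed paired t
  d <- c(0.1, -0.1, 0.05, -0.05, 0, 0)
  b6 <- base[1:6, ]
  x <- rep(0.5, 6)
  g1 <- dplyr::mutate(b6, sensitivity = x, specificity = x, degenerate = FALSE)
  g2 <- dplyr::mutate(b6, sensitivity = x - d, specificity = x, degenerate = FALSE)
  pc3 <- paired_compare(g1, g2)
  tstat <- mean(d) / (stats::sd(d) / sqrt(6))
  p_manual <- 2 * stats::pt(-abs(tstat), df = 5)
  expect_equal(pc3$p_sensitivity, p_manual)
  expect_equal(pc3$p_sensitivity, 1.0)  # mean difference is exactly zero

  expect_error(paired_compare(mk(s, sp)[1, ], mk(s, sp)[1, ]),
               class = "fpmiron_invalid_input")
})

test_that("summaries average retained cells only, as percentages", {
  cells <- tibble::tibble(
    outcome_cutoff = c(11, 11.5, 12, 12.5),
    threshold_rank = "q50",
    sensitivity = c(0.2, 0.4, NA, 0.9),
    specificity = c(0.5, 0.7, 0.6, 0.1),
    ppv = c(0.3, 0.5, 0.4, 0.2),
    npv = c(0.6, 0.8, 0.7, 0.3),
    degenerate = c(FALSE, FALSE, FALSE, TRUE)
  )
  s <- suppressMessages(summarize_cells(cells))
  expect_equal(s$sensitivity, 30)        # mean(0.2, 0.4) * 100, NA dropped
  expect_equal(s$specificity, 60)        # mean(0.5, 0.7, 0.6)
  expect_equal(s$n_cells, 3)
  one <- summarize_cells(cells[1, ])
  expect_equal(one$sensitivity, 20)
  expect_error(summarize_cells(dplyr::mutate(cells, degenerate = TRUE)),
               class = "fpmiron_degenerate")
})

test_that("full comparison produces the 24-row report with both methods", {
  cohort <- generate_cohort(sim_config(n_participants = 27, seed = 4), quiet = TRUE)
  profiles <- suppressMessages(build_profiles(cohort$recalls, cohort$foods))
  cmp <- compare_methods(profiles, cohort$panels, quiet = TRUE)
  expect_s3_class(cmp, "fpm_comparison")
  expect_equal(nrow(cmp$summary), 24)
  expect_equal(nrow(dplyr::distinct(cmp$summary, outcome, variable)), 12)
  expect_setequal(unique(cmp$summary$method), c("MIE", "FPM"))
  expect_true(all(cmp$summary$sensitivity >= 0 & cmp$summary$sensitivity <= 100,
                  na.rm = TRUE))
  expect_true(all(cmp$summary$p_sensitivity > 0 & cmp$summary$p_sensitivity <= 1))
  # ROC points live in the unit square
  expect_true(all(cmp$roc$fpr >= 0 & cmp$roc$fpr <= 1))
  expect_true(all(cmp$roc$tpr >= 0 & cmp$roc$tpr <= 1))
  # plotting returns a ggplot without error
  expect_s3_class(plot_roc(cmp, "ferritin"), "ggplot")
})

test_that("flipping a variable's direction complements its per-cell accuracy", {
  cohort <- generate_cohort(sim_config(n_participants = 40, seed = 12), quiet = TRUE)
  profiles <- suppressMessages(build_profiles(cohort$recalls, cohort$foods))
  fwd <- roc_grid(profiles, cohort$panels, "phytate", "MIE", "hemoglobin",
                  direction = "inhibitor", quiet = TRUE)
  rev <- roc_grid(profiles, cohort$panels, "phytate", "MIE", "hemoglobin",
                  direction = "enhancer", quiet = TRUE)
  # with no ties at the threshold, reversing direction swaps the 2x2 rows:
  # sensitivity_rev = 1 - sensitivity_fwd cell by cell
  expect_equal(rev$sensitivity, 1 - fwd$sensitivity)
  expect_equal(rev$specificity, 1 - fwd$specificity)
})
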