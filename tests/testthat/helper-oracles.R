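# Independent oracles and tiny fixture builders shared across the suite.

# Two-sided Fisher p by direct log-binomial-coefficient enumeration.
# Independent of the package's dhyper-based path; same tie tolerance as
# stats::fisher.test (relative 1e-7).
oracle_fisher <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  r1 <- tp + fp
  c1 <- tp + fn
  lo <- max(0, r1 - (n - c1))
  hi <- min(r1, c1)
  k <- lo:hi
  logp <- lchoose(c1, k) + lchoose(n - c1, r1 - k) - lchoose(n, r1)
  p <- exp(logp)
  obs <- p[k == tp]
  min(sum(p[p <= obs * (1 + 1e-7)]), 1)
}

# Brute-force accuracy metrics recounted item by item from raw labels.
oracle_metrics <- function(test_pos, outcome_pos) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(test_pos)) {
    if (test_pos[i] && outcome_pos[i]) tp <- tp + 1
    else if (test_pos[i] && !outcome_pos[i]) fp <- fp + 1
    else if (!test_pos[i] && outcome_pos[i]) fn <- fn + 1
    else tn <- tn + 1
  }
  list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_
  )
}

# A minimal four-food composition table covering all label combinations:
# "ironrich" high in iron only, "vitc" high in ascorbic only, "bran" high in
# phytate and ratio, "plain" low in everything.
tiny_foods <- function() {
  tibble::tibble(
    food_id = c("ironrich", "vitc", "bran", "plain"),
    name = c("fortified cereal", "orange", "wheat bran", "white rice"),
    iron_mg_per_100g = c(2.5, 0.1, 0.34, 0.2),
    ascorbic_mg_per_100g = c(0, 50, 0, 1),
    phytate_mg_per_100g = c(0, 0, 800, 10)
  )
}

# Recall items: one participant, chosen foods, 100 g each, all on day 1
# unless a day vector is given.
tiny_items <- function(food_ids, pid = "p1", days = 1L, grams = 100) {
  tibble::tibble(
    participant_id = pid,
    day_index = as.integer(rep_len(days, length(food_ids))),
    food_id = food_ids,
    grams_consumed = rep_len(grams, length(food_ids))
  )
}

# Random small cohort of raw labels for oracle-equivalence sweeps.
random_labels <- function(n) {
  list(test = sample(c(TRUE, FALSE), n, replace = TRUE),
       outcome = sample(c(TRUE, FALSE), n, replace = TRUE))
}
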