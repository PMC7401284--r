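# fpmiron

Validation tooling for **food pattern modeling (FPM)**, a portion-free
dietary assessment method, against conventional **mean dietary intake
estimates (MIE)** from multi-day 24 h recalls, for predicting hematological
indices of iron status.

## The problem

Repeated multiple-pass 24 h recalls are the reference standard for dietary
assessment but are expensive and memory-dependent, which limits their use in
community nutrition programs. FPM replaces quantified intake with a simple
pattern score: every food a participant reports is classified **high** or
**low** nutrient density per 100 g against a fixed cutoff, and the diet is
summarised per variable *v* as

    density_v = (# consumed foods labeled high for v) / (# foods consumed)

with no portions or frequencies. Whether this cheap score predicts iron
status as well as the full recall arithmetic is an empirical question. This
package implements both variable sets from the same item-level records and
runs a head-to-head diagnostic-accuracy protocol against hemoglobin, serum
ferritin, and acute iron absorption, for the four variables governing
non-heme iron bioavailability:

| variable           | density cutoff (per 100 g) | role      |
|--------------------|---------------------------|-----------|
| iron               | 0.35 mg                   | enhancer  |
| ascorbic acid      | 24 mg                     | enhancer  |
| phytate            | 50 mg                     | inhibitor |
| phytate:iron ratio | 1 (molar)                 | inhibitor |

The phytate:iron ratio uses the molar convention by default
(`(phytate/660.04)/(iron/55.845)`); the raw mass ratio is a config switch.

The protocol: cohort quartiles of each dietary variable provide candidate
test thresholds; biomarker cutoff grids (hemoglobin 11.0–14.0 g/dL by 0.5;
ferritin 5–55 by 5; absorption 0–50% by 5) provide candidate outcome
dichotomies; every (cutoff × threshold) cell yields a 2×2 table,
sensitivity/specificity/PPV/NPV and a Fisher exact p-value; methods are
summarised by the unweighted mean over non-degenerate cells and compared by
paired t-tests on per-cell sensitivity and specificity. A synthetic cohort
generator with a configurable linear-Gaussian diet→biomarker link makes the
whole pipeline testable without any external data.

## Worked example

```r
library(fpmiron)
library(dplyr)

cohort   <- generate_cohort(sim_config(n_participants = 27, seed = 42), quiet = TRUE)
profiles <- build_profiles(cohort$recalls, cohort$foods)
profiles[1:3, c("participant_id", "mie_iron_mg_day", "mie_ratio", "fpm_iron", "fpm_ratio")]
#> # A tibble: 3 × 5
#>   participant_id mie_iron_mg_day mie_ratio fpm_iron fpm_ratio
#>   <chr>                    <dbl>     <dbl>    <dbl>     <dbl>
#> 1 P0001                    11.9       5.09   0.44      0.24
#> 2 P0002                     3.75      1.37   0.0952    0.333
#> 3 P0003                     9.44      2.38   0.423     0.0769
```

Participant P0001 averaged 11.9 mg/day of iron over their three recalls,
with a mean phytate:iron molar ratio of 5.09 (inhibitory territory: above
1); 44% of the items they reported were high-iron foods and 24% were
high-ratio foods.

```r
cmp <- compare_methods(profiles, cohort$panels, quiet = TRUE)
filter(cmp$summary, outcome == "ferritin", variable == "iron")
#>    outcome variable method sensitivity specificity  ppv  npv n_cells
#> 1 ferritin     iron    MIE        32.6        40.4 44.0 37.5      30
#> 2 ferritin     iron    FPM        32.5        42.5 42.5 39.2      30
#>   p_sensitivity p_specificity
#> 1         0.988         0.411
#> 2         0.988         0.411
```

For predicting ferritin from iron intake on this simulated 27-woman cohort,
the two assessment methods average nearly identical sensitivity (32.6 vs
32.5%) and similar specificity (40.4 vs 42.5%) over the 30 retained grid
cells, and the paired tests find no difference (p = 0.99 and 0.41) — the
small-cohort behaviour the method comparison is designed to probe.
`plot_roc(cmp, "ferritin")` draws the per-cell ROC point clouds.

The same pipeline runs from the shell via the bundled wrapper:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "fpm.R", package = "fpmiron"))') \
    simulate --out-dir run1
```

followed by `score` and `compare` with a YAML config naming the CSVs (see
`?run_config`). Every stage writes a provenance JSON (config echo, seed,
row counts).

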