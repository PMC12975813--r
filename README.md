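# eventseg

Analysis toolkit for naturalistic event-segmentation studies: participants
watch a long narrative stimulus (e.g. a 22-minute sitcom episode) and press a
button whenever one meaningful unit of the story ends and another begins.
`eventseg` turns those button-press logs — together with ASRS (Adult ADHD
Self-Report Scale) questionnaires, two-condition temporal-order memory trials
and a semantic quiz — into the study's complete statistical analysis, and
ships a seeded synthetic-cohort generator so the entire pipeline can be run
and verified without any participant data.

It is written for behavioral/cognitive researchers working with
individual-differences designs around event segmentation: every user-facing
function takes a data frame and returns a tibble, so the stages chain with
the pipe, and fitted results support `tidy()`, `glance()` and `autoplot()`.

## The measures

Press times are binned into binary temporal vectors at 100-ms resolution
(13,200 timepoints for a 1320-s stimulus). From these the package computes,
per participant:

- **Number of segmentations** — the raw press count.
- **Jaccard overlap with a prototypical segmentation.** Each press is
  expanded into a centered 5-s window (0.38% of the episode) to absorb
  inter-individual response-timing variation, then
  `J(A, B) = |A ∩ B| / |A ∪ B|` over the set bins of the individual (A) and
  prototypical (B) vectors.
- **Inter-subject agreement.** Each binary vector is convolved with a
  Gaussian kernel (σ = 2 s, FWHM ≈ 4.7 s) and Pearson-correlated with the
  leave-one-out mean of all other participants' convolved vectors.
- **Peak latency.** Lagged Pearson correlations between the convolved
  individual and prototypical vectors over ±10 s; the lag of the maximum is
  the participant's response latency relative to the prototypical
  boundaries (positive = responses follow the boundaries).

Prototypical boundaries are derived from an independent norming sample by
greedy consensus clustering: presses within a 10-s window are pooled (one
per participant) and clusters supported by ≥ 6 of 10 viewers become reliable
boundaries at their averaged timestamp.

The memory side discards trials with response times below 0.5 s or above
15 s, scores per-condition hit rates for within-scene and across-scenes
temporal-order pairs and the semantic proportion correct (chance 0.33), and
the battery then computes Cronbach's alpha for the ASRS, every
ASRS-by-performance Pearson correlation, the within-vs-across paired t test
(Cohen's d from the SD of differences) and the one-sample peak-latency test.

## Worked example

```r
library(eventseg)

params <- sim_params(seed = 42)       # study conditions: n = 71, 1320 s, 30 boundaries
study  <- simulate_study(params)      # cohort + norming sample + prototypical set

metrics <- seg_metrics(study$presses, study$proto, duration_s = 1320)
head(metrics, 3)
#> # A tibble: 3 × 5
#>   participant_id n_presses jaccard agreement peak_latency_s
#>   <chr>              <int>   <dbl>     <dbl>          <dbl>
#> 1 p01                   26   0.453     0.769            1
#> 2 p02                   24   0.492     0.808            1
#> 3 p03                   24   0.283     0.511            1.1

scores  <- score_memory(filter_rt(study$memory_trials))
#> filter_rt: discarded 51 of 1988 trials (2.57%) outside [0.5, 15] s
battery <- run_battery(metrics, scores, study$semantic, study$asrs)
glance(battery)
#> # A tibble: 1 × 5
#>       n cronbach_alpha n_tests n_significant alpha_level
#>   <int>          <dbl>   <int>         <int>       <dbl>
#> 1    71          0.806      19            10        0.05
```

Each participant row gives the press count, the windowed Jaccard overlap
with the prototypical boundaries, the leave-one-out agreement, and the
peak latency in seconds. The battery's `tidy()` output holds one row per
test; the planted cohort structure shows up exactly where the design says
it should:

```r
dplyr::filter(tidy(battery), test %in%
  c("asrs_x_n_presses", "asrs_x_acc_across", "within_vs_across_paired_t"))
#> # A tibble: 3 × 10
#>   test                      estimate statistic    df        p significant ...
#> 1 asrs_x_n_presses            -0.616     -6.50    69 1.06e- 8 TRUE
#> 2 asrs_x_acc_across           -0.514     -4.98    69 4.56e- 6 TRUE
#> 3 within_vs_across_paired_t    0.171      9.81    70 8.66e-15 TRUE
```

Higher ASRS totals go with fewer reported boundaries and lower
across-boundary order memory, while within-scene accuracy exceeds
across-scenes accuracy — the correlational structure the generator plants.
`autoplot(battery)` draws the ASRS scatter grid,
`plot_press_raster(study$presses, study$proto)` the press raster, and
`autoplot(lag_curve(...))` a participant's lag curve.

File-based analyses use the same stages over CSVs:

```r
stage_simulate("fixtures", sim_params(seed = 1))   # writes all input CSVs
run_pipeline("fixtures")                           # seg_metrics.csv, results.csv, report.md, ...
```

or, from a shell, via the thin wrapper `inst/cli/eventseg.R`
(`simulate | prototypical | segmetrics | memory | analyze | run`).

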