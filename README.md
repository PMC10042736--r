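# nucexpel

Quantification of **nuclear expulsion** — the release of decondensed
chromatin from dying (apoptotic) cells — in single-cell fluorescence
time-lapse movies.

Tumor cells carrying an H2B chromatin reporter show, under apoptotic
stimuli, a characteristic sequence: baseline → chromatin condensation
(sometimes fragmentation into apoptotic bodies) → in a Padi4-dependent
subset of cells, a rapid expansion of the chromatin signal as the nucleus is
expelled. `nucexpel` turns movies of this assay into per-cell calls and
population summaries, for imaging labs that need the per-cell statistic and
the calibration machinery rather than raw image processing.

## The statistic

For each tracked cell, the raw nuclear area trace is normalized by its
pre-treatment baseline, `e(t) = area(t) / baseline_area`, and the
**expulsion score** is the maximum numerical gradient of `e` over a grid of
time intervals:

```
score = max over t, w ∈ W of  [ e(t + w) − e(t) ] / w ,   W = {1, 2, 4, 8} frames
```

i.e. the fastest sustained increase in chromatin area, in fold-change per
frame. A detection threshold is calibrated by a receiver operating
characteristic curve between a known-positive population (Padi4 wild-type
cells) and a known-negative population (Padi4 knockout); the default
operating point maximizes Youden's J = TPR − FPR. A cell is called as
undergoing nuclear expulsion when its score strictly exceeds the threshold,
and each condition is summarised as `percent_expulsion = 100 ·
n_positive_calls / n_scored`. Calcium-indicator movies can additionally be
scored for per-cell calcium spikes (inside the chromatin mask) and their
timing relative to expulsion onset.

Because the original imaging data are not public, the package includes a
first-class synthetic-movie generator with per-cell ground truth
(`simulate_movie()`), used throughout the test suite to validate the
pipeline end to end.

## Worked example

```r
library(nucexpel)

# a small wild-type-like field: all cells apoptotic, 85% truly expelling
cfg <- simulation_config(n_cells = 100, fraction_apoptotic = 1,
                         fraction_expelling = 0.85, seed = 11)
sim <- simulate_movie(cfg)
res <- analyze_movie(sim)          # segment -> track -> normalize -> score
summary(res$scores$score)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#> 0.06436 0.44781 0.51605 0.58515 0.62951 3.05114

# knockout-like negative control: apoptosis, zero true expulsion
ko  <- simulate_movie(simulation_config(n_cells = 100, fraction_apoptotic = 1,
                                        fraction_expelling = 0, seed = 12))
kres <- analyze_movie(ko)

roc <- build_roc(res$scores$score, kres$scores$score)
roc
#> <expulsion_roc> 100 pos / 100 neg cells, AUC = 0.9149
thr <- select_threshold(roc, "youden")
thr
#> [1] 0.387297
classify_and_summarize(
  dplyr::bind_rows(dplyr::mutate(res$scores,  condition = "WT"),
                   dplyr::mutate(kres$scores, condition = "KO")), thr)$summary
#> # A tibble: 2 x 6
#>   condition n_cells n_scored n_unscorable n_positive_calls percent_expulsion
#>   <chr>       <int>    <int>        <int>            <int>             <dbl>
#> 1 KO            100      100            0                0                 0
#> 2 WT            100      100            0               82                82
```

82 of 100 wild-type-like cells are called as undergoing nuclear expulsion
(83 truly expel in this realization), and none of the knockout-like cells
are — the score separates expanding from merely condensing/fragmenting
chromatin, and the Youden threshold (0.39 fold/frame here) sits in the gap
between the two score distributions.

`run_benchmark()` scales this to pooled multi-field cohorts, and
`run_pipeline()` orchestrates simulate → track → score → calibrate →
calcium → report from one config list, writing CSV/JSON artifacts and a
hash manifest. `autoplot(roc)`, `plot_median_expansion()` and
`plot_expansion_histogram()` produce the standard figures.

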