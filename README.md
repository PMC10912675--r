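# myoscore

Continuous single-cell differentiation scores from live-imaging
trajectories of myoblast differentiation and fusion.

## What it does

During induced myoblast differentiation a cell gradually slows down, becomes
more directionally persistent, accumulates F-actin, reaches a terminally
differentiated (fusion-competent) state, and fuses into a myotube. Live
imaging gives per-cell nucleus tracks — but no direct readout of where each
cell sits along that transition.

`myoscore` infers one. It partitions each track into overlapping 2.5-h
temporal segments (31 frames at 5-min sampling, lag 1 frame), extracts a
fixed catalog of time-series features from the displacement series
(dx_t, dy_t) = (x_t − x_{t−1}, y_t − y_{t−1}) and/or the five actin-window
statistics, selects features under Benjamini–Yekutieli FDR control, and
trains a random forest to separate "differentiated" segments (differentiating
condition, hours 12.3–14.8) from "undifferentiated" ones (control segments).
The forest's class probability, evaluated along the whole track, is the
**differentiation score** s(t) ∈ [0, 1] — a monotone proxy for the cell's
state. From each score trajectory the package derives:

- **onset** — last time of the longest run with s ∈ [0.2, 0.3];
- **high stable state** — first time of the longest run with s ∈ [0.7, 0.8];
- **duration** — high stable minus onset;
- **terminal differentiation** — first time of the longest run with s > 0.78;
- **monotonicity** — Spearman ρ of s vs t over the 7.5–14.5 h window;
- **fusion coupling** — per-cell gap between annotated fusion and estimated
  terminal time, with Pearson correlation and D'Agostino K² normality checks.

Group trajectories are compared with two-sample t fields corrected by 1D
random field theory: the critical threshold u* solves
α/2 = S_t(u, ν) + R·(√(4 ln 2)/2π)·(1 + u²/ν)^(−(ν−1)/2), with resel count
R = (nodes − 1)/FWHM and FWHM estimated from normalized residual gradients.
Simple-measurement baselines (local density within 50 µm, speed, actin mean
and derivative, persistence) are included for the contrast between
*discriminating conditions* and *tracking a monotone per-cell state*.

A bundled simulator (`simulate_experiment`) generates two-condition
experiments — differentiating cells with state-dependent speed/persistence,
sigmoidal actin rise and fusion ~3 h after terminal differentiation;
proliferating controls with growing density — with per-cell ground truth, so
the whole pipeline is testable without any data download.

## Worked example

```r
library(myoscore)
cfg   <- pipeline_config()   # 31-frame segments, bands 0.2-0.3 / 0.7-0.8, 0.78, ...
train <- simulate_experiment(sim_config(n_cells_per_condition = 40, seed = 1), cfg)
test  <- simulate_experiment(sim_config(n_cells_per_condition = 40, seed = 2), cfg)

model <- fit_state_classifier(train, mode = "motility", config = cfg, seed = 1)
model
#> <model_bundle> motility forest: 100 trees, depth 12, min node 1; 43 features
#>   training: undifferentiated=70, differentiated=40; cv AUC 0.969

ev <- evaluate(model, held_out_features(test, "motility", cfg))
sprintf("held-out AUC %.3f, accuracy %.3f", ev$auc, ev$accuracy)
#> "held-out AUC 0.933, accuracy 0.978"

diff_cells <- unique(test$tracks$cell_id[test$tracks$condition == "ERKi"])
scores <- score_trajectories(model, test, cells = diff_cells)
timing <- state_timing(scores, cfg)
head(timing[, c("cell_id", "onset_h", "duration_h", "terminal_h", "rho_time")], 4)
#>    cell_id   onset_h duration_h terminal_h   rho_time
#> 1 ERKi_001  4.250000  7.1666667   11.58333  0.9333374
#> 2 ERKi_002  4.916667         NA   13.00000  0.7394164
#> 3 ERKi_003 15.666667  0.6666667   16.50000 -0.4578106
#> 4 ERKi_004  6.750000  5.1666667   12.00000  0.9000825

fc <- fusion_coupling(timing, test$fusion)
sprintf("n=%d cells: median gap %.2f h, Pearson r=%.2f", fc$n, fc$gap_median, fc$pearson_r)
#> "n=40 cells: median gap 4.03 h, Pearson r=0.87"
```

The classifier separates held-out conditions almost perfectly (AUC 0.93),
per-cell scores rise monotonically through the differentiation window
(ρ mostly > 0.7), and estimated terminal-differentiation times correlate
strongly with the simulated fusion times (r = 0.87). The estimated
fusion gap (4.0 h) sits above the generative 3 h because the score crosses
the 0.78 threshold part-way through the gradual transition — see the
vignette (`vignettes/differentiation-scoring.Rmd`) for why this is a
property of thresholding an uncalibrated monotone score.

A thin command-line front end wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/myoscore.R", package="myoscore"))') \
    simulate --out tracks.csv --truth truth.csv --n 150 --seed 1
```

with subcommands `simulate`, `segment`, `train`, `score`, `metrics`, `rft`
and `baseline`.

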