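## Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

## hand-built 2-cell track table
tiny_track_df <- function() {
  data.frame(
    cell_id = rep(c("a", "b"), each = 3),
    condition = "custom",
    frame = rep(0:2, 2),
    x_um = c(10, 11, 12, 50, 50, 50),
    y_um = c(5, 5, 5, 40, 41, 42),
    stringsAsFactors = FALSE)
}

## small simulated experiment pair (train/test seeds differ) plus a trained
## motility model; reused across classifier/metrics/baseline tests
small_study <- function() {
  if (!is.null(.fixtures$study)) return(.fixtures$study)
  cfg <- pipeline_config()
  ts_train <- simulate_experiment(sim_config(n_cells_per_condition = 25, seed = 101), cfg)
  ts_test <- simulate_experiment(sim_config(n_cells_per_condition = 25, seed = 202), cfg)
  model <- suppressWarnings(
    fit_state_classifier(ts_train, mode = "motility", config = cfg, seed = 7))
  diff_cells <- unique(ts_test$tracks$cell_id[ts_test$tracks$condition == "ERKi"])
  scores <- suppressWarnings(
    score_trajectories(model, ts_test, cells = diff_cells, config = cfg))
  .fixtures$study <- list(cfg = cfg, ts_train = ts_train, ts_test = ts_test,
                          model = model, scores = scores)
  .fixtures$study
}

## brute-force O(n^2) oracle for the longest run satisfying a predicate:
## enumerate every contiguous window, keep those where the predicate holds
## everywhere, take the longest (earliest on ties)
oracle_longest_run <- function(values, pred) {
  n <- length(values)
  best <- NULL
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (all(pred(values[i:j]))) {
        if (is.null(best) || (j - i) > (best[2] - best[1])) best <- c(i, j)
      }
    }
  }
  best
}
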