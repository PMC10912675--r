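## ---- simple single-cell measurements and their one-feature classifiers ---
##
## The "simple measurement" baselines quantify whether trivial per-cell
## readouts (crowding, speed, actin level, actin trend, persistence) can
## discriminate the conditions, and whether they behave as a continuous
## state readout (they generally discriminate but are not monotone in time
## per cell, unlike the dynamics-based differentiation score).

#' Local cell density over time
#'
#' For every cell and frame, the number of OTHER cells whose nucleus lies
#' within `density_radius_um` (boundary inclusive). Cells are counted within
#' their own condition only, since each condition is imaged in its own field
#' of view. Run on registered tracks.
#'
#' @param ts A `track_set`.
#' @param config A [pipeline_config()].
#' @return data.frame `cell_id`, `frame`, `t_hours`, `value`.
#' @export
local_density <- function(ts, config = ts$config) {
  stopifnot(inherits(ts, "track_set"))
  r <- config$density_radius_um
  out <- lapply(split(ts$tracks, list(ts$tracks$condition, ts$tracks$frame),
                      drop = TRUE), function(d) {
    n <- nrow(d)
    cnt <- if (n == 1L) 0L else {
      dm <- as.matrix(stats::dist(cbind(d$x_um, d$y_um)))
      as.integer(rowSums(dm <= r) - 1L)
    }
    data.frame(cell_id = d$cell_id, frame = d$frame, t_hours = d$t_hours,
               value = cnt, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$cell_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Instantaneous speed series
#'
#' Per-step Euclidean displacement magnitude, in micrometres per frame
#' (divide by `frame_interval_min` for um/min), timestamped at the step's
#' end frame.
#'
#' @inheritParams local_density
#' @return data.frame `cell_id`, `frame`, `t_hours`, `value`.
#' @export
speed_series <- function(ts, config = ts$config) {
  stopifnot(inherits(ts, "track_set"))
  out <- lapply(split(ts$tracks, ts$tracks$cell_id), function(d) {
    if (nrow(d) < 2L) return(NULL)
    data.frame(cell_id = d$cell_id[-1], frame = d$frame[-1],
               t_hours = d$t_hours[-1],
               value = sqrt(diff(d$x_um)^2 + diff(d$y_um)^2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Migration persistence over sliding windows
#'
#' Ratio of net displacement to full path length within each window of
#' `window_frames` frames (default: one segment length), timestamped at the
#' window end. Persistence 1 means straight-line migration; a closed loop
#' gives 0; a zero-length path is defined as 0.
#'
#' @inheritParams local_density
#' @param window_frames Window length in frames (>= 2).
#' @return data.frame `cell_id`, `frame`, `t_hours`, `value` in \[0, 1\].
#' @export
persistence_series <- function(ts, window_frames = ts$config$segment_len_frames,
                               config = ts$config) {
  stopifnot(inherits(ts, "track_set"), window_frames >= 2L)
  W <- as.integer(window_frames)
  out <- lapply(split(ts$tracks, ts$tracks$cell_id), function(d) {
    n <- nrow(d)
    if (n < W) return(NULL)
    steps <- sqrt(diff(d$x_um)^2 + diff(d$y_um)^2)
    cum <- c(0, cumsum(steps))
    starts <- seq_len(n - W + 1L)
    ends <- starts + W - 1L
    path <- cum[ends] - cum[starts]
    net <- sqrt((d$x_um[ends] - d$x_um[starts])^2 + (d$y_um[ends] - d$y_um[starts])^2)
    p <- ifelse(path > 0, net / path, 0)
    data.frame(cell_id = d$cell_id[ends], frame = d$frame[ends],
               t_hours = d$t_hours[ends], value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Temporal derivative of the actin-window mean
#'
#' First difference of the actin mean divided by the frame interval
#' (intensity units per hour), timestamped at the later frame.
#'
#' @inheritParams local_density
#' @return data.frame `cell_id`, `frame`, `t_hours`, `value`.
#' @export
actin_derivative <- function(ts, config = ts$config) {
  stopifnot(inherits(ts, "track_set"))
  if (!has_actin(ts)) stop("tracks carry no actin statistics", call. = FALSE)
  dt_h <- config$frame_interval_min / 60
  out <- lapply(split(ts$tracks, ts$tracks$cell_id), function(d) {
    if (nrow(d) < 2L) return(NULL)
    data.frame(cell_id = d$cell_id[-1], frame = d$frame[-1],
               t_hours = d$t_hours[-1], value = diff(d$actin_mean) / dt_h,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

simple_measurement <- function(ts, name, config) {
  switch(name,
         local_density = local_density(ts, config),
         speed = speed_series(ts, config),
         actin_mean = {
           if (!has_actin(ts)) stop("tracks carry no actin statistics", call. = FALSE)
           data.frame(cell_id = ts$tracks$cell_id, frame = ts$tracks$frame,
                      t_hours = ts$tracks$t_hours, value = ts$tracks$actin_mean,
                      stringsAsFactors = FALSE)
         },
         actin_derivative = actin_derivative(ts, config),
         persistence = persistence_series(ts, config = config),
         stop("unknown measurement '", name, "'", call. = FALSE))
}

## per-segment mean of each measurement -> feature_matrix over the segments
simple_segment_features <- function(ts, segs, measurements, config = ts$config) {
  vals <- lapply(measurements, function(m) simple_measurement(ts, m, config))
  names(vals) <- measurements
  n <- nrow(segs$meta)
  x <- matrix(NA_real_, n, length(measurements),
              dimnames = list(NULL, measurements))
  seg_by_cell <- split(seq_len(n), segs$meta$cell_id)
  for (m in measurements) {
    v <- vals[[m]]
    by_cell <- split(v, v$cell_id)
    for (cid in names(seg_by_cell)) {
      d <- by_cell[[cid]]
      if (is.null(d)) next
      idx <- seg_by_cell[[cid]]
      prefix <- c(0, cumsum(d$value))  # frames within a cell are contiguous
      s <- match(pmax(segs$meta$start_frame[idx], d$frame[1]), d$frame)
      e <- match(pmin(segs$meta$end_frame[idx], d$frame[nrow(d)]), d$frame)
      ok <- !is.na(s) & !is.na(e) & e >= s
      x[idx[ok], m] <- (prefix[e[ok] + 1L] - prefix[s[ok]]) / (e[ok] - s[ok] + 1L)
    }
  }
  x[!is.finite(x)] <- 0
  structure(list(x = x, meta = segs$meta, mode = "simple"), class = "feature_matrix")
}

#' Single-measurement baseline classifier
#'
#' Trains a random forest on the mean of one simple measurement (or all of
#' density, speed, actin mean and persistence together) per labelled
#' temporal segment, evaluates condition discrimination on held-out tracks,
#' and reports the per-cell score-vs-time Spearman distribution over the
#' differentiation window for side-by-side comparison with the
#' dynamics-based classifiers.
#'
#' @param ts_train,ts_test Labelled-condition `track_set`s (disjoint cells).
#' @param measurement One of `"local_density"`, `"speed"`, `"actin_mean"`,
#'   `"actin_derivative"`, `"persistence"`, or `"all"` (the four main
#'   measurements combined).
#' @param config A [pipeline_config()].
#' @param seed Seed for training.
#' @param rho_conditions Conditions whose cells enter the per-cell
#'   monotonicity distribution (default the differentiating condition).
#' @return List: `model`, `auc`, `evaluation`, `timing` (per-cell table with
#'   `rho_time`), `rho_median`.
#' @export
simple_classifier <- function(ts_train, ts_test, measurement = "local_density",
                              config = ts_train$config, seed = 1L,
                              rho_conditions = "ERKi") {
  meas <- if (identical(measurement, "all")) {
    c("local_density", "speed", "actin_mean", "persistence")
  } else measurement
  segs_tr <- make_segments(ts_train, config)
  segs_tr <- assign_training_labels(segs_tr, config)
  segs_tr <- make_training_set(segs_tr, seed = seed)
  fm_tr <- simple_segment_features(ts_train, segs_tr, meas, config)
  grid <- expand.grid(max_depth = c(6L, 12L), min_node = 1L, num_trees = 100L)
  model <- train_classifier(fm_tr, grid = grid, seed = seed, select = FALSE)

  segs_te <- make_segments(ts_test, config)
  segs_te <- assign_training_labels(segs_te, config)
  lab_te <- subset_segments(segs_te, !is.na(segs_te$meta$label))
  fm_te <- simple_segment_features(ts_test, lab_te, meas, config)
  ev <- evaluate(model, fm_te)

  ## per-cell monotonicity of the baseline score over the diff window
  w <- config$diff_window_hours
  idx <- segs_te$meta$condition %in% rho_conditions &
    segs_te$meta$t_end_h >= w[1] & segs_te$meta$t_end_h <= w[2]
  sub <- subset_segments(segs_te, idx)
  fm_sub <- simple_segment_features(ts_test, sub, meas, config)
  scores <- data.frame(cell_id = sub$meta$cell_id, t_hours = sub$meta$t_end_h,
                       score = predict_scores(model, fm_sub),
                       stringsAsFactors = FALSE)
  timing <- state_timing(scores, config)
  list(model = model, auc = ev$auc, evaluation = ev[c("auc", "accuracy", "precision", "recall", "n")],
       timing = timing, rho_median = stats::median(timing$rho_time, na.rm = TRUE))
}
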