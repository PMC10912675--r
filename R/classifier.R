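#' Default random-forest hyperparameter grid
#'
#' Spans the published optima for the motility (`max_depth` 12, 100 trees)
#' and actin (`max_depth` 20, 200 trees) classifiers plus a neighbouring
#' depth, with `min_samples_leaf` fixed at 1.
#'
#' @return data.frame with columns `max_depth`, `min_node`, `num_trees`.
#' @export
default_grid <- function() {
  expand.grid(max_depth = c(12L, 16L, 20L), min_node = 1L,
              num_trees = c(100L, 200L))
}

#' Train a differentiation-state random forest
#'
#' Selects features under Benjamini-Yekutieli FDR control, grid-searches the
#' forest hyperparameters with stratified k-fold cross-validation maximizing
#' AUC, and refits the best configuration on all labelled segments. Scores
#' are the forest's class probability for "differentiated" (no calibration is
#' applied; the score is used as a monotone, not linear, state proxy).
#'
#' @param fm A labelled `feature_matrix` (training rows are those with a
#'   non-`NA` label).
#' @param grid Hyperparameter grid as from [default_grid()].
#' @param cv_folds Number of stratified folds (>= 2).
#' @param seed Seed controlling fold assignment and forest growth.
#' @param alpha FDR level for feature selection; `select = FALSE` skips
#'   selection and uses every column.
#' @param select Whether to run feature selection.
#' @return A `model_bundle`: fitted forest, selected feature names, mode,
#'   chosen hyperparameters, cross-validation table and training metadata.
#' @export
train_classifier <- function(fm, grid = default_grid(), cv_folds = 5L,
                             seed = 1L, alpha = 0.05, select = TRUE) {
  stopifnot(inherits(fm, "feature_matrix"), cv_folds >= 2L)
  keep <- !is.na(fm$meta$label)
  y <- factor(fm$meta$label[keep], levels = c("undifferentiated", "differentiated"))
  if (nlevels(droplevels(y)) < 2L) {
    stop("training requires both classes", call. = FALSE)
  }
  feats <- if (select) select_features(fm, alpha) else colnames(fm$x)
  if (!length(feats)) {
    warning("no features survived selection at alpha = ", alpha,
            "; falling back to the full catalog", call. = FALSE)
    feats <- colnames(fm$x)
  }
  x <- as.data.frame(fm$x[keep, feats, drop = FALSE])

  folds <- stratified_folds(y, cv_folds, seed)
  cv_auc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    aucs <- numeric(cv_folds)
    for (f in seq_len(cv_folds)) {
      tr <- folds != f
      if (nlevels(droplevels(y[tr])) < 2L || nlevels(droplevels(y[!tr])) < 2L) {
        stop("stratification error: a fold contains a single class", call. = FALSE)
      }
      fit <- fit_forest(x[tr, , drop = FALSE], y[tr], grid[g, ], seed)
      p <- stats::predict(fit, data = x[!tr, , drop = FALSE])$predictions[, "differentiated"]
      aucs[f] <- auc_rank(p, y[!tr] == "differentiated")
    }
    cv_auc[g] <- mean(aucs)
  }
  best <- which.max(cv_auc)  # earliest grid row on ties
  forest <- fit_forest(x, y, grid[best, ], seed)
  structure(list(
    forest = forest,
    features = feats,
    mode = fm$mode,
    best = as.list(grid[best, ]),
    cv = cbind(grid, cv_auc = cv_auc),
    class_counts = table(y),
    seed = seed), class = "model_bundle")
}

fit_forest <- function(x, y, par, seed) {
  ranger::ranger(x = x, y = y, probability = TRUE,
                 num.trees = par$num_trees, max.depth = par$max_depth,
                 min.node.size = par$min_node, importance = "impurity",
                 seed = seed, num.threads = 1L)
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("<model_bundle> %s forest: %d trees, depth %d, min node %d; %d features\n",
              x$mode, x$best$num_trees, x$best$max_depth, x$best$min_node,
              length(x$features)))
  cat(sprintf("  training: %s; cv AUC %.3f\n",
              paste(names(x$class_counts), x$class_counts, sep = "=", collapse = ", "),
              max(x$cv$cv_auc)))
  invisible(x)
}

#' Differentiation scores for feature rows
#'
#' @param model A `model_bundle`.
#' @param fm A `feature_matrix` containing all of the model's selected
#'   features (an error names any missing column).
#' @return Numeric scores in \[0, 1\], the forest's probability of the
#'   "differentiated" class.
#' @export
predict_scores <- function(model, fm) {
  stopifnot(inherits(model, "model_bundle"), inherits(fm, "feature_matrix"))
  missing_cols <- setdiff(model$features, colnames(fm$x))
  if (length(missing_cols)) {
    stop("feature matrix is missing model feature(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- as.data.frame(fm$x[, model$features, drop = FALSE])
  stats::predict(model$forest, data = x, num.threads = 1L)$predictions[, "differentiated"]
}

#' Score trajectories for every cell in a track set
#'
#' Segments each track at lag 1, extracts the model's feature mode and scores
#' every segment. Each score is timestamped at its segment's final frame (the
#' time at which the score becomes available), so a track of N frames yields
#' N - L + 1 scores.
#'
#' @param model A `model_bundle`.
#' @param ts A `track_set`.
#' @param cells Optional cell ids to restrict to.
#' @param t_range Optional `(lo, hi)` hours; only segments whose end time
#'   falls inside are scored (saves work when only a window is needed).
#' @param config A [pipeline_config()].
#' @return data.frame with columns `cell_id`, `condition`, `t_hours`, `score`,
#'   times strictly increasing within each cell.
#' @export
score_trajectories <- function(model, ts, cells = NULL, t_range = NULL,
                               config = ts$config) {
  stopifnot(inherits(model, "model_bundle"), inherits(ts, "track_set"))
  if (!is.null(cells)) {
    ts$tracks <- ts$tracks[ts$tracks$cell_id %in% cells, , drop = FALSE]
  }
  segs <- make_segments(ts, config)
  if (!nrow(segs$meta)) {
    warning("no segments could be formed; returning an empty trajectory", call. = FALSE)
    return(data.frame(cell_id = character(0), condition = character(0),
                      t_hours = numeric(0), score = numeric(0)))
  }
  if (!is.null(t_range)) {
    segs <- subset_segments(segs, segs$meta$t_end_h >= t_range[1] &
                              segs$meta$t_end_h <= t_range[2])
  }
  fm <- extract_features(segs, model$mode)
  data.frame(cell_id = segs$meta$cell_id, condition = segs$meta$condition,
             t_hours = segs$meta$t_end_h, score = predict_scores(model, fm),
             stringsAsFactors = FALSE)
}

#' Score trajectory for a single cell
#'
#' @inheritParams score_trajectories
#' @param cell_id The cell to score.
#' @return data.frame `t_hours`, `score`; empty (with a warning) for a track
#'   shorter than one segment.
#' @export
score_trajectory <- function(model, ts, cell_id, config = ts$config) {
  out <- suppressWarnings(score_trajectories(model, ts, cells = cell_id, config = config))
  if (!nrow(out)) {
    warning("track '", cell_id, "' is shorter than one segment; empty trajectory",
            call. = FALSE)
  }
  out[, c("t_hours", "score")]
}

#' Evaluate a classifier on labelled segments
#'
#' @param model A `model_bundle`.
#' @param fm A labelled `feature_matrix` (held-out cells).
#' @param threshold Score threshold for the hard metrics.
#' @return List with `auc`, `accuracy`, `precision`, `recall`, `n`, and the
#'   score/label vectors (for ROC plotting).
#' @export
evaluate <- function(model, fm, threshold = 0.5) {
  keep <- !is.na(fm$meta$label)
  lab <- fm$meta$label[keep] == "differentiated"
  if (!any(lab) || all(lab)) {
    stop("AUC undefined: evaluation set contains a single class", call. = FALSE)
  }
  sub <- fm
  sub$x <- fm$x[keep, , drop = FALSE]
  sub$meta <- fm$meta[keep, , drop = FALSE]
  s <- predict_scores(model, sub)
  pred <- s > threshold
  tp <- sum(pred & lab); fp <- sum(pred & !lab); fn <- sum(!pred & lab)
  list(auc = auc_rank(s, lab),
       accuracy = mean(pred == lab),
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = tp / (tp + fn),
       n = length(s), scores = s, labels = lab)
}

#' AUC of condition discrimination over time
#'
#' At each segment-end time, computes the AUC of the segment scores for
#' separating the differentiating condition (`ERKi`, treated as positive)
#' from the control (`DMSO`), i.e. how well the model tells the conditions
#' apart as the experiment progresses.
#'
#' @param model A `model_bundle`.
#' @param ts A `track_set` containing both conditions.
#' @param times Optional vector of hours; only segments ending within half a
#'   frame of one of these times are scored (a coarse grid keeps this cheap).
#' @param config A [pipeline_config()].
#' @return data.frame `t_hours`, `auc`, `n_pos`, `n_neg`; time points with a
#'   single condition are omitted.
#' @export
auc_over_time <- function(model, ts, times = NULL, config = ts$config) {
  traj <- score_trajectories(model, ts, config = config)
  traj <- traj[traj$condition %in% c("ERKi", "DMSO"), , drop = FALSE]
  if (!nrow(traj)) return(data.frame(t_hours = numeric(0), auc = numeric(0),
                                     n_pos = integer(0), n_neg = integer(0)))
  if (!is.null(times)) {
    tol <- config$frame_interval_min / 60 / 2
    hit <- vapply(traj$t_hours, function(tt) any(abs(tt - times) <= tol), logical(1))
    traj <- traj[hit, , drop = FALSE]
    traj$t_hours <- vapply(traj$t_hours, function(tt) times[which.min(abs(tt - times))],
                           numeric(1))
  }
  out <- lapply(split(traj, traj$t_hours), function(d) {
    pos <- d$condition == "ERKi"
    if (!any(pos) || all(pos)) return(NULL)
    data.frame(t_hours = d$t_hours[1], auc = auc_rank(d$score, pos),
               n_pos = sum(pos), n_neg = sum(!pos))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out[order(out$t_hours), , drop = FALSE]
}

#' Impurity-based feature importance
#'
#' @param model A fitted `model_bundle`.
#' @return data.frame `feature`, `importance` (nonnegative, summing to 1),
#'   in descending order.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "model_bundle"))
  imp <- model$forest$variable.importance
  if (is.null(imp)) stop("model carries no importance scores", call. = FALSE)
  imp <- pmax(imp, 0)
  imp <- imp / sum(imp)
  ord <- order(imp, decreasing = TRUE)
  data.frame(feature = names(imp)[ord], importance = unname(imp[ord]),
             stringsAsFactors = FALSE)
}

#' Save / load a model bundle
#'
#' Round-tripping through disk preserves predictions bit-exactly.
#'
#' @param model A `model_bundle`.
#' @param path File path (RDS format).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "model_bundle"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "model_bundle"))
  model
}
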