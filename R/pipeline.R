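#' Fit a differentiation-state classifier from raw tracks
#'
#' Convenience wrapper chaining the training pipeline: segment the tracks,
#' assign training labels, balance the classes, extract the requested feature
#' mode, select features and grid-search the forest.
#'
#' @param ts A `track_set` containing labelled conditions (`ERKi`, `DMSO`).
#' @param mode Feature mode: `"motility"`, `"actin"` or `"combined"`.
#' @param config A [pipeline_config()].
#' @param seed Seed for subsampling, folds and forest growth.
#' @param grid Hyperparameter grid (see [default_grid()]).
#' @param cv_folds Cross-validation folds.
#' @param neg_pos_ratio Negatives kept per positive (see [make_training_set()]).
#' @param label_window_hours,first_fusion_time_h Passed to
#'   [assign_training_labels()].
#' @return A `model_bundle`.
#' @export
fit_state_classifier <- function(ts, mode = "motility", config = ts$config,
                                 seed = 1L, grid = default_grid(),
                                 cv_folds = 5L, neg_pos_ratio = 1.75,
                                 label_window_hours = NULL,
                                 first_fusion_time_h = NULL) {
  segs <- make_segments(ts, config)
  segs <- assign_training_labels(segs, config,
                                 first_fusion_time_h = first_fusion_time_h,
                                 label_window_hours = label_window_hours)
  train <- make_training_set(segs, neg_pos_ratio = neg_pos_ratio, seed = seed)
  fm <- extract_features(train, mode)
  train_classifier(fm, grid = grid, cv_folds = cv_folds, seed = seed,
                   alpha = config$alpha)
}

#' Labelled held-out feature matrix from a test track set
#'
#' Applies the same segmentation and labelling to an independent experiment
#' and returns the labelled segments' features, for [evaluate()].
#'
#' @inheritParams fit_state_classifier
#' @return A labelled `feature_matrix`.
#' @export
held_out_features <- function(ts, mode = "motility", config = ts$config,
                              label_window_hours = NULL,
                              first_fusion_time_h = NULL) {
  segs <- make_segments(ts, config)
  segs <- assign_training_labels(segs, config,
                                 first_fusion_time_h = first_fusion_time_h,
                                 label_window_hours = label_window_hours)
  extract_features(subset_segments(segs, !is.na(segs$meta$label)), mode)
}
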