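#' Pipeline configuration
#'
#' Bundles the constants shared across the scoring pipeline: imaging geometry,
#' temporal-segment shape, the score bands used by the timing estimators, and
#' significance levels.
#'
#' @param frame_interval_min Minutes between consecutive frames.
#' @param pixel_size_um Physical pixel size in micrometres.
#' @param segment_len_frames Frames per temporal segment. The default of 31
#'   frames spans 2.5 h at 5-min sampling (30 intervals plus both endpoints).
#' @param segment_lag_frames Frames between consecutive segment starts
#'   (1 = maximal overlap, one new segment per frame).
#' @param actin_window_um Side of the square actin quantification window, in
#'   micrometres, centred on the nucleus.
#' @param density_radius_um Neighbourhood radius for local density counts.
#' @param onset_band Closed score interval whose longest run marks the
#'   differentiation onset (its last time point).
#' @param high_band Closed score interval whose longest run marks the high
#'   stable state (its first time point).
#' @param terminal_threshold Score that the longest strictly-above run must
#'   exceed to define terminal differentiation.
#' @param diff_window_hours Time window (hours) over which score-vs-time
#'   monotonicity (Spearman) is evaluated.
#' @param label_window_hours Fixed window (hours) used to label differentiating
#'   cells as "differentiated" during training.
#' @param alpha Significance level for feature selection and group inference.
#'
#' @return An object of class `pipeline_config` (a validated named list).
#' @export
pipeline_config <- function(frame_interval_min = 5,
                            pixel_size_um = 0.462,
                            segment_len_frames = 31L,
                            segment_lag_frames = 1L,
                            actin_window_um = 32,
                            density_radius_um = 50,
                            onset_band = c(0.2, 0.3),
                            high_band = c(0.7, 0.8),
                            terminal_threshold = 0.78,
                            diff_window_hours = c(7.5, 14.5),
                            label_window_hours = c(12.3, 14.8),
                            alpha = 0.05) {
  cfg <- list(
    frame_interval_min = as.numeric(frame_interval_min),
    pixel_size_um = as.numeric(pixel_size_um),
    segment_len_frames = as.integer(segment_len_frames),
    segment_lag_frames = as.integer(segment_lag_frames),
    actin_window_um = as.numeric(actin_window_um),
    density_radius_um = as.numeric(density_radius_um),
    onset_band = as.numeric(onset_band),
    high_band = as.numeric(high_band),
    terminal_threshold = as.numeric(terminal_threshold),
    diff_window_hours = as.numeric(diff_window_hours),
    label_window_hours = as.numeric(label_window_hours),
    alpha = as.numeric(alpha)
  )
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  pos <- c("frame_interval_min", "pixel_size_um", "segment_len_frames",
           "segment_lag_frames", "actin_window_um", "density_radius_um")
  for (f in pos) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] <= 0) {
      stop("pipeline_config: '", f, "' must be positive", call. = FALSE)
    }
  }
  if (cfg$segment_lag_frames > cfg$segment_len_frames) {
    stop("pipeline_config: segment_lag_frames must not exceed segment_len_frames",
         call. = FALSE)
  }
  for (f in c("onset_band", "high_band", "diff_window_hours", "label_window_hours")) {
    b <- cfg[[f]]
    if (length(b) != 2L || any(!is.finite(b)) || b[1] > b[2]) {
      stop("pipeline_config: '", f, "' must be a non-decreasing interval of length 2",
           call. = FALSE)
    }
  }
  if (!(cfg$onset_band[2] < cfg$high_band[1] &&
        cfg$high_band[1] < cfg$terminal_threshold &&
        cfg$terminal_threshold <= 1)) {
    stop("pipeline_config: need onset_band max < high_band min < terminal_threshold <= 1",
         call. = FALSE)
  }
  if (!is.finite(cfg$alpha) || cfg$alpha < 0 || cfg$alpha > 1) {
    stop("pipeline_config: alpha must lie in [0, 1]", call. = FALSE)
  }
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(sprintf("  segment: %d frames @ %g min (lag %d)\n",
              x$segment_len_frames, x$frame_interval_min, x$segment_lag_frames))
  cat(sprintf("  actin window %g um, density radius %g um, pixel %g um\n",
              x$actin_window_um, x$density_radius_um, x$pixel_size_um))
  cat(sprintf("  bands: onset [%g, %g], high [%g, %g], terminal > %g\n",
              x$onset_band[1], x$onset_band[2], x$high_band[1], x$high_band[2],
              x$terminal_threshold))
  cat(sprintf("  correlation window %g-%g h, label window %g-%g h, alpha %g\n",
              x$diff_window_hours[1], x$diff_window_hours[2],
              x$label_window_hours[1], x$label_window_hours[2], x$alpha))
  invisible(x)
}

#' Read / write a pipeline configuration file
#'
#' The on-disk format is a flat `key: value` YAML mapping with interval fields
#' written as two-element sequences. Unknown keys are rejected.
#'
#' @param path File path.
#' @return `read_pipeline_config()` returns a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read config files", call. = FALSE)
  }
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @param cfg A `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to write config files", call. = FALSE)
  }
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Simulation configuration
#'
#' Parameters of the synthetic two-condition experiment: a differentiating
#' condition in which each cell slows down, becomes more directionally
#' persistent and ramps up actin after a per-cell onset time, then fuses a few
#' hours after terminal differentiation; and a proliferating control whose
#' cells keep undifferentiated dynamics and divide, so local density grows.
#'
#' Speeds are mean step speeds in micrometres per minute; heading sigmas are
#' the per-frame standard deviation (radians) of the heading increment of the
#' persistent random walk (small sigma = persistent motion). Onset, duration
#' and the differentiation-to-fusion gap are drawn per cell from normal
#' distributions with the given means/SDs (hours).
#'
#' @param n_cells_per_condition Cells seeded per condition.
#' @param duration_hours Length of the imaging window; imaging starts 1.5 h
#'   after treatment, so the default 21.5 h spans 1.5-23 h.
#' @param frame_interval_min Minutes per frame.
#' @param field_um Field of view (width, height) in micrometres; boundaries
#'   are reflective.
#' @param speed_undiff_um_min,speed_diff_um_min Mean step speed before/after
#'   differentiation.
#' @param heading_sigma_undiff,heading_sigma_diff Heading-increment SD
#'   before/after differentiation.
#' @param onset_mean_h,onset_sd_h Per-cell differentiation onset distribution.
#' @param duration_mean_h,duration_sd_h Per-cell differentiation duration
#'   (onset to terminal) distribution.
#' @param actin_base Baseline actin-window mean intensity (arbitrary units).
#' @param actin_fold Fold change of the actin mean at the differentiated
#'   plateau relative to baseline.
#' @param actin_noise_cv Multiplicative coefficient of variation of the
#'   per-frame actin readout.
#' @param fusion_gap_mean_h,fusion_gap_sd_h Terminal-differentiation-to-fusion
#'   gap distribution.
#' @param division_rate_per_cell_h Division rate (per cell per hour) in the
#'   control condition only.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_cells_per_condition = 150L,
                       duration_hours = 21.5,
                       frame_interval_min = 5,
                       field_um = c(1500, 1500),
                       speed_undiff_um_min = 0.8,
                       speed_diff_um_min = 0.3,
                       heading_sigma_undiff = 1.2,
                       heading_sigma_diff = 0.4,
                       onset_mean_h = 11,
                       onset_sd_h = 2,
                       duration_mean_h = 3.5,
                       duration_sd_h = 1,
                       actin_base = 100,
                       actin_fold = 1.8,
                       actin_noise_cv = 0.05,
                       fusion_gap_mean_h = 3,
                       fusion_gap_sd_h = 0.75,
                       division_rate_per_cell_h = 0.03,
                       seed = 1L) {
  sim <- list(
    n_cells_per_condition = as.integer(n_cells_per_condition),
    duration_hours = as.numeric(duration_hours),
    frame_interval_min = as.numeric(frame_interval_min),
    field_um = as.numeric(field_um),
    speed_undiff_um_min = as.numeric(speed_undiff_um_min),
    speed_diff_um_min = as.numeric(speed_diff_um_min),
    heading_sigma_undiff = as.numeric(heading_sigma_undiff),
    heading_sigma_diff = as.numeric(heading_sigma_diff),
    onset_mean_h = as.numeric(onset_mean_h),
    onset_sd_h = as.numeric(onset_sd_h),
    duration_mean_h = as.numeric(duration_mean_h),
    duration_sd_h = as.numeric(duration_sd_h),
    actin_base = as.numeric(actin_base),
    actin_fold = as.numeric(actin_fold),
    actin_noise_cv = as.numeric(actin_noise_cv),
    fusion_gap_mean_h = as.numeric(fusion_gap_mean_h),
    fusion_gap_sd_h = as.numeric(fusion_gap_sd_h),
    division_rate_per_cell_h = as.numeric(division_rate_per_cell_h),
    seed = as.integer(seed)
  )
  class(sim) <- "sim_config"
  validate_sim_config(sim)
}

validate_sim_config <- function(sim) {
  stopifnot(inherits(sim, "sim_config"))
  if (sim$n_cells_per_condition < 1L) stop("sim_config: need at least one cell", call. = FALSE)
  for (f in c("duration_hours", "frame_interval_min", "speed_undiff_um_min",
              "speed_diff_um_min", "actin_base", "actin_fold")) {
    if (!is.finite(sim[[f]]) || sim[[f]] <= 0) {
      stop("sim_config: '", f, "' must be positive", call. = FALSE)
    }
  }
  for (f in c("heading_sigma_undiff", "heading_sigma_diff", "onset_sd_h",
              "duration_sd_h", "actin_noise_cv", "fusion_gap_sd_h",
              "division_rate_per_cell_h")) {
    if (!is.finite(sim[[f]]) || sim[[f]] < 0) {
      stop("sim_config: '", f, "' must be nonnegative", call. = FALSE)
    }
  }
  if (length(sim$field_um) != 2L || any(sim$field_um <= 0)) {
    stop("sim_config: field_um must be two positive lengths", call. = FALSE)
  }
  if (sim$onset_mean_h + sim$duration_mean_h >= 1.5 + sim$duration_hours) {
    stop("sim_config: mean terminal time falls outside the imaging window", call. = FALSE)
  }
  sim
}
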