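#' Construct a track set
#'
#' A `track_set` holds per-frame nucleus positions for a collection of cells,
#' optional per-frame actin-window intensity statistics, the pipeline
#' configuration, and optional fusion annotations / simulator ground truth.
#'
#' Coordinates are micrometres in image convention (origin top-left, y down);
#' frames are 0-based; `t_hours` counts from treatment time (imaging typically
#' starts at 1.5 h).
#'
#' @param tracks data.frame with columns `cell_id`, `condition`, `frame`,
#'   `t_hours`, `x_um`, `y_um` and optionally `actin_min`, `actin_max`,
#'   `actin_mean`, `actin_median`, `actin_std`.
#' @param config A [pipeline_config()].
#' @param truth Optional simulator ground truth (per-cell `onset_h`,
#'   `terminal_h`, `fusion_h`).
#' @param fusion Optional fusion annotations (`cell_id`, `fusion_time_hours`).
#' @param provenance Free-text origin note.
#' @return An object of class `track_set`.
#' @export
track_set <- function(tracks, config = pipeline_config(), truth = NULL,
                      fusion = NULL, provenance = "") {
  stopifnot(is.data.frame(tracks), inherits(config, "pipeline_config"))
  required <- c("cell_id", "frame", "x_um", "y_um")
  missing_cols <- setdiff(required, names(tracks))
  if (length(missing_cols)) {
    stop("track table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tracks$cell_id <- as.character(tracks$cell_id)
  tracks$frame <- as.integer(tracks$frame)
  if (is.null(tracks$condition)) tracks$condition <- "custom"
  if (is.null(tracks$t_hours)) {
    tracks$t_hours <- 1.5 + tracks$frame * config$frame_interval_min / 60
  }
  tracks <- tracks[order(tracks$cell_id, tracks$frame), , drop = FALSE]
  rownames(tracks) <- NULL
  if (anyDuplicated(tracks[, c("cell_id", "frame")])) {
    dup <- tracks[duplicated(tracks[, c("cell_id", "frame")]), ]
    stop("duplicate (cell_id, frame) rows, e.g. cell '", dup$cell_id[1],
         "' frame ", dup$frame[1], call. = FALSE)
  }
  dt <- stats::ave(tracks$t_hours, tracks$cell_id, FUN = function(t) c(1, diff(t)))
  if (any(dt <= 0)) {
    stop("t_hours must be strictly increasing within each track", call. = FALSE)
  }
  actin_cols <- paste0("actin_", c("min", "max", "mean", "median", "std"))
  have <- actin_cols %in% names(tracks)
  if (any(have) && !all(have)) {
    stop("actin statistics must be all present or all absent; missing: ",
         paste(actin_cols[!have], collapse = ", "), call. = FALSE)
  }
  structure(list(tracks = tracks, config = config, truth = truth,
                 fusion = fusion, provenance = provenance),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  n_cells <- length(unique(x$tracks$cell_id))
  cat(sprintf("<track_set> %d cells, %d rows, conditions: %s\n",
              n_cells, nrow(x$tracks),
              paste(sort(unique(x$tracks$condition)), collapse = ", ")))
  if (has_actin(x)) cat("  actin-window statistics present\n")
  if (!is.null(x$truth)) cat("  simulator ground truth attached\n")
  if (!is.null(x$fusion)) cat("  fusion annotations attached\n")
  invisible(x)
}

has_actin <- function(ts) "actin_mean" %in% names(ts$tracks)

#' Number of cells in a track set
#' @param ts A `track_set`.
#' @export
n_cells <- function(ts) length(unique(ts$tracks$cell_id))

#' Read a track table from CSV
#'
#' Expects the documented track-CSV dialect: required columns `cell_id`,
#' `frame`, `x_um`, `y_um`; optional `t_hours` (derived from the frame index
#' and frame interval when absent, with imaging starting at 1.5 h),
#' `condition`, and the five `actin_*` statistics.
#'
#' @param path CSV file path.
#' @param config A [pipeline_config()].
#' @return A `track_set`.
#' @export
read_tracks <- function(path, config = pipeline_config()) {
  if (!file.exists(path)) stop("track file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("cell_id", "frame", "x_um", "y_um")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("track CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  track_set(df, config = config, provenance = paste0("read_tracks:", path))
}

#' Write a track table to CSV
#' @param ts A `track_set`.
#' @param path Output CSV path.
#' @export
write_tracks <- function(ts, path) {
  stopifnot(inherits(ts, "track_set"))
  utils::write.csv(ts$tracks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read fusion annotations (columns `cell_id`, `fusion_time_hours`)
#' @param path CSV file path.
#' @export
read_fusion_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("cell_id", "fusion_time_hours"), names(df))
  if (length(missing_cols)) {
    stop("fusion CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$cell_id <- as.character(df$cell_id)
  df
}

#' Read per-frame registration offsets (columns `frame`, `dx_um`, `dy_um`)
#' @param path CSV file path.
#' @export
read_frame_offsets <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("frame", "dx_um", "dy_um"), names(df))
  if (length(missing_cols)) {
    stop("offsets CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df[order(df$frame), , drop = FALSE]
}

#' Estimate per-frame stage-drift offsets from the tracks themselves
#'
#' For each adjacent frame pair the offset increment is the median, over all
#' cells present in both frames, of the per-cell displacement; increments are
#' accumulated from frame 0 (offset zero) so that `offset[k]` is the drift of
#' frame `k` relative to the first frame. The median is robust to a minority
#' of fast-moving cells, but with very few cells genuine motion is read as
#' drift.
#'
#' @param ts A `track_set`.
#' @return data.frame with columns `frame`, `dx_um`, `dy_um`, one row per
#'   frame present in the set.
#' @export
estimate_frame_offsets <- function(ts) {
  stopifnot(inherits(ts, "track_set"))
  tr <- ts$tracks
  frames <- sort(unique(tr$frame))
  if (length(frames) < 2L) stop("need at least two frames to estimate offsets", call. = FALSE)
  dx <- dy <- numeric(length(frames))
  by_frame <- split(tr[, c("cell_id", "x_um", "y_um")], tr$frame)
  for (k in 2:length(frames)) {
    a <- by_frame[[as.character(frames[k - 1])]]
    b <- by_frame[[as.character(frames[k])]]
    shared <- intersect(a$cell_id, b$cell_id)
    if (!length(shared)) {
      stop("no cells shared between frames ", frames[k - 1], " and ", frames[k],
           "; cannot estimate drift across this gap", call. = FALSE)
    }
    ia <- match(shared, a$cell_id); ib <- match(shared, b$cell_id)
    dx[k] <- dx[k - 1] + stats::median(b$x_um[ib] - a$x_um[ia])
    dy[k] <- dy[k - 1] + stats::median(b$y_um[ib] - a$y_um[ia])
  }
  data.frame(frame = frames, dx_um = dx, dy_um = dy)
}

#' Apply per-frame translation offsets to a track set
#'
#' Subtracts `offset[k]` from every position observed at frame `k`
#' (translation-only registration); all other fields are unchanged.
#'
#' @param ts A `track_set`.
#' @param offsets data.frame as returned by [estimate_frame_offsets()] or
#'   [read_frame_offsets()]; must cover every frame present in `ts`.
#' @return The registered `track_set`.
#' @export
register_tracks <- function(ts, offsets) {
  stopifnot(inherits(ts, "track_set"))
  frames <- sort(unique(ts$tracks$frame))
  if (!setequal(offsets$frame, frames)) {
    stop("offsets must cover exactly the ", length(frames),
         " frames present in the track set", call. = FALSE)
  }
  idx <- match(ts$tracks$frame, offsets$frame)
  ts$tracks$x_um <- ts$tracks$x_um - offsets$dx_um[idx]
  ts$tracks$y_um <- ts$tracks$y_um - offsets$dy_um[idx]
  ts
}

#' Inject a rigid per-frame drift into a track set (testing aid)
#'
#' Adds `rate_um_per_frame * frame` to every position, emulating cumulative
#' stage drift that [estimate_frame_offsets()] should recover.
#'
#' @param ts A `track_set`.
#' @param rate_um_per_frame Numeric length-2 drift per frame (dx, dy).
#' @export
inject_drift <- function(ts, rate_um_per_frame) {
  stopifnot(inherits(ts, "track_set"), length(rate_um_per_frame) == 2L)
  ts$tracks$x_um <- ts$tracks$x_um + rate_um_per_frame[1] * ts$tracks$frame
  ts$tracks$y_um <- ts$tracks$y_um + rate_um_per_frame[2] * ts$tracks$frame
  ts
}

#' Actin intensity statistics in a window around a nucleus
#'
#' Crops a square window of side `actin_window_um` (in pixels:
#' `round(actin_window_um / pixel_size_um)`, 69 px at the defaults) centred on
#' the nucleus position and returns the five summary statistics of the pixel
#' intensities. Windows extending beyond the image are clipped at the border,
#' not discarded.
#'
#' @param frame_image Numeric matrix, rows = y, columns = x.
#' @param center_um Length-2 numeric (x, y) in micrometres; must fall inside
#'   the image.
#' @param config A [pipeline_config()] supplying `pixel_size_um` and
#'   `actin_window_um`.
#' @return Named numeric vector `c(min, max, mean, median, std)`; `std` is the
#'   sample standard deviation (0 for a single-pixel window).
#' @export
quantify_actin_window <- function(frame_image, center_um, config = pipeline_config()) {
  stopifnot(is.matrix(frame_image), length(center_um) == 2L)
  p <- config$pixel_size_um
  nx <- ncol(frame_image); ny <- nrow(frame_image)
  if (center_um[1] < 0 || center_um[1] >= nx * p ||
      center_um[2] < 0 || center_um[2] >= ny * p) {
    stop("window center (", center_um[1], ", ", center_um[2],
         ") um lies outside the image", call. = FALSE)
  }
  cx <- floor(center_um[1] / p) + 1L
  cy <- floor(center_um[2] / p) + 1L
  side <- max(1L, round(config$actin_window_um / p))
  lo <- (side - 1L) %/% 2L
  hi <- side - 1L - lo
  cols <- max(1L, cx - lo):min(nx, cx + hi)
  rows <- max(1L, cy - lo):min(ny, cy + hi)
  px <- frame_image[rows, cols]
  s <- if (length(px) > 1L) stats::sd(px) else 0
  c(min = min(px), max = max(px), mean = mean(px),
    median = stats::median(px), std = s)
}
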