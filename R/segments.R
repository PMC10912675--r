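#' Partition tracks into overlapping temporal segments
#'
#' Slides a window of `segment_len_frames` frames (default 31, i.e. 2.5 h at
#' 5-min sampling) along each gap-free track at a lag of `segment_lag_frames`
#' (default 1 frame = 5 min), producing for each window the per-step
#' displacement series (dx, dy; one entry fewer than the window length) and,
#' when present, the five actin-statistic series. A track of N frames yields
#' `N - L + 1` segments at lag 1.
#'
#' @param ts A `track_set`.
#' @param config A [pipeline_config()]; defaults to the one stored in `ts`.
#' @return A `segment_set`: list with `meta` (data.frame: `cell_id`,
#'   `condition`, `start_frame`, `end_frame`, `t_start_h`, `t_end_h`,
#'   `label`), displacement matrices `dx`, `dy` (segments x L-1), an `actin`
#'   list of five matrices (segments x L) or `NULL`, the segment length `L`
#'   and the config. Tracks shorter than L are skipped with one warning;
#'   a track with missing frames raises an error naming the cell.
#' @export
make_segments <- function(ts, config = ts$config) {
  stopifnot(inherits(ts, "track_set"))
  L <- config$segment_len_frames
  lag <- config$segment_lag_frames
  with_act <- has_actin(ts)
  acols <- paste0("actin_", c("min", "max", "mean", "median", "std"))

  by_cell <- split(ts$tracks, ts$tracks$cell_id)
  skipped <- character(0)
  meta <- list(); dxs <- list(); dys <- list()
  act <- if (with_act) stats::setNames(vector("list", 5), acols) else NULL

  for (tr in by_cell) {
    nf <- nrow(tr)
    if (any(diff(tr$frame) != 1L)) {
      stop("track '", tr$cell_id[1], "' has missing frames; segmentation requires gap-free tracks",
           call. = FALSE)
    }
    if (nf < L) { skipped <- c(skipped, tr$cell_id[1]); next }
    starts <- seq.int(1L, nf - L + 1L, by = lag)
    idx_disp <- outer(starts, 0:(L - 2L), "+")   # rows: segments, into step series
    idx_full <- outer(starts, 0:(L - 1L), "+")
    dx <- diff(tr$x_um); dy <- diff(tr$y_um)
    meta[[length(meta) + 1L]] <- data.frame(
      cell_id = tr$cell_id[1], condition = tr$condition[1],
      start_frame = tr$frame[starts], end_frame = tr$frame[starts + L - 1L],
      t_start_h = tr$t_hours[starts], t_end_h = tr$t_hours[starts + L - 1L],
      label = NA_character_, stringsAsFactors = FALSE)
    dxs[[length(dxs) + 1L]] <- matrix(dx[idx_disp], nrow = length(starts))
    dys[[length(dys) + 1L]] <- matrix(dy[idx_disp], nrow = length(starts))
    if (with_act) {
      for (a in acols) {
        act[[a]] <- c(act[[a]], list(matrix(tr[[a]][idx_full], nrow = length(starts))))
      }
    }
  }
  if (length(skipped)) {
    warning(length(skipped), " track(s) shorter than ", L, " frames skipped: ",
            paste(utils::head(skipped, 5), collapse = ", "),
            if (length(skipped) > 5) ", ..." else "", call. = FALSE)
  }
  if (!length(meta)) {
    return(structure(list(meta = data.frame(), dx = NULL, dy = NULL,
                          actin = NULL, L = L, config = config),
                     class = "segment_set"))
  }
  structure(list(
    meta = do.call(rbind, meta),
    dx = do.call(rbind, dxs),
    dy = do.call(rbind, dys),
    actin = if (with_act) lapply(act, function(m) do.call(rbind, m)) else NULL,
    L = L, config = config), class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d segments of %d frames from %d cells\n",
              nrow(x$meta), x$L, length(unique(x$meta$cell_id))))
  if (!is.null(x$actin)) cat("  actin series present\n")
  if (any(!is.na(x$meta$label))) {
    cat("  labels:", paste(names(table(x$meta$label)), table(x$meta$label),
                           sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of segments in a segment set
#' @param segs A `segment_set`.
#' @export
n_segments <- function(segs) nrow(segs$meta)

#' Subset a segment set by row indices
#' @param segs A `segment_set`.
#' @param idx Integer or logical row index into the segments.
#' @export
subset_segments <- function(segs, idx) {
  segs$meta <- segs$meta[idx, , drop = FALSE]
  rownames(segs$meta) <- NULL
  segs$dx <- segs$dx[idx, , drop = FALSE]
  segs$dy <- segs$dy[idx, , drop = FALSE]
  if (!is.null(segs$actin)) {
    segs$actin <- lapply(segs$actin, function(m) m[idx, , drop = FALSE])
  }
  segs
}

#' Assign training labels to temporal segments
#'
#' Differentiating-condition (`ERKi`) cells contribute one "differentiated"
#' segment each: the segment whose span coincides (to within one frame) with
#' the positive-label window. The window is, in order of precedence, the
#' explicit `label_window_hours` argument; `[first_fusion - span, first_fusion]`
#' when `first_fusion_time_h` is given (span = one segment length); or the
#' fixed window in `config$label_window_hours` (default 12.3-14.8 h). Control
#' (`DMSO`) cells are tiled with non-overlapping segments across the whole
#' experiment, all labelled "undifferentiated". Segments from perturbation
#' conditions (`p38i`, `ERKi_p38i`) or any other condition are never labelled.
#'
#' @param segs A `segment_set` from [make_segments()].
#' @param config A [pipeline_config()].
#' @param first_fusion_time_h Optional first fusion time observed in the field
#'   of view; anchors the positive-label window to `[t - span, t]`.
#' @param label_window_hours Optional explicit `(start, end)` window in hours.
#' @return The `segment_set` with its `label` column filled
#'   ("differentiated" / "undifferentiated" / `NA`).
#' @export
assign_training_labels <- function(segs, config = segs$config,
                                   first_fusion_time_h = NULL,
                                   label_window_hours = NULL) {
  stopifnot(inherits(segs, "segment_set"))
  if (!nrow(segs$meta)) return(segs)
  dt_h <- config$frame_interval_min / 60
  span <- (segs$L - 1L) * dt_h
  win <- if (!is.null(label_window_hours)) {
    as.numeric(label_window_hours)
  } else if (!is.null(first_fusion_time_h)) {
    c(first_fusion_time_h - span, first_fusion_time_h)
  } else {
    config$label_window_hours
  }
  t_min <- min(segs$meta$t_start_h); t_max <- max(segs$meta$t_end_h)
  if (win[1] < t_min - dt_h || win[2] > t_max + dt_h) {
    stop(sprintf("label window [%.2f, %.2f] h lies outside the imaged span [%.2f, %.2f] h",
                 win[1], win[2], t_min, t_max), call. = FALSE)
  }
  meta <- segs$meta
  meta$label <- NA_character_

  ## positives: per differentiating cell, the segment starting nearest win[1]
  for (id in unique(meta$cell_id[meta$condition == "ERKi"])) {
    rows <- which(meta$cell_id == id)
    d <- abs(meta$t_start_h[rows] - win[1])
    j <- rows[which.min(d)]
    if (min(d) <= dt_h / 2 + 1e-9 && abs(meta$t_end_h[j] - win[2]) <= span / 2) {
      meta$label[j] <- "differentiated"
    }
  }

  ## negatives: non-overlapping tiling of each control track
  ctl <- which(meta$condition == "DMSO")
  if (length(ctl)) {
    first_start <- stats::ave(meta$start_frame[ctl], meta$cell_id[ctl], FUN = min)
    tile <- (meta$start_frame[ctl] - first_start) %% segs$L == 0L
    meta$label[ctl[tile]] <- "undifferentiated"
  }
  segs$meta <- meta
  segs
}

#' Build a balanced training segment set
#'
#' Keeps all labelled segments and subsamples the (far more numerous)
#' undifferentiated segments down to `neg_pos_ratio` negatives per positive,
#' matching the roughly 1.75:1 class balance of published training sets so
#' the forest's raw confidence scores keep their full dynamic range.
#'
#' @param segs A labelled `segment_set` (see [assign_training_labels()]).
#' @param neg_pos_ratio Maximum negatives per positive; `Inf` keeps all.
#' @param seed Seed for the subsample.
#' @return A `segment_set` containing only labelled segments.
#' @export
make_training_set <- function(segs, neg_pos_ratio = 1.75, seed = 1L) {
  stopifnot(inherits(segs, "segment_set"))
  pos <- which(segs$meta$label %in% "differentiated")
  neg <- which(segs$meta$label %in% "undifferentiated")
  if (!length(pos) || !length(neg)) {
    stop("training set needs both differentiated and undifferentiated segments",
         call. = FALSE)
  }
  n_keep <- min(length(neg), ceiling(neg_pos_ratio * length(pos)))
  if (n_keep < length(neg)) {
    neg <- sort(with_seed(seed, sample(neg, n_keep)))
  }
  subset_segments(segs, sort(c(pos, neg)))
}

#' Write / read a segment set as a long-format CSV
#'
#' Series are serialized as semicolon-joined numbers, one row per segment, so
#' segmentations can be persisted and re-loaded reproducibly.
#'
#' @param segs A `segment_set`.
#' @param path CSV path.
#' @export
write_segments <- function(segs, path) {
  ser <- function(m) apply(m, 1L, function(r) paste(format(r, digits = 15, trim = TRUE), collapse = ";"))
  df <- segs$meta
  df$dx <- ser(segs$dx); df$dy <- ser(segs$dy)
  if (!is.null(segs$actin)) for (a in names(segs$actin)) df[[a]] <- ser(segs$actin[[a]])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_segments
#' @param config A [pipeline_config()] for the returned set.
#' @export
read_segments <- function(path, config = pipeline_config()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  de <- function(col) do.call(rbind, lapply(strsplit(col, ";", fixed = TRUE), as.numeric))
  acols <- paste0("actin_", c("min", "max", "mean", "median", "std"))
  with_act <- all(acols %in% names(df))
  meta_cols <- c("cell_id", "condition", "start_frame", "end_frame",
                 "t_start_h", "t_end_h", "label")
  meta <- df[, meta_cols]
  meta$label <- ifelse(meta$label %in% c("differentiated", "undifferentiated"),
                       meta$label, NA_character_)
  dx <- de(df$dx)
  structure(list(meta = meta, dx = dx, dy = de(df$dy),
                 actin = if (with_act) stats::setNames(lapply(acols, function(a) de(df[[a]])), acols) else NULL,
                 L = ncol(dx) + 1L, config = config),
            class = "segment_set")
}
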