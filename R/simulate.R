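#' Simulate a two-condition live-imaging experiment
#'
#' Generates synthetic single-cell tracks with the statistical structure the
#' scoring pipeline assumes. Differentiating cells (condition `ERKi`) follow a
#' persistent random walk whose mean step speed and heading-increment SD
#' interpolate linearly from undifferentiated to differentiated values across
#' each cell's own onset-to-terminal window; their actin-window mean rises
#' sigmoidally (centred at the onset, 10-90% rise time matched to the cell's
#' differentiation duration) from `actin_base` to `actin_base * actin_fold`
#' with multiplicative noise, and each cell fuses a few hours after terminal
#' differentiation, after which its motion variance collapses to near zero.
#' Control cells (condition `DMSO`) keep undifferentiated dynamics and flat
#' actin throughout, and divide at a constant per-cell rate, so local density
#' grows over the experiment. Boundaries are reflective. A fixed seed yields
#' bit-identical output; the caller's RNG state is left untouched.
#'
#' @param sim A [sim_config()].
#' @param config Optional [pipeline_config()] to attach to the returned
#'   `track_set`; its frame interval is taken from `sim`.
#' @return A `track_set` with per-frame `state` labels
#'   (undiff/transition/diff/fused), attached ground `truth` (per-cell
#'   `onset_h`, `terminal_h`, `fusion_h`) and fusion annotations for fusions
#'   observed within the imaging window.
#' @export
simulate_experiment <- function(sim = sim_config(), config = NULL) {
  sim <- validate_sim_config(sim)
  if (is.null(config)) config <- pipeline_config(frame_interval_min = sim$frame_interval_min)
  with_seed(sim$seed, simulate_experiment_impl(sim, config))
}

simulate_experiment_impl <- function(sim, config) {
  dt_min <- sim$frame_interval_min
  dt_h <- dt_min / 60
  n_frames <- round(sim$duration_hours / dt_h) + 1L
  t <- 1.5 + (seq_len(n_frames) - 1L) * dt_h
  n <- sim$n_cells_per_condition

  rows <- list()
  truth <- list()

  ## ---- differentiating condition ----
  onset <- pmax(stats::rnorm(n, sim$onset_mean_h, sim$onset_sd_h), 0.5)
  durn <- pmax(stats::rnorm(n, sim$duration_mean_h, sim$duration_sd_h), 0.5)
  terminal <- onset + durn
  fusion <- terminal + pmax(stats::rnorm(n, sim$fusion_gap_mean_h, sim$fusion_gap_sd_h), 0.1)
  for (i in seq_len(n)) {
    id <- sprintf("ERKi_%03d", i)
    u <- pmin(pmax((t - onset[i]) / durn[i], 0), 1)
    fused <- t >= fusion[i]
    speed <- sim$speed_undiff_um_min + u * (sim$speed_diff_um_min - sim$speed_undiff_um_min)
    sigma <- sim$heading_sigma_undiff + u * (sim$heading_sigma_diff - sim$heading_sigma_undiff)
    speed[fused] <- 0.02
    sigma[fused] <- 0.2
    pos <- walk_positions(n_frames, speed, sigma, dt_min, sim$field_um)
    s <- durn[i] / log(81)  # logistic scale: 10-90% rise spans the duration
    actin_mu <- sim$actin_base * (1 + (sim$actin_fold - 1) * stats::plogis((t - onset[i]) / s))
    ac <- actin_stats_noisy(actin_mu, sim$actin_noise_cv)
    state <- ifelse(fused, "fused", ifelse(u >= 1, "diff", ifelse(u > 0, "transition", "undiff")))
    rows[[length(rows) + 1L]] <- data.frame(
      cell_id = id, condition = "ERKi", frame = seq_len(n_frames) - 1L,
      t_hours = t, x_um = pos[, 1], y_um = pos[, 2], ac, state = state,
      stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(
      cell_id = id, condition = "ERKi", onset_h = onset[i],
      terminal_h = terminal[i], fusion_h = fusion[i], stringsAsFactors = FALSE)
  }

  ## ---- proliferating control: queue of cells, divisions spawn daughters ----
  queue <- lapply(seq_len(n), function(i) {
    list(birth_frame = 0L, start = stats::runif(2) * sim$field_um)
  })
  k <- 0L
  while (length(queue)) {
    cell <- queue[[1]]; queue <- queue[-1]
    k <- k + 1L
    id <- sprintf("DMSO_%03d", k)
    nf <- n_frames - cell$birth_frame
    frames <- cell$birth_frame + seq_len(nf) - 1L
    speed <- rep(sim$speed_undiff_um_min, nf)
    sigma <- rep(sim$heading_sigma_undiff, nf)
    pos <- walk_positions(nf, speed, sigma, dt_min, sim$field_um, start = cell$start)
    ac <- actin_stats_noisy(rep(sim$actin_base, nf), sim$actin_noise_cv)
    rows[[length(rows) + 1L]] <- data.frame(
      cell_id = id, condition = "DMSO", frame = frames, t_hours = t[frames + 1L],
      x_um = pos[, 1], y_um = pos[, 2], ac, state = "undiff",
      stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(
      cell_id = id, condition = "DMSO", onset_h = NA_real_,
      terminal_h = NA_real_, fusion_h = NA_real_, stringsAsFactors = FALSE)
    ## division times: Poisson process along this cell's lifetime
    if (sim$division_rate_per_cell_h > 0) {
      t_rel <- 0
      span <- (nf - 1L) * dt_h
      repeat {
        t_rel <- t_rel + stats::rexp(1, sim$division_rate_per_cell_h)
        if (t_rel >= span) break
        div_frame <- cell$birth_frame + as.integer(ceiling(t_rel / dt_h))
        at <- div_frame - cell$birth_frame + 1L
        start <- pos[at, ] + stats::rnorm(2, 0, 2)
        start <- c(fold_reflect(start[1], sim$field_um[1]),
                   fold_reflect(start[2], sim$field_um[2]))
        if (div_frame <= n_frames - 2L) {
          queue[[length(queue) + 1L]] <- list(birth_frame = div_frame, start = start)
        }
      }
    }
  }

  tracks <- do.call(rbind, rows)
  truth <- do.call(rbind, truth)
  last_t <- t[n_frames]
  fus <- truth[truth$condition == "ERKi" & !is.na(truth$fusion_h) &
                 truth$fusion_h <= last_t, c("cell_id", "fusion_h")]
  names(fus) <- c("cell_id", "fusion_time_hours")
  rownames(fus) <- NULL
  track_set(tracks, config = config, truth = truth, fusion = fus,
            provenance = sprintf("simulate_experiment(seed=%d)", sim$seed))
}

## persistent random walk with per-frame parameters, reflective boundaries
walk_positions <- function(n_frames, speed_um_min, sigma_rad, dt_min, field_um,
                           start = NULL) {
  if (is.null(start)) start <- stats::runif(2) * field_um
  if (n_frames == 1L) return(matrix(start, 1L, 2L))
  nstep <- n_frames - 1L
  heading <- stats::runif(1, 0, 2 * pi) +
    cumsum(stats::rnorm(nstep, 0, sigma_rad[seq_len(nstep)]))
  mean_step <- speed_um_min[seq_len(nstep)] * dt_min
  len <- pmax(stats::rnorm(nstep, mean_step, 0.1 * mean_step), 0)
  x <- start[1] + cumsum(c(0, len * cos(heading)))
  y <- start[2] + cumsum(c(0, len * sin(heading)))
  cbind(fold_reflect(x, field_um[1]), fold_reflect(y, field_um[2]))
}

## reflect coordinates into [0, w] (triangle-wave folding)
fold_reflect <- function(z, w) {
  z <- z %% (2 * w)
  ifelse(z > w, 2 * w - z, z)
}

## five consistent actin-window statistics around a mean intensity curve
actin_stats_noisy <- function(mu, cv) {
  m <- length(mu)
  mean_obs <- mu * (1 + stats::rnorm(m, 0, cv))
  median_obs <- mean_obs * (1 + stats::rnorm(m, 0, 0.3 * cv))
  std_obs <- 0.08 * mu * abs(1 + stats::rnorm(m, 0, cv))
  min_obs <- pmin(mean_obs, median_obs) - 2 * std_obs
  max_obs <- pmax(mean_obs, median_obs) + 2.5 * std_obs
  data.frame(actin_min = min_obs, actin_max = max_obs, actin_mean = mean_obs,
             actin_median = median_obs, actin_std = std_obs)
}

#' Render synthetic actin images for selected frames
#'
#' Draws, per frame, an image of Gaussian blobs centred on each cell with
#' amplitude equal to that cell's actin-window mean, over additive Gaussian
#' background noise. Intended as a fixture for [quantify_actin_window()]:
#' window statistics recomputed from these images track the generative means.
#'
#' @param ts A `track_set` carrying `actin_mean`.
#' @param sim The [sim_config()] used to generate `ts` (for the field size).
#' @param frames Integer vector of frame indices to render (0-based).
#' @param pixel_size_um Rendered pixel size (coarser than the acquisition
#'   pixel keeps fixtures small).
#' @param sigma_um Blob standard deviation.
#' @param background_sd Background noise SD (intensity units).
#' @param seed Seed for the background noise.
#' @return Named list of numeric matrices (rows = y), one per frame.
#' @export
render_actin_frames <- function(ts, sim, frames = 0L, pixel_size_um = 1,
                                sigma_um = 8, background_sd = 1, seed = 1L) {
  stopifnot(inherits(ts, "track_set"))
  if (!has_actin(ts)) stop("tracks carry no actin means; nothing to render", call. = FALSE)
  if (any(sim$field_um < 6 * sigma_um)) {
    stop("field too small to support blobs of sigma ", sigma_um, " um", call. = FALSE)
  }
  nx <- ceiling(sim$field_um[1] / pixel_size_um)
  ny <- ceiling(sim$field_um[2] / pixel_size_um)
  px <- (seq_len(nx) - 0.5) * pixel_size_um
  py <- (seq_len(ny) - 0.5) * pixel_size_um
  with_seed(seed, {
    out <- lapply(frames, function(f) {
      img <- matrix(stats::rnorm(nx * ny, 0, background_sd), ny, nx)
      sub <- ts$tracks[ts$tracks$frame == f, , drop = FALSE]
      for (i in seq_len(nrow(sub))) {
        gx <- exp(-(px - sub$x_um[i])^2 / (2 * sigma_um^2))
        gy <- exp(-(py - sub$y_um[i])^2 / (2 * sigma_um^2))
        img <- img + sub$actin_mean[i] * outer(gy, gx)
      }
      img
    })
    names(out) <- as.character(frames)
    out
  })
}
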