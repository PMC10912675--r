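#' Longest run satisfying a predicate
#'
#' Finds the maximal-length contiguous run of values for which `predicate`
#' is `TRUE`; among equal-length runs the earliest wins.
#'
#' @param values Numeric vector.
#' @param predicate Function mapping the vector to a logical vector.
#' @return `c(start, end)` 1-based indices, or `NULL` if no value qualifies.
#' @export
longest_run <- function(values, predicate) {
  flag <- predicate(values)
  stopifnot(is.logical(flag), length(flag) == length(values))
  flag[is.na(flag)] <- FALSE
  longest_true_run(flag)
}

in_band <- function(band) function(x) x >= band[1] & x <= band[2]

as_trajectory <- function(st) {
  stopifnot(is.data.frame(st), all(c("t_hours", "score") %in% names(st)))
  st[order(st$t_hours), , drop = FALSE]
}

#' Differentiation onset time
#'
#' The onset is the last stable time below threshold: the final time point of
#' the longest run of scores inside the onset band (default \[0.2, 0.3\],
#' bounds inclusive).
#'
#' @param st Score trajectory: data.frame with `t_hours`, `score`.
#' @param config A [pipeline_config()].
#' @return Hours, or `NA` if no score enters the band.
#' @export
detect_onset <- function(st, config = pipeline_config()) {
  st <- as_trajectory(st)
  r <- longest_run(st$score, in_band(config$onset_band))
  if (is.null(r)) NA_real_ else st$t_hours[r[2]]
}

#' High stable state time
#'
#' The first time point of the longest run of scores inside the high band
#' (default \[0.7, 0.8\], bounds inclusive).
#'
#' @inheritParams detect_onset
#' @return Hours, or `NA`.
#' @export
detect_high_stable <- function(st, config = pipeline_config()) {
  st <- as_trajectory(st)
  r <- longest_run(st$score, in_band(config$high_band))
  if (is.null(r)) NA_real_ else st$t_hours[r[1]]
}

#' Differentiation process duration
#'
#' Time elapsed from the onset to the high stable state. `NA` when either
#' endpoint is undefined or when the high run precedes the onset run (the
#' trajectory then has no coherent low-to-high transition).
#'
#' @inheritParams detect_onset
#' @return Hours, or `NA`.
#' @export
differentiation_duration <- function(st, config = pipeline_config()) {
  onset <- detect_onset(st, config)
  high <- detect_high_stable(st, config)
  if (is.na(onset) || is.na(high)) return(NA_real_)
  d <- high - onset
  if (d < 0) {
    message("high stable state precedes onset; duration undefined for this cell")
    return(NA_real_)
  }
  d
}

#' Terminal differentiation time
#'
#' First time point of the longest run of scores strictly above the terminal
#' threshold (default 0.78; the run requirement avoids local score peaks).
#'
#' @inheritParams detect_onset
#' @return Hours, or `NA`.
#' @export
terminal_time <- function(st, config = pipeline_config()) {
  st <- as_trajectory(st)
  thr <- config$terminal_threshold
  r <- longest_run(st$score, function(x) x > thr)
  if (is.null(r)) NA_real_ else st$t_hours[r[1]]
}

#' Score-vs-time monotonicity over the differentiation window
#'
#' Spearman correlation between score and time restricted to the critical
#' differentiation window (default 7.5-14.5 h), the per-cell measure of a
#' monotone state increase.
#'
#' @inheritParams detect_onset
#' @return List `rho`, `p`, `n`; `rho`/`p` are `NA` (with `n` reported) when
#'   fewer than 3 points fall inside the window.
#' @export
score_time_correlation <- function(st, config = pipeline_config()) {
  st <- as_trajectory(st)
  w <- config$diff_window_hours
  sub <- st[st$t_hours >= w[1] & st$t_hours <= w[2], , drop = FALSE]
  if (nrow(sub) < 3L) return(list(rho = NA_real_, p = NA_real_, n = nrow(sub)))
  ct <- suppressWarnings(stats::cor.test(sub$t_hours, sub$score, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = nrow(sub))
}

#' Per-cell state timing table
#'
#' Applies all timing estimators and the score-time correlation to each
#' cell's score trajectory.
#'
#' @param scores data.frame with `cell_id`, `t_hours`, `score` (e.g. from
#'   [score_trajectories()]).
#' @param config A [pipeline_config()].
#' @return data.frame with one row per cell: `cell_id`, `onset_h`,
#'   `high_stable_h`, `duration_h`, `terminal_h`, `rho_time`, `rho_p`.
#' @export
state_timing <- function(scores, config = pipeline_config()) {
  stopifnot(all(c("cell_id", "t_hours", "score") %in% names(scores)))
  out <- lapply(split(scores, scores$cell_id), function(d) {
    ct <- score_time_correlation(d, config)
    data.frame(cell_id = d$cell_id[1],
               onset_h = detect_onset(d, config),
               high_stable_h = detect_high_stable(d, config),
               duration_h = suppressMessages(differentiation_duration(d, config)),
               terminal_h = terminal_time(d, config),
               rho_time = ct$rho, rho_p = ct$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Coupling between terminal differentiation and fusion
#'
#' Joins per-cell terminal-differentiation times with fusion annotations and
#' reports the per-cell gap distribution, the Pearson correlation between
#' terminal and fusion times (a linear association is assumed), and
#' D'Agostino K-squared normality p-values for the terminal, fusion and gap
#' distributions.
#'
#' @param timings data.frame from [state_timing()] (needs `cell_id`,
#'   `terminal_h`).
#' @param fusion data.frame with `cell_id`, `fusion_time_hours`.
#' @return List: `n`, `gap_median`, `gap_mean`, `pearson_r`, `pearson_p`,
#'   `normality_p` (named vector for terminal/fusion/gap), and the merged
#'   per-cell `data`.
#' @export
fusion_coupling <- function(timings, fusion) {
  stopifnot(all(c("cell_id", "terminal_h") %in% names(timings)),
            all(c("cell_id", "fusion_time_hours") %in% names(fusion)))
  d <- merge(timings[, c("cell_id", "terminal_h")], fusion, by = "cell_id")
  d <- d[is.finite(d$terminal_h) & is.finite(d$fusion_time_hours), , drop = FALSE]
  if (nrow(d) < 3L) {
    stop("fusion coupling needs at least 3 cells with both terminal and fusion times",
         call. = FALSE)
  }
  d$gap_h <- d$fusion_time_hours - d$terminal_h
  ct <- suppressWarnings(stats::cor.test(d$terminal_h, d$fusion_time_hours,
                                         method = "pearson"))
  norm_p <- function(x) if (length(x) >= 8L) d_agostino_k2(x)$p.value else NA_real_
  list(n = nrow(d),
       gap_median = stats::median(d$gap_h),
       gap_mean = mean(d$gap_h),
       pearson_r = unname(ct$estimate),
       pearson_p = ct$p.value,
       normality_p = c(terminal = norm_p(d$terminal_h),
                       fusion = norm_p(d$fusion_time_hours),
                       gap = norm_p(d$gap_h)),
       data = d)
}

#' D'Agostino K-squared normality test
#'
#' Omnibus test combining transformed sample skewness and kurtosis into
#' `K2 = Z1(g1)^2 + Z2(g2)^2`, referred to a chi-squared distribution with 2
#' degrees of freedom. Requires at least 8 observations.
#'
#' @param x Numeric vector.
#' @return List `statistic` (K2) and `p.value`.
#' @export
d_agostino_k2 <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L) stop("D'Agostino K-squared test requires n >= 8", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  b1 <- m3 / m2^1.5
  b2 <- m4 / m2^2

  ## skewness: Johnson SU transformation
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  a <- sqrt(2 / (w2 - 1))
  z1 <- if (y == 0) 0 else delta * log(y / a + sqrt((y / a)^2 + 1))

  ## kurtosis: Anscombe-Glynn transformation
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xs <- (b2 - eb2) / sqrt(vb2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  aa <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  denom <- 1 + xs * sqrt(2 / (aa - 4))
  term <- sign(denom) * ((1 - 2 / aa) / abs(denom))^(1 / 3)
  z2 <- (1 - 2 / (9 * aa) - term) / sqrt(2 / (9 * aa))

  k2 <- z1^2 + z2^2
  list(statistic = k2, p.value = stats::pchisq(k2, df = 2, lower.tail = FALSE))
}
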