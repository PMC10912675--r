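## ---- fixed temporal-feature catalog ------------------------------------
##
## 30 named features per channel, computed on every segment series. The
## catalog is explicit (not delegated to an external feature library) so
## column names and values are stable across platforms and runs.

feature_names <- c(
  "mean", "std", "median", "min", "max", "skewness", "kurtosis",
  "abs_energy", "mean_abs_change", "mean_change", "var_first_diff",
  "autocorr_lag1", "autocorr_lag2", "autocorr_lag5", "autocorr_lag10",
  "n_peaks", "longest_above_mean", "longest_below_mean", "count_above_mean",
  "trend_slope", "trend_stderr", "complexity_ce",
  "q10", "q25", "q75", "q90",
  "first_loc_max", "last_loc_max", "first_loc_min", "last_loc_min")

## features for one channel: X is a segments x length matrix
channel_features <- function(X) {
  n <- nrow(X); m <- ncol(X)
  mu <- rowMeans(X)
  cent <- X - mu
  ss <- rowSums(cent^2)
  var_pop <- ss / m
  sd_pop <- sqrt(var_pop)
  std <- sqrt(ss / max(m - 1L, 1L))

  skew <- rowSums(cent^3) / m / sd_pop^3
  skew[!is.finite(skew)] <- 0
  kurt <- rowSums(cent^4) / m / var_pop^2 - 3
  kurt[!is.finite(kurt)] <- 0

  D <- X[, -1L, drop = FALSE] - X[, -m, drop = FALSE]
  mean_abs_change <- rowMeans(abs(D))
  mean_change <- (X[, m] - X[, 1L]) / (m - 1L)
  var_first_diff <- if (ncol(D) >= 2L) {
    apply(D, 1L, stats::var)
  } else rep(0, n)

  ac <- function(l) {
    if (m < l + 2L) return(rep(0, n))
    num <- rowSums(cent[, seq_len(m - l), drop = FALSE] *
                     cent[, (l + 1L):m, drop = FALSE]) / (m - l)
    out <- num / var_pop
    out[!is.finite(out)] <- 0
    out
  }

  ## peak at t: strictly above its 3 left neighbours, >= its 3 right
  ## neighbours (plateau ties credited to the leftmost point)
  n_peaks <- rep(0, n)
  if (m >= 7L) {
    core <- 4L:(m - 3L)
    is_peak <- matrix(TRUE, n, length(core))
    for (o in 1:3) {
      is_peak <- is_peak & (X[, core, drop = FALSE] > X[, core - o, drop = FALSE]) &
        (X[, core, drop = FALSE] >= X[, core + o, drop = FALSE])
    }
    n_peaks <- rowSums(is_peak)
  }

  above <- X > mu
  run_len <- function(flags) {
    apply(flags, 1L, function(f) {
      r <- longest_true_run(f)
      if (is.null(r)) 0L else r[2] - r[1] + 1L
    })
  }
  longest_above <- run_len(above)
  longest_below <- run_len(X < mu)
  count_above <- rowSums(above)

  tt <- 0:(m - 1L)
  sxx <- sum((tt - mean(tt))^2)
  sxy <- rowSums(cent * rep(tt - mean(tt), each = n))
  slope <- sxy / sxx
  sse <- pmax(ss - slope * sxy, 0)
  stderr <- if (m > 2L) sqrt(sse / (m - 2L) / sxx) else rep(0, n)

  ce <- sqrt(rowSums(D^2))
  qs <- t(apply(X, 1L, stats::quantile, probs = c(0.1, 0.25, 0.75, 0.9), names = FALSE))

  loc <- function(M, ties) (max.col(M, ties.method = ties) - 1L) / (m - 1L)

  out <- cbind(
    mu, std, apply(X, 1L, stats::median), X[cbind(seq_len(n), max.col(-X, "first"))],
    X[cbind(seq_len(n), max.col(X, "first"))], skew, kurt,
    rowSums(X^2), mean_abs_change, mean_change, var_first_diff,
    ac(1L), ac(2L), ac(5L), ac(10L),
    n_peaks, longest_above, longest_below, count_above,
    slope, stderr, ce, qs,
    loc(X, "first"), loc(X, "last"), loc(-X, "first"), loc(-X, "last"))
  colnames(out) <- feature_names
  out
}

#' Extract the temporal-feature catalog from segments
#'
#' Computes, for every segment, a fixed catalog of 30 named statistics per
#' channel: distribution summaries (mean, SD, median, extremes, skewness,
#' kurtosis, quantiles), energy and change measures (absolute energy, mean
#' (absolute) change, variance of the first difference - the
#' acceleration-variance analogue for displacement channels - and the
#' complexity estimate `sqrt(sum(diff^2))`), autocorrelations at lags 1, 2, 5
#' and 10, peak and run counts, a linear-trend slope with its standard error,
#' and normalized first/last locations of the extrema. Motility mode uses the
#' dx and dy displacement channels (features of displacements, so they are
#' invariant to where the cell is); actin mode uses the five window-statistic
#' channels; combined concatenates both. Undefined values (constant series,
#' short lags) are imputed to 0, never NaN.
#'
#' @param segs A `segment_set`.
#' @param mode One of `"motility"`, `"actin"`, `"combined"`.
#' @return A `feature_matrix`: list with numeric matrix `x` (segments x
#'   features, columns named `<channel>__<feature>`) and `meta` copied from
#'   the segments (including any labels).
#' @export
extract_features <- function(segs, mode = c("motility", "actin", "combined")) {
  stopifnot(inherits(segs, "segment_set"))
  mode <- match.arg(mode)
  if (!nrow(segs$meta)) stop("no segments to extract features from", call. = FALSE)
  chans <- list()
  if (mode %in% c("motility", "combined")) {
    chans$dx <- segs$dx
    chans$dy <- segs$dy
  }
  if (mode %in% c("actin", "combined")) {
    if (is.null(segs$actin)) {
      stop("mode '", mode, "' requires actin series, which these segments lack",
           call. = FALSE)
    }
    chans <- c(chans, segs$actin)
  }
  mats <- lapply(names(chans), function(ch) {
    f <- channel_features(chans[[ch]])
    colnames(f) <- paste(ch, colnames(f), sep = "__")
    f
  })
  x <- do.call(cbind, mats)
  stopifnot(all(is.finite(x)))
  structure(list(x = x, meta = segs$meta, mode = mode), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d segments x %d features (mode %s)\n",
              nrow(x$x), ncol(x$x), x$mode))
  invisible(x)
}

#' Select discriminative features under FDR control
#'
#' Tests each feature for association with the class label by a two-sample
#' Mann-Whitney U test, corrects the p-values with the Benjamini-Yekutieli
#' step-up procedure (valid under arbitrary dependence between features), and
#' returns the surviving feature names in stable column order.
#'
#' @param fm A labelled `feature_matrix`.
#' @param alpha FDR level; `0` selects nothing.
#' @return Character vector of selected column names.
#' @export
select_features <- function(fm, alpha = 0.05) {
  stopifnot(inherits(fm, "feature_matrix"))
  lab <- fm$meta$label
  keep <- !is.na(lab)
  lab <- lab[keep]
  if (length(unique(lab)) < 2L) {
    stop("feature selection needs both classes present", call. = FALSE)
  }
  if (alpha <= 0) return(character(0))
  x <- fm$x[keep, , drop = FALSE]
  pos <- lab == "differentiated"
  p <- vapply(seq_len(ncol(x)), function(j) {
    a <- x[pos, j]; b <- x[!pos, j]
    if (max(a, b) == min(a, b)) return(1)
    suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
  }, numeric(1))
  p[!is.finite(p)] <- 1
  padj <- stats::p.adjust(p, method = "BY")
  colnames(x)[padj <= alpha]
}
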