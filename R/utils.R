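## evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Area under the ROC curve by rank statistic
#'
#' Mann-Whitney form of the AUC: the probability that a random positive
#' outscores a random negative, with ties counted half.
#'
#' @param scores Numeric scores.
#' @param positive Logical vector, `TRUE` for the positive class.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  positive <- as.logical(positive)
  np <- sum(positive); nn <- sum(!positive)
  if (np == 0L || nn == 0L) {
    stop("AUC undefined: need both classes in the evaluation set", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

## stratified k-fold assignment; returns integer fold id per observation
stratified_folds <- function(y, k, seed) {
  y <- as.factor(y)
  if (any(table(y) < k)) {
    stop("stratification error: a class has fewer members than folds", call. = FALSE)
  }
  folds <- integer(length(y))
  with_seed(seed, {
    for (lv in levels(y)) {
      idx <- which(y == lv)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

## longest run of TRUE in a logical vector: c(start, end) indices or NULL
longest_true_run <- function(flag) {
  if (!length(flag) || !any(flag)) return(NULL)
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values)
  best <- cand[which.max(r$lengths[cand])]  # which.max takes the earliest tie
  c(starts[best], ends[best])
}
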