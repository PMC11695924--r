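# Probability calibration: isotonic regression (pool-adjacent-violators),
# the Venn-Abers interval predictor, and expected calibration error.

# Weighted PAVA on values already sorted by score. Returns the fitted
# nondecreasing vector. Single linear pass with back-merging; exact
# minimizer of the weighted isotonic least-squares problem.
.pava <- function(y, w) {
  n <- length(y)
  if (n == 0L) return(numeric(0))
  val <- numeric(n)
  wt <- numeric(n)
  cnt <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    k <- k + 1L
    val[k] <- y[i]
    wt[k] <- w[i]
    cnt[k] <- 1L
    while (k > 1L && val[k - 1L] > val[k]) {
      tw <- wt[k - 1L] + wt[k]
      val[k - 1L] <- (wt[k - 1L] * val[k - 1L] + wt[k] * val[k]) / tw
      wt[k - 1L] <- tw
      cnt[k - 1L] <- cnt[k - 1L] + cnt[k]
      k <- k - 1L
    }
  }
  rep(val[seq_len(k)], cnt[seq_len(k)])
}

# pool duplicate scores (weighted mean of values) before PAVA, so the
# minimizer is unique and the step function is well defined at tied scores
.pool_ties <- function(scores, values, weights) {
  ord <- order(scores)
  s <- scores[ord]
  v <- values[ord]
  w <- weights[ord]
  grp <- cumsum(c(TRUE, diff(s) > 0))
  ws <- as.vector(tapply(w, grp, sum))
  vs <- as.vector(tapply(w * v, grp, sum)) / ws
  list(scores = s[!duplicated(grp)], values = vs, weights = ws)
}

#' Isotonic regression by pool-adjacent-violators
#'
#' Fits the nondecreasing step function minimizing
#' \eqn{\sum_i w_i (\hat p_i - y_i)^2} over the score-sorted training data:
#' the exact solution computed in one linear pooling pass. Tied scores with
#' conflicting labels are pooled (weighted average) before fitting. The
#' fitted values preserve the (weighted) label mean, a defining property of
#' the pool-adjacent-violators solution.
#'
#' @param scores numeric predictor (raw search scores).
#' @param labels 0/1 correctness labels, same length as `scores`.
#' @param weights optional positive case weights.
#' @return object of class `isotonic_model`: ascending unique `knots`,
#'   nondecreasing fitted values `fit`, pooled `weights`, and the
#'   tie-pooling record `n_pooled`.
#' @examples
#' m <- pava_fit(c(1, 2, 3), c(0, 1, 1))
#' m$fit # already isotonic: 0, 1, 1
#' @export
pava_fit <- function(scores, labels, weights = NULL) {
  if (length(scores) != length(labels)) stop("`scores` and `labels` lengths differ")
  if (length(scores) < 1L) stop("need at least one observation")
  if (anyNA(scores) || anyNA(labels)) stop("missing values not allowed")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  if (is.null(weights)) weights <- rep(1, length(scores))
  pooled <- .pool_ties(scores, as.numeric(labels), weights)
  fit <- .pava(pooled$values, pooled$weights)
  structure(list(knots = pooled$scores, fit = fit, weights = pooled$weights,
                 n = length(scores),
                 n_pooled = length(scores) - length(pooled$scores)),
            class = "isotonic_model")
}

#' @export
print.isotonic_model <- function(x, ...) {
  cat(sprintf("<isotonic_model> %d observations, %d knots (%d tie-pooled)\n",
              x$n, length(x$knots), x$n_pooled))
  invisible(x)
}

#' Predict from a fitted isotonic model
#'
#' Step-function evaluation: a score falling in the interval between two
#' knots takes the left knot's fitted value, a score equal to a knot takes
#' that knot's value, and scores outside the knot range clamp to the
#' terminal fitted values.
#'
#' @param model an [isotonic_model][pava_fit].
#' @param score numeric vector of scores.
#' @return fitted probabilities in `[0, 1]`.
#' @export
isotonic_predict <- function(model, score) {
  stopifnot(inherits(model, "isotonic_model"))
  j <- findInterval(score, model$knots)
  model$fit[pmax(j, 1L)]
}

#' Venn-Abers probability interval for test scores
#'
#' For each test score the calibration set is augmented with the test point
#' carrying each hypothetical label `b` in `{0, 1}`; an isotonic regression
#' is fitted to the augmented data and its fitted value at the test point is
#' read off, giving the pair `(p0, p1)`. Under exchangeability the interval
#' `[p0, p1]` is a valid probability of correctness, and its width shrinks
#' as the calibration set grows. Test points are calibrated one at a time
#' (the inductive form).
#'
#' @param cal_scores,cal_labels calibration scores and 0/1 labels.
#' @param test_scores scores to calibrate.
#' @param point point-estimate rule: `"midpoint"` `(p0+p1)/2` (default) or
#'   the log-loss-optimal `"logloss"` `p1 / (1 - p0 + p1)`.
#' @return data frame of class `venn_abers` with columns `score`, `p0`,
#'   `p1`, `p_point`.
#' @examples
#' venn_abers(c(0.1, 0.9), c(0, 1), 0.9) # p0 = 0.5, p1 = 1
#' @export
venn_abers <- function(cal_scores, cal_labels, test_scores,
                       point = c("midpoint", "logloss")) {
  point <- match.arg(point)
  if (length(cal_scores) != length(cal_labels)) stop("calibration lengths differ")
  if (length(cal_scores) < 1L) stop("need at least one calibration pair")
  if (!all(cal_labels %in% c(0, 1))) stop("labels must be 0 or 1")
  p0 <- numeric(length(test_scores))
  p1 <- numeric(length(test_scores))
  for (k in seq_along(test_scores)) {
    s <- test_scores[k]
    for (b in c(0, 1)) {
      pooled <- .pool_ties(c(cal_scores, s), c(as.numeric(cal_labels), b),
                           rep(1, length(cal_scores) + 1L))
      fit <- .pava(pooled$values, pooled$weights)
      at <- fit[findInterval(s, pooled$scores)]
      if (b == 0) p0[k] <- at else p1[k] <- at
    }
  }
  swap <- p0 > p1
  if (any(swap)) { # numerically guaranteed p0 <= p1; guard regardless
    tmp <- p0[swap]; p0[swap] <- p1[swap]; p1[swap] <- tmp
  }
  pp <- switch(point, midpoint = (p0 + p1) / 2, logloss = p1 / (1 - p0 + p1))
  structure(data.frame(score = test_scores, p0 = p0, p1 = p1, p_point = pp),
            point = point, class = c("venn_abers", "data.frame"))
}

#' Summarize Venn-Abers interval widths
#'
#' The gap `p1 - p0` measures how far the predictor is from a single
#' calibrated probability; on well-behaved data it shrinks toward 0 as the
#' calibration set grows.
#'
#' @param outputs a [venn_abers()] data frame (or any data frame with
#'   columns `p0`, `p1`).
#' @return list with `mean`, `median`, `max` gap.
#' @export
venn_abers_gap <- function(outputs) {
  if (!NROW(outputs)) stop("`outputs` must be non-empty")
  gaps <- outputs$p1 - outputs$p0
  list(mean = mean(gaps), median = median(gaps), max = max(gaps))
}

#' Expected calibration error
#'
#' Partitions `[0, 1]` into `n_bins` equal-width bins and returns the
#' bin-size-weighted mean absolute difference between the empirical match
#' frequency and the mean predicted probability per bin. Empty bins
#' contribute nothing.
#'
#' @param probabilities predicted probabilities in `[0, 1]`.
#' @param labels 0/1 outcomes.
#' @param n_bins number of bins (default 10).
#' @return ECE in `[0, 1]`.
#' @export
ece <- function(probabilities, labels, n_bins = 10L) {
  if (length(probabilities) != length(labels)) stop("lengths differ")
  if (n_bins < 1L) stop("`n_bins` must be >= 1")
  if (any(probabilities < 0 | probabilities > 1)) stop("probabilities outside [0, 1]")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  bin <- pmin(floor(probabilities * n_bins) + 1L, n_bins)
  total <- 0
  n <- length(probabilities)
  for (k in unique(bin)) {
    sel <- bin == k
    total <- total + sum(sel) / n * abs(mean(labels[sel]) - mean(probabilities[sel]))
  }
  total
}
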