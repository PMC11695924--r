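# Applying calibrated thresholds, baseline selectors, Kneedle elbow
# detection, prefilter evaluation against structural ground truth, and the
# exchangeability diagnostic.

#' Build retrieval sets from a score matrix and a threshold
#'
#' One [retrieval_set()] per query. Boundary inclusion defaults to `>=` for
#' similarity scores and `<=` for distances; `strict = TRUE` switches to
#' strict inequality.
#'
#' @param matrix a [score_matrix()].
#' @param lambda threshold in the matrix's own score orientation.
#' @param strict use strict inequality at the boundary.
#' @return list of `retrieval_set` objects, one per query (empty sets
#'   permitted: abstention).
#' @export
build_retrieval_sets <- function(matrix, lambda, strict = FALSE) {
  stopifnot(inherits(matrix, "score_matrix"))
  rule <- if (matrix$score_kind == "similarity") {
    if (strict) "gt" else "geq"
  } else {
    if (strict) "lt" else "leq"
  }
  cmp <- switch(rule,
    geq = function(s) s >= lambda,
    gt  = function(s) s > lambda,
    leq = function(s) s <= lambda,
    lt  = function(s) s < lambda)
  lapply(seq_along(matrix$query_ids), function(i) {
    retrieval_set(matrix$query_ids[i],
                  matrix$lookup_ids[cmp(matrix$scores[i, ])],
                  lambda, rule)
  })
}

#' Kneedle elbow of a descending-sorted curve
#'
#' Min-max normalizes the index to `x` in `[0, 1]` and the values to `y` in
#' `[0, 1]`, then returns the point maximizing the vertical distance between
#' the chord joining the endpoints and the curve — the knee where the rate
#' of decrease slows significantly. This is the no-smoothing, sensitivity-1,
#' vertical-chord-distance form of the algorithm, invariant to positive
#' affine transforms of the values.
#'
#' @param values nonincreasing numeric vector, length at least 3.
#' @return list with `index` (position of the elbow) and `value` (the
#'   original value there).
#' @export
kneedle_elbow <- function(values) {
  n <- length(values)
  if (n < 3L) stop("need at least 3 values to locate an elbow")
  if (is.unsorted(rev(values))) stop("`values` must be nonincreasing (descending-sorted)")
  rng <- max(values) - min(values)
  if (rng == 0) stop("constant sequence: no elbow")
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (values - min(values)) / rng
  # chord from (0, 1) to (1, 0); vertical distance below it
  dist <- (1 - x) - y
  if (max(dist) <= 0) stop("curve never drops below the endpoint chord: no elbow")
  idx <- which.max(dist)
  list(index = idx, value = values[idx])
}

# rates for one query's retrieval set against the hit set defined by Z
.query_prefilter_rates <- function(retrieved, z, z_threshold) {
  hits <- names(z)[z >= z_threshold]
  n_hits <- length(hits)
  fnr <- if (n_hits) sum(!(hits %in% retrieved)) / n_hits else NA_real_
  fdr <- if (length(retrieved)) {
    mean(z[retrieved] < z_threshold)
  } else {
    0
  }
  c(fnr = fnr, tpr = if (n_hits) 1 - fnr else NA_real_, fdr = fdr,
    retained = length(retrieved) / length(z))
}

#' Evaluate a calibrated prefilter against structural ground truth
#'
#' Treats lookup proteins with structural alignment score `Z` at or above a
#' threshold as true hits and scores each query's retrieval set against
#' them: FNR (hits missed), TPR (`1 - FNR`), FDR (retrieved items below the
#' Z threshold) and the retained fraction of the database. Lookup ids
#' without a reported Z take `unreported_z` (0 by default: aligners do not
#' report `Z < 2`). The Z threshold may be a number or `"kneedle"`, in which
#' case the elbow of each query's descending-sorted Z curve is used.
#'
#' @param retrieval_sets list of [retrieval_set()] objects.
#' @param z_table either a named numeric vector (lookup id -> Z, shared by
#'   all queries) or a data frame with columns `query_id`, `lookup_id`, `z`.
#' @param z_threshold numeric threshold, or `"kneedle"`.
#' @param unreported_z value substituted for lookup ids with no Z entry.
#' @return object of class `prefilter_report`: per-query table and
#'   mean/std/min/median/max aggregates. Queries with zero hits are excluded
#'   from the FNR/TPR aggregates and counted in `n_no_hits`.
#' @export
prefilter_stats <- function(retrieval_sets, z_table, z_threshold = "kneedle",
                            unreported_z = 0) {
  per_pair <- is.data.frame(z_table)
  if (per_pair && !all(c("query_id", "lookup_id", "z") %in% names(z_table))) {
    stop("per-pair `z_table` needs columns query_id, lookup_id, z")
  }
  rows <- lapply(retrieval_sets, function(rs) {
    z <- if (per_pair) {
      zz <- z_table[z_table$query_id == rs$query_id, ]
      setNames(zz$z, zz$lookup_id)
    } else {
      z_table
    }
    # lookup ids seen only in the retrieval set take the unreported value
    extra <- setdiff(rs$members, names(z))
    if (length(extra)) z <- c(z, setNames(rep(unreported_z, length(extra)), extra))
    thr <- if (identical(z_threshold, "kneedle")) {
      kneedle_elbow(sort(z, decreasing = TRUE))$value
    } else {
      z_threshold
    }
    c(.query_prefilter_rates(rs$members, z, thr),
      z_prime = if (identical(z_threshold, "kneedle")) thr else NA_real_,
      frac_z_lt2 = mean(z < 2))
  })
  per_query <- as.data.frame(do.call(rbind, rows))
  per_query$query_id <- vapply(retrieval_sets, function(r) r$query_id, character(1))
  agg <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(c(mean = NA, std = NA, min = NA, median = NA, max = NA))
    c(mean = mean(v), std = sd(v), min = min(v), median = median(v), max = max(v))
  }
  structure(list(
    per_query = per_query[, c("query_id", "fnr", "tpr", "fdr", "retained",
                              "z_prime", "frac_z_lt2")],
    aggregate = sapply(per_query[, c("fnr", "tpr", "fdr", "retained",
                                     "z_prime", "frac_z_lt2")], agg),
    n_no_hits = sum(is.na(per_query$fnr)),
    z_threshold = z_threshold,
    unreported_z = unreported_z
  ), class = "prefilter_report")
}

#' @export
print.prefilter_report <- function(x, ...) {
  cat(sprintf("<prefilter_report> %d queries (%d with no hits above threshold)\n",
              nrow(x$per_query), x$n_no_hits))
  print(round(x$aggregate, 4))
  invisible(x)
}

#' Max-separation baseline selector
#'
#' Greedy class selection used as a baseline for enzyme annotation: sort
#' the class distances ascending, look for the largest gap between
#' consecutive distances among the first `m` candidates, and return every
#' class at or below the gap. Always returns at least one class (it cannot
#' abstain — the contrast with conformal selection, which can return the
#' empty set).
#'
#' @param distances named numeric vector, class id -> distance (smaller =
#'   closer); at least 2 classes.
#' @param m candidate window for the gap search (default 10).
#' @return character vector of selected class ids, never empty.
#' @export
maxsep_select <- function(distances, m = 10L) {
  if (length(distances) < 2L) stop("need at least 2 classes")
  ord <- order(distances)
  d <- distances[ord]
  w <- min(m, length(d) - 1L)
  gaps <- diff(d)[seq_len(w)]
  i_star <- which.max(gaps) # ties break toward the smaller index: smallest set
  names(d)[seq_len(i_star)]
}

#' Empirical p-value baseline selector
#'
#' Scores each class distance against a background sample of distances:
#' `p = (1 + #{background <= d}) / (1 + |background|)` (add-one,
#' permutation-style, so p is never 0), selecting classes with `p <= p_cut`.
#' May return the empty set.
#'
#' @param distances named numeric vector, class id -> distance.
#' @param background numeric vector of background distances (non-empty).
#' @param p_cut significance cutoff in `(0, 1)`.
#' @return character vector of selected class ids (possibly empty).
#' @export
pvalue_select <- function(distances, background, p_cut = 0.05) {
  if (!length(background)) stop("`background` must be non-empty")
  if (!is.numeric(p_cut) || p_cut <= 0 || p_cut >= 1) stop("`p_cut` must lie in (0, 1)")
  p <- vapply(distances, function(d) (1 + sum(background <= d)) / (1 + length(background)),
              numeric(1))
  names(distances)[p <= p_cut]
}

#' Compare two empirical loss distributions
#'
#' The exchangeability diagnostic: evaluates both samples' empirical CDFs
#' on the pooled support and reports the maximum absolute gap (the
#' Kolmogorov-Smirnov distance) together with the full table for plotting.
#' Near-overlapping CDFs of losses computed on two data splits (e.g. two
#' time periods) are evidence that the exchangeability assumption behind
#' the risk guarantees is reasonable.
#'
#' @param losses_a,losses_b non-empty numeric samples.
#' @return list with `max_gap` and a data frame `table` (`value`, `cdf_a`,
#'   `cdf_b`, `gap`).
#' @export
loss_cdf_compare <- function(losses_a, losses_b) {
  if (!length(losses_a) || !length(losses_b)) stop("both samples must be non-empty")
  support <- sort(unique(c(losses_a, losses_b)))
  cdf_a <- vapply(support, function(v) mean(losses_a <= v), numeric(1))
  cdf_b <- vapply(support, function(v) mean(losses_b <= v), numeric(1))
  gap <- abs(cdf_a - cdf_b)
  list(max_gap = max(gap),
       table = data.frame(value = support, cdf_a = cdf_a, cdf_b = cdf_b, gap = gap))
}
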