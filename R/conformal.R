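# Threshold calibration: per-query loss curves over a candidate grid,
# conformal risk control for monotone losses, Learn-then-Test for
# non-monotone losses, and the per-level hierarchical certificate.
#
# Everything here works in the canonical permissiveness orientation:
# retrieval sets are {j : canonical score <= lambda} and grow with lambda.

# ---- pairwise structure ----------------------------------------------------

# nq x nl integer matrix of hierarchical mismatch depths, multi-label
# minimum rule on both sides; vectorized over lookup items per query label.
.pair_depth_matrix <- function(annotations, query_ids, lookup_ids, wildcard_agrees = TRUE) {
  lk <- annotations[lookup_ids]
  lk <- lapply(lk, function(a) if (inherits(a, "hierarchy_label")) list(a) else a)
  single <- all(vapply(lk, length, integer(1)) == 1L)
  lab_of <- function(a) if (inherits(a, "hierarchy_label")) list(a) else a

  depth_against <- function(ql, labs) {
    lev <- vapply(labs, function(l) l$levels, character(4))
    wld <- vapply(labs, function(l) l$wildcard, logical(4))
    agree <- lev == ql$levels
    if (wildcard_agrees) agree <- agree | wld | ql$wildcard
    run <- agree[1, ]
    lead <- as.integer(run)
    for (k in 2:4) {
      run <- run & agree[k, ]
      lead <- lead + run
    }
    4L - lead
  }

  flat <- unlist(lk, recursive = FALSE)
  counts <- vapply(lk, length, integer(1))
  idx <- rep(seq_along(lk), counts)

  out <- matrix(NA_integer_, length(query_ids), length(lookup_ids),
                dimnames = list(query_ids, lookup_ids))
  for (i in seq_along(query_ids)) {
    qlabs <- lab_of(annotations[[query_ids[i]]])
    if (is.null(qlabs) || !length(qlabs)) stop(sprintf("query '%s' has no annotation", query_ids[i]))
    d <- rep(4L, length(lookup_ids))
    for (ql in qlabs) {
      dl <- depth_against(ql, flat)
      if (single) {
        d <- pmin(d, dl)
      } else {
        d <- pmin(d, vapply(split(dl, idx), min, integer(1)))
      }
    }
    out[i, ] <- d
  }
  out
}

# nq x nl logical match matrix under a match_spec
.match_matrix <- function(annotations, query_ids, lookup_ids, spec) {
  if (spec$mode == "hierarchical") {
    return(.pair_depth_matrix(annotations, query_ids, lookup_ids,
                              spec$wildcard_agrees) <= spec$max_depth)
  }
  key <- function(ids) vapply(ids, function(id) {
    a <- annotations[[id]]
    if (is.null(a) || !length(a)) NA_character_ else paste(sort(unique(a)), collapse = ";")
  }, character(1))
  if (spec$mode == "pfam_exact") {
    qk <- key(query_ids); lk <- key(lookup_ids)
    m <- outer(qk, lk, `==`)
    m[is.na(m)] <- FALSE # unannotated on either side: non-match
    dimnames(m) <- list(query_ids, lookup_ids)
    return(m)
  }
  # pfam_partial: inverted index accession -> lookup columns
  m <- matrix(FALSE, length(query_ids), length(lookup_ids),
              dimnames = list(query_ids, lookup_ids))
  acc2col <- new.env(parent = emptyenv())
  for (j in seq_along(lookup_ids)) {
    for (a in annotations[[lookup_ids[j]]]) {
      assign(a, c(acc2col[[a]], j), envir = acc2col)
    }
  }
  for (i in seq_along(query_ids)) {
    cols <- unlist(lapply(annotations[[query_ids[i]]], function(a) acc2col[[a]]))
    if (length(cols)) m[i, unique(cols)] <- TRUE
  }
  m
}

# ---- loss curves -----------------------------------------------------------

.classify_row <- function(r, tol = 1e-12) {
  d <- diff(r)
  dec <- all(d <= tol)
  inc <- all(d >= -tol)
  if (dec && inc) "constant" else if (dec) "decreasing" else if (inc) "increasing" else "none"
}

#' Evaluate per-query loss curves over a threshold grid
#'
#' For every calibration query and every candidate threshold, evaluates the
#' loss of the retrieval set that threshold would produce. Thresholds live
#' on the canonical permissiveness scale (sets grow with lambda); the grid
#' is either supplied in the user's score orientation or built by policy
#' from the observed scores. Monotonicity of each loss curve in the
#' permissiveness parameter is auto-detected (violations up to `1e-12` are
#' treated as float noise) and routes the curves to [crc_threshold()] or
#' [ltt_threshold()].
#'
#' @param matrix a [score_matrix()] whose rows are the calibration queries.
#' @param annotations an [annotation_table()] covering both sides.
#' @param spec a [match_spec()]; for `loss = "hierarchical"` its
#'   `cost_vector` and `aggregate` are used.
#' @param loss `"fnr"`, `"fdr"` or `"hierarchical"`.
#' @param grid numeric vector of candidate thresholds in the user's score
#'   orientation, `"all"` for all unique scores, or `NULL` for the default
#'   policy: a `grid_size`-point quantile grid of the scores plus the two
#'   extremes.
#' @param grid_size number of quantile points for the default grid policy.
#' @return object of class `loss_curve_set`: the ascending canonical grid,
#'   the `n x |grid|` loss matrix, the loss bound `B`, per-row monotonicity
#'   and the overall direction.
#' @export
build_loss_curves <- function(matrix, annotations, spec,
                              loss = c("fnr", "fdr", "hierarchical"),
                              grid = NULL, grid_size = 200L) {
  loss <- match.arg(loss)
  stopifnot(inherits(matrix, "score_matrix"), inherits(spec, "match_spec"))
  canon <- canonical_scores(matrix)
  if (is.numeric(grid)) {
    g <- sort(unique(user_to_canonical(grid, matrix$score_kind)))
  } else if (identical(grid, "all")) {
    g <- sort(unique(as.vector(canon)))
  } else if (is.null(grid)) {
    g <- sort(unique(as.vector(
      quantile(canon, probs = seq(0, 1, length.out = grid_size), names = FALSE))))
  } else {
    stop("`grid` must be numeric, \"all\", or NULL")
  }
  if (!length(g)) stop("empty threshold grid")

  nq <- length(matrix$query_ids)
  L <- matrix(0, nq, length(g))
  no_true <- logical(nq)

  if (loss == "hierarchical") {
    depth <- .pair_depth_matrix(annotations, matrix$query_ids, matrix$lookup_ids,
                                spec$wildcard_agrees)
    costs <- spec$cost_vector$costs
    B <- spec$cost_vector$B
    for (i in seq_len(nq)) {
      ord <- order(canon[i, ])
      cost_sorted <- costs[depth[i, ord] + 1L]
      n_ret <- findInterval(g, canon[i, ord])
      if (spec$aggregate == "max") {
        run <- cummax(cost_sorted)
        L[i, ] <- ifelse(n_ret == 0L, 0, run[pmax(n_ret, 1L)])
      } else {
        run <- cumsum(cost_sorted)
        L[i, ] <- ifelse(n_ret == 0L, 0, run[pmax(n_ret, 1L)] / pmax(n_ret, 1L))
      }
    }
  } else {
    match_mat <- .match_matrix(annotations, matrix$query_ids, matrix$lookup_ids, spec)
    B <- 1
    for (i in seq_len(nq)) {
      ci <- canon[i, ]
      n_ret <- findInterval(g, sort(ci))
      cm <- ci[match_mat[i, ]]
      n_match_ret <- findInterval(g, sort(cm))
      if (loss == "fdr") {
        L[i, ] <- ifelse(n_ret == 0L, 0, (n_ret - n_match_ret) / pmax(n_ret, 1L))
      } else {
        if (!length(cm)) {
          no_true[i] <- TRUE # FNR undefined: convention 0, flagged
          L[i, ] <- 0
        } else {
          L[i, ] <- (length(cm) - n_match_ret) / length(cm)
        }
      }
    }
  }

  row_dir <- apply(L, 1, .classify_row)
  direction <- if (any(row_dir == "none")) {
    "none"
  } else if (any(row_dir == "decreasing") && any(row_dir == "increasing")) {
    "none"
  } else if (any(row_dir == "decreasing")) {
    "decreasing"
  } else if (any(row_dir == "increasing")) {
    "increasing"
  } else {
    "constant"
  }

  structure(list(
    grid = g,
    grid_user = canonical_to_user(g, matrix$score_kind),
    losses = L,
    B = B,
    loss_type = loss,
    score_kind = matrix$score_kind,
    query_ids = matrix$query_ids,
    row_direction = row_dir,
    direction = direction,
    monotone = all(row_dir != "none"),
    no_true_matches = no_true
  ), class = "loss_curve_set")
}

#' @export
print.loss_curve_set <- function(x, ...) {
  cat(sprintf("<loss_curve_set> %s loss, %d queries x %d thresholds (B = %g, %s)\n",
              x$loss_type, nrow(x$losses), length(x$grid), x$B,
              if (x$monotone) paste0("monotone ", x$direction) else "non-monotone"))
  if (any(x$no_true_matches)) {
    cat(sprintf("  %d queries with no true matches (FNR convention: loss 0, flagged)\n",
                sum(x$no_true_matches)))
  }
  invisible(x)
}

# subset rows of a loss_curve_set (calibration/test splits); monotonicity
# classification is inherited, not recomputed
.subset_curves <- function(curves, rows) {
  out <- curves
  out$losses <- curves$losses[rows, , drop = FALSE]
  out$query_ids <- curves$query_ids[rows]
  out$row_direction <- curves$row_direction[rows]
  out$no_true_matches <- curves$no_true_matches[rows]
  rd <- out$row_direction
  out$direction <- if (any(rd == "none")) "none"
    else if (any(rd == "decreasing") && any(rd == "increasing")) "none"
    else if (any(rd == "decreasing")) "decreasing"
    else if (any(rd == "increasing")) "increasing"
    else "constant"
  out$monotone <- all(rd != "none")
  out
}

.new_calibration_result <- function(curves, method, alpha, delta, idx, rhat,
                                    crit, crit_name, extra = list()) {
  fallback <- is.na(idx)
  lam_canon <- if (fallback) -Inf else curves$grid[idx]
  res <- c(list(
    lambda_hat = canonical_to_user(lam_canon, curves$score_kind),
    lambda_canonical = lam_canon,
    method = method,
    alpha = alpha,
    delta = delta,
    n = nrow(curves$losses),
    B = curves$B,
    loss_type = curves$loss_type,
    score_kind = curves$score_kind,
    grid = curves$grid,
    grid_user = curves$grid_user,
    grid_index = idx,
    empirical_risk = if (fallback) NA_real_ else rhat[idx],
    fallback = fallback,
    diagnostics = data.frame(
      lambda_canonical = curves$grid,
      lambda = curves$grid_user,
      risk = rhat,
      crit = crit,
      check.names = FALSE
    )
  ), extra)
  names(res$diagnostics)[names(res$diagnostics) == "crit"] <- crit_name
  structure(res, class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> method = %s, loss = %s, alpha = %g%s\n",
              toupper(x$method), x$loss_type, x$alpha,
              if (!is.na(x$delta)) sprintf(", delta = %g", x$delta) else ""))
  if (x$fallback) {
    cat("  no grid value qualified: fully restrictive threshold (empty sets)\n")
  } else {
    cat(sprintf("  lambda_hat = %.6g (%s orientation), empirical risk = %.4g, n = %d\n",
                x$lambda_hat, x$score_kind, x$empirical_risk, x$n))
  }
  invisible(x)
}

#' Conformal risk control threshold
#'
#' Selects the retrieval threshold from calibration loss curves so that the
#' expected loss of deployed retrieval sets on exchangeable future queries
#' is at most `alpha`. The selection rule is the conformal one: find the
#' boundary of the grid region where the empirical risk satisfies
#' \deqn{\hat R(\lambda) \le \alpha - (B - \alpha)/n,}
#' the finite-sample-corrected level (with loss bound `B = 1` this is the
#' textbook `alpha - (1 - alpha)/n`). For losses nonincreasing in
#' permissiveness (FNR-type) this is the least permissive qualifying grid
#' value — the smallest risk-controlled retrieval sets; for losses
#' nondecreasing in permissiveness (hierarchical max-loss) the search is
#' mirrored and the most permissive qualifying value is returned. Constant
#' (e.g. identically zero) curves return the most permissive grid value.
#'
#' Requires every per-query curve to be monotone; non-monotone losses such
#' as FDR must use [ltt_threshold()].
#'
#' @param curves a [build_loss_curves()] result with monotone rows.
#' @param alpha target risk; attainable in principle for `alpha` in
#'   `[B/(n+1), B)` (at the left endpoint only exactly-zero empirical risk
#'   qualifies).
#' @return a `calibration_result`; on an unattainable criterion the fully
#'   restrictive threshold (empty sets) is returned with a warning.
#' @export
crc_threshold <- function(curves, alpha) {
  stopifnot(inherits(curves, "loss_curve_set"))
  if (!curves$monotone) {
    stop("loss curves are not monotone in the threshold; use ltt_threshold() for non-monotone risks such as FDR")
  }
  n <- nrow(curves$losses)
  B <- curves$B
  if (alpha < B / (n + 1) || alpha >= B) {
    warning(sprintf("alpha = %g outside (B/(n+1), B) = (%g, %g); criterion may be unattainable",
                    alpha, B / (n + 1), B))
  }
  alpha_adj <- alpha - (B - alpha) / n
  rhat <- colMeans(curves$losses)
  ok <- rhat <= alpha_adj
  idx <- if (!any(ok)) {
    warning("no grid value satisfies the conformal criterion; returning the fully restrictive threshold (empty sets)")
    NA_integer_
  } else if (curves$direction == "decreasing") {
    min(which(ok))
  } else {
    max(which(ok))
  }
  .new_calibration_result(curves, "crc", alpha, NA_real_, idx, rhat,
                          crit = ok, crit_name = "satisfied",
                          extra = list(adjusted_level = alpha_adj))
}

#' Learn-then-Test threshold for non-monotone risks
#'
#' Treats each candidate threshold as a hypothesis "risk at lambda exceeds
#' alpha" and rejects it only when a finite-sample upper confidence bound
#' falls below `alpha`:
#' \deqn{R^+(\lambda) = \hat R(\lambda) + B\sqrt{\log(1/\delta) / (2n)}}
#' (Hoeffding, losses rescaled by the bound `B`). Multiple testing over the
#' grid is controlled by fixed-sequence testing from the most restrictive to
#' the most permissive threshold: candidates are validated in order and
#' testing stops at the first failure; the returned threshold is the last
#' validated one, so the risk guarantee holds simultaneously at level
#' `delta` without a Bonferroni power loss.
#'
#' @param curves a [build_loss_curves()] result (monotonicity not required).
#' @param alpha target risk level.
#' @param delta failure probability in `(0, 1)`.
#' @param bound concentration bound; only `"hoeffding"` is implemented.
#' @return a `calibration_result` whose diagnostics table carries
#'   `risk_upper` and the per-threshold pass/tested record.
#' @export
ltt_threshold <- function(curves, alpha, delta = 0.1, bound = "hoeffding") {
  stopifnot(inherits(curves, "loss_curve_set"))
  bound <- match.arg(bound, "hoeffding")
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0 || delta >= 1) {
    stop("`delta` must lie in (0, 1)")
  }
  n <- nrow(curves$losses)
  B <- curves$B
  rhat <- colMeans(curves$losses)
  penalty <- B * sqrt(log(1 / delta) / (2 * n))
  rplus <- rhat + penalty
  pass <- rplus <= alpha
  # fixed-sequence: restrictive -> permissive, stop at first failure
  first_fail <- if (all(pass)) length(pass) + 1L else min(which(!pass))
  idx <- if (first_fail == 1L) {
    warning("no threshold validated by LTT at the given alpha/delta; returning the fully restrictive threshold (empty sets)")
    NA_integer_
  } else {
    first_fail - 1L
  }
  res <- .new_calibration_result(curves, "ltt", alpha, delta, idx, rhat,
                                 crit = pass, crit_name = "validated",
                                 extra = list(penalty = penalty, bound = bound))
  res$diagnostics$risk_upper <- rplus
  res$diagnostics$tested <- seq_along(rplus) <= min(first_fail, length(rplus))
  res$risk_upper <- if (is.na(idx)) NA_real_ else rplus[idx]
  res
}

#' Per-level certificate implied by hierarchical risk control
#'
#' Controlling the expected hierarchical loss at level `alpha` with costs
#' `c_0, ..., c_4` simultaneously bounds the probability of every mismatch
#' depth: `P(loss = c_i) <= alpha / c_i` for each positive cost (with
#' `alpha / 0 = Inf` at depth 0). This function reports the implied bound
#' and the empirical frequency of each loss level on held-out losses, and
#' flags frequencies exceeding their bound by more than 3 binomial standard
#' errors.
#'
#' @param losses numeric vector of realized hierarchical losses at the
#'   deployed threshold; values must lie in the cost vector's range.
#' @param cost_vector a [cost_vector()].
#' @param alpha the risk level the threshold was calibrated at.
#' @return data frame (class `hierarchical_certificate`) with columns
#'   `depth`, `cost`, `bound`, `frequency`, `se`, `violated`.
#' @export
hierarchical_risk_certificate <- function(losses, cost_vector, alpha) {
  stopifnot(inherits(cost_vector, "cost_vector"))
  costs <- cost_vector$costs
  if (any(losses < 0 | losses > cost_vector$B)) {
    stop("losses outside [0, B] for the given cost vector")
  }
  n <- length(losses)
  freq <- vapply(costs, function(ci) mean(abs(losses - ci) < 1e-9), numeric(1))
  bound <- ifelse(costs > 0, alpha / costs, Inf)
  se <- sqrt(pmax(freq * (1 - freq), 0) / max(n, 1))
  out <- data.frame(depth = 0:4, cost = costs, bound = bound,
                    frequency = freq, se = se,
                    violated = freq > bound + 3 * se)
  class(out) <- c("hierarchical_certificate", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "n") <- n
  out
}

#' Resampled calibration/test coverage trials
#'
#' The package's simulation harness for checking the marginal risk
#' guarantee: repeatedly shuffles the queries of a precomputed
#' [loss_curve_set][build_loss_curves] into a calibration half and a test
#' half, calibrates a threshold on the calibration rows, and records the
#' mean test-row loss at that threshold. Under exchangeability the mean
#' test risk across trials should not exceed `alpha` beyond Monte-Carlo
#' noise.
#'
#' @param curves loss curves for the full query pool.
#' @param n_cal number of calibration queries per trial.
#' @param alpha target risk level.
#' @param method `"crc"` or `"ltt"`.
#' @param n_trials number of resampled splits.
#' @param delta LTT failure probability.
#' @param seed optional integer seed for the shuffle schedule.
#' @return data frame with one row per trial: `lambda_hat` (user
#'   orientation), `cal_risk`, `test_risk`, `fallback`.
#' @export
risk_coverage_trials <- function(curves, n_cal, alpha, method = c("crc", "ltt"),
                                 n_trials = 100L, delta = 0.1, seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(curves, "loss_curve_set"))
  n <- nrow(curves$losses)
  if (n_cal >= n) stop("`n_cal` must leave at least one test query")
  runner <- function() {
    out <- data.frame(trial = seq_len(n_trials), lambda_hat = NA_real_,
                      cal_risk = NA_real_, test_risk = NA_real_, fallback = FALSE)
    for (t in seq_len(n_trials)) {
      cal <- sample.int(n, n_cal)
      cc <- .subset_curves(curves, cal)
      res <- withCallingHandlers(
        if (method == "crc") crc_threshold(cc, alpha) else ltt_threshold(cc, alpha, delta),
        warning = function(w) invokeRestart("muffleWarning"))
      test <- setdiff(seq_len(n), cal)
      if (res$fallback) {
        # empty sets: FNR is 1 for every test query with true matches, 0 otherwise;
        # FDR and hierarchical losses of the empty set are 0
        tl <- if (curves$loss_type == "fnr") mean(!curves$no_true_matches[test]) else 0
        out$fallback[t] <- TRUE
        out$test_risk[t] <- tl
      } else {
        out$lambda_hat[t] <- res$lambda_hat
        out$cal_risk[t] <- res$empirical_risk
        out$test_risk[t] <- mean(curves$losses[test, res$grid_index])
      }
    }
    out
  }
  if (is.null(seed)) runner() else with_seed(seed, runner())
}
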