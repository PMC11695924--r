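# Independent oracles used to pin down expected values. Each oracle is a
# direct transcription of the defining criterion (exhaustive scan, closed
# form, or two-pass recount), deliberately sharing no code with the
# implementation path it checks.

# Isotonic least squares via the max-min closed form:
#   fit_i = max_{j<=i} min_{k>=i} mean(y[j..k])   (weighted)
# Expects scores without ties (the implementation pre-pools ties).
oracle_isotonic <- function(scores, labels, weights = rep(1, length(labels))) {
  ord <- order(scores)
  y <- labels[ord]
  w <- weights[ord]
  n <- length(y)
  fit <- numeric(n)
  for (i in seq_len(n)) {
    best <- -Inf
    for (j in seq_len(i)) {
      mn <- Inf
      for (k in i:n) {
        mn <- min(mn, sum(w[j:k] * y[j:k]) / sum(w[j:k]))
      }
      best <- max(best, mn)
    }
    fit[i] <- best
  }
  list(knots = scores[ord], fit = fit)
}

# Exhaustive scan of the conformal criterion over the grid.
oracle_crc_index <- function(losses, alpha, B, direction) {
  n <- nrow(losses)
  ok <- logical(ncol(losses))
  for (j in seq_len(ncol(losses))) {
    ok[j] <- mean(losses[, j]) <= alpha - (B - alpha) / n
  }
  if (!any(ok)) return(NA_integer_)
  if (direction == "decreasing") min(which(ok)) else max(which(ok))
}

# Fixed-sequence LTT scan: restrictive -> permissive, stop at first failure.
oracle_ltt_index <- function(losses, alpha, delta, B) {
  n <- nrow(losses)
  pen <- B * sqrt(log(1 / delta) / (2 * n))
  last <- NA_integer_
  for (j in seq_len(ncol(losses))) {
    if (mean(losses[, j]) + pen <= alpha) last <- j else break
  }
  last
}

# Two-pass reference ECE.
oracle_ece <- function(p, y, k) {
  edges <- seq(0, 1, length.out = k + 1)
  tot <- 0
  for (b in seq_len(k)) {
    sel <- if (b < k) p >= edges[b] & p < edges[b + 1] else p >= edges[b] & p <= edges[b + 1]
    if (any(sel)) tot <- tot + sum(sel) / length(p) * abs(mean(y[sel]) - mean(p[sel]))
  }
  tot
}

# Brute-force chord-distance table for the Kneedle elbow.
oracle_kneedle_index <- function(values) {
  n <- length(values)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (values - min(values)) / (max(values) - min(values))
  which.max((1 - x) - y)
}

# Two-sample KS critical value at level 0.05.
ks_crit_05 <- function(n, m) 1.358 * sqrt((n + m) / (n * m))

# Wrap a bare loss matrix as a loss_curve_set (for oracle-equivalence tests
# on hand-constructed curves).
make_curves <- function(losses, grid = seq_len(ncol(losses)), B = 1,
                        loss_type = "fnr", score_kind = "distance") {
  row_dir <- apply(losses, 1, conformalpr:::.classify_row)
  direction <- if (any(row_dir == "none")) "none"
    else if (any(row_dir == "decreasing") && any(row_dir == "increasing")) "none"
    else if (any(row_dir == "decreasing")) "decreasing"
    else if (any(row_dir == "increasing")) "increasing"
    else "constant"
  structure(list(
    grid = grid, grid_user = grid, losses = losses, B = B,
    loss_type = loss_type, score_kind = score_kind,
    query_ids = sprintf("Q%d", seq_len(nrow(losses))),
    row_direction = row_dir, direction = direction,
    monotone = all(row_dir != "none"),
    no_true_matches = logical(nrow(losses))
  ), class = "loss_curve_set")
}

# Random monotone loss matrix (rows sorted to the requested direction).
random_monotone_losses <- function(n, L, B = 1, direction = "decreasing") {
  m <- matrix(runif(n * L, 0, B), n, L)
  t(apply(m, 1, sort, decreasing = (direction == "decreasing")))
}

ec <- function(x) parse_hierarchy_label(x, "EC")

# seeded evaluation that restores the caller's RNG state
with_seed_helper <- function(seed, f) withr::with_seed(seed, f())
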