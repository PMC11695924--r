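# conformal_calibration: loss curves, CRC, LTT, hierarchical certificate

test_that("build_loss_curves matches hand-enumerated FNR sets", {
  # 1 query, similarity scores (0.9, 0.2), true match only at 0.9
  sm <- score_matrix(matrix(c(0.9, 0.2), 1), "q", c("hit", "miss"), "similarity")
  ann <- annotation_table(c("q", "hit", "miss"), list("PF1", "PF1", "PF2"))
  cv <- build_loss_curves(sm, ann, match_spec("pfam_exact"), loss = "fnr",
                          grid = c(0.1, 0.5, 0.95))
  # canonical grid is ascending permissiveness: sim thresholds 0.95, 0.5, 0.1
  expect_equal(cv$grid_user, c(0.95, 0.5, 0.1))
  expect_equal(as.vector(cv$losses), c(1, 0, 0))
  expect_identical(cv$direction, "decreasing")
})

test_that("identically-zero losses give all-zero constant curves", {
  sm <- score_matrix(matrix(c(0.9, 0.8), 1), "q", c("a", "b"), "similarity")
  ann <- annotation_table(c("q", "a", "b"), list("PF1", "PF1", "PF1"))
  cv <- build_loss_curves(sm, ann, match_spec("pfam_exact"), loss = "fdr", grid = "all")
  expect_true(all(cv$losses == 0))
  expect_identical(cv$direction, "constant")
  # constant curves: CRC returns the most permissive grid value
  r <- crc_threshold(cv, 0.5)
  expect_equal(r$lambda_canonical, max(cv$grid))
})

test_that("an FDR dip-then-rise instance trips the non-monotone flag and routes to LTT", {
  # descending scores: match, non-match, match -> FDR over growing sets: 0, 1/2, 1/3
  sm <- score_matrix(matrix(c(0.9, 0.6, 0.3), 1), "q", c("m1", "x", "m2"), "similarity")
  ann <- annotation_table(c("q", "m1", "x", "m2"), list("PF1", "PF1", "PF2", "PF1"))
  cv <- build_loss_curves(sm, ann, match_spec("pfam_exact"), loss = "fdr", grid = "all")
  expect_false(cv$monotone)
  expect_identical(cv$direction, "none")
  expect_error(crc_threshold(cv, 0.2), "ltt_threshold")
})

test_that("the conformal criterion reduces to R(lambda) <= 0 at n = 9, alpha = 0.1", {
  # forced by the finite-sample correction: 0.1 - 0.9/9 = 0
  L <- random_monotone_losses(9, 12)
  L[, 12] <- 0 # make the criterion attainable exactly at zero risk
  cv <- make_curves(L)
  r <- crc_threshold(cv, 0.1)
  expect_equal(r$adjusted_level, 0)
  expect_equal(r$empirical_risk, 0)
})

test_that("CRC agrees with the exhaustive-scan oracle on random monotone instances", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(3:20, 1)
    L <- sample(5:50, 1)
    direction <- sample(c("decreasing", "increasing"), 1)
    B <- sample(c(1, 4), 1)
    losses <- random_monotone_losses(n, L, B, direction)
    alpha <- runif(1, B / (n + 1) + 0.01, B - 0.01)
    cv <- make_curves(losses, B = B,
                      loss_type = if (direction == "decreasing") "fnr" else "hierarchical")
    idx <- oracle_crc_index(losses, alpha, B, cv$direction)
    if (is.na(idx)) {
      expect_warning(r <- crc_threshold(cv, alpha), "restrictive")
      expect_true(r$fallback)
    } else {
      r <- crc_threshold(cv, alpha)
      expect_equal(r$grid_index, idx)
      expect_lte(r$empirical_risk, alpha - (B - alpha) / n)
    }
  }
})

test_that("LTT agrees with the fixed-sequence oracle and the Hoeffding arithmetic", {
  # single lambda, Rhat = 0.05, n = 100, delta = 0.1:
  # bound = 0.05 + sqrt(log(10)/200) ~ 0.157 -> validated at alpha = 0.2, not at 0.1
  losses <- matrix(rep(c(0, 1), c(95, 5)), 100, 1)
  cv <- make_curves(losses, grid = 1, loss_type = "fdr")
  r <- ltt_threshold(cv, alpha = 0.2, delta = 0.1)
  expect_equal(r$risk_upper, 0.05 + sqrt(log(10) / 200))
  expect_false(r$fallback)
  expect_warning(r2 <- ltt_threshold(cv, alpha = 0.1, delta = 0.1), "restrictive")
  expect_true(r2$fallback)

  set.seed(202)
  for (i in 1:50) {
    n <- sample(3:20, 1)
    L <- sample(5:50, 1)
    losses <- matrix(runif(n * L), n, L) # arbitrary non-monotone curves
    cv <- make_curves(losses, loss_type = "fdr")
    alpha <- runif(1, 0.05, 0.95)
    delta <- runif(1, 0.05, 0.5)
    idx <- oracle_ltt_index(losses, alpha, delta, 1)
    if (is.na(idx)) {
      expect_warning(r <- ltt_threshold(cv, alpha, delta), "restrictive")
      expect_true(r$fallback)
    } else {
      r <- ltt_threshold(cv, alpha, delta)
      expect_equal(r$grid_index, idx)
      expect_lte(r$risk_upper, alpha)
    }
  }
  expect_error(ltt_threshold(make_curves(matrix(0, 2, 2)), 0.1, delta = 1.5), "delta")
})

test_that("LTT reaches the most permissive grid value when risk vanishes and n is large", {
  cv <- make_curves(matrix(0, 5000, 20), loss_type = "fdr")
  r <- ltt_threshold(cv, alpha = 0.1, delta = 0.1)
  expect_equal(r$grid_index, 20L)
})

test_that("lambda_hat is monotone in alpha", {
  set.seed(303)
  losses <- random_monotone_losses(15, 30, 1, "decreasing")
  cv <- make_curves(losses)
  alphas <- seq(0.15, 0.9, by = 0.05)
  idxs <- vapply(alphas, function(a) crc_threshold(cv, a)$grid_index, integer(1))
  # larger alpha never yields a more restrictive (here: larger-index) threshold
  expect_true(all(diff(idxs) <= 0))

  lossesI <- random_monotone_losses(15, 30, 1, "increasing")
  cvI <- make_curves(lossesI, loss_type = "hierarchical")
  idxsI <- vapply(alphas, function(a) crc_threshold(cvI, a)$grid_index, integer(1))
  expect_true(all(diff(idxsI) >= 0))
})

test_that("hierarchical_risk_certificate reports the alpha/c_i ladder", {
  cert <- hierarchical_risk_certificate(rep(0, 50), cost_vector(), 0.1)
  expect_equal(cert$bound, c(Inf, 0.1, 0.05, 0.1 / 3, 0.025))
  expect_false(any(cert$violated))
  expect_equal(cert$frequency, c(1, 0, 0, 0, 0))

  # a loss level far above its bound is flagged
  bad <- c(rep(4, 30), rep(0, 70))
  cert2 <- hierarchical_risk_certificate(bad, cost_vector(), 0.1)
  expect_true(cert2$violated[5])
  expect_error(hierarchical_risk_certificate(c(0, 9), cost_vector(), 0.1), "outside")
})

test_that("coverage trials hold the FNR guarantee on a synthetic instance", {
  inst <- gen_flat_instance(generator_spec(seed = 404, n_query = 120, n_lookup = 400))
  cv <- build_loss_curves(inst$scores, inst$annotations, match_spec("pfam_exact"),
                          loss = "fnr", grid_size = 80)
  tr <- risk_coverage_trials(cv, n_cal = 90, alpha = 0.2, method = "crc",
                             n_trials = 50, seed = 1)
  mcse <- sd(tr$test_risk) / sqrt(nrow(tr))
  expect_lte(mean(tr$test_risk), 0.2 + 3 * mcse)
  expect_true(all(tr$cal_risk <= 0.2 - (1 - 0.2) / 90, na.rm = TRUE))
})
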