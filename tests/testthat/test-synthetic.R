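# synthetic_data: determinism, stochastic ordering, stated-world structure

test_that("generators are deterministic in spec + seed and vary with seed", {
  s1 <- generator_spec(seed = 31, n_query = 20, n_lookup = 50)
  a <- gen_flat_instance(s1)
  b <- gen_flat_instance(s1)
  expect_identical(a$scores$scores, b$scores$scores)
  expect_identical(a$match, b$match)
  d <- gen_flat_instance(generator_spec(seed = 32, n_query = 20, n_lookup = 50))
  expect_false(identical(a$scores$scores, d$scores$scores))

  h1 <- gen_hierarchy_instance(generator_spec(seed = 31, n_query = 15))
  h2 <- gen_hierarchy_instance(generator_spec(seed = 31, n_query = 15))
  expect_identical(h1$scores$scores, h2$scores$scores)

  p1 <- gen_prefilter_instance(generator_spec(seed = 31, n_query = 5, n_lookup = 60))
  p2 <- gen_prefilter_instance(generator_spec(seed = 31, n_query = 5, n_lookup = 60))
  expect_identical(p1$z, p2$z)
  expect_error(generator_spec(n_query = 0), "degenerate")
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99)
  x1 <- runif(1)
  set.seed(99)
  invisible(gen_flat_instance(generator_spec(seed = 5, n_query = 5, n_lookup = 10)))
  x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("flat instance: masks agree with annotations; scores stochastically ordered", {
  inst <- gen_flat_instance(generator_spec(seed = 33, n_query = 50, n_lookup = 200))
  ann <- inst$annotations
  # the returned mask is exactly the pfam_exact predicate on the annotations
  for (i in sample(50, 5)) {
    q <- inst$scores$query_ids[i]
    for (j in sample(200, 20)) {
      v <- inst$scores$lookup_ids[j]
      expect_identical(unname(inst$match[i, j]), setequal(ann[[q]], ann[[v]]))
      expect_identical(unname(inst$partial_match[i, j]),
                       length(intersect(ann[[q]], ann[[v]])) > 0L)
    }
  }
  # exact implies partial
  expect_true(all(inst$partial_match[inst$match]))
  # match scores dominate non-match scores
  expect_gt(mean(inst$scores$scores[inst$match]), mean(inst$scores$scores[!inst$match]))
  q75 <- quantile(inst$scores$scores[!inst$match], 0.75)
  expect_gt(mean(inst$scores$scores[inst$match] > q75), 0.5)
})

test_that("flat instance boundary regimes behave as stated", {
  # one shared profile: every pair matches; components separable enough that a
  # mid-range threshold achieves FDR 0 and FNR 0
  sep <- generator_spec(seed = 34, n_query = 10, n_lookup = 30, n_profiles = 1,
                        match_shape = c(40, 2), nonmatch_shape = c(2, 40))
  inst <- gen_flat_instance(sep)
  expect_true(all(inst$match))
  # distinct vocabulary per protein: no query has a true exact match
  lone <- generator_spec(seed = 35, n_query = 8, n_lookup = 20,
                         n_profiles = 500, vocab_size = 400, mean_extra_labels = 2)
  inst2 <- gen_flat_instance(lone)
  cv <- build_loss_curves(inst2$scores, inst2$annotations, match_spec("pfam_exact"),
                          loss = "fnr", grid_size = 10)
  expect_true(mean(cv$no_true_matches) > 0.8) # profile collisions are rare, not impossible
})

test_that("compress_top pushes score mass toward 1 (near-1 pileup)", {
  plain <- gen_flat_instance(generator_spec(seed = 36, n_query = 20, n_lookup = 100))
  squashed <- gen_flat_instance(generator_spec(seed = 36, n_query = 20, n_lookup = 100,
                                               compress_top = TRUE))
  expect_gt(mean(squashed$scores$scores > 0.9), mean(plain$scores$scores > 0.9))
  expect_true(all(squashed$scores$scores <= 1))
})

test_that("hierarchy instance: zero noise makes the nearest centroid the true leaf", {
  spec <- generator_spec(seed = 37, n_query = 40, noise_sd = 0)
  inst <- gen_hierarchy_instance(spec)
  nearest <- apply(inst$scores$scores, 1, which.min)
  expect_identical(unname(inst$catalog[nearest]), inst$truth$label)
  # hierarchical loss of the singleton nearest-centroid set is 0
  for (i in sample(40, 5)) {
    q <- inst$scores$query_ids[i]
    c_id <- inst$scores$lookup_ids[nearest[i]]
    expect_equal(hierarchical_set_loss(inst$annotations[[q]],
                                       list(inst$annotations[[c_id]]),
                                       cost_vector()), 0)
  }
})

test_that("hierarchy instance: distances grow with tree separation; non-members sit far out", {
  inst <- gen_hierarchy_instance(generator_spec(seed = 38, n_query = 300))
  spec <- generator_spec(seed = 38, n_query = 300)
  # mean distance at each mismatch depth tracks base + step * depth
  ann <- inst$annotations
  depths <- conformalpr:::.pair_depth_matrix(ann, inst$scores$query_ids,
                                             inst$scores$lookup_ids, TRUE)
  for (d in 0:4) {
    sel <- depths == d
    if (any(sel)) {
      expect_equal(mean(inst$scores$scores[sel]),
                   spec$base_distance + spec$level_step * d,
                   tolerance = 0.05)
    }
  }

  nm <- gen_hierarchy_instance(generator_spec(seed = 39, n_query = 50, nonmember_frac = 1))
  expect_true(all(!nm$truth$is_member))
  # all distances beyond any member-like threshold: conformal sets all empty
  sets <- build_retrieval_sets(nm$scores, 9)
  expect_true(all(vapply(sets, function(s) length(s$members) == 0L, logical(1))))
})

test_that("hierarchy instance supports multiple valid labels per query", {
  inst <- gen_hierarchy_instance(generator_spec(seed = 40, n_query = 10, labels_per_query = 2))
  nlabs <- vapply(inst$truth$query_id, function(q) length(inst$annotations[[q]]), integer(1))
  expect_true(all(nlabs == 2))
})

test_that("prefilter instance: Z floor, non-homolog point mass and S-Z coupling", {
  spec <- generator_spec(seed = 41, n_query = 30, n_lookup = 400)
  inst <- gen_prefilter_instance(spec)
  z <- inst$z$z
  expect_true(all(z == 0 | z >= 2)) # sub-2 scores are reported as 0
  hom <- as.vector(inst$homolog)
  expect_true(all(z[!hom] == 0))

  # noise-free, strictly monotone link: similarity ranking equals Z ranking
  nf <- generator_spec(seed = 42, n_query = 2, n_lookup = 500, homolog_prob = 1,
                       z_noise_sd = 0, sim_noise_sd = 0)
  inst2 <- gen_prefilter_instance(nf)
  s <- as.vector(inst2$scores$scores)
  z2 <- inst2$z$z
  pos <- z2 > 0
  expect_equal(cor(s[pos], z2[pos], method = "spearman"), 1, tolerance = 1e-12)

  # all non-homologs: the whole database sits below Z = 2
  none <- gen_prefilter_instance(generator_spec(seed = 43, n_query = 5, n_lookup = 100,
                                                homolog_prob = 0))
  expect_equal(mean(none$z$z < 2), 1)

  # rank correlation between S and Z among homolog pairs matches the
  # large-sample target of the same link simulated independently
  big_u <- with_seed_helper(1234, function() {
    u <- runif(2e5)
    s <- pmin(pmax(0.55 + 0.4 * u + rnorm(2e5, 0, spec$sim_noise_sd), 0), 1)
    zr <- 2 + (spec$z_max - 2) * u^1.5 + rnorm(2e5, 0, spec$z_noise_sd)
    cor(s, ifelse(zr < 2, 0, zr), method = "spearman")
  })
  got <- cor(as.vector(inst$scores$scores)[hom], z[hom], method = "spearman")
  expect_equal(got, big_u, tolerance = 0.05)
})

test_that("exchangeability smoke test: random halves have overlapping loss CDFs", {
  inst <- gen_flat_instance(generator_spec(seed = 44, n_query = 200, n_lookup = 400))
  cv <- build_loss_curves(inst$scores, inst$annotations, match_spec("pfam_exact"),
                          loss = "fnr", grid_size = 50)
  mid <- ncol(cv$losses) %/% 2
  set.seed(45)
  half <- sample(200, 100)
  gap <- loss_cdf_compare(cv$losses[half, mid], cv$losses[-half, mid])$max_gap
  expect_lt(gap, ks_crit_05(100, 100))
})
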