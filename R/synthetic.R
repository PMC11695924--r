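# Seeded generators producing exchangeable score/label instances with the
# statistical structure the calibration experiments assume: flat
# match/non-match score mixtures with Pfam-style multi-label annotations,
# hierarchical label trees with distance-correlated scores, and joint
# similarity/structural-Z distributions for prefilter evaluation.

#' Specification for the synthetic-data generators
#'
#' One object carries every knob of the three generators; each generator
#' reads the fields it needs and records the spec in the output manifest so
#' any fixture is reconstructible. Identical spec + seed give byte-identical
#' output (Mersenne-Twister, pinned).
#'
#' Defaults state the emulated world: 400 queries against a 2000-protein
#' lookup (the 300 calibration / 100 test design), ~2% exact-match rate via
#' 50 annotation profiles, Beta(8,2) match vs Beta(2,8) non-match score
#' mixtures (stochastically ordered, overlapping enough that thresholding is
#' non-trivial), a 4/3/3/3-branching label tree whose centroid distances
#' grow by `level_step` per level of tree separation, and a monotone
#' similarity-to-Z link with the below-2 reporting floor of structural
#' aligners.
#'
#' @param seed integer RNG seed.
#' @param n_query,n_lookup instance dimensions.
#' @param n_profiles number of distinct annotation profiles (flat model).
#' @param vocab_size Pfam accession vocabulary size.
#' @param mean_extra_labels Poisson mean for accessions per profile beyond
#'   the first (capped at 4 total).
#' @param match_shape,nonmatch_shape Beta shape pairs for the match and
#'   non-match score components; the match component must stochastically
#'   dominate.
#' @param compress_top squash scores toward the top of the range
#'   (`s^(1/compress_power)`), mimicking the near-1 pileup of real
#'   embedding-model similarities.
#' @param compress_power exponent used when `compress_top = TRUE`.
#' @param branching integer branching factors of the 4-level label tree.
#' @param base_distance mean centroid distance for an exact-leaf match.
#' @param level_step mean distance increment per tree-level of separation.
#' @param noise_sd Gaussian noise on centroid distances.
#' @param nonmember_frac fraction of queries far from every centroid (the
#'   non-enzyme/abstention analogue).
#' @param labels_per_query maximum number of valid labels per query; extra
#'   labels model ambiguous multi-assignment annotations.
#' @param homolog_prob per-pair homology probability (prefilter model).
#' @param z_max top of the structural Z range.
#' @param z_noise_sd,sim_noise_sd noise scales of the Z link and the
#'   similarity channel.
#' @return object of class `generator_spec`.
#' @export
generator_spec <- function(seed = 1L,
                           n_query = 400L, n_lookup = 2000L,
                           n_profiles = 50L, vocab_size = 30L,
                           mean_extra_labels = 0.7,
                           match_shape = c(8, 2), nonmatch_shape = c(2, 8),
                           compress_top = FALSE, compress_power = 5,
                           branching = c(4L, 3L, 3L, 3L),
                           base_distance = 1, level_step = 2, noise_sd = 0.7,
                           nonmember_frac = 0, labels_per_query = 1L,
                           homolog_prob = 0.05, z_max = 30,
                           z_noise_sd = 2, sim_noise_sd = 0.05) {
  if (n_query < 1L || n_lookup < 1L) stop("degenerate spec: zero-size instance")
  if (length(branching) != 4L || any(branching < 1L)) stop("degenerate branching: need 4 positive factors")
  spec <- list(seed = as.integer(seed), n_query = as.integer(n_query),
               n_lookup = as.integer(n_lookup), n_profiles = as.integer(n_profiles),
               vocab_size = as.integer(vocab_size), mean_extra_labels = mean_extra_labels,
               match_shape = match_shape, nonmatch_shape = nonmatch_shape,
               compress_top = isTRUE(compress_top), compress_power = compress_power,
               branching = as.integer(branching), base_distance = base_distance,
               level_step = level_step, noise_sd = noise_sd,
               nonmember_frac = nonmember_frac, labels_per_query = as.integer(labels_per_query),
               homolog_prob = homolog_prob, z_max = z_max,
               z_noise_sd = z_noise_sd, sim_noise_sd = sim_noise_sd)
  structure(spec, class = "generator_spec")
}

#' Flat match/non-match instance (Pfam-style annotation search)
#'
#' Draws an annotation profile (a small set of Pfam accessions) for every
#' query and lookup protein from a shared catalog; a pair is an exact match
#' when the profiles coincide and a partial match when they share an
#' accession. Scores come from the corresponding mixture component, so the
#' match and non-match score distributions are stochastically ordered but
#' overlap — thresholding has a real FDR/FNR trade-off.
#'
#' @param spec a [generator_spec()].
#' @return list: `scores` (similarity [score_matrix()]), `annotations`
#'   ([annotation_table()] covering both sides), `match` and
#'   `partial_match` (logical query x lookup masks), `manifest`.
#' @export
gen_flat_instance <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  with_seed(spec$seed, {
    vocab <- sprintf("PF%05d", seq_len(spec$vocab_size))
    sizes <- pmin(1L + rpois(spec$n_profiles, spec$mean_extra_labels), 4L)
    profiles <- lapply(sizes, function(k) sort(sample(vocab, k)))
    pkey <- vapply(profiles, paste, character(1), collapse = ";")

    qp <- sample.int(spec$n_profiles, spec$n_query, replace = TRUE)
    lp <- sample.int(spec$n_profiles, spec$n_lookup, replace = TRUE)

    exact_pp <- outer(pkey, pkey, `==`)
    share_pp <- matrix(FALSE, spec$n_profiles, spec$n_profiles)
    for (a in seq_len(spec$n_profiles)) {
      for (b in seq_len(spec$n_profiles)) {
        share_pp[a, b] <- length(intersect(profiles[[a]], profiles[[b]])) > 0L
      }
    }
    match <- exact_pp[qp, lp, drop = FALSE]
    partial <- share_pp[qp, lp, drop = FALSE]

    n <- spec$n_query * spec$n_lookup
    s <- numeric(n)
    is_m <- as.vector(match)
    s[is_m] <- rbeta(sum(is_m), spec$match_shape[1], spec$match_shape[2])
    s[!is_m] <- rbeta(sum(!is_m), spec$nonmatch_shape[1], spec$nonmatch_shape[2])
    if (spec$compress_top) s <- s^(1 / spec$compress_power)
    scores <- matrix(s, spec$n_query, spec$n_lookup)

    qid <- sprintf("Q%04d", seq_len(spec$n_query))
    lid <- sprintf("L%05d", seq_len(spec$n_lookup))
    dimnames(match) <- dimnames(partial) <- list(qid, lid)
    ann <- annotation_table(c(qid, lid), c(profiles[qp], profiles[lp]), kind = "pfam")

    list(scores = score_matrix(scores, qid, lid, "similarity"),
         annotations = ann, match = match, partial_match = partial,
         manifest = run_manifest("gen_flat_instance", unclass(spec)))
  })
}

#' Hierarchical label-tree instance (enzyme-classification style)
#'
#' Builds a 4-level label tree from the branching factors, one class
#' centroid per leaf. Every member query gets a true leaf; its distance to
#' each centroid is `base_distance + level_step * depth + noise`, where
#' depth is the hierarchical mismatch depth between the true leaf and the
#' centroid's leaf — so distances grow stochastically with tree separation.
#' A `nonmember_frac` fraction of queries sits far from every centroid (the
#' correct retrieval for them is the empty set).
#'
#' @param spec a [generator_spec()].
#' @return list: `scores` (distance [score_matrix()], queries x centroids),
#'   `annotations` ([annotation_table()] with true labels for member
#'   queries and every centroid), `catalog` (centroid id -> label string),
#'   `truth` (data frame: `query_id`, `label`, `is_member`), `manifest`.
#' @export
gen_hierarchy_instance <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  with_seed(spec$seed, {
    b <- spec$branching
    leaves <- expand.grid(l4 = seq_len(b[4]), l3 = seq_len(b[3]),
                          l2 = seq_len(b[2]), l1 = seq_len(b[1]))
    leaf_str <- sprintf("%d.%d.%d.%d", leaves$l1, leaves$l2, leaves$l3, leaves$l4)
    n_leaf <- length(leaf_str)
    cid <- sprintf("C%03d", seq_len(n_leaf))
    labels <- lapply(leaf_str, parse_hierarchy_label, scheme = "EC")

    # depth between leaves from the level index matrix
    lev <- as.matrix(leaves[, c("l1", "l2", "l3", "l4")])
    depth_between <- function(i) {
      agree1 <- lev[, 1] == lev[i, 1]
      agree2 <- agree1 & lev[, 2] == lev[i, 2]
      agree3 <- agree2 & lev[, 3] == lev[i, 3]
      agree4 <- agree3 & lev[, 4] == lev[i, 4]
      4L - (agree1 + agree2 + agree3 + agree4)
    }

    n_non <- round(spec$nonmember_frac * spec$n_query)
    is_member <- c(rep(TRUE, spec$n_query - n_non), rep(FALSE, n_non))
    is_member <- sample(is_member)
    true_leaf <- ifelse(is_member, sample.int(n_leaf, spec$n_query, replace = TRUE), NA)

    d <- matrix(NA_real_, spec$n_query, n_leaf)
    for (i in seq_len(spec$n_query)) {
      mu <- if (is_member[i]) {
        spec$base_distance + spec$level_step * depth_between(true_leaf[i])
      } else {
        rep(spec$base_distance + spec$level_step * 6, n_leaf)
      }
      d[i, ] <- pmax(mu + rnorm(n_leaf, 0, spec$noise_sd), 0)
    }

    qid <- sprintf("Q%04d", seq_len(spec$n_query))
    # optional extra valid labels: siblings of the true leaf (ambiguous annotation)
    q_labels <- lapply(seq_len(spec$n_query), function(i) {
      if (!is_member[i]) return(NULL)
      labs <- list(labels[[true_leaf[i]]])
      if (spec$labels_per_query > 1L) {
        sibs <- which(depth_between(true_leaf[i]) == 1L)
        extra <- head(sibs, spec$labels_per_query - 1L)
        labs <- c(labs, labels[extra])
      }
      labs
    })
    member_ids <- qid[is_member]
    ann <- annotation_table(c(member_ids, cid),
                            c(q_labels[is_member], lapply(labels, list)),
                            kind = "hierarchy")
    list(scores = score_matrix(d, qid, cid, "distance"),
         annotations = ann,
         catalog = setNames(leaf_str, cid),
         truth = data.frame(query_id = qid,
                            label = ifelse(is_member, leaf_str[true_leaf], NA_character_),
                            is_member = is_member),
         manifest = run_manifest("gen_hierarchy_instance", unclass(spec)))
  })
}

#' Joint similarity/structural-Z instance (prefilter evaluation)
#'
#' Homologous query-lookup pairs draw a latent quality `u ~ Unif(0,1)`; both
#' the fast-model similarity and the structural Z-score are monotone in `u`
#' plus noise, so similarity rankings track Z by construction. Z below 2 is
#' reported as 0 (structural aligners do not emit sub-significant scores);
#' non-homologous pairs have Z = 0 and background similarities.
#'
#' @param spec a [generator_spec()].
#' @return list: `scores` (similarity [score_matrix()]), `z` (data frame
#'   `query_id`, `lookup_id`, `z`), `homolog` (logical mask), `manifest`.
#' @export
gen_prefilter_instance <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  with_seed(spec$seed, {
    n <- spec$n_query * spec$n_lookup
    hom <- matrix(rbinom(n, 1, spec$homolog_prob) == 1L, spec$n_query, spec$n_lookup)
    s <- numeric(n)
    z <- numeric(n)
    ih <- as.vector(hom)
    nh <- sum(ih)
    u <- runif(nh)
    s[ih] <- pmin(pmax(0.55 + 0.4 * u + rnorm(nh, 0, spec$sim_noise_sd), 0), 1)
    zraw <- 2 + (spec$z_max - 2) * u^1.5 + rnorm(nh, 0, spec$z_noise_sd)
    z[ih] <- ifelse(zraw < 2, 0, zraw)
    s[!ih] <- 0.6 * rbeta(n - nh, 2, 5)
    qid <- sprintf("Q%04d", seq_len(spec$n_query))
    lid <- sprintf("L%05d", seq_len(spec$n_lookup))
    dimnames(hom) <- list(qid, lid)
    list(scores = score_matrix(matrix(s, spec$n_query, spec$n_lookup), qid, lid, "similarity"),
         z = data.frame(query_id = rep(qid, times = spec$n_lookup),
                        lookup_id = rep(lid, each = spec$n_query),
                        z = z),
         homolog = hom,
         manifest = run_manifest("gen_prefilter_instance", unclass(spec)))
  })
}
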