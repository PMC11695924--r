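# Loss functions the calibrator can control: pairwise match predicates,
# set-level FDR and FNR, and the hierarchical mismatch loss.

#' Per-depth mismatch costs for the hierarchical loss
#'
#' Five nonnegative, nondecreasing costs indexed by mismatch depth: `c[1]`
#' (depth 0) is the cost of an exact match, `c[5]` (depth 4) the cost of a
#' top-level class mismatch. The loss bound `B = max(costs)` is carried into
#' calibration. The default `(0, 1, 2, 3, 4)` makes the set loss of a
#' singleton reduce to the mismatch depth itself; `(0, 1, 2, 4, 100)` is a
#' sensible alternative when class-level mistakes must be severely
#' penalized.
#'
#' @param costs numeric vector of length 5.
#' @return object of class `cost_vector` with a `B` field.
#' @export
cost_vector <- function(costs = c(0, 1, 2, 3, 4)) {
  costs <- as.numeric(costs)
  if (length(costs) != 5L) stop("`costs` must have length 5 (mismatch depths 0..4)")
  if (any(costs < 0) || anyNA(costs)) stop("costs must be nonnegative and finite")
  if (any(!is.finite(costs))) stop("costs must be finite (the loss bound B must be < Inf)")
  if (is.unsorted(costs)) stop("costs must be nondecreasing in mismatch depth")
  structure(list(costs = costs, B = max(costs)), class = "cost_vector")
}

#' @export
print.cost_vector <- function(x, ...) {
  cat("<cost_vector> depths 0..4:", paste(x$costs, collapse = ", "),
      sprintf("(B = %g)\n", x$B))
  invisible(x)
}

#' Specify what counts as a functional match
#'
#' * `pfam_exact`: identical Pfam accession sets.
#' * `pfam_partial`: at least one shared Pfam accession.
#' * `hierarchical`: match depth (see [pair_match_depth()]) at most
#'   `max_depth`; `max_depth = 0` demands agreement down to the
#'   family/serial level, `max_depth = 1` tolerates family-level divergence
#'   while preserving superfamily homology.
#'
#' @param mode match predicate; Pfam modes ignore `cost_vector`.
#' @param cost_vector a [cost_vector()] (hierarchical mode only).
#' @param max_depth maximum [pair_match_depth()] still considered a match in
#'   hierarchical mode.
#' @param aggregate set aggregation for [hierarchical_set_loss()]: the
#'   maximum over retrieved items (default) or the mean.
#' @param wildcard_agrees should a wildcard level count as agreement? The
#'   default tolerates preliminary annotations such as `2.3.1.*`.
#' @return object of class `match_spec`.
#' @export
match_spec <- function(mode = c("pfam_exact", "pfam_partial", "hierarchical"),
                       cost_vector = conformalpr::cost_vector(),
                       max_depth = 0L,
                       aggregate = c("max", "mean"),
                       wildcard_agrees = TRUE) {
  mode <- match.arg(mode)
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(cost_vector, "cost_vector"))
  structure(list(mode = mode, cost_vector = cost_vector,
                 max_depth = as.integer(max_depth), aggregate = aggregate,
                 wildcard_agrees = isTRUE(wildcard_agrees)),
            class = "match_spec")
}

#' Hierarchical mismatch depth between two labels
#'
#' Returns `4 - L` where `L` is the number of leading hierarchy levels on
#' which the two labels agree: 0 is an exact match, 4 means the labels
#' disagree already at the top (class) level. A wildcard level counts as
#' agreement by default, so a preliminary annotation `2.3.1.*` matches
#' `2.3.1.13` at depth 0 (set `wildcard_agrees = FALSE` for the strict
#' reading).
#'
#' @param query_label,hit_label `hierarchy_label` objects sharing a scheme.
#' @param wildcard_agrees treat wildcards as agreeing (default `TRUE`).
#' @return integer in `0:4`.
#' @examples
#' a <- parse_hierarchy_label("2.1.1.13", "EC")
#' b <- parse_hierarchy_label("2.1.1.12", "EC")
#' pair_match_depth(a, b) # 1: family-level mismatch
#' @export
pair_match_depth <- function(query_label, hit_label, wildcard_agrees = TRUE) {
  stopifnot(inherits(query_label, "hierarchy_label"), inherits(hit_label, "hierarchy_label"))
  if (!identical(query_label$scheme, hit_label$scheme)) {
    stop(sprintf("labels use different schemes (%s vs %s)",
                 query_label$scheme, hit_label$scheme))
  }
  agree <- query_label$levels == hit_label$levels
  if (wildcard_agrees) agree <- agree | query_label$wildcard | hit_label$wildcard
  mism <- which(!agree)
  if (!length(mism)) 0L else 5L - mism[1]
}

# minimum cost of one retrieved item against all valid query labels,
# honouring the multi-label minimum rule on both sides
.item_cost <- function(query_labels, item_labels, costs, wildcard_agrees) {
  best <- Inf
  for (ql in query_labels) {
    for (il in item_labels) {
      d <- pair_match_depth(ql, il, wildcard_agrees)
      best <- min(best, costs[d + 1L])
      if (best == costs[1L]) return(best)
    }
  }
  best
}

#' Hierarchical loss of a retrieval set
#'
#' Each retrieved item is scored by its mismatch cost against the query's
#' ground-truth label; when the query (or an item) carries several valid
#' labels the minimum over label pairs is taken, so a model is never
#' penalized for agreeing with one of several admissible assignments. The
#' set loss is the maximum item cost (the worst retrieved protein dominates;
#' `aggregate = "mean"` is available). The empty set scores 0: abstention is
#' never penalized.
#'
#' @param query_labels `hierarchy_label` or non-empty list thereof (multiple
#'   valid assignments allowed).
#' @param retrieved_labels list with one element per retrieved item; each
#'   element a `hierarchy_label` or list thereof.
#' @param cost_vector a [cost_vector()].
#' @param aggregate `"max"` (default) or `"mean"`.
#' @param wildcard_agrees see [pair_match_depth()].
#' @return loss in `[0, B]`.
#' @examples
#' q <- parse_hierarchy_label("2.1.1.13", "EC")
#' hit <- parse_hierarchy_label("2.1.1.12", "EC")
#' hierarchical_set_loss(q, list(hit), cost_vector()) # 1
#' @export
hierarchical_set_loss <- function(query_labels, retrieved_labels,
                                  cost_vector = conformalpr::cost_vector(),
                                  aggregate = c("max", "mean"),
                                  wildcard_agrees = TRUE) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(cost_vector, "cost_vector"))
  if (inherits(query_labels, "hierarchy_label")) query_labels <- list(query_labels)
  if (!length(query_labels)) stop("`query_labels` must be non-empty")
  if (!length(retrieved_labels)) return(0)
  item_costs <- vapply(retrieved_labels, function(item) {
    if (inherits(item, "hierarchy_label")) item <- list(item)
    .item_cost(query_labels, item, cost_vector$costs, wildcard_agrees)
  }, numeric(1))
  if (aggregate == "max") max(item_costs) else mean(item_costs)
}

# Pairwise match predicate between a query's payload and a hit's payload.
# Unannotated hits (NULL payload) count as non-matches, never dropped:
# dropping them would bias the FDR downward.
.pair_matches <- function(query_payload, hit_payload, spec) {
  if (is.null(query_payload) || is.null(hit_payload)) return(FALSE)
  switch(spec$mode,
    pfam_exact = setequal(query_payload, hit_payload),
    pfam_partial = length(intersect(query_payload, hit_payload)) > 0L,
    hierarchical = {
      q <- if (inherits(query_payload, "hierarchy_label")) list(query_payload) else query_payload
      h <- if (inherits(hit_payload, "hierarchy_label")) list(hit_payload) else hit_payload
      best <- min(vapply(q, function(ql) {
        min(vapply(h, function(hl) pair_match_depth(ql, hl, spec$wildcard_agrees), numeric(1)))
      }, numeric(1)))
      best <= spec$max_depth
    })
}

.match_vector <- function(query_id, ids, annotations, spec) {
  qp <- annotations[[query_id]]
  vapply(ids, function(id) .pair_matches(qp, annotations[[id]], spec), logical(1))
}

#' False discovery rate of a retrieval set
#'
#' The fraction of retrieved lookup proteins that are not functional matches
#' of the query, `FP / (FP + TP)`. The empty set scores 0 (no discoveries,
#' no false discoveries). FDR is not monotone in the retrieval threshold,
#' which is why it is calibrated with [ltt_threshold()] rather than
#' [crc_threshold()].
#'
#' @param query_id query identifier (must be annotated).
#' @param retrieval a [retrieval_set()].
#' @param annotations an [annotation_table()] covering query and retrieved
#'   ids; missing ids count as non-matches.
#' @param spec a [match_spec()].
#' @return loss in `[0, 1]`.
#' @export
fdr_loss <- function(query_id, retrieval, annotations, spec) {
  stopifnot(inherits(retrieval, "retrieval_set"), inherits(spec, "match_spec"))
  ids <- retrieval$members
  if (!length(ids)) return(0)
  mean(!.match_vector(query_id, ids, annotations, spec))
}

#' False negative rate of a retrieval set
#'
#' `FN / (FN + TP)`: the fraction of the query's true matches in the lookup
#' universe that the retrieval set missed. A query with no true matches
#' scores 0 and the result carries attribute `no_true_matches = TRUE` so
#' callers can flag or exclude such queries from calibration.
#'
#' @inheritParams fdr_loss
#' @param lookup_ids the full lookup universe against which false negatives
#'   are counted.
#' @return loss in `[0, 1]`.
#' @export
fnr_loss <- function(query_id, retrieval, annotations, spec, lookup_ids) {
  stopifnot(inherits(retrieval, "retrieval_set"), inherits(spec, "match_spec"))
  truth <- .match_vector(query_id, lookup_ids, annotations, spec)
  m <- lookup_ids[truth]
  if (!length(m)) {
    return(structure(0, no_true_matches = TRUE))
  }
  sum(!(m %in% retrieval$members)) / length(m)
}
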