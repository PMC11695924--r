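# Domain types shared by every module: score matrices, hierarchy labels,
# annotation tables, retrieval sets, and the canonical threshold orientation.

#' Construct a query-by-lookup score matrix
#'
#' The universal input of the package: a dense matrix of scores
#' \eqn{S_{ij} = f(q_i, v_j)} between query proteins (rows) and lookup
#' proteins (columns), together with a declared score kind. `score_kind` is
#' set exactly once here and propagated to all downstream operations so that
#' similarity (larger = closer) and distance (smaller = closer) inputs are
#' never confused.
#'
#' @param scores numeric matrix, rows = queries, columns = lookup proteins;
#'   no missing values.
#' @param query_ids,lookup_ids character identifiers; default to dimnames.
#'   Identifiers are opaque strings, no sequence semantics attached.
#' @param score_kind `"similarity"` or `"distance"`.
#' @return an object of class `score_matrix`.
#' @examples
#' m <- matrix(c(0.95, 0.4, 0.2, 0.88), nrow = 2, byrow = TRUE)
#' sm <- score_matrix(m, c("q1", "q2"), c("v1", "v2"), "similarity")
#' @export
score_matrix <- function(scores,
                         query_ids = rownames(scores),
                         lookup_ids = colnames(scores),
                         score_kind = c("similarity", "distance")) {
  score_kind <- match.arg(score_kind)
  if (!is.matrix(scores) || !is.numeric(scores)) {
    stop("`scores` must be a numeric matrix")
  }
  if (anyNA(scores)) stop("`scores` contains missing values; dense score matrices must be complete")
  if (is.null(query_ids) || is.null(lookup_ids)) {
    stop("query and lookup identifiers are required (dimnames or explicit arguments)")
  }
  query_ids <- as.character(query_ids)
  lookup_ids <- as.character(lookup_ids)
  if (length(query_ids) != nrow(scores)) stop("length(query_ids) must equal nrow(scores)")
  if (length(lookup_ids) != ncol(scores)) stop("length(lookup_ids) must equal ncol(scores)")
  if (anyDuplicated(query_ids)) stop("duplicate query identifiers")
  if (anyDuplicated(lookup_ids)) stop("duplicate lookup identifiers")
  dimnames(scores) <- list(query_ids, lookup_ids)
  structure(
    list(scores = scores, query_ids = query_ids, lookup_ids = lookup_ids,
         score_kind = score_kind),
    class = "score_matrix"
  )
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix> %d queries x %d lookup proteins (%s scores)\n",
              length(x$query_ids), length(x$lookup_ids), x$score_kind))
  cat(sprintf("  score range: [%.4g, %.4g]\n", min(x$scores), max(x$scores)))
  invisible(x)
}

#' @export
dim.score_matrix <- function(x) dim(x$scores)

# Canonical "permissiveness" orientation: retrieval sets are
# {j : canonical score <= lambda}, nested nondecreasing in lambda.
# Similarity maps via negation, distance passes through.
canonical_scores <- function(x) {
  stopifnot(inherits(x, "score_matrix"))
  if (x$score_kind == "similarity") -x$scores else x$scores
}

canonical_to_user <- function(lambda, score_kind) {
  if (score_kind == "similarity") -lambda else lambda
}

user_to_canonical <- canonical_to_user # negation is an involution

#' Parse a hierarchical EC/SCOPe label
#'
#' EC numbers (`2.1.1.13`) and SCOPe identifiers (`a.1.1.1`) are 4-level
#' ordered labels: class, subclass, sub-subclass, serial for EC; class,
#' fold, superfamily, family for SCOPe. Partially characterized labels use
#' `*` for unspecified deeper levels (`2.3.1.*`); missing trailing
#' components are treated as wildcards. Once a level is a wildcard every
#' deeper level must be too.
#'
#' @param text label string, dot-separated, at most 4 components. Embedded
#'   whitespace (as in printed tables, `"2.3. 1. *"`) is tolerated.
#' @param scheme `"EC"`, `"SCOPe"` or `"generic"`.
#' @return an object of class `hierarchy_label` with fields `scheme`,
#'   `levels` (4 strings) and `wildcard` (4 logicals).
#' @examples
#' parse_hierarchy_label("2.1.1.13", "EC")
#' parse_hierarchy_label("2.3.1.*", "EC")  # wildcard serial
#' @seealso [format_hierarchy_label()], [pair_match_depth()]
#' @export
parse_hierarchy_label <- function(text, scheme = c("EC", "SCOPe", "generic")) {
  scheme <- match.arg(scheme)
  if (length(text) != 1L || !is.character(text)) stop("`text` must be a single string")
  raw <- gsub("[[:space:]]", "", text)
  if (!nzchar(raw)) stop("empty hierarchy label")
  parts <- strsplit(raw, ".", fixed = TRUE)[[1]]
  if (length(parts) > 4L) {
    stop(sprintf("hierarchy label '%s' has %d components; at most 4 allowed", text, length(parts)))
  }
  if (any(!nzchar(parts))) {
    bad <- which(!nzchar(parts))[1]
    stop(sprintf("hierarchy label '%s' has an empty component at level %d", text, bad))
  }
  parts <- c(parts, rep("*", 4L - length(parts)))
  wildcard <- parts == "*"
  if (any(wildcard)) {
    first <- which(wildcard)[1]
    if (any(!wildcard[first:4L])) {
      offending <- parts[first:4L][!wildcard[first:4L]][1]
      stop(sprintf(
        "hierarchy label '%s': wildcard precedes concrete level '%s' (wildcards must trail)",
        text, offending))
    }
  }
  structure(list(scheme = scheme, levels = parts, wildcard = wildcard),
            class = "hierarchy_label")
}

#' Format a hierarchy label back to its canonical string
#'
#' Inverse of [parse_hierarchy_label()]: `parse -> format -> parse` is the
#' identity for any valid label.
#'
#' @param label a `hierarchy_label`.
#' @return canonical dot-separated string, wildcards printed as `*`.
#' @export
format_hierarchy_label <- function(label) {
  stopifnot(inherits(label, "hierarchy_label"))
  paste(label$levels, collapse = ".")
}

#' @export
format.hierarchy_label <- function(x, ...) format_hierarchy_label(x)

#' @export
print.hierarchy_label <- function(x, ...) {
  cat(sprintf("<%s> %s\n", x$scheme, format_hierarchy_label(x)))
  invisible(x)
}

#' Build an annotation table
#'
#' Maps protein identifiers to annotation payloads: either sets of Pfam
#' accessions (`kind = "pfam"`, de-duplicated) or non-empty lists of
#' [hierarchy labels][parse_hierarchy_label] (`kind = "hierarchy"`; multiple
#' valid EC assignments per protein are allowed). Identifiers absent from
#' the table are treated as explicitly unannotated by the loss functions
#' (they count as non-matches, never silently dropped).
#'
#' @param ids character identifiers.
#' @param annotations list parallel to `ids`: character vectors of Pfam
#'   accessions, or lists of `hierarchy_label` objects (single labels are
#'   wrapped).
#' @param kind `"pfam"` or `"hierarchy"`.
#' @return object of class `annotation_table` (a named list with a `kind`
#'   attribute).
#' @export
annotation_table <- function(ids, annotations, kind = c("pfam", "hierarchy")) {
  kind <- match.arg(kind)
  ids <- as.character(ids)
  if (length(ids) != length(annotations)) stop("`ids` and `annotations` lengths differ")
  if (anyDuplicated(ids)) stop("duplicate identifiers in annotation table")
  payload <- lapply(annotations, function(a) {
    if (kind == "pfam") {
      unique(as.character(a))
    } else {
      if (inherits(a, "hierarchy_label")) a <- list(a)
      if (!length(a) || !all(vapply(a, inherits, logical(1), "hierarchy_label"))) {
        stop("hierarchy annotations must be non-empty lists of hierarchy_label objects")
      }
      a
    }
  })
  names(payload) <- ids
  structure(payload, kind = kind, class = "annotation_table")
}

annotation_kind <- function(tab) attr(tab, "kind")

#' @export
print.annotation_table <- function(x, ...) {
  cat(sprintf("<annotation_table> %d proteins, kind = %s\n", length(x), attr(x, "kind")))
  invisible(x)
}

#' Read an annotation table from TSV
#'
#' Expected format: `id<TAB>annotation[;annotation...]`, UTF-8, optional
#' header. Pfam payloads are accessions such as `PF00001`; hierarchical
#' payloads use dot notation (`2.1.1.13`, `a.1.1.1`, wildcards `2.3.1.*`).
#'
#' @param path file path.
#' @param kind `"pfam"` or `"hierarchy"`.
#' @param scheme label scheme for `kind = "hierarchy"`.
#' @return an [annotation_table()].
#' @export
read_annotation_table <- function(path, kind = c("pfam", "hierarchy"),
                                  scheme = c("EC", "SCOPe", "generic")) {
  kind <- match.arg(kind)
  scheme <- match.arg(scheme)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("annotation file '%s' is empty", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(fields[[1]]) >= 2 && identical(tolower(fields[[1]][1]), "id")) {
    fields <- fields[-1]
  }
  bad <- which(vapply(fields, length, integer(1)) < 2L)
  if (length(bad)) {
    stop(sprintf("annotation file '%s': line %d has fewer than 2 tab-separated fields", path, bad[1]))
  }
  ids <- vapply(fields, `[`, character(1), 1L)
  ann <- lapply(fields, function(f) strsplit(f[2], ";", fixed = TRUE)[[1]])
  if (kind == "hierarchy") {
    ann <- lapply(ann, function(a) lapply(a, parse_hierarchy_label, scheme = scheme))
  }
  annotation_table(ids, ann, kind = kind)
}

#' Load a score matrix from a delimited text file
#'
#' Two dialects are supported. `"triples"`: TSV rows
#' `query_id<TAB>lookup_id<TAB>score` (header optional); identifiers are
#' ordered by first appearance, duplicate (query, lookup) pairs are
#' rejected, and pairs absent from the file take the `absent` value (an
#' explicitly declared convention; by default absent pairs are an error).
#' `"dense"`: TSV with lookup ids as the header row and query ids as the
#' first column.
#'
#' @param path file path.
#' @param format `"triples"` or `"dense"`.
#' @param score_kind `"similarity"` or `"distance"`.
#' @param absent value for (query, lookup) pairs missing from a triples
#'   file, or `NULL` (default) to require a complete matrix.
#' @return a [score_matrix()].
#' @export
load_score_matrix <- function(path, format = c("triples", "dense"),
                              score_kind = c("similarity", "distance"),
                              absent = NULL) {
  format <- match.arg(format)
  score_kind <- match.arg(score_kind)
  lines <- readLines(path, encoding = "UTF-8")
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop(sprintf("score file '%s' is empty", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)

  if (format == "triples") {
    if (length(fields[[1]]) != 3L) {
      stop(sprintf("'%s' line %d: expected 3 tab-separated fields", path, lineno[1]))
    }
    # header is optional: drop the first row when its score field is non-numeric
    if (is.na(suppressWarnings(as.numeric(fields[[1]][3])))) {
      fields <- fields[-1]
      lineno <- lineno[-1]
    }
    nf <- vapply(fields, length, integer(1))
    if (any(nf != 3L)) {
      stop(sprintf("'%s' line %d: expected 3 tab-separated fields, found %d",
                   path, lineno[which(nf != 3L)[1]], nf[nf != 3L][1]))
    }
    q <- vapply(fields, `[`, character(1), 1L)
    v <- vapply(fields, `[`, character(1), 2L)
    s <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3L)))
    if (anyNA(s)) {
      stop(sprintf("'%s' line %d: non-numeric score '%s'",
                   path, lineno[which(is.na(s))[1]],
                   vapply(fields, `[`, character(1), 3L)[which(is.na(s))[1]]))
    }
    key <- paste(q, v, sep = "\r")
    if (anyDuplicated(key)) {
      stop(sprintf("'%s' line %d: duplicate (query, lookup) pair (%s, %s)",
                   path, lineno[which(duplicated(key))[1]],
                   q[which(duplicated(key))[1]], v[which(duplicated(key))[1]]))
    }
    qid <- unique(q)
    vid <- unique(v)
    m <- matrix(NA_real_, length(qid), length(vid), dimnames = list(qid, vid))
    m[cbind(match(q, qid), match(v, vid))] <- s
    if (anyNA(m)) {
      if (is.null(absent)) {
        miss <- which(is.na(m), arr.ind = TRUE)[1, ]
        stop(sprintf(
          "'%s': pair (%s, %s) is absent and no `absent` score convention was declared",
          path, qid[miss[1]], vid[miss[2]]))
      }
      m[is.na(m)] <- absent
    }
    return(score_matrix(m, qid, vid, score_kind))
  }

  # dense: header row of lookup ids, first column of query ids
  header <- fields[[1]]
  vid <- header[-1]
  body <- fields[-1]
  lineno <- lineno[-1]
  nf <- vapply(body, length, integer(1))
  if (any(nf != length(header))) {
    stop(sprintf("'%s' line %d: ragged dense row (%d fields, expected %d)",
                 path, lineno[which(nf != length(header))[1]],
                 nf[nf != length(header)][1], length(header)))
  }
  qid <- vapply(body, `[`, character(1), 1L)
  vals <- suppressWarnings(vapply(body, function(f) as.numeric(f[-1]), numeric(length(vid))))
  vals <- matrix(vals, nrow = length(vid)) # vapply returns columns per row
  if (anyNA(vals)) {
    bad <- which(apply(vals, 2, anyNA))[1]
    stop(sprintf("'%s' line %d: non-numeric score in dense row", path, lineno[bad]))
  }
  score_matrix(t(vals), qid, vid, score_kind)
}

#' Construct a retrieval set
#'
#' The set of lookup proteins whose score passes the inclusion rule against
#' a threshold; may be empty (abstention, the correct answer for a query
#' with no homologs in the database).
#'
#' @param query_id query identifier.
#' @param members character vector of retrieved lookup ids.
#' @param threshold threshold used (user score orientation).
#' @param rule one of `"geq"`, `"gt"`, `"leq"`, `"lt"`.
#' @return object of class `retrieval_set`.
#' @export
retrieval_set <- function(query_id, members, threshold, rule = c("geq", "gt", "leq", "lt")) {
  rule <- match.arg(rule)
  structure(list(query_id = as.character(query_id),
                 members = as.character(members),
                 threshold = threshold, rule = rule),
            class = "retrieval_set")
}

#' @export
print.retrieval_set <- function(x, ...) {
  op <- c(geq = ">=", gt = ">", leq = "<=", lt = "<")[[x$rule]]
  cat(sprintf("<retrieval_set> query %s: %d hits (score %s %.6g)\n",
              x$query_id, length(x$members), op, x$threshold))
  invisible(x)
}
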