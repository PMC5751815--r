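#' Build a pairwise node-similarity table
#'
#' Assembles the sparse nonnegative similarity matrix S between the query and
#' target node sets. Only entries strictly greater than the threshold `s_t`
#' are retained; each retained entry defines a pseudo-edge, the only conduit
#' of cross-network random-walk flow. With the default `s_t = 0`, any
#' strictly positive score creates a pseudo-edge.
#'
#' @param scores A data frame with columns (query id, target id, score), in
#'   that order. Scores must be nonnegative reals (e.g. BLAST bit scores, but
#'   any nonnegative similarity is accepted).
#' @param query,target `netquery_network` objects the scores refer to.
#' @param s_t Similarity threshold; entries with score `> s_t` become
#'   pseudo-edges, entries at or below it are dropped.
#' @return A `netquery_similarity` object: sparse `|V_Q| x |V_T|` matrix `S`,
#'   the threshold `s_t`, and the two id vectors.
#' @details Rows naming identifiers absent from either network are dropped
#'   with an informational message (they are not an error: similarity files
#'   routinely cover a larger universe than one network pair). Duplicate
#'   (query, target) rows keep the maximum score, the usual best-hit
#'   convention for BLAST-derived tables.
#' @export
similarity_from_scores <- function(scores, query, target, s_t = 0) {
  scores <- as.data.frame(scores)
  if (ncol(scores) < 3) {
    abort("`scores` must have columns (query id, target id, score).")
  }
  q <- as.character(scores[[1]])
  t <- as.character(scores[[2]])
  s <- as.numeric(scores[[3]])
  if (anyNA(s)) abort("Similarity scores must be parseable as numbers.")
  if (any(s < 0)) abort("Similarity scores must be nonnegative.")
  qi <- match(q, query$node_ids)
  ti <- match(t, target$node_ids)
  unknown <- is.na(qi) | is.na(ti)
  if (any(unknown)) {
    inform(sprintf(
      "Dropped %d similarity row(s) naming nodes absent from the networks.",
      sum(unknown)
    ))
    qi <- qi[!unknown]; ti <- ti[!unknown]; s <- s[!unknown]
  }
  if (length(s)) {
    key <- paste(qi, ti)
    if (anyDuplicated(key)) {
      warn(sprintf(
        "%d duplicate (query, target) similarity pair(s); keeping the maximum score.",
        sum(duplicated(key))
      ))
      ord <- order(key, -s)
      keep <- !duplicated(key[ord])
      qi <- qi[ord][keep]; ti <- ti[ord][keep]; s <- s[ord][keep]
    }
    keep <- s > s_t
    qi <- qi[keep]; ti <- ti[keep]; s <- s[keep]
  }
  if (!length(s)) {
    abort("No pseudo-edges: every similarity score is at or below `s_t`; the networks are incomparable.")
  }
  S <- sparseMatrix(i = qi, j = ti, x = s,
                    dims = c(n_nodes(query), n_nodes(target)))
  structure(
    list(S = S, s_t = s_t,
         query_ids = query$node_ids, target_ids = target$node_ids),
    class = "netquery_similarity"
  )
}

#' Read a similarity table from TSV
#'
#' Expects rows `(query_id, target_id, score)` separated by tabs or spaces;
#' `#` comments and blank lines are skipped.
#'
#' @inheritParams similarity_from_scores
#' @param path Path to the similarity TSV.
#' @param header If `TRUE`, discard the first non-comment row.
#' @return A `netquery_similarity` object; see [similarity_from_scores()].
#' @export
read_similarity <- function(path, query, target, s_t = 0, header = FALSE) {
  rows <- read_token_rows(path, min_tokens = 3, header = header)
  tk <- rows$tokens
  df <- data.frame(
    query_id = vapply(tk, `[[`, character(1), 1L),
    target_id = vapply(tk, `[[`, character(1), 2L),
    score = suppressWarnings(as.numeric(vapply(tk, `[[`, character(1), 3L)))
  )
  if (anyNA(df$score)) {
    bad <- which(is.na(df$score))[1]
    abort(sprintf("Malformed score at line %d of '%s'.", rows$lines[bad], path))
  }
  similarity_from_scores(df, query, target, s_t = s_t)
}

#' @export
print.netquery_similarity <- function(x, ...) {
  cat(sprintf(
    "<netquery_similarity> %d x %d, %d pseudo-edge(s), s_t = %g\n",
    nrow(x$S), ncol(x$S), length(x$S@x), x$s_t
  ))
  invisible(x)
}

#' @export
as_tibble.netquery_similarity <- function(x, ...) {
  tr <- Matrix::summary(x$S)
  tibble(
    query_id = x$query_ids[tr$i],
    target_id = x$target_ids[tr$j],
    score = tr$x
  ) |> dplyr::arrange(.data$query_id, .data$target_id)
}
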