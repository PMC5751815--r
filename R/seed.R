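#' Maximum-weight bipartite matching of the correspondence matrix
#'
#' Selects a one-to-one partial matching between query and target nodes that
#' maximizes total steady-state flow. Only pairs with strictly positive flow
#' may be matched (zero flow is no evidence of correspondence). Among equally
#' optimal matchings the lexicographically smallest one is returned:
#' query nodes are fixed in ascending index order, each to its
#' smallest-index optimal target (or left unmatched if that is optimal).
#'
#' @param C A `netquery_correspondence` or a nonnegative weight matrix.
#' @return An integer vector of length `|V_Q|`: `matching[i]` is the target
#'   index matched to query node `i`, or `NA` if unmatched. The total matched
#'   weight is attached as attribute `weight`.
#' @export
match_seed <- function(C) {
  ids_q <- NULL; ids_t <- NULL
  if (inherits(C, "netquery_correspondence")) {
    ids_q <- C$query_ids; ids_t <- C$target_ids
    C <- C$C
  }
  C <- methods::as(methods::as(C, "CsparseMatrix"), "TsparseMatrix")
  tr <- data.frame(i = C@i + 1L, j = C@j + 1L, x = C@x)
  tr <- tr[tr$x > 0, , drop = FALSE]
  if (!nrow(tr)) abort("Cannot match: the correspondence matrix has no positive entries.")
  nq <- nrow(C)

  w_star <- matching_weight(tr)
  tol <- 1e-9 * max(1, w_star)

  # lexicographic refinement: fix query rows one by one, keeping optimality
  matching <- rep(NA_integer_, nq)
  fixed_w <- 0
  rows_with <- sort(unique(tr$i))
  for (q in rows_with) {
    cand <- sort(tr$j[tr$i == q])
    chosen <- NA_integer_
    for (t in cand) {
      w_qt <- tr$x[tr$i == q & tr$j == t]
      rest <- tr[tr$i != q & tr$j != t, , drop = FALSE]
      if (fixed_w + w_qt + matching_weight(rest) >= w_star - tol) {
        chosen <- t
        break
      }
    }
    if (is.na(chosen)) {
      # leaving q unmatched must preserve optimality
      rest <- tr[tr$i != q, , drop = FALSE]
      stopifnot(fixed_w + matching_weight(rest) >= w_star - tol)
    } else {
      matching[q] <- chosen
      fixed_w <- fixed_w + tr$x[tr$i == q & tr$j == chosen]
      tr <- tr[tr$i != q & tr$j != chosen, , drop = FALSE]
    }
  }
  attr(matching, "weight") <- w_star
  attr(matching, "query_ids") <- ids_q
  attr(matching, "target_ids") <- ids_t
  matching
}

# Optimal total weight of a max-weight bipartite matching over a positive
# triplet table (columns i, j, x); 0 for an empty table.
matching_weight <- function(tr) {
  if (!nrow(tr)) return(0)
  rows <- sort(unique(tr$i)); cols <- sort(unique(tr$j))
  nr <- length(rows); nc <- length(cols)
  g <- igraph::make_empty_graph(n = nr + nc, directed = FALSE)
  igraph::V(g)$type <- c(rep(FALSE, nr), rep(TRUE, nc))
  g <- igraph::add_edges(g, rbind(match(tr$i, rows), nr + match(tr$j, cols)))
  igraph::E(g)$weight <- tr$x
  m <- igraph::max_bipartite_match(g, types = igraph::V(g)$type,
                                   weights = igraph::E(g)$weight)
  mm <- m$matching[seq_len(nr)]
  w <- 0
  for (k in seq_len(nr)) {
    if (!is.na(mm[k])) {
      jj <- cols[mm[k] - nr]
      w <- w + max(tr$x[tr$i == rows[k] & tr$j == jj])
    }
  }
  w
}

#' Induce the seed subnetwork from a matching
#'
#' Takes the target subgraph induced on the matched target nodes. If it is
#' disconnected, the largest connected component becomes the seed (ties:
#' the component with the highest summed correspondence, then the lowest
#' node index). If every matched node is isolated from the others, the seed
#' is the single matched node with the maximum correspondence score.
#'
#' @param matching Output of [match_seed()].
#' @param target The target `netquery_network`.
#' @param C The `netquery_correspondence` (or matrix) used for the matching;
#'   needed for tie-breaking and the single-node fallback.
#' @return A `netquery_seed` (see [new_seed_state()]).
#' @export
induce_seed <- function(matching, target, C) {
  if (inherits(C, "netquery_correspondence")) C <- C$C
  matched_q <- which(!is.na(matching))
  if (!length(matched_q)) abort("Empty matching: nothing to induce a seed from.")
  matched_t <- matching[matched_q]
  score_of <- stats::setNames(
    vapply(seq_along(matched_q), function(k) C[matched_q[k], matched_t[k]], numeric(1)),
    matched_t
  )
  comps <- node_set_components(target, matched_t)
  sizes <- lengths(comps)
  if (max(sizes) == 1L) {
    # all matched nodes pairwise disconnected: single best-scoring node
    best_t <- matched_t[order(-score_of[as.character(matched_t)], matched_t)][1]
    return(new_seed_state(best_t, target))
  }
  cand <- which(sizes == max(sizes))
  if (length(cand) > 1) {
    csum <- vapply(cand, function(k) sum(score_of[as.character(comps[[k]])]), numeric(1))
    cand <- cand[csum == max(csum)]
    if (length(cand) > 1) {
      cand <- cand[which.min(vapply(cand, function(k) min(comps[[k]]), integer(1)))]
    }
  }
  new_seed_state(comps[[cand[1]]], target)
}

#' Construct a seed state
#'
#' The evolving subnetwork in the target during seed selection, extension and
#' pruning: its node set, induced internal edges, conductance, frontier
#' (neighboring target nodes), and the extension history.
#'
#' @param nodes Integer target node indices.
#' @param target The target `netquery_network`.
#' @return A `netquery_seed` with fields `nodes`, `internal_edges` (integer
#'   matrix of target indices), `conductance`, `frontier`, and `history`
#'   (tibble, one row per accepted extension step).
#' @export
new_seed_state <- function(nodes, target) {
  nodes <- sort(unique(as.integer(nodes)))
  stopifnot(length(nodes) >= 1, all(nodes >= 1), all(nodes <= n_nodes(target)))
  sub <- induced_subnetwork(target, nodes)
  em <- cbind(nodes[sub$edges[, 1]], nodes[sub$edges[, 2]])
  colnames(em) <- c("i", "j")
  structure(
    list(
      nodes = nodes,
      internal_edges = em,
      conductance = conductance(target, nodes),
      frontier = node_set_frontier(target, nodes),
      history = tibble(
        step = integer(), node = character(), p1 = numeric(), p2 = numeric(),
        r = integer(), conductance_before = numeric(),
        conductance_after = numeric(), n_candidates = integer()
      )
    ),
    class = "netquery_seed"
  )
}

#' @export
print.netquery_seed <- function(x, ...) {
  cat(sprintf(
    "<netquery_seed> %d node(s), %d internal edge(s), conductance %s, frontier %d\n",
    length(x$nodes), nrow(x$internal_edges),
    format(x$conductance, digits = 4), length(x$frontier)
  ))
  invisible(x)
}
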