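#' Stationary distribution within the seed subnetwork
#'
#' For a connected undirected subnetwork the walker's stationary probability
#' at a node is its degree within the subnetwork over the total degree. A
#' seed with no internal edge (a single node) gets the uniform distribution.
#'
#' @param seed A `netquery_seed`.
#' @return Numeric vector over `seed$nodes` (same order), summing to 1.
#' @export
seed_stationary <- function(seed) {
  n <- length(seed$nodes)
  if (!nrow(seed$internal_edges)) return(rep(1 / n, n))
  d <- tabulate(match(as.vector(seed$internal_edges), seed$nodes), nbins = n)
  d / sum(d)
}

#' Entry probability of a frontier node
#'
#' Probability that a walker positioned in the seed according to the seed's
#' stationary distribution steps out to `v` in one move. The escape step
#' happens in the full target network, so each seed node leaves along any of
#' its target edges with probability 1/degree(target).
#'
#' @param seed A `netquery_seed`.
#' @param target The target `netquery_network`.
#' @param v A frontier node index.
#' @return `P1(v)` in `[0, 1]`.
#' @export
entry_probability <- function(seed, target, v) {
  pi_s <- seed_stationary(seed)
  d_t <- rowSums(target$adj)
  nb <- Matrix::which(target$adj[v, ] != 0)
  inside <- intersect(nb, seed$nodes)
  if (!length(inside)) return(0)
  sum(pi_s[match(inside, seed$nodes)] / d_t[inside])
}

#' Association probability of a frontier node
#'
#' Probability that the walker leaves the seed to `v` and returns to the seed
#' on the next step: `P2(v) = P1(v) * r(v) / degree(v)`, where `r(v)` counts
#' the target edges from `v` back into the seed. Nodes interacting often with
#' the seed score high, which favors functionally coherent growth.
#'
#' @inheritParams entry_probability
#' @return `P2(v)` in `[0, P1(v)]`.
#' @export
association_probability <- function(seed, target, v) {
  r <- sum(target$adj[v, seed$nodes])
  d <- sum(target$adj[v, ])
  entry_probability(seed, target, v) * r / d
}

#' Conductance of a node set in a network
#'
#' Cut edges over the smaller side's volume:
#' `phi = cut(S) / min(vol(S), 2m - vol(S))`, with `cut` the number of edges
#' with exactly one endpoint in `S`, `vol` the summed degrees over `S`, and
#' `m` the total number of undirected edges. Low conductance means densely
#' connected inside and sparsely connected to the rest — the signature of a
#' functional module. Degenerate sets (volume 0, or the entire edge mass)
#' return `Inf`.
#'
#' @param target A `netquery_network`.
#' @param node_set Integer node indices (non-empty).
#' @return The conductance, or `Inf` for degenerate sets.
#' @export
conductance <- function(target, node_set) {
  node_set <- unique(as.integer(node_set))
  stopifnot(length(node_set) >= 1)
  d <- rowSums(target$adj)
  vol <- sum(d[node_set])
  internal2 <- sum(target$adj[node_set, node_set])  # 2 * internal edges
  cut <- vol - internal2
  m2 <- sum(d)
  denom <- min(vol, m2 - vol)
  if (denom == 0) return(Inf)
  cut / denom
}

# Score the whole frontier: P1, P2 and r for every neighboring node of the
# seed, ranked by P2 descending with index-ascending tie-break.
candidate_scores <- function(seed, target) {
  fr <- seed$frontier
  if (!length(fr)) {
    return(tibble(node = integer(), p1 = numeric(), p2 = numeric(), r = integer()))
  }
  pi_s <- seed_stationary(seed)
  d_t <- rowSums(target$adj)
  A_fs <- target$adj[fr, seed$nodes, drop = FALSE]
  r <- as.integer(rowSums(A_fs))
  # P1: sum over adjacent seed nodes of pi_s / d_target
  p1 <- as.vector(A_fs %*% (pi_s / d_t[seed$nodes]))
  p2 <- p1 * r / d_t[fr]
  tibble(node = as.integer(fr), p1 = p1, p2 = p2, r = r) |>
    dplyr::arrange(dplyr::desc(.data$p2), .data$node)
}

# The winning extension candidate under the top-K screening rule, or NULL if
# the frontier is empty. Among the K highest-association candidates, picks
# the one minimizing the conductance of the grown seed (ties: higher P2,
# then lower node index).
best_candidate <- function(seed, target, K = 20) {
  sc <- candidate_scores(seed, target)
  if (!nrow(sc)) return(NULL)
  top <- utils::head(sc, K)
  phi_after <- vapply(
    top$node, function(v) conductance(target, c(seed$nodes, v)), numeric(1)
  )
  top$conductance_after <- phi_after
  ord <- order(top$conductance_after, -top$p2, top$node)
  win <- top[ord[1], ]
  win$n_candidates <- nrow(sc)
  win
}

# Relative conductance decrease of a candidate step; an infinite starting
# conductance counts as a full decrease when the step makes it finite.
relative_drop <- function(phi_old, phi_new) {
  if (is.infinite(phi_old)) return(if (is.finite(phi_new)) 1 else 0)
  (phi_old - phi_new) / phi_old
}

# Grow the seed by one node, updating edges, conductance, frontier, history.
add_seed_node <- function(seed, target, win) {
  grown <- new_seed_state(c(seed$nodes, win$node), target)
  grown$history <- dplyr::bind_rows(
    seed$history,
    tibble(
      step = nrow(seed$history) + 1L,
      node = target$node_ids[win$node],
      p1 = win$p1, p2 = win$p2, r = win$r,
      conductance_before = seed$conductance,
      conductance_after = win$conductance_after,
      n_candidates = win$n_candidates
    )
  )
  grown
}

#' Perform one extension step
#'
#' Ranks the frontier by association probability, screens the top `K`
#' candidates, and adds the one whose inclusion minimizes the conductance of
#' the grown seed. Candidates outside the top `K` are never considered, even
#' if adding them would lower conductance further.
#'
#' @param seed A `netquery_seed`.
#' @param target The target `netquery_network`.
#' @param K Number of highest-association candidates screened per step.
#' @return The updated `netquery_seed`, or the string `"stop"` when the
#'   frontier is empty.
#' @export
extend_step <- function(seed, target, K = 20) {
  win <- best_candidate(seed, target, K)
  if (is.null(win)) return("stop")
  add_seed_node(seed, target, win)
}

#' Grow the seed to the fully extended subnetwork
#'
#' Repeats [extend_step()] until one of the stop conditions holds: the seed
#' has reached `max_size` nodes; the best candidate's relative conductance
#' decrease falls below `min_rel_drop` (the "more than 10%" rule at the
#' default); or the frontier is empty. Every accepted step therefore strictly
#' decreases conductance by at least `min_rel_drop` of its current value.
#'
#' @inheritParams extend_step
#' @param max_size Maximum seed size (nodes). The pipeline default is
#'   `ceiling(1.5 * |V_Q|)`, allowing moderate node insertions while bounding
#'   drift away from the query.
#' @param min_rel_drop Minimum relative conductance decrease to accept a
#'   step.
#' @return The fully extended `netquery_seed`; attribute `stop_reason` is one
#'   of `"max_size"`, `"conductance"`, `"frontier_empty"`.
#' @export
extend <- function(seed, target, K = 20, max_size = NULL, min_rel_drop = 0.10) {
  if (is.null(max_size)) abort("`max_size` must be given (pipeline uses ceiling(1.5 * query size)).")
  reason <- NULL
  repeat {
    if (length(seed$nodes) >= max_size) { reason <- "max_size"; break }
    win <- best_candidate(seed, target, K)
    if (is.null(win)) { reason <- "frontier_empty"; break }
    if (relative_drop(seed$conductance, win$conductance_after) < min_rel_drop) {
      reason <- "conductance"; break
    }
    seed <- add_seed_node(seed, target, win)
  }
  attr(seed, "stop_reason") <- reason
  seed
}
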