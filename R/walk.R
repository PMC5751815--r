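#' Intra-network random-walk transition matrix
#'
#' Degree-normalized adjacency D^-1 A: from each node the walker moves to a
#' uniformly chosen neighbor within the same network. Zero-degree nodes keep
#' an all-zero row here; the combination step decides what happens to them.
#'
#' @param net A `netquery_network`.
#' @return A sparse row-stochastic matrix (zero rows allowed for isolated
#'   nodes).
#' @export
intra_transition <- function(net) {
  d <- rowSums(net$adj)
  inv <- ifelse(d > 0, 1 / d, 0)
  Diagonal(x = inv) %*% net$adj
}

#' Cross-network transition matrices over pseudo-edges
#'
#' The query-to-target block normalizes each query node's similarity row to
#' total mass one; the target-to-query block normalizes each target node's
#' similarity column likewise (as rows of the transposed score matrix). So a
#' jump across a pseudo-edge is taken with probability proportional to the
#' similarity score, relative to the node's total similarity mass. Nodes with
#' no pseudo-edge get an all-zero row.
#'
#' @param sim A `netquery_similarity`.
#' @return List with `P_QT` (|V_Q| x |V_T|) and `P_TQ` (|V_T| x |V_Q|),
#'   both sparse with rows summing to 1 where nonempty.
#' @export
cross_transitions <- function(sim) {
  S <- sim$S
  rq <- rowSums(S)
  rt <- colSums(S)
  P_QT <- Diagonal(x = ifelse(rq > 0, 1 / rq, 0)) %*% S
  P_TQ <- Diagonal(x = ifelse(rt > 0, 1 / rt, 0)) %*% Matrix::t(S)
  list(P_QT = P_QT, P_TQ = P_TQ)
}

#' Assemble the integrated-network walk
#'
#' Concatenates the four blocks into the transition matrix over the union of
#' query and target nodes, then renormalizes each row to total mass one. A
#' node holding both intra-network edges and pseudo-edges therefore splits
#' its mass half intra / half cross; a node with only one kind keeps full
#' mass there; a node with neither receives a unit self-loop (counted in the
#' returned object).
#'
#' @param P_Q,P_T Intra-network blocks from [intra_transition()].
#' @param P_QT,P_TQ Cross blocks from [cross_transitions()].
#' @return A `netquery_walk`: the combined stochastic matrix `P`, the number
#'   of query (`nq`) and target (`nt`) nodes, the raw blocks, and the
#'   post-renormalization cross blocks used for flow scoring.
#' @export
combine_walk <- function(P_Q, P_T, P_QT, P_TQ) {
  nq <- nrow(P_Q); nt <- nrow(P_T)
  stopifnot(ncol(P_Q) == nq, ncol(P_T) == nt,
            nrow(P_QT) == nq, ncol(P_QT) == nt,
            nrow(P_TQ) == nt, ncol(P_TQ) == nq)
  P <- rbind(cbind(P_Q, P_QT), cbind(P_TQ, P_T))
  rs <- rowSums(P)
  isolated <- which(rs == 0)
  if (length(isolated)) {
    P <- P + sparseMatrix(i = isolated, j = isolated, x = 1,
                          dims = dim(P))
    rs[isolated] <- 1
  }
  P <- Diagonal(x = 1 / rs) %*% P
  structure(
    list(
      P = methods::as(P, "CsparseMatrix"),
      nq = nq, nt = nt,
      blocks = list(P_Q = P_Q, P_T = P_T, P_QT = P_QT, P_TQ = P_TQ),
      n_isolated = length(isolated)
    ),
    class = "netquery_walk"
  )
}

#' Build the integrated walk for a query/target/similarity triple
#'
#' Convenience wrapper: computes the intra-network transitions of both
#' networks, the cross transitions of the similarity table, and combines
#' them. The resulting walk carries the node identifiers of both networks.
#'
#' @param query,target `netquery_network` objects.
#' @param sim A `netquery_similarity` built on the same pair.
#' @return A `netquery_walk` (see [combine_walk()]) with `query_ids` and
#'   `target_ids` attached.
#' @export
integrated_walk <- function(query, target, sim) {
  stopifnot(nrow(sim$S) == n_nodes(query), ncol(sim$S) == n_nodes(target))
  cross <- cross_transitions(sim)
  w <- combine_walk(intra_transition(query), intra_transition(target),
                    cross$P_QT, cross$P_TQ)
  w$query_ids <- query$node_ids
  w$target_ids <- target$node_ids
  w$pseudo_support <- sim$S != 0
  w
}

#' @export
print.netquery_walk <- function(x, ...) {
  cat(sprintf(
    "<netquery_walk> %d query + %d target nodes; %d self-loop row(s)\n",
    x$nq, x$nt, x$n_isolated
  ))
  invisible(x)
}

# Post-renormalization cross blocks of the combined walk: the transition
# probabilities the walker actually uses to traverse pseudo-edges.
walk_cross_blocks <- function(walk) {
  qi <- seq_len(walk$nq)
  ti <- walk$nq + seq_len(walk$nt)
  list(P_QT = walk$P[qi, ti, drop = FALSE],
       P_TQ = walk$P[ti, qi, drop = FALSE])
}

#' Stationary distribution of a random walk by power iteration
#'
#' Iterates the lazy walk (I + P)/2 from the uniform distribution until the
#' L1 fixed-point residual of P itself falls below `tol`. The lazy step makes
#' the chain aperiodic (an integrated query/target graph with no intra edges
#' is bipartite and would otherwise oscillate) while leaving the fixed points
#' of P unchanged.
#'
#' If the walk's support graph is disconnected, the iteration runs on the
#' pseudo-edge-bearing component with the most nodes; all other nodes get
#' stationary probability zero. For a plain transition matrix with no
#' pseudo-edge information, the largest component carries the walk.
#'
#' @param x A `netquery_walk` or a row-stochastic (sparse) matrix.
#' @param tol L1 convergence tolerance on `pi P - pi`.
#' @param max_iter Maximum number of power iterations.
#' @return A `netquery_stationary`: `pi` (sums to 1 over the active
#'   component), `iterations`, `residual`, and `component` (indices carrying
#'   the walk).
#' @export
stationary_distribution <- function(x, tol = 1e-10, max_iter = 10000) {
  if (inherits(x, "netquery_walk")) {
    P <- x$P
    pseudo_nodes <- if (!is.null(x$pseudo_support)) {
      tr <- Matrix::summary(methods::as(x$pseudo_support, "TsparseMatrix"))
      unique(c(tr$i, x$nq + tr$j))
    } else NULL
  } else {
    P <- x
    pseudo_nodes <- NULL
  }
  n <- nrow(P)
  rs <- rowSums(P)
  if (max(abs(rs - 1)) > 1e-8) {
    abort("Transition matrix rows must sum to 1; run combine_walk() first.")
  }
  # components of the (structurally symmetric) support graph
  g <- igraph::graph_from_adjacency_matrix(P != 0, mode = "max", diag = FALSE)
  comp <- igraph::components(g)
  membership <- comp$membership
  eligible <- seq_len(comp$no)
  if (!is.null(pseudo_nodes) && length(pseudo_nodes)) {
    eligible <- unique(membership[pseudo_nodes])
  }
  sizes <- comp$csize[eligible]
  best <- eligible[sizes == max(sizes)]
  if (length(best) > 1) {
    # tie: component containing the lowest node index
    first_idx <- vapply(best, function(k) min(which(membership == k)), integer(1))
    best <- best[which.min(first_idx)]
  }
  active <- which(membership == best)
  Psub <- P[active, active, drop = FALSE]
  v <- rep(1 / length(active), length(active))
  it <- 0L
  repeat {
    vP <- as.vector(v %*% Psub)
    res <- sum(abs(vP - v))
    if (res <= tol) break
    it <- it + 1L
    if (it > max_iter) {
      abort(sprintf(
        "Power iteration did not converge in %d iterations (residual %.3e).",
        max_iter, res
      ))
    }
    v <- 0.5 * (v + vP)
  }
  pi_full <- numeric(n)
  pi_full[active] <- v / sum(v)
  structure(
    list(pi = pi_full, iterations = it, residual = res, component = active),
    class = "netquery_stationary"
  )
}

#' @export
print.netquery_stationary <- function(x, ...) {
  cat(sprintf(
    "<netquery_stationary> %d active node(s), %d iteration(s), residual %.2e\n",
    length(x$component), x$iterations, x$residual
  ))
  invisible(x)
}

#' Steady-state flow correspondence matrix
#'
#' Scores each pseudo-edge by the total stationary probability mass the
#' walker carries across it per step, in both directions:
#' `C[i, j] = pi(q_i) P_QT[i, j] + P_TQ[j, i] pi(t_j)`, using the combined
#' walk's post-renormalization cross blocks (the transitions the walker
#' actually takes). High flow means the pair is favored both by similarity
#' and by matching interaction context.
#'
#' @param walk A `netquery_walk` from [integrated_walk()].
#' @param pi A `netquery_stationary` computed on the same walk.
#' @return A `netquery_correspondence`: sparse `|V_Q| x |V_T|` flow matrix
#'   `C` (support within the pseudo-edges) plus the id vectors.
#' @export
correspondence <- function(walk, pi) {
  if (inherits(pi, "netquery_stationary")) pi <- pi$pi
  stopifnot(length(pi) == walk$nq + walk$nt)
  cb <- walk_cross_blocks(walk)
  piQ <- pi[seq_len(walk$nq)]
  piT <- pi[walk$nq + seq_len(walk$nt)]
  C <- Diagonal(x = piQ) %*% cb$P_QT + Matrix::t(Diagonal(x = piT) %*% cb$P_TQ)
  C <- methods::as(Matrix::drop0(C), "CsparseMatrix")
  structure(
    list(C = C, query_ids = walk$query_ids, target_ids = walk$target_ids),
    class = "netquery_correspondence"
  )
}

#' @export
print.netquery_correspondence <- function(x, ...) {
  cat(sprintf(
    "<netquery_correspondence> %d x %d, %d scored pair(s)\n",
    nrow(x$C), ncol(x$C), length(x$C@x)
  ))
  invisible(x)
}

#' Tidy a correspondence matrix into a pair table
#'
#' @param x A `netquery_correspondence`.
#' @param ... Unused.
#' @return A tibble with columns `query_id`, `target_id`, `flow`, sorted by
#'   decreasing flow.
#' @export
tidy.netquery_correspondence <- function(x, ...) {
  tr <- Matrix::summary(x$C)
  ids_q <- if (!is.null(x$query_ids)) x$query_ids[tr$i] else as.character(tr$i)
  ids_t <- if (!is.null(x$target_ids)) x$target_ids[tr$j] else as.character(tr$j)
  tibble(query_id = ids_q, target_id = ids_t, flow = tr$x) |>
    dplyr::arrange(dplyr::desc(.data$flow), .data$query_id, .data$target_id)
}

#' Write sparse matrices in MatrixMarket format (debug aid)
#'
#' @param x A sparse matrix, `netquery_walk`, or `netquery_correspondence`.
#' @param path Output `.mtx` path.
#' @export
write_mtx <- function(x, path) {
  if (inherits(x, "netquery_walk")) x <- x$P
  if (inherits(x, "netquery_correspondence")) x <- x$C
  Matrix::writeMM(methods::as(x, "CsparseMatrix"), path)
  invisible(path)
}
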