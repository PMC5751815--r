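#' Induced neighborhood network around the extended seed
#'
#' Builds the network on the extended seed plus all its target neighbors.
#' Its edge set is the seed's internal edges plus every edge between a seed
#' node and a neighbor; edges between two non-seed neighbors are excluded,
#' so the neighborhood enters only through its attachment to the seed.
#'
#' @param extended A `netquery_seed` (typically the output of [extend()]).
#' @param target The target `netquery_network`.
#' @return A `netquery_network` over the seed and its neighbors (node ids
#'   preserved). Attributes: `parent_index` (target indices of its nodes) and
#'   `seed_local` (positions of the seed nodes within it).
#' @export
induce_neighborhood <- function(extended, target) {
  vs <- extended$nodes
  vi <- sort(unique(c(vs, extended$frontier)))
  adj <- target$adj[vi, vi, drop = FALSE]
  seed_local <- match(vs, vi)
  # keep only edges with at least one endpoint in the seed
  in_seed <- logical(length(vi)); in_seed[seed_local] <- TRUE
  em <- Matrix::which(adj != 0, arr.ind = TRUE)
  em <- em[em[, 1] < em[, 2], , drop = FALSE]
  keep <- in_seed[em[, 1]] | in_seed[em[, 2]]
  em <- em[keep, , drop = FALSE]
  if (nrow(em)) em <- em[order(em[, 1], em[, 2]), , drop = FALSE]
  storage.mode(em) <- "integer"
  colnames(em) <- c("i", "j")
  gi <- new_network(target$node_ids[vi], em)
  attr(gi, "parent_index") <- vi
  attr(gi, "seed_local") <- seed_local
  gi
}

#' Personalized PageRank on the induced neighborhood
#'
#' Solves the row-vector fixed point `r = alpha s + (1 - alpha) r M`, where
#' `M` is the degree-normalized adjacency of the induced network (zero-degree
#' rows become self-loops) and the preference vector `s` is uniform over the
#' seed nodes and zero elsewhere. With `alpha = 1` the solution is `s`
#' itself; smaller `alpha` lets relevance diffuse into the neighborhood.
#'
#' @param gi The induced `netquery_network` from [induce_neighborhood()].
#' @param seed_local Integer positions of the seed nodes within `gi`
#'   (defaults to the attribute stored by [induce_neighborhood()]).
#' @param alpha Teleportation constant in `(0, 1]`.
#' @param tol L1 tolerance for the iterative solver and the residual check.
#' @param method `"auto"` uses a direct sparse linear solve up to 2000 nodes
#'   and fixed-point iteration beyond; `"direct"` / `"iterative"` force one.
#' @return A `netquery_ppr`: `r` (sums to 1), `alpha`, `s`, `M`, `method`,
#'   `iterations`, `residual`.
#' @export
personalized_pagerank <- function(gi, seed_local = attr(gi, "seed_local"),
                                  alpha = 0.5, tol = 1e-12,
                                  method = c("auto", "direct", "iterative")) {
  method <- match.arg(method)
  n <- n_nodes(gi)
  stopifnot(length(seed_local) >= 1, all(seed_local >= 1), all(seed_local <= n))
  d <- rowSums(gi$adj)
  M <- Diagonal(x = ifelse(d > 0, 1 / d, 0)) %*% gi$adj
  dangling <- which(d == 0)
  if (length(dangling)) {
    M <- M + sparseMatrix(i = dangling, j = dangling, x = 1, dims = c(n, n))
  }
  s <- numeric(n)
  s[seed_local] <- 1 / length(seed_local)
  it <- 0L
  if (alpha >= 1) {
    r <- s
  } else if (method == "direct" || (method == "auto" && n <= 2000)) {
    # r (I - (1-alpha) M) = alpha s  =>  solve the transposed system
    A <- Diagonal(n) - (1 - alpha) * Matrix::t(M)
    r <- as.vector(Matrix::solve(A, alpha * s))
    method <- "direct"
  } else {
    r <- s
    max_iter <- 100000L
    repeat {
      r_new <- alpha * s + (1 - alpha) * as.vector(r %*% M)
      it <- it + 1L
      if (sum(abs(r_new - r)) <= tol) { r <- r_new; break }
      if (it >= max_iter) {
        abort(sprintf(
          "PPR iteration did not converge in %d iterations (residual %.3e).",
          max_iter, sum(abs(r_new - r))
        ))
      }
      r <- r_new
    }
    method <- "iterative"
  }
  residual <- sum(abs(r - alpha * s - (1 - alpha) * as.vector(r %*% M)))
  structure(
    list(r = stats::setNames(r, gi$node_ids), alpha = alpha, s = s, M = M,
         method = method, iterations = it, residual = residual),
    class = "netquery_ppr"
  )
}

#' @export
print.netquery_ppr <- function(x, ...) {
  cat(sprintf(
    "<netquery_ppr> %d node(s), alpha = %g, method = %s, residual %.2e\n",
    length(x$r), x$alpha, x$method, x$residual
  ))
  invisible(x)
}

#' Prune the induced network by cumulative PageRank mass
#'
#' Nodes are ranked by PageRank value (ties: seed members first, then lower
#' node index) and kept until the cumulative mass reaches `mass`, including
#' the node that crosses it. The induced-network subgraph on the kept set is
#' then reduced to its largest connected component (ties: highest summed
#' PageRank, then lowest node index). The kept set may recruit neighbors
#' that were never in the seed and may drop former seed nodes.
#'
#' @param ppr A `netquery_ppr`.
#' @param gi The induced network the PageRank was computed on.
#' @param seed_local Positions of seed nodes within `gi` (for tie-breaking).
#' @param mass Cumulative-probability threshold.
#' @return A list: `kept_local` (positions within `gi`, sorted), `prefix_local`
#'   (the mass-rule prefix before the connectivity filter), and `ranking`
#'   (tibble of the full ordering with cumulative mass).
#' @export
prune_by_mass <- function(ppr, gi, seed_local = attr(gi, "seed_local"), mass = 0.5) {
  r <- as.numeric(ppr$r)
  r <- r / sum(r)
  n <- length(r)
  is_seed <- logical(n); is_seed[seed_local] <- TRUE
  ord <- order(-r, !is_seed, seq_len(n))
  cum <- cumsum(r[ord])
  k <- which(cum >= mass)[1]
  if (is.na(k)) k <- n
  prefix <- ord[seq_len(k)]
  ranking <- tibble(
    node = gi$node_ids[ord], rank = seq_len(n), ppr = r[ord],
    cumulative = cum, in_seed = is_seed[ord], kept = seq_len(n) <= k
  )
  comps <- node_set_components(gi, prefix)
  sizes <- lengths(comps)
  cand <- which(sizes == max(sizes))
  if (length(cand) > 1) {
    csum <- vapply(cand, function(kk) sum(r[comps[[kk]]]), numeric(1))
    cand <- cand[csum == max(csum)]
    if (length(cand) > 1) {
      cand <- cand[which.min(vapply(cand, function(kk) min(comps[[kk]]), integer(1)))]
    }
  }
  list(
    kept_local = sort(comps[[cand[1]]]),
    prefix_local = sort(prefix),
    ranking = ranking
  )
}
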