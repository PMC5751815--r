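# Independent brute-force oracles. These deliberately share no code with the
# implementation: set arithmetic, explicit loops and dense linear algebra
# only.

# Optimal total weight of a bipartite matching restricted to positive
# entries of W, by exhaustive recursion over the positive pairs.
oracle_matching_weight <- function(W) {
  trip <- which(W > 0, arr.ind = TRUE)
  best <- 0
  rec <- function(k, used_r, used_c, w) {
    if (k > nrow(trip)) {
      best <<- max(best, w)
      return(invisible())
    }
    rec(k + 1, used_r, used_c, w)
    i <- trip[k, 1]; j <- trip[k, 2]
    if (!(i %in% used_r) && !(j %in% used_c)) {
      rec(k + 1, c(used_r, i), c(used_c, j), w + W[i, j])
    }
  }
  if (nrow(trip)) rec(1, integer(), integer(), 0)
  best
}

# Conductance by explicit edge counting over an edge-list matrix (rows i<j).
oracle_conductance <- function(edges, n, node_set) {
  inside <- rep(FALSE, n); inside[node_set] <- TRUE
  cut <- 0; vol <- 0; m <- nrow(edges)
  for (k in seq_len(m)) {
    a <- edges[k, 1]; b <- edges[k, 2]
    if (inside[a]) vol <- vol + 1
    if (inside[b]) vol <- vol + 1
    if (xor(inside[a], inside[b])) cut <- cut + 1
  }
  denom <- min(vol, 2 * m - vol)
  if (denom == 0) return(Inf)
  cut / denom
}

# Association probability by enumerating every 2-step walk that starts in
# the seed (weighted by the seed-internal degree distribution), leaves to v,
# and returns to the seed.
oracle_p2 <- function(adj, seed_nodes, v) {
  n <- nrow(adj)
  d <- rowSums(adj)
  sub <- adj[seed_nodes, seed_nodes, drop = FALSE]
  ds <- rowSums(sub)
  pi_s <- if (sum(ds) > 0) ds / sum(ds) else rep(1 / length(seed_nodes), length(seed_nodes))
  p <- 0
  for (k in seq_along(seed_nodes)) {
    i <- seed_nodes[k]
    for (mid in which(adj[i, ] == 1)) {
      if (mid != v) next
      for (back in which(adj[mid, ] == 1)) {
        if (back %in% seed_nodes) {
          p <- p + pi_s[k] * (1 / d[i]) * (1 / d[mid])
        }
      }
    }
  }
  p
}

# Stationary distribution via a dense left-eigenvector solve (eigenvalue 1).
oracle_stationary_eigen <- function(P) {
  P <- as.matrix(P)
  e <- eigen(t(P))
  k <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, k])
  v / sum(v)
}

# Random connected graph on n nodes: ER edges plus a random spanning tree.
random_connected_graph <- function(n, p = 0.3) {
  g <- igraph::sample_gnp(n, p)
  perm <- sample.int(n)
  for (k in 2:n) {
    g <- igraph::add_edges(g, c(perm[k - 1], perm[k]))
  }
  g <- igraph::simplify(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  network_from_edges(data.frame(a = paste0("n", el[, 1]), b = paste0("n", el[, 2])),
                     nodes = paste0("n", seq_len(n)))
}

# A random small integrated walk: two connected graphs plus a random
# positive similarity table touching every query node.
random_integrated_walk <- function(nq = 5, nt = 7, extra_pairs = 6) {
  q <- random_connected_graph(nq, 0.5)
  t <- random_connected_graph(nt, 0.35)
  pairs <- unique(rbind(
    cbind(seq_len(nq), sample.int(nt, nq, replace = TRUE)),
    cbind(sample.int(nq, extra_pairs, replace = TRUE),
          sample.int(nt, extra_pairs, replace = TRUE))
  ))
  sim <- similarity_from_scores(
    data.frame(q = q$node_ids[pairs[, 1]], t = t$node_ids[pairs[, 2]],
               s = stats::runif(nrow(pairs), 0.5, 5)),
    q, t, s_t = 0
  )
  list(query = q, target = t, sim = sim, walk = integrated_walk(q, t, sim))
}
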