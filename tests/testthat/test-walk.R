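test_that("intra-network transitions are degree-normalized rows", {
  Pt <- as.matrix(intra_transition(triangle()))
  expect_equal(sort(Pt[1, ]), c(0, 0.5, 0.5))
  expect_equal(rowSums(Pt), rep(1, 3), ignore_attr = TRUE)

  net <- network_from_edges(data.frame(a = c("a", "b"), b = c("b", "c")))
  P <- as.matrix(intra_transition(net))
  expect_equal(P[2, ], c(0.5, 0, 0.5), ignore_attr = TRUE)  # middle of the path
  expect_equal(P[1, ], c(0, 1, 0), ignore_attr = TRUE)      # endpoint

  star <- network_from_edges(data.frame(a = rep("c0", 3), b = paste0("l", 1:3)))
  Ps <- as.matrix(intra_transition(star))
  expect_equal(Ps[1, ], c(0, 1, 1, 1) / 3, ignore_attr = TRUE)
})

test_that("cross transitions normalize similarity mass per node", {
  q1 <- network_from_edges(data.frame(a = "q1", b = "q2"))
  t1 <- network_from_edges(data.frame(a = "t1", b = "t2"))

  sim <- similarity_from_scores(
    data.frame(q = c("q1", "q1"), t = c("t1", "t2"), s = c(2, 2)), q1, t1)
  cr <- cross_transitions(sim)
  expect_equal(as.matrix(cr$P_QT)[1, ], c(0.5, 0.5), ignore_attr = TRUE)
  expect_equal(as.vector(cr$P_TQ[, 1]), c(1, 1))  # each target fully to q1
  expect_equal(as.vector(cr$P_QT[2, ]), c(0, 0))  # q2 has no pseudo-edge

  sim2 <- similarity_from_scores(
    data.frame(q = c("q1", "q1"), t = c("t1", "t2"), s = c(1, 3)), q1, t1)
  expect_equal(as.vector(cross_transitions(sim2)$P_QT[1, ]), c(0.25, 0.75))
})

test_that("the combined walk is stochastic with the half/half split", {
  fx <- tiny_triple()
  walk <- integrated_walk(fx$query, fx$target, fx$sim)
  expect_lte(max(abs(Matrix::rowSums(walk$P) - 1)), 1e-12)

  # q1 has intra edges and one pseudo-edge: half intra, half cross
  P <- as.matrix(walk$P)
  expect_equal(sum(P[1, 1:3]), 0.5)
  expect_equal(sum(P[1, 4:8]), 0.5)
  # t5 has only intra edges: full mass stays in the target block
  expect_equal(sum(P[8, 4:8]), 1)
  # pseudo-edge support matches in both cross blocks
  cb <- netquery:::walk_cross_blocks(walk)
  expect_equal(as.matrix(cb$P_QT != 0), t(as.matrix(cb$P_TQ != 0)),
               ignore_attr = TRUE)

  # a fully isolated node becomes a unit self-loop row
  qi <- network_from_edges(data.frame(a = "q1", b = "q2"), nodes = "q3")
  simi <- similarity_from_scores(
    data.frame(q = c("q1", "q2"), t = c("t1", "t2"), s = c(1, 1)),
    qi, network_from_edges(data.frame(a = "t1", b = "t2")))
  wi <- integrated_walk(qi, network_from_edges(data.frame(a = "t1", b = "t2")), simi)
  expect_equal(wi$n_isolated, 1)
  expect_equal(as.matrix(wi$P)[3, 3], 1)
})

test_that("power iteration reaches the degree-proportional stationary law", {
  set.seed(11)
  for (k in 1:5) {
    net <- random_connected_graph(sample(5:20, 1))
    pi <- stationary_distribution(intra_transition(net))
    d <- network_degree(net)
    expect_lt(max(abs(pi$pi - d / sum(d))), 1e-8)
    expect_equal(sum(pi$pi), 1, tolerance = 1e-10)
  }
})

test_that("stationary handles symmetry, disconnection and non-convergence", {
  # two identical triangles under uniform similarity: pi is uniform
  q <- triangle(c("q1", "q2", "q3"))
  t <- triangle(c("t1", "t2", "t3"))
  sim <- similarity_from_scores(
    expand.grid(q = q$node_ids, t = t$node_ids, s = 1), q, t)
  pi <- stationary_distribution(integrated_walk(q, t, sim))
  expect_equal(pi$pi, rep(1 / 6, 6), tolerance = 1e-9)

  # disconnected: the pseudo-edge-bearing component carries the walk
  t2 <- network_from_edges(data.frame(
    a = c("t1", "t2", "t3", "x1"), b = c("t2", "t3", "t1", "x2")))
  sim2 <- similarity_from_scores(
    data.frame(q = "q1", t = "t1", s = 5), q, t2)
  pi2 <- stationary_distribution(integrated_walk(q, t2, sim2))
  x_idx <- 3 + match(c("x1", "x2"), t2$node_ids)
  expect_equal(pi2$pi[x_idx], c(0, 0))
  expect_equal(sum(pi2$pi), 1, tolerance = 1e-10)

  expect_error(
    stationary_distribution(intra_transition(path4()), tol = 0, max_iter = 3),
    "did not converge"
  )
})

test_that("correspondence measures steady-state pseudo-edge flow", {
  # 1 query node, 1 target node, one pseudo-edge, no intra edges:
  # the 2-state chain alternates, pi = (1/2, 1/2), flow = 1/2 + 1/2 = 1
  q <- network_from_edges(data.frame(a = character(), b = character()),
                          nodes = "q1")
  t <- network_from_edges(data.frame(a = character(), b = character()),
                          nodes = "t1")
  sim <- similarity_from_scores(data.frame(q = "q1", t = "t1", s = 3), q, t)
  walk <- integrated_walk(q, t, sim)
  pi <- stationary_distribution(walk)
  C <- correspondence(walk, pi)
  expect_equal(as.numeric(C$C[1, 1]), 1, tolerance = 1e-10)

  # support is exactly the pseudo-edges; entries nonnegative
  fx <- tiny_triple()
  w <- integrated_walk(fx$query, fx$target, fx$sim)
  Cx <- correspondence(w, stationary_distribution(w))
  expect_equal(as.matrix(Cx$C != 0), as.matrix(fx$sim$S != 0), ignore_attr = TRUE)
  expect_true(all(Cx$C@x >= 0))

  # total flow conservation: sum(C) equals the stationary mass crossing
  # sides per step, computed directly from pi and the combined blocks
  cb <- netquery:::walk_cross_blocks(w)
  pi <- stationary_distribution(w)$pi
  out_q <- sum(pi[1:3] * Matrix::rowSums(cb$P_QT))
  out_t <- sum(pi[4:8] * Matrix::rowSums(cb$P_TQ))
  expect_equal(sum(Cx$C), out_q + out_t, tolerance = 1e-12)
})

test_that("scaling all similarity scores leaves P, pi and C unchanged", {
  set.seed(7)
  fx <- random_integrated_walk()
  scaled_scores <- as_tibble(fx$sim)
  scaled_scores$score <- scaled_scores$score * 7.3
  sim2 <- similarity_from_scores(scaled_scores, fx$query, fx$target)
  w1 <- fx$walk
  w2 <- integrated_walk(fx$query, fx$target, sim2)
  expect_lt(max(abs(w1$P - w2$P)), 1e-12)
  C1 <- correspondence(w1, stationary_distribution(w1))
  C2 <- correspondence(w2, stationary_distribution(w2))
  expect_lt(max(abs(C1$C - C2$C)), 1e-12)
})

test_that("zero stationary mass means zero flow for that component", {
  # the integrated graph splits in two; only the larger pseudo-edge-bearing
  # component carries mass, so the other's C entries are exactly zero
  q <- network_from_edges(data.frame(a = "q1", b = "q2"), nodes = "q3")
  t <- network_from_edges(data.frame(
    a = c("t1", "t2", "u1"), b = c("t2", "t3", "u2")))
  sim <- similarity_from_scores(
    data.frame(q = c("q1", "q2", "q3"), t = c("t1", "t2", "u1"), s = c(4, 4, 4)),
    q, t)
  walk <- integrated_walk(q, t, sim)
  pi <- stationary_distribution(walk)
  C <- correspondence(walk, pi)
  u1_col <- match("u1", t$node_ids)
  expect_equal(as.numeric(C$C[3, u1_col]), 0)
  expect_gt(as.numeric(C$C[1, 1]), 0)
})
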