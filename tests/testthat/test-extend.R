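test_that("seed-internal stationary law is degree-proportional", {
  t <- two_k4_bridge()
  seed_tri <- new_seed_state(1:3, triangle())
  expect_equal(seed_stationary(seed_tri), rep(1 / 3, 3))

  p <- path4()
  seed_path3 <- new_seed_state(1:3, p)
  expect_equal(seed_stationary(seed_path3), c(1 / 4, 1 / 2, 1 / 4))

  expect_equal(seed_stationary(new_seed_state(1, t)), 1)
})

test_that("entry probability sums escape terms over target degrees", {
  # v adjacent to one seed node with pi_s = 1/2 and target degree 4
  net <- network_from_edges(data.frame(
    a = c("s1", "s2", "s3", "s2", "s2", "s2"),
    b = c("s2", "s3", "s1", "v", "x1", "x2")
  ))
  seed <- new_seed_state(1:3, net)
  v <- match("v", net$node_ids)
  # pi_s uniform over the triangle; only s2 touches v, d_T(s2) = 5
  expect_equal(entry_probability(seed, net, v), (1 / 3) / 5)

  # frontier-adjacent to nothing in the seed: probability 0
  x1 <- match("x1", net$node_ids)
  expect_equal(entry_probability(seed, net, match("x2", net$node_ids)),
               entry_probability(seed, net, x1))

  # v adjacent to every node of a triangle seed, each with target degree 3
  net2 <- network_from_edges(data.frame(
    a = c("a", "b", "c", "v", "v", "v"),
    b = c("b", "c", "a", "a", "b", "c")
  ))
  seed2 <- new_seed_state(1:3, net2)
  expect_equal(entry_probability(seed2, net2, match("v", net2$node_ids)), 1 / 3)
})

test_that("association probability multiplies the 2-hop return chance", {
  net2 <- network_from_edges(data.frame(
    a = c("a", "b", "c", "v", "v", "v"),
    b = c("b", "c", "a", "a", "b", "c")
  ))
  seed2 <- new_seed_state(1:3, net2)
  v <- match("v", net2$node_ids)
  # P1 = 1/3, r = 3, d_T(v) = 3 so P2 = P1 (all neighbors in the seed)
  expect_equal(association_probability(seed2, net2, v),
               entry_probability(seed2, net2, v))

  # r < d: P2 = P1 * r / d
  net3 <- network_from_edges(data.frame(
    a = c("a", "b", "c", "v", "v", "v", "v"),
    b = c("b", "c", "a", "a", "b", "z1", "z2")
  ))
  seed3 <- new_seed_state(1:3, net3)
  v3 <- match("v", net3$node_ids)
  expect_equal(association_probability(seed3, net3, v3),
               entry_probability(seed3, net3, v3) * 2 / 4)
})

test_that("association probability equals brute-force 2-step enumeration", {
  set.seed(5)
  for (k in 1:25) {
    net <- random_connected_graph(sample(5:10, 1))
    adj <- as.matrix(net$adj)
    nodes <- sample(seq_len(n_nodes(net)), sample(2:4, 1))
    comps <- netquery:::node_set_components(net, nodes)
    nodes <- comps[[which.max(lengths(comps))]]
    seed <- new_seed_state(nodes, net)
    for (v in seed$frontier) {
      p2 <- association_probability(seed, net, v)
      expect_equal(p2, oracle_p2(adj, seed$nodes, v), tolerance = 1e-12)
      p1 <- entry_probability(seed, net, v)
      expect_gte(p1 - p2, -1e-12)
      expect_lte(p1, 1)
      expect_gte(p2, 0)
    }
  }
})

test_that("conductance matches brute-force cut/volume counting", {
  t <- two_k4_bridge()
  expect_equal(conductance(t, 1:4), 1 / 13)  # cut 1, vol 3+3+3+4 = 13
  expect_equal(conductance(t, 1:8), Inf)     # whole graph: denominator 0
  # a single node's cut equals its volume
  expect_equal(conductance(t, 1), 1)

  set.seed(17)
  for (k in 1:30) {
    net <- random_connected_graph(sample(4:12, 1))
    subset <- sample(seq_len(n_nodes(net)), sample(1:(n_nodes(net) - 1), 1))
    expect_equal(conductance(net, subset),
                 oracle_conductance(net$edges, n_nodes(net), subset))
  }
})

test_that("extension screens top-K by association then minimizes conductance", {
  # forced choice: a single frontier node that lowers conductance
  targ <- two_k4_bridge()
  seed <- new_seed_state(1:3, targ)  # 3 of the first K4
  grown <- extend_step(seed, targ, K = 20)
  expect_equal(setdiff(grown$nodes, seed$nodes), 4)  # completes the clique

  # empty frontier: stop
  iso <- network_from_edges(data.frame(a = "a", b = "b"), nodes = "z")
  seed_iso <- new_seed_state(1:2, iso)
  expect_identical(extend_step(seed_iso, iso, K = 5), "stop")

  # equal conductance-after: higher association probability wins
  # star around s: two leaves v1, v2; v1 also touches a second seed node
  net <- network_from_edges(data.frame(
    a = c("s1", "s2", "s1", "s2", "s1"),
    b = c("s2", "v1", "v1", "x", "v2")
  ))
  seed2 <- new_seed_state(1:2, net)
  sc <- netquery:::candidate_scores(seed2, net)
  expect_equal(net$node_ids[sc$node[1]], "v1")  # ranked first by P2
  expect_true(all(diff(sc$p2) <= 1e-15))

  # K screening: the best-conductance node outside the top K is ignored
  # frontier: a (high P2, poor conductance), b likewise, c (low P2 but
  # would close a clique). With K = 2, c is never considered.
  k4 <- base::t(utils::combn(1:4, 2))
  edges <- data.frame(
    a = paste0("n", c(k4[, 1], 1, 2, 1, 2, 5, 5)),
    b = paste0("n", c(k4[, 2], 5, 5, 6, 7, 8, 9))
  )
  net3 <- network_from_edges(edges)
  seed3 <- new_seed_state(1:4, net3)
  sc3 <- netquery:::candidate_scores(seed3, net3)
  expect_gt(nrow(sc3), 2)
  third <- sc3$node[3]
  win <- netquery:::best_candidate(seed3, net3, K = 2)
  expect_false(win$node == third)
  phi3 <- conductance(net3, c(seed3$nodes, third))
  expect_true(all(phi3 <= win$conductance_after + 1e-12) ||
                win$node %in% sc3$node[1:2])
})

test_that("extend applies size, conductance-drop and frontier stop rules", {
  t <- two_k4_bridge()
  seed <- new_seed_state(1:3, t)

  # already at max size: unchanged
  same <- extend(seed, t, max_size = 3)
  expect_equal(same$nodes, seed$nodes)
  expect_equal(attr(same, "stop_reason"), "max_size")

  # growth completes the K4 then stops: crossing the bridge raises phi
  grown <- extend(seed, t, max_size = 8)
  expect_equal(grown$nodes, 1:4)
  expect_equal(attr(grown, "stop_reason"), "conductance")

  # every accepted step strictly decreases conductance by >= 10%
  h <- grown$history
  expect_true(all(h$conductance_after <= 0.9 * h$conductance_before + 1e-12))
  # monotone growth, deterministic traces
  grown2 <- extend(new_seed_state(1:3, t), t, max_size = 8)
  expect_identical(grown$history, grown2$history)
})
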