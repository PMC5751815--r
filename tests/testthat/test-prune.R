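test_that("the induced neighborhood keeps only seed-touching edges", {
  # star seed {center} with 3 target neighbors -> K1,3
  star <- network_from_edges(data.frame(a = rep("c0", 3), b = paste0("l", 1:3)))
  seed <- new_seed_state(1, star)
  gi <- induce_neighborhood(seed, star)
  expect_equal(n_nodes(gi), 4)
  expect_equal(n_edges(gi), 3)

  # two frontier nodes connected to each other: their mutual edge excluded
  net <- network_from_edges(data.frame(
    a = c("s1", "s2", "s1", "s2", "f1"),
    b = c("s2", "f1", "f2", "f2", "f2")
  ))
  seed2 <- new_seed_state(1:2, net)
  gi2 <- induce_neighborhood(seed2, net)
  tab <- as_tibble(gi2)
  expect_false(any(tab$from == "f1" & tab$to == "f2" |
                     tab$from == "f2" & tab$to == "f1"))
  expect_equal(n_edges(gi2), 4)  # 1 seed edge + 3 seed-to-frontier edges

  # seed with no frontier: the induced network is the seed itself
  iso <- network_from_edges(data.frame(a = "a", b = "b"))
  seed3 <- new_seed_state(1:2, iso)
  gi3 <- induce_neighborhood(seed3, iso)
  expect_equal(gi3$node_ids, c("a", "b"))
})

test_that("personalized PageRank solves its fixed point", {
  # alpha = 1 returns the preference vector exactly
  net <- path4()
  seed <- new_seed_state(1:2, net)
  gi <- induce_neighborhood(seed, net)
  r1 <- personalized_pagerank(gi, alpha = 1)
  expect_equal(as.numeric(r1$r), r1$s)

  # 2-node graph (1 seed, 1 neighbor, 1 edge), alpha = 0.5: r = (2/3, 1/3)
  two <- network_from_edges(data.frame(a = "s", b = "f"))
  seed2 <- new_seed_state(1, two)
  gi2 <- induce_neighborhood(seed2, two)
  r2 <- personalized_pagerank(gi2, alpha = 0.5)
  expect_equal(as.numeric(r2$r), c(2 / 3, 1 / 3), tolerance = 1e-12)

  # vertex-transitive graph with all-node preference: uniform solution
  tri <- triangle()
  gi3 <- tri
  attr(gi3, "seed_local") <- 1:3
  r3 <- personalized_pagerank(gi3, alpha = 0.5)
  expect_equal(as.numeric(r3$r), rep(1 / 3, 3), tolerance = 1e-12)

  # residual bound and normalization hold on every solve
  expect_lte(r2$residual, 10 * 1e-12)
  expect_equal(sum(r2$r), 1, tolerance = 1e-12)
})

test_that("direct and iterative PageRank solvers agree", {
  set.seed(41)
  for (k in 1:10) {
    fx <- random_integrated_walk(nq = 4, nt = sample(8:14, 1))
    w <- fx$walk
    C <- correspondence(w, stationary_distribution(w))
    seed <- induce_seed(match_seed(C), fx$target, C)
    gi <- induce_neighborhood(seed, fx$target)
    rd <- personalized_pagerank(gi, method = "direct")
    ri <- personalized_pagerank(gi, method = "iterative", tol = 1e-14)
    expect_lt(max(abs(rd$r - ri$r)), 1e-10)
  }
})

test_that("mass pruning keeps the minimal crossing prefix, then the largest component", {
  net <- network_from_edges(data.frame(
    a = c("a", "b"), b = c("b", "c")))
  attr(net, "seed_local") <- 1:3

  fake_ppr <- function(r, gi) {
    structure(list(r = stats::setNames(r, gi$node_ids), alpha = 0.5,
                   s = rep(1 / 3, 3), M = NULL), class = "netquery_ppr")
  }

  # r = (0.6, 0.3, 0.1): the first node alone crosses 0.5
  pr <- prune_by_mass(fake_ppr(c(0.6, 0.3, 0.1), net), net, seed_local = 1:3)
  expect_equal(net$node_ids[pr$kept_local], "a")

  # r sorted (0.4, 0.3, 0.3): two nodes needed to reach 0.5
  pr2 <- prune_by_mass(fake_ppr(c(0.3, 0.3, 0.4), net), net, seed_local = 1:3)
  expect_equal(length(pr2$prefix_local), 2)
  expect_true(match("c", net$node_ids) %in% pr2$prefix_local)

  # the kept prefix is the unique minimal one under the stated order
  rank <- pr2$ranking
  expect_true(all(diff(rank$cumulative) > 0))
  expect_lt(rank$cumulative[1], 0.5)
  expect_gte(rank$cumulative[2], 0.5)

  # disconnected kept set: the larger component wins
  net2 <- network_from_edges(data.frame(
    a = c("a", "b", "d"), b = c("b", "c", "e")))
  pr3 <- prune_by_mass(
    structure(list(r = stats::setNames(rep(0.2, 5), net2$node_ids)),
              class = "netquery_ppr"),
    net2, seed_local = seq_len(5), mass = 0.8)
  expect_equal(sort(net2$node_ids[pr3$kept_local]), c("a", "b", "c"))

  # ties in r: seed members outrank non-seed members
  pr4 <- prune_by_mass(fake_ppr(c(0.25, 0.5, 0.25), net), net, seed_local = 3)
  expect_equal(pr4$ranking$node[1:2], c("b", "c"))
})

test_that("pruning can recruit a neighbor and drop a seed node", {
  # seed = 8-cycle h1..h8; the hub neighbor n touches h1..h7 and collects
  # more PageRank than any single seed node, while h8 leaks its mass into
  # dangling leaves: n enters the final result and h8 leaves it.
  net <- recruitment_fixture()
  seed <- new_seed_state(match(paste0("h", 1:8), net$node_ids), net)
  gi <- induce_neighborhood(seed, net)
  ppr <- personalized_pagerank(gi, alpha = 0.5)
  expect_gt(ppr$r[["n"]], max(ppr$r[paste0("h", 1:8)]))
  pruned <- prune_by_mass(ppr, gi, mass = 0.5)
  kept <- gi$node_ids[pruned$kept_local]
  expect_true("n" %in% kept)        # recruited: never in the seed
  expect_false("h8" %in% kept)      # a seed node is dropped
  # final result is connected and non-empty
  comps <- netquery:::node_set_components(gi, pruned$kept_local)
  expect_equal(length(comps), 1)
  expect_gt(length(kept), 0)
})
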