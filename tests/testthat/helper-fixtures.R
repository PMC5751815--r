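# Small hand-built fixtures shared across test files.

# Path graph a-b-c-d as a network.
path4 <- function() {
  network_from_edges(data.frame(a = c("a", "b", "c"), b = c("b", "c", "d")))
}

# Triangle graph.
triangle <- function(ids = c("a", "b", "c")) {
  network_from_edges(data.frame(a = ids[c(1, 2, 3)], b = ids[c(2, 3, 1)]))
}

# Two K4 cliques joined by a single bridge edge (nodes 1-4 and 5-8).
two_k4_bridge <- function() {
  k4 <- t(combn(1:4, 2))
  edges <- rbind(k4, k4 + 4, c(4, 5))
  network_from_edges(data.frame(a = paste0("n", edges[, 1]),
                                b = paste0("n", edges[, 2])))
}

# Write lines to a temp file and return its path.
tmp_lines <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# A tiny query/target/similarity triple where homologs are unambiguous:
# the query triangle q1-q2-q3 maps onto the target triangle t1-t2-t3
# hanging off a path t4-t5.
tiny_triple <- function() {
  q <- triangle(c("q1", "q2", "q3"))
  t <- network_from_edges(data.frame(
    a = c("t1", "t2", "t3", "t3", "t4"),
    b = c("t2", "t3", "t1", "t4", "t5")
  ))
  sim <- similarity_from_scores(
    data.frame(q = c("q1", "q2", "q3"), t = c("t1", "t2", "t3"),
               s = c(10, 10, 10)),
    q, t, s_t = 0
  )
  list(query = q, target = t, sim = sim)
}

# Seed cycle h1..h8 with a hub neighbor n (adjacent to h1..h7) and a seed
# node h8 burdened with dangling leaves: under personalized PageRank at
# alpha = 0.5 the hub out-ranks every seed node.
recruitment_fixture <- function() {
  h <- paste0("h", 1:8)
  network_from_edges(data.frame(
    a = c(h, rep("n", 7), rep("h8", 6)),
    b = c(h[c(2:8, 1)], h[1:7], paste0("x", 1:6))
  ))
}
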