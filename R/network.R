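#' @importFrom Matrix sparseMatrix Diagonal rowSums colSums
#' @importFrom rlang abort warn inform .data
#' @importFrom tibble tibble as_tibble
NULL

#' Construct an undirected network from an edge table
#'
#' Builds a simple undirected graph (no self-loops, no duplicate edges) from
#' a two-column table of interactions. Node indexing is deterministic: nodes
#' are numbered in order of first appearance while scanning the edge rows
#' left-to-right, so the same table always yields the same internal indices.
#'
#' @param edges A data frame whose first two columns hold the endpoint
#'   identifiers of each undirected edge (coerced to character).
#' @param nodes Optional character vector of node identifiers. Nodes listed
#'   here but absent from `edges` are kept as isolated nodes; identifiers are
#'   appended after the edge-derived ones, preserving their own order.
#' @return An object of class `netquery_network` with elements `node_ids`
#'   (character), `edges` (integer matrix, one row per undirected edge with
#'   column 1 < column 2, sorted), and `adj` (sparse symmetric 0/1 adjacency).
#' @examples
#' net <- network_from_edges(data.frame(a = c("a", "b"), b = c("b", "c")))
#' network_degree(net)
#' @export
network_from_edges <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2) {
    abort("`edges` must have at least two columns (the edge endpoints).")
  }
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  if (anyNA(a) || anyNA(b)) abort("Edge endpoints must not be missing.")
  # first-appearance order, interleaving the two endpoints of each row
  node_ids <- unique(as.vector(rbind(a, b)))
  if (!is.null(nodes)) node_ids <- unique(c(node_ids, as.character(nodes)))
  ia <- match(a, node_ids)
  ib <- match(b, node_ids)
  self <- ia == ib
  if (any(self)) {
    warn(sprintf("Dropped %d self-loop(s).", sum(self)))
    ia <- ia[!self]
    ib <- ib[!self]
  }
  lo <- pmin(ia, ib)
  hi <- pmax(ia, ib)
  keep <- !duplicated(cbind(lo, hi))
  em <- cbind(lo[keep], hi[keep])
  if (nrow(em)) em <- em[order(em[, 1], em[, 2]), , drop = FALSE]
  storage.mode(em) <- "integer"
  colnames(em) <- c("i", "j")
  new_network(node_ids, em)
}

new_network <- function(node_ids, edge_mat) {
  n <- length(node_ids)
  if (n == 0L) abort("Network has no nodes.")
  if (nrow(edge_mat)) {
    adj <- sparseMatrix(
      i = c(edge_mat[, 1], edge_mat[, 2]),
      j = c(edge_mat[, 2], edge_mat[, 1]),
      x = 1, dims = c(n, n)
    )
  } else {
    adj <- sparseMatrix(i = integer(), j = integer(), x = numeric(), dims = c(n, n))
  }
  structure(
    list(node_ids = node_ids, edges = edge_mat, adj = adj),
    class = "netquery_network"
  )
}

#' Read an undirected network from a TSV edge list
#'
#' Each non-comment row must contain at least two whitespace- or
#' tab-separated tokens, the two endpoint identifiers; extra tokens (e.g. a
#' weight column) are ignored. Lines starting with `#` and blank lines are
#' skipped. Node identity is the literal string token: no case folding, no
#' identifier mapping.
#'
#' @param path Path to the edge-list file.
#' @param header If `TRUE`, the first non-comment row is discarded.
#' @param nodes_path Optional path to a sidecar file with one node identifier
#'   per line; used to declare isolated nodes.
#' @return A [network_from_edges()] object.
#' @export
read_network <- function(path, header = FALSE, nodes_path = NULL) {
  rows <- read_token_rows(path, min_tokens = 2, header = header)
  if (length(rows$tokens) == 0L) abort(sprintf("No edges found in '%s'.", path))
  a <- vapply(rows$tokens, `[[`, character(1), 1L)
  b <- vapply(rows$tokens, `[[`, character(1), 2L)
  nodes <- NULL
  if (!is.null(nodes_path)) {
    nodes <- readLines(nodes_path, warn = FALSE)
    nodes <- trimws(nodes)
    nodes <- nodes[nzchar(nodes) & !startsWith(nodes, "#")]
  }
  network_from_edges(data.frame(a = a, b = b), nodes = nodes)
}

# Shared tolerant line parser: skips '#' comments and blank lines, splits on
# runs of whitespace, and reports the 1-based file line of any malformed row.
read_token_rows <- function(path, min_tokens, header = FALSE) {
  if (!file.exists(path)) abort(sprintf("File not found: '%s'.", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (header && length(keep)) keep <- keep[-1]
  tokens <- strsplit(trimws(lines[keep]), "[ \t]+")
  bad <- which(lengths(tokens) < min_tokens)
  if (length(bad)) {
    abort(sprintf(
      "Malformed row at line %d of '%s': expected >= %d fields, got %d.",
      keep[bad[1]], path, min_tokens, lengths(tokens)[bad[1]]
    ))
  }
  list(tokens = tokens, lines = keep)
}

#' @export
print.netquery_network <- function(x, ...) {
  cat(sprintf(
    "<netquery_network> %d nodes, %d undirected edges\n",
    length(x$node_ids), nrow(x$edges)
  ))
  invisible(x)
}

#' Node degrees of a network
#'
#' @param net A `netquery_network`.
#' @return Named integer vector of degrees, in node-index order.
#' @export
network_degree <- function(net) {
  d <- as.integer(rowSums(net$adj))
  names(d) <- net$node_ids
  d
}

#' Number of nodes / undirected edges
#' @param net A `netquery_network`.
#' @export
n_nodes <- function(net) length(net$node_ids)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

#' Edge table of a network
#'
#' @param x A `netquery_network`.
#' @param ... Unused.
#' @return A tibble with columns `from` and `to` (node identifiers).
#' @export
as_tibble.netquery_network <- function(x, ...) {
  tibble(
    from = x$node_ids[x$edges[, 1]],
    to = x$node_ids[x$edges[, 2]]
  )
}

#' Convert to an igraph graph
#' @param net A `netquery_network`.
#' @return An undirected `igraph` graph with vertex names set to node ids.
#' @export
as_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = n_nodes(net), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = net$node_ids)
  if (nrow(net$edges)) g <- igraph::add_edges(g, t(net$edges))
  g
}

# Induced subnetwork on a set of node indices; node ids are preserved and
# re-indexed in ascending original-index order. Returns the subnetwork plus
# the original indices of its nodes.
induced_subnetwork <- function(net, idx) {
  idx <- sort(unique(as.integer(idx)))
  sub_adj <- net$adj[idx, idx, drop = FALSE]
  em <- Matrix::which(sub_adj != 0, arr.ind = TRUE)
  em <- em[em[, 1] < em[, 2], , drop = FALSE]
  if (nrow(em)) em <- em[order(em[, 1], em[, 2]), , drop = FALSE]
  storage.mode(em) <- "integer"
  colnames(em) <- c("i", "j")
  sub <- new_network(net$node_ids[idx], em)
  attr(sub, "parent_index") <- idx
  sub
}

# Connected components over a set of node indices of `net` (induced
# subgraph), returned as a list of integer vectors of original indices.
node_set_components <- function(net, idx) {
  idx <- sort(unique(as.integer(idx)))
  if (!length(idx)) return(list())
  sub <- net$adj[idx, idx, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)
  lapply(seq_len(comp$no), function(k) idx[comp$membership == k])
}

# Neighbors (in `net`) of a set of node indices, excluding the set itself.
node_set_frontier <- function(net, idx) {
  if (!length(idx)) return(integer())
  nb <- Matrix::which(rowSums(net$adj[, idx, drop = FALSE]) > 0)
  setdiff(as.integer(nb), as.integer(idx))
}
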