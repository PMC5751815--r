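#' Generate a planted-module benchmark instance
#'
#' Builds a fully self-contained test case for the querying pipeline: a
#' connected query module; a target network containing a perturbed copy of
#' it (node/edge deletions, inserted nodes) embedded in a random background
#' with sparse attachment edges; and a similarity table with high scores for
#' the surviving query-to-copy pairs and low positive noise scores scattered
#' over random non-homolog pairs. The perturbation emulates the
#' insertion/deletion structure of conserved modules across species, where
#' an insertion in one network is a deletion seen from the other.
#'
#' @param query_size Number of query nodes (connected modules of 4-25 nodes
#'   are the intended regime).
#' @param target_size Total target nodes (planted module plus background).
#' @param background `"er"` (Erdos-Renyi) or `"ba"` (Barabasi-Albert): two
#'   standard nulls with very different degree structure.
#' @param er_p Edge probability of the ER background.
#' @param ba_m Edges attached per new node in the BA background.
#' @param node_delete_rate Probability that a query node is absent from the
#'   planted copy.
#' @param edge_delete_rate Probability that a surviving copied edge is
#'   dropped.
#' @param node_insert_count Extra target-side nodes wired into the planted
#'   module.
#' @param homolog_score_mean Mean similarity score of true homolog pairs.
#' @param noise_score_rate Fraction of random non-homolog query-target pairs
#'   that receive a noise score.
#' @param noise_score_mean Mean of the (exponential) noise scores; the
#'   default keeps homolog scores ten times the noise level.
#' @param attach_prob Probability that each planted-module node gains one
#'   edge to a random background node (at least one attachment is forced).
#' @param seed RNG seed; the whole instance is drawn from a single stream,
#'   so equal seeds reproduce the instance exactly.
#' @return A `netquery_instance`: `query`, `target` (networks), `similarity`
#'   (threshold 0), `truth_map` (tibble `query_id` -> `target_id` for
#'   surviving nodes), `planted_nodes` (target ids of the planted module,
#'   inserted nodes included), `params`, `seed`.
#' @export
generate_planted_instance <- function(query_size = 8, target_size = 300,
                                      background = c("er", "ba"), er_p = 0.02,
                                      ba_m = 2, node_delete_rate = 0,
                                      edge_delete_rate = 0,
                                      node_insert_count = 0,
                                      homolog_score_mean = 50,
                                      noise_score_rate = 0.05,
                                      noise_score_mean = homolog_score_mean / 10,
                                      attach_prob = 0.3, seed = NULL) {
  background <- match.arg(background)
  stopifnot(query_size >= 2, target_size > query_size + node_insert_count,
            node_delete_rate >= 0, node_delete_rate <= 1,
            edge_delete_rate >= 0, edge_delete_rate <= 1,
            noise_score_rate >= 0, noise_score_rate <= 1,
            homolog_score_mean > 0)
  if (!is.null(seed)) set.seed(seed)

  # 1. connected query module (ER, resampled until connected)
  p_query <- min(0.9, max(0.35, 2 * log(query_size) / query_size))
  gq <- resample_until(
    function() igraph::sample_gnp(query_size, p_query),
    igraph::is_connected, "a connected query module"
  )
  query_ids <- sprintf("q%02d", seq_len(query_size))
  qe <- igraph::as_edgelist(gq, names = FALSE)
  query <- network_from_edges(
    data.frame(a = query_ids[qe[, 1]], b = query_ids[qe[, 2]]),
    nodes = query_ids
  )

  # 2. perturbed planted copy: delete nodes/edges, insert nodes, keep it
  #    connected (bounded resampling)
  module <- resample_until(
    function() perturb_module(qe, query_size, node_delete_rate,
                              edge_delete_rate, node_insert_count),
    function(m) length(m$kept) >= 2 && module_connected(m),
    "a connected planted module"
  )
  n_module <- length(module$kept) + node_insert_count
  n_bg <- target_size - n_module

  # 3. background graph plus sparse attachment edges
  bg <- switch(background,
    er = igraph::sample_gnp(n_bg, er_p),
    ba = igraph::sample_pa(n_bg, m = ba_m, directed = FALSE)
  )
  be <- igraph::as_edgelist(bg, names = FALSE)

  # assign target indices: module nodes scattered among the background
  perm <- sample.int(target_size)
  module_pos <- perm[seq_len(n_module)]           # copy nodes then inserted
  bg_pos <- perm[n_module + seq_len(n_bg)]
  target_ids <- sprintf("t%04d", seq_len(target_size))

  copy_pos <- module_pos[seq_along(module$kept)]  # aligned with module$kept
  ins_pos <- module_pos[length(module$kept) + seq_len(node_insert_count)]
  loc <- integer(query_size)                      # query index -> target pos
  loc[module$kept] <- copy_pos

  edges <- rbind(
    cbind(loc[module$edges[, 1]], loc[module$edges[, 2]]),
    if (length(ins_pos)) cbind(ins_pos[module$insert_edges[, 1]],
                               copy_pos[module$insert_edges[, 2]]),
    if (nrow(be)) cbind(bg_pos[be[, 1]], bg_pos[be[, 2]])
  )
  attach_from <- module_pos[stats::runif(n_module) < attach_prob]
  if (!length(attach_from)) attach_from <- module_pos[1]
  edges <- rbind(edges, cbind(attach_from,
                              sample(bg_pos, length(attach_from), replace = TRUE)))
  target <- network_from_edges(
    data.frame(a = target_ids[edges[, 1]], b = target_ids[edges[, 2]]),
    nodes = target_ids
  )

  # 4. similarity: high truth scores, scattered low noise scores
  truth <- tibble(
    query_id = query_ids[module$kept],
    target_id = target_ids[copy_pos],
    score = abs(stats::rnorm(length(module$kept), homolog_score_mean,
                             0.1 * homolog_score_mean))
  )
  n_noise <- round(noise_score_rate * query_size * target_size)
  noise <- tibble(query_id = character(), target_id = character(),
                  score = numeric())
  if (n_noise > 0) {
    pair_idx <- sample.int(query_size * target_size, n_noise)
    qi <- ((pair_idx - 1) %% query_size) + 1
    ti <- ((pair_idx - 1) %/% query_size) + 1
    is_truth <- loc[qi] == ti & qi %in% module$kept
    noise <- tibble(
      query_id = query_ids[qi[!is_truth]],
      target_id = target_ids[ti[!is_truth]],
      score = stats::rexp(sum(!is_truth), rate = 1 / noise_score_mean)
    )
  }
  sim <- similarity_from_scores(dplyr::bind_rows(truth, noise),
                                query, target, s_t = 0)

  structure(
    list(
      query = query, target = target, similarity = sim,
      truth_map = truth[, c("query_id", "target_id")],
      planted_nodes = sort(c(target_ids[copy_pos], target_ids[ins_pos])),
      params = list(
        query_size = query_size, target_size = target_size,
        background = background, er_p = er_p, ba_m = ba_m,
        node_delete_rate = node_delete_rate,
        edge_delete_rate = edge_delete_rate,
        node_insert_count = node_insert_count,
        homolog_score_mean = homolog_score_mean,
        noise_score_rate = noise_score_rate,
        noise_score_mean = noise_score_mean, attach_prob = attach_prob
      ),
      seed = seed
    ),
    class = "netquery_instance"
  )
}

# Apply node/edge deletions and node insertions to a copied module.
# Returns kept query indices, surviving edges (query-index pairs), and
# insertion edges as (inserted-node ordinal, position within kept).
perturb_module <- function(qe, query_size, node_delete_rate,
                           edge_delete_rate, node_insert_count) {
  kept <- which(stats::runif(query_size) >= node_delete_rate)
  ek <- qe[qe[, 1] %in% kept & qe[, 2] %in% kept, , drop = FALSE]
  ek <- ek[stats::runif(nrow(ek)) >= edge_delete_rate, , drop = FALSE]
  insert_edges <- NULL
  if (node_insert_count > 0 && length(kept) >= 1) {
    insert_edges <- do.call(rbind, lapply(seq_len(node_insert_count), function(k) {
      deg <- min(length(kept), 1 + stats::rbinom(1, 2, 0.5))
      cbind(k, sample(seq_along(kept), deg))
    }))
  }
  list(kept = kept, edges = ek, insert_edges = insert_edges)
}

module_connected <- function(m) {
  n_ins <- if (is.null(m$insert_edges)) 0L else max(m$insert_edges[, 1])
  n <- length(m$kept) + n_ins
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(m$edges)) {
    g <- igraph::add_edges(g, t(cbind(match(m$edges[, 1], m$kept),
                                      match(m$edges[, 2], m$kept))))
  }
  if (n_ins) {
    g <- igraph::add_edges(g, t(cbind(length(m$kept) + m$insert_edges[, 1],
                                      m$insert_edges[, 2])))
  }
  igraph::is_connected(g)
}

resample_until <- function(draw, ok, what, max_tries = 1000) {
  for (k in seq_len(max_tries)) {
    x <- draw()
    if (ok(x)) return(x)
  }
  abort(sprintf("Could not generate %s in %d attempts; the parameter combination is infeasible.",
                what, max_tries))
}

#' @export
print.netquery_instance <- function(x, ...) {
  cat(sprintf(
    "<netquery_instance> query %d node(s); target %d node(s), %d edge(s); planted module %d node(s)\n",
    n_nodes(x$query), n_nodes(x$target), n_edges(x$target),
    length(x$planted_nodes)
  ))
  invisible(x)
}

#' Write a planted instance as pipeline input files
#'
#' Emits `<prefix>_query.tsv`, `<prefix>_target.tsv`, `<prefix>_sim.tsv`
#' (the formats [read_network()] and [read_similarity()] consume), plus
#' `<prefix>_truth.tsv` (the surviving homolog map) and
#' `<prefix>_planted.tsv` (the planted complex, one tab-separated line, as
#' [read_complexes()] reads).
#'
#' @param instance A `netquery_instance`.
#' @param out_prefix Output path prefix.
#' @export
write_instance <- function(instance, out_prefix) {
  readr::write_tsv(as_tibble(instance$query), paste0(out_prefix, "_query.tsv"),
                   col_names = FALSE)
  readr::write_tsv(as_tibble(instance$target), paste0(out_prefix, "_target.tsv"),
                   col_names = FALSE)
  readr::write_tsv(as_tibble(instance$similarity), paste0(out_prefix, "_sim.tsv"),
                   col_names = FALSE)
  readr::write_tsv(instance$truth_map, paste0(out_prefix, "_truth.tsv"))
  writeLines(paste(instance$planted_nodes, collapse = "\t"),
             paste0(out_prefix, "_planted.tsv"))
  invisible(out_prefix)
}
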