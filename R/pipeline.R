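#' Run the full network-querying pipeline
#'
#' Executes the four stages end to end: (1) steady-state-flow node
#' correspondence between query and target; (2) seed selection by
#' maximum-weight bipartite matching; (3) greedy extension by association
#' probability and conductance minimization; (4) personalized-PageRank
#' pruning of the induced neighborhood, returning the largest connected
#' piece. The pipeline is fully deterministic: the same inputs and
#' configuration always give the same result.
#'
#' @param query,target `netquery_network` objects.
#' @param sim A `netquery_similarity` built on the pair (its threshold `s_t`
#'   already applied).
#' @param config A [netquery_config()].
#' @return A `netquery_result` with fields `final_nodes`, `final_edges`
#'   (target-induced edge tibble), `seed_nodes`, `extended_nodes`,
#'   `correspondence_used` (tibble of matched pairs and their flow),
#'   `log` (ordered tibble of pipeline events), plus the extension history,
#'   PageRank ranking and the configuration.
#' @export
run_query <- function(query, target, sim, config = netquery_config()) {
  say <- function(...) if (config$verbose) inform(sprintf(...))
  log <- list()
  note <- function(stage, key, value) {
    log[[length(log) + 1]] <<- tibble(stage = stage, key = key,
                                      value = as.character(value))
  }
  note("input", "query_nodes", n_nodes(query))
  note("input", "query_edges", n_edges(query))
  note("input", "target_nodes", n_nodes(target))
  note("input", "target_edges", n_edges(target))
  note("input", "pseudo_edges", length(sim$S@x))

  say("Computing steady-state flow correspondence ...")
  walk <- integrated_walk(query, target, sim)
  pi <- stationary_distribution(walk, tol = config$power_tol,
                                max_iter = config$power_max_iter)
  C <- correspondence(walk, pi)
  note("correspondence", "power_iterations", pi$iterations)
  note("correspondence", "residual", format(pi$residual, digits = 3))
  note("correspondence", "scored_pairs", length(C$C@x))

  say("Selecting the seed by maximum-weight bipartite matching ...")
  matching <- match_seed(C)
  used <- tibble(
    query_id = query$node_ids[which(!is.na(matching))],
    target_id = target$node_ids[matching[!is.na(matching)]],
    flow = vapply(which(!is.na(matching)),
                  function(q) C$C[q, matching[q]], numeric(1))
  )
  seed <- induce_seed(matching, target, C)
  seed_ids <- target$node_ids[seed$nodes]
  note("seed", "matched_pairs", nrow(used))
  note("seed", "matching_weight", format(attr(matching, "weight"), digits = 6))
  note("seed", "seed_nodes", paste(seed_ids, collapse = ","))
  note("seed", "seed_conductance", format(seed$conductance, digits = 4))

  say("Extending the seed (K = %d, max size %d) ...", config$K,
      ceiling(config$max_size_factor * n_nodes(query)))
  max_size <- ceiling(config$max_size_factor * n_nodes(query))
  extended <- extend(seed, target, K = config$K, max_size = max_size,
                     min_rel_drop = config$min_rel_drop)
  extended_ids <- target$node_ids[extended$nodes]
  for (k in seq_len(nrow(extended$history))) {
    h <- extended$history[k, ]
    note("extend", sprintf("step_%02d", h$step),
         sprintf("added=%s p2=%.4g conductance=%.4g->%.4g (of %d candidates)",
                 h$node, h$p2, h$conductance_before, h$conductance_after,
                 h$n_candidates))
  }
  note("extend", "stop_reason", attr(extended, "stop_reason"))
  note("extend", "extended_nodes", paste(extended_ids, collapse = ","))

  say("Pruning by personalized PageRank (alpha = %g, mass %g) ...",
      config$alpha, config$mass)
  gi <- induce_neighborhood(extended, target)
  ppr <- personalized_pagerank(gi, alpha = config$alpha, tol = config$ppr_tol)
  pruned <- prune_by_mass(ppr, gi, mass = config$mass)
  parent <- attr(gi, "parent_index")
  final_idx <- parent[pruned$kept_local]
  final_ids <- target$node_ids[final_idx]
  final_net <- induced_subnetwork(target, final_idx)
  note("prune", "induced_nodes", n_nodes(gi))
  note("prune", "ppr_method", ppr$method)
  note("prune", "ppr_ranking",
       paste(sprintf("%s:%.4g", pruned$ranking$node, pruned$ranking$ppr),
             collapse = ","))
  note("prune", "kept_before_connectivity",
       paste(gi$node_ids[pruned$prefix_local], collapse = ","))
  note("prune", "final_nodes", paste(final_ids, collapse = ","))

  structure(
    list(
      final_nodes = final_ids,
      final_edges = as_tibble(final_net),
      seed_nodes = seed_ids,
      extended_nodes = extended_ids,
      correspondence_used = used,
      extension_history = extended$history,
      ppr_ranking = pruned$ranking,
      log = dplyr::bind_rows(log),
      config = config
    ),
    class = "netquery_result"
  )
}

#' @export
print.netquery_result <- function(x, ...) {
  cat(sprintf(
    "<netquery_result> %d final node(s), %d edge(s) (seed %d -> extended %d -> final %d)\n",
    length(x$final_nodes), nrow(x$final_edges),
    length(x$seed_nodes), length(x$extended_nodes), length(x$final_nodes)
  ))
  invisible(x)
}

#' Tidy / summarize a querying result
#'
#' `tidy()` returns one row per node that appeared at any pipeline stage,
#' with its role: `seed` (from the matching), `extended` (added during
#' extension), or `recruited` (entered only at the PageRank pruning step).
#' `glance()` gives a one-row run summary.
#'
#' @param x A `netquery_result`.
#' @param ... Unused.
#' @export
tidy.netquery_result <- function(x, ...) {
  nodes <- unique(c(x$seed_nodes, x$extended_nodes, x$final_nodes))
  tibble(
    node = nodes,
    role = dplyr::case_when(
      nodes %in% x$seed_nodes ~ "seed",
      nodes %in% x$extended_nodes ~ "extended",
      TRUE ~ "recruited"
    ),
    in_final = nodes %in% x$final_nodes
  ) |> dplyr::arrange(dplyr::desc(.data$in_final), .data$role, .data$node)
}

#' @rdname tidy.netquery_result
#' @export
glance.netquery_result <- function(x, ...) {
  tibble(
    n_seed = length(x$seed_nodes),
    n_extended = length(x$extended_nodes),
    n_final = length(x$final_nodes),
    n_final_edges = nrow(x$final_edges),
    n_extension_steps = nrow(x$extension_history),
    stop_reason = x$log$value[x$log$key == "stop_reason"][1],
    n_recruited = sum(!x$final_nodes %in% x$extended_nodes),
    matching_weight = as.numeric(x$log$value[x$log$key == "matching_weight"][1])
  )
}

#' Write a querying result to files
#'
#' Emits `<prefix>_nodes.tsv` (node, role, in_final), `<prefix>_edges.tsv`
#' (the target-induced edges of the final subnetwork), and
#' `<prefix>_log.tsv` (the machine-readable stage/key/value run log).
#' Outputs are bit-identical across runs with identical inputs.
#'
#' @param result A `netquery_result`.
#' @param out_prefix Path prefix for the three files.
#' @export
write_result <- function(result, out_prefix) {
  dir <- dirname(out_prefix)
  if (!dir.exists(dir)) abort(sprintf("Output directory '%s' does not exist.", dir))
  readr::write_tsv(tidy(result), paste0(out_prefix, "_nodes.tsv"))
  readr::write_tsv(result$final_edges, paste0(out_prefix, "_edges.tsv"))
  readr::write_tsv(result$log, paste0(out_prefix, "_log.tsv"))
  invisible(out_prefix)
}

#' Read back the node set of a written result
#'
#' @param path A `<prefix>_nodes.tsv` file written by [write_result()].
#' @param final_only Keep only nodes of the final subnetwork.
#' @return Character vector of node identifiers.
#' @export
read_result_nodes <- function(path, final_only = TRUE) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if (final_only) tab <- tab[tab$in_final, ]
  tab$node
}

#' Run the pipeline from files
#'
#' Reads the query network, target network and similarity table, runs
#' [run_query()], and (optionally) writes the result files. Input problems —
#' including a similarity table with no pseudo-edges above the threshold —
#' fail before any output file is created.
#'
#' @param query_path,target_path Edge-list TSV paths.
#' @param sim_path Similarity TSV path.
#' @param out_prefix Optional output prefix for [write_result()].
#' @param config A [netquery_config()]; its `s_t` is applied when loading
#'   the similarity table.
#' @return The `netquery_result`, invisibly when writing.
#' @export
run_query_files <- function(query_path, target_path, sim_path,
                            out_prefix = NULL, config = netquery_config()) {
  query <- read_network(query_path)
  target <- read_network(target_path)
  sim <- read_similarity(sim_path, query, target, s_t = config$s_t)
  result <- run_query(query, target, sim, config = config)
  if (!is.null(out_prefix)) {
    write_result(result, out_prefix)
    return(invisible(result))
  }
  result
}

#' Evaluate one or many written results against references
#'
#' Batch companion to [evaluate_result()]: takes result node files (as
#' written by [write_result()]), a complex file, and optional annotation and
#' per-term p-value tables, and returns one summary row per result. Metrics
#' whose inputs are missing come back `NA`.
#'
#' @param result_paths Character vector of `*_nodes.tsv` paths.
#' @param complexes_path Reference complex file (see [read_complexes()]).
#' @param annotations_path,roots_path Optional annotation TSV and its
#'   term-to-root sidecar.
#' @param pvalues_path Optional TSV with columns `result`, `term`, `p_value`
#'   (FDR-corrected), where `result` matches the file's base prefix.
#' @param m_t Match-score threshold for specific hits.
#' @return A tibble, one row per result file.
#' @export
run_eval <- function(result_paths, complexes_path, annotations_path = NULL,
                     roots_path = NULL, pvalues_path = NULL, m_t = 0.5) {
  cx <- read_complexes(complexes_path)
  ann <- if (!is.null(annotations_path)) {
    read_annotations(annotations_path, format = "tsv", roots_path = roots_path)
  }
  pv <- if (!is.null(pvalues_path)) {
    readr::read_tsv(pvalues_path, show_col_types = FALSE)
  }
  purrr::map_dfr(result_paths, function(p) {
    nodes <- read_result_nodes(p)
    tag <- sub("_nodes\\.tsv$", "", basename(p))
    tp <- if (!is.null(pv)) pv[pv$result == tag, c("term", "p_value")]
    rep <- evaluate_result(nodes, cx, ann = ann, term_pvalues = tp, m_t = m_t)
    dplyr::bind_cols(tibble(result = tag), glance(rep))
  })
}
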