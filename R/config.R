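#' Pipeline configuration
#'
#' Collects every tunable parameter of the querying pipeline with its
#' default. Defaults follow the published operating point of the method:
#' top `K = 20` extension candidates per step, teleportation `alpha = 0.5`,
#' pruning at cumulative PageRank mass `0.5`, a 10% minimum relative
#' conductance drop, and a match-score threshold `m_t = 0.5`; the similarity
#' threshold `s_t = 0` makes any strictly positive score a pseudo-edge, and
#' the size cap factor 1.5 bounds extension at `ceiling(1.5 * |V_Q|)` nodes.
#'
#' @param s_t Similarity threshold for pseudo-edges (strict).
#' @param K Extension candidates screened per step.
#' @param alpha PageRank teleportation constant.
#' @param mass Cumulative PageRank mass kept at pruning.
#' @param min_rel_drop Minimum relative conductance decrease per extension
#'   step.
#' @param max_size_factor Extension size cap as a multiple of the query size.
#' @param power_tol,power_max_iter Stationary-distribution power iteration
#'   controls.
#' @param ppr_tol PageRank solver tolerance.
#' @param m_t Match-score threshold for specific hits.
#' @param mt_comparator `">="` or `">"` at the `m_t` boundary.
#' @param verbose Emit progress messages.
#' @return A `netquery_config` (named list).
#' @export
netquery_config <- function(s_t = 0, K = 20, alpha = 0.5, mass = 0.5,
                            min_rel_drop = 0.10, max_size_factor = 1.5,
                            power_tol = 1e-10, power_max_iter = 10000,
                            ppr_tol = 1e-12, m_t = 0.5,
                            mt_comparator = ">=", verbose = FALSE) {
  cfg <- list(
    s_t = s_t, K = as.integer(K), alpha = alpha, mass = mass,
    min_rel_drop = min_rel_drop, max_size_factor = max_size_factor,
    power_tol = power_tol, power_max_iter = as.integer(power_max_iter),
    ppr_tol = ppr_tol, m_t = m_t, mt_comparator = mt_comparator,
    verbose = isTRUE(verbose)
  )
  stopifnot(cfg$alpha > 0, cfg$alpha <= 1, cfg$mass > 0, cfg$mass <= 1,
            cfg$K >= 1, cfg$mt_comparator %in% c(">=", ">"))
  structure(cfg, class = "netquery_config")
}

#' @export
print.netquery_config <- function(x, ...) {
  cat("<netquery_config>\n")
  for (nm in names(x)) cat(sprintf("  %-15s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read / write a configuration file
#'
#' The configuration round-trips losslessly through a YAML key-value file;
#' parameters absent from the file keep their defaults.
#'
#' @param path YAML file path.
#' @return For `read_config()`, a `netquery_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  merge_config(overrides = vals)
}

#' @rdname read_config
#' @param config A `netquery_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Merge configuration layers
#'
#' Resolves parameters with the precedence command-line flag > configuration
#' file > built-in default. Unknown parameter names are an error.
#'
#' @param file_values Named list read from a config file (or `NULL`).
#' @param overrides Named list of explicit overrides (e.g. parsed CLI flags),
#'   applied last.
#' @return A `netquery_config`.
#' @export
merge_config <- function(file_values = NULL, overrides = NULL) {
  cfg <- unclass(netquery_config())
  for (layer in list(file_values, overrides)) {
    if (is.null(layer)) next
    bad <- setdiff(names(layer), names(cfg))
    if (length(bad)) abort(sprintf("Unknown configuration parameter(s): %s.",
                                   paste(bad, collapse = ", ")))
    cfg[names(layer)] <- layer
  }
  do.call(netquery_config, cfg)
}
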