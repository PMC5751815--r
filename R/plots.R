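#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_tile
#'   geom_col labs scale_fill_gradient theme_minimal
NULL

#' Plot the extension trace of a querying result
#'
#' Conductance of the growing seed at each accepted extension step; a flat
#' or short trace means the matched seed was already a tight module.
#'
#' @param object A `netquery_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.netquery_result <- function(object, ...) {
  h <- object$extension_history
  trace <- tibble(
    step = c(0L, h$step),
    conductance = c(
      if (nrow(h)) h$conductance_before[1] else conductance_of_result(object),
      h$conductance_after
    )
  )
  ggplot(trace, aes(x = .data$step, y = .data$conductance)) +
    geom_line(color = "grey40") +
    geom_point(size = 2) +
    labs(
      x = "extension step", y = "seed conductance",
      title = "Seed extension trace",
      subtitle = sprintf("%d seed, %d extended, %d final node(s)",
                         length(object$seed_nodes),
                         length(object$extended_nodes),
                         length(object$final_nodes))
    ) +
    theme_minimal()
}

conductance_of_result <- function(object) {
  x <- object$log$value[object$log$key == "seed_conductance"]
  if (length(x)) as.numeric(x[1]) else NA_real_
}

#' Heatmap of a correspondence matrix
#'
#' Tile plot of the steady-state flow over scored query-target pairs;
#' intended for the small matrices of worked examples, not genome-scale
#' runs.
#'
#' @param object A `netquery_correspondence`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.netquery_correspondence <- function(object, ...) {
  tab <- tidy(object)
  ggplot(tab, aes(x = .data$target_id, y = .data$query_id, fill = .data$flow)) +
    geom_tile() +
    scale_fill_gradient(low = "grey95", high = "firebrick") +
    labs(x = "target node", y = "query node", fill = "flow",
         title = "Steady-state flow correspondence") +
    theme_minimal()
}

#' Bar chart of a personalized PageRank vector
#'
#' Nodes in rank order with the pruning mass threshold in view.
#'
#' @param object A `netquery_ppr`.
#' @param mass Cumulative-mass threshold to annotate (the pruning default).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.netquery_ppr <- function(object, mass = 0.5, ...) {
  r <- sort(object$r, decreasing = TRUE)
  tab <- tibble(
    node = factor(names(r), levels = names(r)),
    ppr = as.numeric(r),
    kept = cumsum(as.numeric(r)) - as.numeric(r) < mass
  )
  ggplot(tab, aes(x = .data$node, y = .data$ppr, fill = .data$kept)) +
    geom_col() +
    labs(x = NULL, y = "PageRank value", fill = sprintf("within %.0f%% mass", 100 * mass),
         title = "Personalized PageRank ranking") +
    theme_minimal()
}
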