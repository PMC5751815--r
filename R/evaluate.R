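#' Match score between two protein sets
#'
#' The Jaccard similarity index `|X intersect Y| / |X union Y|`, used to
#' compare a querying result with a reference complex.
#'
#' @param set_x,set_y Non-empty character vectors of member identifiers.
#' @return A number in `[0, 1]`.
#' @export
match_score <- function(set_x, set_y) {
  set_x <- unique(as.character(set_x))
  set_y <- unique(as.character(set_y))
  if (!length(set_x) || !length(set_y)) abort("match_score() requires two non-empty sets.")
  length(intersect(set_x, set_y)) / length(union(set_x, set_y))
}

#' Specific-hit classification against reference complexes
#'
#' Scores the result against every reference complex with [match_score()]
#' and flags a specific hit when the best score clears the threshold `m_t`.
#'
#' @param result_nodes Character vector: the querying result's node set.
#' @param complexes A `netquery_complexes` (see [read_complexes()]) or a
#'   named list of character vectors.
#' @param m_t Match-score threshold.
#' @param comparator `">="` (default) counts a best match exactly at `m_t`
#'   as a hit; `">"` requires strict excess.
#' @return A list: `is_specific_hit`, `best_complex`, `best_score`, and
#'   `match_scores` (tibble over all complexes, sorted by score).
#' @export
specific_hit <- function(result_nodes, complexes, m_t = 0.5,
                         comparator = c(">=", ">")) {
  comparator <- match.arg(comparator)
  cx <- if (inherits(complexes, "netquery_complexes")) complexes$complexes else complexes
  if (!length(cx)) abort("The reference complex set is empty.")
  if (is.null(names(cx))) names(cx) <- paste0("complex_", seq_along(cx))
  scores <- vapply(cx, function(members) match_score(result_nodes, members), numeric(1))
  tab <- tibble(complex = names(cx), match_score = unname(scores)) |>
    dplyr::arrange(dplyr::desc(.data$match_score), .data$complex)
  best <- tab$match_score[1]
  hit <- if (comparator == ">=") best >= m_t else best > m_t
  list(
    is_specific_hit = hit,
    best_complex = tab$complex[1],
    best_score = best,
    match_scores = tab
  )
}

#' Information content of an annotation term
#'
#' `IC(g) = -log2(|g| / |root(g)|)`: the rarer a term among the proteins of
#' its root ontology (biological process, cellular component or molecular
#' function), the more informative an enrichment in it.
#'
#' @param ann A `netquery_annotations` (see [read_annotations()]).
#' @param term A term identifier present in `ann`.
#' @return The information content in bits.
#' @export
information_content <- function(ann, term) {
  if (!term %in% names(ann$term_to_proteins)) {
    abort(sprintf("Term '%s' is not in the annotation table.", term))
  }
  g <- length(ann$term_to_proteins[[term]])
  root <- ann$term_to_root[[term]]
  root_n <- ann$root_sizes[[root]]
  if (is.null(root_n) || root_n <= 0) abort(sprintf("Root '%s' has no proteins.", root))
  -log2(g / root_n)
}

#' Keep only informative terms
#'
#' Filters the annotation table to terms whose information content strictly
#' exceeds `min_ic` (default 2 bits, i.e. annotation frequency below 1/4
#' within the root); a term exactly at the boundary is excluded.
#'
#' @param ann A `netquery_annotations`.
#' @param min_ic Information-content cutoff (strict).
#' @return The filtered `netquery_annotations`; root sizes are preserved.
#' @export
filter_informative_terms <- function(ann, min_ic = 2) {
  ic <- vapply(names(ann$term_to_proteins), function(tm) information_content(ann, tm),
               numeric(1))
  keep <- names(ic)[ic > min_ic]
  ann$term_to_proteins <- ann$term_to_proteins[keep]
  ann$term_to_root <- ann$term_to_root[keep]
  ann
}

#' Specificity of a querying result
#'
#' The fraction of result nodes annotated with the best-enriched term:
#' `|result intersect annotated| / |result|`. A low value signals many
#' irrelevant nodes even when the module itself was found.
#'
#' @param result_nodes Character vector: the querying result's node set.
#' @param annotated_nodes Character vector: proteins annotated with the term
#'   selected as best enriched (smallest corrected p-value).
#' @return A number in `[0, 1]`.
#' @export
specificity <- function(result_nodes, annotated_nodes) {
  result_nodes <- unique(as.character(result_nodes))
  if (!length(result_nodes)) abort("specificity() requires a non-empty result.")
  length(intersect(result_nodes, unique(as.character(annotated_nodes)))) /
    length(result_nodes)
}

#' Score a querying result against references and annotations
#'
#' Computes every metric the supplied inputs allow: match scores and the
#' specific-hit flag always; hit flags only when an externally computed
#' FDR-corrected enrichment p-value is supplied (the enrichment test itself
#' is an external tool's job); specificity only when annotations identify
#' the best term's protein set.
#'
#' @inheritParams specific_hit
#' @param ann Optional `netquery_annotations`.
#' @param term_pvalues Optional data frame with columns `term` and `p_value`
#'   (FDR-corrected) for terms tested on this result.
#' @param p_threshold Corrected-p cutoff for (meaningful) hits.
#' @param connected Is the result connected? Used for the meaningful-hit
#'   flag; results produced by [run_query()] always are.
#' @return A `netquery_report` list; see [tidy.netquery_report()].
#' @export
evaluate_result <- function(result_nodes, complexes, ann = NULL,
                            term_pvalues = NULL, m_t = 0.5,
                            comparator = c(">=", ">"), p_threshold = 0.01,
                            connected = TRUE) {
  comparator <- match.arg(comparator)
  sh <- specific_hit(result_nodes, complexes, m_t = m_t, comparator = comparator)
  best_term <- NA_character_
  best_p <- NA_real_
  is_hit <- NA
  is_meaningful_hit <- NA
  spec <- NA_real_
  if (!is.null(term_pvalues) && nrow(term_pvalues)) {
    tp <- as.data.frame(term_pvalues)
    ord <- order(tp$p_value, tp$term)
    best_term <- as.character(tp$term[ord[1]])
    best_p <- as.numeric(tp$p_value[ord[1]])
    is_hit <- best_p < p_threshold
    is_meaningful_hit <- is_hit && isTRUE(connected)
    if (!is.null(ann) && best_term %in% names(ann$term_to_proteins)) {
      spec <- specificity(result_nodes, ann$term_to_proteins[[best_term]])
    }
  }
  structure(
    list(
      n_result_nodes = length(unique(as.character(result_nodes))),
      match_scores = sh$match_scores,
      best_complex = sh$best_complex,
      best_match_score = sh$best_score,
      is_specific_hit = sh$is_specific_hit,
      m_t = m_t, comparator = comparator,
      best_term = best_term, best_p_value = best_p,
      is_hit = is_hit, is_meaningful_hit = is_meaningful_hit,
      specificity = spec
    ),
    class = "netquery_report"
  )
}

#' @export
print.netquery_report <- function(x, ...) {
  cat(sprintf(
    paste0("<netquery_report> %d node(s); best match %.3f vs '%s' (specific hit: %s)\n",
           "  hit: %s, meaningful hit: %s, specificity: %s\n"),
    x$n_result_nodes, x$best_match_score, x$best_complex, x$is_specific_hit,
    format(x$is_hit), format(x$is_meaningful_hit),
    ifelse(is.na(x$specificity), "unavailable", format(x$specificity, digits = 3))
  ))
  invisible(x)
}

#' Tidy / summarize a metric report
#'
#' `tidy()` returns the per-complex match-score table; `glance()` returns a
#' one-row summary with the headline metrics.
#'
#' @param x A `netquery_report`.
#' @param ... Unused.
#' @export
tidy.netquery_report <- function(x, ...) x$match_scores

#' @rdname tidy.netquery_report
#' @export
glance.netquery_report <- function(x, ...) {
  tibble(
    n_result_nodes = x$n_result_nodes,
    best_complex = x$best_complex,
    best_match_score = x$best_match_score,
    is_specific_hit = x$is_specific_hit,
    is_hit = x$is_hit,
    is_meaningful_hit = x$is_meaningful_hit,
    specificity = x$specificity,
    best_term = x$best_term,
    best_p_value = x$best_p_value
  )
}

#' Write a metric report as TSV and JSON
#'
#' @param report A `netquery_report`.
#' @param out_prefix Path prefix; writes `<prefix>_report.tsv` (one-row
#'   summary) and `<prefix>_report.json`.
#' @export
write_report <- function(report, out_prefix) {
  g <- glance(report)
  readr::write_tsv(g, paste0(out_prefix, "_report.tsv"))
  jsonlite::write_json(as.list(g), paste0(out_prefix, "_report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(out_prefix)
}

# ---- annotation and complex readers -----------------------------------------

#' Read a term-to-protein annotation table
#'
#' Two formats are supported. `"tsv"`: rows `(term, protein)` plus a
#' mandatory sidecar mapping each term to its root ontology (`BP`, `CC` or
#' `MF`). `"gaf"`: GAF 2.x tab-separated lines, using the DB object id
#' (column 2), GO id (column 5), evidence code (column 7) and aspect
#' (column 9, `P`/`F`/`C`); only rows with experimental evidence codes
#' (`EXP`, `IDA`, `IPI`, `IMP`, `IGI`, `IEP`) are retained.
#'
#' @param path Annotation file path.
#' @param format `"tsv"` or `"gaf"`.
#' @param roots_path For `"tsv"`: path to a two-column TSV `(term, root)`.
#' @return A `netquery_annotations`: `term_to_proteins` (named list of
#'   character vectors), `term_to_root` (named character), and `root_sizes`
#'   (distinct proteins per root).
#' @export
read_annotations <- function(path, format = c("tsv", "gaf"), roots_path = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    rows <- read_token_rows(path, min_tokens = 2)
    term <- vapply(rows$tokens, `[[`, character(1), 1L)
    protein <- vapply(rows$tokens, `[[`, character(1), 2L)
    if (is.null(roots_path)) {
      abort("TSV annotations need `roots_path` mapping each term to BP/CC/MF.")
    }
    rr <- read_token_rows(roots_path, min_tokens = 2)
    term_to_root <- stats::setNames(
      vapply(rr$tokens, `[[`, character(1), 2L),
      vapply(rr$tokens, `[[`, character(1), 1L)
    )
  } else {
    evidence_ok <- c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP")
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    fields <- fields[lengths(fields) >= 9]
    keep <- vapply(fields, function(f) f[[7]] %in% evidence_ok, logical(1))
    fields <- fields[keep]
    if (!length(fields)) abort("No annotation rows with experimental evidence codes.")
    protein <- vapply(fields, `[[`, character(1), 2L)
    term <- vapply(fields, `[[`, character(1), 5L)
    aspect <- vapply(fields, `[[`, character(1), 9L)
    root_of_aspect <- c(P = "BP", F = "MF", C = "CC")
    term_to_root <- tapply(unname(root_of_aspect[aspect]), term, function(x) x[1])
    term_to_root <- stats::setNames(as.character(term_to_root), names(term_to_root))
  }
  terms <- unique(term)
  missing_root <- setdiff(terms, names(term_to_root))
  if (length(missing_root)) {
    abort(sprintf("%d term(s) have no root assignment (e.g. '%s').",
                  length(missing_root), missing_root[1]))
  }
  term_to_proteins <- lapply(split(protein, term), function(p) sort(unique(p)))
  term_to_root <- term_to_root[names(term_to_proteins)]
  roots <- sort(unique(term_to_root))
  root_sizes <- vapply(roots, function(rt) {
    length(unique(unlist(term_to_proteins[term_to_root == rt], use.names = FALSE)))
  }, integer(1))
  structure(
    list(term_to_proteins = term_to_proteins,
         term_to_root = term_to_root,
         root_sizes = as.list(root_sizes)),
    class = "netquery_annotations"
  )
}

#' @export
print.netquery_annotations <- function(x, ...) {
  cat(sprintf("<netquery_annotations> %d term(s), roots: %s\n",
              length(x$term_to_proteins),
              paste(sprintf("%s=%d", names(x$root_sizes), unlist(x$root_sizes)),
                    collapse = ", ")))
  invisible(x)
}

#' Read a reference complex set
#'
#' One complex per line, tab-separated member identifiers; blank lines and
#' `#` comments are skipped.
#'
#' @param path File path.
#' @param named If `TRUE`, the first token of each line is the complex name;
#'   otherwise complexes are auto-named `complex_1`, `complex_2`, ...
#' @return A `netquery_complexes`: named list of member-id vectors.
#' @export
read_complexes <- function(path, named = FALSE) {
  rows <- read_token_rows(path, min_tokens = if (named) 2 else 1)
  cx <- lapply(rows$tokens, function(tk) {
    if (named) tk[-1] else tk
  })
  names(cx) <- if (named) {
    vapply(rows$tokens, `[[`, character(1), 1L)
  } else {
    paste0("complex_", seq_along(cx))
  }
  empty <- !lengths(cx)
  if (any(empty)) abort("Every complex must have at least one member.")
  structure(list(complexes = cx), class = "netquery_complexes")
}

#' @export
print.netquery_complexes <- function(x, ...) {
  cat(sprintf("<netquery_complexes> %d complex(es), sizes %s\n",
              length(x$complexes),
              paste(range(lengths(x$complexes)), collapse = "-")))
  invisible(x)
}
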