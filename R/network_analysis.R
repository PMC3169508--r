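#' Pathway-level interaction network
#'
#' Draws a directed edge between an ordered pathway pair whenever its
#' empirical p-value falls strictly below the significance threshold; nodes
#' are the pathways carrying at least one such edge. Node annotation
#' includes in/out degree, normalized betweenness and, when an enrichment
#' table is supplied, a flag for pathways enriched at p < 0.05.
#'
#' @param pairs Pair table from [run_all_pairs()] (or a `crosstalk_result`).
#' @param enrich Optional enrichment table from [gene_set_enrichment()].
#' @param p_threshold Edge significance threshold (strict `<`). Default
#'   0.001, reachable with the pooled two-stage permutations.
#' @param enrich_threshold Enrichment flag threshold. Default 0.05.
#' @return A `pathway_network`: list with `nodes` (tibble: `pathway_id`,
#'   `in_degree`, `out_degree`, `betweenness_normalized`, `enriched`),
#'   `edges` (tibble: `source_pathway`, `target_pathway`, `score`,
#'   `n_paths`, `p_value`) and `graph` (directed igraph).
#' @export
build_pathway_network <- function(pairs, enrich = NULL, p_threshold = 0.001,
                                  enrich_threshold = 0.05) {
  if (inherits(pairs, "crosstalk_result")) pairs <- pairs$pairs
  stopifnot(p_threshold > 0, p_threshold < 1)
  edges <- pairs[!is.na(pairs$p_value) & pairs$p_value < p_threshold &
                   pairs$score > 0, , drop = FALSE]
  edges <- dplyr::select(edges, "source_pathway", "target_pathway",
                         "score", "n_paths", "p_value")
  node_ids <- sort(unique(c(edges$source_pathway, edges$target_pathway)))
  g <- igraph::graph_from_data_frame(
    edges[, c("source_pathway", "target_pathway")],
    directed = TRUE, vertices = node_ids
  )
  if (igraph::ecount(g) > 0) {
    igraph::E(g)$score <- edges$score
    igraph::E(g)$p_value <- edges$p_value
    igraph::E(g)$kind <- "crosstalk"
  }
  nodes <- centrality_table(g)
  nodes$enriched <- if (!is.null(enrich)) {
    e <- enrich[match(nodes$pathway_id, enrich$pathway_id), , drop = FALSE]
    !is.na(e$p) & e$p < enrich_threshold
  } else {
    NA
  }
  igraph::V(g)$enriched <- nodes$enriched
  igraph::V(g)$kind <- "pathway"
  structure(list(nodes = nodes, edges = tibble::as_tibble(edges), graph = g),
            class = "pathway_network")
}

#' @export
print.pathway_network <- function(x, ...) {
  cat("Pathway interaction network:", nrow(x$nodes), "pathways,",
      nrow(x$edges), "directed edges\n")
  invisible(x)
}

centrality_table <- function(g) {
  n <- igraph::vcount(g)
  btw <- if (n >= 3) {
    # normalized by the (n-1)(n-2) ordered node pairs excluding the node
    igraph::betweenness(g, directed = TRUE, weights = NA) / ((n - 1) * (n - 2))
  } else {
    rep(0, n)
  }
  tibble::tibble(
    pathway_id = igraph::V(g)$name,
    in_degree = as.integer(igraph::degree(g, mode = "in")),
    out_degree = as.integer(igraph::degree(g, mode = "out")),
    betweenness_normalized = as.numeric(btw)
  )
}

#' Degree and normalized betweenness of a pathway network
#'
#' Betweenness is computed on the directed graph and normalized by the
#' maximum possible centrality — the number of ordered node pairs excluding
#' the focal node, (n-1)(n-2) — so a node lying on every shortest path
#' between every other ordered pair scores 1.
#'
#' @param net A `pathway_network` from [build_pathway_network()] (or a bare
#'   igraph).
#' @param directed Compute betweenness on the directed graph (default TRUE);
#'   set FALSE for the undirected variant.
#' @return A tibble with `pathway_id`, `in_degree`, `out_degree`,
#'   `betweenness_normalized`.
#' @export
centrality_stats <- function(net, directed = TRUE) {
  g <- if (inherits(net, "pathway_network")) net$graph else net
  stopifnot(igraph::is_igraph(g), igraph::vcount(g) > 0)
  if (!directed) g <- igraph::as_undirected(g, mode = "collapse")
  centrality_table(g)
}

#' Detailed pathway + protein network
#'
#' Expands a set of significant pairs into the network of proteins and
#' interactions that compose their paths: protein-protein interaction edges
#' for consecutive interior nodes and membership edges linking each terminal
#' xref to its pathway. Proteins are annotated with their t and q statistics
#' when a gene table is supplied (flagged significant at q < 0.05), pathways
#' with their enrichment flag.
#'
#' @param result A `crosstalk_result`, or a path-record tibble.
#' @param pairs Optional pair subset (tibble with `source_pathway`,
#'   `target_pathway`) restricting which pairs' paths are included; default
#'   all pairs with recorded paths.
#' @param stats Optional gene statistics table.
#' @param enrich Optional enrichment table.
#' @param q_threshold Significance flag threshold on gene q-values. Default
#'   0.05.
#' @return A `detailed_network`: list with `nodes` (tibble: `id`, `kind`,
#'   `t`, `q`, `significant`), `edges` (tibble: `from`, `to`, `kind`) and
#'   `graph` (directed igraph).
#' @export
extract_detailed_network <- function(result, pairs = NULL, stats = NULL,
                                     enrich = NULL, q_threshold = 0.05) {
  paths <- if (inherits(result, "crosstalk_result")) result$paths else result
  if (!is.null(pairs)) {
    keep <- paste(paths$source_pathway, paths$target_pathway) %in%
      paste(pairs$source_pathway, pairs$target_pathway)
    paths <- paths[keep, , drop = FALSE]
  }
  edge_rows <- purrr::pmap(
    list(paths$source_pathway, paths$target_pathway, paths$nodes),
    function(pn, pm, nodes) {
      k <- length(nodes)
      tibble::tibble(
        from = c(pn, if (k > 1) nodes[-k], nodes[k]),
        to = c(nodes[1], if (k > 1) nodes[-1], pm),
        kind = c("membership", if (k > 1) rep("interaction", k - 1),
                 "membership")
      )
    }
  )
  edges <- if (length(edge_rows) > 0) {
    dplyr::distinct(dplyr::bind_rows(edge_rows))
  } else {
    tibble::tibble(from = character(), to = character(), kind = character())
  }
  pw_ids <- sort(unique(c(paths$source_pathway, paths$target_pathway)))
  protein_ids <- sort(unique(unlist(paths$nodes, use.names = FALSE)))
  nodes <- tibble::tibble(
    id = c(pw_ids, protein_ids),
    kind = rep(c("pathway", "protein"), c(length(pw_ids), length(protein_ids)))
  )
  if (!is.null(stats)) {
    m <- match(nodes$id, stats$gene_id)
    nodes$t <- stats$t[m]
    nodes$q <- stats$q[m]
    nodes$significant <- !is.na(nodes$q) & nodes$q < q_threshold
  } else {
    nodes$t <- NA_real_
    nodes$q <- NA_real_
    nodes$significant <- NA
  }
  if (!is.null(enrich)) {
    me <- match(nodes$id, enrich$pathway_id)
    nodes$significant <- ifelse(
      nodes$kind == "pathway" & !is.na(me),
      !is.na(enrich$p[me]) & enrich$p[me] < 0.05,
      nodes$significant
    )
  }
  g <- igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "detailed_network")
}

#' @export
print.detailed_network <- function(x, ...) {
  cat("Detailed cross-talk network:",
      sum(x$nodes$kind == "pathway"), "pathways,",
      sum(x$nodes$kind == "protein"), "proteins,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Classify paths as direct or indirect
#'
#' A path is direct when every interior protein belongs to the source or
#' target pathway (zero free intermediates) and indirect otherwise. Reports
#' totals, the indirect fraction, and the breakdown by intermediate count.
#'
#' @param paths Path records (or a `crosstalk_result`).
#' @return A `path_summary`: list with `n_paths`, `n_direct`, `n_indirect`,
#'   `fraction_indirect` and `by_intermediates` (tibble: `n_intermediates`,
#'   `n_paths`).
#' @export
classify_paths <- function(paths) {
  if (inherits(paths, "crosstalk_result")) paths <- paths$paths
  n <- nrow(paths)
  n_direct <- sum(paths$classification == "direct")
  by_int <- dplyr::count(paths, .data$n_intermediates, name = "n_paths")
  structure(
    list(
      n_paths = n, n_direct = n_direct, n_indirect = n - n_direct,
      fraction_indirect = if (n > 0) (n - n_direct) / n else NA_real_,
      by_intermediates = by_int
    ),
    class = "path_summary"
  )
}

#' @export
print.path_summary <- function(x, ...) {
  cat(sprintf("%d paths: %d direct, %d indirect (fraction indirect %.3f)\n",
              x$n_paths, x$n_direct, x$n_indirect,
              if (x$n_paths > 0) x$fraction_indirect else NA))
  invisible(x)
}

#' Proteins involved in most pathway interactions
#'
#' Ranks proteins by the number of distinct significant ordered pathway
#' pairs whose paths contain them — candidates for key regulators of
#' cross-talk. Ties are broken by the number of paths, then lexically.
#'
#' @param result A `crosstalk_result`.
#' @param k Number of proteins to return (`Inf` for all). Default 10.
#' @param p_threshold Only pairs below this p-value are counted; `NULL`
#'   counts every pair with recorded paths. Default 0.001.
#' @return A tibble with `protein`, `n_pairs`, `n_paths`, ranked.
#' @export
top_crosstalk_proteins <- function(result, k = 10, p_threshold = 0.001) {
  stopifnot(k >= 1)
  paths <- result$paths
  if (!is.null(p_threshold)) {
    sig <- result$pairs[!is.na(result$pairs$p_value) &
                          result$pairs$p_value < p_threshold, , drop = FALSE]
    keep <- paste(paths$source_pathway, paths$target_pathway) %in%
      paste(sig$source_pathway, sig$target_pathway)
    paths <- paths[keep, , drop = FALSE]
  }
  if (nrow(paths) == 0L) {
    return(tibble::tibble(protein = character(), n_pairs = integer(),
                          n_paths = integer()))
  }
  long <- tibble::tibble(
    pair = rep(paste(paths$source_pathway, paths$target_pathway, sep = "->"),
               lengths(paths$nodes)),
    protein = unlist(paths$nodes, use.names = FALSE)
  )
  ranked <- long |>
    dplyr::distinct() |>
    dplyr::count(.data$protein, name = "n_pairs")
  path_counts <- dplyr::count(long, .data$protein, name = "n_paths")
  ranked <- dplyr::left_join(ranked, path_counts, by = "protein") |>
    dplyr::arrange(dplyr::desc(.data$n_pairs), dplyr::desc(.data$n_paths),
                   .data$protein)
  head(ranked, n = k)
}
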