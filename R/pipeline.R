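#' One-call pathway cross-talk analysis
#'
#' Runs the full pipeline: merge strongly overlapping pathways, build the
#' unified pathway/protein graph, weight its edges by the sigmoid-transformed
#' t-statistics, score and test every ordered pathway pair, and (optionally)
#' compute pathway enrichment for node annotation.
#'
#' @param pathways A pathway collection (see [read_pathways_gmt()]).
#' @param network An interaction table (see [read_interaction_table()]).
#' @param stats A gene statistics table (see [read_gene_stats()]).
#' @param merge_threshold Overlap at which pathways are merged before
#'   analysis; `NULL` skips merging. Default 0.75.
#' @param wp Sigmoid [weight_params()].
#' @param params Search [core_params()].
#' @param enrich Also compute [gene_set_enrichment()]? Default TRUE.
#' @param enrich_perms Permutations for the enrichment null. Default 10000.
#' @return A `crosstalk_result` with elements `pairs`, `paths`, `params`,
#'   plus `collection` (the analysed, post-merge collection), `merge` (the
#'   merge report or `NULL`) and `enrichment` (tibble or `NULL`).
#' @export
#' @examples
#' fix <- generate_fixture(fixture_spec(n_proteins = 60, n_pathways = 4,
#'                                      planted_pairs = tibble::tibble(
#'                                        source = "P01", target = "P02",
#'                                        n_bridges = 1L,
#'                                        bridge_indirect = FALSE,
#'                                        effect_T = 6),
#'                                      seed = 7))
#' res <- pathway_crosstalk(fix$pathways, fix$network, fix$stats,
#'                          params = core_params(n_perm_initial = 20,
#'                                               n_perm_extra = 0, seed = 7),
#'                          enrich_perms = 200)
#' tidy(res)
pathway_crosstalk <- function(pathways, network, stats,
                              merge_threshold = 0.75,
                              wp = weight_params(), params = core_params(),
                              enrich = TRUE, enrich_perms = 10000) {
  merge_report <- NULL
  pc <- validate_pathway_collection(pathways)
  if (!is.null(merge_threshold)) {
    merge_report <- merge_overlapping_pathways(pc, threshold = merge_threshold)
    pc <- merge_report$merged_collection
  }
  g <- build_unified_graph(pc, network)
  g <- assign_edge_weights(g, stats, wp)
  res <- run_all_pairs(g, pc, params)
  res$collection <- pc
  res$merge <- merge_report
  res$enrichment <- if (isTRUE(enrich)) {
    gene_set_enrichment(pc, stats, n_perm = enrich_perms,
                        seed = params$seed + 1L)
  }
  res
}

#' @export
print.crosstalk_result <- function(x, ...) {
  n_sig <- sum(x$pairs$p_value < 0.001 & x$pairs$score > 0, na.rm = TRUE)
  cat("Pathway cross-talk result\n")
  cat("  ordered pairs evaluated:", nrow(x$pairs), "\n")
  cat("  pairs with >= 1 admissible path:", sum(x$pairs$score > 0), "\n")
  cat("  significant at p < 0.001:", n_sig, "\n")
  cat("  paths recorded:", nrow(x$paths), "\n")
  invisible(x)
}

#' Tidy a cross-talk result into its pair table
#'
#' @param x A `crosstalk_result`.
#' @param ... Unused.
#' @return The ordered pair tibble (`source_pathway`, `target_pathway`,
#'   `score`, `n_paths`, `p_value`, `n_permutations`), sorted by p-value
#'   then decreasing score.
#' @exportS3Method generics::tidy
tidy.crosstalk_result <- function(x, ...) {
  dplyr::arrange(x$pairs, .data$p_value, dplyr::desc(.data$score))
}

#' One-row summary of a cross-talk result
#'
#' @param x A `crosstalk_result`.
#' @param p_threshold Significance threshold used for the edge count.
#'   Default 0.001.
#' @param ... Unused.
#' @return A one-row tibble: pair counts, significant edge count, path
#'   counts and indirect fraction.
#' @exportS3Method generics::glance
glance.crosstalk_result <- function(x, p_threshold = 0.001, ...) {
  cls <- classify_paths(x)
  tibble::tibble(
    n_pairs = nrow(x$pairs),
    n_pairs_with_paths = sum(x$pairs$score > 0),
    n_significant = sum(x$pairs$p_value < p_threshold & x$pairs$score > 0,
                        na.rm = TRUE),
    n_paths = cls$n_paths,
    n_direct = cls$n_direct,
    n_indirect = cls$n_indirect,
    fraction_indirect = cls$fraction_indirect
  )
}

#' Volcano-style overview of pathway pair scores
#'
#' Scatter of interaction score against empirical p-value (on a
#' reciprocal-rank-like -log10 axis) for every ordered pathway pair with at
#' least one path; pairs significant at the threshold are highlighted.
#' Zero-p pairs are drawn at the resolution limit 1/n_permutations.
#'
#' @param object A `crosstalk_result`.
#' @param p_threshold Highlight threshold. Default 0.001.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.crosstalk_result <- function(object, p_threshold = 0.001, ...) {
  d <- object$pairs[object$pairs$score > 0, , drop = FALSE]
  d$p_plot <- pmax(d$p_value, ifelse(d$n_permutations > 0,
                                     1 / pmax(d$n_permutations, 1), 1))
  d$significant <- d$p_value < p_threshold
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score,
                                  y = -log10(.data$p_plot),
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(p_threshold),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "interaction score (sum of inverse path lengths)",
                  y = "-log10 empirical p",
                  colour = paste0("p < ", format(p_threshold))) +
    ggplot2::theme_minimal()
}

#' Plot a pathway interaction network
#'
#' Simple force-directed drawing of the significant pathway network with
#' node size by total degree and colour by enrichment flag.
#'
#' @param object A `pathway_network` from [build_pathway_network()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pathway_network <- function(object, ...) {
  g <- object$graph
  if (igraph::vcount(g) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "empty network"))
  }
  set.seed(1L)
  xy <- igraph::layout_with_fr(g)
  nodes <- object$nodes
  nodes$x <- xy[, 1]; nodes$y <- xy[, 2]
  el <- igraph::as_edgelist(g)
  seg <- tibble::tibble(
    x = nodes$x[match(el[, 1], nodes$pathway_id)],
    y = nodes$y[match(el[, 1], nodes$pathway_id)],
    xend = nodes$x[match(el[, 2], nodes$pathway_id)],
    yend = nodes$y[match(el[, 2], nodes$pathway_id)]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey60",
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$in_degree + .data$out_degree,
                                     colour = .data$enriched)) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$pathway_id),
                       vjust = -1, size = 3) +
    ggplot2::scale_size_continuous(range = c(2, 8)) +
    ggplot2::theme_void() +
    ggplot2::labs(size = "degree", colour = "enriched")
}
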