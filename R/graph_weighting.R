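#' Sigmoid weighting parameters
#'
#' Parameters of the soft threshold that turns a signed moderated
#' t-statistic into an edge weight: `mu` is the |t| that receives weight 0.5
#' (the center of the threshold) and `alpha` its steepness — a higher value
#' gives a sharper cutoff. The defaults (`mu = 3`, `alpha = 2`) emphasise
#' genes with |t| >= 3 by giving them low weights.
#'
#' @param mu Center of the soft threshold, in t-statistic units. Default 3.
#' @param alpha Steepness, must be positive. Default 2.
#' @return An object of class `weight_params`.
#' @export
weight_params <- function(mu = 3, alpha = 2) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(alpha), length(alpha) == 1L, alpha > 0)
  structure(list(mu = mu, alpha = alpha), class = "weight_params")
}

#' @export
print.weight_params <- function(x, ...) {
  cat("Sigmoid weight transform: f(T) = 1 / (1 + exp(alpha * (|T| - mu)))",
      sprintf("\n  mu = %g (|T| receiving weight 0.5), alpha = %g\n",
              x$mu, x$alpha))
  invisible(x)
}

#' Sigmoid transform of a t-statistic into an edge weight
#'
#' `f(T) = 1 / (1 + exp(alpha * (|T| - mu)))`: a decreasing logistic in |T|
#' with values in (0, 1), equal to 0.5 exactly at |T| = mu. Strong
#' differential expression gives weights near 0 (short path steps); |T| near
#' 0 gives weights near 1, close to the weight of a gene without data.
#'
#' @param t Signed t-statistic(s); only the absolute value matters.
#' @param wp A [weight_params()] object.
#' @return Weight(s) in (0, 1), same length as `t`.
#' @export
#' @examples
#' sigmoid_weight(c(-3, 0, 6), weight_params(mu = 3, alpha = 2))
sigmoid_weight <- function(t, wp = weight_params()) {
  stopifnot(inherits(wp, "weight_params"), all(is.finite(t)))
  1 / (1 + exp(wp$alpha * (abs(t) - wp$mu)))
}

#' Build the unified pathway/protein graph
#'
#' Creates a directed graph with two node kinds: pathways and genes/proteins
#' ("xrefs", identifiers in the unified namespace). Each undirected
#' interaction row contributes two directed interaction edges (one in each
#' direction); a directed row contributes one. Each pathway is connected to
#' each of its member xrefs by a reciprocal pair of membership edges, so
#' paths can both leave a source pathway and enter a target pathway. Xref
#' nodes are the union of genes appearing in the collection or the
#' interaction table. Vertices are ordered lexically so shortest-path
#' tie-breaks are reproducible.
#'
#' @param pc A pathway collection.
#' @param it An interaction table (see [read_interaction_table()]).
#' @return An igraph object with vertex attributes `kind` ("pathway"/"xref")
#'   and `n_pathways` (for xrefs, the number of pathways annotating them) and
#'   edge attribute `kind` ("membership"/"interaction"). Edge weights are
#'   added by [assign_edge_weights()].
#' @export
build_unified_graph <- function(pc, it) {
  pc <- validate_pathway_collection(pc)
  xrefs <- sort(unique(c(unlist(pc$members, use.names = FALSE),
                         it$source, it$target)))
  clash <- intersect(xrefs, pc$pathway_id)
  if (length(clash) > 0L) {
    abort(paste0("Identifier(s) used both as pathway id and gene id: ",
                 paste(head(clash, 3), collapse = ", ")))
  }
  membership_count <- table(unlist(lapply(pc$members, unique),
                                   use.names = FALSE))
  vertices <- tibble::tibble(
    name = c(sort(pc$pathway_id), xrefs),
    kind = rep(c("pathway", "xref"), c(nrow(pc), length(xrefs))),
    n_pathways = c(rep(NA_integer_, nrow(pc)),
                   as.integer(ifelse(is.na(match(xrefs, names(membership_count))),
                                     0L, membership_count[xrefs])))
  )

  # interaction edges: undirected rows expand to both directions, then dedupe
  inter <- tibble::tibble(
    from = c(it$source, it$target[!it$directed]),
    to = c(it$target, it$source[!it$directed])
  )
  inter <- dplyr::distinct(inter)
  # membership edges: pathway -> member and member -> pathway
  pw <- rep(pc$pathway_id, lengths(pc$members))
  mb <- unlist(pc$members, use.names = FALSE)
  memb <- tibble::tibble(from = c(pw, mb), to = c(mb, pw))

  edges <- dplyr::bind_rows(inter, memb)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = vertices)
  igraph::E(g)$kind <- rep(c("interaction", "membership"),
                           c(nrow(inter), nrow(memb)))
  g
}

#' Assign data-driven edge weights to the unified graph
#'
#' Every edge takes its weight from its *target* node: 0 if the target is a
#' pathway node (entering a pathway is free, so path lengths do not depend on
#' which membership edge closes the path), the sigmoid-transformed statistic
#' `f(t)` if the target gene was measured, and the maximum weight 1 if no
#' data is available for it. Paths through differentially expressed genes
#' are thereby short.
#'
#' @param g Unified graph from [build_unified_graph()].
#' @param stats Gene statistics table (see [read_gene_stats()]).
#' @param wp A [weight_params()] object.
#' @return The graph with an edge attribute `weight` in \[0, 1\] and a vertex
#'   attribute `node_weight` (the weight every incoming edge of that node
#'   carries).
#' @export
assign_edge_weights <- function(g, stats, wp = weight_params()) {
  stopifnot(igraph::is_igraph(g))
  t_lookup <- setNames(stats$t, stats$gene_id)
  vt <- t_lookup[igraph::V(g)$name]
  node_w <- ifelse(igraph::V(g)$kind == "pathway", 0,
                   ifelse(is.na(vt), 1, sigmoid_weight(ifelse(is.na(vt), 0, vt), wp)))
  igraph::V(g)$node_weight <- node_w
  heads <- igraph::head_of(g, igraph::E(g))
  igraph::E(g)$weight <- node_w[as.integer(heads)]
  g
}

#' Gene-set enrichment by mean absolute t-statistic
#'
#' For each pathway the enrichment score is the mean of |t| over its
#' *measured* members, testing for association with differential expression
#' regardless of direction. Significance is empirical: the null distribution
#' is the score of random gene sets of the same measured size, drawn without
#' replacement from all measured genes, and `p` is the fraction of null
#' scores at or above the observed score. Pathways with no measured member
#' get `NA` score and p-value.
#'
#' @param pc A pathway collection.
#' @param stats Gene statistics table.
#' @param n_perm Number of random gene sets per pathway size. Default 10000.
#' @param seed Optional integer seed for the permutation draws.
#' @return A tibble with columns `pathway_id`, `n_genes_measured`, `score`
#'   and `p`.
#' @export
gene_set_enrichment <- function(pc, stats, n_perm = 10000, seed = NULL) {
  pc <- validate_pathway_collection(pc)
  stopifnot(n_perm >= 1)
  if (nrow(stats) == 0L) {
    abort("Gene statistics table is empty")
  }
  if (!is.null(seed)) set.seed(seed)
  abs_t <- abs(stats$t)
  names(abs_t) <- stats$gene_id
  n_universe <- length(abs_t)

  measured <- lapply(pc$members, function(m) abs_t[m[m %in% names(abs_t)]])
  sizes <- lengths(measured)
  score <- vapply(measured, function(x) {
    if (length(x) == 0L) NA_real_ else mean(x)
  }, numeric(1))

  # one null distribution per distinct measured size
  null_by_size <- lapply(
    setNames(nm = unique(sizes[sizes > 0L & sizes <= n_universe])),
    function(s) {
      s <- as.integer(s)
      vapply(seq_len(n_perm),
             function(i) mean(abs_t[sample.int(n_universe, s)]),
             numeric(1))
    }
  )
  p <- vapply(seq_along(sizes), function(i) {
    s <- sizes[i]
    if (s == 0L || s > n_universe) return(NA_real_)
    mean(null_by_size[[as.character(s)]] >= score[i])
  }, numeric(1))

  tibble::tibble(
    pathway_id = pc$pathway_id,
    n_genes_measured = as.integer(sizes),
    score = score,
    p = p
  )
}
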