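# Builders for tiny hand-specified inputs and the exhaustive path oracle.

make_collection <- function(...) {
  sets <- list(...)
  tibble::tibble(
    pathway_id = names(sets),
    name = paste("pathway", names(sets)),
    source = "test",
    members = unname(sets)
  )
}

make_net <- function(source, target, directed = FALSE, itype = "binding",
                     provenance = "test") {
  tibble::tibble(source = source, target = target,
                 directed = directed, itype = itype, provenance = provenance)
}

make_stats <- function(t) {
  tibble::tibble(gene_id = names(t), t = unname(t),
                 p = NA_real_, q = NA_real_)
}

build_weighted <- function(pc, it, stats, wp = weight_params()) {
  assign_edge_weights(build_unified_graph(pc, it), stats, wp)
}

# A weighted pair subgraph for two pathways joined by a single chain of
# `n_bridge` proteins: Pn - b1 - ... - bk - Pm, where b1 is a member of Pn,
# bk a member of Pm, and the middle proteins belong to no pathway.
chain_fixture <- function(n_bridge, t_value = 8, extra_pathway_genes = 0) {
  stopifnot(n_bridge >= 2)
  bridge <- sprintf("x%02d", seq_len(n_bridge))
  pn_members <- c(bridge[1], if (extra_pathway_genes > 0)
    sprintf("a%02d", seq_len(extra_pathway_genes)))
  pm_members <- c(bridge[n_bridge], if (extra_pathway_genes > 0)
    sprintf("z%02d", seq_len(extra_pathway_genes)))
  pc <- make_collection(Pn = pn_members, Pm = pm_members)
  it <- make_net(bridge[-n_bridge], bridge[-1])
  stats <- make_stats(setNames(rep(t_value, n_bridge), bridge))
  build_weighted(pc, it, stats)
}

# Exhaustive reference for the non-redundant shortest-path procedure:
# enumerate every simple path, take the minimum-length one, delete its
# interior edges, repeat. Independent of the Dijkstra-based implementation.
oracle_nonredundant_paths <- function(sub, pn, pm, l_max) {
  path_len <- function(g, vp) {
    ids <- igraph::get_edge_ids(g, rbind(vp[-length(vp)], vp[-1]))
    sum(igraph::E(g)$weight[ids])
  }
  out <- list()
  repeat {
    simple <- igraph::all_simple_paths(sub, from = pn, to = pm, mode = "out")
    if (length(simple) == 0L) break
    lens <- vapply(simple, function(vp) path_len(sub, as.integer(vp)),
                   numeric(1))
    best <- which.min(lens)
    if (lens[best] > l_max) break
    vp <- simple[[best]]
    nm <- vp$name
    out[[length(out) + 1L]] <- list(
      nodes = nm[-c(1L, length(nm))], length = lens[best]
    )
    ends_ok <- function(a, b) a %in% c(pn, pm) | b %in% c(pn, pm)
    vpi <- as.integer(vp)
    eids <- igraph::get_edge_ids(sub, rbind(vpi[-length(vpi)], vpi[-1]))
    epn <- igraph::ends(sub, eids, names = TRUE)
    deletable <- eids[!ends_ok(epn[, 1], epn[, 2])]
    if (length(deletable) == 0L) break
    sub <- igraph::delete_edges(sub, deletable)
  }
  out
}

# Random two-pathway problem on at most `n_max` proteins with continuous
# statistics, returning the weighted pair subgraph ready for path search.
random_pair_problem <- function(seed, n_max = 15) {
  set.seed(seed)
  n <- sample(6:n_max, 1)
  genes <- sprintf("g%02d", seq_len(n))
  n_edges <- sample(n:(2 * n), 1)
  ends <- cbind(sample(genes, n_edges, replace = TRUE),
                sample(genes, n_edges, replace = TRUE))
  ends <- ends[ends[, 1] != ends[, 2], , drop = FALSE]
  it <- make_net(ends[, 1], ends[, 2],
                 directed = runif(nrow(ends)) < 0.3,
                 itype = ifelse(runif(nrow(ends)) < 0.3, "tf_target",
                                "binding"))
  it <- dplyr::distinct(it, source, target, .keep_all = TRUE)
  k <- sample(2:4, 1)
  pn_members <- sample(genes, k)
  pm_members <- sample(genes, k)
  if (all(pm_members %in% pn_members)) {
    pm_members[1] <- sample(setdiff(genes, pn_members), 1)
  }
  pc <- make_collection(Pn = pn_members, Pm = pm_members)
  stats <- make_stats(setNames(runif(n, 0, 8) * sample(c(-1, 1), n, TRUE),
                               genes))
  g <- build_weighted(pc, it, stats)
  g_pn <- neighborhood_subgraph(g, "Pn", 5)
  if (!"Pm" %in% igraph::V(g_pn)$name) return(NULL)
  pair_subgraph(g_pn, "Pn", "Pm")
}
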