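#' Core parameters of the cross-talk search
#'
#' @param nb Neighborhood radius in visited edges around the source pathway;
#'   with membership edges at both ends, `nb = 5` limits a path to at most
#'   three protein-protein edges. Default 5.
#' @param l_max Maximum summed edge weight of a path for it to contribute to
#'   a pair's score; 0.9 keeps out paths through genes with low significance
#'   or no data (whose single step already weighs close to 1). Default 0.9.
#' @param n_perm_initial Permutations in the first significance stage.
#'   Default 100.
#' @param n_perm_extra Additional permutations for pairs whose first-stage
#'   p-value falls below `p_extend`; p-values are recomputed over the pooled
#'   draws. Default 1000.
#' @param p_extend First-stage p-value below which a pair's null is extended.
#'   Default 0.1.
#' @param seed Integer seed controlling every random draw of a run.
#' @param n_strata Number of strength (weighted degree) quantile strata used
#'   to match replacement proteins during pathway randomization. Default 20.
#' @param keep_null Keep the permutation null scores per pair (list-column
#'   `null_scores`)? Default FALSE.
#' @return An object of class `core_params`.
#' @export
core_params <- function(nb = 5, l_max = 0.9, n_perm_initial = 100,
                        n_perm_extra = 1000, p_extend = 0.1, seed = 1L,
                        n_strata = 20, keep_null = FALSE) {
  stopifnot(nb >= 3, l_max > 0, n_perm_initial >= 1, n_perm_extra >= 0,
            p_extend > 0, p_extend <= 1, n_strata >= 1)
  structure(
    list(nb = as.integer(nb), l_max = l_max,
         n_perm_initial = as.integer(n_perm_initial),
         n_perm_extra = as.integer(n_perm_extra), p_extend = p_extend,
         seed = as.integer(seed), n_strata = as.integer(n_strata),
         keep_null = isTRUE(keep_null)),
    class = "core_params"
  )
}

#' @export
print.core_params <- function(x, ...) {
  cat(sprintf(
    "Cross-talk search parameters: nb = %d, l_max = %g,\n  permutations %d (+%d when p < %g), %d strength strata, seed %d\n",
    x$nb, x$l_max, x$n_perm_initial, x$n_perm_extra, x$p_extend,
    x$n_strata, x$seed))
  invisible(x)
}

#' Neighborhood subgraph around a source pathway
#'
#' Induced subgraph on the nodes reachable from `pn` within `nb` directed
#' steps, where every edge traversal — membership or interaction — counts as
#' one visited edge. This bounds both the search space and the number of
#' protein-protein edges a path may use.
#'
#' @param g Weighted unified graph.
#' @param pn Pathway node id.
#' @param nb Hop radius (>= 0).
#' @return An igraph subgraph with all attributes preserved.
#' @export
neighborhood_subgraph <- function(g, pn, nb) {
  stopifnot(nb >= 0)
  if (!pn %in% igraph::V(g)$name) {
    abort(paste0("Pathway node not in graph: ", pn))
  }
  vids <- igraph::ego(g, order = nb, nodes = pn, mode = "out",
                      mindist = 0)[[1]]
  igraph::induced_subgraph(g, sort(as.integer(vids)))
}

#' Pair subgraph for one ordered pathway pair
#'
#' Restricts a source-pathway neighborhood to the nodes relevant for paths
#' from `pn` to `pm`: the two pathway nodes, their member xrefs, and xrefs
#' annotated to no pathway at all (free intermediates). Xrefs belonging to
#' any other pathway are removed — a route through them is two interactions
#' with that pathway as intermediate, not a direct pair interaction. For
#' xrefs shared by `pn` and `pm` the membership edge into `pm` is removed, so
#' mere membership overlap cannot masquerade as a path; a shared protein can
#' still serve as an interior step between distinct partners in the two
#' pathways.
#'
#' @param g_pn Neighborhood subgraph from [neighborhood_subgraph()].
#' @param pn,pm Source and target pathway ids (must differ).
#' @return An igraph subgraph.
#' @export
pair_subgraph <- function(g_pn, pn, pm) {
  if (identical(pn, pm)) {
    abort("Self-interaction of a pathway with itself is undefined")
  }
  vn <- igraph::V(g_pn)$name
  if (!all(c(pn, pm) %in% vn)) {
    abort("Both pathway nodes must be present in the neighborhood subgraph")
  }
  members_pn <- igraph::neighbors(g_pn, pn, mode = "out")$name
  members_pm <- igraph::neighbors(g_pn, pm, mode = "out")$name
  free <- vn[igraph::V(g_pn)$kind == "xref" &
               !is.na(igraph::V(g_pn)$n_pathways) &
               igraph::V(g_pn)$n_pathways == 0L]
  keep <- unique(c(pn, pm, members_pn, members_pm, free))
  sub <- igraph::induced_subgraph(
    g_pn, sort(match(keep, vn))
  )
  overlap <- intersect(members_pn, members_pm)
  if (length(overlap) > 0L) {
    eids <- igraph::get_edge_ids(
      sub, rbind(match(overlap, igraph::V(sub)$name),
                 match(pm, igraph::V(sub)$name))
    )
    sub <- igraph::delete_edges(sub, eids[eids > 0])
  }
  sub
}

#' Iteratively extract non-redundant weighted shortest paths
#'
#' Repeats: find the weighted shortest path from `pn` to `pm` (length = sum
#' of edge weights); if none exists or its length exceeds `l_max`, stop;
#' otherwise record it and delete its edges except those that connect `pn`
#' or `pm`, so the next iteration must use a distinct interior route.
#' Returned paths are therefore mutually edge-disjoint on their interior
#' (xref-to-xref) edges and come out in non-decreasing length order.
#'
#' @param sub Pair subgraph from [pair_subgraph()], with weights assigned.
#' @param pn,pm Source and target pathway ids.
#' @param l_max Maximum admissible path length.
#' @return A tibble of path records: `source_pathway`, `target_pathway`,
#'   `nodes` (list-column of interior xref ids in order), `length`,
#'   `n_intermediates` (interior xrefs annotated to no pathway) and
#'   `classification` (`"direct"` iff no intermediates).
#' @export
find_nonredundant_shortest_paths <- function(sub, pn, pm, l_max = 0.9) {
  w <- igraph::E(sub)$weight
  if (!is.null(w) && any(w < 0)) {
    abort("Negative edge weight encountered; weights must be in [0, 1]")
  }
  vkind <- setNames(igraph::V(sub)$n_pathways, igraph::V(sub)$name)
  records <- list()
  repeat {
    sp <- suppressWarnings(igraph::shortest_paths(
      sub, from = pn, to = pm, mode = "out",
      weights = igraph::E(sub)$weight, output = "both"
    ))
    vp <- sp$vpath[[1]]
    if (length(vp) == 0L) break
    ep <- sp$epath[[1]]
    len <- sum(igraph::E(sub)$weight[as.integer(ep)])
    if (len > l_max) break
    interior <- vp$name[-c(1L, length(vp))]
    n_int <- sum(!is.na(vkind[interior]) & vkind[interior] == 0L)
    records[[length(records) + 1L]] <- tibble::tibble(
      source_pathway = pn, target_pathway = pm,
      nodes = list(interior), length = len,
      n_intermediates = as.integer(n_int),
      classification = if (n_int == 0L) "direct" else "indirect"
    )
    ends <- igraph::ends(sub, ep, names = TRUE)
    deletable <- ep[ends[, 1] != pn & ends[, 1] != pm &
                      ends[, 2] != pn & ends[, 2] != pm]
    if (length(deletable) == 0L) {
      # cannot happen when overlap edges into pm were removed; guard anyway
      warn("Shortest path has no deletable interior edge; stopping")
      break
    }
    sub <- igraph::delete_edges(sub, deletable)
  }
  if (length(records) == 0L) {
    return(empty_path_records())
  }
  dplyr::bind_rows(records)
}

empty_path_records <- function() {
  tibble::tibble(
    source_pathway = character(), target_pathway = character(),
    nodes = list(), length = numeric(), n_intermediates = integer(),
    classification = character()
  )
}

#' Interaction score of a pathway pair
#'
#' The sum of inverse path lengths over the pair's non-redundant shortest
#' paths: many short (strongly regulated) routes give a high score. An empty
#' path set scores 0.
#'
#' @param lengths Numeric vector of path lengths, all positive (a zero-length
#'   path between two pathways is impossible: the first membership step
#'   already carries the member's positive weight).
#' @return A non-negative number.
#' @export
#' @examples
#' interaction_score(c(0.3, 0.6)) # 10/3 + 5/3 = 5
interaction_score <- function(lengths) {
  if (length(lengths) == 0L) return(0)
  if (any(lengths <= 0)) {
    abort("Path lengths must be positive")
  }
  sum(1 / lengths)
}

#' Strength strata of the protein nodes
#'
#' Computes each xref node's strength (weighted degree: the sum of weights
#' over incident interaction edges, both directions) on the weighted unified
#' graph and bins the xrefs into `n_strata` quantile strata. These strata
#' drive connectivity-matched pathway randomization.
#'
#' @param g Weighted unified graph.
#' @param n_strata Number of quantile bins. Default 20.
#' @return A tibble with columns `xref`, `strength`, `stratum`.
#' @export
xref_strength_strata <- function(g, n_strata = 20) {
  inter <- igraph::subgraph_from_edges(
    g, igraph::E(g)[igraph::E(g)$kind == "interaction"],
    delete.vertices = FALSE
  )
  is_xref <- igraph::V(g)$kind == "xref"
  s <- igraph::strength(inter, vids = igraph::V(inter)[is_xref],
                        mode = "all", loops = FALSE)
  tibble::tibble(
    xref = names(s),
    strength = as.numeric(s),
    stratum = dplyr::ntile(as.numeric(s), n_strata)
  )
}

#' Rewire a pathway to strength-matched random proteins
#'
#' Produces a randomized version of pathway `pm` by re-attaching its
#' membership edges: each member xref is replaced by a distinct xref sampled
#' from the same strength stratum, excluding current members and already-used
#' replacements, so the randomized pathway has connectivity similar to the
#' original. When a stratum offers no eligible node the nearest-strength
#' eligible xref is used instead. The rest of the graph is untouched and the
#' member count is preserved. Draws consume the global RNG stream.
#'
#' @param g Weighted unified graph.
#' @param pm Pathway id to randomize.
#' @param strata Strength strata from [xref_strength_strata()].
#' @return A graph in which `pm`'s membership edges point to the replacement
#'   xrefs (with the usual weights: the node weight into an xref, 0 into the
#'   pathway).
#' @export
randomize_pathway <- function(g, pm, strata) {
  members <- sort(igraph::neighbors(g, pm, mode = "out")$name)
  pool <- strata[!(strata$xref %in% members), , drop = FALSE]
  member_strat <- strata[match(members, strata$xref), , drop = FALSE]
  replacements <- character(length(members))
  for (i in seq_along(members)) {
    elig <- pool$xref[pool$stratum == member_strat$stratum[i] &
                        !(pool$xref %in% replacements)]
    if (length(elig) == 0L) {
      rest <- pool[!(pool$xref %in% replacements), , drop = FALSE]
      if (nrow(rest) == 0L) {
        abort("No eligible replacement xref left during randomization")
      }
      elig <- rest$xref[which.min(abs(rest$strength - member_strat$strength[i]))]
    }
    replacements[i] <- elig[sample.int(length(elig), 1L)]
  }
  g2 <- igraph::delete_edges(g, igraph::incident(g, pm, mode = "all"))
  node_w <- setNames(igraph::V(g2)$node_weight, igraph::V(g2)$name)
  # interleave pm->r (weight of r) and r->pm (weight 0)
  ep <- character(0)
  ww <- numeric(0)
  for (r in replacements) {
    ep <- c(ep, pm, r, r, pm)
    ww <- c(ww, node_w[[r]], 0)
  }
  igraph::add_edges(g2, ep, attr = list(kind = "membership", weight = ww))
}

# Score one ordered pair on a given weighted graph (steps: neighborhood,
# pair subgraph, non-redundant shortest paths, sum of inverse lengths).
score_pair <- function(g, pn, pm, nb, l_max, return_paths = FALSE) {
  g_pn <- neighborhood_subgraph(g, pn, nb)
  if (!pm %in% igraph::V(g_pn)$name) {
    return(if (return_paths) list(score = 0, paths = empty_path_records())
           else 0)
  }
  sub <- pair_subgraph(g_pn, pn, pm)
  paths <- find_nonredundant_shortest_paths(sub, pn, pm, l_max)
  s <- interaction_score(paths$length)
  if (return_paths) list(score = s, paths = paths) else s
}

#' Empirical p-values for scored pathway pairs
#'
#' Two-stage permutation test. For each pair with a positive score the
#' target pathway is rewired [n_perm_initial][core_params()] times with
#' [randomize_pathway()]; the whole search (neighborhood, pair subgraph,
#' non-redundant shortest paths, score) is re-run against each randomized
#' graph and `p = #(null score >= observed) / n`. Pairs below `p_extend`
#' receive `n_perm_extra` additional permutations and `p` is recomputed over
#' the pooled draws. Pairs with score 0 are assigned `p = 1` without
#' permutation (null scores are never negative, so ties at zero always
#' count). The permutation count actually used is recorded per pair.
#'
#' @param g Weighted unified graph.
#' @param pairs Pair table with columns `source_pathway`, `target_pathway`,
#'   `score` (as produced inside [run_all_pairs()]).
#' @param params A [core_params()] object. The caller is responsible for
#'   seeding the RNG (as [run_all_pairs()] does).
#' @param strata Optional precomputed [xref_strength_strata()].
#' @return `pairs` with columns `p_value`, `n_permutations` (and
#'   `null_scores` when `params$keep_null`).
#' @export
empirical_pvalues <- function(g, pairs, params = core_params(),
                              strata = NULL) {
  if (is.null(strata)) strata <- xref_strength_strata(g, params$n_strata)
  n <- nrow(pairs)
  p_value <- rep(1, n)
  n_permutations <- rep(0L, n)
  null_scores <- vector("list", n)
  for (i in seq_len(n)) {
    if (pairs$score[i] <= 0) next
    pn <- pairs$source_pathway[i]
    pm <- pairs$target_pathway[i]
    draw_null <- function(k) {
      vapply(seq_len(k), function(j) {
        score_pair(randomize_pathway(g, pm, strata), pn, pm,
                   params$nb, params$l_max)
      }, numeric(1))
    }
    nulls <- draw_null(params$n_perm_initial)
    p1 <- sum(nulls >= pairs$score[i]) / length(nulls)
    if (p1 < params$p_extend && params$n_perm_extra > 0L) {
      nulls <- c(nulls, draw_null(params$n_perm_extra))
    }
    p_value[i] <- sum(nulls >= pairs$score[i]) / length(nulls)
    n_permutations[i] <- length(nulls)
    if (params$keep_null) null_scores[[i]] <- nulls
  }
  pairs$p_value <- p_value
  pairs$n_permutations <- n_permutations
  if (params$keep_null) pairs$null_scores <- null_scores
  pairs
}

#' Score and test every ordered pathway pair
#'
#' The full cross-talk search: for each source pathway `pn` the
#' `nb`-neighborhood is built once; every other pathway reachable inside it
#' is paired, the pair subgraph constructed, the non-redundant weighted
#' shortest paths extracted and summed into a score, and significance is
#' assessed by the two-stage strength-matched permutation test. Unreachable
#' pairs are reported with score 0 and p 1 without permutation. The run is
#' fully deterministic given `params$seed`.
#'
#' @param g Weighted unified graph ([assign_edge_weights()]).
#' @param pc The pathway collection the graph was built from (post-merging).
#' @param params A [core_params()] object.
#' @return A `crosstalk_result`: list with `pairs` (one row per ordered
#'   pair: `source_pathway`, `target_pathway`, `score`, `n_paths`,
#'   `p_value`, `n_permutations`), `paths` (all path records) and `params`.
#' @export
run_all_pairs <- function(g, pc, params = core_params()) {
  pc <- validate_pathway_collection(pc)
  stopifnot(inherits(params, "core_params"))
  if (is.null(igraph::E(g)$weight)) {
    abort("Edge weights missing; call assign_edge_weights() first")
  }
  set.seed(params$seed)
  ids <- sort(pc$pathway_id)
  strata <- xref_strength_strata(g, params$n_strata)

  pair_rows <- list()
  path_rows <- list()
  for (pn in ids) {
    g_pn <- neighborhood_subgraph(g, pn, params$nb)
    reachable <- intersect(ids, igraph::V(g_pn)$name)
    for (pm in setdiff(ids, pn)) {
      if (pm %in% reachable) {
        sub <- pair_subgraph(g_pn, pn, pm)
        paths <- find_nonredundant_shortest_paths(sub, pn, pm, params$l_max)
        s <- interaction_score(paths$length)
      } else {
        paths <- empty_path_records()
        s <- 0
      }
      pair_rows[[paste(pn, pm)]] <- tibble::tibble(
        source_pathway = pn, target_pathway = pm,
        score = s, n_paths = nrow(paths)
      )
      if (nrow(paths) > 0L) path_rows[[paste(pn, pm)]] <- paths
    }
  }
  pairs <- dplyr::bind_rows(pair_rows)
  paths <- if (length(path_rows) > 0L) dplyr::bind_rows(path_rows) else
    empty_path_records()
  pairs <- empirical_pvalues(g, pairs, params, strata = strata)

  structure(
    list(pairs = pairs, paths = paths, params = params),
    class = "crosstalk_result"
  )
}
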