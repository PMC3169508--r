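#' Specification of a synthetic cross-talk benchmark
#'
#' Describes a synthetic dataset with known ground truth: a scale-free-like
#' protein interaction network, pathways sampled as connected modules from
#' it, background t-statistics, and planted cross-talking pathway pairs
#' wired through dedicated high-|t| bridges. Because the bridges are
#' vertex-disjoint, recovering all of them exercises the edge-deleting
#' non-redundant path loop, not just reachability.
#'
#' @param n_proteins Number of proteins (>= 20). Default 300.
#' @param degree_exponent Power-law exponent of the degree tail. Default 2.5.
#' @param mean_degree Mean degree of the interaction network. Default 4.
#' @param directed_fraction Fraction of edges that are directed
#'   (transcription-factor-target-like); the rest are undirected bindings.
#'   Default 0.15.
#' @param n_pathways Number of pathways. Default 12.
#' @param pathway_size_range Min/max pathway size. Default c(8, 15).
#' @param overlap_pairs Optional tibble (`a`, `b`, `fraction`) forcing
#'   pathway `b` to share `fraction` of the smaller size with pathway `a`
#'   (exercises merging and shared-member semantics). Default none.
#' @param planted_pairs Tibble (`source`, `target`, `n_bridges`,
#'   `bridge_indirect`, `effect_T`) of planted ordered cross-talk pairs.
#'   Default: three direct pairs P01->P02, P03->P04, P05->P06 with two
#'   bridges each at effect |t| = 6.
#' @param background_T_sd Standard deviation of the null t-statistics.
#'   Default 1.
#' @param seed Integer seed; every generator step derives from it.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_proteins = 300, degree_exponent = 2.5,
                         mean_degree = 4, directed_fraction = 0.15,
                         n_pathways = 12, pathway_size_range = c(8, 15),
                         overlap_pairs = NULL, planted_pairs = NULL,
                         background_T_sd = 1, seed = 1L) {
  stopifnot(n_proteins >= 20, degree_exponent > 1, mean_degree > 0,
            directed_fraction >= 0, directed_fraction <= 1,
            n_pathways >= 2, length(pathway_size_range) == 2L,
            pathway_size_range[1] >= 2,
            pathway_size_range[2] >= pathway_size_range[1],
            background_T_sd >= 0)
  if (is.null(planted_pairs)) {
    planted_pairs <- tibble::tibble(
      source = c("P01", "P03", "P05"), target = c("P02", "P04", "P06"),
      n_bridges = 2L, bridge_indirect = FALSE, effect_T = 6
    )
  }
  structure(
    list(n_proteins = as.integer(n_proteins),
         degree_exponent = degree_exponent, mean_degree = mean_degree,
         directed_fraction = directed_fraction,
         n_pathways = as.integer(n_pathways),
         pathway_size_range = as.integer(pathway_size_range),
         overlap_pairs = overlap_pairs,
         planted_pairs = tibble::as_tibble(planted_pairs),
         background_T_sd = background_T_sd, seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

fixture_gene_ids <- function(n) sprintf("g%04d", seq_len(n))

fixture_pathway_ids <- function(n) sprintf("P%02d", seq_len(n))

#' Generate a synthetic protein interaction network
#'
#' Draws a simple random graph with a heavy-tailed (power-law fitness)
#' degree distribution and the requested mean degree, then marks a random
#' fraction of edges as directed (type `tf_target`); the rest are undirected
#' `binding` rows. Deterministic given the spec seed.
#'
#' @param spec A [fixture_spec()].
#' @return An interaction table (tibble: `source`, `target`, `directed`,
#'   `itype`, `provenance`).
#' @export
generate_interaction_network <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  n <- spec$n_proteins
  m <- round(n * spec$mean_degree / 2)
  if (m < n - 1 || m > n * (n - 1) / 2) {
    abort("Infeasible fixture: mean_degree too small or too large for n_proteins")
  }
  g <- igraph::sample_fitness_pl(n, m, exponent.out = spec$degree_exponent)
  ends <- igraph::as_edgelist(g, names = FALSE)
  ids <- fixture_gene_ids(n)
  directed <- runif(nrow(ends)) < spec$directed_fraction
  tibble::tibble(
    source = ids[ends[, 1]],
    target = ids[ends[, 2]],
    directed = directed,
    itype = ifelse(directed, "tf_target", "binding"),
    provenance = "synthetic"
  )
}

#' Generate a synthetic pathway collection
#'
#' Pathways are connected modules: members are drawn by seeded breadth-first
#' growth from a random start protein in the interaction network (topped up
#' with random proteins if the component is exhausted). Pairs designated in
#' `spec$overlap_pairs` share the requested fraction of members so that
#' merging and shared-protein path semantics can be exercised.
#'
#' @param spec A [fixture_spec()].
#' @param net Interaction table from [generate_interaction_network()].
#' @return A pathway collection tibble.
#' @export
generate_pathway_collection <- function(spec, net) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed + 1L)
  ids <- fixture_gene_ids(spec$n_proteins)
  g <- igraph::graph_from_data_frame(net[, c("source", "target")],
                                     directed = FALSE, vertices = ids)
  sizes <- sample(seq(spec$pathway_size_range[1], spec$pathway_size_range[2]),
                  spec$n_pathways, replace = TRUE)
  pw_ids <- fixture_pathway_ids(spec$n_pathways)
  members <- vector("list", spec$n_pathways)
  taken <- character(0)
  # BFS growth restricted to proteins not yet claimed by another pathway, so
  # incidental overlap stays low and overlap_pairs alone controls sharing
  grow <- function(size, avoid) {
    pool <- setdiff(ids, avoid)
    if (length(pool) < size) {
      abort("Infeasible fixture: not enough unclaimed proteins for a pathway")
    }
    start <- pool[sample.int(length(pool), 1L)]
    ord <- igraph::bfs(g, root = start, unreachable = FALSE)$order
    reach <- igraph::V(g)$name[as.integer(ord[!is.na(ord)])]
    got <- head(setdiff(reach, avoid), size)
    if (length(got) < size) {
      got <- c(got, sample(setdiff(pool, got), size - length(got)))
    }
    got
  }
  for (i in seq_len(spec$n_pathways)) {
    ov <- NULL
    if (!is.null(spec$overlap_pairs)) {
      hit <- which(match(spec$overlap_pairs$b, pw_ids) == i)
      if (length(hit) == 1L) ov <- spec$overlap_pairs[hit, , drop = FALSE]
    }
    if (is.null(ov)) {
      members[[i]] <- grow(sizes[i], taken)
    } else {
      donor <- members[[match(ov$a, pw_ids)]]
      n_shared <- ceiling(ov$fraction * min(length(donor), sizes[i]))
      shared <- sample(donor, n_shared)
      fresh <- grow(max(sizes[i] - n_shared, 0L), taken)
      members[[i]] <- union(shared, fresh)
    }
    taken <- union(taken, members[[i]])
  }
  tibble::tibble(
    pathway_id = pw_ids,
    name = paste("Synthetic pathway", seq_len(spec$n_pathways)),
    source = "synthetic",
    members = members
  )
}

#' Generate gene statistics with planted cross-talk bridges
#'
#' Background t-statistics are drawn from Normal(0, `background_T_sd`). For
#' each planted pair, `n_bridges` vertex-disjoint bridges are wired between
#' proteins exclusive to the source and target pathways — directly
#' (member-member) or through a fresh pathway-free intermediate — adding the
#' bridge edges to the network where missing, and every bridge gene receives
#' |t| = `effect_T` with random sign. Two-sided normal p-values and
#' Benjamini-Hochberg q-values accompany the t column.
#'
#' @param spec A [fixture_spec()].
#' @param net Interaction table (will be extended by bridge edges).
#' @param pc Pathway collection from [generate_pathway_collection()].
#' @return A list: `stats` (gene statistics tibble), `network` (the extended
#'   interaction table) and `manifest` (tibble of planted bridges:
#'   `source_pathway`, `target_pathway`, `bridge`, `nodes` list-column,
#'   `indirect`).
#' @export
generate_gene_stats_with_planted_paths <- function(spec, net, pc) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed + 2L)
  ids <- fixture_gene_ids(spec$n_proteins)
  t_stat <- setNames(rnorm(length(ids), 0, spec$background_T_sd), ids)

  n_member_of <- table(unlist(pc$members, use.names = FALSE))
  in_no_pathway <- setdiff(ids, names(n_member_of))
  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  existing <- edge_key(net$source, net$target)
  new_edges <- list()
  used <- character(0)
  manifest <- list()

  for (r in seq_len(nrow(spec$planted_pairs))) {
    pp <- spec$planted_pairs[r, ]
    mem <- setNames(pc$members, pc$pathway_id)
    if (!all(c(pp$source, pp$target) %in% pc$pathway_id)) {
      abort(paste0("Planted pair references unknown pathway: ",
                   pp$source, "->", pp$target))
    }
    excl <- function(p, other) {
      m <- mem[[p]]
      m[n_member_of[m] == 1L & !(m %in% used) & !(m %in% mem[[other]])]
    }
    src_pool <- sort(excl(pp$source, pp$target))
    tgt_pool <- sort(excl(pp$target, pp$source))
    if (length(src_pool) < pp$n_bridges || length(tgt_pool) < pp$n_bridges) {
      abort(paste0("Cannot place ", pp$n_bridges,
                   " vertex-disjoint bridges for ", pp$source, "->", pp$target))
    }
    src <- sample(src_pool, pp$n_bridges)
    tgt <- sample(tgt_pool, pp$n_bridges)
    for (b in seq_len(pp$n_bridges)) {
      if (isTRUE(pp$bridge_indirect)) {
        free_pool <- setdiff(in_no_pathway, used)
        if (length(free_pool) == 0L) {
          abort("No pathway-free protein left for an indirect bridge")
        }
        mid <- sample(free_pool, 1L)
        bridge_nodes <- c(src[b], mid, tgt[b])
      } else {
        bridge_nodes <- c(src[b], tgt[b])
      }
      for (j in seq_len(length(bridge_nodes) - 1L)) {
        a <- bridge_nodes[j]; z <- bridge_nodes[j + 1L]
        if (!edge_key(a, z) %in% existing) {
          new_edges[[length(new_edges) + 1L]] <- tibble::tibble(
            source = a, target = z, directed = FALSE, itype = "binding",
            provenance = "planted"
          )
          existing <- c(existing, edge_key(a, z))
        }
      }
      t_stat[bridge_nodes] <- pp$effect_T * sample(c(-1, 1),
                                                   length(bridge_nodes),
                                                   replace = TRUE)
      used <- c(used, bridge_nodes)
      manifest[[length(manifest) + 1L]] <- tibble::tibble(
        source_pathway = pp$source, target_pathway = pp$target,
        bridge = b, nodes = list(bridge_nodes),
        indirect = isTRUE(pp$bridge_indirect)
      )
    }
  }

  p <- 2 * stats::pnorm(-abs(t_stat))
  stats_tbl <- tibble::tibble(
    gene_id = ids, t = as.numeric(t_stat[ids]),
    p = as.numeric(p[ids]),
    q = stats::p.adjust(as.numeric(p[ids]), method = "BH")
  )
  list(
    stats = stats_tbl,
    network = dplyr::bind_rows(net, dplyr::bind_rows(new_edges)),
    manifest = if (length(manifest) > 0) dplyr::bind_rows(manifest) else
      tibble::tibble(source_pathway = character(), target_pathway = character(),
                     bridge = integer(), nodes = list(), indirect = logical())
  )
}

#' Generate a complete synthetic benchmark
#'
#' Runs the three fixture generators in sequence and returns every input the
#' cross-talk pipeline needs together with the planted ground truth.
#'
#' @param spec A [fixture_spec()].
#' @return A list: `pathways`, `network`, `stats`, `manifest`, `spec`.
#' @export
#' @examples
#' fix <- generate_fixture(fixture_spec(n_proteins = 60, n_pathways = 4,
#'                                      seed = 7))
#' fix$manifest
generate_fixture <- function(spec = fixture_spec()) {
  net <- generate_interaction_network(spec)
  pc <- generate_pathway_collection(spec, net)
  gs <- generate_gene_stats_with_planted_paths(spec, net, pc)
  list(pathways = pc, network = gs$network, stats = gs$stats,
       manifest = gs$manifest, spec = spec)
}

#' Write a synthetic benchmark to standard input files
#'
#' Writes the GMT pathway file, the interaction TSV, the gene statistics TSV
#' and the planted-truth manifest TSV under a directory, in the formats the
#' readers of this package consume.
#'
#' @param fix A fixture from [generate_fixture()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of files written.
#' @export
write_fixture_files <- function(fix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    pathways = file.path(dir, "pathways.gmt"),
    network = file.path(dir, "network.tsv"),
    stats = file.path(dir, "stats.tsv"),
    manifest = file.path(dir, "planted_manifest.tsv")
  )
  writeLines(
    vapply(seq_len(nrow(fix$pathways)), function(i) {
      paste(c(fix$pathways$pathway_id[i], fix$pathways$name[i],
              fix$pathways$members[[i]]), collapse = "\t")
    }, character(1)),
    files[["pathways"]]
  )
  net <- dplyr::rename(fix$network, type = "itype")
  net$directed <- as.integer(net$directed)
  readr::write_tsv(net, files[["network"]], progress = FALSE)
  readr::write_tsv(fix$stats, files[["stats"]], progress = FALSE)
  manifest <- fix$manifest
  manifest$nodes <- vapply(manifest$nodes, paste, character(1), collapse = "|")
  readr::write_tsv(manifest, files[["manifest"]], progress = FALSE)
  invisible(files)
}
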