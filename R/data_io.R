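#' Read a pathway collection from a GMT file
#'
#' Parses tab-separated gene sets: one pathway per line with the pathway id
#' in the first field, a free-text description in the second, and member gene
#' identifiers in the remaining fields. Duplicate members within a line are
#' collapsed; pathways whose description matches an excluded name (exact,
#' case-insensitive) are dropped, which supports removing whole categories
#' such as disease gene sets from an analysis collection.
#'
#' @param path Path to a GMT file.
#' @param exclude_names Character vector of pathway names (descriptions) to
#'   drop, matched exactly and case-insensitively.
#' @param source Label recorded in the `source` column (defaults to the file
#'   name).
#' @param id_map Optional identifier map from [read_id_map()]; applied to the
#'   member genes. Unmapped identifiers are kept verbatim.
#'
#' @return A pathway collection: a tibble with columns `pathway_id`, `name`,
#'   `source` and a list-column `members` of character vectors.
#' @export
#' @examples
#' gmt <- tempfile(fileext = ".gmt")
#' writeLines(c("P1\tGlycolysis\tg1\tg2\tg2", "P2\tTCA cycle\tg2\tg3"), gmt)
#' read_pathways_gmt(gmt)
read_pathways_gmt <- function(path, exclude_names = character(),
                              source = basename(path), id_map = NULL) {
  if (!file.exists(path)) {
    abort(paste0("GMT file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    abort(paste0("GMT file is empty: ", path))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 3L)) {
    bad <- which(n_fields < 3L)[1L]
    abort(paste0(
      "Malformed GMT line ", bad, " in ", path,
      ": expected at least 3 tab-separated fields, found ", n_fields[bad]
    ))
  }
  pc <- tibble::tibble(
    pathway_id = vapply(fields, `[[`, character(1), 1L),
    name = vapply(fields, `[[`, character(1), 2L),
    source = source,
    members = lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  )
  if (anyDuplicated(pc$pathway_id)) {
    abort(paste0(
      "Duplicate pathway ids in ", path, ": ",
      paste(unique(pc$pathway_id[duplicated(pc$pathway_id)]), collapse = ", ")
    ))
  }
  if (length(exclude_names) > 0L) {
    pc <- pc[!(tolower(pc$name) %in% tolower(exclude_names)), , drop = FALSE]
  }
  if (!is.null(id_map)) {
    pc$members <- lapply(pc$members, function(m) unique(map_ids(m, id_map)))
  }
  if (any(lengths(pc$members) == 0L)) {
    abort("Every pathway must have at least one member gene")
  }
  validate_pathway_collection(pc)
}

validate_pathway_collection <- function(pc) {
  stopifnot(
    is.data.frame(pc),
    all(c("pathway_id", "name", "source", "members") %in% names(pc)),
    !anyDuplicated(pc$pathway_id),
    all(lengths(pc$members) > 0L)
  )
  tibble::as_tibble(pc)
}

.itype_levels <- c("reaction", "association", "binding", "tf_target")

#' Read a protein interaction table
#'
#' Reads a tab-separated edge table with mandatory columns `source`,
#' `target`, `directed` (0/1 or logical), `type` and `provenance`, plus an
#' optional `score` column carrying a confidence score in \[0,1\]. Rows with a
#' confidence score below `min_score` are excluded (scoreless rows, e.g.
#' curated reactions, always pass), self-loops are dropped, and duplicate
#' (source, target, type) rows are collapsed.
#'
#' @param path Path to the TSV file.
#' @param min_score Minimum confidence score; rows with `score < min_score`
#'   are dropped. Default 0.4.
#' @param id_map Optional identifier map from [read_id_map()].
#'
#' @return A tibble with columns `source`, `target`, `directed` (logical),
#'   `itype` and `provenance`.
#' @export
read_interaction_table <- function(path, min_score = 0.4, id_map = NULL) {
  it <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  mandatory <- c("source", "target", "directed", "type", "provenance")
  missing <- setdiff(mandatory, names(it))
  if (length(missing) > 0L) {
    abort(paste0("Interaction table ", path, " is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  bad_type <- setdiff(unique(it$type), .itype_levels)
  if (length(bad_type) > 0L) {
    abort(paste0("Unknown interaction type(s): ",
                 paste(bad_type, collapse = ", "),
                 ". Allowed: ", paste(.itype_levels, collapse = ", ")))
  }
  it$directed <- as.logical(as.integer(it$directed))
  if (anyNA(it$directed)) {
    abort("Column 'directed' must be 0/1 or TRUE/FALSE")
  }
  if ("score" %in% names(it)) {
    score <- suppressWarnings(as.numeric(it$score))
    it <- it[is.na(score) | score >= min_score, , drop = FALSE]
    it$score <- NULL
  }
  if (!is.null(id_map)) {
    it$source <- map_ids(it$source, id_map)
    it$target <- map_ids(it$target, id_map)
  }
  it <- it[it$source != it$target, , drop = FALSE]
  it <- dplyr::rename(it, itype = "type")
  it <- dplyr::distinct(it, .data$source, .data$target, .data$itype,
                        .keep_all = TRUE)
  tibble::as_tibble(it[, c("source", "target", "directed", "itype", "provenance")])
}

#' Read a per-gene statistics table
#'
#' Reads a tab-separated table with columns `gene_id` and `t` (the signed
#' moderated t-statistic from the upstream differential-expression analysis)
#' and optional `p` and `q` columns. When a gene appears more than once —
#' typically because several probes or source identifiers map to the same
#' unified id — the row with the largest absolute t is kept and a warning is
#' raised.
#'
#' @param path Path to the TSV file.
#' @param id_map Optional identifier map from [read_id_map()].
#'
#' @return A tibble with columns `gene_id`, `t` and (always present, possibly
#'   all-`NA`) `p` and `q`.
#' @export
read_gene_stats <- function(path, id_map = NULL) {
  gs <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("gene_id", "t") %in% names(gs))) {
    abort(paste0("Gene statistics table ", path,
                 " must have columns gene_id and t"))
  }
  t_num <- suppressWarnings(as.numeric(gs$t))
  if (anyNA(t_num)) {
    abort(paste0("Non-numeric t value at row ", which(is.na(t_num))[1L],
                 " of ", path))
  }
  gs$t <- t_num
  for (col in c("p", "q")) {
    gs[[col]] <- if (col %in% names(gs)) {
      suppressWarnings(as.numeric(gs[[col]]))
    } else {
      NA_real_
    }
  }
  if (!is.null(id_map)) {
    gs$gene_id <- map_ids(gs$gene_id, id_map)
  }
  if (anyDuplicated(gs$gene_id)) {
    dup <- unique(gs$gene_id[duplicated(gs$gene_id)])
    warn(paste0(length(dup), " duplicated gene id(s); keeping the row with ",
                "largest |t| for each (e.g. ", dup[1L], ")"))
    gs <- gs[order(-abs(gs$t)), , drop = FALSE]
    gs <- gs[!duplicated(gs$gene_id), , drop = FALSE]
  }
  tibble::as_tibble(gs[, c("gene_id", "t", "p", "q")])
}

#' Read a two-column identifier map
#'
#' A plain mapping table (columns `from`, `to`) applied at read time to
#' translate source-database identifiers into the unified namespace.
#'
#' @param path Path to a TSV with columns `from` and `to`.
#' @return A tibble with columns `from` and `to`.
#' @export
read_id_map <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("from", "to") %in% names(m))) {
    abort("Identifier map must have columns 'from' and 'to'")
  }
  tibble::as_tibble(m[, c("from", "to")])
}

map_ids <- function(ids, id_map) {
  idx <- match(ids, id_map$from)
  unmapped <- sum(is.na(idx) & !is.na(ids))
  if (unmapped > 0L) {
    inform(paste0(unmapped, " identifier(s) not in the map; kept verbatim"))
  }
  ifelse(is.na(idx), ids, id_map$to[idx])
}

#' Write cross-talk results as tables and Cytoscape-readable networks
#'
#' Emits, under a common file prefix: the pathway-pair table
#' (`<prefix>_pairs.tsv`), the path table (`<prefix>_paths.tsv`), the
#' pathway-level interaction network (`<prefix>_pathways.graphml` / `.sif`
#' plus a node attribute table) and the detailed pathway+protein network
#' (`<prefix>_detailed.graphml` / `.sif` plus a node attribute table). The
#' GraphML files carry node-type, enrichment and expression attributes so the
#' networks load into Cytoscape with their annotation intact.
#'
#' @param result A `crosstalk_result` from [run_all_pairs()] or
#'   [pathway_crosstalk()].
#' @param out_prefix Output path prefix; parent directory must exist or be
#'   creatable.
#' @param p_threshold Significance threshold for an edge in the pathway-level
#'   network (strict `<`). Default 0.001.
#' @param enrich Optional enrichment table from [gene_set_enrichment()].
#' @param stats Optional gene statistics table; adds per-gene `t` and `q`
#'   attributes to protein nodes of the detailed network.
#'
#' @return Invisibly, a character vector of the files written.
#' @export
write_network_files <- function(result, out_prefix, p_threshold = 0.001,
                                enrich = NULL, stats = NULL) {
  stopifnot(inherits(result, "crosstalk_result"))
  dir.create(dirname(out_prefix), showWarnings = FALSE, recursive = TRUE)

  pairs_out <- dplyr::select(
    result$pairs,
    source_pathway = "source_pathway", target_pathway = "target_pathway",
    score = "score", n_paths = "n_paths", p_value = "p_value",
    n_permutations = "n_permutations"
  )
  paths_out <- tibble::tibble(
    pair = paste(result$paths$source_pathway, result$paths$target_pathway,
                 sep = "->"),
    nodes = vapply(result$paths$nodes, paste, character(1), collapse = "|"),
    length = result$paths$length,
    n_intermediates = result$paths$n_intermediates,
    classification = result$paths$classification
  )
  files <- c(
    pairs = paste0(out_prefix, "_pairs.tsv"),
    paths = paste0(out_prefix, "_paths.tsv")
  )
  readr::write_tsv(pairs_out, files[["pairs"]], progress = FALSE)
  readr::write_tsv(paths_out, files[["paths"]], progress = FALSE)

  net <- build_pathway_network(result$pairs, enrich = enrich,
                               p_threshold = p_threshold)
  files <- c(files, write_one_network(net$graph, net$nodes,
                                      paste0(out_prefix, "_pathways"),
                                      label = "pathways",
                                      sif_relation = "crosstalk"))

  sig <- result$pairs[!is.na(result$pairs$p_value) &
                        result$pairs$p_value < p_threshold &
                        result$pairs$score > 0, , drop = FALSE]
  det <- extract_detailed_network(result, pairs = sig, stats = stats,
                                  enrich = enrich)
  files <- c(files, write_one_network(det$graph, det$nodes,
                                      paste0(out_prefix, "_detailed"),
                                      label = "detailed"))
  invisible(files)
}

# GraphML via igraph plus a hand-rolled SIF (three-column, Cytoscape dialect)
# and a node attribute TSV.
write_one_network <- function(graph, nodes, prefix, label,
                              sif_relation = NULL) {
  graphml <- paste0(prefix, ".graphml")
  sif <- paste0(prefix, ".sif")
  attrs <- paste0(prefix, "_nodes.tsv")
  igraph::write_graph(graph, graphml, format = "graphml")
  el <- igraph::as_edgelist(graph)
  rel <- if (is.null(sif_relation)) {
    if (igraph::ecount(graph) > 0) igraph::E(graph)$kind else character(0)
  } else {
    rep(sif_relation, nrow(el))
  }
  sif_lines <- if (nrow(el) > 0) {
    paste(el[, 1], rel, el[, 2], sep = "\t")
  } else {
    character(0)
  }
  # isolated nodes appear as bare names so Cytoscape still shows them
  isolated <- setdiff(igraph::V(graph)$name, as.vector(el))
  writeLines(c(sif_lines, isolated), sif)
  readr::write_tsv(nodes, attrs, progress = FALSE)
  setNames(c(graphml, sif, attrs),
           paste0(label, c("_graphml", "_sif", "_nodes")))
}
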