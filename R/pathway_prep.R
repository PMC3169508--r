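#' Overlap between two gene sets
#'
#' Fraction of shared members, with a configurable denominator. The default
#' relates the intersection to the smaller set, the most inclusive reading of
#' "percent overlap": a pathway fully contained in a larger one scores 1.
#'
#' @param a,b Non-empty character vectors of members (treated as sets).
#' @param denominator One of `"min"` (|a n b| / min(|a|,|b|), default),
#'   `"union"` (Jaccard) or `"mean"`.
#' @return A number in \[0, 1\].
#' @export
#' @examples
#' pairwise_overlap(c("g1", "g2", "g3", "g4"), c("g1", "g2", "g3", "g9"))
pairwise_overlap <- function(a, b, denominator = c("min", "union", "mean")) {
  denominator <- match.arg(denominator)
  a <- unique(a)
  b <- unique(b)
  if (length(a) == 0L || length(b) == 0L) {
    abort("pairwise_overlap() requires two non-empty sets")
  }
  inter <- length(intersect(a, b))
  denom <- switch(denominator,
    min = min(length(a), length(b)),
    union = length(union(a, b)),
    mean = (length(a) + length(b)) / 2
  )
  inter / denom
}

#' Merge pathways with high member overlap
#'
#' Collections assembled from several databases contain near-duplicate gene
#' sets describing the same biological process. This routine repeatedly scans
#' all pathway pairs and merges (member union) each pathway that has a
#' partner at or above the overlap threshold with its most-overlapping
#' partner, until no pair reaches the threshold. Within a round pathways are
#' processed in lexical id order and a pathway already consumed by an earlier
#' merge in the same round is skipped; ties in overlap are broken towards the
#' lexically smaller partner id, so the result does not depend on input
#' order. The merged id is the sorted concatenation of the constituent ids.
#'
#' @param pc A pathway collection (see [read_pathways_gmt()]).
#' @param threshold Overlap at or above which two pathways are merged.
#'   Default 0.75.
#' @param denominator Overlap denominator passed to [pairwise_overlap()].
#'
#' @return A `merge_report`: a list with `merged_collection` (a pathway
#'   collection), `lineage` (tibble mapping `merged_id` to each
#'   `original_id`) and `rounds` (number of scans performed, including the
#'   final scan that found nothing to merge).
#' @export
merge_overlapping_pathways <- function(pc, threshold = 0.75,
                                       denominator = c("min", "union", "mean")) {
  denominator <- match.arg(denominator)
  pc <- validate_pathway_collection(pc)
  stopifnot(threshold > 0, threshold <= 1)

  members <- setNames(pc$members, pc$pathway_id)
  meta <- setNames(pc$name, pc$pathway_id)
  src <- setNames(pc$source, pc$pathway_id)
  # current id -> original constituent ids
  lineage <- setNames(as.list(pc$pathway_id), pc$pathway_id)

  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    ids <- sort(names(members))
    merged_any <- FALSE
    consumed <- character(0)
    for (id in ids) {
      if (id %in% consumed || !id %in% names(members)) next
      others <- setdiff(names(members), c(id, consumed))
      if (length(others) == 0L) next
      ov <- vapply(others, function(o) {
        pairwise_overlap(members[[id]], members[[o]], denominator)
      }, numeric(1))
      if (max(ov) < threshold) next
      best <- sort(others[ov == max(ov)])[1L]
      new_members <- union(members[[id]], members[[best]])
      new_lineage <- c(lineage[[id]], lineage[[best]])
      new_id <- paste(sort(new_lineage), collapse = "+")
      new_name <- paste(sort(unique(c(meta[[id]], meta[[best]]))),
                        collapse = " + ")
      new_src <- paste(sort(unique(c(src[[id]], src[[best]]))), collapse = ";")
      members[[id]] <- NULL; members[[best]] <- NULL
      lineage[[id]] <- NULL; lineage[[best]] <- NULL
      meta <- meta[setdiff(names(meta), c(id, best))]
      src <- src[setdiff(names(src), c(id, best))]
      members[[new_id]] <- new_members
      lineage[[new_id]] <- new_lineage
      meta[[new_id]] <- new_name
      src[[new_id]] <- new_src
      consumed <- c(consumed, id, best, new_id)
      merged_any <- TRUE
    }
    if (!merged_any) break
  }

  ids <- names(members)
  merged <- tibble::tibble(
    pathway_id = ids,
    name = unname(meta[ids]),
    source = unname(src[ids]),
    members = unname(members[ids])
  )
  lineage_tbl <- tibble::tibble(
    merged_id = rep(ids, lengths(lineage[ids])),
    original_id = unlist(lineage[ids], use.names = FALSE)
  )
  structure(
    list(merged_collection = validate_pathway_collection(merged),
         lineage = lineage_tbl, rounds = rounds),
    class = "merge_report"
  )
}

#' @export
print.merge_report <- function(x, ...) {
  cat("Pathway merge report:", nrow(x$lineage), "pathways ->",
      nrow(x$merged_collection), "after", x$rounds, "round(s)\n")
  invisible(x)
}
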