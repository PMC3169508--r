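# |T| that the sigmoid maps to a requested weight, at default parameters
t_for_weight <- function(w, wp = weight_params()) {
  wp$mu + log(1 / w - 1) / wp$alpha
}

test_that("t_for_weight inverts the sigmoid", {
  expect_equal(sigmoid_weight(t_for_weight(0.2)), 0.2)
  expect_equal(sigmoid_weight(t_for_weight(0.45)), 0.45)
})

test_that("neighborhood radius counts every visited edge", {
  # Pn - x1 - x2 - x3 - x4 - Pm: the target pathway sits at hop 5
  g4 <- chain_fixture(4)
  nb5 <- neighborhood_subgraph(g4, "Pn", 5)
  expect_true("Pm" %in% igraph::V(nb5)$name)
  nb4 <- neighborhood_subgraph(g4, "Pn", 4)
  expect_false("Pm" %in% igraph::V(nb4)$name)
  # one more bridging protein pushes Pm out of reach at nb = 5
  g5 <- chain_fixture(5)
  expect_false("Pm" %in% igraph::V(neighborhood_subgraph(g5, "Pn", 5))$name)
  # degenerate radius
  nb0 <- neighborhood_subgraph(g4, "Pn", 0)
  expect_equal(igraph::V(nb0)$name, "Pn")
  expect_error(neighborhood_subgraph(g4, "NOPE", 5), "NOPE")
})

test_that("pair subgraph excludes members of third pathways", {
  pc <- make_collection(P1 = "a", P2 = "b", P3 = "m")
  it <- make_net(c("a", "m"), c("m", "b"))
  g <- build_weighted(pc, it, make_stats(c(a = 8, m = 8, b = 8)))
  sub <- pair_subgraph(neighborhood_subgraph(g, "P1", 5), "P1", "P2")
  expect_false("m" %in% igraph::V(sub)$name)
  expect_equal(nrow(find_nonredundant_shortest_paths(sub, "P1", "P2")), 0L)
  expect_error(pair_subgraph(neighborhood_subgraph(g, "P1", 5), "P1", "P1"),
               "undefined")
})

test_that("a shared protein with distinct partners still bridges the pair", {
  # A belongs to both pathways, B only to P1, E only to P2, with
  # interactions B-A and A-E. Removing the membership edge A->P2 blocks the
  # overlap-only route P1->A->P2, but A keeps acting as a bridge towards
  # P2's distinct partner E (P1->A->E->P2, with P1->B->A->E->P2 as the
  # longer alternative).
  pc <- make_collection(P1 = c("A", "B"), P2 = c("A", "E"))
  it <- make_net(c("B", "A"), c("A", "E"))
  g <- build_weighted(pc, it, make_stats(c(A = 8, B = 8, E = 8)))
  sub <- pair_subgraph(neighborhood_subgraph(g, "P1", 5), "P1", "P2")
  paths <- find_nonredundant_shortest_paths(sub, "P1", "P2")
  expect_equal(nrow(paths), 1L)
  expect_equal(paths$nodes[[1]], c("A", "E"))
  # no recovered path consists of the shared protein alone
  expect_false(any(vapply(paths$nodes, identical, logical(1), "A")))
  # the membership edge into the target pathway is gone from the subgraph
  expect_equal(igraph::get_edge_ids(sub, c("A", "P2")), 0)
})

test_that("a fully shared chain contributes no pathway interaction", {
  # Figure-4B-like topology: both shared proteins lack distinct partners
  pc <- make_collection(P1 = c("A", "B"), P2 = c("A", "B"))
  it <- make_net("A", "B")
  g <- build_weighted(pc, it, make_stats(c(A = 8, B = 8)))
  sub <- pair_subgraph(neighborhood_subgraph(g, "P1", 5), "P1", "P2")
  expect_equal(nrow(find_nonredundant_shortest_paths(sub, "P1", "P2")), 0L)
})

test_that("path lengths are summed edge weights and respect l_max", {
  pc <- make_collection(Pn = "x", Pm = "y")
  it <- make_net("x", "y")
  stats <- make_stats(c(x = t_for_weight(0.2), y = t_for_weight(0.3)))
  g <- build_weighted(pc, it, stats)
  sub <- pair_subgraph(neighborhood_subgraph(g, "Pn", 5), "Pn", "Pm")
  paths <- find_nonredundant_shortest_paths(sub, "Pn", "Pm", l_max = 0.9)
  expect_equal(nrow(paths), 1L)
  expect_equal(paths$length, 0.5)
  expect_equal(paths$nodes[[1]], c("x", "y"))
  expect_equal(paths$classification, "direct")

  # a single bridge of length 0.95 fails the cap
  stats2 <- make_stats(c(x = t_for_weight(0.475), y = t_for_weight(0.475)))
  g2 <- build_weighted(pc, it, stats2)
  sub2 <- pair_subgraph(neighborhood_subgraph(g2, "Pn", 5), "Pn", "Pm")
  expect_equal(nrow(find_nonredundant_shortest_paths(sub2, "Pn", "Pm", 0.9)),
               0L)
})

test_that("vertex-disjoint bridges are all recovered in ascending length", {
  pc <- make_collection(Pn = c("x1", "x2"), Pm = c("y1", "y2"))
  it <- make_net(c("x1", "x2"), c("y1", "y2"))
  stats <- make_stats(c(
    x1 = t_for_weight(0.2), y1 = t_for_weight(0.2),   # bridge of length 0.4
    x2 = t_for_weight(0.35), y2 = t_for_weight(0.35)  # bridge of length 0.7
  ))
  g <- build_weighted(pc, it, stats)
  sub <- pair_subgraph(neighborhood_subgraph(g, "Pn", 5), "Pn", "Pm")
  paths <- find_nonredundant_shortest_paths(sub, "Pn", "Pm", l_max = 0.9)
  expect_equal(nrow(paths), 2L)
  expect_equal(paths$length, c(0.4, 0.7))
  expect_equal(paths$nodes, list(c("x1", "y1"), c("x2", "y2")))
  # interior interaction edges of distinct paths never overlap
  interior <- lapply(paths$nodes, function(n) {
    if (length(n) > 1) paste(n[-length(n)], n[-1]) else character(0)
  })
  expect_equal(anyDuplicated(unlist(interior)), 0L)
})

test_that("interaction scores sum inverse lengths", {
  expect_equal(interaction_score(0.5), 2)
  expect_equal(interaction_score(c(0.3, 0.6)), 5)
  expect_equal(interaction_score(numeric(0)), 0)
  expect_error(interaction_score(c(0.5, 0)), "positive")
})

test_that("greedy path extraction matches the exhaustive oracle", {
  checked <- 0L
  for (seed in 1:60) {
    sub <- random_pair_problem(seed)
    if (is.null(sub)) next
    for (l_max in c(0.9, 1.5)) {
      got <- find_nonredundant_shortest_paths(sub, "Pn", "Pm", l_max)
      want <- oracle_nonredundant_paths(sub, "Pn", "Pm", l_max)
      expect_equal(nrow(got), length(want), info = paste("seed", seed))
      if (length(want) > 0) {
        expect_equal(got$nodes, lapply(want, `[[`, "nodes"),
                     info = paste("seed", seed))
        expect_equal(got$length, vapply(want, `[[`, numeric(1), "length"),
                     tolerance = 1e-9)
      }
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 40L)
})

test_that("pathway randomization preserves member count and the rest of the graph", {
  fix <- generate_fixture(fixture_spec(n_proteins = 60, n_pathways = 4,
                                       planted_pairs = tibble::tibble(
                                         source = "P01", target = "P02",
                                         n_bridges = 1L,
                                         bridge_indirect = FALSE,
                                         effect_T = 6),
                                       seed = 5))
  g <- build_weighted(fix$pathways, fix$network, fix$stats)
  strata <- xref_strength_strata(g)
  members <- sort(igraph::neighbors(g, "P02", mode = "out")$name)
  set.seed(1)
  g2 <- randomize_pathway(g, "P02", strata)
  members2 <- sort(igraph::neighbors(g2, "P02", mode = "out")$name)
  expect_equal(length(members2), length(members))
  expect_equal(anyDuplicated(members2), 0L)
  expect_false(any(members2 %in% members))
  # interaction edges and other pathways untouched
  expect_equal(sum(igraph::E(g2)$kind == "interaction"),
               sum(igraph::E(g)$kind == "interaction"))
  expect_equal(sort(igraph::neighbors(g2, "P01", mode = "out")$name),
               sort(igraph::neighbors(g, "P01", mode = "out")$name))
  # reciprocal membership with the usual weights
  eid <- igraph::get_edge_ids(g2, c("P02", members2[1], members2[1], "P02"))
  expect_equal(igraph::E(g2)$weight[eid[2]], 0)
  nw <- setNames(igraph::V(g2)$node_weight, igraph::V(g2)$name)
  expect_equal(igraph::E(g2)$weight[eid[1]], nw[[members2[1]]])
})

test_that("randomization draws replacements from the member's strength stratum", {
  # two clearly separated strength groups: a clique of strong nodes vs
  # sparsely connected weak nodes (all unmeasured, so edge weights are 1)
  strong <- sprintf("s%02d", 1:8)
  weak <- sprintf("w%02d", 1:8)
  cl <- t(utils::combn(strong, 2))
  wk <- cbind(weak[c(1, 3, 5, 7)], weak[c(2, 4, 6, 8)])
  pc <- make_collection(Pm = c(strong[1], weak[1]), Px = c(strong[2], weak[2]))
  it <- make_net(c(cl[, 1], wk[, 1]), c(cl[, 2], wk[, 2]))
  g <- build_weighted(pc, it, make_stats(c(dummy = 0)))
  strata <- xref_strength_strata(g)
  s_strong <- strata$strength[match(strong[1], strata$xref)]
  s_weak <- strata$strength[match(weak[1], strata$xref)]
  expect_gt(s_strong, 3 * s_weak)
  set.seed(42)
  hits <- replicate(500, {
    g2 <- randomize_pathway(g, "Pm", strata)
    repl <- igraph::neighbors(g2, "Pm", mode = "out")$name
    c(any(repl %in% strong), any(repl %in% weak))
  })
  expect_gte(mean(hits[1, ]), 0.95) # strong member replaced by a strong node
  expect_gte(mean(hits[2, ]), 0.95) # weak member replaced by a weak node
})

test_that("empirical p-values follow the pooled two-stage convention", {
  fix <- generate_fixture(fixture_spec(n_proteins = 60, n_pathways = 4,
                                       planted_pairs = tibble::tibble(
                                         source = "P01", target = "P02",
                                         n_bridges = 1L,
                                         bridge_indirect = FALSE,
                                         effect_T = 6),
                                       seed = 5))
  params <- core_params(n_perm_initial = 20, n_perm_extra = 30,
                        p_extend = 0.5, seed = 5, keep_null = TRUE)
  g <- build_weighted(fix$pathways, fix$network, fix$stats)
  res <- run_all_pairs(g, fix$pathways, params)
  scored <- res$pairs[res$pairs$score > 0, ]
  expect_gt(nrow(scored), 0)
  for (i in seq_len(nrow(scored))) {
    nulls <- scored$null_scores[[i]]
    expect_equal(scored$n_permutations[i], length(nulls))
    expect_true(scored$n_permutations[i] %in% c(20L, 50L))
    expect_equal(scored$p_value[i], mean(nulls >= scored$score[i]))
    # the pair was extended exactly when its first-stage p fell below 0.5
    p1 <- mean(nulls[1:20] >= scored$score[i])
    expect_equal(scored$n_permutations[i] == 50L, p1 < 0.5)
  }
  # unscored pairs: p = 1 by the ties-count convention, no permutations spent
  unscored <- res$pairs[res$pairs$score == 0, ]
  expect_true(all(unscored$p_value == 1))
  expect_true(all(unscored$n_permutations == 0L))
})

test_that("identical seeds reproduce the full result exactly", {
  fix <- generate_fixture(fixture_spec(n_proteins = 60, n_pathways = 4,
                                       planted_pairs = tibble::tibble(
                                         source = "P01", target = "P02",
                                         n_bridges = 1L,
                                         bridge_indirect = FALSE,
                                         effect_T = 6),
                                       seed = 5))
  g <- build_weighted(fix$pathways, fix$network, fix$stats)
  params <- core_params(n_perm_initial = 15, n_perm_extra = 15, seed = 77)
  r1 <- run_all_pairs(g, fix$pathways, params)
  r2 <- run_all_pairs(g, fix$pathways, params)
  expect_equal(r1$pairs, r2$pairs)
  expect_equal(r1$paths, r2$paths)
})

test_that("directed bridges produce directed cross-talk", {
  pc <- make_collection(Pn = "a", Pm = "b")
  it <- make_net("a", "b", directed = TRUE, itype = "tf_target")
  g <- build_weighted(pc, it, make_stats(c(a = 8, b = 8)))
  params <- core_params(n_perm_initial = 5, n_perm_extra = 0, seed = 1)
  res <- run_all_pairs(g, pc, params)
  fwd <- res$pairs[res$pairs$source_pathway == "Pn", ]
  rev <- res$pairs[res$pairs$source_pathway == "Pm", ]
  expect_gt(fwd$score, 0)
  expect_equal(rev$score, 0)
  expect_equal(nrow(res$pairs), 2L)
})

test_that("an unregulated dataset yields no admissible paths", {
  # with all |T| = 0 every interaction step weighs ~0.9975, so even the
  # shortest two-step route is ~1.995 > l_max
  fix <- generate_fixture(fixture_spec(n_proteins = 60, n_pathways = 4,
                                       planted_pairs = tibble::tibble(
                                         source = "P01", target = "P02",
                                         n_bridges = 1L,
                                         bridge_indirect = FALSE,
                                         effect_T = 0),
                                       background_T_sd = 0, seed = 5))
  g <- build_weighted(fix$pathways, fix$network, fix$stats)
  res <- run_all_pairs(g, fix$pathways,
                       core_params(n_perm_initial = 5, n_perm_extra = 0,
                                   seed = 1))
  expect_equal(nrow(res$pairs), 12L) # 4 * 3 ordered pairs evaluated
  expect_true(all(res$pairs$score == 0))
  expect_true(all(res$pairs$p_value == 1))
})
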