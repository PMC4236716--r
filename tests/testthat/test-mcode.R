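test_that("vertex weights match brute-force k-core oracles", {
  cl5 <- igraph::make_full_graph(5)
  igraph::V(cl5)$name <- letters[1:5]
  expect_equal(mcode_vertex_weight(cl5, "a"), 4.0)
  expect_equal(oracle_vertex_weight(cl5, "a"), 4.0)

  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", paste0("l", 1:4))
  expect_equal(mcode_vertex_weight(star, "hub"), 0.4)
  expect_equal(oracle_vertex_weight(star, "hub"), 0.4)
  expect_equal(mcode_vertex_weight(star, "l1"), 0)   # degree below threshold

  g <- random_connected_graph_seeded(40, seed = 15, extra = 80)
  w <- mcode_vertex_weights(g)
  for (v in igraph::V(g)$name) {
    expect_equal(unname(w[v]), oracle_vertex_weight(g, v), tolerance = 1e-12)
  }
})

test_that("cliques joined through a bridge vertex are split into two modules", {
  mods <- mcode(bridged_six_cliques())
  expect_length(mods, 2L)
  expect_equal(vapply(mods, `[[`, 1.0, "score"), c(6, 6))
  expect_setequal(unlist(lapply(mods, `[[`, "members")),
                  c(paste0("a", 1:6), paste0("b", 1:6)))
})

test_that("a direct bridge edge merges the two cliques (greedy expansion dialect)", {
  c1 <- igraph::make_full_graph(6); igraph::V(c1)$name <- paste0("a", 1:6)
  c2 <- igraph::make_full_graph(6); igraph::V(c2)$name <- paste0("b", 1:6)
  g <- igraph::add_edges(igraph::disjoint_union(c1, c2), c("a1", "b1"))
  mods <- mcode(g)
  # both bridge endpoints carry full clique weight (5), which passes the
  # 0.8 * 5 expansion gate, so the greedy pass absorbs both cliques
  expect_length(mods, 1L)
  expect_length(mods[[1]]$members, 12L)
  expect_equal(mods[[1]]$score, 31 / 66 * 12, tolerance = 1e-12)
})

test_that("pendant vertices never enter and haircut trims singly-connected tails", {
  cl <- igraph::make_full_graph(6)
  igraph::V(cl)$name <- paste0("a", 1:6)
  gp <- igraph::add_vertices(cl, 1, name = "p")
  gp <- igraph::add_edges(gp, c("a1", "p"))
  mods <- mcode(gp)
  expect_length(mods, 1L)
  expect_setequal(mods[[1]]$members, paste0("a", 1:6))
  expect_equal(mods[[1]]$score, 6)

  # low-weight tail vertex p (a1-p-q) is admitted under a permissive score
  # threshold (q stays out: degree 1 is below the degree threshold), then
  # the 2-core haircut removes p again
  gt <- igraph::add_vertices(cl, 2, name = c("p", "q"))
  gt <- igraph::add_edges(gt, c("a1", "p", "p", "q"))
  loose <- mcode_params(node_score_threshold = 0.9)
  with_hair <- mcode(gt, loose)
  expect_setequal(with_hair[[1]]$members, paste0("a", 1:6))
  no_hair <- mcode(gt, mcode_params(node_score_threshold = 0.9, haircut = FALSE))
  expect_setequal(no_hair[[1]]$members, c(paste0("a", 1:6), "p"))
})

test_that("planted cliques in a scale-free background are recovered", {
  p <- generator_params(module_size = 8, module_size_step = 0, seed = 37)
  pl <- plant_modules(generate_ppi(p), p)
  mods <- mcode(pl$network)
  expect_gte(length(mods), 3L)
  top3 <- lapply(mods[1:3], `[[`, "members")
  for (truth in pl$modules) {
    expect_gte(max(vapply(top3, jaccard, 1.0, truth)), 0.75)
  }
})

test_that("modules are disjoint, 2-core-containing and deterministically ranked", {
  g <- generate_ppi(generator_params(n_proteins = 400, attachment_edges = 3,
                                     seed = 51))
  mods <- mcode(g)
  members <- unlist(lapply(mods, `[[`, "members"))
  expect_equal(anyDuplicated(members), 0L)
  for (m in mods) {
    sub <- igraph::induced_subgraph(g, m$members)
    expect_gte(max(igraph::coreness(sub)), 2)
    expect_true(all(igraph::degree(sub) >= 2))   # haircut left a 2-core
  }
  scores <- vapply(mods, `[[`, 1.0, "score")
  expect_true(all(diff(scores) <= 1e-12))
  expect_identical(mcode(g), mods)

  expect_error(mcode(g, mcode_params(fluff = TRUE)), "not implemented")
})

test_that("raising the score threshold never shrinks the seed module", {
  g <- generate_ppi(generator_params(n_proteins = 300, attachment_edges = 3,
                                     seed = 61))
  sizes <- vapply(c(0.1, 0.2, 0.4, 0.6, 0.8), function(vwp) {
    mods <- mcode(g, mcode_params(node_score_threshold = vwp, haircut = FALSE))
    w <- mcode_vertex_weights(g)
    top_seed <- names(which.max(w))[1]
    m <- Filter(function(x) x$seed_node == top_seed, mods)
    if (length(m) == 0) 0L else length(m[[1]]$members)
  }, 1L)
  expect_true(all(diff(sizes) >= 0))
})
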