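test_that("eigenvector centrality matches closed forms on small graphs", {
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("A", "B", "C")
  expect_equal(unname(eigenvector_centrality(tri)), rep(1 / sqrt(3), 3),
               tolerance = 1e-9)

  path <- igraph::make_graph(~ A - B, B - C)
  expect_equal(unname(eigenvector_centrality(path)[c("A", "B", "C")]),
               c(0.5, sqrt(0.5), 0.5), tolerance = 1e-9)

  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", paste0("leaf", 1:4))
  evc <- eigenvector_centrality(star)
  expect_equal(unname(evc["hub"]), sqrt(0.5), tolerance = 1e-9)
  expect_equal(unname(evc["leaf1"]), sqrt(0.5) / 2, tolerance = 1e-9)
})

test_that("power iteration agrees with a dense eigensolver on random graphs", {
  withr::with_seed(41, {
    for (i in 1:30) {
      g <- random_connected_graph(sample(5:50, 1))
      expect_lt(max(abs(eigenvector_centrality(g) - oracle_evc(g))), 1e-8)
    }
  })
  # bipartite graph: the diagonal shift must prevent oscillation
  bip <- igraph::make_full_bipartite_graph(3, 4)
  igraph::V(bip)$name <- letters[1:7]
  expect_lt(max(abs(eigenvector_centrality(bip) - oracle_evc(bip))), 1e-8)
})

test_that("centrality scores are nonnegative and L2-normalized", {
  withr::with_seed(8, {
    g <- random_connected_graph(80)
    evc <- eigenvector_centrality(g)
    expect_true(all(evc >= 0))
    expect_equal(sum(evc^2), 1, tolerance = 1e-8)
  })
})

test_that("degree-preserving randomization conserves every node's degree", {
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("A", "B", "C")
  expect_same_graph(degree_preserving_randomize(tri, seed = 1), tri)

  g <- generate_ppi(generator_params(seed = 6))
  deg <- igraph::degree(g)
  r1 <- degree_preserving_randomize(g, seed = 10)
  expect_identical(igraph::degree(r1)[names(deg)], deg)
  expect_false(igraph::any_multiple(r1))
  expect_false(igraph::any_loop(r1))
  # determinism and seed-to-seed mixing
  expect_same_graph(degree_preserving_randomize(g, seed = 10), r1)
  r2 <- degree_preserving_randomize(g, seed = 11)
  shared <- nrow(merge(as.data.frame(spanet:::.edge_table(r1)),
                       as.data.frame(spanet:::.edge_table(r2))))
  expect_gte(1 - shared / igraph::ecount(g), 0.10)
})

test_that("ensembles are complete, aligned and reproducible", {
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("A", "B", "C")
  ens <- build_evc_ensemble(tri, R = 5, seed = 2)
  expect_equal(dim(ens$samples), c(3L, 5L))
  # the triangle is rewiring-invariant, so every sample equals the observed
  expect_equal(ens$samples, matrix(rep(ens$observed, 5), nrow = 3,
                                   dimnames = dimnames(ens$samples)),
               tolerance = 1e-12)

  g <- random_connected_graph_seeded(40, seed = 3)
  e1 <- build_evc_ensemble(g, R = 10, seed = 4)
  e2 <- build_evc_ensemble(g, R = 10, seed = 4)
  expect_identical(e1$samples, e2$samples)
})

test_that("tuning follows the degenerate zero-variance rules", {
  obs <- c(a = 0.6, b = 0.8)
  samples <- rbind(a = rep(0.6, 10), b = rep(0.5, 10))
  ens <- structure(list(observed = obs, samples = samples, R = 10L),
                   class = "evc_ensemble")
  g <- igraph::make_graph(~ a - b)
  rec <- tune_network(g, ens, alpha = 1e-4)$records
  expect_false(rec$retained[rec$node == "a"])   # samples equal observed
  expect_true(rec$retained[rec$node == "b"])    # constant but different
  expect_equal(rec$p_value[rec$node == "a"], 1)
  expect_equal(rec$p_value[rec$node == "b"], 0)
})

test_that("a 10-sigma departure is retained at alpha = 1e-4 with R = 100", {
  withr::with_seed(5, {
    x <- stats::rnorm(100, mean = 0.5, sd = 0.01)
    x <- 0.5 + (x - mean(x)) / stats::sd(x) * 0.01   # exact mean/sd
    obs <- c(v = 0.5 + 10 * 0.01, w = 0.5)
    samples <- rbind(v = x, w = x)
    ens <- structure(list(observed = obs, samples = samples, R = 100L),
                     class = "evc_ensemble")
    g <- igraph::make_graph(~ v - w)
    rec <- tune_network(g, ens, alpha = 1e-4)$records
    expect_true(rec$retained[rec$node == "v"])
    expect_false(rec$retained[rec$node == "w"])
  })
})

test_that("tuned network is a subgraph and retention shrinks with alpha", {
  g <- random_connected_graph_seeded(60, seed = 12)
  ens <- build_evc_ensemble(g, R = 30, seed = 13)
  kept <- vapply(c(0.1, 0.01, 1e-3, 1e-4, 1e-5), function(a) {
    res <- tune_network(g, ens, alpha = a)
    expect_true(all(igraph::V(res$network)$name %in% igraph::V(g)$name))
    sum(res$records$retained)
  }, 1L)
  expect_true(all(diff(kept) <= 0))
})

test_that("retention decisions match an independent t-test re-implementation", {
  b <- synthetic_benchmark(small_benchmark_params(seed = 23))
  el <- igraph::as_edgelist(b$network)
  etn <- spa_reconstruct(b$core_proteins, b$annotations,
                         data.frame(protein_a = el[, 1], protein_b = el[, 2]))
  ens <- build_evc_ensemble(etn, R = 50, seed = 29)
  rec <- tune_network(etn, ens, alpha = 1e-4)$records
  want <- oracle_retained(ens, alpha = 1e-4)
  names(want) <- names(ens$observed)
  expect_identical(stats::setNames(rec$retained, rec$node)[names(want)], want)
})
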