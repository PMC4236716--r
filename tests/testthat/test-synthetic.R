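test_that("preferential-attachment interactome is deterministic, simple and heavy-tailed", {
  p <- generator_params(seed = 5)
  g1 <- generate_ppi(p)
  g2 <- generate_ppi(p)
  expect_same_graph(g1, g2)
  expect_true(igraph::is_connected(g1))
  expect_false(igraph::any_loop(g1))
  deg <- igraph::degree(g1)
  expect_equal(sum(deg), 2 * igraph::ecount(g1))   # handshake lemma
  expect_gte(max(deg), 5 * stats::median(deg))
})

test_that("degree distribution of a 2000-node interactome has a power-law tail", {
  g <- generate_ppi(generator_params(n_proteins = 2000, seed = 2))
  tab <- table(igraph::degree(g))
  k <- as.numeric(names(tab))
  keep <- k >= 2
  fit <- stats::lm(log10(as.numeric(tab)[keep]) ~ log10(k[keep]))
  slope <- unname(stats::coef(fit)[2])
  expect_gte(slope, -3.5)
  expect_lte(slope, -1.5)
})

test_that("planted modules are disjoint cliques with bounded bridges", {
  p <- generator_params(seed = 9)
  pl <- plant_modules(generate_ppi(p), p)
  sizes <- vapply(pl$modules, length, 1L)
  expect_equal(sizes, c(8L, 9L, 10L))
  all_members <- unlist(pl$modules)
  expect_equal(anyDuplicated(all_members), 0L)
  for (mod in pl$modules) {
    sub <- igraph::induced_subgraph(pl$network, mod)
    n <- igraph::vcount(sub)
    expect_equal(igraph::ecount(sub), n * (n - 1) / 2)   # clique completion
    deg_total <- sum(igraph::degree(pl$network, mod))
    bridges <- deg_total - 2 * igraph::ecount(sub)
    expect_gte(bridges, 1)
    expect_lte(bridges, floor(n / 2))
  }
  expect_error(
    plant_modules(generate_ppi(generator_params(n_proteins = 20)),
                  generator_params(n_proteins = 20, n_planted_modules = 2,
                                   module_size = 6)),
    "half")
})

test_that("annotation generator plants a permissible truth of the right size", {
  p <- generator_params(seed = 3)
  b <- synthetic_benchmark(p)
  table <- build_annotation_table(b$core_proteins, b$annotations)
  # pooled table covers the core vocabulary exactly
  expect_equal(table$component_terms, b$core_vocabulary[[1]])
  expect_equal(table$function_terms, b$core_vocabulary[[2]])
  expect_equal(table$process_terms, b$core_vocabulary[[3]])
  # every core and exactly the planted permissible proteins pass the rule
  pass <- names(b$annotations)[
    vapply(b$annotations, is_permissible, TRUE, table = table)]
  expect_setequal(pass, b$permissible_truth)

  p2 <- generator_params(n_proteins = 1000, permissible_fraction = 0.3, seed = 8)
  b2 <- synthetic_benchmark(p2)
  n_noncore_perm <- length(setdiff(b2$permissible_truth, b2$core_proteins))
  expect_gte(n_noncore_perm, 0.95 * 0.3 * 1000 - 0.3 * p2$n_cores)
  expect_lte(n_noncore_perm, 1.05 * 0.3 * 1000)
})

test_that("unknown-function proteins are root-only in modules, unannotated outside", {
  b <- synthetic_benchmark(generator_params(seed = 4))
  expect_length(b$unknown_truth, round(0.01 * 500))
  module_nodes <- unlist(b$planted_modules)
  for (u in b$unknown_truth) {
    terms <- b$annotations[[u]]$process_terms
    if (u %in% module_nodes) {
      expect_identical(terms, GO_BP_ROOT)
    } else {
      expect_length(terms, 0)
    }
  }
  in_modules <- vapply(b$planted_modules,
                       function(m) sum(m %in% b$unknown_truth), 1L)
  expect_true(all(in_modules == 1L))
})

test_that("expression generator plants active-TF signal and is calibrated under the null", {
  genes <- sprintf("g%04d", 1:5000)
  regnet <- data.frame(tf = "TF1", target = genes[1:40])
  p_hot <- generate_expression(regnet, "TF1", genes, effect = 8, seed = 2)
  expect_lt(stats::median(p_hot[genes[1:40]]), 1e-6)

  p_null <- generate_expression(regnet, character(), genes, effect = 4, seed = 2)
  ks <- stats::ks.test(p_null, "punif")
  expect_gt(ks$p.value, 0.01)

  expect_identical(generate_expression(regnet, "TF1", genes, 4, seed = 7),
                   generate_expression(regnet, "TF1", genes, 4, seed = 7))
  expect_error(generate_expression(regnet, "TF1", genes, effect = 0), "effect")
})

test_that("full benchmark satisfies its declared invariants and is reproducible", {
  p <- generator_params(seed = 21)
  b1 <- synthetic_benchmark(p)
  expect_true(validate_benchmark(b1))
  b2 <- synthetic_benchmark(p)
  expect_same_graph(b1$network, b2$network)
  expect_identical(b1$gene_pvalues, b2$gene_pvalues)
  expect_identical(b1$permissible_truth, b2$permissible_truth)
})

test_that("benchmark files round-trip through the package readers", {
  b <- synthetic_benchmark(small_benchmark_params())
  d <- withr::local_tempdir()
  write_benchmark(b, d)
  g <- read_network(file.path(d, "ppi.tsv"))
  expect_same_graph(g, b$network)
  ann <- read_gaf(file.path(d, "annotations.gaf"))
  nonempty <- names(b$annotations)[vapply(b$annotations, function(a)
    length(unlist(a)) > 0, TRUE)]
  expect_setequal(names(ann), nonempty)
  expect_identical(read_id_list(file.path(d, "cores.txt")), b$core_proteins)
  p <- read_pvalues(file.path(d, "pvalues.tsv"))
  expect_equal(unname(p[names(b$gene_pvalues)]), unname(b$gene_pvalues),
               tolerance = 1e-12)
})
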