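test_that("hypergeometric upper tail matches exhaustive summation", {
  expect_equal(hypergeometric_p(5, 5, 5, 5), 1.0)
  expect_equal(hypergeometric_p(0, 5, 10, 50), 1.0)
  expect_equal(hypergeometric_p(3, 5, 5, 50), oracle_hyper(3, 5, 5, 50),
               tolerance = 1e-12)

  withr::with_seed(71, {
    for (i in 1:200) {
      N <- sample(2:200, 1)
      K <- sample.int(N, 1)
      n <- sample.int(N, 1)
      k <- sample(0:min(n, K), 1)
      p <- hypergeometric_p(k, n, K, N)
      o <- oracle_hyper(k, n, K, N)
      expect_lt(abs(p - o) / max(o, .Machine$double.xmin), 1e-10)
    }
  })
  expect_error(hypergeometric_p(6, 5, 5, 50), "bounds")
})

test_that("BH adjustment reproduces hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  withr::with_seed(5, {
    p <- stats::runif(50)
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p))
  })
  # re-adjustment is the identity on tied adjusted families but not on
  # arbitrary monotone inputs: the step-up factor m/i re-scales them
  expect_equal(bh_adjust(c(0.03, 0.03, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.5, 1)), c(1, 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("module enrichment flags planted terms and skips small modules", {
  N <- 100
  prots <- sprintf("p%03d", 1:N)
  ann <- stats::setNames(lapply(seq_len(N), function(i) {
    terms <- "GO:0000100"            # shared background term
    if (i <= 5) terms <- c(terms, "GO:0000200")
    annotation_set("GO:0000001", "GO:0000002", terms)
  }), prots)
  mod5 <- list(members = prots[1:5], seed_node = prots[1], score = 5, rank = 1L)
  res <- enrich_modules(list(mod5), ann, reference = prots, alpha = 1e-4)
  hit <- res[res$term == "GO:0000200", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$k, 5L)
  expect_equal(hit$K, 5L)
  expect_equal(hit$p_value, 1 / choose(100, 5), tolerance = 1e-12)
  # the universally shared term is not enriched
  expect_false("GO:0000100" %in% res$term)

  mod4 <- list(members = prots[1:4], seed_node = prots[1], score = 4, rank = 1L)
  expect_equal(nrow(enrich_modules(list(mod4), ann, prots)), 0L)
})

test_that("modules matching reference proportions yield no significant record", {
  N <- 60
  prots <- sprintf("q%02d", 1:N)
  # term carried by exactly half of every stratum
  ann <- stats::setNames(lapply(seq_len(N), function(i) {
    annotation_set("GO:0000001", "GO:0000002",
                   if (i %% 2 == 0) c("GO:0000300", "GO:0000100") else "GO:0000100")
  }), prots)
  mod <- list(members = prots[1:10], seed_node = prots[1], score = 1, rank = 1L)
  res <- enrich_modules(list(mod), ann, prots, alpha = 1e-4)
  expect_equal(nrow(res), 0L)
})

test_that("enrichment is invariant under module-member reordering", {
  b <- synthetic_benchmark(small_benchmark_params(seed = 43))
  mods <- mcode(b$network)
  ref <- igraph::V(b$network)$name
  r1 <- enrich_modules(mods, b$annotations, ref, alpha = 0.05)
  mods_shuffled <- lapply(mods, function(m) {
    m$members <- withr::with_seed(9, sample(m$members))
    m
  })
  r2 <- enrich_modules(mods_shuffled, b$annotations, ref, alpha = 0.05)
  expect_equal(r1, r2)
})

test_that("unknown-function candidates are extracted with their reason", {
  mods <- list(list(members = sprintf("m%d", 1:6), seed_node = "m1",
                    score = 6, rank = 1L))
  ann <- list(
    m1 = annotation_set("c", "f", "GO:0000010"),
    m2 = annotation_set("c", "f", character()),
    m3 = annotation_set("c", "f", spanet::GO_BP_ROOT),
    m4 = annotation_set("c", "f", c(spanet::GO_BP_ROOT, "GO:0000010")),
    m5 = annotation_set("c", "f", "GO:0000011"),
    m6 = annotation_set("c", "f", "GO:0000012"))
  cand <- unknown_function_candidates(mods, ann)
  expect_equal(cand$protein, c("m2", "m3"))
  expect_equal(cand$reason, c("no_process_annotation", "root_only"))
})

test_that("planted unknown-function proteins are recovered exactly", {
  b <- synthetic_benchmark(generator_params(seed = 47))
  mods <- mcode(b$network)
  cand <- unknown_function_candidates(mods, b$annotations)
  in_modules <- intersect(b$unknown_truth,
                          unlist(lapply(Filter(function(m)
                            length(m$members) >= 5, mods), `[[`, "members")))
  expect_setequal(cand$protein, in_modules)
  expect_gt(nrow(cand), 0L)
  expect_true(all(cand$reason == "root_only"))
  # the planted complexes are functionally coherent: with the whole network
  # annotation as reference, each large module carries enriched process terms
  ref <- igraph::V(b$network)$name
  enr <- enrich_modules(mods, b$annotations, ref, alpha = 1e-4, min_size = 5)
  big_ranks <- vapply(Filter(function(m) length(m$members) >= 8, mods),
                      `[[`, 1L, "rank")
  expect_true(all(big_ranks %in% enr$module_rank))
})
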