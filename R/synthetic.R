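# Synthetic benchmark: a scale-free interactome with planted dense modules,
# a three-aspect annotation vocabulary whose core sub-vocabulary defines the
# ground-truth permissible set, a TF->target regulome with planted active
# regulators, and gene-level expression p-values. Every pipeline stage has a
# known truth to recover, so the whole analysis is testable offline.

#' Parameters of the synthetic benchmark generator
#'
#' Defaults describe the study conditions the package is validated under: a
#' 500-protein preferential-attachment interactome with 3 planted 8-cliques,
#' 14 core proteins (the size of the literature-curated seed set the method
#' was published with), a 130-term core vocabulary inside a 400-term GO-like
#' vocabulary (mirroring the published 130-term annotation collection
#' table), 30% permissible non-core proteins, 1% unknown-function proteins,
#' and a 20-TF regulome with 3 active TFs of effect size 4.
#'
#' @param n_proteins Number of proteins in the interactome.
#' @param attachment_edges Edges added per node during preferential
#'   attachment (must be < `n_proteins`).
#' @param n_aspect_terms Integer vector of 3: vocabulary size per GO aspect
#'   (C, F, P).
#' @param core_vocab_terms Integer vector of 3: size of the core (seed)
#'   vocabulary per aspect; must be <= `n_aspect_terms` componentwise.
#' @param permissible_fraction Fraction of non-core proteins constructed to
#'   satisfy the permissibility rule.
#' @param n_planted_modules,module_size Number and base size (>= 5) of
#'   planted cliques.
#' @param module_size_step Size increment between successive planted
#'   cliques (module i has `module_size + (i - 1) * module_size_step`
#'   members). The default 1 plants complexes of graded sizes, as real
#'   protein complexes vary in size; equal-size cliques (`step = 0`) make
#'   the network's dominant eigenpair nearly degenerate, which leaves
#'   eigenvector centrality ill-conditioned.
#' @param n_cores Number of core (seed) proteins.
#' @param n_tfs,targets_per_tf,n_active_tfs Regulome shape.
#' @param active_tf_effect Noncentrality of the expression signal on active
#'   TF targets (> 0).
#' @param unknown_fraction Fraction of proteins with an empty
#'   biological-process annotation (candidate ground truth).
#' @param seed Integer master seed.
#' @return Validated list of class `generator_params`.
#' @export
generator_params <- function(n_proteins = 500,
                             attachment_edges = 2,
                             n_aspect_terms = c(60, 120, 220),
                             core_vocab_terms = c(10, 40, 80),
                             permissible_fraction = 0.3,
                             n_planted_modules = 3,
                             module_size = 8,
                             module_size_step = 1,
                             n_cores = 14,
                             n_tfs = 20,
                             targets_per_tf = 30,
                             n_active_tfs = 3,
                             active_tf_effect = 4,
                             unknown_fraction = 0.01,
                             seed = 1L) {
  p <- list(
    n_proteins = .check_count(n_proteins, "n_proteins", min = 10L),
    attachment_edges = .check_count(attachment_edges, "attachment_edges"),
    n_aspect_terms = vapply(seq_len(3L), function(i)
      .check_count(n_aspect_terms[i], "n_aspect_terms"), 1L),
    core_vocab_terms = vapply(seq_len(3L), function(i)
      .check_count(core_vocab_terms[i], "core_vocab_terms"), 1L),
    permissible_fraction = .check_fraction(permissible_fraction, "permissible_fraction"),
    n_planted_modules = .check_count(n_planted_modules, "n_planted_modules", min = 0L),
    module_size = .check_count(module_size, "module_size", min = 5L),
    module_size_step = .check_count(module_size_step, "module_size_step", min = 0L),
    n_cores = .check_count(n_cores, "n_cores"),
    n_tfs = .check_count(n_tfs, "n_tfs"),
    targets_per_tf = .check_count(targets_per_tf, "targets_per_tf"),
    n_active_tfs = .check_count(n_active_tfs, "n_active_tfs", min = 0L),
    active_tf_effect = active_tf_effect,
    unknown_fraction = .check_fraction(unknown_fraction, "unknown_fraction"),
    seed = .check_count(seed, "seed", min = 0L)
  )
  if (p$attachment_edges >= p$n_proteins) {
    stop("attachment_edges must be smaller than n_proteins")
  }
  if (any(p$core_vocab_terms > p$n_aspect_terms)) {
    stop("core vocabulary cannot exceed the aspect vocabulary")
  }
  if (sum(.module_sizes(p)) > p$n_proteins / 2) {
    stop("planted modules may cover at most half of the proteins")
  }
  if (p$active_tf_effect <= 0) stop("active_tf_effect must be > 0")
  if (p$n_active_tfs > p$n_tfs) stop("n_active_tfs cannot exceed n_tfs")
  structure(p, class = "generator_params")
}

.protein_ids <- function(n) sprintf("YP%04d", seq_len(n))

.module_sizes <- function(params) {
  if (params$n_planted_modules == 0L) return(integer())
  params$module_size +
    (seq_len(params$n_planted_modules) - 1L) * params$module_size_step
}

#' Scale-free interactome by preferential attachment
#'
#' Grows a simple, connected, undirected graph by preferential attachment
#' (`attachment_edges` edges per incoming node), giving the heavy-tailed
#' degree distribution characteristic of interactomes.
#'
#' @param params A [generator_params()] list (uses `n_proteins`,
#'   `attachment_edges`, `seed`).
#' @return A named `igraph` graph.
#' @export
generate_ppi <- function(params = generator_params()) {
  g <- withr::with_seed(params$seed,
    igraph::sample_pa(params$n_proteins, m = params$attachment_edges,
                      directed = FALSE))
  g <- igraph::simplify(g)
  igraph::V(g)$name <- .protein_ids(params$n_proteins)
  g
}

#' Plant dense modules (cliques) into a network
#'
#' Selects `n_planted_modules` disjoint node sets of graded sizes
#' (`module_size`, `module_size + module_size_step`, ...; see
#' [generator_params()]), avoiding the strongest hubs so the background
#' stays intact, completes
#' each set to a clique, and prunes each set's edges to the rest of the
#' graph down to between 1 and `module_size / 2` bridge edges. Connectivity
#' of the host graph is repaired afterwards by re-attaching any stranded
#' component through one of its non-module nodes.
#'
#' @param network Host `igraph` graph.
#' @param params A [generator_params()] list.
#' @return List with `network` (modified graph) and `modules` (list of
#'   member-name character vectors).
#' @export
plant_modules <- function(network, params = generator_params()) {
  k <- params$n_planted_modules
  sizes <- .module_sizes(params)
  if (k == 0L) return(list(network = network, modules = list()))
  if (sum(sizes) > igraph::vcount(network) / 2) {
    stop("not enough nodes to plant disjoint modules")
  }
  withr::with_seed(.stage_seed(params$seed, 1L), {
    deg <- igraph::degree(network)
    eligible <- igraph::V(network)$name[order(deg)][
      seq_len(floor(0.8 * igraph::vcount(network)))]
    picked <- sample(eligible, sum(sizes))
    modules <- split(picked, rep(seq_len(k), times = sizes))
    modules <- lapply(modules, sort)

    for (mod in modules) {
      size <- length(mod)
      ids <- match(mod, igraph::V(network)$name)
      # complete the module to a clique
      pairs <- t(combn(ids, 2L))
      have <- igraph::get_edge_ids(network, t(pairs), error = FALSE)
      new_pairs <- pairs[have == 0L, , drop = FALSE]
      if (nrow(new_pairs) > 0L) {
        network <- igraph::add_edges(network, t(new_pairs))
      }
      # prune external edges down to the bridge budget
      inc <- sort(unique(unlist(igraph::incident_edges(network, ids))))
      ends <- igraph::ends(network, inc, names = TRUE)
      external <- inc[!(ends[, 1L] %in% mod & ends[, 2L] %in% mod)]
      budget <- sample(seq_len(max(1L, floor(size / 2))), 1L)
      if (length(external) > budget) {
        drop <- sample(seq_along(external), length(external) - budget)
        network <- igraph::delete_edges(network, external[drop])
      } else if (length(external) == 0L) {
        outside <- setdiff(igraph::V(network)$name, mod)
        network <- igraph::add_edges(
          network, c(sample(mod, 1L), sample(outside, 1L)))
      }
    }

    # reconnect any stranded background component via non-module nodes
    module_nodes <- unlist(modules, use.names = FALSE)
    repeat {
      comp <- igraph::components(network)
      if (comp$no == 1L) break
      main <- which.max(comp$csize)
      small <- which(comp$membership != main)
      small_comp <- comp$membership[small[1L]]
      from_pool <- igraph::V(network)$name[comp$membership == small_comp]
      to_pool <- igraph::V(network)$name[comp$membership == main]
      from_nm <- setdiff(from_pool, module_nodes)
      to_nm <- setdiff(to_pool, module_nodes)
      from <- if (length(from_nm) > 0L) sample(from_nm, 1L) else sample(from_pool, 1L)
      to <- if (length(to_nm) > 0L) sample(to_nm, 1L) else sample(to_pool, 1L)
      network <- igraph::add_edges(network, c(from, to))
    }
    list(network = igraph::simplify(network), modules = unname(modules))
  })
}

.term_ids <- function(aspect_index, n) {
  sprintf("GO:%07d", aspect_index * 1000000L + seq_len(n))
}

#' Annotations with a planted permissible set
#'
#' Builds a three-aspect vocabulary whose first `core_vocab_terms` ids per
#' aspect form the core vocabulary; the biological-process core vocabulary
#' includes the aspect root term (in real annotation sets, seed lists
#' contain incompletely characterized proteins annotated to the root). Core
#' proteins draw all their terms from the core vocabulary, covering it
#' exactly, so the pooled table equals the core vocabulary. A fixed count
#' of non-core proteins - the permissible truth, sampled to include every
#' planted module member - receives at least one core-vocabulary term in
#' every aspect, and each planted module additionally carries a distinctive
#' process term shared by its members (complexes are functionally
#' coherent). Every remaining protein has at least one aspect with no
#' core-vocabulary term. Unknown-function proteins inside planted modules
#' are annotated to the process root only (they stay permissible and flow
#' through to the candidate report); unknown-function background proteins
#' get an empty process set.
#'
#' @param network The (planted) interactome.
#' @param cores Character vector of core protein ids.
#' @param planted_modules List of module member vectors (may be empty).
#' @param unknown Character vector of unknown-function protein ids.
#' @param params A [generator_params()] list.
#' @return List with `annotations` (named list of [annotation_set]),
#'   `permissible_truth` (character; includes the cores) and
#'   `core_vocabulary` (list of 3 term vectors).
#' @export
generate_annotations <- function(network, cores, planted_modules = list(),
                                 unknown = character(), params = generator_params()) {
  if (length(cores) == 0L) stop("`cores` must be non-empty")
  nodes <- igraph::V(network)$name
  stopifnot(all(cores %in% nodes), all(unknown %in% nodes))
  vocab <- lapply(seq_len(3L), function(a) .term_ids(a, params$n_aspect_terms[a]))
  vocab[[3L]][1L] <- GO_BP_ROOT
  core_vocab <- lapply(seq_len(3L), function(a) vocab[[a]][seq_len(params$core_vocab_terms[a])])
  noncore_vocab <- lapply(seq_len(3L), function(a) setdiff(vocab[[a]], core_vocab[[a]]))

  withr::with_seed(.stage_seed(params$seed, 2L), {
    noncore <- setdiff(nodes, cores)
    module_nodes <- setdiff(unlist(planted_modules, use.names = FALSE), cores)
    unknown_root <- intersect(unknown, module_nodes)
    unknown_empty <- setdiff(unknown, module_nodes)
    forced <- module_nodes
    n_perm <- round(params$permissible_fraction * length(noncore))
    pool <- setdiff(noncore, c(forced, unknown_empty))
    extra <- sample(pool, max(0L, n_perm - length(forced)))
    permissible <- sort(c(forced, extra))

    # one distinctive process term per planted module, shared by members
    module_terms <- sample(setdiff(core_vocab[[3L]], GO_BP_ROOT),
                           length(planted_modules))
    module_term_of <- character(0)
    for (i in seq_along(planted_modules)) {
      module_term_of[planted_modules[[i]]] <- module_terms[i]
    }

    draw <- function(v, lo, hi) sample(v, min(length(v), sample(lo:hi, 1L)))
    annotations <- vector("list", length(nodes))
    names(annotations) <- nodes

    # cores: core-vocabulary terms only; round-robin so the pooled table
    # covers the core vocabulary exactly
    core_assign <- lapply(seq_len(3L), function(a) {
      owner <- rep_len(seq_along(cores), length(core_vocab[[a]]))
      split(core_vocab[[a]], owner)
    })
    for (i in seq_along(cores)) {
      get_terms <- function(a) {
        owned <- if (i <= length(core_assign[[a]])) core_assign[[a]][[i]] else character()
        unique(c(owned, draw(core_vocab[[a]], 1L, 3L)))
      }
      annotations[[cores[i]]] <- annotation_set(get_terms(1L), get_terms(2L), get_terms(3L))
    }

    for (prot in noncore) {
      if (prot %in% unknown_root) {
        terms <- list(draw(core_vocab[[1L]], 1L, 3L),
                      draw(core_vocab[[2L]], 1L, 3L), GO_BP_ROOT)
      } else if (prot %in% permissible) {
        terms <- lapply(seq_len(3L), function(a)
          c(draw(core_vocab[[a]], 1L, 3L), draw(noncore_vocab[[a]], 0L, 2L)))
        if (prot %in% names(module_term_of)) {
          terms[[3L]] <- c(terms[[3L]], module_term_of[[prot]])
        }
      } else if (prot %in% unknown_empty) {
        terms <- list(draw(vocab[[1L]], 1L, 3L), draw(vocab[[2L]], 1L, 3L), character())
      } else {
        # at least one aspect with zero core-vocabulary terms
        blocked <- sample(3L, sample(1L:2L, 1L))
        terms <- lapply(seq_len(3L), function(a) {
          if (a %in% blocked) draw(noncore_vocab[[a]], 1L, 3L)
          else draw(vocab[[a]], 1L, 3L)
        })
      }
      annotations[[prot]] <- annotation_set(terms[[1L]], terms[[2L]], terms[[3L]])
    }

    list(annotations = annotations,
         permissible_truth = sort(union(permissible, cores)),
         core_vocabulary = core_vocab)
  })
}

#' Synthetic TF-to-target regulome
#'
#' @param genes Character vector of scoreable gene ids.
#' @param params A [generator_params()] list.
#' @return List with `regnet` (data.frame `tf`, `target`) and `active_tfs`.
#' @export
generate_regnet <- function(genes, params = generator_params()) {
  withr::with_seed(.stage_seed(params$seed, 3L), {
    tfs <- sprintf("TF%02d", seq_len(params$n_tfs))
    regnet <- do.call(rbind, lapply(tfs, function(tf) {
      data.frame(tf = tf,
                 target = sample(genes, min(params$targets_per_tf, length(genes))),
                 stringsAsFactors = FALSE)
    }))
    list(regnet = regnet, active_tfs = tfs[seq_len(params$n_active_tfs)])
  })
}

#' Gene-level expression p-values with planted active regulators
#'
#' Targets of active TFs draw their p-value from a two-sided normal test
#' with noncentrality `effect` (test statistic ~ Normal(effect, 1), p =
#' 2 * (1 - pnorm(|T|))); all other genes draw Uniform(0, 1) p-values.
#'
#' @param regnet Data.frame with columns `tf`, `target`.
#' @param active_tfs Character vector, subset of `regnet$tf`.
#' @param genes All gene ids to score.
#' @param effect Noncentrality (> 0).
#' @param seed Integer seed.
#' @return Named numeric vector of p-values in (0, 1].
#' @export
generate_expression <- function(regnet, active_tfs, genes, effect = 4, seed = 1L) {
  if (effect <= 0) stop("effect must be > 0")
  if (!all(active_tfs %in% regnet$tf)) stop("active TFs must appear in the regnet")
  withr::with_seed(seed, {
    p <- setNames(runif(length(genes)), genes)
    hot <- intersect(unique(regnet$target[regnet$tf %in% active_tfs]), genes)
    if (length(hot) > 0L) {
      stat <- rnorm(length(hot), mean = effect, sd = 1)
      p[hot] <- 2 * pnorm(-abs(stat))
    }
    pmax(p, .Machine$double.xmin)
  })
}

#' Generate the full synthetic benchmark
#'
#' @param params A [generator_params()] list.
#' @return List of class `synthetic_benchmark` with fields `network`,
#'   `annotations`, `core_proteins`, `permissible_truth`, `planted_modules`,
#'   `unknown_truth`, `core_vocabulary`, `regnet`, `active_tfs`,
#'   `gene_pvalues` and `params`.
#' @export
synthetic_benchmark <- function(params = generator_params()) {
  g0 <- generate_ppi(params)
  pl <- plant_modules(g0, params)
  g <- pl$network
  nodes <- igraph::V(g)$name
  module_nodes <- unlist(pl$modules, use.names = FALSE)

  misc <- withr::with_seed(.stage_seed(params$seed, 4L), {
    cores <- sample(setdiff(nodes, module_nodes), params$n_cores)
    n_unknown <- round(params$unknown_fraction * length(nodes))
    unknown <- character()
    if (n_unknown > 0L && length(pl$modules) > 0L) {
      unknown <- vapply(pl$modules, function(m) sample(m, 1L), "")
      unknown <- unknown[seq_len(min(length(unknown), n_unknown))]
    }
    if (length(unknown) < n_unknown) {
      pool <- setdiff(nodes, c(cores, module_nodes))
      unknown <- c(unknown, sample(pool, n_unknown - length(unknown)))
    }
    list(cores = sort(cores), unknown = sort(unknown))
  })

  ann <- generate_annotations(g, misc$cores, pl$modules, misc$unknown, params)
  g <- .wire_modules_to_backbone(g, pl$modules, ann$permissible_truth,
                                 seed = .stage_seed(params$seed, 6L))
  reg <- generate_regnet(nodes, params)
  pvals <- generate_expression(reg$regnet, reg$active_tfs, nodes,
                               effect = params$active_tf_effect,
                               seed = .stage_seed(params$seed, 5L))

  bench <- structure(list(
    network = g,
    annotations = ann$annotations,
    core_proteins = misc$cores,
    permissible_truth = ann$permissible_truth,
    planted_modules = pl$modules,
    unknown_truth = misc$unknown,
    core_vocabulary = ann$core_vocabulary,
    regnet = reg$regnet,
    active_tfs = reg$active_tfs,
    gene_pvalues = pvals,
    params = params
  ), class = "synthetic_benchmark")
  validate_benchmark(bench)
  bench
}

# Planted complexes must be reachable through the permissible backbone,
# otherwise the reconstruction stage discards them with the small-component
# sweep and no downstream stage can recover them. For each planted module
# outside the largest permissible component, one existing bridge edge is
# re-pointed at a permissible backbone node (bridge counts and module
# density are unchanged); stranded background components are then
# re-attached through non-module nodes.
.wire_modules_to_backbone <- function(network, modules, permissible, seed) {
  if (length(modules) == 0L) return(network)
  withr::with_seed(seed, {
    module_nodes <- unlist(modules, use.names = FALSE)
    for (mod in modules) {
      sub <- igraph::induced_subgraph(network, permissible)
      comp <- igraph::components(sub)
      main <- igraph::V(sub)$name[comp$membership == which.max(comp$csize)]
      if (any(mod %in% main)) next
      ids <- match(mod, igraph::V(network)$name)
      inc <- sort(unique(unlist(igraph::incident_edges(network, ids))))
      ends <- igraph::ends(network, inc, names = TRUE)
      ext <- which(!(ends[, 1L] %in% mod & ends[, 2L] %in% mod))
      pick <- ext[1L]
      anchor <- intersect(mod, permissible)
      target_pool <- setdiff(main, module_nodes)
      network <- igraph::delete_edges(network, inc[pick])
      network <- igraph::add_edges(
        network, c(sample(anchor, 1L), sample(target_pool, 1L)))
    }
    repeat {
      comp <- igraph::components(network)
      if (comp$no == 1L) break
      main <- which.max(comp$csize)
      small_comp <- comp$membership[which(comp$membership != main)[1L]]
      from_pool <- igraph::V(network)$name[comp$membership == small_comp]
      to_pool <- igraph::V(network)$name[comp$membership == main]
      from_nm <- setdiff(from_pool, module_nodes)
      to_nm <- setdiff(to_pool, module_nodes)
      from <- if (length(from_nm) > 0L) sample(from_nm, 1L) else sample(from_pool, 1L)
      to <- if (length(to_nm) > 0L) sample(to_nm, 1L) else sample(to_pool, 1L)
      network <- igraph::add_edges(network, c(from, to))
    }
    igraph::simplify(network)
  })
}

#' Check the structural invariants of a benchmark
#'
#' Asserts: cores are permissible; every planted module is a connected
#' subgraph with density >= 0.8 and disjoint from the others; every protein
#' has annotations in all aspects unless flagged unknown; p-values lie in
#' (0, 1].
#'
#' @param bench A `synthetic_benchmark`.
#' @return Invisibly `TRUE`; stops on violation.
#' @export
validate_benchmark <- function(bench) {
  stopifnot(inherits(bench, "synthetic_benchmark"))
  if (!all(bench$core_proteins %in% bench$permissible_truth)) {
    stop("invariant violated: cores must be permissible")
  }
  seen <- character()
  for (mod in bench$planted_modules) {
    if (length(intersect(mod, seen)) > 0L) stop("planted modules overlap")
    seen <- c(seen, mod)
    sub <- igraph::induced_subgraph(bench$network, mod)
    n <- igraph::vcount(sub)
    if (!igraph::is_connected(sub)) stop("planted module is disconnected")
    if (igraph::ecount(sub) / (n * (n - 1L) / 2) < 0.8) {
      stop("planted module density below 0.8")
    }
  }
  for (prot in names(bench$annotations)) {
    a <- bench$annotations[[prot]]
    if (prot %in% bench$unknown_truth) next
    if (length(a$component_terms) == 0L || length(a$function_terms) == 0L ||
        length(a$process_terms) == 0L) {
      stop("protein ", prot, " lacks annotations in some aspect")
    }
  }
  p <- bench$gene_pvalues
  if (any(p <= 0 | p > 1)) stop("gene p-values must lie in (0, 1]")
  invisible(TRUE)
}

#' Hierarchical clique-tree network
#'
#' Deterministic hierarchical model: a 5-clique is replicated four times at
#' every level and the peripheral nodes of the replicas are wired to the
#' original central hub. The mean clustering coefficient of such networks
#' decays as C(k) ~ k^-1, so the analytic target exponent of the
#' clustering power law is w = 1.
#'
#' @param levels Number of replication rounds (network has `5^(levels+1)`
#'   nodes).
#' @return A named `igraph` graph.
#' @export
generate_hierarchical_ppi <- function(levels = 3) {
  levels <- .check_count(levels, "levels", min = 1L)
  base <- 5L
  edges <- t(combn(seq_len(base), 2L))      # K5; node 1 is the hub
  n <- base
  peripheral <- 2:5
  for (l in seq_len(levels)) {
    new_edges <- edges
    new_peripheral <- integer()
    for (r in seq_len(4L)) {
      offset <- r * n
      new_edges <- rbind(new_edges, edges + offset)
      rep_per <- peripheral + offset
      new_peripheral <- c(new_peripheral, rep_per)
      new_edges <- rbind(new_edges, cbind(rep_per, 1L))
    }
    edges <- new_edges
    peripheral <- new_peripheral
    n <- n * 5L
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  igraph::V(g)$name <- sprintf("H%04d", seq_len(igraph::vcount(g)))
  g
}

#' Write a benchmark to disk as plain-text files
#'
#' Emits: `ppi.tsv` (edge list), `ppi_biogrid.tab2.txt` (TAB 2.0),
#' `annotations.gaf`, `cores.txt`, `regnet.tsv`, `pvalues.tsv` and
#' `truth.tsv` (node table flagging permissible / module / unknown truth).
#'
#' @param bench A `synthetic_benchmark`.
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_network(bench$network, file.path(dir, "ppi.tsv"), format = "edge_tsv")
  el <- .edge_table(bench$network)
  write_biogrid_tab2(
    data.frame(protein_a = el[, 1L], protein_b = el[, 2L],
               interaction_class = "physical", stringsAsFactors = FALSE),
    file.path(dir, "ppi_biogrid.tab2.txt"))
  write_gaf(bench$annotations, file.path(dir, "annotations.gaf"))
  writeLines(bench$core_proteins, file.path(dir, "cores.txt"))
  .write_tsv(bench$regnet, file.path(dir, "regnet.tsv"))
  .write_tsv(data.frame(gene = names(bench$gene_pvalues),
                        p = unname(bench$gene_pvalues)),
             file.path(dir, "pvalues.tsv"))
  nodes <- igraph::V(bench$network)$name
  module_of <- setNames(rep(NA_integer_, length(nodes)), nodes)
  for (i in seq_along(bench$planted_modules)) {
    module_of[bench$planted_modules[[i]]] <- i
  }
  .write_tsv(data.frame(
    protein = nodes,
    core = nodes %in% bench$core_proteins,
    permissible = nodes %in% bench$permissible_truth,
    planted_module = unname(module_of),
    unknown_function = nodes %in% bench$unknown_truth
  ), file.path(dir, "truth.tsv"))
  invisible(dir)
}
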