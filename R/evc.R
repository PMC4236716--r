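# Eigenvector-centrality tuning: per-node significance of the observed
# centrality against a degree-preserving random-network ensemble.

#' Eigenvector centrality by power iteration
#'
#' Scores every node by the dominant eigenvector of the adjacency matrix,
#' computed by power iteration on the shifted operator A + I. The +1
#' diagonal shift guarantees convergence on bipartite components (where the
#' plain iteration oscillates) and leaves the eigenvector unchanged. The
#' result is nonnegative and L2-normalized. On a disconnected graph the
#' global dominant eigenvector is returned, so nodes outside the dominant
#' component score (numerically) zero.
#'
#' @param network An `igraph` simple undirected graph.
#' @param tol Convergence threshold on the max-norm difference of successive
#'   iterates.
#' @param max_iter Iteration cap; exceeding it is an error.
#' @return Named numeric vector of centrality scores (`sum(x^2) == 1`).
#' @export
eigenvector_centrality <- function(network, tol = 1e-10, max_iter = 100000L) {
  n <- igraph::vcount(network)
  if (n == 0L) stop("network is empty")
  A <- igraph::as_adjacency_matrix(network, sparse = TRUE)
  x <- rep(1 / sqrt(n), n)
  for (it in seq_len(max_iter)) {
    y <- as.numeric(A %*% x) + x      # (A + I) x
    y <- y / sqrt(sum(y^2))
    if (max(abs(y - x)) < tol) {
      return(setNames(y, igraph::V(network)$name))
    }
    x <- y
  }
  stop("power iteration did not converge within ", max_iter, " iterations")
}

#' Degree-preserving randomization by double edge swaps
#'
#' Rewires the graph with repeated double-edge swaps (`swap_multiplier`
#' times the edge count attempted swaps); swaps that would create a
#' self-loop or a duplicate edge are rejected, so the result is a simple
#' graph on the same node set with every node's degree unchanged. Graphs
#' that admit no valid swap are returned as a copy.
#'
#' @param network An `igraph` simple undirected graph with >= 2 edges.
#' @param seed Integer seed (the global RNG state is left untouched).
#' @param swap_multiplier Attempted swaps per edge.
#' @return A rewired `igraph` graph.
#' @export
degree_preserving_randomize <- function(network, seed, swap_multiplier = 10) {
  if (igraph::ecount(network) < 2L) stop("randomization needs >= 2 edges")
  niter <- .check_count(swap_multiplier, "swap_multiplier") * igraph::ecount(network)
  withr::with_seed(seed,
    igraph::rewire(network, igraph::keeping_degseq(loops = FALSE, niter = niter)))
}

#' Null ensemble of eigenvector centralities
#'
#' Generates `R` independent degree-preserving randomizations of the input
#' network and computes eigenvector centrality on each, aligned per node.
#'
#' @param network An `igraph` simple undirected graph.
#' @param R Ensemble size (the published analysis used 100 random networks).
#' @param seed Integer seed; replicate r uses sub-seed `seed + r`.
#' @param swap_multiplier Attempted swaps per edge in each randomization.
#' @return A list of class `evc_ensemble` with fields `observed` (named
#'   vector), `samples` (nodes x R matrix) and `R`.
#' @export
build_evc_ensemble <- function(network, R = 100, seed = 1L, swap_multiplier = 10) {
  R <- .check_count(R, "R", min = 2L)
  observed <- eigenvector_centrality(network)
  nodes <- names(observed)
  samples <- matrix(NA_real_, nrow = length(nodes), ncol = R,
                    dimnames = list(nodes, NULL))
  for (r in seq_len(R)) {
    gr <- degree_preserving_randomize(network, seed = .stage_seed(seed, r),
                                      swap_multiplier = swap_multiplier)
    evc <- tryCatch(eigenvector_centrality(gr), error = function(e) {
      stop("EVC failed on randomized replicate ", r, ": ", conditionMessage(e))
    })
    samples[, r] <- evc[nodes]
  }
  structure(list(observed = observed, samples = samples, R = R),
            class = "evc_ensemble")
}

#' Tune a network by centrality significance
#'
#' For every node, the `R` random-network centrality scores are tested
#' against the node's observed centrality as the hypothesized mean
#' (one-sample two-tailed t-test, `R - 1` degrees of freedom). Nodes whose
#' observed centrality is significantly different from random expectation
#' (`p < alpha`) are retained; the tuned network is the subgraph induced on
#' the retained nodes. Degenerate zero-variance samples follow the limit of
#' the test: a constant sample equal to the observed value is never
#' significant (p = 1), a constant sample different from it always is
#' (p = 0).
#'
#' The induced subgraph is not re-reduced to its largest component;
#' set `keep_largest_component = TRUE` to add that sweep.
#'
#' @param network The network the ensemble was built from.
#' @param ensemble An `evc_ensemble` from [build_evc_ensemble()].
#' @param alpha Two-tailed significance level (default 0.0001, i.e. 99.99%
#'   confidence).
#' @param keep_largest_component Reduce the tuned network to its largest
#'   connected component (off by default).
#' @return List with `network` (tuned `igraph`) and `records` (data.frame
#'   with columns `node`, `observed_evc`, `mean_random_evc`, `t_statistic`,
#'   `p_value`, `retained`, sorted by p).
#' @export
tune_network <- function(network, ensemble, alpha = 0.0001,
                         keep_largest_component = FALSE) {
  stopifnot(inherits(ensemble, "evc_ensemble"))
  alpha <- .check_prob(alpha, "alpha")
  if (ensemble$R < 2L) stop("ensemble must hold >= 2 replicates")
  obs <- ensemble$observed
  S <- ensemble$samples
  stopifnot(identical(rownames(S), names(obs)))

  m <- rowMeans(S)
  s <- apply(S, 1L, sd)
  tstat <- (m - obs) / (s / sqrt(ensemble$R))
  p <- 2 * pt(-abs(tstat), df = ensemble$R - 1L)
  zero_var <- s < 1e-14
  same <- zero_var & abs(m - obs) < 1e-12
  p[zero_var] <- 0
  p[same] <- 1
  tstat[zero_var] <- Inf
  tstat[same] <- 0

  records <- data.frame(node = names(obs), observed_evc = unname(obs),
                        mean_random_evc = unname(m), t_statistic = unname(tstat),
                        p_value = unname(p), retained = unname(p < alpha),
                        stringsAsFactors = FALSE)
  records <- records[order(records$p_value, records$node), ]
  rownames(records) <- NULL

  kept <- records$node[records$retained]
  tuned <- igraph::induced_subgraph(network, kept)
  if (keep_largest_component && igraph::vcount(tuned) > 0L) {
    comp <- igraph::components(tuned)
    tuned <- igraph::induced_subgraph(tuned, which(comp$membership == which.max(comp$csize)))
  }
  list(network = tuned, records = records)
}
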