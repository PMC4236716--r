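# Descriptive topology panel and the hierarchical-modularity signature
# C(k) ~ k^-w (mean local clustering versus degree on log-log axes).

#' Topology summary of a connected network
#'
#' Computes the descriptive panel used to characterize reconstructed
#' networks: node/edge counts, diameter, average shortest path length,
#' average local clustering coefficient (0 for nodes of degree < 2), the
#' degree distribution, betweenness centralities normalized by
#' (n-1)(n-2)/2, and the clustering power-law fit of
#' [fit_clustering_power_law()] (NA when fewer than 3 usable degree bins
#' exist).
#'
#' @param network A connected simple undirected `igraph` graph (path
#'   metrics are undefined otherwise; pass the largest component).
#' @return List of class `topology_summary`.
#' @export
summarize_topology <- function(network) {
  if (igraph::vcount(network) == 0L) stop("network is empty")
  if (!igraph::is_connected(network)) {
    stop("network is disconnected; summarize its largest connected component")
  }
  deg <- igraph::degree(network)
  cc <- igraph::transitivity(network, type = "local", isolates = "zero")
  cc[deg < 2L] <- 0
  names(cc) <- igraph::V(network)$name
  fit <- tryCatch(fit_clustering_power_law(network),
                  error = function(e) list(w = NA_real_, r2 = NA_real_))
  structure(list(
    n_nodes = igraph::vcount(network),
    n_edges = igraph::ecount(network),
    diameter = igraph::diameter(network, unconnected = FALSE),
    avg_shortest_path = igraph::mean_distance(network),
    avg_clustering = mean(cc),
    degree_distribution = table(deg),
    betweenness = igraph::betweenness(network, normalized = TRUE),
    power_law_w = fit$w,
    power_law_r2 = fit$r2
  ), class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat("<topology_summary> ", x$n_nodes, " nodes, ", x$n_edges, " edges\n",
      "  diameter ", x$diameter,
      ", avg shortest path ", signif(x$avg_shortest_path, 4),
      ", avg clustering ", signif(x$avg_clustering, 4), "\n",
      "  C(k) ~ k^-w fit: w = ", signif(x$power_law_w, 4),
      " (r2 = ", signif(x$power_law_r2, 4), ")\n", sep = "")
  invisible(x)
}

#' Mean local clustering coefficient per degree, C(k)
#'
#' @param network A simple undirected `igraph` graph.
#' @return Data.frame with columns `k` (degree) and `ck` (mean local
#'   clustering of nodes with that degree); raw integer-degree bins.
#' @export
clustering_by_degree <- function(network) {
  deg <- igraph::degree(network)
  cc <- igraph::transitivity(network, type = "local", isolates = "zero")
  cc[deg < 2L] <- 0
  ck <- tapply(cc, deg, mean)
  data.frame(k = as.integer(names(ck)), ck = as.numeric(ck))
}

#' Power-law exponent of the clustering-degree curve
#'
#' Fits C(k) ~ k^-w by ordinary least squares of log10 C(k) on log10 k over
#' raw integer-degree bins. Bins with k < 2 (local clustering undefined) or
#' C(k) = 0 (log-undefined) are excluded. A clearly positive exponent w with
#' a good fit signals hierarchical modularity; flat curves give w ~ 0.
#'
#' @param network A simple undirected `igraph` graph with at least 3 usable
#'   degree bins, or a data.frame with columns `k` and `ck` (a precomputed
#'   clustering-degree curve).
#' @return List with `w` (= minus the fitted slope), `r2`, and the `bins`
#'   data.frame used for the fit.
#' @export
fit_clustering_power_law <- function(network) {
  bins <- if (is.data.frame(network)) {
    stopifnot(all(c("k", "ck") %in% names(network)))
    network
  } else {
    clustering_by_degree(network)
  }
  bins <- bins[bins$k >= 2L & bins$ck > 0, , drop = FALSE]
  if (nrow(bins) < 3L) {
    stop("fewer than 3 usable degree bins for the C(k) power-law fit")
  }
  fit <- lm(log10(ck) ~ log10(k), data = bins)
  # noiseless curves fit exactly; summary.lm's perfect-fit warning is moot
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(w = -unname(coef(fit)[2L]), r2 = r2, bins = bins)
}
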