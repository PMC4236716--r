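# Independent reference implementations used as oracles. These deliberately
# avoid the code paths (and, where possible, the libraries) they check.

# Dominant eigenvector of the adjacency matrix via a dense eigensolver.
oracle_evc <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  e <- eigen(A, symmetric = TRUE)
  v <- e$vectors[, which.max(e$values)]
  v <- abs(v)
  v <- v / sqrt(sum(v^2))
  stats::setNames(v, igraph::V(g)$name)
}

# Random connected graph: random spanning tree plus extra random edges.
random_connected_graph <- function(n, extra = n) {
  edges <- cbind(2:n, vapply(2:n, function(i) sample.int(i - 1L, 1L), 1L))
  more <- cbind(sample.int(n, extra, replace = TRUE),
                sample.int(n, extra, replace = TRUE))
  more <- more[more[, 1L] != more[, 2L], , drop = FALSE]
  g <- igraph::graph_from_edgelist(rbind(edges, more), directed = FALSE)
  g <- igraph::simplify(g)
  igraph::V(g)$name <- sprintf("n%03d", seq_len(igraph::vcount(g)))
  g
}

random_connected_graph_seeded <- function(n, seed, extra = n) {
  withr::with_seed(seed, random_connected_graph(n, extra))
}

# Plain-R BFS giving distances and shortest-path counts from one source.
.bfs_counts <- function(adj, s, n) {
  dist <- rep(Inf, n)
  sigma <- numeric(n)
  dist[s] <- 0
  sigma[s] <- 1
  frontier <- s
  while (length(frontier) > 0L) {
    nxt <- integer()
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          nxt <- c(nxt, w)
        }
        if (dist[w] == dist[v] + 1) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, sigma = sigma)
}

# Brute-force topology panel: BFS distances/path counts from every source,
# pair-sum betweenness, and triangle-count clustering.
oracle_topology <- function(g) {
  n <- igraph::vcount(g)
  nodes <- igraph::V(g)$name
  adj <- lapply(igraph::adjacent_vertices(g, igraph::V(g)), as.integer)
  bfs <- lapply(seq_len(n), .bfs_counts, adj = adj, n = n)
  D <- do.call(rbind, lapply(bfs, `[[`, "dist"))
  S <- do.call(rbind, lapply(bfs, `[[`, "sigma"))

  btw <- numeric(n)
  for (v in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n - 1L)) {
      for (t in (s + 1L):n) {
        if (s == v || t == v) next
        if (D[s, t] == D[s, v] + D[v, t]) {
          tot <- tot + S[s, v] * S[v, t] / S[s, t]
        }
      }
    }
    btw[v] <- tot / ((n - 1) * (n - 2) / 2)
  }

  A <- as.matrix(igraph::as_adjacency_matrix(g))
  deg <- rowSums(A)
  cc <- vapply(seq_len(n), function(v) {
    if (deg[v] < 2) return(0)
    nb <- which(A[v, ] == 1)
    tri <- sum(A[nb, nb]) / 2
    2 * tri / (deg[v] * (deg[v] - 1))
  }, 1.0)

  ut <- D[upper.tri(D)]
  list(diameter = max(ut), avg_shortest_path = mean(ut),
       avg_clustering = mean(cc),
       betweenness = stats::setNames(btw, nodes),
       clustering = stats::setNames(cc, nodes))
}

# Brute-force highest k-core of a graph: try k from high to low, each time
# iteratively deleting vertices of degree < k.
oracle_highest_kcore <- function(g) {
  for (k in rev(seq_len(igraph::vcount(g)))) {
    h <- g
    repeat {
      low <- which(igraph::degree(h) < k)
      if (length(low) == 0L) break
      h <- igraph::delete_vertices(h, low)
    }
    if (igraph::vcount(h) > 0L) return(list(k = k, graph = h))
  }
  list(k = 0L, graph = g)
}

# MCODE vertex weight recomputed from the brute-force k-core oracle.
oracle_vertex_weight <- function(g, v, degree_threshold = 2) {
  if (igraph::degree(g, v) < degree_threshold) return(0)
  nb <- igraph::neighbors(g, v)
  sub <- igraph::induced_subgraph(g, c(igraph::V(g)[v], nb))
  hk <- oracle_highest_kcore(sub)
  n <- igraph::vcount(hk$graph)
  if (n < 2L) return(0)
  hk$k * igraph::ecount(hk$graph) / (n * (n - 1) / 2)
}

# Exhaustive upper-tail hypergeometric probability by summing the pmf.
oracle_hyper <- function(k, n, K, N) {
  if (k == 0) return(1)
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Hand-rolled Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Independent per-node re-implementation of the tuning decision using
# stats::t.test.
oracle_retained <- function(ensemble, alpha) {
  vapply(seq_along(ensemble$observed), function(i) {
    x <- ensemble$samples[i, ]
    mu <- ensemble$observed[i]
    if (stats::sd(x) < 1e-14) return(abs(mean(x) - mu) >= 1e-12)
    stats::t.test(x, mu = mu)$p.value < alpha
  }, TRUE)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Two 6-cliques joined through a single articulation (bridge) vertex.
bridged_six_cliques <- function() {
  c1 <- igraph::make_full_graph(6)
  igraph::V(c1)$name <- paste0("a", 1:6)
  c2 <- igraph::make_full_graph(6)
  igraph::V(c2)$name <- paste0("b", 1:6)
  g <- igraph::disjoint_union(c1, c2)
  g <- igraph::add_vertices(g, 1, name = "x")
  igraph::add_edges(g, c("a1", "x", "x", "b1"))
}

expect_same_graph <- function(g1, g2) {
  expect_setequal(igraph::V(g1)$name, igraph::V(g2)$name)
  e1 <- spanet:::.edge_table(g1)
  e2 <- spanet:::.edge_table(g2)
  expect_identical(e1, e2)
}
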