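# MCODE dense-module detection: local-neighborhood vertex weighting,
# greedy seeded expansion, and 2-core haircut post-processing.

#' MCODE parameters
#'
#' Defaults follow the published analysis: loops excluded from scoring,
#' degree threshold 2, node score threshold 0.2, k-core threshold 2,
#' maximum depth 100, haircut on, fluff off.
#'
#' @param degree_threshold Vertices below this degree get weight 0.
#' @param node_score_threshold Fraction in `[0, 1]`; a neighbor joins a
#'   module only if its weight exceeds `(1 - node_score_threshold)` times
#'   the seed's weight (strict inequality).
#' @param kcore_threshold Modules that contain no k-core at this k are
#'   discarded.
#' @param max_depth Breadth-first expansion layers from the seed vertex.
#' @param haircut Trim each module to its 2-core (iterated removal of
#'   singly-connected members).
#' @param fluff Parsed for interface completeness; enabling it is an error
#'   (not implemented; it was off in the analysis this package supports).
#' @return List of class `mcode_params`.
#' @export
mcode_params <- function(degree_threshold = 2,
                         node_score_threshold = 0.2,
                         kcore_threshold = 2,
                         max_depth = 100,
                         haircut = TRUE,
                         fluff = FALSE) {
  structure(list(
    degree_threshold = .check_count(degree_threshold, "degree_threshold", min = 0L),
    node_score_threshold = .check_fraction(node_score_threshold, "node_score_threshold"),
    kcore_threshold = .check_count(kcore_threshold, "kcore_threshold"),
    max_depth = .check_count(max_depth, "max_depth"),
    haircut = isTRUE(haircut),
    fluff = isTRUE(fluff)
  ), class = "mcode_params")
}

# Highest k-core of an igraph subgraph: the subgraph induced on vertices of
# maximal coreness, together with that core number.
.highest_kcore <- function(g) {
  core <- igraph::coreness(g)
  kmax <- max(core)
  list(k = kmax, graph = igraph::induced_subgraph(g, which(core == kmax)))
}

#' MCODE vertex weight
#'
#' The weight of vertex v is k times the density of the highest k-core of
#' its closed neighborhood N(v) plus v itself; density is 2E / (n (n - 1))
#' with loops excluded. Vertices whose degree falls below the degree
#' threshold are weighted 0.
#'
#' @param network A simple undirected `igraph` graph.
#' @param v Vertex name (or index).
#' @param params An [mcode_params()] list.
#' @return Nonnegative numeric weight.
#' @export
mcode_vertex_weight <- function(network, v, params = mcode_params()) {
  w <- mcode_vertex_weights(network, params)
  vid <- if (is.character(v)) v else igraph::V(network)$name[v]
  unname(w[vid])
}

#' MCODE vertex weights for every vertex
#'
#' @inheritParams mcode_vertex_weight
#' @return Named numeric vector of weights.
#' @export
mcode_vertex_weights <- function(network, params = mcode_params()) {
  nodes <- igraph::V(network)$name
  deg <- igraph::degree(network)
  w <- numeric(length(nodes))
  names(w) <- nodes
  nb <- igraph::adjacent_vertices(network, igraph::V(network))
  for (i in seq_along(nodes)) {
    if (deg[i] < params$degree_threshold) next
    closed <- c(i, as.integer(nb[[i]]))
    sub <- igraph::induced_subgraph(network, closed)
    hk <- .highest_kcore(sub)
    n <- igraph::vcount(hk$graph)
    dens <- if (n < 2L) 0 else igraph::ecount(hk$graph) / (n * (n - 1L) / 2)
    w[i] <- hk$k * dens
  }
  w
}

#' MCODE dense-module detection
#'
#' Greedy seeded expansion: vertices are visited in decreasing weight order
#' (ties broken by lexicographic vertex id); from each unvisited positive-
#' weight seed, a breadth-first expansion (at most `max_depth` layers) adds
#' unvisited neighbors whose weight strictly exceeds
#' `(1 - node_score_threshold)` times the seed weight. Members are owned by
#' the first module that claims them, so module node sets are pairwise
#' disjoint. Post-processing: with haircut on, each module is trimmed to its
#' 2-core; modules that contain no k-core at `kcore_threshold`, or fewer
#' than 2 members, are discarded. A module's score is its subgraph density
#' times its size; modules are ranked by score, then size, then
#' lexicographic smallest member.
#'
#' @param network A simple undirected `igraph` graph with named vertices.
#' @param params An [mcode_params()] list.
#' @return List of modules; each module is a list with fields `members`
#'   (sorted character vector), `seed_node`, `score` and `rank`.
#' @export
mcode <- function(network, params = mcode_params()) {
  stopifnot(inherits(params, "mcode_params"))
  if (params$fluff) stop("fluff post-processing is not implemented (it is off by design)")
  nodes <- igraph::V(network)$name
  if (is.null(nodes)) stop("network vertices must be named")
  w <- mcode_vertex_weights(network, params)
  order_idx <- order(-w, nodes)
  visited <- setNames(logical(length(nodes)), nodes)
  adj <- lapply(igraph::adjacent_vertices(network, igraph::V(network)),
                function(vs) nodes[as.integer(vs)])
  names(adj) <- nodes

  raw <- list()
  for (i in order_idx) {
    seed <- nodes[i]
    if (visited[seed] || w[seed] <= 0) next
    threshold <- (1 - params$node_score_threshold) * w[seed]
    members <- seed
    visited[seed] <- TRUE
    frontier <- seed
    depth <- 0L
    while (length(frontier) > 0L && depth < params$max_depth) {
      cand <- sort(unique(unlist(adj[frontier], use.names = FALSE)))
      cand <- cand[!visited[cand] & w[cand] > threshold]
      if (length(cand) == 0L) break
      visited[cand] <- TRUE
      members <- c(members, cand)
      frontier <- cand
      depth <- depth + 1L
    }
    raw[[length(raw) + 1L]] <- list(seed = seed, members = members)
  }

  modules <- list()
  for (m in raw) {
    sub <- igraph::induced_subgraph(network, m$members)
    if (params$haircut) {
      keep <- igraph::V(sub)$name[igraph::coreness(sub) >= 2L]
      if (length(keep) == 0L) next
      sub <- igraph::induced_subgraph(sub, keep)
    }
    n <- igraph::vcount(sub)
    if (n < 2L) next
    if (max(igraph::coreness(sub)) < params$kcore_threshold) next
    dens <- igraph::ecount(sub) / (n * (n - 1L) / 2)
    modules[[length(modules) + 1L]] <- list(
      members = sort(igraph::V(sub)$name),
      seed_node = m$seed,
      score = dens * n
    )
  }
  if (length(modules) == 0L) return(list())

  first_member <- vapply(modules, function(m) m$members[1L], "")
  sizes <- vapply(modules, function(m) length(m$members), 1L)
  scores <- vapply(modules, function(m) m$score, 1.0)
  ord <- order(-scores, -sizes, first_member)
  modules <- modules[ord]
  for (r in seq_along(modules)) modules[[r]]$rank <- r
  modules
}

#' Tabulate a module list
#'
#' @param modules Module list from [mcode()].
#' @return Data.frame with columns `rank`, `score`, `size`, `seed_node` and
#'   comma-joined `members`.
#' @export
modules_to_table <- function(modules) {
  if (length(modules) == 0L) {
    return(data.frame(rank = integer(), score = numeric(), size = integer(),
                      seed_node = character(), members = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    rank = vapply(modules, `[[`, 1L, "rank"),
    score = vapply(modules, `[[`, 1.0, "score"),
    size = vapply(modules, function(m) length(m$members), 1L),
    seed_node = vapply(modules, `[[`, "", "seed_node"),
    members = vapply(modules, function(m) paste(m$members, collapse = ","), ""),
    stringsAsFactors = FALSE
  )
}
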