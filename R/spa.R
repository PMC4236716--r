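#' Seed-guided network reconstruction (selective permissibility algorithm)
#'
#' Reconstructs a phenotype-focused protein network from a set of core
#' (seed) proteins, a GO annotation map and a physical-interaction table.
#' The admission filter is the pooled core-protein annotation table: a
#' candidate protein is admitted only if it shares at least one GO term
#' with the table in each of the three aspects (see [is_permissible()]);
#' core proteins are admitted unconditionally. Physical interactions between
#' admitted proteins form the raw network; self-loops are removed, duplicate
#' edges collapsed and only the largest connected component is retained, so
#' admitted proteins (including cores) without any surviving interaction are
#' absent from the result.
#'
#' The rule is applied in a single, non-iterative pass: the result is a pure
#' function of its inputs, independent of the order of interaction records.
#'
#' @param cores Character vector of core protein identifiers.
#' @param annotations Named list of [annotation_set] objects.
#' @param interactions Data.frame of interaction records with columns
#'   `protein_a`, `protein_b` and optionally `interaction_class` (only
#'   `"physical"` rows are used when present).
#' @param log Internal logger (optional).
#' @return An `igraph` simple connected undirected graph whose vertex
#'   attribute `core` flags the surviving core proteins. The pooled table is
#'   attached as the graph attribute `annotation_table`.
#' @export
spa_reconstruct <- function(cores, annotations, interactions, log = NULL) {
  cores <- unique(as.character(cores))
  if (length(cores) == 0L) stop("`cores` must be non-empty")
  if (nrow(interactions) == 0L) stop("`interactions` must be non-empty")
  log <- if (is.null(log)) .logger(quiet = TRUE) else log

  known_cores <- intersect(cores, names(annotations))
  if (length(known_cores) < length(cores)) {
    .log_msg(log, "cores without annotations dropped from the table: ",
             paste(setdiff(cores, known_cores), collapse = ", "),
             level = "WARN")
  }
  if (length(known_cores) == 0L) stop("no core protein has annotations")
  table <- build_annotation_table(known_cores, annotations)

  admitted <- names(annotations)[
    vapply(annotations, is_permissible, TRUE, table = table)]
  admitted <- union(admitted, cores)
  .log_msg(log, "SPA admission: ", length(admitted), " candidate proteins (",
           length(cores), " cores + ",
           length(setdiff(admitted, cores)), " permissible)")

  if ("interaction_class" %in% names(interactions)) {
    interactions <- interactions[interactions$interaction_class == "physical", ,
                                 drop = FALSE]
  }
  a <- trimws(as.character(interactions$protein_a))
  b <- trimws(as.character(interactions$protein_b))
  keep <- a %in% admitted & b %in% admitted & a != b
  if (!any(keep)) stop("no physical interaction joins two admitted proteins")
  g <- igraph::graph_from_edgelist(cbind(a[keep], b[keep]), directed = FALSE)
  g <- igraph::simplify(g)
  .log_msg(log, "raw admitted network: ", igraph::vcount(g), " nodes, ",
           igraph::ecount(g), " edges, ",
           igraph::count_components(g), " components")

  lost_cores <- setdiff(cores, igraph::V(g)$name)
  if (length(lost_cores) > 0L) {
    .log_msg(log, "core protein(s) eliminated for lack of physical interactions: ",
             paste(lost_cores, collapse = ", "), level = "WARN")
  }

  comp <- igraph::components(g)
  g <- igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
  if (igraph::vcount(g) == 0L) stop("reconstruction produced an empty network")
  igraph::V(g)$core <- igraph::V(g)$name %in% cores
  g$annotation_table <- table
  .log_msg(log, "largest component retained: ", igraph::vcount(g), " nodes, ",
           igraph::ecount(g), " edges")
  g
}
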