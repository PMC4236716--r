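# Readers and writers for the external formats: BioGRID TAB 2.0, GAF 2.x,
# SIF / two-column edge TSV, plain id lists, regulatory edge lists and
# per-gene p-value tables.

# BioGRID TAB 2.0 column positions used here (1-based, 24 columns total).
.BG_SYS_A <- 6L   # Systematic Name Interactor A
.BG_SYS_B <- 7L
.BG_SYM_A <- 8L   # Official Symbol Interactor A
.BG_SYM_B <- 9L
.BG_TYPE  <- 13L  # Experimental System Type (physical / genetic)
.BG_MIN_COLS <- 13L

#' Read a BioGRID TAB 2.0 interaction file
#'
#' Parses the tab-separated BioGRID TAB 2.0 format (header lines start with
#' `#`). Systematic (ORF) names are preferred as node identifiers; the
#' official gene symbol is used only where the systematic name column holds
#' the `-` placeholder. The reader is non-lossy: duplicate pairs are kept
#' (deduplication happens in the network builder).
#'
#' @param path Path to the TAB 2.0 file.
#' @param keep Interaction classes to retain: any subset of
#'   `c("physical", "genetic", "other")`.
#' @return A data.frame with columns `protein_a`, `protein_b`,
#'   `interaction_class` and `source_line` (1-based line number in the
#'   file).
#' @export
read_biogrid_tab2 <- function(path, keep = "physical") {
  keep <- match.arg(keep, c("physical", "genetic", "other"),
                    several.ok = TRUE)
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty BioGRID file: ", path)
  is_comment <- startsWith(lines, "#")
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    if (is_comment[i] || !nzchar(trimws(lines[i]))) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < .BG_MIN_COLS) {
      stop(sprintf("line %d of %s has %d columns; BioGRID TAB 2.0 needs >= %d",
                   i, path, length(f), .BG_MIN_COLS))
    }
    a <- trimws(f[.BG_SYS_A]); b <- trimws(f[.BG_SYS_B])
    if (a == "-" || a == "") a <- trimws(f[.BG_SYM_A])
    if (b == "-" || b == "") b <- trimws(f[.BG_SYM_B])
    if (a == "" || b == "") stop(sprintf("line %d: empty interactor identifier", i))
    cls <- tolower(trimws(f[.BG_TYPE]))
    if (!cls %in% c("physical", "genetic")) cls <- "other"
    recs[[i]] <- data.frame(protein_a = a, protein_b = b,
                            interaction_class = cls, source_line = i,
                            stringsAsFactors = FALSE)
  }
  recs <- recs[!vapply(recs, is.null, TRUE)]
  if (length(recs) == 0L) stop("no interaction records in ", path)
  out <- do.call(rbind, recs)
  out[out$interaction_class %in% keep, , drop = FALSE]
}

#' Write interaction records as a BioGRID TAB 2.0 file
#'
#' Companion writer used by the synthetic benchmark; emits the 24-column
#' TAB 2.0 layout with systematic names and a header comment line.
#'
#' @param records Data.frame with columns `protein_a`, `protein_b`,
#'   `interaction_class`.
#' @param path Output path.
#' @export
write_biogrid_tab2 <- function(records, path) {
  n <- nrow(records)
  cls <- as.character(records$interaction_class)
  fields <- matrix("-", nrow = n, ncol = 24L)
  fields[, 1L] <- as.character(seq_len(n))
  fields[, .BG_SYS_A] <- records$protein_a
  fields[, .BG_SYS_B] <- records$protein_b
  fields[, .BG_SYM_A] <- records$protein_a
  fields[, .BG_SYM_B] <- records$protein_b
  fields[, 12L] <- "Synthetic-System"
  fields[, .BG_TYPE] <- cls
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#BioGRID Interaction ID\tsynthetic TAB 2.0", con)
  writeLines(apply(fields, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a GAF 2.x gene-association file
#'
#' Comment lines start with `!`. Rows whose qualifier contains `NOT` are
#' excluded per GAF semantics; duplicate (protein, term, aspect) entries are
#' collapsed. The aspect column routes each term into the cellular
#' component / molecular function / biological process partition.
#'
#' @param path Path to the GAF file.
#' @return Named list of [annotation_set] objects keyed by the database
#'   object id (column 2; systematic name).
#' @export
read_gaf <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "!") & nzchar(trimws(lines))
  rows <- which(keep)
  acc <- list()  # protein -> list(C=, F=, P=)
  for (i in rows) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L) {
      stop(sprintf("line %d of %s has %d columns; GAF 2.x needs >= 9", i, path, length(f)))
    }
    qualifier <- f[4L]
    if (grepl("(^|\\|)NOT($|\\|)", qualifier)) next
    go <- trimws(f[5L])
    if (!.is_go_id(go)) {
      stop(sprintf("line %d of %s: missing or malformed GO id '%s'", i, path, go))
    }
    aspect <- trimws(f[9L])
    if (!aspect %in% c("C", "F", "P")) {
      stop(sprintf("line %d of %s: unknown GO aspect code '%s'", i, path, aspect))
    }
    id <- trimws(f[2L])
    if (id == "") stop(sprintf("line %d of %s: empty object id", i, path))
    if (is.null(acc[[id]])) acc[[id]] <- list(C = character(), F = character(), P = character())
    acc[[id]][[aspect]] <- c(acc[[id]][[aspect]], go)
  }
  lapply(acc, function(x) {
    annotation_set(component_terms = x$C, function_terms = x$F, process_terms = x$P)
  })
}

#' Write an annotation map as a GAF 2.2 file
#'
#' @param annotations Named list of [annotation_set] objects.
#' @param path Output path.
#' @param taxon NCBI taxon id string used in column 13.
#' @export
write_gaf <- function(annotations, path, taxon = "taxon:559292") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("!gaf-version: 2.2", con)
  for (id in names(annotations)) {
    a <- annotations[[id]]
    for (asp in c("C", "F", "P")) {
      terms <- switch(asp,
                      C = a$component_terms,
                      F = a$function_terms,
                      P = a$process_terms)
      for (term in terms) {
        writeLines(paste("SYN", id, id, "involved_in", term, "SYN:0000001",
                         "IEA", "", asp, "", "", "protein", taxon,
                         "20130101", "SYN", "", "", sep = "\t"), con)
      }
    }
  }
  invisible(path)
}

# Canonical edge table of an igraph network: endpoints in lexicographic
# order within an edge, edges sorted; each undirected edge appears once.
.edge_table <- function(network) {
  el <- igraph::as_edgelist(network, names = TRUE)
  if (nrow(el) > 0L) {
    swap <- el[, 1L] > el[, 2L]
    tmp <- el[swap, 1L]
    el[swap, 1L] <- el[swap, 2L]
    el[swap, 2L] <- tmp
    el <- el[order(el[, 1L], el[, 2L]), , drop = FALSE]
  }
  el
}

#' Write a network as SIF or two-column edge TSV
#'
#' Each undirected edge is written once with its endpoints in lexicographic
#' order. In SIF, isolated nodes are written on their own line per the SIF
#' singleton convention; the relationship type is `pp`.
#'
#' @param network An `igraph` undirected graph with named vertices.
#' @param path Output path.
#' @param format `"sif"` or `"edge_tsv"`.
#' @export
write_network <- function(network, path, format = c("edge_tsv", "sif")) {
  format <- match.arg(format)
  if (igraph::vcount(network) == 0L) stop("refusing to write an empty network")
  el <- .edge_table(network)
  iso <- setdiff(igraph::V(network)$name, unique(as.vector(el)))
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "sif") {
    if (nrow(el) > 0L) writeLines(paste(el[, 1L], "pp", el[, 2L], sep = "\t"), con)
    if (length(iso) > 0L) writeLines(sort(iso), con)
  } else {
    writeLines("protein_a\tprotein_b", con)
    if (nrow(el) > 0L) writeLines(paste(el[, 1L], el[, 2L], sep = "\t"), con)
    if (length(iso) > 0L) {
      warning(length(iso), " isolated node(s) dropped by edge_tsv format")
    }
  }
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path Path to the file.
#' @param format `"sif"` or `"edge_tsv"` (autodetected from content when
#'   omitted: SIF lines have 3 fields with `pp` in the middle).
#' @return An `igraph` simple undirected graph.
#' @export
read_network <- function(path, format = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty network file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (is.null(format)) {
    format <- if (any(vapply(fields, function(f) length(f) == 3L && f[2L] == "pp", TRUE)))
      "sif" else "edge_tsv"
  }
  if (format == "edge_tsv" && identical(fields[[1L]], c("protein_a", "protein_b"))) {
    fields <- fields[-1L]
  }
  edges <- character(0)
  singletons <- character(0)
  for (f in fields) {
    if (format == "sif") {
      if (length(f) == 1L) singletons <- c(singletons, f) else edges <- c(edges, f[1L], f[3L])
    } else {
      if (length(f) < 2L) stop("malformed edge line in ", path)
      edges <- c(edges, f[1L], f[2L])
    }
  }
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2L, byrow = TRUE),
                                   directed = FALSE)
  g <- igraph::simplify(g)
  if (length(singletons) > 0L) {
    g <- igraph::add_vertices(g, length(setdiff(singletons, igraph::V(g)$name)),
                              name = setdiff(singletons, igraph::V(g)$name))
  }
  g
}

#' Read a newline-terminated identifier list (e.g. core proteins)
#'
#' @param path Path to the list file; blank lines and `#` comments ignored.
#' @return Character vector of identifiers.
#' @export
read_id_list <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("no identifiers in ", path)
  unique(lines)
}

#' Read a TF-to-target regulatory edge list (TSV: tf, target)
#'
#' @param path Path to the two-column TSV (a `tf`/`target` header row is
#'   permitted).
#' @return Data.frame with columns `tf` and `target`, deduplicated.
#' @export
read_regnet <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("tf", "target"))
  if (nrow(df) > 0L &&
      identical(unname(tolower(unlist(df[1L, ]))), c("tf", "target"))) {
    df <- df[-1L, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no regulatory edges in ", path)
  unique(df[, c("tf", "target")])
}

#' Read a per-gene p-value table (TSV: gene, p)
#'
#' @param path Path to the two-column TSV (a header row is permitted).
#' @return Named numeric vector of p-values.
#' @export
read_pvalues <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("gene", "p"))
  if (nrow(df) > 0L && is.na(suppressWarnings(as.numeric(df$p[1L])))) {
    df <- df[-1L, , drop = FALSE]
  }
  p <- as.numeric(df$p)
  if (anyNA(p)) stop("non-numeric p-value in ", path)
  setNames(p, df$gene)
}
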