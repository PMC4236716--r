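#' Per-protein GO annotation set
#'
#' Container for one protein's GO terms, partitioned into the three GO
#' aspects: cellular component, molecular function and biological process.
#' Aspect sets may be empty; a protein whose biological-process set is empty
#' is treated downstream as having unknown biological function.
#'
#' @param component_terms,function_terms,process_terms Character vectors of
#'   GO identifiers (deduplicated on construction).
#' @return An object of class `annotation_set`, a list with fields
#'   `component_terms`, `function_terms` and `process_terms`.
#' @export
annotation_set <- function(component_terms = character(),
                           function_terms = character(),
                           process_terms = character()) {
  structure(
    list(
      component_terms = sort(unique(as.character(component_terms))),
      function_terms  = sort(unique(as.character(function_terms))),
      process_terms   = sort(unique(as.character(process_terms)))
    ),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("<annotation_set> C:", length(x$component_terms),
      " F:", length(x$function_terms),
      " P:", length(x$process_terms), "\n", sep = "")
  invisible(x)
}

.is_go_id <- function(x) grepl("^GO:[0-9]{7}$", x)

#' Pooled annotation collection table of the core proteins
#'
#' The union, per GO aspect, of the core (seed) proteins' annotation sets.
#' This table is the admission filter of the selective permissibility
#' algorithm: a candidate protein enters the reconstructed network only if
#' it shares at least one term with the table in every aspect.
#'
#' @param cores Character vector of core protein identifiers.
#' @param annotations Named list of [annotation_set] objects keyed by
#'   protein identifier; every core must be present.
#' @return An object of class `annotation_table` with fields
#'   `component_terms`, `function_terms`, `process_terms`,
#'   `n_core_proteins`.
#' @export
build_annotation_table <- function(cores, annotations) {
  cores <- unique(as.character(cores))
  if (length(cores) == 0L) stop("`cores` must be non-empty")
  missing <- setdiff(cores, names(annotations))
  if (length(missing) > 0L) {
    stop("core protein(s) absent from annotation map: ",
         paste(missing, collapse = ", "))
  }
  pool <- function(field) {
    sort(unique(unlist(lapply(annotations[cores], `[[`, field),
                       use.names = FALSE)))
  }
  tab <- structure(
    list(
      component_terms = pool("component_terms"),
      function_terms  = pool("function_terms"),
      process_terms   = pool("process_terms"),
      n_core_proteins = length(cores)
    ),
    class = "annotation_table"
  )
  empty <- c("component", "function", "process")[
    vapply(tab[1:3], length, 1L) == 0L]
  if (length(empty) > 0L) {
    warning("annotation table has empty aspect(s): ",
            paste(empty, collapse = ", "),
            " - the permissibility rule will reject every protein",
            call. = FALSE)
  }
  tab
}

#' @export
print.annotation_table <- function(x, ...) {
  cat("<annotation_table> pooled from ", x$n_core_proteins, " core proteins; C:",
      length(x$component_terms), " F:", length(x$function_terms),
      " P:", length(x$process_terms), " terms\n", sep = "")
  invisible(x)
}

#' Selective-permissibility admission rule
#'
#' A protein is permissible when its annotation set intersects the pooled
#' core-protein table in every one of the three GO aspects (at least one
#' shared component term, one shared function term and one shared process
#' term). A protein lacking any annotation in some aspect cannot satisfy
#' that aspect and is therefore non-permissible.
#'
#' @param protein_annotations An [annotation_set].
#' @param table An `annotation_table` from [build_annotation_table()].
#' @return Logical flag.
#' @export
is_permissible <- function(protein_annotations, table) {
  stopifnot(inherits(table, "annotation_table"))
  if (is.null(protein_annotations)) return(FALSE)
  any(protein_annotations$component_terms %in% table$component_terms) &&
    any(protein_annotations$function_terms %in% table$function_terms) &&
    any(protein_annotations$process_terms %in% table$process_terms)
}

# Write the pooled table as a TSV (one term per row with its aspect).
.write_annotation_table <- function(table, path) {
  df <- data.frame(
    term = c(table$component_terms, table$function_terms, table$process_terms),
    aspect = rep(c("C", "F", "P"),
                 c(length(table$component_terms),
                   length(table$function_terms),
                   length(table$process_terms))),
    stringsAsFactors = FALSE
  )
  .write_tsv(df, path)
}
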