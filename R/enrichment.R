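# Hypergeometric GO biological-process enrichment of modules with
# Benjamini-Hochberg FDR, and extraction of unknown-function candidates.

#' GO biological-process root term
#'
#' A protein annotated only to the aspect root carries no functional
#' information; such proteins count as unknown-function candidates.
#' @export
GO_BP_ROOT <- "GO:0008150"

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability that a module
#' of n proteins drawn from a reference of N proteins, K of which carry the
#' term, contains k or more carriers. Computed in log space via
#' [stats::phyper()].
#'
#' @param k Carriers observed in the module.
#' @param n Module size (members in the reference).
#' @param K Carriers in the reference.
#' @param N Reference size.
#' @return Probability in `[0, 1]`.
#' @export
hypergeometric_p <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || k > min(n, K) || n > N || K > N) {
    stop(sprintf("invalid hypergeometric bounds: k=%d n=%d K=%d N=%d", k, n, K, N))
  }
  if (k == 0L) return(1.0)
  phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values in the input order (monotone non-decreasing in
#'   sorted order, capped at 1, never below the raw p).
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' GO biological-process enrichment of modules
#'
#' One hypergeometric test per (module, process term present in the module),
#' for modules with at least `min_size` members; the reference set is the
#' whole annotation of the analyzed network (every protein of `reference`
#' carrying at least one process term). Benjamini-Hochberg correction is
#' applied within each module's term family; records with `q < alpha` are
#' reported sorted by q (then module, then term).
#'
#' @param modules Module list from [mcode()].
#' @param annotations Named list of [annotation_set] objects.
#' @param reference Character vector: the protein universe (typically all
#'   nodes of the analyzed network). Proteins without process annotations
#'   are dropped from the universe.
#' @param alpha FDR significance level (default 0.0001).
#' @param min_size Smallest module tested (default 5).
#' @return Data.frame of enrichment records: `module_rank`, `term`, `k`,
#'   `n`, `K`, `N`, `p_value`, `q_value`.
#' @export
enrich_modules <- function(modules, annotations, reference,
                           alpha = 0.0001, min_size = 5) {
  alpha <- .check_prob(alpha, "alpha")
  min_size <- .check_count(min_size, "min_size")
  reference <- intersect(reference, names(annotations))
  ref_terms <- lapply(annotations[reference], `[[`, "process_terms")
  reference <- reference[vapply(ref_terms, length, 1L) > 0L]
  if (length(reference) == 0L) stop("empty reference set: no process-annotated protein")
  ref_terms <- ref_terms[reference]
  N <- length(reference)
  term_counts <- table(unlist(ref_terms, use.names = FALSE))

  out <- list()
  for (m in modules) {
    if (length(m$members) < min_size) next
    members <- intersect(m$members, reference)
    n <- length(members)
    if (n == 0L) next
    mod_terms <- table(unlist(ref_terms[members], use.names = FALSE))
    terms <- names(mod_terms)
    if (length(terms) == 0L) next
    k <- as.integer(mod_terms)
    K <- as.integer(term_counts[terms])
    p <- vapply(seq_along(terms),
                function(i) hypergeometric_p(k[i], n, K[i], N), 1.0)
    q <- bh_adjust(p)
    out[[length(out) + 1L]] <- data.frame(
      module_rank = m$rank, term = terms, k = k, n = n, K = K, N = N,
      p_value = p, q_value = q, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(module_rank = integer(), term = character(),
                      k = integer(), n = integer(), K = integer(), N = integer(),
                      p_value = numeric(), q_value = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[res$q_value < alpha, , drop = FALSE]
  res <- res[order(res$q_value, res$module_rank, res$term), ]
  rownames(res) <- NULL
  res
}

#' Unknown-function candidate proteins within modules
#'
#' Members of reported modules whose biological-process annotation is empty
#' (`no_process_annotation`) or consists only of the biological-process root
#' term (`root_only`): the module context nominates them as candidates for
#' the phenotype while their own function is uncharacterized.
#'
#' @param modules Module list from [mcode()].
#' @param annotations Named list of [annotation_set] objects; proteins
#'   absent from the map count as unannotated.
#' @param min_module_size Only modules at least this large contribute
#'   candidates (default 5, matching the enrichment filter).
#' @return Data.frame with columns `protein`, `module_rank`, `reason`,
#'   ordered by module rank then protein id.
#' @export
unknown_function_candidates <- function(modules, annotations, min_module_size = 5) {
  out <- list()
  for (m in modules) {
    if (length(m$members) < min_module_size) next
    for (prot in sort(m$members)) {
      pr <- annotations[[prot]]
      terms <- if (is.null(pr)) character() else pr$process_terms
      reason <- if (length(terms) == 0L) "no_process_annotation"
        else if (all(terms == GO_BP_ROOT)) "root_only"
        else NA_character_
      if (!is.na(reason)) {
        out[[length(out) + 1L]] <- data.frame(
          protein = prot, module_rank = m$rank, reason = reason,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(protein = character(), module_rank = integer(),
                      reason = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$module_rank, res$protein), ]
  rownames(res) <- NULL
  res
}
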