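# Reporter transcription factors: aggregate the expression significance of
# a TF's targets into a size-corrected z-score against an empirical
# background of random gene sets.

#' Inverse-normal transform of gene p-values
#'
#' Maps each gene's p-value to z = qnorm(1 - p); p-values are clipped to
#' `[1e-15, 1 - 1e-15]` before the transform so extreme inputs stay finite.
#'
#' @param gene_pvalues Named numeric vector of p-values in `(0, 1]`.
#' @return Named numeric vector of z-scores.
#' @export
gene_z_scores <- function(gene_pvalues) {
  p <- as.numeric(gene_pvalues)
  bad <- is.na(p) | p <= 0 | p > 1
  if (any(bad)) {
    stop("p-value outside (0, 1] for gene(s): ",
         paste(head(names(gene_pvalues)[bad], 5L), collapse = ", "))
  }
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  setNames(qnorm(1 - p), names(gene_pvalues))
}

#' Reporter transcription-factor scoring
#'
#' For each TF with n scored targets, the raw score is the targets' z-sum
#' divided by sqrt(n). Because z-sums of larger target sets have larger
#' spread under dependence, the raw score is size-corrected against an
#' empirical background: for every distinct n, `background_samples` random
#' gene sets of size n are drawn from all scored genes and
#' `corrected_z = (raw_z - mu_n) / sigma_n`. The reporter p-value is the
#' upper-tail standard-normal probability of the corrected score; no
#' correction across TFs is applied (the published threshold is a raw
#' p < 0.05). Regulatory edges are deduplicated; targets without a z-score
#' are excluded; TFs left with no scored target are skipped with a warning.
#'
#' @param regnet Data.frame with columns `tf` and `target`.
#' @param gene_z Named numeric vector from [gene_z_scores()].
#' @param background_samples Random sets per distinct target-set size
#'   (>= 1000).
#' @param seed Integer seed for the background sampling.
#' @param alpha Significance threshold (default 0.05).
#' @return Data.frame sorted by p-value: `tf`, `n_targets_scored`, `raw_z`,
#'   `corrected_z`, `p_value`, `significant`.
#' @export
score_reporters <- function(regnet, gene_z, background_samples = 10000,
                            seed = 1L, alpha = 0.05) {
  stopifnot(all(c("tf", "target") %in% names(regnet)))
  background_samples <- .check_count(background_samples, "background_samples",
                                     min = 1000L)
  alpha <- .check_prob(alpha, "alpha")
  regnet <- unique(regnet[, c("tf", "target")])
  all_tfs <- unique(regnet$tf)
  regnet <- regnet[regnet$target %in% names(gene_z), , drop = FALSE]
  targets <- split(regnet$target, regnet$tf)
  skipped <- setdiff(all_tfs, names(targets))
  if (length(skipped) > 0L) {
    warning("TF(s) skipped with no scored target: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  if (length(targets) == 0L) stop("no TF has a scored target")

  ns <- vapply(targets, length, 1L)
  z <- gene_z
  raw <- vapply(targets, function(tg) sum(z[tg]) / sqrt(length(tg)), 1.0)

  bg <- withr::with_seed(seed, {
    sizes <- sort(unique(ns))
    stats_by_n <- lapply(sizes, function(n) {
      sums <- vapply(seq_len(background_samples), function(i) {
        sum(z[sample.int(length(z), n)]) / sqrt(n)
      }, 1.0)
      c(mu = mean(sums), sigma = sd(sums))
    })
    names(stats_by_n) <- as.character(sizes)
    stats_by_n
  })

  corrected <- vapply(seq_along(targets), function(i) {
    st <- bg[[as.character(ns[i])]]
    if (st["sigma"] < 1e-12) 0 else unname((raw[i] - st["mu"]) / st["sigma"])
  }, 1.0)
  p <- pnorm(corrected, lower.tail = FALSE)

  res <- data.frame(tf = names(targets), n_targets_scored = unname(ns),
                    raw_z = unname(raw), corrected_z = corrected,
                    p_value = p, significant = p < alpha,
                    stringsAsFactors = FALSE)
  res <- res[order(res$p_value, res$tf), ]
  rownames(res) <- NULL
  res
}
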