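#' Pipeline configuration
#'
#' Bundles every tunable threshold of the pipeline with its published
#' default: the centrality-tuning test level (`alpha_tuning = 0.0001`, a
#' two-tailed t-test at 99.99% confidence), the size of the
#' degree-preserving null ensemble (`n_random = 100`), the MCODE
#' parameterization (degree threshold 2; node score threshold 0.2; k-core
#' threshold 2; maximum depth 100; haircut on; fluff off), the
#' module-enrichment level (`enrichment_alpha = 0.0001`) applied to modules
#' with at least `min_module_size = 5` members, and the reporter-TF level
#' (`reporter_alpha = 0.05`).
#'
#' @param alpha_tuning Significance level of the per-node centrality t-test.
#' @param n_random Number of degree-preserving random networks.
#' @param mcode_degree_threshold,mcode_node_score_threshold,mcode_kcore,mcode_max_depth,mcode_haircut,mcode_fluff
#'   MCODE parameters; see [mcode_params()].
#' @param enrichment_alpha FDR level for module GO enrichment.
#' @param min_module_size Smallest module size that is tested for enrichment.
#' @param reporter_alpha Significance level for reporter transcription factors.
#' @param seed Integer seed owned by the pipeline; every randomized stage
#'   derives its sub-seed from it.
#' @param swap_multiplier Attempted double-edge swaps per edge during each
#'   randomization.
#' @param background_samples Random gene sets per target-set size for the
#'   reporter background.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha_tuning = 0.0001,
                            n_random = 100,
                            mcode_degree_threshold = 2,
                            mcode_node_score_threshold = 0.2,
                            mcode_kcore = 2,
                            mcode_max_depth = 100,
                            mcode_haircut = TRUE,
                            mcode_fluff = FALSE,
                            enrichment_alpha = 0.0001,
                            min_module_size = 5,
                            reporter_alpha = 0.05,
                            seed = 1L,
                            swap_multiplier = 10,
                            background_samples = 10000) {
  cfg <- list(
    alpha_tuning = .check_prob(alpha_tuning, "alpha_tuning"),
    n_random = .check_count(n_random, "n_random"),
    mcode_degree_threshold = .check_count(mcode_degree_threshold, "mcode_degree_threshold"),
    mcode_node_score_threshold = .check_fraction(mcode_node_score_threshold,
                                                 "mcode_node_score_threshold"),
    mcode_kcore = .check_count(mcode_kcore, "mcode_kcore"),
    mcode_max_depth = .check_count(mcode_max_depth, "mcode_max_depth"),
    mcode_haircut = isTRUE(mcode_haircut),
    mcode_fluff = isTRUE(mcode_fluff),
    enrichment_alpha = .check_prob(enrichment_alpha, "enrichment_alpha"),
    min_module_size = .check_count(min_module_size, "min_module_size"),
    reporter_alpha = .check_prob(reporter_alpha, "reporter_alpha"),
    seed = .check_count(seed, "seed", min = 0L),
    swap_multiplier = .check_count(swap_multiplier, "swap_multiplier"),
    background_samples = .check_count(background_samples, "background_samples")
  )
  structure(cfg, class = "pipeline_config")
}

#' Read a flat key = value configuration file
#'
#' Every key has the published default (see [pipeline_config()]); unknown
#' keys are errors, by design: a config file that silently ignores a typo is
#' not reproducible.
#'
#' @param path Path to the text file; `#` comments and blank lines ignored.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: '", ln, "'")
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    if (!key %in% names(formals(pipeline_config))) {
      stop("unknown configuration key: '", key, "'")
    }
    args[[key]] <- if (val %in% c("on", "true", "TRUE", "yes")) TRUE
      else if (val %in% c("off", "false", "FALSE", "no")) FALSE
      else as.numeric(val)
  }
  do.call(pipeline_config, args)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (k in names(x)) cat("  ", k, " = ", format(x[[k]]), "\n", sep = "")
  invisible(x)
}
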