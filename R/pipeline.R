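#' Run the full candidate-gene pipeline
#'
#' Chains the stages: read inputs, reconstruct the seed-guided network
#' ([spa_reconstruct()]), tune it against the degree-preserving centrality
#' null ([build_evc_ensemble()], [tune_network()]), summarize topology
#' ([summarize_topology()]), detect dense modules ([mcode()]), enrich them
#' for biological-process terms ([enrich_modules()]), extract
#' unknown-function candidates ([unknown_function_candidates()]) and - when
#' regulatory inputs are given - score reporter transcription factors
#' ([score_reporters()]). Deterministic for a fixed `config$seed`: a second
#' run writes byte-identical reports. Every stage logs its input size,
#' output size and thresholds.
#'
#' @param config A [pipeline_config()].
#' @param ppi_path Interaction file: BioGRID TAB 2.0, SIF or two-column edge
#'   TSV (autodetected).
#' @param gaf_path GAF 2.x annotation file.
#' @param cores_path Newline-terminated list of core protein ids.
#' @param out_dir Report directory (created; existing files overwritten).
#' @param regnet_path,pvalues_path Optional reporter-stage inputs; when
#'   either is missing the reporter stage is skipped with a logged notice.
#' @param quiet Suppress console log messages.
#' @return Invisibly, a list with the in-memory stage results (`etn`,
#'   `tuning`, `topology`, `modules`, `enrichment`, `candidates`,
#'   `reporters`).
#' @export
run_pipeline <- function(config, ppi_path, gaf_path, cores_path, out_dir,
                         regnet_path = NULL, pvalues_path = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- .logger(file = file.path(out_dir, "pipeline.log"), quiet = quiet)
  .log_msg(log, "pipeline seed = ", config$seed,
           "; alpha_tuning = ", config$alpha_tuning,
           "; n_random = ", config$n_random,
           "; enrichment_alpha = ", config$enrichment_alpha,
           "; min_module_size = ", config$min_module_size,
           "; reporter_alpha = ", config$reporter_alpha)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  interactions <- stage("read_ppi", .read_interactions(ppi_path))
  .log_msg(log, "interactions read: ", nrow(interactions), " physical records")
  annotations <- stage("read_gaf", read_gaf(gaf_path))
  .log_msg(log, "annotations read: ", length(annotations), " proteins")
  cores <- stage("read_cores", read_id_list(cores_path))
  .log_msg(log, "core proteins read: ", length(cores))

  etn <- stage("reconstruct",
               spa_reconstruct(cores, annotations, interactions, log = log))
  write_network(etn, file.path(out_dir, "etn.tsv"), format = "edge_tsv")
  .write_annotation_table(etn$annotation_table,
                          file.path(out_dir, "annotation_table.tsv"))

  ensemble <- stage("tune", build_evc_ensemble(
    etn, R = config$n_random, seed = .stage_seed(config$seed, 100L),
    swap_multiplier = config$swap_multiplier))
  tuned <- stage("tune", tune_network(etn, ensemble, alpha = config$alpha_tuning))
  .log_msg(log, "tuning: ", sum(tuned$records$retained), " of ",
           nrow(tuned$records), " nodes retained at alpha = ", config$alpha_tuning,
           " with R = ", config$n_random)
  write_network(tuned$network, file.path(out_dir, "tetn.tsv"), format = "edge_tsv")
  .write_tsv(.format_tuning(tuned$records), file.path(out_dir, "tuning_table.tsv"))

  topo <- stage("topology", summarize_topology(etn))
  .write_tsv(data.frame(
    network = "etn", n_nodes = topo$n_nodes, n_edges = topo$n_edges,
    diameter = topo$diameter,
    avg_shortest_path = round(topo$avg_shortest_path, 6),
    avg_clustering = round(topo$avg_clustering, 6),
    power_law_w = round(topo$power_law_w, 6),
    power_law_r2 = round(topo$power_law_r2, 6)
  ), file.path(out_dir, "topology_summary.tsv"))
  .write_tsv(data.frame(k = as.integer(names(topo$degree_distribution)),
                        n_nodes = as.integer(topo$degree_distribution)),
             file.path(out_dir, "degree_distribution.tsv"))
  ck <- clustering_by_degree(etn)
  ck$ck <- round(ck$ck, 6)
  .write_tsv(ck, file.path(out_dir, "clustering_by_degree.tsv"))
  .log_msg(log, "topology: diameter ", topo$diameter, ", C(k) exponent w = ",
           round(topo$power_law_w, 3))

  mparams <- mcode_params(
    degree_threshold = config$mcode_degree_threshold,
    node_score_threshold = config$mcode_node_score_threshold,
    kcore_threshold = config$mcode_kcore,
    max_depth = config$mcode_max_depth,
    haircut = config$mcode_haircut,
    fluff = config$mcode_fluff)
  modules <- stage("modules", mcode(tuned$network, mparams))
  .log_msg(log, "mcode: ", length(modules), " modules in the tuned network")
  mtab <- modules_to_table(modules)
  mtab$score <- round(mtab$score, 6)
  .write_tsv(mtab, file.path(out_dir, "modules.tsv"))

  enr <- stage("enrich", enrich_modules(
    modules, annotations, reference = igraph::V(tuned$network)$name,
    alpha = config$enrichment_alpha, min_size = config$min_module_size))
  enr$p_value <- signif(enr$p_value, 8)
  enr$q_value <- signif(enr$q_value, 8)
  .write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
  cand <- stage("enrich", unknown_function_candidates(
    modules, annotations, min_module_size = config$min_module_size))
  .write_tsv(cand, file.path(out_dir, "candidates.tsv"))
  .log_msg(log, "enrichment: ", nrow(enr), " significant term records; ",
           nrow(cand), " unknown-function candidates")

  reporters <- NULL
  if (is.null(regnet_path) || is.null(pvalues_path)) {
    .log_msg(log, "reporter stage skipped: regulatory network or p-value ",
             "table not provided", level = "NOTE")
  } else {
    regnet <- stage("reporter", read_regnet(regnet_path))
    pvals <- stage("reporter", read_pvalues(pvalues_path))
    z <- stage("reporter", gene_z_scores(pvals))
    reporters <- stage("reporter", score_reporters(
      regnet, z, background_samples = config$background_samples,
      seed = .stage_seed(config$seed, 200L), alpha = config$reporter_alpha))
    rtab <- reporters
    rtab$raw_z <- round(rtab$raw_z, 6)
    rtab$corrected_z <- round(rtab$corrected_z, 6)
    rtab$p_value <- signif(rtab$p_value, 8)
    .write_tsv(rtab, file.path(out_dir, "reporter_tfs.tsv"))
    .log_msg(log, "reporter: ", sum(reporters$significant), " of ",
             nrow(reporters), " TFs significant at alpha = ",
             config$reporter_alpha)
  }

  invisible(list(etn = etn, tuning = tuned, topology = topo, modules = modules,
                 enrichment = enr, candidates = cand, reporters = reporters))
}

# Round the tuning table for stable on-disk formatting.
.format_tuning <- function(records) {
  records$observed_evc <- signif(records$observed_evc, 8)
  records$mean_random_evc <- signif(records$mean_random_evc, 8)
  records$t_statistic <- signif(records$t_statistic, 8)
  records$p_value <- signif(records$p_value, 8)
  records
}

# Sniff the interaction file format: BioGRID TAB 2.0 (>= 13 tab fields or a
# '#BioGRID' header), else SIF / two-column edge TSV.
.read_interactions <- function(path) {
  first <- readLines(path, n = 5L)
  nfields <- max(lengths(strsplit(first, "\t", fixed = TRUE)))
  if (startsWith(first[1L], "#BioGRID") || nfields >= .BG_MIN_COLS) {
    return(read_biogrid_tab2(path, keep = "physical"))
  }
  g <- read_network(path)
  el <- .edge_table(g)
  data.frame(protein_a = el[, 1L], protein_b = el[, 2L],
             interaction_class = "physical",
             source_line = seq_len(nrow(el)), stringsAsFactors = FALSE)
}
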