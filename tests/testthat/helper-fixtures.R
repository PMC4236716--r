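# In-code fixtures: tiny files and annotation maps built at test time.

# A 3-interaction BioGRID TAB 2.0 snippet: two physical rows, one genetic.
write_biogrid_fixture <- function(path) {
  pad <- function(a, b, type) {
    f <- rep("-", 24)
    f[1] <- "1"; f[6] <- a; f[7] <- b
    f[8] <- paste0(a, "sym"); f[9] <- paste0(b, "sym")
    f[13] <- type
    paste(f, collapse = "\t")
  }
  writeLines(c(
    "#BioGRID Interaction ID\theader",
    pad("YAL001C", "YBR002W", "physical"),
    pad("YAL001C", "YCR003W", "genetic"),
    pad("YBR002W", "YCR003W", "physical")
  ), path)
  path
}

# Minimal GAF content. rows = list of character vectors
# c(id, qualifier, go, aspect).
write_gaf_fixture <- function(path, rows) {
  lines <- c("!gaf-version: 2.2",
             vapply(rows, function(r) {
               paste("SYN", r[1], r[1], r[2], r[3], "SYN:1", "IEA", "",
                     r[4], "", "", "protein", "taxon:1", "20130101",
                     "SYN", "", "", sep = "\t")
             }, ""))
  writeLines(lines, path)
  path
}

# Hand-built annotation map: cores {X, Y}; A-D permissible by construction;
# E shares C and F terms but no P term.
tiny_annotations <- function() {
  list(
    X = annotation_set("GO:0000001", "GO:0000011", c("GO:0000021", "GO:0000022")),
    Y = annotation_set("GO:0000002", "GO:0000011", "GO:0000022"),
    A = annotation_set("GO:0000001", "GO:0000011", "GO:0000021"),
    B = annotation_set("GO:0000002", "GO:0000011", "GO:0000022"),
    C = annotation_set("GO:0000001", "GO:0000011", "GO:0000022"),
    D = annotation_set("GO:0000002", "GO:0000011", "GO:0000021"),
    E = annotation_set("GO:0000001", "GO:0000011", "GO:0000099")
  )
}

interactions_df <- function(pairs) {
  data.frame(protein_a = pairs[, 1], protein_b = pairs[, 2],
             interaction_class = "physical",
             source_line = seq_len(nrow(pairs)), stringsAsFactors = FALSE)
}

# Small benchmark kept fast for file-level pipeline tests.
small_benchmark_params <- function(seed = 1L) {
  generator_params(n_proteins = 300, n_planted_modules = 2, module_size = 7,
                   n_cores = 8, targets_per_tf = 20, n_tfs = 10,
                   n_active_tfs = 2, seed = seed)
}
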