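#' @importFrom stats pt sd qnorm pnorm phyper p.adjust setNames lm coef rbinom runif rnorm
#' @importFrom utils read.delim write.table head combn
NULL

# Stage offsets added to the pipeline seed so that every randomized stage
# draws from its own deterministic stream.
.stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((as.numeric(seed) + stage) %% .Machine$integer.max)
}

.check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

.check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1) {
    stop(sprintf("`%s` must be a probability strictly inside (0, 1)", name), call. = FALSE)
  }
  as.numeric(x)
}

.check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must lie in [0, 1]", name), call. = FALSE)
  }
  as.numeric(x)
}

# Deterministic, timestamp-free stage logging. Reports run byte-identically
# for a fixed seed, so log lines carry no clocks.
.log_msg <- function(log, ..., level = "INFO") {
  line <- sprintf("[%s] %s", level, paste0(...))
  if (!is.null(log$file)) cat(line, "\n", sep = "", file = log$file, append = TRUE)
  if (isTRUE(log$quiet)) return(invisible(line))
  message(line)
  invisible(line)
}

.logger <- function(file = NULL, quiet = FALSE) {
  if (!is.null(file) && file.exists(file)) unlink(file)
  list(file = file, quiet = quiet)
}

# Write a data.frame as a TSV report table with stable formatting.
.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
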