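#!/usr/bin/env Rscript
# Thin command-line wrapper over the package's pipeline functions.
#
#   Rscript scripts/pipeline.R run <config.yaml> [--seed N] [--out DIR]
#   Rscript scripts/pipeline.R generate [--seed N] [--out DIR]
#
# `run` executes the full analysis from a YAML configuration; `generate`
# only writes a synthetic cohort (annotation, truth table and per-stage
# inputs) using the generator defaults.

suppressPackageStartupMessages(library(enhmeth))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L || !args[1] %in% c("run", "generate")) {
  cat("usage: pipeline.R run <config.yaml> [--seed N] [--out DIR]\n",
      "       pipeline.R generate [--seed N] [--out DIR]\n")
  quit(status = 2L)
}
mode <- args[1]
get_arg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1L && i < length(args)) args[i + 1L] else default
}

status <- tryCatch({
  config <- if (mode == "run" && length(args) >= 2L &&
                !startsWith(args[2], "--")) {
    read_pipeline_config(args[2])
  } else {
    pipeline_config()
  }
  seed <- get_arg("--seed")
  if (!is.null(seed)) config$seed <- as.integer(seed)
  out <- get_arg("--out")
  if (!is.null(out)) config$out_dir <- out
  if (mode == "generate") {
    cohort <- simulate_cohort(do.call(effect_config,
                                      c(config$generator,
                                        list(seed = config$seed))))
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_bed(cohort$annotation,
              file.path(config$out_dir, "annotation.bed"))
    write.table(cohort$truth, file.path(config$out_dir, "truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(cohort$region_signal$counts,
                file.path(config$out_dir, "region_counts.tsv"),
                sep = "\t", quote = FALSE)
    write.table(cohort$survival_os,
                file.path(config$out_dir, "survival_os.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cat("cohort written to", config$out_dir, "\n")
  } else {
    manifest <- run_pipeline(config)
    for (nm in names(manifest$counts)) {
      cat(sprintf("%s\t%s\n", nm, format(manifest$counts[[nm]])))
    }
    cat("outputs written to", config$out_dir, "\n")
  }
  0L
}, error = function(e) {
  message("error: ", conditionMessage(e))
  if (grepl("config|yaml|must be|validation", conditionMessage(e),
            ignore.case = TRUE)) 2L else 1L
})
quit(status = status)
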