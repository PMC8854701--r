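#!/usr/bin/env Rscript
# Thin command-line wrapper over endoclone::run_pipeline().
#
# Usage:
#   Rscript scripts/run_pipeline.R --out <dir> [--seed <int>]
#     [--input <dir>] [--stages filter,burden,signatures,dnds,cluster,timing]
#
# Without --input a synthetic cohort is simulated with the default
# configuration; with --input the directory must contain mutations.tsv,
# glands.tsv and clinical.tsv.

suppressMessages(library(endoclone))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
out <- get_arg("--out", "pipeline_out")
seed <- as.integer(get_arg("--seed", "1"))
input <- get_arg("--input", NA)
stages <- strsplit(get_arg(
  "--stages", "filter,burden,signatures,dnds,cluster,timing"), ",")[[1]]

cfg <- pipeline_config(
  input_dir = if (is.na(input)) NULL else input,
  stages = stages,
  seed = seed
)
run_pipeline(cfg, out)
cat("pipeline outputs written to", out, "\n")
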