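#!/usr/bin/env Rscript
# Thin wrapper over protophys::run_pipeline().
# Usage: Rscript scripts/run_pipeline.R [--config cfg.yaml] [--seed <int>] --out DIR

suppressMessages(library(protophys))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
cfg_path <- get_arg("--config", NA)
out <- get_arg("--out", "pipeline_out")
cfg <- if (!is.na(cfg_path)) read_run_config(cfg_path) else
  run_config(seed = as.integer(get_arg("--seed", "1")))
run_pipeline(cfg, out)
cat("report bundle written to", out, "\n")
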