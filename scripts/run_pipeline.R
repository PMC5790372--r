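#!/usr/bin/env Rscript
# Thin command-line wrapper around speechtrack::run_pipeline().
#
# Usage: Rscript scripts/run_pipeline.R [config.yaml] [--out dir]

suppressPackageStartupMessages(library(speechtrack))

args <- commandArgs(trailingOnly = TRUE)
config <- list()
out_dir <- NULL
i <- 1
while (i <= length(args)) {
  if (args[i] == "--out") { out_dir <- args[i + 1]; i <- i + 2 }
  else { config <- args[i]; i <- i + 1 }
}
manifest <- run_pipeline(config, out_dir = out_dir)
for (s in names(manifest$stages))
  cat(sprintf("%-18s %s\n", s, manifest$stages[[s]]$status))
cat("manifest:", file.path(manifest$config$out_dir, "manifest.json"), "\n")
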