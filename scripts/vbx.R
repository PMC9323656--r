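#!/usr/bin/env Rscript

# Thin command-line wrapper over the virtualbiopsy package.
#
#   Rscript scripts/vbx.R simulate --out <dir> [--seed <int>]
#   Rscript scripts/vbx.R all --input <cohort dir> --out <dir> [--alpha a]
#   Rscript scripts/vbx.R all --synthetic --out <dir> [--seed s] [--alpha a]
#
# `simulate` writes a synthetic cohort directory (NIfTI volumes and masks,
# VOI JSONs, cohort.csv); `all` runs extraction, noise filtering, selection,
# ROC/Youden, survival and IHC analyses and writes the report bundle.

suppressMessages(library(virtualbiopsy))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) == 0) stop("usage: vbx.R <simulate|all> [options]")
cmd <- args[1]
opt <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i)) return(default)
  if (i == length(args) || startsWith(args[i + 1], "--")) return(TRUE)
  args[i + 1]
}

seed <- as.integer(opt("--seed", "1"))
out <- opt("--out", "vbx-output")
alpha <- as.numeric(opt("--alpha", "0.05"))

if (cmd == "simulate") {
  generate_cohort(cohort_config(seed = seed), dir = out)
  message("synthetic cohort written to ", out)
} else if (cmd == "all") {
  cfg <- if (isTRUE(opt("--synthetic")) || is.null(opt("--input")))
    pipeline_config(seed = seed, alpha = alpha, out_dir = out)
  else
    pipeline_config(synthetic = NULL, input_dir = opt("--input"),
                    alpha = alpha, out_dir = out)
  report <- run_pipeline(cfg)
  print(report)
} else {
  stop("unknown subcommand: ", cmd)
}
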