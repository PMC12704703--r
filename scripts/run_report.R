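#!/usr/bin/env Rscript
# Thin command-line wrapper over icbtcea::run_report().
#
# Usage:
#   Rscript scripts/run_report.R --out <dir> [--config <file>] [--seed <int>]
#          [--psa-n <int>] [--stages base,oneway,twoway,threshold,psa]

suppressPackageStartupMessages({
  library(optparse)
  library(icbtcea)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "parameter configuration file (YAML or JSON)"),
  make_option("--out", type = "character", default = "results/report",
              help = "output directory [default %default]"),
  make_option("--seed", type = "integer", default = 1,
              help = "master seed for the PSA [default %default]"),
  make_option("--psa-n", type = "integer", default = 10000, dest = "psa_n",
              help = "number of PSA draws [default %default]"),
  make_option("--stages", type = "character",
              default = "base,oneway,twoway,threshold,psa",
              help = "comma-separated stages [default %default]")
)))

report <- run_report(opts$out, config = opts$config, seed = opts$seed,
                     psa_n = opts$psa_n,
                     stages = strsplit(opts$stages, ",")[[1]])
print(report)
if (length(report$errors)) quit(status = 1)
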