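#!/usr/bin/env Rscript
# Thin command-line wrapper over the hdmea package.
#
#   Rscript scripts/hdmea.R run --config cfg.yaml [--seed N] [--outdir DIR]
#   Rscript scripts/hdmea.R synth --outdir DIR [--seed N] [--condition hyper]
#   Rscript scripts/hdmea.R compare --a a.csv --b b.csv --column value
#
# `run` executes the configured pipeline stages; `synth` writes one
# synthetic recording container; `compare` applies Welch's unpaired
# two-tailed t-test to a column of two CSV files.

suppressMessages({
  library(optparse)
  library(hdmea)
})

args <- commandArgs(trailingOnly = TRUE)
if (!length(args)) stop("usage: hdmea.R <run|synth|compare> [options]")
cmd <- args[1]
rest <- args[-1]

if (cmd == "run") {
  o <- parse_args(OptionParser(option_list = list(
    make_option("--config", type = "character", default = NULL),
    make_option("--seed", type = "integer", default = NULL),
    make_option("--outdir", type = "character", default = NULL))),
    args = rest)
  cfg <- if (is.null(o$config)) list() else yaml::read_yaml(o$config)
  if (!is.null(o$seed)) cfg$seed <- o$seed
  if (!is.null(o$outdir)) cfg$outdir <- o$outdir
  run_pipeline(cfg)
} else if (cmd == "synth") {
  o <- parse_args(OptionParser(option_list = list(
    make_option("--outdir", type = "character", default = "hdmea_run"),
    make_option("--seed", type = "integer", default = 1L),
    make_option("--condition", type = "character", default = "control"))),
    args = rest)
  run_pipeline(list(seed = o$seed, outdir = o$outdir,
                    stages = list(synth = TRUE),
                    synth = list(condition = o$condition)))
} else if (cmd == "compare") {
  o <- parse_args(OptionParser(option_list = list(
    make_option("--a", type = "character"),
    make_option("--b", type = "character"),
    make_option("--column", type = "character"))),
    args = rest)
  a <- utils::read.csv(o$a)[[o$column]]
  b <- utils::read.csv(o$b)[[o$column]]
  print(welch_test(a, b, labels = c(o$a, o$b)))
} else {
  stop("unknown subcommand: ", cmd)
}
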