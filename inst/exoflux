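#!/usr/bin/env Rscript

# Thin command-line wrapper over the exoflux package.
#
#   exoflux simulate     --out-prefix run1 [--config sim.yaml] [--seed N]
#   exoflux preprocess   --in-prefix run1 --out-prefix run1_corr [--config thr.yaml]
#   exoflux call         --in-prefix run1_corr --strain WT --out calls.tsv
#   exoflux differential --in-prefix run1_corr --wt WT --mutant yeaV_OE --out diff.tsv
#   exoflux infer        --in-prefix run1_corr --gene yeaV --out inf.tsv
#   exoflux score        --inferences inf.tsv --truth run1_truth.tsv
#
# --config points at a YAML file whose keys override exoflux_thresholds()
# (or sim_config() for `simulate`). All tables are TSV.

suppressPackageStartupMessages({
  library(optparse)
  library(exoflux)
})

`%||%` <- function(a, b) if (is.null(a)) b else a

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) {
  stop("usage: exoflux <simulate|preprocess|call|differential|infer|score> [options]")
}
cmd <- args[1]
rest <- args[-1]

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--in-prefix", type = "character", default = NULL,
              dest = "in_prefix"),
  make_option("--out-prefix", type = "character", default = "exoflux_run",
              dest = "out_prefix"),
  make_option("--out", type = "character", default = NULL),
  make_option("--strain", type = "character", default = "WT"),
  make_option("--wt", type = "character", default = "WT"),
  make_option("--mutant", type = "character", default = NULL),
  make_option("--gene", type = "character", default = NULL),
  make_option("--inferences", type = "character", default = NULL),
  make_option("--truth", type = "character", default = NULL)
)), args = rest)

load_overrides <- function(path) {
  if (is.null(path)) return(list())
  yaml::read_yaml(path)
}

thresholds_from <- function(opts) {
  do.call(exoflux_thresholds, load_overrides(opts$config))
}

read_prefix <- function(prefix) {
  read_peak_matrix(paste0(prefix, "_intensities.tsv"),
                   paste0(prefix, "_samples.tsv"),
                   paste0(prefix, "_features.tsv"))
}

if (cmd == "simulate") {
  ov <- load_overrides(opts$config)
  if (!is.null(ov$strains)) ov$strains <- do.call(tibble::tibble, ov$strains)
  cfg <- do.call(sim_config, c(ov, list(seed = opts$seed)))
  sim <- simulate_serum_experiment(cfg)
  write_peak_matrix(sim$matrix, opts$out_prefix)
  readr::write_tsv(sim$truth, paste0(opts$out_prefix, "_truth.tsv"))
} else if (cmd == "preprocess") {
  th <- thresholds_from(opts)
  m <- read_prefix(opts$in_prefix)
  corr <- loess_qc_correct(m, th)
  corr$features <- dedupe_features(corr, th)
  write_peak_matrix(corr, opts$out_prefix)
} else if (cmd == "call") {
  th <- thresholds_from(opts)
  m <- read_prefix(opts$in_prefix)
  write_calls(call_strain_transport(m, opts$strain, th),
              opts$out %||% "transport_calls.tsv")
} else if (cmd == "differential") {
  th <- thresholds_from(opts)
  m <- read_prefix(opts$in_prefix)
  write_calls(select_differential(m, opts$wt, opts$mutant, th),
              opts$out %||% "differential_calls.tsv")
} else if (cmd == "infer") {
  th <- thresholds_from(opts)
  m <- read_prefix(opts$in_prefix)
  write_calls(infer_transporter(m, opts$gene, wt = opts$wt, thresholds = th),
              opts$out %||% "direction_inferences.tsv")
} else if (cmd == "score") {
  inf <- read_calls(opts$inferences)
  truth <- readr::read_tsv(opts$truth, show_col_types = FALSE)
  print.data.frame(score_recovery(inf, truth))
} else {
  stop("unknown subcommand: ", cmd)
}
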