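#!/usr/bin/env Rscript
# Thin command-line front end over the phenokarst package.
#
#   Rscript scripts/pipeline.R simulate --scenario paper_like --seed 7 --out data/
#   Rscript scripts/pipeline.R analyze --plots data/plots.csv --cover data/cover.csv \
#       --phenology data/phenology.csv --temperature data/temperature.csv --out results/
#   Rscript scripts/pipeline.R analyze --scenario paper_like --seed 7 --out results/
#
# Logging goes to standard error; results only to files.

suppressMessages(library(phenokarst))
suppressMessages(library(optparse))

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) < 1 || !argv[1] %in% c("simulate", "analyze")) {
  stop("Usage: pipeline.R <simulate|analyze> [options]; see script header.")
}
cmd <- argv[1]

opts <- parse_args(OptionParser(option_list = list(
  make_option("--scenario", type = "character", default = NULL),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--plots", type = "character", default = NULL),
  make_option("--cover", type = "character", default = NULL),
  make_option("--phenology", type = "character", default = NULL),
  make_option("--temperature", type = "character", default = NULL),
  make_option("--out", type = "character", default = "results"),
  make_option("--species", type = "character", default = NULL),
  make_option("--no-ln-tdd", action = "store_true", default = FALSE,
              dest = "no_ln_tdd"),
  make_option("--no-sqrt-ilg", action = "store_true", default = FALSE,
              dest = "no_sqrt_ilg")
)), args = argv[-1])

if (cmd == "simulate") {
  if (is.null(opts$scenario)) stop("simulate requires --scenario")
  bundle <- generate_landscape(scenario_config(opts$scenario), seed = opts$seed)
  write_dataset(bundle, opts$out)
  message(sprintf("Wrote dataset (%d plots) to %s", nrow(bundle$plots), opts$out))
} else {
  paths <- NULL
  if (!is.null(opts$plots)) {
    paths <- list(plots = opts$plots, cover = opts$cover,
                  phenology = opts$phenology, temperature = opts$temperature)
  }
  run_pipeline(paths = paths, scenario = opts$scenario, seed = opts$seed,
               out_dir = opts$out,
               sqrt_ilg = !opts$no_sqrt_ilg, ln_tdd = !opts$no_ln_tdd,
               focal_species = opts$species)
}
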