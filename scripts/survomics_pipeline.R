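#!/usr/bin/env Rscript
# Thin command-line wrapper over survomics::run_pipeline().
#
# Usage:
#   Rscript scripts/survomics_pipeline.R --config config.yaml \
#       [--stages simulate,labels,featurize,select,evaluate] \
#       [--seed 1] [--log-level info]

suppressPackageStartupMessages({
  library(optparse)
  library(survomics)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", help = "YAML pipeline config"),
  make_option("--stages", type = "character",
              default = "simulate,labels,featurize,select,evaluate"),
  make_option("--seed", type = "integer", default = NA_integer_,
              help = "override the config's master seed"),
  make_option("--log-level", type = "character", default = "info",
              dest = "log_level", help = "info or quiet")
)))

if (is.null(opts$config)) stop("--config is required", call. = FALSE)
config <- yaml::read_yaml(opts$config)
if (!is.na(opts$seed)) config$seed <- opts$seed
stages <- strsplit(opts$stages, ",", fixed = TRUE)[[1]]

run <- function() run_pipeline(config, stages = stages)
if (opts$log_level == "quiet") suppressMessages(run()) else run()
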