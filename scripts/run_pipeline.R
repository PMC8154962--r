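#!/usr/bin/env Rscript
# Thin command-line wrapper over ulcerscore::run_pipeline().
# Usage:
#   Rscript scripts/run_pipeline.R --config cfg.yaml --out outdir --seed 1 \
#       [--n-bootstrap N] [--thresholds LO:HI:STEP] [--verbose]

suppressPackageStartupMessages({
  library(optparse)
  library(ulcerscore)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character",
              default = system.file("extdata", "demo_config.yaml",
                                    package = "ulcerscore")),
  make_option("--out", type = "character", default = "pipeline_out"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--n-bootstrap", type = "integer", default = NA_integer_,
              dest = "n_bootstrap"),
  make_option("--thresholds", type = "character", default = NULL,
              help = "LO:HI:STEP, e.g. 0.005:0.30:0.005"),
  make_option("--verbose", action = "store_true", default = FALSE)
)))

config <- yaml::read_yaml(opts$config)
if (!is.na(opts$n_bootstrap)) config$n_bootstrap <- opts$n_bootstrap
if (!is.null(opts$thresholds)) {
  parts <- as.numeric(strsplit(opts$thresholds, ":")[[1]])
  if (length(parts) != 3 || anyNA(parts)) {
    stop("--thresholds must be LO:HI:STEP")
  }
  config$thresholds <- list(lo = parts[1], hi = parts[2], step = parts[3])
}

status <- tryCatch({
  run_pipeline(config, out_dir = opts$out, seed = opts$seed,
               verbose = opts$verbose)
  0L
}, error = function(e) {
  message(conditionMessage(e))
  1L
})
quit(status = status)
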