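#!/usr/bin/env Rscript

# Thin command-line wrapper over the spongenet package.
#   Rscript scripts/spongenet.R simulate --config cfg.yaml [--overwrite]
#   Rscript scripts/spongenet.R infer    --config cfg.yaml
#   Rscript scripts/spongenet.R isoform  --config cfg.yaml
#   Rscript scripts/spongenet.R compare  --a net_a.tsv --b net_b.tsv --out cmp.json

suppressMessages({
  library(spongenet)
  library(optparse)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) {
  stop("Usage: spongenet.R <simulate|infer|isoform|compare> [options]")
}
cmd <- args[1]

if (cmd == "compare") {
  opts <- parse_args(OptionParser(option_list = list(
    make_option("--a", type = "character"),
    make_option("--b", type = "character"),
    make_option("--out", type = "character", default = NULL)
  )), args = args[-1])
  cmp <- run_compare(opts$a, opts$b, output_path = opts$out)
  print(cmp$summary)
} else {
  opts <- parse_args(OptionParser(option_list = list(
    make_option("--config", type = "character"),
    make_option("--seed", type = "integer", default = NULL),
    make_option("--overwrite", action = "store_true", default = FALSE)
  )), args = args[-1])
  overrides <- if (is.null(opts$seed)) list() else list(seed = opts$seed)
  cfg <- do.call(read_pipeline_config, c(list(opts$config), overrides))
  switch(cmd,
    simulate = run_simulate(cfg, overwrite = opts$overwrite),
    infer = invisible(run_infer(cfg)),
    isoform = invisible(run_isoform(cfg)),
    stop("Unknown command: ", cmd)
  )
}
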