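#!/usr/bin/env Rscript
# Thin command-line wrapper over electrotick::run_pipeline(). Either point
# it at a YAML config or give a stage plus flags:
#
#   Rscript scripts/electrotick.R --config run.yaml
#   Rscript scripts/electrotick.R --stage solve_rig --gap-mm 3 --voltage 750 \
#       --out out/rig
#   Rscript scripts/electrotick.R --stage simulate_staircase --seed 1 \
#       --out out/sim

suppressPackageStartupMessages({
  library(optparse)
  library(electrotick)
})

opt_list <- list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML config file (overrides other flags)"),
  make_option("--stage", type = "character", default = NULL),
  make_option("--gap-mm", type = "double", default = NULL, dest = "gap_mm"),
  make_option("--voltage", type = "double", default = NULL),
  make_option("--gradient-kvm", type = "double", default = NULL,
              dest = "gradient_kvm"),
  make_option("--e-star-kvm", type = "double", default = NULL,
              dest = "e_star_kvm"),
  make_option("--cv", type = "double", default = NULL),
  make_option("--data", type = "character", default = NULL),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = NULL,
              help = "output directory"),
  make_option("--verbose", action = "store_true", default = FALSE))

opts <- parse_args(OptionParser(option_list = opt_list))

cfg <- if (!is.null(opts$config)) {
  yaml::read_yaml(opts$config)
} else {
  drop <- c("config", "out", "verbose", "help")
  Filter(Negate(is.null), opts[setdiff(names(opts), drop)])
}

res <- tryCatch(run_pipeline(cfg, out_dir = opts$out), error = function(e) {
  message("error: ", conditionMessage(e))
  quit(status = 1L)
})
if (opts$verbose) str(res$result, max.level = 1)
message("artifacts in ", res$out_dir)
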