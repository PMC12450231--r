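#!/usr/bin/env Rscript

# Thin command-line front end over the package:
#   Rscript scripts/coopsim.R simulate  --scenario S1 --seed 1 --ticks 1200 \
#       --width 128 --height 64 --out run.csv
#   Rscript scripts/coopsim.R sweep     --seed 1 --repetitions 3 --ticks 1200 \
#       --width 128 --height 64 --outdir sweep_out
#   Rscript scripts/coopsim.R summarize --outdir sweep_out

suppressPackageStartupMessages({
  library(coopclim)
  library(optparse)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1 ||
    !args[1] %in% c("simulate", "sweep", "summarize")) {
  stop("usage: coopsim.R <simulate|sweep|summarize> [options]")
}
cmd <- args[1]

ol <- list(
  make_option("--scenario", type = "character", default = "S1"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--ticks", type = "integer", default = 1200L),
  make_option("--width", type = "integer", default = 128L),
  make_option("--height", type = "integer", default = 64L),
  make_option("--n-agents", type = "integer", default = 10L,
              dest = "n_agents"),
  make_option("--prob-cooperation", type = "double", default = 0.2,
              dest = "prob_cooperation"),
  make_option("--alpha", type = "double", default = 0.2),
  make_option("--cost", type = "double", default = 10),
  make_option("--repetitions", type = "integer", default = 3L),
  make_option("--out", type = "character", default = "run.csv"),
  make_option("--outdir", type = "character", default = "sweep_out")
)
opt <- parse_args(OptionParser(option_list = ol), args = args[-1])

base_cfg <- function() {
  coop_config(scenario = opt$scenario, width = opt$width,
              height = opt$height, ticks = opt$ticks,
              n_agents = opt$n_agents,
              prob_cooperation = opt$prob_cooperation,
              alpha = opt$alpha, cost = opt$cost)
}

if (cmd == "simulate") {
  run <- run_simulation(base_cfg(), seed = opt$seed)
  write_run_csv(run, opt$out)
  ev_path <- sub("\\.csv$", "_events.csv", opt$out)
  readr::write_csv(run$events, ev_path)
  message("run written to ", opt$out, " (events: ", ev_path, ")")
  print(glance(run))
} else if (cmd == "sweep") {
  plan <- experiment_plan(repetitions = opt$repetitions,
                          base_seed = opt$seed)
  message("running ", nrow(plan), " simulations ...")
  sweep <- run_sweep(plan, base_cfg())
  dir.create(opt$outdir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(sweep$runs, file.path(opt$outdir, "runs.csv"))
  readr::write_csv(sweep$summary, file.path(opt$outdir, "summary.csv"))
  readr::write_csv(sweep$plan, file.path(opt$outdir, "plan.csv"))
  readr::write_csv(summarize_outcomes(sweep),
                   file.path(opt$outdir, "outcomes.csv"))
  message("sweep written to ", opt$outdir)
} else {
  runs <- readr::read_csv(file.path(opt$outdir, "runs.csv"),
                          show_col_types = FALSE)
  fin <- dplyr::filter(runs, tick == max(tick))
  print(dplyr::summarise(
    dplyr::group_by(fin, cell, region),
    final_population = mean(population),
    final_cooperators = mean(cooperators),
    final_defectors = mean(defectors)
  ), n = 50)
}
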