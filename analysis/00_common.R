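# Shared setup for the numbered analysis scripts: parses --seed, simulates
# (or re-loads) the synthetic study, and points all outputs at results/.
# Bulky intermediates are cached under scratch/ so each script stays fast.

suppressMessages({
  library(neuromethylome)
  library(data.table)
})

.args <- commandArgs(trailingOnly = TRUE)
analysis_seed <- {
  i <- which(.args == "--seed")
  if (length(i) == 1L && i < length(.args)) as.integer(.args[i + 1L]) else 1L
}

results_dir <- "results"
dir.create(results_dir, recursive = TRUE, showWarnings = FALSE)
dir.create("scratch", recursive = TRUE, showWarnings = FALSE)

# Simulate the full study design once per seed and memoise it on disk.
get_study <- function(seed = analysis_seed) {
  cache <- file.path("scratch", sprintf("study_seed%d.rds", seed))
  if (file.exists(cache)) return(readRDS(cache))
  study <- simulate_study(sim_config(seed = seed))
  saveRDS(study, cache)
  study
}

neuron_samples <- c("neuron_invitro", "neuron_invivo", "glia", "fetal")
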