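#!/usr/bin/env Rscript
# Global corrected weighted methylation levels per sample and context, and
# their distribution over genomic feature classes. This is the desk-scale
# analogue of the study's global-level comparison across differentiation
# stages: mCA accumulates in the neuron groups only, and the in vitro neuron
# is CG-hypermethylated relative to the in vivo neuron.

source("analysis/00_common.R")

study <- get_study()

global <- rbindlist(lapply(study$samples, function(s)
  rbindlist(lapply(c("CG", "CA", "CC", "CT", "CH"), function(cx)
    cbind(sample = s$name, weighted_level(s, cx))))))
fwrite(global, file.path(results_dir, "global_levels.tsv"), sep = "\t")

wide <- dcast(global, sample ~ context, value.var = "corrected_level")
cat("Global corrected levels (percent):\n")
print(wide[, lapply(.SD, function(x)
  if (is.numeric(x)) round(100 * x, 2) else x)])
cat("\nmCA ordering: in vitro neuron >= in vivo neuron >> ESC >> glia/fetal:",
    with(wide[match(c("neuron_invitro", "neuron_invivo", "esc", "glia"),
                    sample)],
         CA[1] > CA[3] && CA[2] > CA[3] && CA[3] > CA[4]), "\n")
cat("CG hypermethylation in vitro (percentage points):",
    round(100 * (wide$CG[wide$sample == "neuron_invitro"] -
                   wide$CG[wide$sample == "neuron_invivo"]), 2), "\n")

classes <- rbindlist(lapply(study$samples[neuron_samples], function(s)
  rbindlist(lapply(c("CG", "CH"), function(cx)
    cbind(sample = s$name, feature_class_summary(s, study$annotation, cx))))))
fwrite(classes, file.path(results_dir, "feature_class_levels.tsv"), sep = "\t")
cat("\nwrote global_levels.tsv, feature_class_levels.tsv\n")
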