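#!/usr/bin/env Rscript
# Generate the synthetic smAFM dataset used by the downstream analyses:
# saw-tooth retraction curves of the CNTN4 ectodomain pulled at 0.5 um/s
# through a 0.02 N/m cantilever, with ground truth. 150 curves keep the
# workflow quick; scripts/acceptance.R runs the full 500-curve recovery.

library(afmunfold)

seed <- 1
out_dir <- "results/curves"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

arch <- cntn4_architecture()
message("architecture: ", nrow(arch$domains), " domains; predicted unfolding lengths (nm):")
print(round(predicted_unfolding_length(arch), 1))

em <- event_model()          # population parameters of the measured mixtures
cfg <- sim_config()          # 0.5 um/s, 0.02 N/m, 5 pN noise

ds <- synthesize_dataset(150, arch, em, cfg, seed = seed, dir = out_dir)
message(sprintf("wrote %d curves + truth table to %s", length(ds$curves), out_dir))
message(sprintf("scripted events: %d (%.1f per curve)",
                nrow(ds$truth), nrow(ds$truth) / length(ds$curves)))
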