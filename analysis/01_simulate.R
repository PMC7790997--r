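#!/usr/bin/env Rscript

# Stage 1: simulate the synthetic biomonitoring study.
#
# Generates the family-structured cohort (72 probands, 29 unrelated
# controls, 76 parents; 37 mother/father, 33 father/proband and 32
# mother/proband pairs), latent log-normal exposures with age effects
# and within-family correlation, and duplicate-injection GC-MS/MS peak
# tables over 5 batches with their full QC complement (calibration
# levels, instrument/method blanks, matrix spikes, SRM aliquots,
# low-level spikes, donor serum pairs).

suppressPackageStartupMessages(library(exposcreen))

seed <- 1L
out_dir <- "results/simulated_study"

cfg <- synthetic_config(seed = seed)
sim <- simulate_study(cfg)
write_simulation(sim, out_dir)

cat("simulated study written to", out_dir, "\n")
cat(sprintf("  subjects: %d (%d probands, %d controls, %d parents)\n",
            nrow(sim$subjects),
            sum(sim$subjects$role == "proband"),
            sum(sim$subjects$role == "control"),
            sum(sim$subjects$role %in% c("mother", "father"))))
cat(sprintf("  panel: %d chemicals; batches: %d; samples: %d (%d study + %d QC)\n",
            nrow(sim$panel), cfg$n_batches, nrow(sim$samples),
            sum(sim$samples$sample_type == "study"),
            sum(sim$samples$sample_type != "study")))
cat(sprintf("  peak observations: %d (duplicate injections)\n",
            nrow(sim$peaks)))
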