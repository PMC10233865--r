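#!/usr/bin/env Rscript
# Stage 1: generate the synthetic heterogeneous chemical-target network.
#
# The generator plants latent blocks shared by chemicals and targets, so the
# three evidence layers carry mutually consistent signal: chemicals of one
# block bind that block's targets, share fingerprint bits, and their targets
# interact. Two profiles are emitted: the default study scale (~400
# chemicals / 1000 targets) and the small profile used for the evaluation
# stages.

suppressPackageStartupMessages(library(hetlink))
seed <- 1L

dir.create("results", showWarnings = FALSE)
cat("simulating small profile (40 chemicals, 100 targets)...\n")
sim <- run_simulate(tiny_config(seed = derive_seed(seed, "simulate-tiny")),
                    "results/net_tiny")
cat(sprintf("  %d activity records, %d scored protein pairs\n",
            nrow(sim$ctc_records), nrow(sim$ppi_pairs)))

cat("simulating study-scale profile (400 chemicals, 1000 targets)...\n")
sim2 <- run_simulate(generator_config(seed = derive_seed(seed, "simulate-full")),
                     "results/net_full")
cat(sprintf("  %d activity records, %d scored protein pairs\n",
            nrow(sim2$ctc_records), nrow(sim2$ppi_pairs)))
cat("wrote results/net_tiny and results/net_full\n")
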