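#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic cohort.
#
# Generates a 20-participant competitive-decision dataset under the default
# study conditions (52 factorial episodes per participant, opponent
# calibrated to 8 points per 20 s) and writes the decisions table, episodes
# table, and ground-truth sidecar under results/data/.

suppressPackageStartupMessages(library(lbarena))

cfg <- default_config(seed = 1L)
validate_config(cfg)

ds <- simulate_dataset(cfg$simulation$n_participants,
                       seed = seed_stream(cfg$seed, "simulate"),
                       practice = cfg$simulation$practice)
paths <- write_dataset(ds, "results/data")

ep <- ds$episodes
cat(sprintf("simulated %d participants, %d episodes, %d decisions\n",
            cfg$simulation$n_participants, nrow(ep), nrow(ds$decisions)))
cat(sprintf("outcomes: %s\n",
            paste(names(table(ep$outcome)), table(ep$outcome),
                  collapse = ", ", sep = " = ")))
cat("wrote:", paste(paths, collapse = ", "), "\n")
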