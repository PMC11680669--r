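#!/usr/bin/env Rscript
# Stage 2: exclusions and covariate standardization.
#
# Applies the study's exclusion rules (response times <= 250 ms or >= 5 s,
# practice episodes, participants under 55% accuracy) to the simulated
# decisions, z-scores the trial-level covariates, and writes the
# model-ready table plus an exclusion tally.

suppressPackageStartupMessages(library(lbarena))

cfg <- default_config(seed = 1L)
decisions <- utils::read.csv("results/data/decisions.csv")
truth <- jsonlite::read_json("results/data/truth.json", simplifyVector = TRUE)

prep <- prepare_decisions(decisions,
                          rt_min_s = cfg$exclusion$rt_min_s,
                          rt_max_s = cfg$exclusion$rt_max_s,
                          min_accuracy = cfg$exclusion$min_accuracy,
                          scaling = truth$scaling)
tally <- attr(prep, "exclusion_tally")
cat(sprintf("excluded %d of %d decisions (%.2f%%)\n",
            tally$n_excluded, tally$n_total,
            100 * tally$fraction_excluded))

utils::write.csv(prep, "results/data/decisions_prepared.csv",
                 row.names = FALSE)
jsonlite::write_json(tally, "results/data/exclusion_tally.json",
                     auto_unbox = TRUE, digits = NA)
cat("wrote results/data/decisions_prepared.csv\n")
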