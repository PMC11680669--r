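#!/usr/bin/env Rscript
# Stage 3: descriptive behavior and the mixed-effects polynomial models.
#
# Summarizes accuracy, response time (ms) and win rate by deadline and
# starting difference, then fits the Bayesian mixed-effects polynomial
# regressions (accuracy on the logit scale, RT on the log-ms scale) and
# writes coefficient tables with Savage-Dickey Bayes factors, credible
# intervals, R-hat, and evidence labels.

suppressPackageStartupMessages(library(lbarena))

cfg <- default_config(seed = 1L)
prep <- utils::read.csv("results/data/decisions_prepared.csv")
episodes <- utils::read.csv("results/data/episodes.csv")

s <- summarize_behavior(prep, episodes)
cat(sprintf("overall: accuracy %.3f, mean RT %.0f ms, win rate %.3f\n",
            s$overall$accuracy, s$overall$mean_rt_ms, s$overall$win_rate))
utils::write.csv(s$by_deadline, "results/behavior_by_deadline.csv",
                 row.names = FALSE)
utils::write.csv(s$by_start_diff, "results/behavior_by_start_diff.csv",
                 row.names = FALSE)

tables <- list()
for (outcome in c("accuracy", "rt")) {
  fit <- fit_behavioral_model(
    behavioral_spec(outcome), prep,
    settings = c(cfg$glmm_sampler,
                 seed = seed_stream(cfg$seed, paste0("glmm_", outcome))))
  tab <- behavioral_report(fit)
  tables[[outcome]] <- tab
  cat("\n", outcome, "model:\n", sep = "")
  print(tab[, c("effect", "estimate", "se", "bf10", "ci_lower",
                "ci_upper", "rhat", "label")], digits = 3)
}
utils::write.csv(do.call(rbind, tables), "results/behavior_coefficients.csv",
                 row.names = FALSE)
cat("\nwrote results/behavior_coefficients.csv\n")
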