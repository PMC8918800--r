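#!/usr/bin/env Rscript
# Stage 6: assemble the figure-level report.
#
# Re-runs the orchestrated study at the workflow scale (all stages derive
# their seeds from one top-level seed, so this reproduces stages 1-5
# exactly where they overlap) and writes results/report.md with one
# section per figure-level analysis.

library(fishcat)

cfg <- study_config(n_per_class = 100, size_levels = c(10000, 50000),
                    n_sim_trials = 400, greedy_iterations = 10,
                    mcmc = list(chains = 3, samples = 5000,
                                burn_in = 1000),
                    seed = 20260922L)
bundle <- run_categorization_study(cfg, verbose = TRUE)
make_report(bundle, "results/report.md")
cat("wrote results/report.md\n")
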