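#!/usr/bin/env Rscript
# Stage 1 — generate the germination trial inputs.
#
# The raw dish records behind the published trial are not deposited, so the
# workflow starts from the seeded generator: four dormancy-breaking
# treatments (GA3 on blotting paper or agar, at 10 or 15 degC), four
# replicate dishes of 20 achenes each, checked daily for 60 days, plus the
# end-of-trial cut-test fates of ungerminated seeds.

library(seedtrends)

seed <- 20260919L
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

sim <- simulate_germination_experiment(seed = seed)
write_schedules(sim$schedules,
                "results/data/schedules.csv", "results/data/dishes.csv")
write.csv(sim$cut_test, "results/data/cut_test.csv", row.names = FALSE)

n_germ <- sum(vapply(sim$schedules, function(s) sum(s$daily_counts),
                     integer(1)))
cat(sprintf("simulated %d dishes (%d treatments x 4 replicates), %d/%d seeds germinated\n",
            length(sim$schedules), nrow(default_germination_config()$treatments),
            n_germ, 20L * length(sim$schedules)))
cat("wrote results/data/{schedules,dishes,cut_test}.csv\n")
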