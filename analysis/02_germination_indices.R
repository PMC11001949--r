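#!/usr/bin/env Rscript
# Stage 2 — germination time-course statistics per dish and per treatment.
#
# Computes the ten classical indices (FGP, MGT, MGR, FDG, LDG, T50, CVt,
# CVG, GRI, GI) for every dish and summarises them as mean +- sd across
# the four replicates of each treatment, the form in which such trials
# are conventionally reported.

library(seedtrends)

schedules <- read_schedules("results/data/schedules.csv",
                            "results/data/dishes.csv")
idx <- germination_index_table(schedules)
write.csv(idx, "results/indices.csv", row.names = FALSE)

summ <- summarize_treatments(idx, digits = c(mgr = 3, cvg = 2, gri = 2,
                                             t50 = 1, .default = 1))
write.csv(summ, "results/treatment_summary.csv", row.names = FALSE)

ct <- read_cut_test("results/data/cut_test.csv")
cut_summary <- data.frame(
  class = c("viable", "empty", "dead"),
  mean_pct = round(c(mean(ct$pct_viable), mean(ct$pct_empty),
                     mean(ct$pct_dead)), 1),
  sd_pct = round(c(sd(ct$pct_viable), sd(ct$pct_empty), sd(ct$pct_dead)), 1)
)
write.csv(cut_summary, "results/cut_test_summary.csv", row.names = FALSE)

fgp <- summ[summ$index == "fgp", ]
cat("final germination percentage by treatment (mean +- sd over 4 dishes):\n")
for (i in seq_len(nrow(fgp))) {
  cat(sprintf("  %-15s %5.1f +- %.1f %%\n", fgp$treatment_id[i],
              fgp$mean[i], fgp$sd[i]))
}
cat(sprintf("cut test on ungerminated seeds: %.1f%% empty, %.1f%% dead, %.1f%% viable\n",
            cut_summary$mean_pct[2], cut_summary$mean_pct[3],
            cut_summary$mean_pct[1]))
cat("wrote results/{indices,treatment_summary,cut_test_summary}.csv\n")
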