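#!/usr/bin/env Rscript
# Stage 3 — nonparametric comparison of the four treatments.
#
# For each germination index: a Kruskal-Wallis omnibus test over the four
# unrelated treatment groups, Mann-Whitney pairwise contrasts judged at
# the Bonferroni-adapted level alpha_B = 0.05/6, and a compact letter
# display (treatments sharing a letter do not differ significantly).
# With four dishes per treatment every p-value is an exact permutation
# probability; at this sample size no pair can clear alpha_B, so the
# letters mostly coincide — the workflow reports that honestly rather
# than overstating four-replicate power.

library(seedtrends)

idx <- read.csv("results/indices.csv")
rows <- list()
for (index in c("fgp", "mgt", "mgr", "fdg", "ldg", "t50", "cvt", "cvg",
                "gri", "gi")) {
  keep <- !is.na(idx[[index]])
  if (length(unique(idx$treatment_id[keep])) < 2) next
  cmp <- compare_groups(idx[[index]][keep], idx$treatment_id[keep],
                        design = "unrelated", alpha = 0.05)
  rows[[index]] <- data.frame(
    index = index,
    omnibus = cmp$omnibus$name,
    statistic = round(cmp$omnibus$statistic, 3),
    p = signif(cmp$omnibus$p, 4),
    n_significant_pairs = sum(cmp$contrasts$significant),
    letters = paste(names(cmp$letters), cmp$letters, sep = "=",
                    collapse = " ")
  )
}
out <- do.call(rbind, rows)
write.csv(out, "results/treatment_comparison.csv", row.names = FALSE)

cat("omnibus tests across treatments (exact permutation p):\n")
print(out[, c("index", "statistic", "p", "n_significant_pairs")],
      row.names = FALSE)
cat(sprintf("pairwise contrasts judged at alpha_B = 0.05/6 = %.5f\n",
            0.05 / 6))
cat("wrote results/treatment_comparison.csv\n")
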