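#!/usr/bin/env Rscript
# Stage 3 — right-left concordance of geometric categories.
#
# Cross-tabulates right vs left categories per sex, reports per-category
# prevalence and specific agreement (with bootstrap CIs), and Cohen's
# kappa. Writes results/concordance.tsv and results/kappa.tsv.

library(carotidgeom)

classified <- read.csv("results/classified.csv")
conc <- concordance_report(classified, n_boot = 2000, seed = 1)
write.table(conc, "results/concordance.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

kap <- do.call(rbind, lapply(c("M", "F", "all"), function(sx) {
  k <- cohens_kappa(build_agreement_table(classified, sx))
  data.frame(sex = sx, kappa = k$kappa, ci_low = k$ci[1], ci_high = k$ci[2])
}))
write.table(kap, "results/kappa.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat("kappa by stratum (only fair right-left agreement is expected):\n")
print(kap, row.names = FALSE)
both_row <- conc[conc$sex == "all" & conc$category == "NEITHER", ]
cat(sprintf("pooled 'neither' agreement: %.1f%% (%.1f-%.1f)\n",
            both_row$agreement_pct, both_row$ci_low, both_row$ci_high))
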