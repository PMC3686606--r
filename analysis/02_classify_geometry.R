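#!/usr/bin/env Rscript
# Stage 2 — exclusions, median split, and phenotype classification.
#
# Applies the analysis-sample exclusions (missing CCA measures, then
# prevalent stroke), computes sex- and side-specific medians from the
# remaining sample, classifies each side into the four geometric patterns,
# and reduces right x left patterns to the ten bilateral phenotypes.
# Writes results/medians.tsv, results/classified.csv, results/phenotypes.tsv.

library(carotidgeom)

cohort <- read_cohort_csv("results/cohort.csv")
ex <- apply_exclusions(cohort)
cat(sprintf("exclusions: %d input -> %d missing measures, %d prevalent -> %d analyzed\n",
            ex$tally[["input"]], ex$tally[["missing_measures"]],
            ex$tally[["prevalent_stroke"]], ex$tally[["analysis"]]))

medians <- compute_medians(ex$cohort)
write.table(medians, "results/medians.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
classified <- classify_cohort(ex$cohort, medians)
write.csv(classified, "results/classified.csv", row.names = FALSE, quote = FALSE)

phen <- tabulate_phenotypes(classified)
write.table(phen, "results/phenotypes.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
comb <- combined_counts(phen)
write.table(comb, "results/combined_phenotypes.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

for (sx in c("F", "M")) {
  sub <- phen[phen$sex == sx, ]
  cat(sprintf("%s: highest incidence in phenotype %d (%.1f%%), reference %.1f%%\n",
              if (sx == "F") "women" else "men",
              sub$phenotype_id[which.max(sub$incidence_pct)],
              max(sub$incidence_pct), sub$incidence_pct[sub$phenotype_id == 10]))
}
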