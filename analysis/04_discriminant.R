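#!/usr/bin/env Rscript
# Discriminant analysis on the simulated cohort: pairwise Fisher LDA over the
# nine features, confusion counts, sensitivity/specificity, Mahalanobis
# separation, plus leave-one-out estimates for comparison. Also prints the
# published confusion-count percentages for side-by-side reading.

suppressPackageStartupMessages(library(hrvtriad))

cohort <- read_feature_table("results/cohort_features.csv")
study <- run_study(cohort,
                   contrasts = list(c("MDD", "Control"), c("CFS", "Control"),
                                    c("MDD", "CFS")),
                   cross_validate = TRUE)
print(study)

for (nm in names(study$contrasts)) {
  ct <- study$contrasts[[nm]]
  write_model_json(ct$model, sprintf("results/model_%s.json", nm))
  utils::write.csv(ct$counts, sprintf("results/confusion_%s.csv", nm),
                   row.names = FALSE)
}
utils::write.csv(study$group_summaries, "results/cohort_group_summaries.csv",
                 row.names = FALSE)

cat("\nPublished resubstitution percentages (for comparison):\n")
rc <- discriminant_reference_counts()
for (nm in names(rc)) {
  ss <- sensitivity_specificity(rc[[nm]]$counts, rc[[nm]]$positive,
                                rc[[nm]]$negative)
  cat(sprintf("  %-16s sensitivity %5.1f%%  specificity %5.1f%%  (d = %.2f)\n",
              nm, ss["sensitivity"], ss["specificity"],
              rc[[nm]]$mahalanobis_d))
}
cat("\nThe simulated cohort separates less sharply than the published one:\n",
    "features are drawn independently per subject, so the within-subject\n",
    "correlation that the real discriminant exploits is absent.\n")
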