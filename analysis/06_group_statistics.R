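#!/usr/bin/env Rscript
# Stage 6: the group-comparison battery.
#
# ANCOVAs of fluency and error metrics controlling for age and NART, with
# Bonferroni-corrected pairwise contrasts (0.05/3 for the three-group
# frontal/posterior/control analysis, 0.05/4 for laterality contrasts
# against controls), plus chi-square demographics tests.
library(fluencygraph)

cohort <- read_cohort("results/cohort")
scored <- read.table("results/scorecards.tsv", header = TRUE, sep = "\t")
m <- merge(cohort$participants, scored, by = "participant_id")
covs <- m[, c("age", "nart")]
m$region <- ifelse(m$group %in% c("LF", "RF"), "frontal",
                   ifelse(m$group %in% c("LP", "RP"), "posterior", "HC"))

rows <- list()
for (v in c("correct_words", "pct_rulebreak", "pct_inappropriate",
            "pct_proper_noun", "pct_permutation", "pct_perseveration",
            "pct_lowfreq", "mean_cluster_size", "relative_switches")) {
  a3 <- ancova(m[[v]], m$region, covs)   # frontal / posterior / HC
  a5 <- ancova(m[[v]], m$group, covs)    # five lateralized groups
  rows[[v]] <- data.frame(
    variable = v,
    F3 = a3$F, df3 = paste0(a3$df_between, ",", a3$df_within), p3 = a3$p,
    eta3 = a3$partial_eta_sq, F5 = a5$F, p5 = a5$p,
    eta5 = a5$partial_eta_sq)
  cat(sprintf("%-20s F(%d,%d) = %6.2f, p = %.4g, eta_p^2 = %.3f\n", v,
              a3$df_between, a3$df_within, a3$F, a3$p, a3$partial_eta_sq))
}
res <- do.call(rbind, rows)
write.table(res, "results/group_ancova.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat(sprintf("\nPost hoc thresholds: 0.05/3 = %.4g; 0.05/4 = %.4g\n",
            bonferroni_threshold(0.05, 3), bonferroni_threshold(0.05, 4)))
ph <- bonferroni_pairwise(m$correct_words, m$region, covs,
                          family_alpha = 0.05, n_comparisons = 3)
write.table(ph, "results/posthoc_fluency.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
print(ph, digits = 4)

tab <- table(m$region, m$gender)
ctest <- categorical_tests(tab)
cat(sprintf("\nGender by region: %s, p = %.3f\n", ctest$method, ctest$p))
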