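#!/usr/bin/env Rscript
# Stage 2: qualitative single-word scoring.
#
# Classifies every uttered token (correct / inappropriate / proper noun /
# permutation / wrong letter / perseveration), computes the percentage
# metrics with total words as denominator, the cohort-relative
# low-frequency threshold (mean - 2 SD of pooled transformed frequencies)
# and Troyer-style cluster/switch statistics.
library(fluencygraph)

cohort <- read_cohort("results/cohort")
lexicon <- read_lexicon("results/cohort/lexicon.tsv")

scored <- score_cohort(cohort$transcripts, lexicon)
write.table(scored, "results/scorecards.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat(sprintf("Low-frequency threshold (mean - 2 SD): %.3f\n",
            attr(scored, "lowfreq_threshold")))
summ <- scorecard_group_summary(scored, cohort$participants)
cat("\nGroup means (correct words | %% rule break | %% low-frequency):\n")
for (g in names(summ)) {
  s <- summ[[g]]
  cat(sprintf("  %s (n=%3d): %5.2f | %5.2f | %5.2f\n", g, s$n,
              s$correct_words$mean, s$pct_rulebreak$mean,
              s$pct_lowfreq$mean))
}
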