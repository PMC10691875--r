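#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort.
#
# Five groups — left/right frontal (LF/RF), left/right posterior (LP/RP)
# and healthy controls (HC) — at the published group sizes (63/80/33/63/136),
# with group-specific correct-word counts, error-subtype rates,
# low-frequency word usage, age and NART distributions. The lexicon is a
# 1000-word Zipf vocabulary of 's' words with a rare bottom decile.
library(fluencygraph)

seed <- 20260921
dir.create("results/cohort", recursive = TRUE, showWarnings = FALSE)

lexicon <- make_lexicon(size = 1000, zipf_s = 1, seed = seed)
write_lexicon(lexicon, "results/cohort/lexicon.tsv")

profiles <- make_default_profiles()
cat("Group profiles (planted means):\n")
print(profiles[, c("group", "n", "mean_correct", "rulebreak_pct",
                   "perseveration_pct", "lowfreq_pct")])

cohort <- simulate_cohort(profiles, lexicon, seed = seed)
write_cohort(cohort, "results/cohort")

cat(sprintf("\nSimulated %d participants; %d total uttered words.\n",
            nrow(cohort$participants),
            sum(lengths(lapply(cohort$transcripts, `[[`, "words")))))
cat("Example transcript (", cohort$transcripts[[1]]$participant_id, "): ",
    paste(cohort$transcripts[[1]]$words, collapse = ", "), "\n", sep = "")
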