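#!/usr/bin/env Rscript
# Stage 3: whole-sequence embeddings and the participant similarity graph.
#
# Each transcript is embedded as a 2048-dimensional hashed-feature vector
# of its full word sequence; pairwise cosine similarities form a complete
# weighted graph with age and NART absolute-difference edge covariates and
# mean word rarity as a node attribute.
library(fluencygraph)

seed <- 20260921
cohort <- read_cohort("results/cohort")
lexicon <- read_lexicon("results/cohort/lexicon.tsv")

G <- build_similarity_graph(cohort, lexicon, d = 2048, seed = seed)
write_graph_edges(G, "results/similarity_edges.tsv")

w <- G$weights[upper.tri(G$weights)]
cat(sprintf("Graph: %d nodes, %d edges; similarity range [%.3f, %.3f], mean %.3f\n",
            length(G$ids), sum(upper.tri(G$weights)), min(w), max(w),
            mean(w)))
grp <- read.table("results/cohort/participants.tsv", header = TRUE,
                  sep = "\t")$group
same <- outer(grp, grp, "==")[upper.tri(G$weights)]
cat(sprintf("Mean similarity within groups %.4f vs between groups %.4f\n",
            mean(w[same]), mean(w[!same])))
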