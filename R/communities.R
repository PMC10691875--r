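#' Characterize communities: composition, medians and TF-IDF words
#'
#' Each community's document is the concatenation of its members' uttered
#' tokens. Term frequency is the term count divided by the document length;
#' inverse document frequency is `log(N_communities / n_communities
#' containing the term)`; words are ranked by tf-idf with alphabetical
#' tie-breaking. Group composition percentages and median fluency
#' (correct words), age and NART are reported per community.
#'
#' @param partition a `block_partition` (or named assignment vector)
#' @param participants cohort metadata data.frame
#' @param transcripts list of transcripts
#' @param scorecards output of [score_cohort()]
#' @param n_top number of characteristic words to keep
#' @return list of per-community profiles
#' @export
profile_communities <- function(partition, participants, transcripts,
                                scorecards, n_top = 10) {
  assignment <- if (inherits(partition, "block_partition"))
    partition$assignment else partition
  ids <- names(assignment)
  stopifnot(all(participants$participant_id %in% ids))
  blocks <- sort(unique(assignment))
  docs <- lapply(blocks, function(bl) {
    members <- ids[assignment == bl]
    toks <- unlist(lapply(transcripts, function(tr)
      if (tr$participant_id %in% members) normalize_token(tr$words)
      else character(0)))
    toks
  })
  nonempty <- lengths(docs) > 0
  if (!all(nonempty)) {
    warning("dropping ", sum(!nonempty), " empty communities")
    blocks <- blocks[nonempty]; docs <- docs[nonempty]
  }
  ncomm <- length(blocks)
  vocab_by_doc <- lapply(docs, unique)
  df_count <- table(unlist(vocab_by_doc))
  lapply(seq_along(blocks), function(j) {
    bl <- blocks[j]
    members <- ids[assignment == bl]
    meta <- participants[participants$participant_id %in% members, ]
    sc <- scorecards[scorecards$participant_id %in% members, ]
    tf <- table(docs[[j]]) / length(docs[[j]])
    idf <- log(ncomm / as.numeric(df_count[names(tf)]))
    tfidf <- as.numeric(tf) * idf
    ord <- order(-tfidf, names(tf))
    top <- data.frame(word = names(tf)[ord], tfidf = tfidf[ord],
                      stringsAsFactors = FALSE)[seq_len(min(n_top,
                                                            length(tf))), ]
    grp_pct <- 100 * table(factor(meta$group,
                                  levels = unique(participants$group))) /
      nrow(meta)
    list(block = bl, n = length(members),
         group_pct = as.list(as.numeric(grp_pct)) |>
           stats::setNames(names(grp_pct)),
         median_fluency = stats::median(sc$correct_words, na.rm = TRUE),
         median_age = stats::median(meta$age),
         median_nart = stats::median(meta$nart),
         top_words = top)
  })
}

#' One-versus-rest community contrasts
#'
#' For each community: Mann-Whitney U tests (normal approximation with tie
#' correction) of age, NART and fluency score against all other
#' communities pooled, plus chi-square tests of each group-membership
#' proportion. The per-test significance threshold defaults to
#' `alpha_family / 40`.
#'
#' @param partition a `block_partition` or named assignment vector
#' @param participants cohort metadata
#' @param scorecards output of [score_cohort()]
#' @param alpha_family family-wise alpha
#' @param divisor Bonferroni divisor (number of tests in the family)
#' @return tidy data.frame of tests
#' @export
community_contrasts <- function(partition, participants, scorecards,
                                alpha_family = 0.05, divisor = 40) {
  assignment <- if (inherits(partition, "block_partition"))
    partition$assignment else partition
  blocks <- sort(unique(assignment))
  if (length(blocks) < 2) stop("need at least 2 communities")
  thr <- alpha_family / divisor
  meta <- merge(participants,
                scorecards[, c("participant_id", "correct_words")],
                by = "participant_id")
  meta$block <- assignment[meta$participant_id]
  vars <- c(age = "age", nart = "nart", fluency = "correct_words")
  rows <- list()
  for (bl in blocks) {
    inb <- meta$block == bl
    for (v in names(vars)) {
      x <- meta[[vars[v]]][inb]; yv <- meta[[vars[v]]][!inb]
      if (length(unique(c(x, yv))) < 2) {
        rows[[length(rows) + 1]] <- data.frame(
          block = bl, variable = v, statistic = NA_real_, p = NA_real_,
          threshold = thr, significant = NA)
        next
      }
      wt <- stats::wilcox.test(x, yv, exact = FALSE, correct = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        block = bl, variable = v, statistic = unname(wt$statistic),
        p = wt$p.value, threshold = thr, significant = wt$p.value < thr)
    }
    for (g in unique(meta$group)) {
      tab <- table(inb, meta$group == g)
      if (any(dim(tab) < 2)) next
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      rows[[length(rows) + 1]] <- data.frame(
        block = bl, variable = paste0("pct_", g),
        statistic = unname(ct$statistic),
        p = ct$p.value, threshold = thr, significant = ct$p.value < thr)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
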