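#' Simulate a fluency cohort with planted group structure
#'
#' Per participant: the correct-word count is a rounded normal truncated at
#' zero with the group's mean/SD; correct words are drawn without
#' replacement from the lexicon, frequency-weighted, except that with
#' probability `lowfreq_pct/100` a draw comes from the lowest-frequency
#' decile instead; word order follows a two-state Markov process
#' (stay-in-cluster with probability `stay_prob`, else switch) over
#' first-two-letter neighbourhoods; and error tokens are interleaved so
#' that each uttered token is independently an error with the profile's
#' subtype rates (as fractions of total words). Permutations are placed
#' immediately after their source word; perseverations repeat a uniformly
#' chosen earlier correct word, by default with at least one intervening
#' response (recurrent mode). Age and NART are normal per profile.
#'
#' An optional "style" plants a sequence-level signal orthogonal to the
#' scorecard metrics: for styled groups, ordinary (non-rare) word draws are
#' restricted with probability `style$strength` to alternating lexicon
#' ranks, which changes which words are produced without changing the
#' frequency profile, rarity or cluster statistics in distribution.
#'
#' @param profiles a `fluency_profiles` data.frame ([make_default_profiles()])
#' @param lexicon a `fluency_lexicon` ([make_lexicon()])
#' @param seed integer; the cohort is a deterministic function of
#'   (profiles, lexicon, seed, options)
#' @param n_per_group optional integer overriding every profile's `n`
#' @param stay_prob probability of staying in the current first-two-letter
#'   neighbourhood when choosing the next correct word
#' @param recurrent_perseverations if `TRUE` (default) planted
#'   perseverations always have an intervening response
#' @param style `NULL`, or `list(groups = <chr>, strength = <prob>)`
#' @return list with `participants` (data.frame: participant_id, group,
#'   age, nart, gender) and `transcripts` (list of lists with
#'   `participant_id`, `words`, `planted` labels)
#' @export
simulate_cohort <- function(profiles, lexicon, seed,
                            n_per_group = NULL, stay_prob = 0.4,
                            recurrent_perseverations = TRUE,
                            style = NULL) {
  validate_profiles(profiles)
  if (nrow(lexicon) == 0) stop("lexicon is empty")
  withr::with_seed(seed, {
    profanity <- packaged_wordlist("profanity")
    names_list <- packaged_wordlist("proper_nouns")
    decile <- lexicon$word[seq_len(nrow(lexicon)) >
                             floor(0.9 * nrow(lexicon))]
    reserved <- c(lexicon$word, profanity, names_list)
    participants <- list(); transcripts <- list(); idx <- 0L
    for (g in seq_len(nrow(profiles))) {
      pr <- profiles[g, ]
      ng <- if (is.null(n_per_group)) pr$n else n_per_group
      styled <- !is.null(style) && pr$group %in% style$groups
      for (i in seq_len(ng)) {
        idx <- idx + 1L
        pid <- sprintf("%s%04d", pr$group, i)
        tr <- simulate_transcript(
          pr, lexicon, decile, profanity, names_list, reserved,
          stay_prob, recurrent_perseverations,
          style_strength = if (styled) style$strength else 0
        )
        participants[[idx]] <- data.frame(
          participant_id = pid, group = pr$group,
          age = stats::rnorm(1, pr$age_mean, pr$age_sd),
          nart = stats::rnorm(1, pr$nart_mean, pr$nart_sd),
          gender = if (stats::runif(1) < pr$male_frac) "M" else "F",
          stringsAsFactors = FALSE
        )
        transcripts[[idx]] <- list(participant_id = pid, words = tr$words,
                                   planted = tr$planted)
      }
    }
    list(participants = do.call(rbind, participants),
         transcripts = transcripts)
  })
}

# draw one correct word not yet used, frequency-weighted; from the rare
# decile when rare = TRUE, otherwise from the full lexicon (possibly
# style-restricted to alternating ranks)
draw_word <- function(lexicon, used, rare, decile, style_strength) {
  pool_idx <- seq_len(nrow(lexicon))
  if (rare) {
    pool_idx <- pool_idx[lexicon$word %in% decile]
  } else if (style_strength > 0 && stats::runif(1) < style_strength) {
    pool_idx <- pool_idx[pool_idx %% 2L == 1L]
  }
  avail <- pool_idx[!(lexicon$word[pool_idx] %in% used)]
  if (length(avail) == 0) avail <- pool_idx # lexicon exhausted; allow reuse
  w <- lexicon$raw_frequency[avail]
  lexicon$word[avail[sample.int(length(avail), 1, prob = w)]]
}

# order chosen words by the two-state cluster process over first-two-letter
# neighbourhoods
order_by_clusters <- function(words, stay_prob) {
  if (length(words) <= 1) return(words)
  remaining <- words
  cur <- remaining[sample.int(length(remaining), 1)]
  out <- cur
  remaining <- remaining[-match(cur, remaining)]
  while (length(remaining)) {
    same <- remaining[substr(remaining, 1, 2) == substr(cur, 1, 2)]
    other <- setdiff(remaining, same)
    pool <- if (length(same) && (stats::runif(1) < stay_prob ||
                                 !length(other))) same else other
    cur <- pool[sample.int(length(pool), 1)]
    out <- c(out, cur)
    remaining <- remaining[-match(cur, remaining)]
  }
  out
}

simulate_transcript <- function(pr, lexicon, decile, profanity, names_list,
                                reserved, stay_prob, recurrent,
                                style_strength) {
  n_correct <- -1
  while (n_correct < 0) n_correct <- round(stats::rnorm(1, pr$mean_correct,
                                                        pr$sd_correct))
  rates <- c(inappropriate = pr$inappropriate_pct,
             proper_noun = pr$proper_noun_pct,
             permutation = pr$permutation_pct,
             perseveration = pr$perseveration_pct) / 100
  q <- sum(rates)
  # per-token error process: each uttered slot is independently an error
  # with total probability q; stop after the n_correct-th correct word
  slots <- character(0); emitted <- 0L
  while (emitted < n_correct) {
    if (stats::runif(1) < q) {
      slots <- c(slots, sample(names(rates), 1, prob = rates))
    } else {
      slots <- c(slots, "correct")
      emitted <- emitted + 1L
    }
  }
  # choose the correct words (rare draws at the planted low-frequency rate)
  used <- character(0)
  for (k in seq_len(n_correct)) {
    rare <- stats::runif(1) < pr$lowfreq_pct / 100
    used <- c(used, draw_word(lexicon, used, rare, decile, style_strength))
  }
  correct_seq <- order_by_clusters(used, stay_prob)
  # assemble tokens, deferring error slots whose preconditions are unmet
  words <- character(0); planted <- character(0)
  correct_emitted <- character(0)
  used_prof <- character(0); used_names <- character(0)
  ci <- 0L
  pending <- character(0)
  emit <- function(w, lab) {
    words <<- c(words, w); planted <<- c(planted, lab)
    if (lab == "correct") correct_emitted <<- c(correct_emitted, w)
  }
  try_error <- function(type) {
    # returns TRUE if the error token could be emitted now
    if (type == "inappropriate") {
      pool <- setdiff(profanity, used_prof)
      if (!length(pool)) pool <- profanity
      w <- pool[sample.int(length(pool), 1)]
      used_prof <<- c(used_prof, w); emit(w, type); return(TRUE)
    }
    if (type == "proper_noun") {
      pool <- setdiff(names_list, used_names)
      if (!length(pool)) pool <- names_list
      w <- pool[sample.int(length(pool), 1)]
      used_names <<- c(used_names, w); emit(w, type); return(TRUE)
    }
    if (type == "permutation") {
      if (!length(correct_emitted)) return(FALSE)
      src <- correct_emitted[length(correct_emitted)]
      for (sfx in c("ing", "ings", "est", "ed")) {
        cand <- paste0(src, sfx)
        if (!(cand %in% c(reserved, words))) {
          emit(cand, type); return(TRUE)
        }
      }
      return(FALSE)
    }
    # perseveration
    eligible <- unique(correct_emitted)
    if (recurrent && length(words))
      eligible <- setdiff(eligible, words[length(words)])
    if (!length(eligible)) return(FALSE)
    emit(eligible[sample.int(length(eligible), 1)], type)
    TRUE
  }
  flush_pending <- function() {
    while (length(pending)) {
      if (!try_error(pending[1])) break
      pending <<- pending[-1]
    }
  }
  for (slot in slots) {
    if (slot == "correct") {
      ci <- ci + 1L
      emit(correct_seq[ci], "correct")
    } else {
      pending <- c(pending, slot)
    }
    flush_pending()
  }
  flush_pending() # undeliverable leftovers (e.g. zero-word transcripts) drop
  list(words = words, planted = planted)
}

#' Write / read cohort artifacts
#'
#' Metadata as TSV (participant_id, group, age, nart, gender); transcripts
#' as JSON-lines, one object per participant.
#' @param cohort output of [simulate_cohort()]
#' @param dir output directory
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(cohort$participants, file.path(dir, "participants.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  con <- file(file.path(dir, "transcripts.jsonl"), "w")
  on.exit(close(con))
  for (tr in cohort$transcripts) {
    writeLines(jsonlite::toJSON(
      list(participant_id = tr$participant_id, words = tr$words,
           annotations = tr$planted),
      auto_unbox = TRUE), con)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  participants <- utils::read.table(file.path(dir, "participants.tsv"),
                                    sep = "\t", header = TRUE,
                                    stringsAsFactors = FALSE)
  lines <- readLines(file.path(dir, "transcripts.jsonl"))
  transcripts <- lapply(lines, function(l) {
    obj <- jsonlite::fromJSON(l)
    list(participant_id = obj$participant_id,
         words = as.character(obj$words),
         planted = as.character(obj$annotations))
  })
  list(participants = participants, transcripts = transcripts)
}
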