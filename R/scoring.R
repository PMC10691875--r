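#' Default suffix-stripping rules for permutation detection
#'
#' Ordered rule list applied to both tokens when testing whether a response
#' is an inflectional variant (permutation) of an earlier response; the
#' first suffix that matches the token ending is stripped once. A match
#' requires the remaining stems to be equal and at least 3 characters long.
#' @export
default_suffix_rules <- function() {
  c("ing", "ings", "ed", "er", "ers", "est", "en", "s", "es", "'s")
}

strip_suffix <- function(token, rules) {
  for (sfx in rules) {
    nch <- nchar(sfx)
    if (nchar(token) > nch && endsWith(token, sfx)) {
      return(substr(token, 1L, nchar(token) - nch))
    }
  }
  token
}

#' Classify each uttered token of a fluency transcript
#'
#' Labels each token with exactly one of `correct`, `inappropriate`,
#' `proper_noun`, `permutation`, `wrong_letter`, `perseveration`.
#' Precedence per token: (1) an exact repeat of any earlier token is a
#' perseveration (recurrent when at least one response intervenes since the
#' nearest earlier occurrence); (2) membership in the profanity list;
#' (3) membership in the proper-noun list; (4) a shared stem with an
#' earlier token under the suffix rules (permutation); (5) not starting
#' with the target letter; (6) otherwise correct. Manual annotations, when
#' given, override the automatic label.
#'
#' @param tokens character vector, in uttered order (normalized internally)
#' @param profanity,proper_nouns word lists (defaults: packaged fixtures)
#' @param target_letter initial letter required by the task
#' @param suffix_rules see [default_suffix_rules()]
#' @param manual optional character vector of manual labels (`NA` = automatic)
#' @return data.frame with columns `token`, `label`, `recurrent`
#' @export
classify_tokens <- function(tokens,
                            profanity = packaged_wordlist("profanity"),
                            proper_nouns = packaged_wordlist("proper_nouns"),
                            target_letter = "s",
                            suffix_rules = default_suffix_rules(),
                            manual = NULL) {
  if (length(tokens) == 0) stop("transcript is empty")
  toks <- normalize_token(tokens)
  n <- length(toks)
  stems <- vapply(toks, strip_suffix, character(1), rules = suffix_rules,
                  USE.NAMES = FALSE)
  label <- character(n)
  recurrent <- rep(FALSE, n)
  for (i in seq_len(n)) {
    earlier <- which(toks[seq_len(i - 1)] == toks[i])
    if (length(earlier) > 0) {
      label[i] <- "perseveration"
      recurrent[i] <- max(earlier) < i - 1
    } else if (toks[i] %in% profanity) {
      label[i] <- "inappropriate"
    } else if (toks[i] %in% proper_nouns) {
      label[i] <- "proper_noun"
    } else if (i > 1 && nchar(stems[i]) >= 3 &&
               stems[i] %in% stems[seq_len(i - 1)]) {
      label[i] <- "permutation"
    } else if (substr(toks[i], 1, 1) != target_letter) {
      label[i] <- "wrong_letter"
    } else {
      label[i] <- "correct"
    }
  }
  if (!is.null(manual)) {
    stopifnot(length(manual) == n)
    override <- !is.na(manual)
    label[override] <- manual[override]
    recurrent[override & label != "perseveration"] <- FALSE
  }
  data.frame(token = toks, label = label, recurrent = recurrent,
             stringsAsFactors = FALSE)
}

#' Troyer-style phonemic clustering and switching statistics
#'
#' Maximal runs of consecutive tokens sharing the same first two letters
#' form clusters; a cluster's size is its run length minus one (singletons
#' have size 0). All uttered tokens, errors and repetitions included,
#' participate. Switches are transitions between runs; the relative number
#' of switches is `switches / (total tokens - 1) * 100`.
#'
#' @param tokens character vector in uttered order
#' @return list with `mean_cluster_size`, `n_switches`, `relative_switches`
#'   (`NaN` for single-token transcripts)
#' @export
cluster_switch <- function(tokens) {
  if (length(tokens) == 0) stop("transcript is empty")
  toks <- normalize_token(tokens)
  key <- substr(toks, 1, 2)
  runs <- rle(key)$lengths
  n_switches <- length(runs) - 1L
  list(
    mean_cluster_size = mean(runs - 1),
    n_switches = n_switches,
    relative_switches = if (length(toks) == 1) NaN else
      100 * n_switches / (length(toks) - 1)
  )
}

#' Score one transcript into a scorecard row
#'
#' Error percentages use the total number of uttered words as denominator;
#' the rule-break percentage counts inappropriate words, proper nouns and
#' permutations (wrong-letter words are tallied but excluded from the
#' rule-break total). The low-frequency percentage is computed over correct
#' words only, against a cohort-level threshold.
#'
#' @param tokens uttered tokens
#' @param labels output of [classify_tokens()] for these tokens
#' @param lexicon a `fluency_lexicon` (or `NULL` to skip frequency fields)
#' @param threshold cohort low-frequency threshold ([lowfreq_threshold()])
#' @return one-row data.frame
#' @export
score_transcript <- function(tokens, labels, lexicon = NULL,
                             threshold = NULL) {
  stopifnot(nrow(labels) == length(tokens))
  total <- length(tokens)
  cnt <- function(l) sum(labels$label == l)
  n_inapp <- cnt("inappropriate"); n_proper <- cnt("proper_noun")
  n_perm <- cnt("permutation"); n_wrong <- cnt("wrong_letter")
  n_pers <- cnt("perseveration")
  n_correct <- cnt("correct")
  pct <- function(k) if (total == 0) NaN else 100 * k / total
  cs <- cluster_switch(tokens)
  if (!is.null(lexicon)) {
    freqs <- lookup_frequency(labels$token, lexicon)
    correct_freqs <- freqs[labels$label == "correct"]
    in_lex <- freqs[!is.na(freqs)]
    mean_freq <- if (length(in_lex)) mean(in_lex) else NaN
    p_low <- if (is.null(threshold)) NA_real_ else
      pct_lowfreq(correct_freqs, threshold)
  } else {
    mean_freq <- NA_real_; p_low <- NA_real_
  }
  data.frame(
    total_words = total,
    correct_words = n_correct,
    n_inappropriate = n_inapp, n_proper_noun = n_proper,
    n_permutation = n_perm, n_wrong_letter = n_wrong,
    n_perseveration = n_pers,
    n_recurrent_perseveration = sum(labels$recurrent),
    pct_rulebreak = pct(n_inapp + n_proper + n_perm),
    pct_inappropriate = pct(n_inapp),
    pct_proper_noun = pct(n_proper),
    pct_permutation = pct(n_perm),
    pct_perseveration = pct(n_pers),
    pct_lowfreq = p_low,
    mean_word_frequency = mean_freq,
    mean_cluster_size = cs$mean_cluster_size,
    n_switches = cs$n_switches,
    relative_switches = cs$relative_switches
  )
}

# scorecard for a participant who produced no words at all: counts are zero,
# every ratio is undefined
empty_scorecard <- function() {
  data.frame(
    total_words = 0L, correct_words = 0L,
    n_inappropriate = 0L, n_proper_noun = 0L, n_permutation = 0L,
    n_wrong_letter = 0L, n_perseveration = 0L,
    n_recurrent_perseveration = 0L,
    pct_rulebreak = NaN, pct_inappropriate = NaN, pct_proper_noun = NaN,
    pct_permutation = NaN, pct_perseveration = NaN, pct_lowfreq = NaN,
    mean_word_frequency = NaN, mean_cluster_size = NaN,
    n_switches = NA_integer_, relative_switches = NaN
  )
}

#' Score a whole cohort of transcripts
#'
#' Two passes: tokens are classified, the cohort-level low-frequency
#' threshold is computed from the pooled transformed frequencies of all
#' correct words (token-level pooling across every participant), then each
#' transcript is scored against that threshold.
#'
#' @param transcripts list of transcripts: each a list with `participant_id`
#'   and `words`
#' @param lexicon a `fluency_lexicon`
#' @param ... passed to [classify_tokens()]
#' @return data.frame of scorecards, one row per participant, with the
#'   threshold stored in `attr(, "lowfreq_threshold")`
#' @export
score_cohort <- function(transcripts, lexicon, ...) {
  labs <- lapply(transcripts, function(tr) {
    if (length(tr$words) == 0) return(NULL)
    classify_tokens(tr$words, ...)
  })
  pooled <- unlist(lapply(labs, function(l) {
    if (is.null(l)) return(numeric(0))
    lookup_frequency(l$token[l$label == "correct"], lexicon)
  }))
  thr <- lowfreq_threshold(pooled)
  cards <- mapply(function(tr, l) {
    if (is.null(l)) return(empty_scorecard())
    score_transcript(tr$words, l, lexicon, thr)
  }, transcripts, labs, SIMPLIFY = FALSE)
  out <- do.call(rbind, cards)
  out <- cbind(participant_id = vapply(transcripts, function(tr)
    tr$participant_id, character(1)), out)
  rownames(out) <- NULL
  attr(out, "lowfreq_threshold") <- thr
  out
}
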