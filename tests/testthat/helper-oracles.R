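# Independent brute-force oracles, coded naively (nested loops, direct
# formulas) and separately from the package implementation.

oracle_strip <- function(tok, rules) {
  for (sfx in rules) {
    if (nchar(tok) > nchar(sfx) &&
        substring(tok, nchar(tok) - nchar(sfx) + 1) == sfx)
      return(substring(tok, 1, nchar(tok) - nchar(sfx)))
  }
  tok
}

oracle_classify <- function(tokens, profanity, proper, letter = "s",
                            rules = c("ing", "ings", "ed", "er", "ers",
                                      "est", "en", "s", "es", "'s")) {
  toks <- tolower(trimws(tokens))
  toks <- gsub("[^a-z']", "", toks)
  n <- length(toks)
  lab <- character(n); rec <- logical(n)
  for (i in seq_len(n)) {
    nearest <- NA
    for (j in seq_len(max(i - 1, 0))) if (toks[j] == toks[i]) nearest <- j
    if (!is.na(nearest)) {
      lab[i] <- "perseveration"
      rec[i] <- nearest < i - 1
    } else if (toks[i] %in% profanity) {
      lab[i] <- "inappropriate"
    } else if (toks[i] %in% proper) {
      lab[i] <- "proper_noun"
    } else {
      perm <- FALSE
      si <- oracle_strip(toks[i], rules)
      if (nchar(si) >= 3) {
        for (j in seq_len(max(i - 1, 0))) {
          if (oracle_strip(toks[j], rules) == si) perm <- TRUE
        }
      }
      if (perm) lab[i] <- "permutation"
      else if (substring(toks[i], 1, 1) != letter) lab[i] <- "wrong_letter"
      else lab[i] <- "correct"
    }
  }
  list(label = lab, recurrent = rec)
}

oracle_cluster <- function(tokens) {
  toks <- tolower(tokens)
  keys <- substring(toks, 1, 2)
  sizes <- c(); len <- 1
  if (length(keys) > 1) {
    for (i in 2:length(keys)) {
      if (keys[i] == keys[i - 1]) len <- len + 1
      else { sizes <- c(sizes, len - 1); len <- 1 }
    }
  }
  sizes <- c(sizes, len - 1)
  list(mean_cluster_size = sum(sizes) / length(sizes),
       n_switches = length(sizes) - 1,
       relative_switches = if (length(toks) == 1) NaN else
         100 * (length(sizes) - 1) / (length(toks) - 1))
}

oracle_scorecard <- function(tokens, profanity, proper, lex_words,
                             lex_trans, threshold) {
  cl <- oracle_classify(tokens, profanity, proper)
  toks <- gsub("[^a-z']", "", tolower(trimws(tokens)))
  total <- length(tokens)
  counts <- c(inappropriate = 0, proper_noun = 0, permutation = 0,
              wrong_letter = 0, perseveration = 0, correct = 0)
  for (l in cl$label) counts[l] <- counts[l] + 1
  nlow <- 0; ncor <- 0
  for (i in seq_along(toks)) {
    if (cl$label[i] == "correct") {
      ncor <- ncor + 1
      k <- which(lex_words == toks[i])
      if (length(k) == 1 && lex_trans[k] <= threshold) nlow <- nlow + 1
    }
  }
  cs <- oracle_cluster(tokens)
  list(total_words = total,
       correct_words = unname(counts["correct"]),
       n_inappropriate = unname(counts["inappropriate"]),
       n_proper_noun = unname(counts["proper_noun"]),
       n_permutation = unname(counts["permutation"]),
       n_wrong_letter = unname(counts["wrong_letter"]),
       n_perseveration = unname(counts["perseveration"]),
       n_recurrent_perseveration = sum(cl$recurrent),
       pct_rulebreak = 100 * (counts[["inappropriate"]] +
                                counts[["proper_noun"]] +
                                counts[["permutation"]]) / total,
       pct_perseveration = 100 * counts[["perseveration"]] / total,
       pct_lowfreq = if (ncor == 0) NaN else 100 * nlow / ncor,
       mean_cluster_size = cs$mean_cluster_size,
       n_switches = cs$n_switches,
       relative_switches = cs$relative_switches)
}

# adjusted Rand index from the contingency-table formula
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- ai * bj / choose(n, 2)
  (nij - expected) / ((ai + bj) / 2 - expected)
}

# WAIC from a draws-by-observations matrix of pointwise log-likelihoods
oracle_waic <- function(lp) {
  lppd <- 0; pw <- 0
  for (i in seq_len(ncol(lp))) {
    lppd <- lppd + log(mean(exp(lp[, i])))
    pw <- pw + var(lp[, i])
  }
  -2 * (lppd - pw)
}

# random transcript generator exercising every label branch: lexicon words,
# profanities, names, inflectional variants, exact repeats, wrong letters
random_transcript <- function(lex_words, profanity, proper, min_len = 3,
                              max_len = 25) {
  n <- sample(min_len:max_len, 1)
  toks <- character(0)
  for (i in seq_len(n)) {
    kind <- sample(c("lex", "prof", "name", "variant", "repeat", "wrong"),
                   1, prob = c(0.55, 0.07, 0.07, 0.12, 0.12, 0.07))
    tok <- switch(kind,
      lex = sample(lex_words, 1),
      prof = sample(profanity, 1),
      name = sample(proper, 1),
      variant = if (length(toks)) paste0(sample(toks, 1),
                                         sample(c("ing", "s", "ed"), 1))
                else sample(lex_words, 1),
      `repeat` = if (length(toks)) sample(toks, 1) else sample(lex_words, 1),
      wrong = paste0(sample(c("t", "b", "m"), 1),
                     paste(sample(letters, 4), collapse = "")))
    toks <- c(toks, tok)
  }
  toks
}

# shared fixtures, built once per test run
.fg_cache <- new.env(parent = emptyenv())
test_lexicon <- function() {
  if (is.null(.fg_cache$lex)) .fg_cache$lex <- make_lexicon(1000, 1, seed = 7)
  .fg_cache$lex
}
test_cohort <- function() {
  if (is.null(.fg_cache$cohort))
    .fg_cache$cohort <- simulate_cohort(make_default_profiles(),
                                        test_lexicon(), seed = 42,
                                        n_per_group = 30)
  .fg_cache$cohort
}
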