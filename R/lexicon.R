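#' Build a synthetic Zipf lexicon of 's' words
#'
#' Generates `size` unique lowercase words starting with 's', with rank-r raw
#' frequency proportional to `r^-zipf_s`, normalized so the top rank has raw
#' frequency 1. On top of the Zipf law, the bottom decile of ranks is scaled
#' down by `10^-rare_gap`: corpus frequency distributions are effectively
#' bimodal between everyday vocabulary and genuinely obscure words, and the
#' gap is what lets a cohort-relative mean-minus-2-SD rule isolate the rare
#' mode (see the package vignette). Set `rare_gap = 0` for a pure Zipf law.
#'
#' Words are random letter strings constructed so that none ends in a
#' morphological suffix recognized by [default_suffix_rules()]; distinct
#' lexicon words therefore never stem-collide and cannot be mistaken for
#' permutations of one another. The seed controls only the word strings;
#' the frequency profile is fully determined by `size`, `zipf_s`, `rare_gap`.
#'
#' @param size number of words (>= 10)
#' @param zipf_s Zipf exponent (> 0)
#' @param seed integer seed for word-string generation
#' @param rare_gap decades by which the bottom-decile frequencies are lowered
#' @return a `fluency_lexicon`: data.frame with columns `word`,
#'   `raw_frequency`, ordered by decreasing frequency
#' @export
make_lexicon <- function(size, zipf_s = 1, seed = 1, rare_gap = 4) {
  if (size < 10) stop("lexicon size must be >= 10")
  stopifnot(zipf_s > 0, rare_gap >= 0)
  freq <- (seq_len(size))^(-zipf_s)
  freq <- freq / freq[1]
  rare <- seq_len(size) > floor(0.9 * size)
  freq[rare] <- freq[rare] * 10^(-rare_gap)
  words <- withr::with_seed(seed, generate_s_words(size))
  lex <- data.frame(word = words, raw_frequency = freq,
                    stringsAsFactors = FALSE)
  attr(lex, "seed") <- seed
  attr(lex, "zipf_s") <- zipf_s
  attr(lex, "rare_gap") <- rare_gap
  attr(lex, "source_tag") <- "synthetic-zipf"
  class(lex) <- c("fluency_lexicon", "data.frame")
  lex
}

# letters that no recognized suffix ends in; words ending in these can never
# be stripped by the permutation rules
safe_final_letters <- c("a", "b", "c", "e", "f", "h", "i", "k", "l", "m",
                        "o", "p", "q", "u", "v", "w", "x", "y", "z")

generate_s_words <- function(size) {
  words <- character(0)
  reserved <- c(packaged_wordlist("profanity"),
                packaged_wordlist("proper_nouns"))
  while (length(words) < size) {
    k <- size - length(words)
    len <- sample(4:8, k, replace = TRUE)
    body <- vapply(len, function(l) {
      paste0(paste(sample(letters, l - 1, replace = TRUE), collapse = ""),
             sample(safe_final_letters, 1))
    }, character(1))
    cand <- paste0("s", body)
    cand <- setdiff(unique(cand), c(words, reserved))
    words <- c(words, cand)
  }
  words[seq_len(size)]
}

#' Load a word-frequency lexicon from a two-column TSV
#'
#' @param path TSV with columns word and raw_frequency (no header)
#' @param source_tag label recorded on the lexicon
#' @return a `fluency_lexicon`
#' @export
read_lexicon <- function(path, source_tag = basename(path)) {
  lex <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("word", "raw_frequency"),
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  if (any(lex$raw_frequency <= 0)) stop("raw frequencies must be positive")
  if (anyDuplicated(lex$word)) stop("lexicon words must be unique")
  lex$word <- tolower(lex$word)
  attr(lex, "source_tag") <- source_tag
  class(lex) <- c("fluency_lexicon", "data.frame")
  lex
}

#' @export
write_lexicon <- function(lexicon, path) {
  utils::write.table(lexicon[, c("word", "raw_frequency")], path,
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Transform raw corpus frequencies to the decimal-log scale
#'
#' `log10(raw * 1e9)`; a raw frequency of 1e-9 maps to 0 and 1 maps to 9.
#' `NA` inputs (words absent from the lexicon) propagate as `NA`.
#'
#' @param raw positive raw frequencies, possibly with `NA`
#' @return transformed frequencies on the decimal-log scale
#' @export
transform_frequency <- function(raw) {
  bad <- !is.na(raw) & raw <= 0
  if (any(bad)) stop("raw frequencies must be positive")
  log10(raw * 1e9)
}

#' Normalize a token for lexicon lookup
#'
#' Lowercases and strips characters other than letters and internal
#' apostrophes.
#' @param x character vector of tokens
#' @export
normalize_token <- function(x) {
  x <- tolower(trimws(x))
  gsub("[^a-z']", "", x)
}

#' Look up transformed frequencies for tokens
#'
#' @param words character vector (normalized internally)
#' @param lexicon a `fluency_lexicon`
#' @return transformed frequencies; `NA` for words absent from the lexicon
#' @export
lookup_frequency <- function(words, lexicon) {
  idx <- match(normalize_token(words), lexicon$word)
  transform_frequency(lexicon$raw_frequency[idx])
}

#' Cohort-relative low-frequency threshold
#'
#' Mean minus two sample standard deviations of the pooled transformed
#' frequencies of all correct words across the whole sample, missing values
#' excluded.
#'
#' @param values transformed frequencies (may contain `NA`)
#' @return the threshold (scalar)
#' @export
lowfreq_threshold <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2) stop("need at least 2 non-missing frequencies")
  mean(v) - 2 * stats::sd(v)
}

#' Percentage of low-frequency words among a participant's correct words
#'
#' A correct word counts as low-frequency when its transformed frequency is
#' at (or below) the threshold; words absent from the lexicon are never
#' low-frequency but stay in the denominator.
#'
#' @param values transformed frequencies of the participant's correct words
#' @param threshold output of [lowfreq_threshold()]
#' @return percentage in `[0, 100]`; `NaN` when there are no correct words
#' @export
pct_lowfreq <- function(values, threshold) {
  if (length(values) == 0) return(NaN)
  100 * sum(!is.na(values) & values <= threshold) / length(values)
}
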