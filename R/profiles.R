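#' Default group profiles for the synthetic cohort
#'
#' One row per participant group: left frontal (LF), right frontal (RF),
#' left posterior (LP), right posterior (RP) and healthy controls (HC).
#' Means and SDs of correct-word counts, error-type percentages,
#' low-frequency-word percentages, ages and NART scores reproduce the
#' group-level summaries of a large focal-lesion phonemic-fluency cohort;
#' the printed rule-break percentage is carried alongside the three
#' subtype rates (means of per-participant ratios are not additive, so the
#' subtype sum can exceed the printed total slightly).
#'
#' @return a `fluency_profiles` data.frame
#' @export
make_default_profiles <- function() {
  p <- data.frame(
    group            = c("LF", "RF", "LP", "RP", "HC"),
    n                = c(63L, 80L, 33L, 63L, 136L),
    mean_correct     = c(11.40, 13.90, 15.27, 15.49, 16.67),
    sd_correct       = c(5.75, 5.59, 4.54, 4.77, 4.05),
    inappropriate_pct = c(1.47, 1.56, 0.69, 1.16, 0.46),
    proper_noun_pct  = c(2.66, 1.26, 1.14, 1.25, 0.80),
    permutation_pct  = c(1.80, 0.73, 0.32, 0.82, 0.81),
    perseveration_pct = c(1.59, 0.90, 3.88, 1.84, 1.73),
    rulebreak_pct    = c(5.40, 3.56, 1.79, 2.64, 2.00),
    lowfreq_pct      = c(4.37, 3.67, 2.30, 3.06, 2.48),
    age_mean         = c(44.38, 48.65, 50.21, 51.48, 47.93),
    age_sd           = c(15.26, 14.93, 14.72, 12.87, 15.38),
    nart_mean        = c(105.88, 108.42, 109.45, 107.96, 108.09),
    nart_sd          = c(12.62, 10.28, 14.31, 11.00, 9.80),
    male_frac        = c(39 / 63, 40 / 80, 23 / 33, 37 / 63, 60 / 136),
    stringsAsFactors = FALSE
  )
  class(p) <- c("fluency_profiles", "data.frame")
  validate_profiles(p)
  p
}

#' Validate group profiles
#'
#' Checks that all percentage fields lie in `[0, 100]`, SDs are
#' non-negative, group sizes are positive, and that the error-subtype rates
#' are consistent with the stated rule-break total (within a one-point
#' tolerance, since group means of per-participant ratios need not add up).
#'
#' @param profiles a `fluency_profiles` data.frame
#' @param tol tolerance for the subtype-sum consistency check
#' @export
validate_profiles <- function(profiles, tol = 1.0) {
  pct_cols <- c("inappropriate_pct", "proper_noun_pct", "permutation_pct",
                "perseveration_pct", "rulebreak_pct", "lowfreq_pct")
  req <- c("group", "n", "mean_correct", "sd_correct", pct_cols,
           "age_mean", "age_sd", "nart_mean", "nart_sd")
  missing <- setdiff(req, names(profiles))
  if (length(missing))
    stop("profiles missing columns: ", paste(missing, collapse = ", "))
  for (cc in pct_cols) {
    if (any(profiles[[cc]] < 0 | profiles[[cc]] > 100))
      stop("profile rate outside [0, 100]: ", cc)
  }
  if (any(profiles$n < 1)) stop("group sizes must be >= 1")
  if (any(profiles$sd_correct < 0 | profiles$age_sd < 0 | profiles$nart_sd < 0))
    stop("SD fields must be non-negative")
  subtype_sum <- profiles$inappropriate_pct + profiles$proper_noun_pct +
    profiles$permutation_pct
  if (any(subtype_sum > profiles$rulebreak_pct + tol))
    stop("error subtype rates exceed the rule-break total beyond tolerance")
  invisible(profiles)
}

#' Path to a packaged word list
#' @param name "profanity" or "proper_nouns"
#' @keywords internal
packaged_wordlist <- function(name) {
  path <- system.file("extdata", paste0(name, ".txt"),
                      package = "fluencygraph")
  if (path == "") { # during development before installation
    path <- file.path("inst", "extdata", paste0(name, ".txt"))
  }
  normalize_token(readLines(path, warn = FALSE))
}

#' Read a one-word-per-line word list
#' @param path file path
#' @export
load_wordlist <- function(path) normalize_token(readLines(path, warn = FALSE))
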