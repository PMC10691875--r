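#' Analysis of covariance with an F-test of the group term
#'
#' Linear model of `y` on group indicators plus covariates; the group
#' effect is tested by residual-sum-of-squares comparison between the
#' covariates-only and full models. Partial eta-squared is
#' `SS_group / (SS_group + SS_residual)`. Covariate-adjusted group means
#' are estimated marginal means at the covariate averages.
#'
#' @param y numeric outcome
#' @param group factor (or coercible)
#' @param covariates data.frame of numeric covariates (e.g. age, NART)
#' @return an `ancova_result` list: `F`, `df_between`, `df_within`, `p`,
#'   `partial_eta_sq`, `adjusted_means`, `model`
#' @export
ancova <- function(y, group, covariates) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2) stop("need at least 2 groups")
  if (any(table(group) < 2)) stop("each group needs n >= 2")
  dat <- data.frame(.y = y, .group = group)
  if (length(covariates) > 0) dat <- cbind(dat, covariates)
  keep <- stats::complete.cases(dat)
  dat <- dat[keep, ]
  cov_terms <- if (length(covariates) == 0) "1" else
    paste(names(covariates), collapse = " + ")
  f0 <- stats::as.formula(paste(".y ~", cov_terms))
  f1 <- stats::as.formula(paste(".y ~ .group +", cov_terms))
  m0 <- stats::lm(f0, data = dat)
  m1 <- stats::lm(f1, data = dat)
  if (any(!is.finite(stats::coef(m1)))) stop("singular design")
  cmp <- stats::anova(m0, m1)
  ss_group <- cmp$`Sum of Sq`[2]
  ss_res <- cmp$RSS[2]
  em <- emmeans::emmeans(m1, ".group")
  res <- list(F = cmp$F[2], df_between = cmp$Df[2],
              df_within = cmp$Res.Df[2], p = cmp$`Pr(>F)`[2],
              partial_eta_sq = ss_group / (ss_group + ss_res),
              adjusted_means = as.data.frame(em), model = m1)
  class(res) <- "ancova_result"
  res
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("ANCOVA group effect: F(%d, %d) = %.3f, p = %.4g, partial eta^2 = %.3f\n",
              x$df_between, x$df_within, x$F, x$p, x$partial_eta_sq))
  invisible(x)
}

#' Bonferroni per-comparison threshold
#'
#' @param family_alpha family-wise alpha (e.g. 0.05)
#' @param n_comparisons number of comparisons in the family
#' @return `family_alpha / n_comparisons`
#' @export
bonferroni_threshold <- function(family_alpha, n_comparisons) {
  if (n_comparisons < 1) stop("n_comparisons must be >= 1")
  family_alpha / n_comparisons
}

#' Covariate-adjusted pairwise group contrasts with Bonferroni thresholds
#'
#' Estimated-marginal-mean pairwise contrasts from the ANCOVA model, with
#' unadjusted p values reported against a per-comparison threshold of
#' `family_alpha / n_comparisons`.
#'
#' @inheritParams ancova
#' @param family_alpha family-wise alpha
#' @param n_comparisons Bonferroni divisor; defaults to the number of
#'   pairwise contrasts
#' @return data.frame of contrasts with `threshold` and `significant`
#' @export
bonferroni_pairwise <- function(y, group, covariates, family_alpha = 0.05,
                                n_comparisons = NULL) {
  a <- ancova(y, group, covariates)
  em <- emmeans::emmeans(a$model, ".group")
  ctr <- as.data.frame(emmeans::contrast(em, "pairwise", adjust = "none"))
  if (is.null(n_comparisons)) n_comparisons <- nrow(ctr)
  thr <- bonferroni_threshold(family_alpha, n_comparisons)
  ctr$threshold <- thr
  ctr$significant <- ctr$p.value < thr
  ctr
}

#' Chi-square / Fisher tests of a contingency table with phi effect size
#'
#' Pearson chi-square without continuity correction by default; Fisher's
#' exact test is used when any expected count falls below 5. For 2x2
#' tables phi is `sqrt(chi^2 / n)`.
#'
#' @param counts matrix of non-negative integer counts
#' @param continuity apply Yates continuity correction to the chi-square
#' @return list: `method`, `statistic` (chi-square, NA for Fisher), `p`,
#'   `phi`, `df`, `n`
#' @export
categorical_tests <- function(counts, continuity = FALSE) {
  counts <- as.matrix(counts)
  if (sum(counts) == 0) stop("empty contingency table")
  n <- sum(counts)
  expected <- outer(rowSums(counts), colSums(counts)) / n
  chi <- suppressWarnings(stats::chisq.test(counts, correct = continuity))
  phi <- if (all(dim(counts) == c(2, 2)))
    sqrt(unname(chi$statistic) / n) else NA_real_
  if (any(expected < 5)) {
    ft <- stats::fisher.test(counts)
    return(list(method = "fisher", statistic = NA_real_, p = ft$p.value,
                phi = phi, df = NA_integer_, n = n))
  }
  list(method = "chisq", statistic = unname(chi$statistic), p = chi$p.value,
       phi = phi, df = unname(chi$parameter), n = n)
}
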