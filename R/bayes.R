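#' Random projection of an embedding matrix
#'
#' Multiplies by a seeded Gaussian matrix with entries `N(0, 1/k)`,
#' reducing `d` columns to `k` latent variables while approximately
#' preserving pairwise geometry (Johnson-Lindenstrauss).
#'
#' @param E numeric matrix (n x d)
#' @param k target dimension (2 <= k < d)
#' @param seed integer seed; the projection is deterministic under it
#' @return n x k matrix of class `projected_features`
#' @export
random_project <- function(E, k = 256, seed = 1) {
  d <- ncol(E)
  if (k >= d) stop("projection dimension k must be smaller than d")
  if (k < 2) stop("k must be >= 2")
  P <- withr::with_seed(seed,
    matrix(stats::rnorm(d * k, sd = 1 / sqrt(k)), d, k))
  out <- E %*% P
  colnames(out) <- paste0("proj", seq_len(k))
  attr(out, "projection_seed") <- seed
  class(out) <- c("projected_features", class(out))
  out
}

#' Bayesian logistic regression via Polya-Gamma Gibbs sampling
#'
#' Exact-likelihood MCMC for `y ~ Bernoulli(logit^-1(a + X b))` using
#' Polya-Gamma latent-variable augmentation. Priors on the (standardized)
#' coefficients: `ridge`, `b_j ~ N(0, tau^2)` with a half-Cauchy(0,1)
#' hyperprior on `tau`; or `horseshoe`, `b_j ~ N(0, lambda_j^2 tau^2)` with
#' half-Cauchy(0,1) local and global scales (both sampled through
#' inverse-gamma auxiliaries). The intercept is unpenalized.
#'
#' @param X numeric matrix of predictors (no intercept column)
#' @param y binary 0/1 response with both classes present
#' @param prior `"ridge"` or `"horseshoe"`
#' @param burn,samples,thin MCMC schedule: `burn` burn-in iterations, then
#'   `samples` iterations of which every `thin`-th is retained
#' @param seed integer seed
#' @param standardize center/scale columns before fitting (default)
#' @return a `bayes_logit_fit`: `draws` (retained draws x (1+p), intercept
#'   first, on the standardized scale), `X` (design used), `y`, `ess`
#'   (per-coefficient effective sample size as a fraction of retained
#'   draws), `ess_fraction_min`
#' @export
fit_bayes_logistic <- function(X, y, prior = c("ridge", "horseshoe"),
                               burn = 10000, samples = 10000, thin = 5,
                               seed = 1, standardize = TRUE) {
  prior <- match.arg(prior)
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2)
    stop("response is all one class; the model is degenerate")
  if (standardize && ncol(X) > 0) {
    mu <- colMeans(X)
    sdv <- apply(X, 2, stats::sd)
    sdv[sdv < 1e-12] <- 1
    X <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  } else {
    mu <- rep(0, ncol(X)); sdv <- rep(1, ncol(X))
  }
  Xd <- cbind(`(Intercept)` = 1, X)
  res <- withr::with_seed(seed,
    gibbs_logistic_cpp(Xd, y, if (prior == "horseshoe") 1L else 0L,
                       as.integer(burn), as.integer(samples),
                       as.integer(thin), 100))
  draws <- res$beta
  colnames(draws) <- colnames(Xd)
  essf <- apply(draws, 2, ess_fraction)
  fit <- list(draws = draws, tau2 = res$tau2, X = Xd, y = y,
              prior = prior, center = mu, scale = sdv,
              mcmc = c(burn = burn, samples = samples, thin = thin),
              seed = seed, ess = essf,
              ess_fraction_min = min(essf))
  class(fit) <- "bayes_logit_fit"
  if (fit$ess_fraction_min < 0.1)
    warning("minimum effective sample size below 10% of retained draws")
  fit
}

# effective sample size fraction by initial-positive-sequence truncation of
# the autocorrelation function (Geyer): sums rho_k while consecutive even
# pair sums remain positive
ess_fraction <- function(x) {
  n <- length(x)
  if (stats::sd(x) < 1e-14) return(1)
  rho <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE,
                    demean = TRUE)$acf[-1]
  s <- 0; k <- 1
  while (k < length(rho)) {
    pair <- rho[k] + rho[k + 1]
    if (is.na(pair) || pair <= 0) break
    s <- s + pair
    k <- k + 2
  }
  min(1, 1 / (1 + 2 * s))
}

loglik_bernoulli <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  sum(ifelse(y == 1, stats::plogis(eta, log.p = TRUE),
             stats::plogis(-eta, log.p = TRUE)))
}

# per-observation log-likelihood for each posterior draw (S x n)
pointwise_loglik <- function(fit, X = fit$X, y = fit$y) {
  eta <- fit$draws %*% t(X)
  sgn <- ifelse(y == 1, 1, -1)
  stats::plogis(sweep(eta, 2, sgn, "*"), log.p = TRUE)
}

#' McFadden pseudo-R-squared of a Bayesian logistic fit
#'
#' `1 - mean_s LL(beta_s) / LL0`, where the numerator averages the full
#' log-likelihood over posterior draws and `LL0` is the log-likelihood of
#' the intercept-only model at the empirical response rate.
#'
#' @param fit a `bayes_logit_fit`
#' @param X design matrix with intercept column (defaults to the fitted one)
#' @param y binary response
#' @export
pseudo_r2 <- function(fit, X = fit$X, y = fit$y) {
  if (length(unique(y)) < 2) stop("pseudo-R2 undefined for constant y")
  ll <- mean(rowSums(pointwise_loglik(fit, X, y)))
  p0 <- mean(y)
  ll0 <- sum(y) * log(p0) + sum(1 - y) * log(1 - p0)
  1 - ll / ll0
}

#' Watanabe-Akaike information criterion from posterior draws
#'
#' `WAIC = -2 (lppd - p_waic)` with `lppd = sum_i log mean_s p(y_i |
#' draw_s)` and `p_waic = sum_i var_s log p(y_i | draw_s)`; lower is
#' better.
#'
#' @inheritParams pseudo_r2
#' @export
waic <- function(fit, X = fit$X, y = fit$y) {
  lp <- pointwise_loglik(fit, X, y)
  if (nrow(lp) < 2) stop("WAIC needs at least 2 posterior draws")
  lppd <- sum(apply(lp, 2, function(v) {
    m <- max(v)
    m + log(mean(exp(v - m)))
  }))
  p_waic <- sum(apply(lp, 2, stats::var))
  -2 * (lppd - p_waic)
}

#' Canonical nested model specifications
#'
#' `baseline`: age, NART and fluency score (ridge prior); `errors`:
#' baseline plus rule-break error proportion, low-frequency word
#' proportion, number of switches, proportion of switches and mean cluster
#' size (ridge); `full`: errors plus projected sequence embeddings
#' (horseshoe, to promote sparsity over the many embedding coordinates).
#'
#' @param mcmc named vector `c(burn=, samples=, thin=)`
#' @export
default_model_specs <- function(mcmc = c(burn = 10000, samples = 10000,
                                         thin = 5)) {
  base_feats <- c("age", "nart", "correct_words")
  err_feats <- c(base_feats, "pct_rulebreak", "pct_lowfreq", "n_switches",
                 "relative_switches", "mean_cluster_size")
  list(
    baseline = list(name = "baseline", features = base_feats,
                    prior = "ridge", embeddings = FALSE, mcmc = mcmc),
    errors = list(name = "errors", features = err_feats,
                  prior = "ridge", embeddings = FALSE, mcmc = mcmc),
    full = list(name = "full", features = err_feats,
                prior = "horseshoe", embeddings = TRUE, mcmc = mcmc)
  )
}

#' Fit and compare the nested predictive models
#'
#' Binary target: frontal lesion (1) versus posterior and healthy-control
#' (0). Each model is fitted by [fit_bayes_logistic()] and summarized by
#' pseudo-R2, WAIC and the minimum effective-sample-size fraction.
#'
#' @param features data.frame containing the scorecard/metadata columns
#'   named in the specs plus a `group` column
#' @param projected matrix of projected embedding features (aligned rows)
#' @param specs list of model specifications ([default_model_specs()])
#' @param frontal_groups group labels coded as 1
#' @param seed integer seed (offset per model for independent chains)
#' @return data.frame with one row per model; fits attached as
#'   `attr(, "fits")`
#' @export
compare_models <- function(features, projected = NULL,
                           specs = default_model_specs(),
                           frontal_groups = c("LF", "RF"), seed = 1) {
  y <- as.integer(features$group %in% frontal_groups)
  rows <- list(); fits <- list()
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    X <- as.matrix(features[, sp$features, drop = FALSE])
    # participants with degenerate transcripts (0-1 words) have undefined
    # ratio metrics; impute at the column mean so rows stay comparable
    # across the nested models
    for (j in seq_len(ncol(X))) {
      bad <- !is.finite(X[, j])
      if (any(bad)) X[bad, j] <- mean(X[!bad, j])
    }
    if (isTRUE(sp$embeddings)) {
      if (is.null(projected)) stop("model '", sp$name,
                                   "' needs projected embeddings")
      X <- cbind(X, projected)
    }
    fit <- try(fit_bayes_logistic(
      X, y, prior = sp$prior, burn = sp$mcmc[["burn"]],
      samples = sp$mcmc[["samples"]], thin = sp$mcmc[["thin"]],
      seed = seed + k), silent = TRUE)
    if (inherits(fit, "try-error")) {
      warning("model '", sp$name, "' failed: ", attr(fit, "condition")$message)
      rows[[k]] <- data.frame(model = sp$name, prior = sp$prior,
                              n_features = ncol(X), pseudo_r2 = NA,
                              waic = NA, ess_fraction_min = NA)
      next
    }
    fits[[sp$name]] <- fit
    rows[[k]] <- data.frame(
      model = sp$name, prior = sp$prior, n_features = ncol(X),
      pseudo_r2 = pseudo_r2(fit), waic = waic(fit),
      ess_fraction_min = fit$ess_fraction_min)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}
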