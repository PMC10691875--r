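test_that("random projection is linear, seeded and geometry-preserving", {
  set.seed(21)
  E <- matrix(rnorm(100 * 1024), 100, 1024)
  E <- E / sqrt(rowSums(E^2))
  P1 <- random_project(E, k = 256, seed = 5)
  P2 <- random_project(E, k = 256, seed = 5)
  expect_identical(P1, P2)
  expect_false(identical(unclass(P1),
                         unclass(random_project(E, k = 256, seed = 6))))
  z <- random_project(rbind(rep(0, 1024), E[1, ]), k = 256, seed = 5)
  expect_equal(unname(z[1, ]), rep(0, 256))
  expect_error(random_project(E, k = 1024, seed = 1), "smaller")
  expect_error(random_project(E, k = 1, seed = 1), ">= 2")
  # Johnson-Lindenstrauss: squared distances preserved within +-30%
  # for at least 99% of pairs
  d0 <- as.matrix(dist(E))^2
  d1 <- as.matrix(dist(P1))^2
  ut <- upper.tri(d0)
  ratio <- d1[ut] / d0[ut]
  expect_gte(mean(ratio > 0.7 & ratio < 1.3), 0.99)
})

test_that("the Gibbs sampler is reproducible and warns on degenerate input", {
  set.seed(2)
  X <- matrix(rnorm(80 * 3), 80, 3)
  y <- rbinom(80, 1, 0.5)
  f1 <- fit_bayes_logistic(X, y, burn = 200, samples = 200, thin = 2,
                           seed = 9)
  f2 <- fit_bayes_logistic(X, y, burn = 200, samples = 200, thin = 2,
                           seed = 9)
  expect_identical(f1$draws, f2$draws)
  expect_equal(nrow(f1$draws), 100)
  expect_error(fit_bayes_logistic(X, rep(1, 80)), "one class")
})

test_that("an intercept-only fit centres on the empirical rate", {
  y <- rep(c(0, 1), 150)
  fit <- fit_bayes_logistic(matrix(numeric(0), 300, 0), y,
                            burn = 1000, samples = 2000, thin = 2,
                            seed = 3)
  expect_lt(abs(mean(fit$draws[, 1])), 3 * sd(fit$draws[, 1]) /
              sqrt(nrow(fit$draws) * fit$ess_fraction_min) + 0.05)
  expect_gt(fit$ess_fraction_min, 0.1)
})

test_that("pseudo-R2 matches its definition exactly on frozen draws", {
  # degenerate posterior at the intercept-only MLE: pseudo-R2 is exactly 0
  y <- c(1, 1, 0, 1, 0, 1)
  p0 <- mean(y)
  fit <- structure(list(draws = matrix(log(p0 / (1 - p0)), 3, 1),
                        X = matrix(1, 6, 1), y = y),
                   class = "bayes_logit_fit")
  expect_equal(pseudo_r2(fit), 0, tolerance = 1e-12)

  # hand-computed value on a 6-point data set with fixed coefficients
  X <- cbind(1, c(-2, -1, 0, 1, 2, 3))
  beta <- c(0.5, -1)
  eta <- X %*% beta
  ll <- sum(y * plogis(eta, log.p = TRUE) +
              (1 - y) * plogis(-eta, log.p = TRUE))
  ll0 <- sum(y) * log(p0) + sum(1 - y) * log(1 - p0)
  fit2 <- structure(list(draws = matrix(beta, 1, 2, byrow = TRUE),
                         X = X, y = y), class = "bayes_logit_fit")
  expect_equal(pseudo_r2(fit2), 1 - ll / ll0, tolerance = 1e-12)
  expect_error(pseudo_r2(fit2, y = rep(1, 6)), "constant")
})

test_that("WAIC equals the hand-computed toy value to 1e-10", {
  # 3 draws x 2 observations
  X <- cbind(1, c(-1, 2))
  y <- c(1, 0)
  draws <- rbind(c(0.2, 0.5), c(-0.1, 1.0), c(0.4, -0.3))
  fit <- structure(list(draws = draws, X = X, y = y),
                   class = "bayes_logit_fit")
  lp <- matrix(0, 3, 2)
  for (s in 1:3) for (i in 1:2) {
    eta <- sum(X[i, ] * draws[s, ])
    p <- 1 / (1 + exp(-eta))
    lp[s, i] <- log(if (y[i] == 1) p else 1 - p)
  }
  expect_equal(waic(fit), oracle_waic(lp), tolerance = 1e-10)

  # identical draws: p_waic = 0 and WAIC = -2 * sum log p
  fit_c <- structure(list(draws = draws[c(1, 1), ], X = X, y = y),
                     class = "bayes_logit_fit")
  expect_equal(waic(fit_c), -2 * sum(lp[1, ]), tolerance = 1e-10)
  fit_1 <- structure(list(draws = draws[1, , drop = FALSE], X = X, y = y),
                     class = "bayes_logit_fit")
  expect_error(waic(fit_1), "at least 2")
})

test_that("pseudo-R2 is invariant to affine rescaling of predictors", {
  set.seed(33)
  n <- 150
  X <- matrix(rnorm(n * 3), n, 3)
  y <- rbinom(n, 1, plogis(X[, 1]))
  f1 <- fit_bayes_logistic(X, y, burn = 500, samples = 500, thin = 1,
                           seed = 4)
  # positive power-of-two scale factors keep column standardization
  # bitwise exact, so the fitted design and sampling path are identical
  X2 <- sweep(X, 2, c(4, 8, 32), "*")
  f2 <- fit_bayes_logistic(X2, y, burn = 500, samples = 500, thin = 1,
                           seed = 4)
  expect_equal(pseudo_r2(f1), pseudo_r2(f2), tolerance = 1e-10)
})

test_that("the horseshoe shrinks noise coefficients harder than ridge", {
  set.seed(44)
  n <- 400; p <- 30
  X <- matrix(rnorm(n * p), n, p)
  y <- rbinom(n, 1, plogis(2 * X[, 1] - 2 * X[, 2]))
  fh <- fit_bayes_logistic(X, y, prior = "horseshoe", burn = 1000,
                           samples = 1000, thin = 2, seed = 7)
  fr <- fit_bayes_logistic(X, y, prior = "ridge", burn = 1000,
                           samples = 1000, thin = 2, seed = 7)
  noise_h <- median(abs(colMeans(fh$draws[, 4:(p + 1)])))
  noise_r <- median(abs(colMeans(fr$draws[, 4:(p + 1)])))
  expect_lt(noise_h, noise_r)
  # both recover the two active coefficients with the right sign
  expect_gt(mean(fh$draws[, 2]), 0)
  expect_lt(mean(fh$draws[, 3]), 0)
})

test_that("posterior intervals are calibrated under the null", {
  set.seed(55)
  cover <- 0; total <- 0
  for (rep in 1:8) {
    X <- matrix(rnorm(200 * 5), 200, 5)
    y <- rbinom(200, 1, 0.5)
    fit <- suppressWarnings(
      fit_bayes_logistic(X, y, burn = 500, samples = 500, thin = 1,
                         seed = 60 + rep))
    for (j in 2:6) {
      qs <- quantile(fit$draws[, j], c(0.025, 0.975))
      cover <- cover + (qs[1] < 0 & qs[2] > 0)
      total <- total + 1
    }
  }
  expect_gte(cover / total, 0.85) # 40 nominal-95% intervals
})

test_that("model comparison table is deterministic and well-formed", {
  set.seed(66)
  n <- 120
  feats <- data.frame(
    group = rep(c("LF", "RF", "LP", "RP", "HC"), each = 24),
    age = rnorm(n, 50, 10), nart = rnorm(n, 108, 10),
    correct_words = rnorm(n, 15, 4), pct_rulebreak = runif(n, 0, 10),
    pct_lowfreq = runif(n, 0, 8), n_switches = rpois(n, 8),
    relative_switches = runif(n, 20, 90),
    mean_cluster_size = runif(n, 0, 2))
  proj <- matrix(rnorm(n * 16), n, 16,
                 dimnames = list(NULL, paste0("proj", 1:16)))
  specs <- default_model_specs(mcmc = c(burn = 300, samples = 300,
                                        thin = 3))
  t1 <- compare_models(feats, proj, specs, seed = 2)
  t2 <- compare_models(feats, proj, specs, seed = 2)
  expect_identical(t1, t2)
  expect_equal(t1$model, c("baseline", "errors", "full"))
  expect_true(all(is.finite(t1$waic)))
  expect_true(all(t1$pseudo_r2 <= 1))
  expect_true(all(t1$ess_fraction_min > 0 & t1$ess_fraction_min <= 1))
})
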