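mk_tr <- function(words, id = "p1") list(participant_id = id, words = words)

test_that("hash embedding is deterministic, normalized and order-sensitive", {
  trs <- list(mk_tr(c("sun", "sea"), "a"), mk_tr(c("sun", "sea"), "b"),
              mk_tr(c("sea", "sun"), "c"))
  E <- embed_sequences(trs, d = 256, seed = 1)
  expect_equal(unname(E["a", ]), unname(E["b", ]))
  expect_false(isTRUE(all.equal(unname(E["a", ]), unname(E["c", ]))))
  expect_equal(unname(sqrt(rowSums(E^2))), rep(1, 3), tolerance = 1e-9)
  E2 <- embed_sequences(trs, d = 256, seed = 1)
  expect_identical(E, E2)
  E3 <- embed_sequences(trs, d = 256, seed = 2)
  expect_false(identical(unname(E), unname(E3)))
  expect_error(embed_sequences(list(), d = 256), "no transcripts")
  expect_error(embed_sequences(trs, d = 8), ">= 16")
  expect_error(embed_sequences(trs, backend = "external"), "stub")
})

test_that("cosine adjacency equals the dot-product oracle", {
  set.seed(5)
  V <- matrix(rnorm(3 * 40), 3, 40)
  rownames(V) <- paste0("p", 1:3)
  g <- cosine_adjacency(V)
  for (i in 1:3) for (j in 1:3) {
    if (i == j) expect_true(is.na(g$weights[i, j]))
    else {
      manual <- sum(V[i, ] * V[j, ]) /
        (sqrt(sum(V[i, ]^2)) * sqrt(sum(V[j, ]^2)))
      expect_equal(g$weights[i, j], manual, tolerance = 1e-12)
    }
  }
  expect_equal(g$weights, t(g$weights))
  expect_true(all(abs(g$weights[upper.tri(g$weights)]) <= 1 + 1e-12))

  # identical and orthogonal vectors
  U <- rbind(c(1, 0, 0, 0), c(1, 0, 0, 0), c(0, 1, 0, 0))
  rownames(U) <- paste0("q", 1:3)
  gu <- cosine_adjacency(U)
  expect_equal(gu$weights[1, 2], 1)
  expect_equal(gu$weights[1, 3], 0)
  expect_error(cosine_adjacency(U[1, , drop = FALSE]), "at least 2")
  expect_error(cosine_adjacency(rbind(U, r = c(0, 0, 0, 0))), "zero-norm")
})

test_that("edge covariates are standardized absolute differences", {
  set.seed(6)
  V <- matrix(rnorm(5 * 32), 5, 32); rownames(V) <- paste0("p", 1:5)
  cov <- data.frame(age = c(20, 30, 40, 50, 60), nart = c(1, 2, 3, 4, 5))
  g <- cosine_adjacency(V, node_covariates = cov)
  D <- g$edge_covariates$age
  vals <- D[upper.tri(D)]
  expect_equal(mean(vals), 0, tolerance = 1e-12)
  expect_equal(sd(vals), 1, tolerance = 1e-12)
  raw <- abs(outer(cov$age, cov$age, "-"))
  expect_equal(cor(vals, raw[upper.tri(raw)]), 1)
})

test_that("self-similarity decays as tokens are randomized", {
  lex <- test_lexicon()
  withr::with_seed(77, {
    base_words <- replicate(15, sample(lex$word, 12), simplify = FALSE)
    mean_sim <- sapply(c(0.2, 0.5, 0.9), function(fr) {
      sims <- sapply(base_words, function(w) {
        w2 <- w
        repl <- sample(length(w), round(fr * length(w)))
        w2[repl] <- sample(setdiff(lex$word, w), length(repl))
        E <- embed_sequences(list(mk_tr(w, "a"), mk_tr(w2, "b")),
                             d = 512, seed = 3)
        sum(E[1, ] * E[2, ])
      })
      mean(sims)
    })
    expect_true(all(diff(mean_sim) < 0))
    # a transcript is always maximally similar to itself
    E <- embed_sequences(list(mk_tr(base_words[[1]], "a"),
                              mk_tr(base_words[[1]], "b")), d = 512,
                         seed = 3)
    expect_equal(sum(E[1, ] * E[2, ]), 1, tolerance = 1e-9)
  })
})

test_that("distinct group vocabularies raise within-group similarity", {
  lex <- test_lexicon()
  half1 <- lex$word[seq(1, 1000, by = 2)]
  half2 <- lex$word[seq(2, 1000, by = 2)]
  withr::with_seed(88, {
    trs <- c(lapply(1:8, function(i) mk_tr(sample(half1, 12),
                                           paste0("a", i))),
             lapply(1:8, function(i) mk_tr(sample(half2, 12),
                                           paste0("b", i))))
    E <- embed_sequences(trs, d = 1024, seed = 4)
    W <- tcrossprod(E)
    grp <- rep(1:2, each = 8)
    within <- W[outer(grp, grp, "==") & upper.tri(W)]
    between <- W[outer(grp, grp, "!=") & upper.tri(W)]
    expect_gt(mean(within), mean(between))
  })
})

test_that("node mean frequency averages in-lexicon tokens only", {
  lex <- data.frame(word = c("sea", "sand"),
                    raw_frequency = c(1e-5, 1e-7))
  class(lex) <- c("fluency_lexicon", "data.frame")
  expect_equal(node_mean_frequency(c("sea", "sea"), lex), 4)
  expect_equal(node_mean_frequency(c("sea", "sand"), lex), 3)
  expect_equal(node_mean_frequency(c("sea", "sand", "zzz"), lex), 3)
  expect_true(is.nan(node_mean_frequency("zzz", lex)))
})

test_that("knn sparsification keeps mutual top-k edges symmetric", {
  set.seed(9)
  V <- matrix(rnorm(12 * 64), 12, 64); rownames(V) <- paste0("p", 1:12)
  g <- cosine_adjacency(V, sparsify_k = 3)
  expect_true(isSymmetric(g$present))
  expect_true(all(rowSums(g$present) >= 3))
  expect_false(any(diag(g$present)))
})
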