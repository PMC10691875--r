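planted_graph <- function(seed, n_per = 30, k = 3, win = 0.9, btw = 0.1,
                          noise = 0.05) {
  withr::with_seed(seed, {
    n <- n_per * k
    truth <- rep(seq_len(k), each = n_per)
    W <- matrix(btw, n, n)
    for (b in seq_len(k)) W[truth == b, truth == b] <- win
    W <- W + matrix(rnorm(n * n, 0, noise), n, n)
    W <- (W + t(W)) / 2
    diag(W) <- NA
    P <- matrix(TRUE, n, n); diag(P) <- FALSE
    g <- structure(list(ids = paste0("p", seq_len(n)), weights = W,
                        present = P, edge_covariates = NULL,
                        node_covariates = NULL),
                   class = "similarity_graph")
    names(truth) <- g$ids
    list(g = g, truth = truth)
  })
}

clique_graph <- function() {
  n <- 20; truth <- rep(1:2, each = 10)
  W <- matrix(NA_real_, n, n); P <- matrix(FALSE, n, n)
  for (b in 1:2) {
    idx <- which(truth == b)
    W[idx, idx] <- 1; P[idx, idx] <- TRUE
  }
  diag(P) <- FALSE; diag(W) <- NA
  g <- structure(list(ids = paste0("p", seq_len(n)), weights = W,
                      present = P, edge_covariates = NULL,
                      node_covariates = NULL), class = "similarity_graph")
  names(truth) <- g$ids
  list(g = g, truth = truth)
}

test_that("disconnected cliques are recovered exactly", {
  cg <- clique_graph()
  part <- fit_sbm(cg$g, seed = 1)
  expect_equal(part$n_blocks, 2)
  expect_equal(compare_partitions(part, cg$truth), 1)
})

test_that("a strongly assortative planted partition is recovered", {
  pg <- planted_graph(seed = 101)
  part <- fit_sbm(pg$g, seed = 1)
  expect_gte(compare_partitions(part, pg$truth), 0.9)
  # determinism under the seed
  part2 <- fit_sbm(pg$g, seed = 1)
  expect_identical(part$assignment, part2$assignment)
  expect_identical(part$description_length, part2$description_length)
})

test_that("description length beats the trivial partitions", {
  pg <- planted_graph(seed = 202)
  part <- fit_sbm(pg$g, seed = 2)
  n <- length(pg$g$ids)
  expect_lte(part$description_length, part$dl_path[1]) # one block
  expect_lte(part$description_length, part$dl_path[n]) # singletons
  expect_true(all(is.finite(part$dl_path)))
})

test_that("description length is invariant to node relabeling", {
  pg <- planted_graph(seed = 303, n_per = 10)
  n <- length(pg$g$ids)
  mult <- matrix(0L, n, n)
  ut <- upper.tri(pg$g$weights)
  mult[ut] <- fluencygraph:::weights_to_multiplicity(pg$g$weights[ut], 8)
  mult <- mult + t(mult)
  b <- unname(pg$truth)
  st <- fluencygraph:::build_stats(mult, pg$g$present, list(), b, 3)
  dl <- fluencygraph:::dl_total(st, n, sum(mult) / 2)
  perm <- withr::with_seed(1, sample(n))
  st_p <- fluencygraph:::build_stats(mult[perm, perm],
                                     pg$g$present[perm, perm], list(),
                                     b[perm], 3)
  dl_p <- fluencygraph:::dl_total(st_p, n, sum(mult) / 2)
  expect_equal(dl, dl_p, tolerance = 1e-10)
})

test_that("incremental node moves agree with recomputed statistics", {
  pg <- planted_graph(seed = 404, n_per = 8)
  n <- length(pg$g$ids)
  mult <- matrix(0L, n, n)
  ut <- upper.tri(pg$g$weights)
  mult[ut] <- fluencygraph:::weights_to_multiplicity(pg$g$weights[ut], 8)
  mult <- mult + t(mult)
  covs <- list(matrix(withr::with_seed(5, rnorm(n * n)), n, n))
  covs[[1]] <- (covs[[1]] + t(covs[[1]])) / 2
  b <- unname(pg$truth)
  st <- fluencygraph:::build_stats(mult, pg$g$present, covs, b, 3)
  for (i in c(1, 9, 20)) {
    r <- b[i]; t_ <- (r %% 3) + 1
    st2 <- fluencygraph:::move_node(st, mult, pg$g$present, covs, b, i,
                                    r, t_, 3)
    b2 <- b; b2[i] <- t_
    ref <- fluencygraph:::build_stats(mult, pg$g$present, covs, b2, 3)
    expect_equal(st2$M, ref$M)
    expect_equal(st2$P, ref$P)
    expect_equal(st2$S1[[1]], ref$S1[[1]], tolerance = 1e-10)
    expect_equal(st2$S2[[1]], ref$S2[[1]], tolerance = 1e-10)
    expect_equal(st2$nvec, ref$nvec)
  }
})

test_that("edge covariates are accepted and leave recovery intact", {
  pg <- planted_graph(seed = 77, n_per = 15)
  n <- length(pg$g$ids)
  cov <- matrix(withr::with_seed(6, rnorm(n * n)), n, n)
  pg$g$edge_covariates <- list(age = (cov + t(cov)) / 2)
  part <- fit_sbm(pg$g, seed = 3)
  expect_gte(compare_partitions(part, pg$truth), 0.9)
})

test_that("partition agreement matches the contingency ARI formula", {
  withr::with_seed(11, {
    a <- sample(1:4, 90, replace = TRUE)
    b <- sample(1:3, 90, replace = TRUE)
    names(a) <- names(b) <- paste0("p", 1:90)
    expect_equal(compare_partitions(a, b), oracle_ari(a, b),
                 tolerance = 1e-12)
    expect_equal(compare_partitions(a, a), 1)
    relab <- c(3, 4, 1, 2)[a]; names(relab) <- names(a)
    expect_equal(compare_partitions(a, relab), 1)
    # unrelated random partitions hover near zero agreement
    aris <- replicate(100, {
      b2 <- sample(b); names(b2) <- names(b)
      compare_partitions(a, b2)
    })
    expect_lt(abs(mean(aris)), 0.1)
    expect_error(compare_partitions(a, b[1:10]), "different participant")
  })
})

test_that("tf-idf community profiles match hand computation", {
  assignment <- c(a1 = 1, a2 = 1, b1 = 2, b2 = 2)
  participants <- data.frame(
    participant_id = names(assignment),
    group = c("LF", "LF", "HC", "HC"),
    age = c(50, 60, 40, 45), nart = c(100, 105, 110, 115),
    gender = "F", stringsAsFactors = FALSE)
  transcripts <- list(
    list(participant_id = "a1", words = c("sea", "sand", "sea")),
    list(participant_id = "a2", words = c("sea", "salt")),
    list(participant_id = "b1", words = c("sun", "sea")),
    list(participant_id = "b2", words = c("sun", "snow")))
  sc <- data.frame(participant_id = names(assignment),
                   correct_words = c(3, 2, 2, 2))
  prof <- profile_communities(assignment, participants, transcripts, sc)
  c1 <- prof[[1]]; c2 <- prof[[2]]
  # community 1 doc: sea sand sea sea salt (5 tokens)
  # "sea" tf 3/5 appears in both docs -> idf log(2/2) = 0
  # "sand" tf 1/5 unique -> idf log 2
  expect_equal(c1$top_words$tfidf[c1$top_words$word == "sea"], 0)
  expect_equal(c1$top_words$tfidf[c1$top_words$word == "sand"],
               log(2) / 5)
  expect_equal(c1$top_words$word[1:2], c("salt", "sand")) # tie: alphabetical
  expect_equal(c2$top_words$tfidf[c2$top_words$word == "sun"],
               (2 / 4) * log(2))
  expect_equal(c1$n, 2)
  expect_equal(c1$group_pct$LF, 100)
  expect_equal(c1$median_age, 55)
})

test_that("one-vs-rest contrasts use the Mann-Whitney U convention", {
  participants <- data.frame(
    participant_id = paste0("p", 1:16),
    group = rep(c("LF", "HC"), each = 8),
    age = c(1:8, 101:108), # index community strictly younger
    nart = rep(100, 16), gender = "F", stringsAsFactors = FALSE)
  sc <- data.frame(participant_id = paste0("p", 1:16),
                   correct_words = withr::with_seed(3, rnorm(16, 15, 3)))
  assignment <- setNames(rep(1:2, each = 8), paste0("p", 1:16))
  ct <- community_contrasts(assignment, participants, sc,
                            alpha_family = 0.05, divisor = 40)
  expect_equal(unique(ct$threshold), 0.05 / 40)
  age1 <- ct[ct$block == 1 & ct$variable == "age", ]
  # all community values below the rest: U = 0 here, n1*n2 for the mirror
  expect_equal(age1$statistic, 0)
  age2 <- ct[ct$block == 2 & ct$variable == "age", ]
  expect_equal(age2$statistic, 64)
  # U statistic equals the brute-force concordant-pair count
  x <- sc$correct_words[1:8]; yv <- sc$correct_words[9:16]
  u <- 0
  for (xi in x) for (yj in yv) u <- u + (xi > yj) + 0.5 * (xi == yj)
  fl1 <- ct[ct$block == 1 & ct$variable == "fluency", ]
  expect_equal(fl1$statistic, u)
  # identical samples: U = n1*n2/2 and p near 1
  sc2 <- sc; sc2$correct_words <- rep(c(1, 2, 3, 4), 4)
  participants2 <- participants; participants2$age <- rep(c(30, 40), 8)
  ct2 <- community_contrasts(assignment, participants2, sc2)
  fl <- ct2[ct2$block == 1 & ct2$variable == "fluency", ]
  expect_equal(fl$statistic, 32)
  expect_gt(fl$p, 0.95)
  expect_error(community_contrasts(setNames(rep(1, 16), paste0("p", 1:16)),
                                   participants, sc), "at least 2")
})
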