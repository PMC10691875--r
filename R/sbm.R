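# Degree-corrected stochastic block model fitted by description-length
# minimization. Edge weights are discretized into Q quantile bins treated as
# multigraph edge multiplicities; standardized edge covariates contribute
# per-block-pair Gaussian marginal-likelihood terms (normal-inverse-gamma
# conjugate prior, so the term is finite for any block size); the partition
# and the block-level edge-count matrix carry explicit prior description
# costs penalizing the number of blocks. Search: agglomerative merges from
# singletons down a block-count ladder, then single-node Metropolis sweeps
# around the best ladder state.

# multiplicities 1..Q from interior weight quantiles
weights_to_multiplicity <- function(w, Q) {
  qs <- stats::quantile(w, probs = seq_len(Q - 1) / Q, names = FALSE,
                        type = 7)
  m <- rep(1L, length(w))
  for (q in qs) m <- m + (w > q)
  as.integer(m)
}

# partition-dependent part of the degree-corrected microcanonical entropy;
# M is the block edge-count matrix over ordered pairs (diagonal counts
# within-block edge ends twice), e its row sums
dl_fit_term <- function(M, e) {
  d <- outer(e, e)
  x <- M > 0 & d > 0
  -0.5 * sum(M[x] * log(M[x] / d[x]))
}

dl_edges_prior <- function(nb, E) lchoose(nb * (nb + 1) / 2 + E - 1, E)

dl_partition_prior <- function(nvec, N) {
  nb <- length(nvec)
  lgamma(N + 1) - sum(lgamma(nvec + 1)) + lchoose(N - 1, nb - 1) + log(N)
}

# negative log marginal likelihood of n values with sum s1 and sum of
# squares s2 under Normal(mu, sigma^2) with NIG(mu0=0, k0=1, a0=1, b0=1)
nig_negml <- function(n, s1, s2) {
  out <- numeric(length(n))
  pos <- n > 0
  np <- n[pos]; s1p <- s1[pos]; s2p <- s2[pos]
  ss <- pmax(s2p - s1p^2 / np, 0)
  bn <- 1 + 0.5 * ss + s1p^2 / (2 * (1 + np))
  out[pos] <- -(lgamma(1 + np / 2) - (1 + np / 2) * log(bn) -
                  0.5 * log1p(np) - (np / 2) * log(2 * pi))
  out
}

dl_cov_term <- function(P, S1, S2) {
  nb <- nrow(P)
  ut <- upper.tri(P)
  off <- sum(nig_negml(P[ut], S1[ut], S2[ut]))
  dg <- sum(nig_negml(diag(P) / 2, diag(S1) / 2, diag(S2) / 2))
  off + dg
}

dl_total <- function(st, N, E) {
  nb <- length(st$e)
  dl <- dl_fit_term(st$M, st$e) + dl_edges_prior(nb, E) +
    dl_partition_prior(st$nvec, N)
  for (k in seq_along(st$S1))
    dl <- dl + dl_cov_term(st$P, st$S1[[k]], st$S2[[k]])
  dl
}

# block-level sufficient statistics for assignment b (values 1..nb)
build_stats <- function(mult, present, covs, b, nb) {
  f <- factor(b, levels = seq_len(nb))
  agg <- function(X) {
    A <- rowsum(X, f)
    t(rowsum(t(A), f))
  }
  st <- list(M = agg(mult), P = agg(present * 1),
             S1 = lapply(covs, function(C) agg(C * present)),
             S2 = lapply(covs, function(C) agg(C^2 * present)),
             nvec = as.vector(table(f)))
  st$e <- rowSums(st$M)
  st
}

f_entry <- function(m, d) ifelse(m > 0 & d > 0, m * log(m / pmax(d, 1e-300)), 0)

# change in description length from merging blocks r and s
merge_delta <- function(st, N, E, r, s) {
  nb <- length(st$e)
  keep <- setdiff(seq_len(nb), c(r, s))
  e <- st$e; M <- st$M
  eu <- e[r] + e[s]
  old_fit <- 2 * sum(f_entry(M[r, keep], e[r] * e[keep]) +
                       f_entry(M[s, keep], e[s] * e[keep])) +
    f_entry(M[r, r], e[r]^2) + f_entry(M[s, s], e[s]^2) +
    2 * f_entry(M[r, s], e[r] * e[s])
  new_vec <- M[r, keep] + M[s, keep]
  new_fit <- 2 * sum(f_entry(new_vec, eu * e[keep])) +
    f_entry(M[r, r] + M[s, s] + 2 * M[r, s], eu^2)
  d <- -0.5 * (new_fit - old_fit)
  for (k in seq_along(st$S1)) {
    P <- st$P; S1 <- st$S1[[k]]; S2 <- st$S2[[k]]
    old_cov <- sum(nig_negml(P[r, keep], S1[r, keep], S2[r, keep])) +
      sum(nig_negml(P[s, keep], S1[s, keep], S2[s, keep])) +
      sum(nig_negml(c(P[r, r] / 2, P[s, s] / 2, P[r, s]),
                    c(S1[r, r] / 2, S1[s, s] / 2, S1[r, s]),
                    c(S2[r, r] / 2, S2[s, s] / 2, S2[r, s])))
    new_cov <- sum(nig_negml(P[r, keep] + P[s, keep],
                             S1[r, keep] + S1[s, keep],
                             S2[r, keep] + S2[s, keep])) +
      nig_negml((P[r, r] + P[s, s] + 2 * P[r, s]) / 2,
                (S1[r, r] + S1[s, s] + 2 * S1[r, s]) / 2,
                (S2[r, r] + S2[s, s] + 2 * S2[r, s]) / 2)
    d <- d + (new_cov - old_cov)
  }
  nr <- st$nvec[r]; ns <- st$nvec[s]
  d <- d + lgamma(nr + 1) + lgamma(ns + 1) - lgamma(nr + ns + 1)
  d <- d + lchoose(N - 1, nb - 2) - lchoose(N - 1, nb - 1)
  d <- d + dl_edges_prior(nb - 1, E) - dl_edges_prior(nb, E)
  d
}

merge_mat <- function(X, r, s) {
  X[r, ] <- X[r, ] + X[s, ]
  X[, r] <- X[, r] + X[, s]
  X[-s, -s, drop = FALSE]
}

apply_merge <- function(st, r, s) {
  st$M <- merge_mat(st$M, r, s)
  st$P <- merge_mat(st$P, r, s)
  st$S1 <- lapply(st$S1, merge_mat, r = r, s = s)
  st$S2 <- lapply(st$S2, merge_mat, r = r, s = s)
  st$nvec[r] <- st$nvec[r] + st$nvec[s]
  st$nvec <- st$nvec[-s]
  st$e <- rowSums(st$M)
  st
}

# core fit on a prepared multigraph; RNG state is the caller's
fit_sbm_core <- function(mult, present, covs, max_blocks, n_sweeps,
                         kcand = 3) {
  N <- nrow(mult)
  E <- sum(mult) / 2
  b <- seq_len(N)
  st <- build_stats(mult, present, covs, b, N)
  dl <- dl_total(st, N, E)
  snapshots <- vector("list", N)
  dls <- numeric(N)
  snapshots[[N]] <- b; dls[N] <- dl
  nb <- N
  while (nb > 1) {
    aff <- st$M / pmax(outer(st$e, st$e), 1)
    diag(aff) <- -Inf
    cand <- matrix(integer(0), ncol = 2)
    for (r in seq_len(nb)) {
      ord <- order(aff[r, ], decreasing = TRUE)
      partners <- ord[seq_len(min(kcand, nb - 1))]
      partners <- partners[aff[r, partners] > -Inf]
      if (!length(partners) || all(st$M[r, partners] == 0))
        partners <- unique(c(partners,
                             sample(setdiff(seq_len(nb), r), 1)))
      cand <- rbind(cand, cbind(pmin(r, partners), pmax(r, partners)))
    }
    cand <- unique(cand)
    deltas <- vapply(seq_len(nrow(cand)), function(i)
      merge_delta(st, N, E, cand[i, 1], cand[i, 2]), numeric(1))
    pick <- which.min(deltas)
    r <- cand[pick, 1]; s <- cand[pick, 2]
    st <- apply_merge(st, r, s)
    b[b == s] <- r
    b[b > s] <- b[b > s] - 1L
    nb <- nb - 1L
    dl <- dl_total(st, N, E) # exact recompute, no incremental drift
    snapshots[[nb]] <- b; dls[nb] <- dl
  }
  eligible <- which(seq_len(N) <= max_blocks)
  best_nb <- eligible[which.min(dls[eligible])]
  b <- snapshots[[best_nb]]
  st <- build_stats(mult, present, covs, b, best_nb)
  dl <- dl_total(st, N, E)
  best <- list(b = b, dl = dl)
  nb <- best_nb
  if (nb > 1 && n_sweeps > 0) {
    for (sw in seq_len(n_sweeps)) {
      for (i in sample.int(N)) {
        r <- b[i]
        if (st$nvec[r] == 1L) next # keep the block count fixed
        t_ <- sample(setdiff(seq_len(nb), r), 1)
        st2 <- move_node(st, mult, present, covs, b, i, r, t_, nb)
        dl2 <- dl_total(st2, N, E)
        if (dl2 < dl || stats::runif(1) < exp(dl - dl2)) {
          st <- st2; dl <- dl2; b[i] <- t_
          if (dl < best$dl) best <- list(b = b, dl = dl)
        }
      }
    }
  }
  # dls is indexed by block count: dls[1] is the one-block partition,
  # dls[N] the all-singletons partition
  list(assignment = best$b, dl = best$dl, dl_path = dls)
}

# stats after moving node i from block r to block t
move_node <- function(st, mult, present, covs, b, i, r, t_, nb) {
  f <- factor(b[-i], levels = seq_len(nb))
  gsum <- function(x) vapply(split(x, f), sum, numeric(1), USE.NAMES = FALSE)
  a <- gsum(mult[-i, i])
  pv <- gsum(present[-i, i] * 1)
  upd <- function(X, v) {
    X[r, ] <- X[r, ] - v; X[, r] <- X[, r] - v
    X[t_, ] <- X[t_, ] + v; X[, t_] <- X[, t_] + v
    X
  }
  st$M <- upd(st$M, a)
  st$P <- upd(st$P, pv)
  for (k in seq_along(covs)) {
    st$S1[[k]] <- upd(st$S1[[k]], gsum(covs[[k]][-i, i] * present[-i, i]))
    st$S2[[k]] <- upd(st$S2[[k]], gsum(covs[[k]][-i, i]^2 * present[-i, i]))
  }
  st$nvec[r] <- st$nvec[r] - 1L
  st$nvec[t_] <- st$nvec[t_] + 1L
  st$e <- rowSums(st$M)
  st
}

#' Fit a degree-corrected stochastic block model to a similarity graph
#'
#' Communities are inferred by minimizing a microcanonical description
#' length over partitions: a degree-corrected block-adjacency term over
#' edge weights discretized into `Q` quantile bins (treated as multigraph
#' multiplicities), Gaussian marginal-likelihood terms per block pair for
#' each standardized edge covariate, and partition/edge-matrix priors that
#' penalize the number of blocks. The search performs agglomerative merges
#' from singletons down the full block-count ladder and then `n_sweeps`
#' single-node Metropolis sweeps (accepting increases with probability
#' `exp(-dDL)`) around the best ladder state; the best description-length
#' state visited is returned. A second hierarchy level is obtained by
#' refitting the model to the block-level multigraph.
#'
#' @param G a `similarity_graph` ([cosine_adjacency()])
#' @param max_blocks upper bound on the number of blocks considered
#' @param n_sweeps Metropolis sweeps after the agglomerative phase
#' @param seed integer; fits are deterministic under the seed
#' @param Q number of weight quantile bins
#' @param hierarchy also fit a coarser second level when the first level
#'   has at least 4 blocks
#' @return a `block_partition`: `assignment` (named integer vector),
#'   `n_blocks`, `description_length` (nats), `dl_path` (description length
#'   at each ladder level, from 1 block up), `hierarchy`, `seed`
#' @export
fit_sbm <- function(G, max_blocks = NULL, n_sweeps = 20, seed = 1, Q = 8,
                    hierarchy = TRUE) {
  n <- length(G$ids)
  if (n < 4) stop("need at least 4 nodes to fit the block model")
  if (is.null(max_blocks)) max_blocks <- n
  ut <- upper.tri(G$weights) & G$present
  w <- G$weights[ut]
  m <- weights_to_multiplicity(w, Q)
  mult <- matrix(0L, n, n)
  mult[ut] <- m
  mult <- mult + t(mult)
  present <- G$present
  covs <- G$edge_covariates
  if (is.null(covs)) covs <- list()
  res <- withr::with_seed(seed, {
    core <- fit_sbm_core(mult, present, covs, max_blocks, n_sweeps)
    hier <- NULL
    nb <- max(core$assignment)
    if (hierarchy && nb >= 4) {
      Mb <- build_stats(mult, present, list(), core$assignment, nb)$M
      diag(Mb) <- 0L
      pres_b <- Mb > 0
      coarse <- fit_sbm_core(Mb, pres_b, list(), nb, n_sweeps)
      hier <- coarse$assignment[core$assignment]
      names(hier) <- G$ids
    }
    list(core = core, hier = hier)
  })
  if (max(res$core$assignment) == max_blocks && max_blocks < n)
    warning("best partition hit the max_blocks boundary")
  assignment <- res$core$assignment
  names(assignment) <- G$ids
  out <- list(assignment = assignment,
              n_blocks = max(assignment),
              description_length = res$core$dl,
              dl_path = res$core$dl_path,
              hierarchy = res$hier,
              Q = Q, seed = seed)
  class(out) <- "block_partition"
  out
}

#' Adjusted agreement between two partitions
#'
#' Adjusted Rand index: 1 iff the partitions are identical up to block
#' relabeling, about 0 for unrelated partitions.
#' @param a,b `block_partition` objects, or named assignment vectors, over
#'   the same participant set
#' @export
compare_partitions <- function(a, b) {
  va <- if (inherits(a, "block_partition")) a$assignment else a
  vb <- if (inherits(b, "block_partition")) b$assignment else b
  if (!is.null(names(va)) && !is.null(names(vb))) {
    if (!setequal(names(va), names(vb)))
      stop("partitions are over different participant sets")
    vb <- vb[names(va)]
  } else if (length(va) != length(vb)) {
    stop("partitions are over different participant sets")
  }
  mclust::adjustedRandIndex(va, vb)
}

#' @export
print.block_partition <- function(x, ...) {
  cat("Block partition:", x$n_blocks, "blocks over",
      length(x$assignment), "nodes\n")
  cat("Description length:", format(x$description_length, digits = 8),
      "nats\n")
  print(table(x$assignment))
  invisible(x)
}
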