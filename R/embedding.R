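#' Embed whole word sequences as fixed-length vectors
#'
#' The default `local-hash` backend joins each transcript's tokens with
#' `", "`, extracts character n-grams (n = 2..4) and adjacent word bigrams,
#' hashes every feature into one of `d` buckets with a seeded 64-bit hash,
#' accumulates signed counts and L2-normalizes, so the representation is
#' order-sensitive and fully deterministic under `(seed, transcript)`.
#' An `external` backend name is an integration stub for a hosted
#' large-language-model embedding service and is never called here.
#'
#' @param transcripts list of transcripts (`participant_id`, `words`)
#' @param d embedding dimension (>= 16); 2048 is the default for the graph
#'   stage, 1024 is conventional for the predictive stage
#' @param seed seed for the hash family
#' @param backend `"local-hash"` (default) or `"external"`
#' @return numeric matrix, one L2-normalized row per transcript, rownames =
#'   participant ids, with attribute `backend_tag`
#' @export
embed_sequences <- function(transcripts, d = 2048, seed = 1,
                            backend = c("local-hash", "external")) {
  backend <- match.arg(backend)
  if (length(transcripts) == 0) stop("no transcripts to embed")
  if (d < 16) stop("embedding dimension must be >= 16")
  if (backend == "external") {
    stop("the external embedding backend is an interface stub: supply a ",
         "function(list-of-token-vectors) -> numeric matrix to an adapter; ",
         "no hosted model is called by this package")
  }
  token_lists <- lapply(transcripts, function(tr) as.character(tr$words))
  E <- hash_embed_cpp(token_lists, as.integer(d), as.integer(seed))
  rownames(E) <- vapply(transcripts, function(tr) tr$participant_id,
                        character(1))
  attr(E, "backend_tag") <- sprintf("local-hash-d%d-seed%d", d, seed)
  E
}

#' Mean transformed word frequency of a transcript
#'
#' Average transformed frequency over uttered tokens found in the lexicon;
#' out-of-lexicon tokens are excluded. Used as the node "rarity" covariate.
#'
#' @param tokens uttered tokens
#' @param lexicon a `fluency_lexicon`
#' @return scalar; `NaN` when no token is in the lexicon
#' @export
node_mean_frequency <- function(tokens, lexicon) {
  f <- lookup_frequency(tokens, lexicon)
  f <- f[!is.na(f)]
  if (!length(f)) return(NaN)
  mean(f)
}

#' Build the pairwise cosine-similarity participant graph
#'
#' Complete weighted graph over participants with edge weight equal to the
#' cosine similarity of their sequence embeddings (dot product of the
#' L2-normalized rows). Node covariates (age, NART, mean word frequency)
#' yield per-edge absolute-difference covariates, standardized to zero
#' mean / unit variance. Optional mutualized k-nearest-neighbour
#' sparsification keeps an edge if it is in either endpoint's top k.
#'
#' @param E embedding matrix from [embed_sequences()]
#' @param node_covariates optional data.frame aligned with rows of `E`
#'   (e.g. columns age, nart); absolute pairwise differences become edge
#'   covariates
#' @param sparsify_k `NULL` (complete graph) or integer k
#' @return a `similarity_graph`: list with `ids`, `weights` (n x n, `NA`
#'   diagonal), `present` (logical adjacency), `edge_covariates` (list of
#'   n x n standardized matrices), `node_covariates`
#' @export
cosine_adjacency <- function(E, node_covariates = NULL, sparsify_k = NULL) {
  n <- nrow(E)
  if (n < 2) stop("need at least 2 embedded participants")
  nrm <- sqrt(rowSums(E^2))
  if (any(nrm < 1e-12)) stop("zero-norm embedding row")
  W <- tcrossprod(E / nrm)
  diag(W) <- NA
  present <- matrix(TRUE, n, n); diag(present) <- FALSE
  if (!is.null(sparsify_k)) {
    k <- as.integer(sparsify_k)
    keep <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      ord <- order(W[i, ], decreasing = TRUE, na.last = TRUE)
      keep[i, ord[seq_len(min(k, n - 1))]] <- TRUE
    }
    present <- keep | t(keep)
    diag(present) <- FALSE
  }
  ecov <- NULL
  if (!is.null(node_covariates)) {
    ecov <- lapply(node_covariates, function(v) {
      D <- abs(outer(as.numeric(v), as.numeric(v), "-"))
      vals <- D[upper.tri(D)]
      (D - mean(vals)) / stats::sd(vals)
    })
  }
  g <- list(ids = rownames(E), weights = W, present = present,
            edge_covariates = ecov, node_covariates = node_covariates,
            sparsify_k = sparsify_k)
  class(g) <- "similarity_graph"
  g
}

#' Assemble a similarity graph directly from a cohort
#'
#' Convenience wrapper: embeds transcripts, computes node covariates
#' (age, NART, mean word frequency) and builds the cosine graph.
#' @inheritParams cosine_adjacency
#' @param cohort output of [simulate_cohort()] (or same shape)
#' @param lexicon a `fluency_lexicon`
#' @param d,seed passed to [embed_sequences()]
#' @export
build_similarity_graph <- function(cohort, lexicon, d = 2048, seed = 1,
                                   sparsify_k = NULL) {
  E <- embed_sequences(cohort$transcripts, d = d, seed = seed)
  nodecov <- data.frame(
    age = cohort$participants$age,
    nart = cohort$participants$nart,
    mean_word_frequency = vapply(cohort$transcripts, function(tr)
      node_mean_frequency(tr$words, lexicon), numeric(1))
  )
  cosine_adjacency(E, node_covariates = nodecov[, c("age", "nart")],
                   sparsify_k = sparsify_k)
}

#' Write a similarity graph as an edge-list TSV
#' @param g a `similarity_graph`
#' @param path output file
#' @export
write_graph_edges <- function(g, path) {
  n <- length(g$ids)
  ut <- which(upper.tri(g$weights) & g$present, arr.ind = TRUE)
  df <- data.frame(id_i = g$ids[ut[, 1]], id_j = g$ids[ut[, 2]],
                   weight = g$weights[ut])
  for (nm in names(g$edge_covariates))
    df[[paste0("d_", nm)]] <- g$edge_covariates[[nm]][ut]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
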