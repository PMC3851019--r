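# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately written from first principles (own lgamma
# formulas, explicit loops) so it never shares code with the package paths
# it checks.

# Build an hcs_corpus directly from a counts matrix.
toy_corpus <- function(counts, term_ids = NULL, doc_ids = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(term_ids)) term_ids <- sprintf("t%d", seq_len(ncol(counts)))
  if (is.null(doc_ids)) doc_ids <- sprintf("d%d@1", seq_len(nrow(counts)))
  dimnames(counts) <- list(doc_ids, term_ids)
  structure(
    list(counts = counts, doc_ids = doc_ids, term_ids = term_ids,
         doc_drug = sub("@.*$", "", doc_ids),
         doc_time = suppressWarnings(as.numeric(sub("^.*@", "", doc_ids)))),
    class = "hcs_corpus"
  )
}

# Token stream of a counts matrix: docs in row order, terms in column order
# within a document (the convention the sampler documents).
oracle_tokens <- function(counts) {
  doc <- integer(0); term <- integer(0)
  for (d in seq_len(nrow(counts))) {
    for (w in seq_len(ncol(counts))) {
      n <- counts[d, w]
      if (n > 0) {
        doc <- c(doc, rep(d, n))
        term <- c(term, rep(w, n))
      }
    }
  }
  list(doc = doc, term = term)
}

# Collapsed joint log p(w, z | alpha, beta), written out long-hand.
oracle_log_joint <- function(doc, term, z, D, V, K, alpha, beta) {
  ll <- 0
  for (d in seq_len(D)) {
    nd <- sum(doc == d)
    ll <- ll + lgamma(K * alpha) - lgamma(nd + K * alpha)
    for (k in seq_len(K)) {
      ndk <- sum(doc == d & z == k)
      ll <- ll + lgamma(ndk + alpha) - lgamma(alpha)
    }
  }
  for (k in seq_len(K)) {
    nk <- sum(z == k)
    ll <- ll + lgamma(V * beta) - lgamma(nk + V * beta)
    for (w in seq_len(V)) {
      nkw <- sum(z == k & term == w)
      ll <- ll + lgamma(nkw + beta) - lgamma(beta)
    }
  }
  ll
}

# Exact per-token marginal posteriors p(z_i = k | w) by enumerating all
# K^N assignments of a tiny corpus.
oracle_token_marginals <- function(counts, K, alpha, beta) {
  tok <- oracle_tokens(counts)
  N <- length(tok$doc)
  stopifnot(N <= 10)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), N)))
  logp <- apply(grid, 1, function(z)
    oracle_log_joint(tok$doc, tok$term, z, nrow(counts), ncol(counts),
                     K, alpha, beta))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  marg <- matrix(0, N, K)
  for (i in seq_len(N)) {
    for (k in seq_len(K)) {
      marg[i, k] <- sum(p[grid[, i] == k])
    }
  }
  list(marginals = marg, log_evidence = max(logp) + log(sum(exp(logp - max(logp)))),
       tokens = tok, assignments = grid, logp = logp)
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# Map planted event groups to fitted topics and return the fitted topic
# index for each group (1..G), using the planted topic-word template.
group_topic_map <- function(model, endpoints = default_endpoints()) {
  phi <- planted_topic_word(endpoints)
  match_topics(phi, model)
}
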