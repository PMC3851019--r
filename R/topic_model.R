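#' LDA configuration
#'
#' Validated hyperparameters and sampler schedule for [fit_lda()]. Defaults
#' follow the common Gibbs-sampling convention for small-vocabulary topic
#' models: a symmetric document-topic prior `alpha = 50 / K`, a symmetric
#' topic-word prior `beta = 0.1`, 2,000 sweeps with 500 discarded as
#' burn-in and every 10th post-burn-in state retained. The seed is
#' mandatory: there is no silent clock seeding.
#'
#' @param n_topics number of topics K (>= 2); the study design fixes K = 3.
#' @param alpha symmetric Dirichlet hyperparameter on document-topic
#'   mixtures (> 0).
#' @param beta symmetric Dirichlet hyperparameter on topic-word
#'   distributions (> 0).
#' @param n_iterations total Gibbs sweeps.
#' @param burn_in sweeps discarded before retaining samples
#'   (0 <= burn_in < n_iterations).
#' @param sample_lag spacing between retained samples (>= 1).
#' @param seed integer random seed.
#' @return An object of class `lda_config`.
#' @export
lda_config <- function(n_topics = 3L, alpha = 50 / n_topics, beta = 0.1,
                       n_iterations = 2000L, burn_in = 500L,
                       sample_lag = 10L, seed = 1L) {
  fail <- function(field, msg) {
    stop(sprintf("invalid LDA config: field '%s' %s", field, msg),
         call. = FALSE)
  }
  if (length(n_topics) != 1 || n_topics < 2) fail("n_topics", "must be >= 2")
  if (length(alpha) != 1 || alpha <= 0) fail("alpha", "must be > 0")
  if (length(beta) != 1 || beta <= 0) fail("beta", "must be > 0")
  if (n_iterations < 1) fail("n_iterations", "must be >= 1")
  if (burn_in < 0 || burn_in >= n_iterations)
    fail("burn_in", "must satisfy 0 <= burn_in < n_iterations")
  if (sample_lag < 1) fail("sample_lag", "must be >= 1")
  if (length(seed) != 1 || is.na(seed) || seed != as.integer(seed))
    fail("seed", "must be a single integer")
  structure(
    list(n_topics = as.integer(n_topics), alpha = as.numeric(alpha),
         beta = as.numeric(beta), n_iterations = as.integer(n_iterations),
         burn_in = as.integer(burn_in), sample_lag = as.integer(sample_lag),
         seed = as.integer(seed)),
    class = "lda_config"
  )
}

# Expand a corpus count matrix to per-token (doc, term) index vectors.
# Documents in corpus order, tokens within a document in term-catalog
# order, so the token stream is a pure function of the corpus.
expand_tokens <- function(counts) {
  idx <- which(t(counts) > 0, arr.ind = TRUE)  # transposed: term-major fast
  n <- t(counts)[idx]
  doc <- rep(idx[, 2], times = n)
  term <- rep(idx[, 1], times = n)
  o <- order(doc, term)
  list(doc = as.integer(doc[o]), term = as.integer(term[o]))
}

#' Fit latent Dirichlet allocation by collapsed Gibbs sampling
#'
#' Runs a collapsed Gibbs sampler over token-level topic assignments of the
#' drug-hour corpus and returns the two conditional probability tables the
#' diagnostics stage consumes: `doc_topic` (p(topic | document)) and
#' `topic_word` (p(word | topic)). Both are posterior means over the
#' retained post-burn-in samples, each sample smoothed by the Dirichlet
#' priors: `(n_dk + alpha) / (n_d + K alpha)` and
#' `(n_kw + beta) / (n_k + V beta)`. Identical corpus, config and seed give
#' an identical model.
#'
#' @param corpus an `hcs_corpus` (every document must contain at least one
#'   token).
#' @param config an [lda_config()].
#' @return An object of class `hcs_lda`: config, `doc_ids`, `term_ids`,
#'   `z` (final token assignments), `doc_topic`, `topic_word`,
#'   `log_likelihood_trace`, `token_posterior` (per-token marginal topic
#'   frequencies across retained samples), `tokens` and `n_retained`.
#' @export
fit_lda <- function(corpus, config = lda_config()) {
  if (!inherits(corpus, "hcs_corpus"))
    stop("corpus must be an hcs_corpus", call. = FALSE)
  if (!inherits(config, "lda_config")) config <- do.call(lda_config, config)
  counts <- corpus$counts
  if (nrow(counts) == 0 || ncol(counts) == 0 || sum(counts) == 0)
    stop("empty corpus: nothing to model", call. = FALSE)
  if (any(rowSums(counts) == 0))
    stop("corpus contains empty document(s): ",
         paste(utils::head(corpus$doc_ids[rowSums(counts) == 0], 5),
               collapse = ", "), call. = FALSE)
  if (any(counts < 0)) stop("corpus counts must be non-negative",
                            call. = FALSE)

  tok <- expand_tokens(counts)
  fit <- with_seed(config$seed, {
    .lda_gibbs_cpp(tok$doc - 1L, tok$term - 1L,
                   D = nrow(counts), V = ncol(counts),
                   K = config$n_topics,
                   alpha = config$alpha, beta = config$beta,
                   n_iter = config$n_iterations, burn_in = config$burn_in,
                   sample_lag = config$sample_lag)
  })
  dimnames(fit$doc_topic) <- list(corpus$doc_ids, NULL)
  dimnames(fit$topic_word) <- list(NULL, corpus$term_ids)
  structure(
    list(config = config, doc_ids = corpus$doc_ids,
         term_ids = corpus$term_ids, z = fit$z,
         doc_topic = fit$doc_topic, topic_word = fit$topic_word,
         log_likelihood_trace = fit$log_likelihood_trace,
         token_posterior = fit$token_posterior,
         tokens = tok, n_retained = fit$n_retained),
    class = "hcs_lda"
  )
}

#' @export
print.hcs_lda <- function(x, ...) {
  cat(sprintf(
    "<hcs_lda> K = %d topics, %d documents, %d terms, %d retained samples\n",
    x$config$n_topics, nrow(x$doc_topic), ncol(x$topic_word), x$n_retained))
  invisible(x)
}

#' Collapsed joint log likelihood of a fitted state
#'
#' Computes log p(w, z | alpha, beta) — the collapsed joint probability of
#' the corpus tokens and the model's current (final-sweep) topic
#' assignments, marginalizing over theta and phi analytically. Used to
#' monitor sampler convergence.
#'
#' @param model an `hcs_lda`.
#' @param corpus the corpus the model was fitted to.
#' @return A single finite log probability in nats.
#' @export
log_likelihood <- function(model, corpus) {
  stopifnot(inherits(model, "hcs_lda"), inherits(corpus, "hcs_corpus"))
  if (!identical(model$term_ids, corpus$term_ids))
    stop("vocabulary mismatch between model and corpus", call. = FALSE)
  if (!identical(model$doc_ids, corpus$doc_ids))
    stop("document set mismatch between model and corpus", call. = FALSE)
  tok <- expand_tokens(corpus$counts)
  if (length(tok$doc) != length(model$z))
    stop("token count mismatch between model and corpus", call. = FALSE)
  collapsed_log_lik(tok$doc, tok$term, model$z,
                    D = nrow(corpus$counts), V = ncol(corpus$counts),
                    K = model$config$n_topics,
                    alpha = model$config$alpha, beta = model$config$beta)
}

# log p(w, z | alpha, beta) from token streams and an assignment vector.
collapsed_log_lik <- function(doc, term, z, D, V, K, alpha, beta) {
  ndk <- matrix(0L, D, K); nkw <- matrix(0L, K, V)
  for (i in seq_along(doc)) {
    ndk[doc[i], z[i]] <- ndk[doc[i], z[i]] + 1L
    nkw[z[i], term[i]] <- nkw[z[i], term[i]] + 1L
  }
  nd <- rowSums(ndk); nk <- rowSums(nkw)
  sum(lgamma(K * alpha) - lgamma(nd + K * alpha)) +
    sum(lgamma(ndk + alpha) - lgamma(alpha)) +
    sum(lgamma(V * beta) - lgamma(nk + V * beta)) +
    sum(lgamma(nkw + beta) - lgamma(beta))
}

#' Rank vocabulary terms within a topic
#'
#' @param model an `hcs_lda`.
#' @param topic topic index in `1..K`.
#' @return A data frame with columns `term` and `p` (p(word | topic)),
#'   sorted by descending probability; ties broken by catalog order.
#' @export
rank_terms <- function(model, topic) {
  stopifnot(inherits(model, "hcs_lda"))
  K <- model$config$n_topics
  if (length(topic) != 1 || topic < 1 || topic > K || topic != as.integer(topic))
    stop(sprintf("topic index must be in 1..%d", K), call. = FALSE)
  p <- model$topic_word[topic, ]
  o <- order(-p, seq_along(p))
  data.frame(term = model$term_ids[o], p = unname(p[o]),
             stringsAsFactors = FALSE)
}

#' Match topics across two fitted models
#'
#' Topic labels are exchangeable across runs; this finds the permutation of
#' `model_b`'s topics that maximizes the summed cosine similarity between
#' matched `topic_word` rows (exact optimal assignment by enumeration of
#' the K! permutations).
#'
#' @param model_a,model_b `hcs_lda` models (or plain K x V `topic_word`
#'   matrices) sharing vocabulary and K.
#' @return An integer vector `perm` with `perm[k]` = topic of `model_b`
#'   matched to topic `k` of `model_a`; attribute `similarity` holds the
#'   per-pair cosine similarities.
#' @export
match_topics <- function(model_a, model_b) {
  tw <- function(m) if (inherits(m, "hcs_lda")) m$topic_word else as.matrix(m)
  a <- tw(model_a); b <- tw(model_b)
  if (nrow(a) != nrow(b) || ncol(a) != ncol(b))
    stop("models must share K and vocabulary size", call. = FALSE)
  if (inherits(model_a, "hcs_lda") && inherits(model_b, "hcs_lda") &&
      !identical(model_a$term_ids, model_b$term_ids))
    stop("vocabulary mismatch between models", call. = FALSE)
  K <- nrow(a)
  if (K > 8) stop("match_topics enumerates permutations; K must be <= 8",
                  call. = FALSE)
  an <- a / sqrt(rowSums(a^2))
  bn <- b / sqrt(rowSums(b^2))
  sim <- an %*% t(bn)
  perms <- permutations_(K)
  scores <- apply(perms, 1, function(p) sum(sim[cbind(seq_len(K), p)]))
  best <- perms[which.max(scores), ]
  structure(as.integer(best),
            similarity = sim[cbind(seq_len(K), best)])
}

# All permutations of 1..n as rows (n small).
permutations_ <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (i in seq_len(n)) {
    rows <- nrow(sub)
    block <- cbind(rep(i, rows), ifelse(sub >= i, sub + 1L, sub))
    out[r + seq_len(rows), ] <- block
    r <- r + rows
  }
  storage.mode(out) <- "integer"
  out
}

#' Simulate a corpus from the LDA generative process
#'
#' Draws documents exactly from the model: theta_d ~ Dirichlet(alpha), each
#' token's topic from Multinomial(theta_d) and its term from the given
#' topic-word distribution. Used by parameter-recovery studies, where the
#' fitted `topic_word` is compared (after [match_topics()]) against the
#' `phi` used to generate.
#'
#' @param phi K x V matrix of topic-word probabilities (rows sum to 1).
#' @param n_docs number of documents.
#' @param doc_length tokens per document (single value or per-document
#'   vector).
#' @param alpha symmetric Dirichlet parameter for document mixtures.
#' @param term_ids optional vocabulary names (defaults to t1..tV).
#' @param seed integer random seed.
#' @return A list with `corpus` (an `hcs_corpus`) and `theta` (the drawn
#'   document mixtures).
#' @export
simulate_lda_corpus <- function(phi, n_docs, doc_length = 300L, alpha = 1,
                                term_ids = NULL, seed = 1L) {
  phi <- as.matrix(phi)
  if (any(abs(rowSums(phi) - 1) > 1e-8))
    stop("phi rows must sum to 1", call. = FALSE)
  K <- nrow(phi); V <- ncol(phi)
  if (is.null(term_ids)) term_ids <- sprintf("t%02d", seq_len(V))
  len <- rep_len(as.integer(doc_length), n_docs)
  with_seed(seed, {
    theta <- matrix(stats::rgamma(n_docs * K, shape = alpha), n_docs, K)
    theta <- theta / rowSums(theta)
    counts <- matrix(0L, n_docs, V, dimnames = list(NULL, term_ids))
    for (d in seq_len(n_docs)) {
      zk <- sample.int(K, len[d], replace = TRUE, prob = theta[d, ])
      nk <- tabulate(zk, nbins = K)
      for (k in which(nk > 0)) {
        w <- sample.int(V, nk[k], replace = TRUE, prob = phi[k, ])
        counts[d, ] <- counts[d, ] + tabulate(w, nbins = V)
      }
    }
    doc_ids <- sprintf("doc_%04d", seq_len(n_docs))
    rownames(counts) <- doc_ids
    list(
      corpus = structure(
        list(counts = counts, doc_ids = doc_ids, term_ids = term_ids,
             doc_drug = doc_ids, doc_time = rep(NA_real_, n_docs)),
        class = "hcs_corpus"),
      theta = theta
    )
  })
}

#' Planted topic-word distributions over the endpoint catalog
#'
#' Builds K topic-word rows concentrated on the endpoint event groups: a
#' topic matched to group g puts mass `1 - leak` spread uniformly over the
#' group's endpoints and `leak` spread over the rest, mirroring the
#' disjoint endpoint-group structure the study plants.
#'
#' @param endpoints endpoint catalog with `event_group`.
#' @param leak total probability leaked outside each topic's own group.
#' @return A G x V probability matrix with endpoint names as columns.
#' @export
planted_topic_word <- function(endpoints = default_endpoints(),
                               leak = 0.08) {
  validate_endpoints(endpoints)
  groups <- sort(unique(endpoints$event_group))
  V <- nrow(endpoints)
  phi <- matrix(0, length(groups), V,
                dimnames = list(NULL, endpoints$name))
  for (gi in seq_along(groups)) {
    own <- endpoints$event_group == groups[gi]
    phi[gi, own] <- (1 - leak) / sum(own)
    phi[gi, !own] <- leak / sum(!own)
  }
  phi
}

#' Write fitted CPTs and sampler trace to TSV
#'
#' Writes `doc_topic.tsv` (doc_id + K probability columns),
#' `topic_word.tsv` (term_id + K probability columns), `loglik_trace.tsv`
#' and a `model.json` metadata file (config, dimensions, document order).
#'
#' @param model an `hcs_lda`.
#' @param directory output directory.
#' @return Invisibly, the named vector of paths written.
#' @export
write_model <- function(model, directory) {
  stopifnot(inherits(model, "hcs_lda"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  K <- model$config$n_topics
  tcols <- sprintf("topic_%d", seq_len(K))
  dt <- data.frame(doc_id = model$doc_ids, model$doc_topic,
                   stringsAsFactors = FALSE)
  names(dt) <- c("doc_id", tcols)
  tw <- data.frame(term_id = model$term_ids, t(model$topic_word),
                   stringsAsFactors = FALSE)
  names(tw) <- c("term_id", tcols)
  paths <- c(
    doc_topic = file.path(directory, "doc_topic.tsv"),
    topic_word = file.path(directory, "topic_word.tsv"),
    loglik = file.path(directory, "loglik_trace.tsv"),
    model = file.path(directory, "model.json")
  )
  write_tsv_(dt, paths["doc_topic"])
  write_tsv_(tw, paths["topic_word"])
  write_tsv_(data.frame(sweep = seq_along(model$log_likelihood_trace),
                        log_likelihood = model$log_likelihood_trace),
             paths["loglik"])
  jsonlite::write_json(
    list(config = unclass(model$config),
         n_documents = length(model$doc_ids),
         n_terms = length(model$term_ids),
         n_retained = model$n_retained,
         term_ids = model$term_ids,
         doc_ids = model$doc_ids,
         package_version = as.character(utils::packageVersion("hcstopics"))),
    paths["model"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
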