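test_that("invalid LDA configs are rejected naming the field", {
  expect_error(lda_config(n_topics = 1), "n_topics")
  expect_error(lda_config(alpha = 0), "alpha")
  expect_error(lda_config(beta = -1), "beta")
  expect_error(lda_config(burn_in = 2000, n_iterations = 2000), "burn_in")
  expect_error(lda_config(sample_lag = 0), "sample_lag")
})

test_that("fit_lda rejects empty corpora and empty documents", {
  expect_error(fit_lda(toy_corpus(matrix(0L, 0, 3))), "empty corpus")
  expect_error(fit_lda(toy_corpus(rbind(c(1, 2), c(0, 0)))),
               "empty document")
})

test_that("CPT rows are normalized, positive, and counts are conserved", {
  corp <- toy_corpus(matrix(sample(1:20, 12), 4, 3))
  m <- fit_lda(corp, lda_config(n_topics = 3, n_iterations = 100,
                                burn_in = 20, sample_lag = 5, seed = 2))
  expect_equal(unname(rowSums(m$doc_topic)), rep(1, 4), tolerance = 1e-9)
  expect_equal(rowSums(m$topic_word), rep(1, 3), tolerance = 1e-9)
  expect_true(all(m$doc_topic > 0) && all(m$topic_word > 0))
  # final-state assignments conserve document lengths
  expect_equal(tabulate(m$tokens$doc, nbins = 4), rowSums(corp$counts),
               ignore_attr = TRUE)
  expect_equal(length(m$z), sum(corp$counts))
  expect_true(all(m$z %in% 1:3))
})

test_that("same seed reproduces the model; different seeds differ", {
  corp <- toy_corpus(matrix(sample(1:30, 20, replace = TRUE), 5, 4))
  cfg <- lda_config(n_topics = 2, n_iterations = 200, burn_in = 50, seed = 5)
  m1 <- fit_lda(corp, cfg)
  m2 <- fit_lda(corp, cfg)
  expect_identical(m1$doc_topic, m2$doc_topic)
  expect_identical(m1$z, m2$z)
  cfg2 <- cfg; cfg2$seed <- 6L
  m3 <- fit_lda(corp, cfg2)
  expect_false(identical(m1$z, m3$z))
})

test_that("separable corpora concentrate one topic per term as beta -> 0", {
  # three documents, each made of copies of a single distinct term
  corp <- toy_corpus(diag(3) * 12)
  m <- fit_lda(corp, lda_config(n_topics = 3, alpha = 0.5, beta = 0.01,
                                n_iterations = 500, burn_in = 200,
                                seed = 3))
  perm <- match_topics(diag(3), m)  # ideal one-hot topics as reference
  conc <- m$topic_word[cbind(perm, 1:3)]
  expect_true(all(conc > 0.95))
})

test_that("collapsed joint log likelihood matches the long-hand oracle", {
  counts <- rbind(c(2, 1, 0), c(0, 1, 2))
  corp <- toy_corpus(counts)
  cfg <- lda_config(n_topics = 3, alpha = 0.8, beta = 0.5,
                    n_iterations = 50, burn_in = 10, seed = 4)
  m <- fit_lda(corp, cfg)
  tok <- oracle_tokens(counts)
  expect_equal(log_likelihood(m, corp),
               oracle_log_joint(tok$doc, tok$term, m$z, 2, 3, 3, 0.8, 0.5))
  # trace is finite and its final entry equals the final-state joint
  expect_true(all(is.finite(m$log_likelihood_trace)))
  expect_equal(tail(m$log_likelihood_trace, 1), log_likelihood(m, corp))
  # single document, single token, K = 1 has closed form:
  # doc side is log 1; word side is log(beta / (V beta))
  corp1 <- toy_corpus(matrix(c(1L, 0L, 0L), 1, 3))
  tok1 <- oracle_tokens(corp1$counts)
  expect_equal(oracle_log_joint(tok1$doc, tok1$term, 1L, 1, 3, 1, 1, 0.5),
               log(0.5 / 1.5))
})

test_that("log_likelihood rejects mismatched vocabularies", {
  corp <- toy_corpus(rbind(c(2, 1), c(1, 2)))
  m <- fit_lda(corp, lda_config(n_topics = 2, n_iterations = 20,
                                burn_in = 5, seed = 1))
  other <- toy_corpus(rbind(c(2, 1), c(1, 2)), term_ids = c("x", "y"))
  expect_error(log_likelihood(m, other), "vocabulary mismatch")
})

test_that("the sampler trace climbs from its random start on planted data", {
  ds <- generate_dataset(sim_config(n_drugs = 20, seed = 21))
  corp <- build_corpus(discretize(build_auc_table(ds)))
  m <- fit_lda(corp, lda_config(n_iterations = 300, burn_in = 100,
                                seed = 21))
  tr <- m$log_likelihood_trace
  expect_true(all(is.finite(tr)))
  # second half fluctuates around a plateau well above the start
  expect_gt(mean(tail(tr, 100)), tr[1])
  # plateau: late fluctuation is small next to the initial climb
  expect_lt(diff(range(tail(tr, 100))), 0.2 * (max(tr) - tr[1]))
})

test_that("rank_terms sorts by probability with catalog-order ties", {
  corp <- toy_corpus(rbind(c(5, 3, 2), c(2, 3, 5)),
                     term_ids = c("a", "b", "c"))
  m <- fit_lda(corp, lda_config(n_topics = 2, n_iterations = 50,
                                burn_in = 10, seed = 1))
  m$topic_word[1, ] <- c(0.5, 0.3, 0.2)
  expect_equal(rank_terms(m, 1)$term, c("a", "b", "c"))
  m$topic_word[2, ] <- rep(1 / 3, 3)
  expect_equal(rank_terms(m, 2)$term, c("a", "b", "c"))  # tie-break
  expect_error(rank_terms(m, 3), "1\\.\\.2")
})

test_that("match_topics returns identity for self and inverts row swaps", {
  corp <- toy_corpus(matrix(sample(1:10, 20, replace = TRUE), 4, 5))
  m <- fit_lda(corp, lda_config(n_topics = 3, n_iterations = 100,
                                burn_in = 20, seed = 9))
  expect_equal(match_topics(m, m), 1:3, ignore_attr = TRUE)
  swapped <- m$topic_word[c(3, 1, 2), ]
  expect_equal(match_topics(m, swapped), c(2, 3, 1), ignore_attr = TRUE)
  expect_error(match_topics(m$topic_word, m$topic_word[, 1:3]),
               "share K and vocabulary")
})

test_that("independent seeds on the planted corpus agree after matching", {
  ds <- generate_dataset(sim_config(seed = 31))
  corp <- build_corpus(discretize(build_auc_table(ds)))
  cfg <- function(s) lda_config(n_iterations = 500, burn_in = 200, seed = s)
  m1 <- fit_lda(corp, cfg(1))
  m2 <- fit_lda(corp, cfg(2))
  perm <- match_topics(m1, m2)
  sims <- vapply(1:3, function(k)
    cosine(m1$topic_word[k, ], m2$topic_word[perm[k], ]), numeric(1))
  expect_true(all(sims >= 0.95))
})

test_that("argmax endpoint grouping on the planted corpus recovers truth", {
  ds <- generate_dataset(sim_config(seed = 31))
  corp <- build_corpus(discretize(build_auc_table(ds)))
  m <- fit_lda(corp, lda_config(n_iterations = 500, burn_in = 200,
                                seed = 14))
  g2t <- group_topic_map(m)
  asn <- assign_endpoints(m)
  truth <- ds$truth$endpoint_groups
  expect_equal(asn$topic[match(truth$endpoint_id, asn$endpoint_id)],
               unname(g2t[truth$event_group]))
  # the matched group-1 topic ranks the four severe-damage endpoints first
  top4 <- rank_terms(m, g2t[1])$term[1:4]
  expect_setequal(top4, truth$endpoint_id[truth$event_group == 1])
})

test_that("simulate_lda_corpus draws documents of the requested shape", {
  phi <- planted_topic_word()
  sim <- simulate_lda_corpus(phi, n_docs = 25, doc_length = 40,
                             alpha = 0.7, seed = 2)
  expect_equal(dim(sim$corpus$counts), c(25, 10))
  expect_equal(unname(rowSums(sim$corpus$counts)), rep(40, 25))
  expect_equal(rowSums(sim$theta), rep(1, 25), tolerance = 1e-12)
  expect_identical(sim$corpus$counts,
                   simulate_lda_corpus(phi, 25, 40, 0.7, seed = 2)$corpus$counts)
})
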