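doc_topic_fixture <- function() {
  dt <- rbind(
    "d1@6" = c(0.8, 0.1, 0.1),
    "d2@6" = c(0.2, 0.6, 0.2),
    "d3@6" = c(0.4, 0.4, 0.2))
  dt
}

test_that("class settings validate their assignment tables", {
  expect_error(class_setting("s", data.frame(drug_id = c("a", "a"),
                                             class_label = c("x", "y"))),
               "exactly one class")
  expect_error(class_setting("s", data.frame(drug_id = "a",
                                             class_label = "x"),
                             classes = c("x", "y")),
               "non-empty")
})

test_that("class_means averages p(topic|document) within classes", {
  dt <- doc_topic_fixture()
  st <- class_setting("s", c(d1 = "A", d2 = "B", d3 = "B"),
                      classes = c("A", "B"))
  mu <- class_means(dt, st, 6)
  expect_equal(unname(mu["A", ]), c(0.8, 0.1, 0.1))
  expect_equal(unname(mu["B", ]), c(0.3, 0.5, 0.2))
  # single class: plain column means; single drug: that drug's row
  st1 <- class_setting("one", c(d1 = "A", d2 = "A", d3 = "A"))
  expect_equal(unname(class_means(dt, st1, 6)[1, ]), colMeans(dt),
               ignore_attr = TRUE)
  # labeled drug without a document at the time point errors
  st2 <- class_setting("s", c(d1 = "A", d9 = "B"))
  expect_error(class_means(dt, st2, 6), "d9")
  expect_error(class_means(dt, st, 24), "24")
})

test_that("diagnostic scores column-normalize the class means", {
  expect_equal(unname(diagnostic_scores(rbind(c(0.3), c(0.3)))),
               matrix(0.5, 2, 1), ignore_attr = TRUE)
  expect_equal(unname(diagnostic_scores(matrix(c(0.2, 0.5, 0.3), 1))),
               matrix(1, 1, 3), ignore_attr = TRUE)  # C = 1
  S <- diagnostic_scores(rbind(c(0.8, 0.1), c(0.2, 0.4)))
  expect_equal(unname(S), rbind(c(0.8, 0.2), c(0.2, 0.8)))
  expect_error(diagnostic_scores(rbind(c(0, 1), c(0, 1))), "degenerate")
  expect_error(diagnostic_scores(rbind(c(-0.1, 1), c(0.5, 1))),
               "non-negative")
})

test_that("diagnostic score properties hold on random mean matrices", {
  set.seed(42)
  for (i in 1:200) {
    C <- sample(2:4, 1); K <- sample(2:5, 1)
    mu <- matrix(runif(C * K, 0.01, 1), C, K)
    S <- diagnostic_scores(mu)
    # column normalization over classes
    expect_equal(colSums(S), rep(1, K), tolerance = 1e-9)
    expect_true(all(S >= 0 & S <= 1))
    # scale invariance per topic column
    sc <- runif(K, 0.1, 10)
    expect_equal(diagnostic_scores(sweep(mu, 2, sc, "*")), S,
                 tolerance = 1e-12)
    # permutation equivariance over topics
    p <- sample(K)
    expect_equal(diagnostic_scores(mu[, p, drop = FALSE]),
                 S[, p, drop = FALSE], tolerance = 1e-15,
                 ignore_attr = TRUE)
  }
})

test_that("diagnostic_topic takes the argmax and flags ties", {
  s <- rbind(A = c(0.7, 0.2, 0.1), B = c(0.4, 0.4, 0.2))
  dg <- diagnostic_topic(s)
  expect_equal(dg$topic, c(1L, 1L))
  expect_equal(dg$tie, c(FALSE, TRUE))
  expect_equal(dg$score, c(0.7, 0.4))
})

test_that("assign_endpoints maps each term to its argmax topic", {
  tw <- rbind(c(0.221, 0.5, 1 / 3), c(0.026, 0.3, 1 / 3),
              c(0.010, 0.2, 1 / 3))
  colnames(tw) <- c("Steatosis", "x", "y")
  asn <- assign_endpoints(tw)
  expect_equal(asn$topic[asn$endpoint_id == "Steatosis"], 1L)
  expect_equal(asn$p[asn$endpoint_id == "Steatosis"], 0.221)
  expect_false(asn$tie[1])
  expect_true(asn$tie[asn$endpoint_id == "y"])   # uniform -> topic 1, tie
  expect_equal(asn$topic[asn$endpoint_id == "y"], 1L)
})

test_that("relabeling topics permutes scores and assignments identically", {
  dt <- doc_topic_fixture()
  st <- class_setting("s", c(d1 = "A", d2 = "B", d3 = "B"))
  p <- c(3, 1, 2)
  mu <- class_means(dt, st, 6)
  mu_p <- class_means(dt[, p], st, 6)
  expect_equal(unname(diagnostic_scores(mu_p)),
               unname(diagnostic_scores(mu)[, p]))
  dg <- diagnostic_topic(diagnostic_scores(mu))
  dg_p <- diagnostic_topic(diagnostic_scores(mu_p))
  expect_equal(dg_p$topic, match(dg$topic, p))
})

test_that("bridge_report joins classes to topics to endpoint sets", {
  asn <- data.frame(endpoint_id = c("e1", "e2", "e3"),
                    topic = c(1L, 1L, 2L), p = c(0.4, 0.3, 0.5),
                    tie = FALSE)
  dt <- rbind("a@6" = c(0.9, 0.1), "b@6" = c(0.2, 0.8))
  st <- class_setting("s", c(a = "nec", b = "non"))
  d <- diagnostic_score_matrix(dt, st, 6)
  rep1 <- bridge_report(asn, list(d))
  expect_equal(nrow(rep1$links), 2)
  expect_equal(rep1$links$endpoints[rep1$links$class_label == "nec"],
               "e1; e2")
  txt <- format(rep1)
  expect_match(txt, "s @ 6 h")
  expect_match(txt, "class nec -> topic 1")
  # degenerate: no diagnostics -> assignment-only report
  rep0 <- bridge_report(asn, list())
  expect_null(rep0$links)
  expect_match(format(rep0), "Endpoint assignment")
  # one setting, one time point -> exactly one section
  expect_equal(length(gregexpr("## s @", txt)[[1]]), 1)
})

test_that("bridge report writes markdown and JSON", {
  dir <- withr::local_tempdir()
  asn <- data.frame(endpoint_id = "e1", topic = 1L, p = 1, tie = FALSE)
  rep1 <- bridge_report(asn, list())
  write_bridge_report(rep1, file.path(dir, "r.md"), file.path(dir, "r.json"))
  expect_true(file.exists(file.path(dir, "r.md")))
  j <- jsonlite::read_json(file.path(dir, "r.json"))
  expect_equal(j$assignment[[1]]$endpoint_id, "e1")
})

test_that("default_settings builds the three binary and one 3-class setting", {
  labels <- data.frame(
    drug_id = sprintf("d%d", 1:6),
    class_label = c("necrosis_6h", "necrosis_6h", "necrosis_24h",
                    "non_necrosis", "non_necrosis", "non_necrosis"))
  st <- default_settings(labels)
  expect_named(st, c("setting_I", "setting_II", "setting_III",
                     "three_class"))
  tab1 <- table(st$setting_I$assignment$class_label)
  expect_equal(unname(tab1["necrosis"]), 2, ignore_attr = TRUE)
  tab3 <- table(st$setting_III$assignment$class_label)
  expect_equal(unname(tab3["necrosis"]), 3, ignore_attr = TRUE)
  expect_equal(length(st$three_class$classes), 3)
})
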