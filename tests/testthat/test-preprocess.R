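test_that("control normalization is pointwise ratio on a shared dose grid", {
  d <- c(25, 50, 100, 200)
  trt <- dose_response_curve(d, c(1, 1.2, 1.5, 2))
  ctl <- dose_response_curve(d, c(1, 1, 1, 1))
  expect_equal(normalize_by_control(trt, trt)$values, rep(1, 4))
  expect_equal(normalize_by_control(
    dose_response_curve(d, 2 * ctl$values), ctl)$values, rep(2, 4))
  expect_equal(
    normalize_by_control(dose_response_curve(c(100, 200), c(1, 1.5)),
                         dose_response_curve(c(100, 200), c(1, 1)))$values,
    c(1, 1.5))
  # difference mode subtracts and shifts the no-effect baseline to 0
  dm <- normalize_by_control(trt, ctl, method = "difference")
  expect_equal(dm$values, trt$values - ctl$values)
  expect_equal(dm$baseline, 0)
})

test_that("normalization rejects mismatched grids and zero controls", {
  trt <- dose_response_curve(c(100, 200), c(1, 2))
  expect_error(
    normalize_by_control(trt, dose_response_curve(c(50, 100), c(1, 1))),
    "mismatch")
  expect_error(
    normalize_by_control(trt, dose_response_curve(c(100, 200), c(0, 1))),
    "dose 100")
})

test_that("AUC is the trapezoidal integral of (value - 1) over log2 dose", {
  d10 <- 200 * 2^(-9:0)  # 9 two-fold steps
  expect_equal(compute_auc(dose_response_curve(d10, rep(1, 10))), 0)
  expect_equal(compute_auc(dose_response_curve(d10, rep(2, 10))), 9)
  expect_equal(compute_auc(dose_response_curve(c(100, 200), c(1, 3))), 1)
  expect_error(dose_response_curve(100, 1), "at least 2")
})

test_that("AUC is invariant to relabeling the dose units", {
  set.seed(4)
  d <- 200 * 2^(-9:0)
  v <- 1 + cumsum(runif(10, 0, 0.2))
  a1 <- compute_auc(dose_response_curve(d, v))
  a2 <- compute_auc(dose_response_curve(d * 1000, v))  # uM -> nM
  expect_equal(a1, a2)
})

test_that("the AUC table has one row per drug and 40 ordered columns", {
  ds <- generate_dataset(sim_config(n_drugs = 4, seed = 9))
  tab <- build_auc_table(ds)
  expect_equal(dim(tab), c(4, 40))
  # time-major then catalog endpoint order
  eps <- default_endpoints()$name
  expect_equal(colnames(tab)[1:10], paste0(eps, "@1"))
  expect_equal(colnames(tab)[31:40], paste0(eps, "@48"))
  expect_false(anyNA(tab))
})

test_that("a single (drug, endpoint, time) yields a 1 x 1 AUC table", {
  d <- 200 * 2^(-4:0)
  curves <- rbind(
    data.frame(drug_id = "d1", endpoint_id = "Steatosis", plate = 2,
               time_h = 6, dose_uM = d, value = c(1, 1, 2, 2, 2),
               is_control = 0),
    data.frame(drug_id = "DMSO", endpoint_id = "Steatosis", plate = 2,
               time_h = 6, dose_uM = d, value = 1, is_control = 1))
  eps <- data.frame(name = c("Steatosis", "Apoptosis"), plate = c(2, 1),
                    event_group = c(1, 2))
  tab <- build_auc_table(curves, endpoints = eps[1, , drop = FALSE])
  expect_equal(dim(tab), c(1, 1))
  expect_equal(colnames(tab), "Steatosis@6")
})

test_that("a missing curve raises a completeness error naming the gap", {
  ds <- generate_dataset(sim_config(n_drugs = 3, seed = 9))
  cur <- ds$curves
  drop <- cur$drug_id == "drug_002" & cur$endpoint_id == "Apoptosis" &
    cur$time_h == 24 & cur$is_control == 0
  expect_error(build_auc_table(cur[!drop, ]),
               "drug_002 / Apoptosis / 24")
})

test_that("discretization maps columns to 1-based equal-width bins", {
  expect_equal(as.vector(discretize(matrix(c(0, 50, 100)), n_bins = 100)),
               c(1L, 51L, 100L))
  expect_equal(as.vector(discretize(matrix(c(5, 5, 5)), n_bins = 100)),
               c(1L, 1L, 1L))
  expect_equal(as.vector(discretize(matrix(c(0, 1)), n_bins = 2)),
               c(1L, 2L))
  expect_error(discretize(matrix(c(0, NA)), n_bins = 10), "non-finite")
  expect_error(discretize(matrix(0:5), n_bins = 1), "n_bins")
})

test_that("within a column a larger AUC never gets a smaller bin", {
  set.seed(11)
  for (rep in 1:20) {
    v <- rnorm(30)
    b <- as.vector(discretize(matrix(v), n_bins = sample(2:100, 1)))
    o <- order(v)
    expect_true(all(diff(b[o]) >= 0))
    expect_equal(b[which.max(v)], max(b))
  }
})

test_that("equal-frequency binning spreads ranks uniformly", {
  v <- c(1, 2, 3, 100)  # outlier dominates equal-width, not equal-freq
  bw <- as.vector(discretize(matrix(v), n_bins = 4))
  bf <- as.vector(discretize(matrix(v), n_bins = 4,
                             scheme = "equal_frequency"))
  expect_equal(bw, c(1L, 1L, 1L, 4L))
  expect_equal(bf, c(1L, 2L, 3L, 4L))
})

test_that("corpus reorientation yields drug-hour documents over endpoints", {
  ds <- generate_dataset(sim_config(n_drugs = 3, seed = 13))
  disc <- discretize(build_auc_table(ds))
  corp <- build_corpus(disc)
  expect_equal(dim(corp$counts), c(12, 10))
  expect_equal(corp$term_ids, default_endpoints()$name)
  # drug-major, time ascending document order
  expect_equal(corp$doc_ids[1:4], paste0("drug_001@", c(1, 6, 24, 48)))
  # conservation: token count equals the discretized table total
  expect_equal(sum(corp$counts), sum(disc))
  # every cell carries at least one token (1-based bins)
  expect_true(all(corp$counts >= 1))
  # orientation: entry for (drug, time, endpoint) matches the table cell
  expect_equal(corp$counts["drug_002@24", "Apoptosis"],
               disc["drug_002", "Apoptosis@24"])
})

test_that("corpus and AUC tables round-trip through their TSV dialects", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(sim_config(n_drugs = 3, seed = 17))
  tab <- build_auc_table(ds)
  p1 <- file.path(dir, "auc.tsv")
  write_auc_table(tab, p1)
  back <- read_auc_table(p1)
  expect_equal(unclass(back), unclass(tab), tolerance = 1e-12,
               ignore_attr = TRUE)

  corp <- build_corpus(discretize(tab))
  p2 <- file.path(dir, "corpus.tsv")
  p3 <- file.path(dir, "corpus_tri.tsv")
  write_corpus(corp, p2, p3)
  back2 <- read_corpus(p2)
  expect_identical(back2$counts, corp$counts)
  expect_equal(back2$doc_time, corp$doc_time)
  # triplet file is 1-based with a dimension header
  tri <- read.delim(p3, header = FALSE, skip = 1)
  expect_equal(sum(tri$V3), sum(corp$counts))
  hdr <- strsplit(readLines(p3, n = 1), "\t")[[1]]
  expect_equal(as.integer(hdr[2:3]), dim(corp$counts))

  # byte-identical rewrite (pipeline determinism at the file level)
  p4 <- file.path(dir, "corpus_again.tsv")
  write_corpus(corp, p4)
  expect_identical(readLines(p2), readLines(p4))
})
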