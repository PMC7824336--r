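test_that("quartile assignment follows the inclusive-median thresholds", {
  q <- assign_quartiles(c(BF = 10, MP = 20, KMP = 30, AC = 40,
                          QS = 50, BM = 60, HOR = 70))
  expect_identical(unname(q[c("BF", "MP")]), c(1L, 1L))
  expect_identical(unname(q[c("KMP", "AC")]), c(2L, 2L))
  expect_identical(unname(q[c("QS", "BM")]), c(3L, 3L))
  expect_identical(unname(q["HOR"]), 4L)

  # ties share the lower quartile; all equal -> everyone in quartile 1
  expect_identical(unname(assign_quartiles(c(a = 7, b = 7, c = 7))),
                   rep(1L, 3))
  expect_identical(unname(assign_quartiles(c(only = 12))), 1L)
})

test_that("quartiles, shares and rankings are invariant under scaling CC counts", {
  set.seed(505)
  comp <- matrix(sample(10:500, 40 * 7, TRUE), nrow = 40,
                 dimnames = list(NULL, c("AC","BF","BM","HOR","KMP","MP","QS")))
  classes <- sample(1:3, 40, TRUE)
  rec1 <- records_from_comp(comp, classes)
  rec2 <- records_from_comp(comp * 13, classes)
  s1 <- aggregate_shares(rec1)
  s2 <- aggregate_shares(rec2)
  expect_equal(s1, s2, ignore_attr = TRUE)
  for (k in 1:3) {
    expect_identical(rank_algorithms(s1, k, attr(s1, "n_patterns")),
                     rank_algorithms(s2, k, attr(s2, "n_patterns")))
  }
})

test_that("per-algorithm quartile shares sum to one in non-empty classes", {
  set.seed(606)
  comp <- matrix(sample(10:500, 60 * 7, TRUE), nrow = 60,
                 dimnames = list(NULL, c("AC","BF","BM","HOR","KMP","MP","QS")))
  classes <- sample(c(1L, 3L, 4L), 60, TRUE)   # class 2 left empty
  rec <- records_from_comp(comp, classes)
  shares <- aggregate_shares(rec)
  n_pat <- attr(shares, "n_patterns")
  expect_identical(n_pat[2L], 0L)
  tot <- shares$q1 + shares$q2 + shares$q3 + shares$q4
  expect_true(all(abs(tot[shares$class != 2L] - 1) < 1e-9))
  expect_true(all(tot[shares$class == 2L] == 0))
  expect_identical(rank_algorithms(shares, 2L), character(0))
})

test_that("an algorithm with strictly minimal CC everywhere ranks first with q1 = 1", {
  set.seed(707)
  algos <- c("AC", "BF", "BM", "HOR", "KMP", "MP", "QS")
  comp <- matrix(sample(100:900, 30 * 7, TRUE), nrow = 30,
                 dimnames = list(NULL, algos))
  comp[, "HOR"] <- 1:30   # strictly below everything else
  rec <- records_from_comp(comp, rep(1L, 30))
  shares <- aggregate_shares(rec)
  hor <- shares[shares$Algo == "HOR", ]
  expect_equal(hor$q1, 1)
  expect_identical(rank_algorithms(shares, 1L)[1L], "HOR")
})

test_that("the selection rule reproduces the published per-class choices", {
  # DNA class 1 column: QS leads the first quartile
  dna1 <- shares_from_percent(
    q1 = c(20.59, 0, 47.92, 38.24, 14.71, 0, 55.88),
    q2 = c(29.41, 23.53, 18.75, 20.59, 35.29, 23.53, 14.71),
    q3 = c(23.53, 26.47, 25.00, 29.41, 23.53, 26.47, 29.41),
    q4 = c(26.47, 50.00, 8.33, 11.76, 26.47, 50.00, 0))
  expect_identical(rank_algorithms(dna1, 1L)[1L], "QS")

  # DNA class 8 column: BM leads
  dna8 <- shares_from_percent(
    q1 = c(5.43, 0, 61.95, 53.92, 0, 0, 53.68),
    q2 = c(36.47, 21.58, 24.38, 24.32, 21.58, 21.58, 25.08),
    q3 = c(31.67, 24.36, 13.68, 21.77, 37.77, 24.56, 21.24),
    q4 = c(26.43, 54.06, 0, 0, 40.65, 53.87, 0))
  expect_identical(rank_algorithms(dna8, 1L)[1L], "BM")

  # natural-language class 6: QS leads; class 7: BM leads
  nl6 <- shares_from_percent(
    q1 = c(0, 0, 64.05, 41.01, 0, 0, 70.13),
    q2 = c(50.13, 0, 35.95, 58.99, 0, 0, 29.87),
    q3 = c(49.87, 32.41, 0, 0, 46.58, 46.08, 0),
    q4 = c(0, 67.59, 0, 0, 53.42, 53.92, 0))
  expect_identical(rank_algorithms(nl6, 1L)[1L], "QS")

  nl7 <- shares_from_percent(
    q1 = c(0, 0, 65.02, 51.24, 0, 0, 59.01),
    q2 = c(58.66, 0, 34.98, 48.76, 0, 0, 40.99),
    q3 = c(41.34, 31.45, 0, 0, 47.70, 45.94, 0),
    q4 = c(0, 68.55, 0, 0, 52.30, 54.06, 0))
  expect_identical(rank_algorithms(nl7, 1L)[1L], "BM")
})

test_that("campaigns produce one record per pattern-algorithm pair", {
  rec <- run_campaign("AAAA", "AA", algorithms = "BF")
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$comp, 6)
  expect_identical(rec$m, 2L)

  rec <- run_campaign("ACGTACGTACGT", c("ACG", "TAC", "GT"))
  expect_identical(nrow(rec), 21L)   # 3 patterns x 7 algorithms
  expect_s3_class(attr(rec, "scheme"), "class_scheme")
  # entropy columns coherent
  expect_equal(rec$PattEntRound, round_entropy(rec$PattEnt))

  # pattern longer than text: recorded with comp = 0
  rec <- run_campaign("ACG", c("ACG", "ACGTACGT"))
  expect_true(all(rec$comp[rec$pattern == "ACGTACGT"] == 0))
})

test_that("model building, prediction and JSON round-trip are coherent", {
  corp <- generate_synthetic_corpus(c("A", "C", "G", "T"), rep(0.25, 4),
                                    5000, seed = 11, id = "dna-sim")
  ps <- sample_patterns(corp, count = 60, seed = 7)
  mod <- build_model(corp, ps, domain = "dna")
  expect_s3_class(mod, "ranking_model")
  expect_identical(sum(mod$class_counts), 60L)
  expect_identical(mod$provenance$seed, 7L)
  for (k in seq_len(mod$scheme$class_count)) {
    r <- mod$rankings[[k]]
    if (length(r)) expect_setequal(r, matcher_ids())
  }

  pred <- predict(mod, "GGGGGGGG")    # entropy 0 -> class containing 0
  expect_identical(attr(pred, "class_index"), 1L)
  pred_hi <- predict(mod, "ACGTACGTACGTACGT")
  expect_identical(attr(pred_hi, "class_index"), mod$scheme$class_count)
  expect_error(predict(mod, ""), "non-empty")

  path <- tempfile(fileext = ".json")
  on.exit(unlink(path), add = TRUE)
  write_model(mod, path)
  mod2 <- read_model(path)
  expect_equal(mod2$scheme$boundaries, mod$scheme$boundaries,
               tolerance = 1e-12)
  expect_identical(mod2$rankings, mod$rankings)
  expect_identical(mod2$class_counts, mod$class_counts)
  expect_equal(mod2$shares$q1, mod$shares$q1, tolerance = 1e-12)
  # a rebuilt model validates perfectly against the original
  rep <- validate_model(mod2, mod$shares)
  expect_true(all(rep$d2 < 1e-12))
})

test_that("campaign occurrences agree with the oracle on a synthetic corpus", {
  corp <- generate_synthetic_corpus(c("A", "C", "G", "T"), rep(0.25, 4),
                                    2000, seed = 3)
  ps <- sample_patterns(corp, count = 25, seed = 5)
  for (p in ps$patterns) {
    ref <- naive_oracle(corp$text, p)
    expect_gte(length(ref), 1L)  # sampled patterns occur in their source
    for (a in matcher_ids()) {
      expect_identical(match_pattern(a, corp$text, p)$occurrences, ref)
    }
  }
})
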