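write_tmp <- function(lines, sep = "\n") {
  path <- tempfile()
  cat(paste(lines, collapse = sep), file = path)
  path
}

test_that("FASTA records are concatenated, uppercased and strictly filtered", {
  path <- write_tmp(c(">r1", "ACGT", ">r2", "GGTT", ""))
  corp <- read_fasta(path)
  expect_identical(corp$text, "ACGTGGTT")
  expect_identical(nchar(corp$text), 8L)
  expect_identical(attr(corp, "n_filtered"), 0L)
  unlink(path)

  path <- write_tmp(c(">r1", "acgt", ""))
  expect_identical(read_fasta(path)$text, "ACGT")
  unlink(path)

  path <- write_tmp(c(">r1", "ACNNGT", ""))
  expect_message(corp <- read_fasta(path), "2 non-ACGT")
  expect_identical(corp$text, "ACGT")
  expect_identical(attr(corp, "n_filtered"), 2L)
  # lax mode keeps ambiguity codes
  corp <- read_fasta(path, strict = FALSE)
  expect_identical(corp$text, "ACNNGT")
  unlink(path)

  expect_error(read_fasta(tempfile()), "not found")
})

test_that("plain text preserves characters and normalizes line endings", {
  path <- write_tmp("In the beginning")
  corp <- read_plain_text(path)
  expect_identical(nchar(corp$text), 16L)
  unlink(path)

  lf <- write_tmp(c("one two", "three"), sep = "\n")
  crlf <- write_tmp(c("one two", "three"), sep = "\r\n")
  expect_identical(read_plain_text(lf)$text, read_plain_text(crlf)$text)
  expect_identical(read_plain_text(lf)$text, "one two three")
  unlink(c(lf, crlf))

  # the worked 32-character pattern is findable in its source line
  path <- write_tmp("praise e name of the LORD. And the LORD said")
  corp <- read_plain_text(path)
  hits <- naive_oracle(corp$text, "e name of the LORD. And the LORD")
  expect_identical(length(hits), 1L)
  unlink(path)

  empty <- write_tmp("")
  expect_error(read_plain_text(empty), "empty")
  unlink(empty)
})

test_that("pattern sampling is seeded, de-duplicated and cycles the lengths", {
  corp <- generate_synthetic_corpus(c("A", "C", "G", "T"), rep(0.25, 4),
                                    3000, seed = 99)
  ps1 <- sample_patterns(corp, lengths = c(2, 4, 8, 16, 32), count = 100,
                         seed = 7)
  ps2 <- sample_patterns(corp, lengths = c(2, 4, 8, 16, 32), count = 100,
                         seed = 7)
  expect_identical(ps1$patterns, ps2$patterns)
  expect_identical(length(ps1$patterns), 100L)
  expect_identical(anyDuplicated(ps1$patterns), 0L)
  # every sampled pattern occurs in its source corpus
  for (p in ps1$patterns[1:20]) {
    expect_gte(length(naive_oracle(corp$text, p)), 1L)
  }
  # lengths deviate from the uniform cycle only by rounding; length 2 can
  # supply at most the 16 distinct dinucleotides, the deficit spills over
  tab <- table(factor(nchar(ps1$patterns), levels = c(2, 4, 8, 16, 32)))
  expect_identical(unname(as.integer(tab["2"])), 16L)
  expect_identical(sum(tab), 100L)
  expect_true(all(abs(tab[-1] - 21) <= 1))

  # with feasible lengths the cycle is exactly uniform
  ps4 <- sample_patterns(corp, lengths = c(4, 8, 16, 32), count = 100,
                         seed = 3)
  tab4 <- table(factor(nchar(ps4$patterns), levels = c(4, 8, 16, 32)))
  expect_true(all(tab4 == 25L))

  ps3 <- sample_patterns(corp, lengths = 3, count = 5, seed = 1)
  expect_true(all(nchar(ps3$patterns) == 3L))
  expect_error(sample_patterns(corp, lengths = 5000, count = 2, seed = 1),
               "pattern length")
  # more distinct patterns than exist cannot be sampled
  tiny <- generate_synthetic_corpus("A", 1, 10, seed = 1)
  expect_error(sample_patterns(tiny, lengths = 2, count = 5, seed = 1),
               "distinct")
})

test_that("synthetic corpora are reproducible with calibrated frequencies", {
  c1 <- generate_synthetic_corpus(c("A", "C", "G", "T"), rep(0.25, 4),
                                  1e5, seed = 1)
  c2 <- generate_synthetic_corpus(c("A", "C", "G", "T"), rep(0.25, 4),
                                  1e5, seed = 1)
  expect_identical(c1$text, c2$text)
  freq <- table(strsplit(c1$text, "")[[1]]) / 1e5
  expect_true(all(abs(freq - 0.25) < 0.01))

  expect_identical(generate_synthetic_corpus("A", 1, 5, seed = 3)$text,
                   "AAAAA")
  expect_error(generate_synthetic_corpus(c("A", "B"), 1, 5, seed = 1),
               "match")
  expect_error(generate_synthetic_corpus(c("A", "B"), c(0.9, 0.2), 5,
                                         seed = 1), "sum to 1")
})

test_that("campaign results survive a CSV round-trip", {
  rec <- run_campaign("ACGTACGTACGT", c("ACG", "TAC", "GT"))
  path <- tempfile(fileext = ".csv")
  write_results(rec, path)
  lines <- readLines(path)
  expect_identical(length(lines), 22L)   # header + 21 records
  expect_match(lines[1], "pattern.*m.*Algo.*comp.*PattEnt.*PattEntRound.*PattEntClass")

  back <- read_results(path)
  expect_identical(back$pattern, rec$pattern)
  expect_identical(back$Algo, rec$Algo)
  expect_identical(back$comp, rec$comp)
  expect_equal(back$PattEnt, rec$PattEnt, tolerance = 1e-12)
  expect_equal(back$PattEntRound, rec$PattEntRound)
  expect_identical(back$PattEntClass, rec$PattEntClass)
  unlink(path)

  # comp = 0 is written as an explicit zero cell
  rec0 <- run_campaign("ACG", "ACGTACGT")
  path0 <- tempfile(fileext = ".csv")
  write_results(rec0, path0)
  expect_match(readLines(path0)[2], ",0,")
  unlink(path0)
})
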