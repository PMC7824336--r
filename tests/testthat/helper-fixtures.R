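# Shared fixture builders: random texts/patterns and printed reference
# tables reconstructed in code.

random_string <- function(n, alphabet = c("A", "C", "G", "T")) {
  if (n == 0L) return("")
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# one random (text, pattern) case over a random alphabet
random_case <- function(max_alpha = 6L, max_n = 60L, max_m = 12L) {
  k <- sample(2:max_alpha, 1L)
  alpha <- LETTERS[seq_len(k)]
  list(text = random_string(sample(0:max_n, 1L), alpha),
       pattern = random_string(sample(1:max_m, 1L), alpha))
}

# the 91 distinct two-decimal DNA entropy observations: the published
# head (0, 0.34, 0.53, 0.54, 0.70, 0.81, 0.90, 0.95, 0.99) and tail
# (1.96 .. 2.00), with interior values filling the count to 91
dna_distinct_entropies <- function() {
  vals <- c(0, 0.34, 0.53, 0.54, 0.70, 0.81, 0.90, 0.95, 0.99,
            seq(1.00, 1.76, by = 0.01),
            1.96, 1.97, 1.98, 1.99, 2.00)
  stopifnot(length(unique(vals)) == 91L)
  vals
}

# the 105 distinct natural-language observations: published head
# (0, 1, 1.5, 2, 2.16, 2.25, 2.41, 2.5, 2.62) and tail (3.83 .. 3.88),
# interior filled to the published count
nl_distinct_entropies <- function() {
  vals <- c(0, 1, 1.5, 2, 2.16, 2.25, 2.41, 2.5, 2.62,
            seq(2.63, 3.53, by = 0.01),
            3.83, 3.84, 3.86, 3.87, 3.88)
  stopifnot(length(unique(vals)) == 105L)
  vals
}

# quartile-share table for one class from printed percentages
shares_from_percent <- function(q1, q2, q3, q4, class_index = 1L) {
  algos <- c("AC", "BF", "BM", "HOR", "KMP", "MP", "QS")
  data.frame(class = class_index, Algo = algos,
             q1 = q1 / 100, q2 = q2 / 100, q3 = q3 / 100, q4 = q4 / 100,
             stringsAsFactors = FALSE)
}

# hand-rolled campaign records with prescribed comparison counts;
# comp_matrix: patterns in rows, algorithms in columns
records_from_comp <- function(comp_matrix, classes) {
  algos <- colnames(comp_matrix)
  n_pat <- nrow(comp_matrix)
  data.frame(
    pattern = rep(sprintf("p%03d", seq_len(n_pat)), each = length(algos)),
    m = 4L,
    Algo = rep(algos, times = n_pat),
    comp = as.vector(t(comp_matrix)),
    PattEnt = 1,
    PattEntRound = 1,
    PattEntClass = rep(classes, each = length(algos)),
    stringsAsFactors = FALSE
  )
}
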