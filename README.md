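# entropymatch

Entropy-guided selection of exact string-matching algorithms.

Given a text domain (DNA, natural-language, ...), which of the classical
exact string matchers will do the least work for a given search pattern?
`entropymatch` answers this with a platform-independent methodology: it
instruments seven classical matchers — brute force (BF), Morris-Pratt (MP),
Knuth-Morris-Pratt (KMP), Apostolico-Crochemore (AC), Quick Search (QS),
Boyer-Moore (BM) and Horspool (HOR) — to count pattern-vs-text character
comparisons (the *CC metric*), groups search patterns into classes by the
Shannon entropy of their character distribution,

    H = -Σ p_i · log2(p_i)   (bits),

and, within each entropy class, reduces every pattern's seven CC counts to
quartiles. The per-class quartile shares induce a ranking of the
algorithms, and the fitted model predicts the expected-cheapest matcher for
any unseen pattern from its entropy alone. Model quality against held-out
campaigns is scored with the double-scaled Euclidean distance
`d2 = sqrt(Σ (p1_i - p2_i)² / md_i) / sqrt(v)`, its similarity complement
`1 - d2`, and the Pearson correlation of the share profiles.

The package is aimed at researchers benchmarking string-matching algorithms
and at practitioners who must pick a matcher for a fixed corpus
(read-mapping preprocessing, text indexing, log scanning).

## Worked example

```r
library(entropymatch)

# a synthetic uniform-DNA corpus and 300 representative patterns
corpus   <- generate_synthetic_corpus(c("A","C","G","T"), rep(0.25, 4),
                                      50000, seed = 7, id = "dna-sim")
patterns <- sample_patterns(corpus, count = 300, seed = 7)
model    <- build_model(corpus, patterns, domain = "dna")
model
#> <ranking_model> domain 'dna': 7 entropy classes, 300 patterns
#>   class 1 (<0.28571, n = 6): best BM
#>   class 2 (0.28571–0.57143, n = 0): best —
#>   class 3 (0.57143–0.85714, n = 16): best BM
#>   class 4 (0.85714–1.14286, n = 17): best BM
#>   class 5 (1.14286–1.42857, n = 17): best BM
#>   class 6 (1.42857–1.71429, n = 72): best BM
#>   class 7 (≥1.71429, n = 172): best BM

# which matcher should search this 16-mer? (entropy 1.9363 -> class 7)
predict(model, "GCATACCTTTCGCAGC")
#> [1] "BM"  "QS"  "HOR" "AC"  "KMP" "MP"  "BF"
#> attr(,"class_index")
#> [1] 7

# validate against held-out patterns, classed on the model's scheme
held_out <- sample_patterns(corpus, count = 150, seed = 8)
records  <- run_campaign(corpus, held_out, scheme = model$scheme)
validate_model(model, records)
#> <validation_report>
#>  class v       d2 similarity pearson_r
#>      1 9 0.000000     1.0000    1.0000
#>      3 9 0.083333     0.9167    0.9481
#>      4 8 0.003676     0.9963    1.0000
#>      5 9 0.140056     0.8599    0.9256
#>      6 9 0.073218     0.9268    0.9633
#>      7 9 0.009866     0.9901    0.9993
```

Reading: on uniform synthetic DNA, Boyer-Moore most often performs the
fewest character comparisons in every populated entropy class (for the
high-entropy class 7 it leads the quartile-1 shares, with QS and HOR
close behind), and the model's quartile-share profiles agree with the
held-out campaign at similarities between 0.86 and 1.00 with strongly
positive correlations. Class 2 attracted no patterns; predictions falling
there are served by the nearest populated class.

Real corpora enter through `read_fasta()` (strict \{A,C,G,T\} filtering of
ambiguity codes) and `read_plain_text()` (every byte significant, newlines
mapped to spaces). A thin command-line front end with `build-model`,
`predict` and `validate` subcommands lives at `inst/cli/entropymatch.R`.

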