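# Model validation: double-scaled Euclidean distance, similarity,
# Pearson correlation and distribution summaries.

#' Scaled squared discrepancy for one variable
#'
#' The summand of the double-scaled Euclidean distance:
#' (p1 - p2)^2 / md, where md is the maximum possible squared discrepancy
#' for the variable. For quartile shares bounded by 0 (0%) and 1 (100%),
#' md = (1 - 0)^2 = 1. Vectorized over all three arguments.
#'
#' @param p1 model share(s), fractions in \[0, 1\].
#' @param p2 validation share(s), fractions in \[0, 1\].
#' @param md maximum possible squared discrepancy, > 0 (default 1).
#' @return non-negative scaled squared discrepancies.
#' @examples
#' scaled_discrepancy(0.58263, 0.96667)  # 0.14749 (to 5 decimals)
#' @export
scaled_discrepancy <- function(p1, p2, md = 1) {
  stopifnot(is.numeric(p1), is.numeric(p2), is.numeric(md))
  if (any(md <= 0)) stop("`md` must be positive", call. = FALSE)
  (p1 - p2)^2 / md
}

#' Double-scaled Euclidean distance and similarity
#'
#' Computes d2 = sqrt(sum_i (p1_i - p2_i)^2 / md_i) / sqrt(v) over v
#' paired variables, and the similarity coefficient 1 - d2. Whenever
#' every squared difference is bounded by its md_i (always true for
#' shares with md = 1), d2 lies in \[0, 1\]: 0 for identical profiles and
#' 1 for maximal discrepancy on every variable.
#'
#' @param p1 numeric vector of model shares.
#' @param p2 numeric vector of validation shares, same length.
#' @param md per-variable maximum squared discrepancies (recycled;
#'   default 1).
#' @return a list with `d2`, `similarity` (= 1 - d2) and `v`.
#' @examples
#' double_scaled_euclidean(c(0, 0), c(1, 1))  # d2 = 1, similarity = 0
#' @export
double_scaled_euclidean <- function(p1, p2, md = 1) {
  stopifnot(is.numeric(p1), is.numeric(p2))
  if (length(p1) != length(p2)) {
    stop("`p1` and `p2` must have the same length", call. = FALSE)
  }
  v <- length(p1)
  if (v < 1L) stop("at least one variable is required", call. = FALSE)
  d1 <- sum(scaled_discrepancy(p1, p2, md))
  d2 <- sqrt(d1) / sqrt(v)
  list(d2 = d2, similarity = 1 - d2, v = v)
}

#' Pearson product-moment correlation
#'
#' Standard Pearson correlation between two equal-length sequences. When
#' either sequence is constant the coefficient is undefined and `NA` is
#' returned.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return correlation in \[-1, 1\], or `NA` when undefined.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y) || length(x) < 2L) {
    stop("`x` and `y` must have equal length >= 2", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Summarize an entropy distribution
#'
#' Sample mean, sample standard deviation (n - 1 denominator) and
#' equal-width histogram counts; used to check that a validation pattern
#' set has a distribution comparable to the model-building set.
#'
#' @param entropies numeric vector (non-empty).
#' @param bins number of equal-width histogram bins (default 10).
#' @return a list with `mean`, `sd` and `counts` (length `bins`).
#' @export
distribution_summary <- function(entropies, bins = 10L) {
  stopifnot(is.numeric(entropies), length(entropies) >= 1L, bins >= 1L)
  rng <- range(entropies)
  if (rng[1L] == rng[2L]) {
    counts <- c(length(entropies), rep(0L, bins - 1L))
  } else {
    breaks <- seq(rng[1L], rng[2L], length.out = bins + 1L)
    counts <- as.integer(
      table(cut(entropies, breaks = breaks, include.lowest = TRUE))
    )
  }
  list(mean = mean(entropies),
       sd = if (length(entropies) > 1L) stats::sd(entropies) else 0,
       counts = counts)
}

# Align model and validation shares of one class into paired vectors.
# Variables are the (algorithm x quartile) cells, ordered alphabetically
# by algorithm and q1..q4 within algorithm; cells that are zero in both
# profiles are dropped.
.align_class_shares <- function(model_shares, test_shares, class_index) {
  m <- model_shares[model_shares$class == class_index, , drop = FALSE]
  t <- test_shares[test_shares$class == class_index, , drop = FALSE]
  algos <- sort(union(m$Algo, t$Algo))
  pick <- function(df, a, q) {
    row <- df[df$Algo == a, , drop = FALSE]
    if (nrow(row) == 0L) 0 else row[[paste0("q", q)]][1L]
  }
  p1 <- p2 <- numeric(0)
  for (a in algos) {
    for (q in 1:4) {
      p1 <- c(p1, pick(m, a, q))
      p2 <- c(p2, pick(t, a, q))
    }
  }
  keep <- p1 != 0 | p2 != 0
  list(p1 = p1[keep], p2 = p2[keep])
}

#' Validate a ranking model against held-out campaign results
#'
#' Compares the model's per-class quartile shares with shares computed
#' from held-out test records (test patterns must be classed on the
#' model's scheme, i.e. the test campaign should be run with
#' `scheme = model$scheme`). The variables compared within a class are
#' the (algorithm x quartile) share cells with a nonzero entry in either
#' profile; for each selected class the report carries the double-scaled
#' Euclidean distance, the similarity coefficient and the Pearson
#' correlation between the two profiles.
#'
#' @param model a `ranking_model`.
#' @param test_records campaign records from [run_campaign()] on the
#'   held-out text/patterns, or a precomputed share data frame from
#'   [aggregate_shares()].
#' @param classes class indices to validate (default: every class with
#'   test patterns).
#' @param md maximum squared discrepancy per variable (default 1, shares
#'   bounded by 0 and 1).
#' @return an object of class `validation_report`: a data frame with one
#'   row per class and columns `class`, `v`, `d2`, `similarity`,
#'   `pearson_r`.
#' @export
validate_model <- function(model, test_records, classes = NULL, md = 1) {
  stopifnot(inherits(model, "ranking_model"))
  if (is.data.frame(test_records) && all(c("q1", "q2", "q3", "q4") %in%
                                         names(test_records))) {
    test_shares <- test_records
  } else {
    test_shares <- aggregate_shares(test_records, model$scheme)
  }
  if (is.null(classes)) {
    n_test <- attr(test_shares, "n_patterns")
    classes <- if (!is.null(n_test)) which(n_test > 0) else
      sort(unique(test_shares$class))
  }
  rows <- lapply(classes, function(k) {
    al <- .align_class_shares(model$shares, test_shares, k)
    if (length(al$p1) == 0L) {
      return(data.frame(class = k, v = 0L, d2 = NA_real_,
                        similarity = NA_real_, pearson_r = NA_real_))
    }
    ds <- double_scaled_euclidean(al$p1, al$p2, md)
    r <- if (length(al$p1) >= 2L) pearson_correlation(al$p1, al$p2)
         else NA_real_
    data.frame(class = k, v = ds$v, d2 = ds$d2,
               similarity = ds$similarity, pearson_r = r)
  })
  report <- do.call(rbind, rows)
  class(report) <- c("validation_report", "data.frame")
  report
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
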