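# Pattern entropy, sample-size calculation and frequency-distribution
# discretization into entropy classes.

#' Shannon entropy of a pattern's character distribution
#'
#' Computes the base-2 Shannon entropy H = -sum(p_i * log2(p_i)) over the
#' relative frequencies of the characters of `pattern`. Every character is
#' significant: spaces, punctuation and case are distinct symbols. Zero-
#' probability terms contribute 0; a pattern made of a single repeated
#' character has entropy 0, and a pattern with k equally frequent distinct
#' characters has entropy log2(k).
#'
#' @param pattern a single non-empty character string.
#' @return entropy in bits (non-negative numeric scalar).
#' @examples
#' shannon_entropy("TCGTAACT")  # 1.90563906222957
#' shannon_entropy("CAAG")      # 1.5
#' @export
shannon_entropy <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || is.na(pattern)) {
    stop("`pattern` must be a single character string", call. = FALSE)
  }
  if (!nzchar(pattern)) stop("`pattern` must be non-empty", call. = FALSE)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  p <- tabulate(factor(chars)) / length(chars)
  -sum(p * log2(p))
}

#' Round an entropy value to two decimals
#'
#' Rounds half away from zero (so 1.905... becomes 1.91 and 0.337...
#' becomes 0.34), matching the convention used for the `PattEntRound`
#' variable throughout the model. Vectorized.
#'
#' @param h entropy value(s) in bits, >= 0.
#' @return value(s) with two decimal places.
#' @export
round_entropy <- function(h) {
  stopifnot(is.numeric(h), all(h >= 0, na.rm = TRUE))
  sign(h) * floor(abs(h) * 100 + 0.5) / 100
}

#' Representative-pattern sample size for a finite population
#'
#' Applies the finite-population correction to the infinite-population
#' sample size n0 = z^2 p (1 - p) / eps^2 and returns
#' ceiling(n0 / (1 + n0 / N)). Fractional respondents are rounded up.
#' With z = 1.96, eps = 0.01, p = 0.5: N = 7682 gives 4269 and N = 2043
#' gives 1685.
#'
#' @param population_size N, a positive integer count of candidate
#'   patterns.
#' @param z_score z, the standard-normal quantile for the confidence level
#'   (default 1.96).
#' @param margin eps, the margin of error as a fraction in (0, 1)
#'   (default 0.01).
#' @param proportion p, the anticipated population proportion in (0, 1)
#'   (default 0.5, the conservative maximum-variance choice).
#' @return required sample size (positive integer).
#' @export
sample_size <- function(population_size, z_score = 1.96, margin = 0.01,
                        proportion = 0.5) {
  if (!is.numeric(population_size) || length(population_size) != 1L ||
      population_size < 1) {
    stop("`population_size` must be a positive number", call. = FALSE)
  }
  stopifnot(z_score > 0, margin > 0, margin < 1,
            proportion > 0, proportion < 1)
  n0 <- z_score^2 * proportion * (1 - proportion) / margin^2
  as.integer(ceiling(n0 / (1 + n0 / population_size)))
}

#' Number of discretization classes
#'
#' The cube-root rule C = round(2 * n^(1/3)), rounded half away from zero
#' with a minimum of one class, where n is the number of observations
#' (here: the count of distinct rounded entropy values). n = 91 and
#' n = 105 both give 9 classes.
#'
#' @param n_observations positive integer.
#' @return positive integer class count.
#' @export
num_classes <- function(n_observations) {
  stopifnot(is.numeric(n_observations), length(n_observations) == 1L,
            n_observations >= 1)
  max(1L, as.integer(floor(2 * n_observations^(1 / 3) + 0.5)))
}

.fmt_bound <- function(x) formatC(x, digits = 5, format = "f")

#' Build an entropy class scheme by frequency-distribution discretization
#'
#' Divides the range of the observed distinct rounded entropies into C
#' equal-width classes, where C comes from [num_classes()] applied to the
#' number of distinct values and the width is h = (max - min) / C.
#' Boundaries are b_k = min + k * h for k = 1 .. C-1. Labels follow the
#' frequency-table convention: the first class is "<b1", interior classes
#' "b_{k-1}–b_k", and the last class "≥b_{C-1}". If all values
#' coincide the scheme degenerates to a single class of width 0.
#'
#' @param values numeric vector of rounded entropies (>= 0); duplicates
#'   are dropped.
#' @return an object of class `class_scheme`: a list with `class_count`,
#'   `width`, `minimum`, `maximum`, `boundaries` and `labels`.
#' @examples
#' sch <- build_class_scheme(c(0, 0.5, 1, 1.5, 2))
#' sch$labels
#' @export
build_class_scheme <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 1L)
  values <- unique(values[!is.na(values)])
  if (length(values) == 0L) stop("no non-missing values", call. = FALSE)
  if (any(values < 0)) stop("entropy values must be >= 0", call. = FALSE)
  mn <- min(values)
  mx <- max(values)
  if (mx == mn) {
    return(structure(
      list(class_count = 1L, width = 0, minimum = mn, maximum = mx,
           boundaries = numeric(0), labels = .fmt_bound(mn)),
      class = "class_scheme"
    ))
  }
  C <- num_classes(length(values))
  h <- (mx - mn) / C
  b <- mn + seq_len(C - 1L) * h
  labels <- character(C)
  labels[1L] <- paste0("<", .fmt_bound(b[1L]))
  if (C > 2L) {
    for (k in 2:(C - 1L)) {
      labels[k] <- paste0(.fmt_bound(b[k - 1L]), "–", .fmt_bound(b[k]))
    }
  }
  labels[C] <- paste0("≥", .fmt_bound(b[C - 1L]))
  structure(
    list(class_count = C, width = h, minimum = mn, maximum = mx,
         boundaries = b, labels = labels),
    class = "class_scheme"
  )
}

#' @export
print.class_scheme <- function(x, ...) {
  cat(sprintf("<class_scheme> %d class(es), width %.5f, range [%.5f, %.5f]\n",
              x$class_count, x$width, x$minimum, x$maximum))
  for (k in seq_len(x$class_count)) cat(sprintf("  %d: %s\n", k, x$labels[k]))
  invisible(x)
}

#' Map rounded entropies to entropy classes
#'
#' A value v belongs to class k when b_{k-1} <= v < b_k (with the first
#' class open below and the last class closed above at its "≥" label).
#' A value outside the scheme's range is assigned to the nearest class:
#' below the minimum it falls in class 1, at or above the last boundary in
#' class C. Vectorized.
#'
#' @param rounded_entropy numeric vector of (rounded) entropy values.
#' @param scheme a `class_scheme` from [build_class_scheme()].
#' @return integer class indices in 1 .. class_count.
#' @export
assign_class <- function(rounded_entropy, scheme) {
  stopifnot(inherits(scheme, "class_scheme"), is.numeric(rounded_entropy))
  if (scheme$class_count == 1L) {
    return(rep(1L, length(rounded_entropy)))
  }
  findInterval(rounded_entropy, scheme$boundaries) + 1L
}
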