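# Instrumented exact string matchers and the matcher registry.

# registry maps algorithm id -> function(text, pattern) returning
# list(occurrences = integer 0-based, comparisons = numeric)
.matcher_registry <- new.env(parent = emptyenv())

.builtin_ids <- c("BF", "MP", "KMP", "AC", "QS", "BM", "HOR")

.init_registry <- function() {
  for (id in .builtin_ids) {
    local({
      algo <- id
      assign(algo, function(text, pattern) .cc_match(algo, text, pattern),
             envir = .matcher_registry)
    })
  }
}

.onLoad <- function(libname, pkgname) {
  .init_registry()
}

#' Identifiers of the available matchers
#'
#' The seven built-in classical matchers are brute force (`BF`),
#' Morris-Pratt (`MP`), Knuth-Morris-Pratt (`KMP`), Apostolico-Crochemore
#' (`AC`), Quick Search (`QS`), Boyer-Moore (`BM`) and Horspool (`HOR`).
#' Further matchers added through [register_matcher()] are listed after the
#' built-ins.
#'
#' @param builtin_only if `TRUE` (default) return only the seven built-in
#'   identifiers, in their canonical order.
#' @return character vector of algorithm identifiers.
#' @export
matcher_ids <- function(builtin_only = TRUE) {
  if (builtin_only) return(.builtin_ids)
  extra <- setdiff(ls(.matcher_registry), .builtin_ids)
  c(.builtin_ids, sort(extra))
}

#' Register an additional instrumented matcher
#'
#' Plug-in point for extending the closed set of built-in matchers. The
#' supplied function must accept `(text, pattern)` and return a list with
#' components `occurrences` (0-based integer offsets, strictly increasing)
#' and `comparisons` (a single non-negative number counting pattern-vs-text
#' character equality tests). Registered matchers participate in campaigns
#' when named in the `algorithms` argument of [run_campaign()].
#'
#' @param id a new algorithm identifier (non-empty string, not one of the
#'   built-in ids).
#' @param fun the matcher function.
#' @return `id`, invisibly.
#' @export
register_matcher <- function(id, fun) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id), is.function(fun))
  if (id %in% .builtin_ids) {
    stop("cannot replace built-in matcher '", id, "'", call. = FALSE)
  }
  assign(id, fun, envir = .matcher_registry)
  invisible(id)
}

.check_text_pattern <- function(text, pattern) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("`text` must be a single character string", call. = FALSE)
  }
  if (!is.character(pattern) || length(pattern) != 1L || is.na(pattern)) {
    stop("`pattern` must be a single character string", call. = FALSE)
  }
  if (!nzchar(pattern)) {
    stop("`pattern` must have length >= 1", call. = FALSE)
  }
  invisible(TRUE)
}

#' Search a text with one instrumented matcher
#'
#' Runs a single exact string-matching algorithm over `text` and reports
#' every (possibly overlapping) occurrence of `pattern` together with the
#' CC metric: the number of pattern-character vs text-character equality
#' tests executed during the scan phase. Preprocessing work (failure
#' functions, shift tables) compares pattern characters with pattern
#' characters and is not counted. Matching is case-sensitive and bytewise;
#' if the pattern is longer than the text no scan is performed, so the
#' occurrence set is empty and the comparison count is 0.
#'
#' @param algorithm an algorithm identifier (see [matcher_ids()]).
#' @param text a single character string (may be empty).
#' @param pattern a single non-empty character string.
#' @return an object of class `search_outcome`: a list with `algorithm`,
#'   `n` (text length), `m` (pattern length), `occurrences` (0-based
#'   strictly increasing integer offsets) and `comparisons`.
#' @examples
#' match_pattern("BF", "ABCABC", "ABC")
#' match_pattern("BM", "GCATCGCAGAGAGTATACAGTACG", "GCAGAGAG")
#' @export
match_pattern <- function(algorithm, text, pattern) {
  stopifnot(is.character(algorithm), length(algorithm) == 1L)
  .check_text_pattern(text, pattern)
  fun <- get0(algorithm, envir = .matcher_registry, inherits = FALSE)
  if (is.null(fun)) {
    stop("unknown algorithm id: '", algorithm, "'; see matcher_ids()",
         call. = FALSE)
  }
  res <- fun(text, pattern)
  structure(
    list(algorithm = algorithm,
         n = nchar(text),
         m = nchar(pattern),
         occurrences = as.integer(res$occurrences),
         comparisons = as.numeric(res$comparisons)),
    class = "search_outcome"
  )
}

#' @export
print.search_outcome <- function(x, ...) {
  cat(sprintf("<search_outcome> %s: n = %d, m = %d, %d occurrence(s), %s comparisons\n",
              x$algorithm, x$n, x$m, length(x$occurrences),
              format(x$comparisons, big.mark = ",")))
  invisible(x)
}

#' Reference occurrence oracle
#'
#' Exhaustively checks every window of the text against the pattern using
#' plain substring extraction, independently of the instrumented matchers.
#' Intended for cross-validating matcher output in tests; it reports
#' occurrences only, not comparison counts.
#'
#' @inheritParams match_pattern
#' @return integer vector of 0-based match offsets.
#' @examples
#' naive_oracle("AABAACAADAABAABA", "AABA")
#' @export
naive_oracle <- function(text, pattern) {
  .check_text_pattern(text, pattern)
  n <- nchar(text)
  m <- nchar(pattern)
  if (m > n) return(integer(0))
  starts <- seq_len(n - m + 1L)
  hits <- substring(text, starts, starts + m - 1L) == pattern
  as.integer(starts[hits] - 1L)
}
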