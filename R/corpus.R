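# Corpus input/output: FASTA and plain-text readers, pattern sampling,
# synthetic corpus generation and campaign-result tables.

new_corpus <- function(id, text, alphabet, format) {
  structure(
    list(id = id, text = text, alphabet = alphabet, format = format),
    class = "corpus"
  )
}

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf("<corpus> %s (%s): %s characters, alphabet size %d\n",
              x$id, x$format, format(nchar(x$text), big.mark = ","),
              length(x$alphabet)))
  invisible(x)
}

#' Read a FASTA file into a corpus
#'
#' Header lines are dropped and all sequence records are concatenated in
#' file order into one searchable text; characters are uppercased. In
#' strict mode every character outside the DNA alphabet \{A, C, G, T\}
#' (ambiguity codes such as N) is removed and the number removed is
#' recorded in the `n_filtered` attribute — genomes routinely contain such
#' codes but the model's DNA alphabet is strictly 4-letter.
#'
#' @param path path to a FASTA file with at least one record.
#' @param strict drop non-ACGT characters (default `TRUE`).
#' @param id corpus identifier (defaults to the file name).
#' @return a `corpus` object; `attr(, "n_filtered")` gives the number of
#'   characters removed in strict mode.
#' @export
read_fasta <- function(path, strict = TRUE, id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  seqs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("not a readable FASTA file: ", path,
                             call. = FALSE)
  )
  if (length(seqs) == 0L) stop("FASTA file has no records: ", path,
                               call. = FALSE)
  text <- toupper(paste(as.character(seqs), collapse = ""))
  n_filtered <- 0L
  if (strict) {
    kept <- gsub("[^ACGT]", "", text)
    n_filtered <- nchar(text) - nchar(kept)
    if (n_filtered > 0L) {
      message(n_filtered, " non-ACGT character(s) removed from ", id)
    }
    text <- kept
  }
  if (!nzchar(text)) stop("FASTA file has an empty sequence: ", path,
                          call. = FALSE)
  out <- new_corpus(id, text,
                    alphabet = sort(unique(strsplit(text, "")[[1]])),
                    format = "fasta")
  attr(out, "n_filtered") <- n_filtered
  out
}

#' Read a plain-text file into a corpus
#'
#' The raw character stream is preserved: case, spaces and punctuation all
#' count as distinct symbols. Line endings (LF or CRLF) are normalized and
#' each newline is replaced by `newline` — a single space by default, so
#' that sampled patterns can span line breaks.
#'
#' @param path path to a non-empty text file.
#' @param newline replacement for line breaks (default `" "`).
#' @param id corpus identifier (defaults to the file name).
#' @return a `corpus` object.
#' @export
read_plain_text <- function(path, newline = " ", id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  text <- paste(lines, collapse = newline)
  if (!nzchar(text)) stop("empty text file: ", path, call. = FALSE)
  new_corpus(id, text,
             alphabet = sort(unique(strsplit(text, "")[[1]])),
             format = "txt")
}

#' Sample representative patterns from a corpus
#'
#' Draws substrings of the corpus text at uniformly random offsets. The
#' requested lengths are cycled so each length receives an (almost) equal
#' share of the patterns; draws are de-duplicated per length. When a
#' length's supply of distinct substrings runs out (e.g. only 16 distinct
#' dinucleotides exist in a DNA text) its deficit is reallocated to the
#' remaining lengths, so the length histogram is uniform up to rounding
#' whenever the text is diverse enough. Sampling fails with an error
#' stating the achieved count if `count` distinct patterns cannot be
#' collected at all.
#'
#' @param corpus a `corpus` object.
#' @param lengths integer vector of pattern lengths, each <= the corpus
#'   text length (default `c(2, 4, 8, 16, 32)`).
#' @param count number of distinct patterns required.
#' @param seed integer seed; the same seed reproduces the same pattern set.
#' @param max_attempts consecutive failed draw rounds tolerated per length
#'   before it is considered exhausted (default 100).
#' @return an object of class `pattern_set`: list with `patterns`,
#'   `lengths`, `seed` and `corpus_id`.
#' @export
sample_patterns <- function(corpus, lengths = c(2L, 4L, 8L, 16L, 32L),
                            count, seed, max_attempts = 100L) {
  stopifnot(inherits(corpus, "corpus"), count >= 1L, length(lengths) >= 1L)
  n <- nchar(corpus$text)
  lengths <- as.integer(sort(unique(lengths)))
  if (any(lengths < 1L) || any(lengths > n)) {
    stop("every pattern length must be in [1, corpus length]", call. = FALSE)
  }
  count <- as.integer(count)
  k <- length(lengths)

  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))

  # cycle allocation: lengths take turns, so targets differ by at most 1
  target <- tabulate(((seq_len(count) - 1L) %% k) + 1L, k)
  pools <- replicate(k, character(0), simplify = FALSE)
  exhausted <- logical(k)

  fill <- function(i, want) {
    l <- lengths[i]
    fails <- 0L
    while (length(pools[[i]]) < want && fails < max_attempts) {
      need <- want - length(pools[[i]])
      start <- sample.int(n - l + 1L, need, replace = TRUE)
      cand <- unique(substring(corpus$text, start, start + l - 1L))
      new <- setdiff(cand, pools[[i]])
      if (length(new) == 0L) {
        fails <- fails + 1L
      } else {
        fails <- 0L
        pools[[i]] <<- c(pools[[i]], new)
      }
    }
    if (length(pools[[i]]) < want) exhausted[i] <<- TRUE
  }

  for (i in seq_len(k)) fill(i, target[i])
  # reallocate deficits round-robin over the lengths still supplying
  while (sum(vapply(pools, length, integer(1))) < count &&
         any(!exhausted)) {
    for (i in which(!exhausted)) {
      if (sum(vapply(pools, length, integer(1))) >= count) break
      fill(i, length(pools[[i]]) + 1L)
    }
  }
  achieved <- sum(vapply(pools, length, integer(1)))
  if (achieved < count) {
    stop("could not sample ", count, " distinct patterns (achieved ",
         achieved, ")", call. = FALSE)
  }

  # assemble round-robin across lengths so truncation stays balanced
  sizes <- vapply(pools, length, integer(1))
  round_no <- unlist(lapply(sizes, seq_len), use.names = FALSE)
  length_no <- rep(seq_len(k), sizes)
  ord <- order(round_no, length_no)
  patterns <- unlist(pools, use.names = FALSE)[ord][seq_len(count)]
  structure(
    list(patterns = patterns, lengths = lengths,
         seed = as.integer(seed), corpus_id = corpus$id),
    class = "pattern_set"
  )
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("<pattern_set> %d patterns from %s (lengths %s, seed %d)\n",
              length(x$patterns), x$corpus_id,
              paste(x$lengths, collapse = ","), x$seed))
  invisible(x)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a synthetic i.i.d. corpus
#'
#' Draws `length` characters independently from `alphabet` with the given
#' symbol probabilities. With the uniform 4-symbol distribution over
#' \{A, C, G, T\} this emulates an i.i.d. DNA text; a skewed multi-symbol
#' distribution emulates English-like text. Generation is deterministic
#' under a fixed seed.
#'
#' @param alphabet character vector of single-character symbols.
#' @param frequencies probability vector of the same length, summing to 1.
#' @param length number of characters to draw.
#' @param seed integer seed.
#' @param id corpus identifier.
#' @return a `corpus` object with format tag `"synthetic"`.
#' @examples
#' generate_synthetic_corpus(c("A", "C", "G", "T"), rep(0.25, 4), 50, seed = 1)
#' @export
generate_synthetic_corpus <- function(alphabet, frequencies, length, seed,
                                      id = "synthetic") {
  stopifnot(is.character(alphabet), length(alphabet) >= 1L,
            all(nchar(alphabet) == 1L), length >= 1L)
  if (length(frequencies) != length(alphabet)) {
    stop("`frequencies` must match `alphabet` in length", call. = FALSE)
  }
  if (abs(sum(frequencies) - 1) > 1e-9 || any(frequencies < 0)) {
    stop("`frequencies` must be non-negative and sum to 1", call. = FALSE)
  }
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  chars <- sample(alphabet, size = length, replace = TRUE,
                  prob = frequencies)
  new_corpus(id, paste(chars, collapse = ""), alphabet = sort(alphabet),
             format = "synthetic")
}

#' Write campaign records to CSV
#'
#' The table uses the campaign's canonical column names:
#' `pattern,m,Algo,comp,PattEnt,PattEntRound,PattEntClass`, with `PattEnt`
#' at full precision and `PattEntRound` at two decimals. Reading the file
#' back with [read_results()] reproduces the records.
#'
#' @param records a campaign record data frame from [run_campaign()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  cols <- c("pattern", "m", "Algo", "comp", "PattEnt", "PattEntRound",
            "PattEntClass")
  missing <- setdiff(cols, names(records))
  if (length(missing)) {
    stop("records lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- records[cols]
  out$PattEnt <- format(out$PattEnt, digits = 15, trim = TRUE,
                        scientific = FALSE)
  out$PattEntRound <- formatC(out$PattEntRound, digits = 2, format = "f")
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read campaign records from CSV
#'
#' @param path a file written by [write_results()].
#' @return a campaign record data frame.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(pattern = "character"))
  rec$m <- as.integer(rec$m)
  rec$comp <- as.numeric(rec$comp)
  rec$PattEnt <- as.numeric(rec$PattEnt)
  rec$PattEntRound <- as.numeric(rec$PattEntRound)
  rec$PattEntClass <- as.integer(rec$PattEntClass)
  rec
}
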