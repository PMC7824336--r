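# Campaign execution, quartile assignment, quartile-share aggregation,
# per-class algorithm ranking and model prediction.

.as_text <- function(x) {
  if (inherits(x, "corpus")) x$text else x
}

.as_patterns <- function(x) {
  if (inherits(x, "pattern_set")) x$patterns else x
}

#' Run a search campaign
#'
#' Searches every pattern with every selected algorithm on one text and
#' collects one record per (pattern, algorithm) pair: the pattern, its
#' length `m`, the algorithm id `Algo`, the comparison count `comp`, the
#' pattern entropy `PattEnt`, its two-decimal rounding `PattEntRound` and
#' the entropy class `PattEntClass`. When no class scheme is supplied, one
#' is built from the distinct rounded entropies of the campaign's own
#' patterns; when validating against an existing model, pass the model's
#' scheme so that test patterns are classed on the model's grid.
#'
#' A pattern longer than the text yields a record with zero occurrences
#' and `comp = 0`.
#'
#' @param text a `corpus` object or a single character string.
#' @param patterns a `pattern_set` or character vector of non-empty
#'   patterns.
#' @param algorithms character vector of algorithm ids (default: the seven
#'   built-ins).
#' @param scheme optional `class_scheme`; built from the campaign's own
#'   rounded entropies when `NULL`.
#' @return a data frame of campaign records with the class scheme attached
#'   as attribute `"scheme"`.
#' @export
run_campaign <- function(text, patterns, algorithms = matcher_ids(),
                         scheme = NULL) {
  text <- .as_text(text)
  patterns <- .as_patterns(patterns)
  stopifnot(is.character(text), length(text) == 1L,
            is.character(patterns), length(patterns) >= 1L,
            is.character(algorithms), length(algorithms) >= 1L)
  if (any(!nzchar(patterns))) {
    stop("patterns must be non-empty strings", call. = FALSE)
  }

  ent <- vapply(patterns, shannon_entropy, numeric(1), USE.NAMES = FALSE)
  ent_round <- round_entropy(ent)
  if (is.null(scheme)) scheme <- build_class_scheme(unique(ent_round))
  cls <- assign_class(ent_round, scheme)

  n_pat <- length(patterns)
  n_alg <- length(algorithms)
  comp <- numeric(n_pat * n_alg)
  for (ip in seq_len(n_pat)) {
    for (ia in seq_len(n_alg)) {
      out <- match_pattern(algorithms[ia], text, patterns[ip])
      comp[(ip - 1L) * n_alg + ia] <- out$comparisons
    }
  }

  records <- data.frame(
    pattern = rep(patterns, each = n_alg),
    m = rep(nchar(patterns), each = n_alg),
    Algo = rep(algorithms, times = n_pat),
    comp = comp,
    PattEnt = rep(ent, each = n_alg),
    PattEntRound = rep(ent_round, each = n_alg),
    PattEntClass = rep(cls, each = n_alg),
    stringsAsFactors = FALSE
  )
  attr(records, "scheme") <- scheme
  records
}

.quartile_indices <- function(cc) {
  q <- stats::quantile(cc, probs = c(0.25, 0.5, 0.75), type = 6,
                       names = FALSE)
  1L + (cc > q[1L]) + (cc > q[2L]) + (cc > q[3L])
}

#' Assign quartiles to algorithms by comparison count
#'
#' For one pattern, the CC counts of the competing algorithms are reduced
#' to quartile ranks. The thresholds Q1, Q2 and Q3 are the 25th, 50th and
#' 75th percentiles of the CC values under the inclusive-median (Weibull)
#' convention; an algorithm falls in quartile 1 when cc <= Q1, quartile 2
#' when cc <= Q2, quartile 3 when cc <= Q3 and quartile 4 otherwise. Ties
#' share the lower quartile, so several algorithms can occupy quartile 1
#' at once; if all counts are equal every algorithm is in quartile 1.
#'
#' @param cc_by_algorithm named numeric vector of CC counts, one per
#'   algorithm.
#' @return named integer vector of quartiles in 1..4.
#' @examples
#' assign_quartiles(c(BF = 70, BM = 10, QS = 20, HOR = 30,
#'                    KMP = 50, MP = 60, AC = 40))
#' @export
assign_quartiles <- function(cc_by_algorithm) {
  stopifnot(is.numeric(cc_by_algorithm), length(cc_by_algorithm) >= 1L)
  q <- .quartile_indices(cc_by_algorithm)
  names(q) <- names(cc_by_algorithm)
  q
}

#' Aggregate per-class quartile shares
#'
#' For every (entropy class, algorithm) pair, computes the fraction of the
#' class's patterns for which that algorithm's CC count fell in each
#' quartile. Shares of a non-empty class sum to 1 per algorithm; classes
#' with no patterns are retained with all-zero shares.
#'
#' @param records campaign records from [run_campaign()].
#' @param scheme the `class_scheme` used to class the records; taken from
#'   `attr(records, "scheme")` when missing.
#' @return a data frame with columns `class`, `Algo`, `q1` .. `q4`, one
#'   row per (class, algorithm); the per-class pattern counts are attached
#'   as attribute `"n_patterns"`.
#' @export
aggregate_shares <- function(records, scheme = attr(records, "scheme")) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  C <- if (!is.null(scheme)) scheme$class_count else max(records$PattEntClass)
  algos <- sort(unique(records$Algo))

  pf <- factor(records$pattern, levels = unique(records$pattern))
  quart <- unsplit(lapply(split(records$comp, pf), .quartile_indices), pf)

  # one class per pattern
  cls_by_pattern <- tapply(records$PattEntClass, pf, function(x) x[1L])
  n_patterns <- tabulate(factor(cls_by_pattern, levels = seq_len(C)), C)

  tab <- table(class = factor(records$PattEntClass, levels = seq_len(C)),
               Algo = factor(records$Algo, levels = algos),
               quartile = factor(quart, levels = 1:4))

  grid <- expand.grid(Algo = algos, class = seq_len(C),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  shares <- data.frame(class = grid$class, Algo = grid$Algo,
                       stringsAsFactors = FALSE)
  for (k in 1:4) {
    cnt <- tab[cbind(as.character(shares$class), shares$Algo,
                     as.character(k))]
    denom <- n_patterns[shares$class]
    shares[[paste0("q", k)]] <- ifelse(denom > 0, cnt / denom, 0)
  }
  attr(shares, "n_patterns") <- n_patterns
  shares
}

#' Rank algorithms within one entropy class
#'
#' Algorithms are ordered by descending share of quartile-1 finishes; ties
#' are broken by descending quartile-2 share, then descending quartile-3
#' share, then ascending quartile-4 share, and finally alphabetically by
#' algorithm id. The first element is the selected (most efficient)
#' algorithm for the class. An empty class yields an empty ranking.
#'
#' @param shares a quartile-share data frame from [aggregate_shares()].
#' @param class_index entropy class index.
#' @param n_patterns optional per-class pattern counts (taken from
#'   `attr(shares, "n_patterns")` when available) used to detect empty
#'   classes.
#' @return character vector of algorithm ids, best first.
#' @export
rank_algorithms <- function(shares, class_index,
                            n_patterns = attr(shares, "n_patterns")) {
  stopifnot(is.data.frame(shares))
  sub <- shares[shares$class == class_index, , drop = FALSE]
  if (nrow(sub) == 0L) stop("class ", class_index, " not present in shares",
                            call. = FALSE)
  if (!is.null(n_patterns) && n_patterns[class_index] == 0L) {
    return(character(0))
  }
  ord <- order(-sub$q1, -sub$q2, -sub$q3, sub$q4, sub$Algo)
  sub$Algo[ord]
}

#' Build an entropy-class ranking model
#'
#' Runs the full pipeline on one domain text: campaign over all patterns
#' and algorithms, entropy discretization of the campaign's rounded
#' pattern entropies, quartile-share aggregation per entropy class and
#' per-class algorithm ranking.
#'
#' @param text a `corpus` or single character string (the domain text).
#' @param patterns a `pattern_set` or character vector of representative
#'   patterns.
#' @param algorithms algorithm ids to rank (default: the seven built-ins).
#' @param domain a label for the modeled domain (e.g. `"dna"`).
#' @param seed the pattern-sampling seed, stored for provenance (taken
#'   from the `pattern_set` when available).
#' @return an object of class `ranking_model`: list with `domain`,
#'   `scheme`, `shares`, `rankings` (one character vector per class),
#'   `class_counts` and `provenance`.
#' @export
build_model <- function(text, patterns, algorithms = matcher_ids(),
                        domain = "domain", seed = NA_integer_) {
  text_id <- if (inherits(text, "corpus")) text$id else "text"
  if (inherits(patterns, "pattern_set") && is.na(seed)) {
    seed <- patterns$seed
  }
  records <- run_campaign(text, patterns, algorithms)
  scheme <- attr(records, "scheme")
  shares <- aggregate_shares(records, scheme)
  n_patterns <- attr(shares, "n_patterns")
  rankings <- lapply(seq_len(scheme$class_count), function(k) {
    rank_algorithms(shares, k, n_patterns)
  })
  structure(
    list(domain = domain,
         scheme = scheme,
         shares = shares,
         rankings = rankings,
         class_counts = n_patterns,
         provenance = list(seed = seed, text_ids = text_id,
                           n_patterns = length(.as_patterns(patterns)))),
    class = "ranking_model"
  )
}

#' @export
print.ranking_model <- function(x, ...) {
  cat(sprintf("<ranking_model> domain '%s': %d entropy classes, %d patterns\n",
              x$domain, x$scheme$class_count, x$provenance$n_patterns))
  for (k in seq_len(x$scheme$class_count)) {
    top <- if (length(x$rankings[[k]])) x$rankings[[k]][1L] else "—"
    cat(sprintf("  class %d (%s, n = %d): best %s\n",
                k, x$scheme$labels[k], x$class_counts[k], top))
  }
  invisible(x)
}

#' Predict the most efficient algorithms for a pattern
#'
#' Computes the pattern's rounded entropy, assigns it to the nearest
#' entropy class of the model's scheme, and returns that class's
#' algorithm ranking (best first). If the assigned class contains no
#' training patterns, the nearest non-empty class (by class index, lower
#' index on ties) is used, extending the nearest-class rule.
#'
#' @param object a `ranking_model`.
#' @param pattern a single non-empty character string.
#' @param ... unused.
#' @return character vector of algorithm ids, most efficient first, with
#'   the assigned class index in attribute `"class_index"`.
#' @export
predict.ranking_model <- function(object, pattern, ...) {
  h <- shannon_entropy(pattern)
  k <- assign_class(round_entropy(h), object$scheme)
  if (object$class_counts[k] == 0L) {
    nonempty <- which(object$class_counts > 0L)
    if (length(nonempty) == 0L) stop("model has no populated classes",
                                     call. = FALSE)
    k <- nonempty[which.min(abs(nonempty - k))]
  }
  structure(object$rankings[[k]], class_index = k, class = NULL)
}

#' Serialize a ranking model to JSON
#'
#' @param model a `ranking_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "ranking_model"))
  sch <- model$scheme
  classes <- lapply(seq_len(sch$class_count), function(k) {
    sub <- model$shares[model$shares$class == k, , drop = FALSE]
    shares_k <- lapply(seq_len(nrow(sub)), function(i) {
      list(q1 = sub$q1[i], q2 = sub$q2[i], q3 = sub$q3[i], q4 = sub$q4[i])
    })
    names(shares_k) <- sub$Algo
    list(index = k,
         label = sch$labels[k],
         n_patterns = model$class_counts[k],
         shares = shares_k,
         ranking = model$rankings[[k]])
  })
  doc <- list(
    domain = model$domain,
    scheme = list(min = sch$minimum, max = sch$maximum,
                  C = sch$class_count, h = sch$width,
                  boundaries = sch$boundaries),
    classes = classes,
    provenance = model$provenance
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a ranking model from JSON
#'
#' @param path a file written by [write_model()].
#' @return a `ranking_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  C <- as.integer(doc$scheme$C)
  scheme <- structure(
    list(class_count = C,
         width = as.numeric(doc$scheme$h),
         minimum = as.numeric(doc$scheme$min),
         maximum = as.numeric(doc$scheme$max),
         boundaries = vapply(doc$scheme$boundaries, as.numeric, numeric(1)),
         labels = vapply(doc$classes, function(cl) cl$label, character(1))),
    class = "class_scheme"
  )
  rows <- do.call(rbind, lapply(doc$classes, function(cl) {
    algos <- names(cl$shares)
    do.call(rbind, lapply(algos, function(a) {
      s <- cl$shares[[a]]
      data.frame(class = cl$index, Algo = a,
                 q1 = s$q1, q2 = s$q2, q3 = s$q3, q4 = s$q4,
                 stringsAsFactors = FALSE)
    }))
  }))
  n_patterns <- vapply(doc$classes, function(cl) as.integer(cl$n_patterns),
                       integer(1))
  attr(rows, "n_patterns") <- n_patterns
  rankings <- lapply(doc$classes, function(cl) {
    vapply(cl$ranking, as.character, character(1))
  })
  structure(
    list(domain = doc$domain,
         scheme = scheme,
         shares = rows,
         rankings = rankings,
         class_counts = n_patterns,
         provenance = list(
           seed = if (is.null(doc$provenance$seed)) NA_integer_ else
             as.integer(doc$provenance$seed),
           text_ids = as.character(unlist(doc$provenance$text_ids)),
           n_patterns = as.integer(doc$provenance$n_patterns))),
    class = "ranking_model"
  )
}
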