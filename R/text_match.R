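# Token-sequence phrase matching: compile a lexicon into patterns, find every
# occurrence in a tokenized corpus, count occurrences per name, and score a
# lexicon's corpus accuracy.

#' Compile a lexicon into a phrase matcher
#'
#' Each name is tokenized with [tokenize_text()] — the same tokenizer applied
#' to documents — and stored as an exact token-sequence pattern. Distinct
#' names that tokenize to the same sequence are all kept and all fire on a
#' hit. Names that tokenize to an empty sequence cannot match anything; they
#' are rejected and listed in the matcher's `rejected` field.
#'
#' Patterns are indexed by their first token, so at each document position
#' only patterns sharing that token are tested.
#'
#' @param names character vector of unique name strings.
#' @return An object of class `phrase_matcher`.
#' @export
compile_matcher <- function(names) {
  names <- as.character(names)
  stopifnot(length(names) > 0L)
  if (anyDuplicated(names)) stop_data("matcher names must be unique")
  pats <- lapply(names, function(n) tokenize_text(n)$tokens)
  empty <- lengths(pats) == 0L
  if (all(empty)) {
    stop_data("all names tokenize to empty patterns; nothing to match")
  }
  keep <- which(!empty)
  pats <- pats[keep]
  by_first <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(pats)) {
    w <- pats[[i]][1L]
    by_first[[w]] <- c(by_first[[w]], i)
  }
  structure(list(names = names[keep], patterns = pats,
                 lengths = lengths(pats), by_first = by_first,
                 rejected = names[empty]),
            class = "phrase_matcher")
}

#' @export
print.phrase_matcher <- function(x, ...) {
  cat("Phrase matcher: ", length(x$patterns), " patterns",
      if (length(x$rejected)) paste0(" (", length(x$rejected),
                                     " names rejected as untokenizable)"),
      "\n", sep = "")
  invisible(x)
}

.match_document <- function(matcher, tokens) {
  n <- length(tokens)
  if (n == 0L) {
    return(list(pattern = integer(), start = integer()))
  }
  hits_p <- integer(); hits_s <- integer()
  bf <- matcher$by_first
  pats <- matcher$patterns
  plen <- matcher$lengths
  for (i in seq_len(n)) {
    cand <- bf[[tokens[i]]]
    if (is.null(cand)) next
    for (p in cand) {
      L <- plen[p]
      if (i + L - 1L > n) next
      if (L == 1L || identical(pats[[p]], tokens[i:(i + L - 1L)])) {
        hits_p <- c(hits_p, p)
        hits_s <- c(hits_s, i)
      }
    }
  }
  list(pattern = hits_p, start = hits_s)
}

#' Find all pattern occurrences in a corpus
#'
#' Reports every occurrence of every pattern, including overlapping and
#' nested spans: a 1-token pattern inside a 3-token pattern's span fires
#' separately — exactly the redundant-count behaviour an unrefined lexicon
#' exhibits. Token indices are 1-based and spans are half-open in the sense
#' that `end_token` is the last token of the span.
#'
#' @param matcher a [compile_matcher()] object.
#' @param corpus an [corpus()] data frame.
#' @return A data frame with columns `doc_id`, `name`, `start_token`,
#'   `end_token`, ordered by doc id, start token, span length, then name.
#' @export
match_corpus <- function(matcher, corpus) {
  stopifnot(inherits(matcher, "phrase_matcher"))
  out <- vector("list", nrow(corpus))
  for (d in seq_len(nrow(corpus))) {
    tokens <- tokenize_text(corpus$text[d])$tokens
    h <- .match_document(matcher, tokens)
    if (length(h$pattern)) {
      out[[d]] <- data.frame(
        doc_id = corpus$doc_id[d],
        name = matcher$names[h$pattern],
        start_token = h$start,
        end_token = h$start + matcher$lengths[h$pattern] - 1L,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) {
    return(data.frame(doc_id = character(), name = character(),
                      start_token = integer(), end_token = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  o <- order_c(res$doc_id, res$start_token,
               res$end_token - res$start_token, res$name)
  res <- res[o, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Count corpus occurrences of each name
#'
#' Counts token-sequence occurrences of every name across the corpus; for
#' single-token names this reduces to comparing each document token against
#' the name, the procedure used when screening short names and abbreviations
#' against reference abstracts. Names absent everywhere (or untokenizable)
#' map to 0.
#'
#' @param names character vector of unique names.
#' @param corpus an [corpus()] data frame.
#' @return A named integer vector of total occurrence counts, in the order
#'   of `names`.
#' @export
count_occurrences <- function(names, corpus) {
  names <- as.character(names)
  counts <- stats::setNames(integer(length(names)), names)
  if (!length(names) || nrow(corpus) == 0L) return(counts)
  tokenizable <- vapply(names, function(n) length(tokenize_text(n)$tokens) > 0L, TRUE)
  if (any(tokenizable)) {
    m <- match_corpus(compile_matcher(names[tokenizable]), corpus)
    if (nrow(m)) {
      tab <- table(m$name)
      counts[names(tab)] <- as.integer(tab)
    }
  }
  counts
}

#' Evaluate a lexicon against a corpus
#'
#' Compiles the lexicon, matches the corpus, and summarizes how much of the
#' lexicon is actually seen in the text: the number of names with at least
#' one occurrence, the character-length range of those identified names, and
#' accuracy — identified names over compiled patterns. Elapsed wall time is
#' recorded for information only; it is hardware-bound and never asserted.
#'
#' @param names character vector of unique lexicon names.
#' @param corpus an [corpus()] data frame.
#' @return A list of class `lexicon_evaluation` with fields `pattern_count`,
#'   `identified_names`, `identified_count`, `min_identified_length`,
#'   `max_identified_length` (`NA` when nothing is identified), `accuracy`,
#'   `elapsed_seconds`.
#' @export
evaluate_lexicon <- function(names, corpus) {
  stopifnot(length(names) > 0L)
  t0 <- proc.time()[["elapsed"]]
  matcher <- compile_matcher(names)
  matches <- match_corpus(matcher, corpus)
  identified <- sort_c(unique(matches$name))
  lens <- nchar(identified, type = "chars")
  structure(list(
    pattern_count = length(matcher$patterns),
    identified_names = identified,
    identified_count = length(identified),
    min_identified_length = if (length(lens)) min(lens) else NA_integer_,
    max_identified_length = if (length(lens)) max(lens) else NA_integer_,
    accuracy = length(identified) / length(matcher$patterns),
    elapsed_seconds = proc.time()[["elapsed"]] - t0
  ), class = "lexicon_evaluation")
}

#' @export
print.lexicon_evaluation <- function(x, ...) {
  cat("Lexicon evaluation\n")
  cat("  patterns compiled:  ", x$pattern_count, "\n")
  cat("  names identified:   ", x$identified_count, "\n")
  if (x$identified_count > 0L) {
    cat("  identified lengths: ", x$min_identified_length, "-",
        x$max_identified_length, " characters\n", sep = "")
  }
  cat(sprintf("  accuracy:            %.4f\n", x$accuracy))
  cat(sprintf("  elapsed:             %.2f s\n", x$elapsed_seconds))
  invisible(x)
}
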