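# Independent reference implementations used to validate the package
# routines. These deliberately take different algorithmic routes than the
# code under test.

# Character-class scan: walk the string one character at a time, marking
# maximal ASCII-alphanumeric runs.
scan_tokens_oracle <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  is_an <- grepl("^[0-9A-Za-z]$", chars)
  tokens <- character(0)
  offsets <- integer(0)
  i <- 1L
  while (i <= length(chars)) {
    if (is_an[i]) {
      j <- i
      while (j < length(chars) && is_an[j + 1L]) j <- j + 1L
      tokens <- c(tokens, tolower(paste(chars[i:j], collapse = "")))
      offsets <- c(offsets, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  list(tokens = tokens, offsets = offsets)
}

# Brute-force sliding-window phrase matching: for every document, every
# window of every pattern length is compared against every pattern of that
# length (by joined-token key).
window_match_oracle <- function(names, corp) {
  pats <- lapply(names, function(n) tokenize_text(n)$tokens)
  keep <- lengths(pats) > 0L
  names <- names[keep]; pats <- pats[keep]
  keys <- vapply(pats, paste, "", collapse = "\x1f")
  out <- list()
  for (d in seq_len(nrow(corp))) {
    toks <- tokenize_text(corp$text[d])$tokens
    n <- length(toks)
    for (L in sort(unique(lengths(pats)))) {
      if (L > n) next
      wins <- vapply(seq_len(n - L + 1L), function(i)
        paste(toks[i:(i + L - 1L)], collapse = "\x1f"), "")
      for (p in which(lengths(pats) == L)) {
        hits <- which(wins == keys[p])
        if (length(hits)) {
          out[[length(out) + 1L]] <- data.frame(
            doc_id = corp$doc_id[d], name = names[p],
            start_token = hits, end_token = hits + L - 1L,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(doc_id = character(), name = character(),
                      start_token = integer(), end_token = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$doc_id, res$start_token, res$end_token - res$start_token,
            res$name, method = "radix"), , drop = FALSE]
}

# Sorted canonical form of a match table for equality comparison.
canon_matches <- function(m) {
  m <- m[order(m$doc_id, m$start_token, m$end_token, m$name,
               method = "radix"), c("doc_id", "name", "start_token",
                                    "end_token"), drop = FALSE]
  rownames(m) <- NULL
  m
}

# Direct pairwise audit that a retained set is an antichain under strict
# word-set inclusion.
expect_antichain <- function(retained) {
  sets <- lapply(retained, function(n) unique(tokenize_text(n)$tokens))
  n <- length(sets)
  violations <- character(0)
  if (n > 1L) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j && length(sets[[j]]) < length(sets[[i]]) &&
            all(sets[[j]] %in% sets[[i]])) {
          violations <- c(violations,
                          sprintf("'%s' strictly contains '%s'",
                                  retained[i], retained[j]))
        }
      }
    }
  }
  expect_identical(violations, character(0))
  invisible(retained)
}

# Every removed name must word-contain its witness, and the witness must be
# retained (or be one of the protected reference names).
expect_valid_witnesses <- function(result, reference = character()) {
  ok_pool <- c(result$retained, reference)
  bad <- character(0)
  for (nm in result$removed) {
    w <- result$witness[[nm]]
    if (is.na(w)) next  # whole tied group removed under remove_all
    if (!(w %in% ok_pool)) {
      bad <- c(bad, sprintf("witness '%s' of '%s' is not retained", w, nm))
      next
    }
    sw <- unique(tokenize_text(w)$tokens)
    sn <- unique(tokenize_text(nm)$tokens)
    if (!all(sw %in% sn)) {
      bad <- c(bad, sprintf("'%s' does not word-contain its witness '%s'",
                            nm, w))
    }
  }
  expect_identical(bad, character(0))
  invisible(result)
}

# Random family of names over a small word alphabet; guarantees unique
# name strings (word sets may still collide, which is the interesting case).
random_name_family <- function(n, alphabet_size = 30L, max_words = 5L) {
  alphabet <- paste0("w", seq_len(alphabet_size))
  nms <- character(0)
  while (length(nms) < n) {
    k <- sample(max_words, 1L)
    nm <- paste(sample(alphabet, k, replace = FALSE), collapse = " ")
    if (!(nm %in% nms)) nms <- c(nms, nm)
  }
  nms
}

# Rebuild a raw-entry stream from a refined lexicon, one row per name,
# keeping a non-administrative term type so a second pipeline pass sees the
# same drug strings.
entries_from_refined <- function(fit) {
  lex <- fit$lexicon
  excl <- fit$config$excluded_term_types
  data.frame(
    name = lex$name,
    source = vapply(lex$sources, `[[`, "", 1L),
    term_type = vapply(lex$term_types,
                       function(t) setdiff(t, excl)[1L], ""),
    stringsAsFactors = FALSE
  )
}

# Expected refinement-report counts compared field by field against a
# fixture manifest.
expect_report_matches_manifest <- function(report, manifest_report) {
  for (f in setdiff(names(manifest_report), "pct")) {
    expect_identical(as.integer(report[[f]]),
                     as.integer(manifest_report[[f]]),
                     label = paste("report field", f))
  }
  for (f in names(manifest_report$pct)) {
    expect_equal(report$pct[[f]], manifest_report$pct[[f]],
                 tolerance = 1e-12, label = paste("report pct", f))
  }
  invisible(report)
}
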