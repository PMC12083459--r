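# Word-set containment pruning.
#
# A mid-length name whose word set strictly contains another name's word set
# would fire together with that shorter name wherever it appears in text,
# inflating occurrence counts ("Acetaminophen 325 MG Oral Tablet" always
# brings "Acetaminophen" with it). The filter removes every such name,
# retaining an antichain of "distinct" names under unordered word-set
# inclusion. Removal is defined by the global strict-superset relation, so
# the outcome does not depend on input order.

.canon_order <- function(names) order_c(nchar(names, type = "chars"), names)

# Shared set-up: word sets, equality groups, sweep order.
.containment_prepare <- function(x, reference) {
  names_in <- if (inherits(x, "drug_lexicon")) x$name else as.character(x)
  if (anyDuplicated(names_in)) stop_data("containment input names must be unique")
  reference <- setdiff(as.character(reference %||% character()), names_in)
  all_names <- c(names_in, reference)
  protected <- c(rep(FALSE, length(names_in)), rep(TRUE, length(reference)))
  sets <- lapply(all_names, function(n) unique(tokenize_text(n)$tokens))
  if (any(lengths(sets) == 0L)) {
    stop_data("names with an empty word set must be removed before ",
              "containment filtering: ",
              paste(utils::head(all_names[lengths(sets) == 0L], 3L), collapse = ", "))
  }
  key <- vapply(sets, function(s) paste(sort_c(s), collapse = "\x1f"), "")
  groups <- split(seq_along(all_names), factor(key, levels = unique(key)))
  key_set <- lapply(groups, function(i) sets[[i[1L]]])
  list(names = all_names, protected = protected, n_input = length(names_in),
       groups = groups, key_set = key_set,
       key_order = order(lengths(key_set), names(groups), method = "radix"))
}

# Decide the fate of one equality group known to be minimal.
.resolve_minimal_group <- function(members, protected, names, policy) {
  prot <- members[protected[members]]
  inp <- members[!protected[members]]
  if (length(prot)) {
    canon <- prot[.canon_order(names[prot])[1L]]
    return(list(canonical = names[canon], retained = integer(),
                removed = inp, witness = rep(names[canon], length(inp))))
  }
  if (length(inp) == 1L) {
    return(list(canonical = names[inp], retained = inp,
                removed = integer(), witness = character()))
  }
  if (policy == "keep_canonical") {
    canon <- inp[.canon_order(names[inp])[1L]]
    rest <- setdiff(inp, canon)
    list(canonical = names[canon], retained = canon,
         removed = rest, witness = rep(names[canon], length(rest)))
  } else {
    list(canonical = NA_character_, retained = integer(),
         removed = inp, witness = rep(NA_character_, length(inp)))
  }
}

.containment_result <- function(prep, retained_idx, removed_idx, witness) {
  inp <- seq_len(prep$n_input)
  retained <- sort_c(prep$names[intersect(retained_idx, inp)])
  keep <- removed_idx %in% inp
  removed <- prep$names[removed_idx[keep]]
  witness <- witness[keep]
  o <- order_c(removed)
  structure(list(retained = retained,
                 removed = removed[o],
                 witness = stats::setNames(witness[o], removed[o]),
                 n_input = prep$n_input),
            class = "containment_result")
}

#' Containment filter over a set of names
#'
#' Removes every name whose word set is a strict superset of some other
#' name's word set; distinct strings with identical word sets are resolved by
#' `policy`. Names in `reference` are compared against (they can knock out an
#' input name) but are never removed or reported themselves — the refinement
#' pipeline uses this to check mid-length names against retained short names
#' when `containment_scope = "all_retained"`.
#'
#' The sweep processes distinct word sets in ascending size with an inverted
#' index from each minimal set's rarest word to the set, so a name is only
#' tested against the few minimal sets that share a word with it; no
#' quadratic all-pairs comparison is performed.
#'
#' @param x character vector of unique names, or a lexicon data frame.
#' @param reference optional character vector of reference names.
#' @param policy `"keep_canonical"` retains one member of each tied word-set
#'   group (shortest string, then lexicographic); `"remove_all"` drops all.
#' @return A list of class `containment_result`: `retained` and `removed`
#'   (both sorted), `witness` (named character; for each removed name one
#'   retained name whose words it contains, `NA` when the policy removed an
#'   entire tied group), `n_input`.
#' @seealso [containment_oracle()] for the quadratic reference
#'   implementation used in testing.
#' @export
filter_by_containment <- function(x, reference = NULL,
                                  policy = c("keep_canonical", "remove_all")) {
  policy <- match.arg(policy)
  prep <- .containment_prepare(x, reference)
  n_keys <- length(prep$groups)
  key_canon <- rep(NA_character_, n_keys)

  # global word frequency over distinct sets, to pick each set's rarest word
  word_freq <- table(unlist(prep$key_set, use.names = FALSE))
  index <- new.env(hash = TRUE, parent = emptyenv())

  retained_idx <- integer()
  removed_idx <- integer()
  witness <- character()

  for (k in prep$key_order) {
    S <- prep$key_set[[k]]
    cand <- unique(unlist(lapply(S, function(w)
      if (!is.null(index[[w]])) index[[w]]), use.names = FALSE))
    hit <- NA_integer_
    if (length(cand)) {
      # order candidates by (size, key) so the chosen witness does not
      # depend on input order
      cand <- cand[order(lengths(prep$key_set)[cand],
                         names(prep$groups)[cand], method = "radix")]
      for (kc in cand) {
        B <- prep$key_set[[kc]]
        if (length(B) < length(S) && all(B %in% S)) { hit <- kc; break }
      }
    }
    members <- prep$groups[[k]]
    if (!is.na(hit)) {
      inp <- members[!prep$protected[members]]
      removed_idx <- c(removed_idx, inp)
      witness <- c(witness, rep(key_canon[hit], length(inp)))
    } else {
      # minimal set: index it under its rarest word, resolve ties
      rare <- S[order(as.integer(word_freq[S]), S, method = "radix")[1L]]
      index[[rare]] <- c(index[[rare]], k)
      res <- .resolve_minimal_group(members, prep$protected, prep$names, policy)
      key_canon[k] <- res$canonical
      retained_idx <- c(retained_idx, res$retained)
      removed_idx <- c(removed_idx, res$removed)
      witness <- c(witness, res$witness)
    }
  }
  .containment_result(prep, retained_idx, removed_idx, witness)
}

#' Quadratic containment oracle
#'
#' Reference implementation of the containment filter by all-pairs strict
#' subset testing; semantics identical to [filter_by_containment()] by
#' definition. Guarded to small inputs — it exists so the indexed sweep can
#' be validated against an independent route, not for production use.
#'
#' @inheritParams filter_by_containment
#' @param max_n guard on the input size (default 5000).
#' @return A `containment_result`, as [filter_by_containment()].
#' @export
containment_oracle <- function(x, reference = NULL,
                               policy = c("keep_canonical", "remove_all"),
                               max_n = 5000L) {
  policy <- match.arg(policy)
  prep <- .containment_prepare(x, reference)
  if (length(prep$names) > max_n) {
    stop_data("containment_oracle is quadratic; refusing ", length(prep$names),
              " names (guard ", max_n, ")")
  }
  ks <- prep$key_set
  n_keys <- length(ks)
  sizes <- lengths(ks)
  # strict containment between every pair of distinct word sets
  dominated <- vapply(seq_len(n_keys), function(i) {
    any(vapply(seq_len(n_keys), function(j) {
      sizes[j] < sizes[i] && all(ks[[j]] %in% ks[[i]])
    }, TRUE))
  }, TRUE)

  key_canon <- rep(NA_character_, n_keys)
  retained_idx <- integer(); removed_idx <- integer(); witness <- character()
  for (k in seq_len(n_keys)) {
    if (dominated[k]) next
    res <- .resolve_minimal_group(prep$groups[[k]], prep$protected,
                                  prep$names, policy)
    key_canon[k] <- res$canonical
    retained_idx <- c(retained_idx, res$retained)
    removed_idx <- c(removed_idx, res$removed)
    witness <- c(witness, res$witness)
  }
  for (k in which(dominated)) {
    subs <- which(!dominated & sizes < sizes[k] &
                    vapply(ks, function(B) all(B %in% ks[[k]]), TRUE))
    w <- if (length(subs)) key_canon[min(subs)] else NA_character_
    inp <- prep$groups[[k]][!prep$protected[prep$groups[[k]]]]
    removed_idx <- c(removed_idx, inp)
    witness <- c(witness, rep(w, length(inp)))
  }
  .containment_result(prep, retained_idx, removed_idx, witness)
}

#' @export
print.containment_result <- function(x, ...) {
  cat("Containment filter: ", length(x$retained), " retained, ",
      length(x$removed), " removed of ", x$n_input, " names\n", sep = "")
  invisible(x)
}

#' Dump removed-name/witness pairs as TSV
#'
#' @param result a `containment_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_containment_audit <- function(result, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("removed_name\twitness_name", con, useBytes = TRUE)
  if (length(result$removed)) {
    writeLines(paste(result$removed, ifelse(is.na(result$witness), "",
                                            result$witness), sep = "\t"),
               con, useBytes = TRUE)
  }
  invisible(path)
}
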