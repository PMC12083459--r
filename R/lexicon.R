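# The lexicon container and the stage-wise refinement pipeline.

#' Construct a drug lexicon
#'
#' A lexicon holds one row per unique drug-name string with its aggregated
#' source vocabularies (SAB codes) and term types (TTY codes).
#'
#' @param name character vector of unique name strings.
#' @param sources list of character vectors of SAB codes, one per name.
#' @param term_types list of character vectors of TTY codes, one per name.
#' @return A data frame of class `drug_lexicon` with columns `name`,
#'   `char_length`, `sources` (list), `term_types` (list).
#' @export
new_lexicon <- function(name, sources, term_types) {
  name <- as.character(name)
  if (anyDuplicated(name)) stop_data("lexicon names must be unique")
  stopifnot(length(sources) == length(name),
            length(term_types) == length(name))
  df <- data.frame(name = name,
                   char_length = nchar(name, type = "chars"),
                   stringsAsFactors = FALSE)
  df$sources <- lapply(sources, as.character)
  df$term_types <- lapply(term_types, as.character)
  class(df) <- c("drug_lexicon", "data.frame")
  df
}

#' Refinement pipeline configuration
#'
#' Thresholds and switches governing the refinement stages. Defaults follow
#' the published pipeline: names of four or fewer characters form the short
#' class, names above 199 characters are discarded, and the administrative
#' term types DF (dose form), DFG (dose form group) and SC (special category)
#' are excluded.
#'
#' @param short_max largest character length of the short class (default 4).
#' @param mid_max largest character length retained at all (default 199);
#'   names longer than this are removed.
#' @param excluded_term_types TTY codes treated as administrative.
#' @param dedup_case_sensitive deduplicate names case-sensitively?
#' @param containment_scope `"mid_only"` compares mid-length names only among
#'   themselves; `"all_retained"` additionally checks them against retained
#'   short names.
#' @param equal_word_set_policy for distinct strings with identical word
#'   sets: `"keep_canonical"` retains one (shortest string, ties broken
#'   lexicographically), `"remove_all"` drops every member.
#' @param min_corpus_occurrences minimum corpus occurrences a short name
#'   needs to be retained (default 1; 0 disables the corpus filter).
#' @param stage_order `"dedup_first"` (default) deduplicates before the
#'   term-type filter; `"tty_first"` drops administrative rows from the raw
#'   stream before deduplication.
#' @param languages,drop_suppressed optional RRF prefilters passed to
#'   [parse_rrf()] when [refine()] is given a file path.
#' @return A list of class `refinement_config`.
#' @export
refinement_config <- function(short_max = 4L,
                              mid_max = 199L,
                              excluded_term_types = c("DF", "DFG", "SC"),
                              dedup_case_sensitive = TRUE,
                              containment_scope = c("mid_only", "all_retained"),
                              equal_word_set_policy = c("keep_canonical", "remove_all"),
                              min_corpus_occurrences = 1L,
                              stage_order = c("dedup_first", "tty_first"),
                              languages = NULL,
                              drop_suppressed = FALSE) {
  short_max <- as.integer(short_max)
  mid_max <- as.integer(mid_max)
  stopifnot(is_count(short_max), is_count(mid_max), short_max > 0L,
            short_max < mid_max, is_count(min_corpus_occurrences))
  structure(list(
    short_max = short_max,
    mid_max = mid_max,
    excluded_term_types = as.character(excluded_term_types),
    dedup_case_sensitive = isTRUE(dedup_case_sensitive),
    containment_scope = match.arg(containment_scope),
    equal_word_set_policy = match.arg(equal_word_set_policy),
    min_corpus_occurrences = as.integer(min_corpus_occurrences),
    stage_order = match.arg(stage_order),
    languages = languages,
    drop_suppressed = isTRUE(drop_suppressed)
  ), class = "refinement_config")
}

#' Read a refinement configuration from a JSON file
#'
#' The file is a flat JSON object whose keys mirror the arguments of
#' [refinement_config()]; omitted keys take their defaults.
#'
#' @param path JSON file.
#' @return A `refinement_config` object.
#' @export
read_config <- function(path) {
  vals <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- names(formals(refinement_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop_data("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  do.call(refinement_config, vals)
}

#' @export
print.refinement_config <- function(x, ...) {
  cat("Refinement configuration\n")
  cat("  short class:       <=", x$short_max, "characters\n")
  cat("  mid class:        ", x$short_max + 1L, "-", x$mid_max, "characters\n")
  cat("  excluded TTYs:    ", paste(x$excluded_term_types, collapse = ", "), "\n")
  cat("  dedup:            ",
      if (x$dedup_case_sensitive) "case-sensitive" else "case-insensitive", "\n")
  cat("  containment scope:", x$containment_scope, "\n")
  cat("  equal word sets:  ", x$equal_word_set_policy, "\n")
  cat("  min occurrences:  ", x$min_corpus_occurrences, "\n")
  cat("  stage order:      ", x$stage_order, "\n")
  invisible(x)
}

#' Deduplicate raw entries into a lexicon
#'
#' Collapses the raw entry stream to one lexicon row per distinct name
#' string (after whitespace trimming; case-sensitively unless configured
#' otherwise). Sources and term types are unioned over all merged rows, so a
#' name contributed by several vocabularies keeps its full provenance.
#'
#' @param entries data frame from [parse_rrf()] (columns `name`, `source`,
#'   `term_type`).
#' @param config a [refinement_config()].
#' @return A list with `lexicon` (a [new_lexicon()] data frame, first-seen
#'   order) and `duplicates_removed` (raw rows minus distinct names).
#' @export
build_lexicon <- function(entries, config = refinement_config()) {
  nm <- trimws(entries$name)
  n <- length(nm)
  if (n == 0L) {
    return(list(lexicon = new_lexicon(character(), list(), list()),
                duplicates_removed = 0L))
  }
  key <- if (config$dedup_case_sensitive) nm else tolower(nm)
  idx <- split(seq_len(n), factor(key, levels = unique(key)))
  first <- vapply(idx, `[[`, 0L, 1L)
  lex <- new_lexicon(
    nm[first],
    sources = lapply(idx, function(i) sort_c(unique(entries$source[i]))),
    term_types = lapply(idx, function(i) sort_c(unique(entries$term_type[i])))
  )
  list(lexicon = lex, duplicates_removed = n - length(idx))
}

#' Remove purely administrative entries
#'
#' An entry is removed only when every one of its term types is in the
#' excluded set: a name that also carries a drug-specific TTY (say both DF
#' and BN) is retained, since dropping it would delete a true drug string.
#'
#' @param lexicon a lexicon data frame.
#' @param config a [refinement_config()].
#' @return A list with `retained` and `removed` lexicons.
#' @export
filter_term_types <- function(lexicon, config = refinement_config()) {
  drop <- vapply(lexicon$term_types,
                 function(t) all(t %in% config$excluded_term_types), TRUE)
  list(retained = lexicon[!drop, , drop = FALSE],
       removed = lexicon[drop, , drop = FALSE])
}

#' Stratify a lexicon by name length
#'
#' Partitions entries into the short (`char_length <= short_max`), mid
#' (`short_max < char_length <= mid_max`) and long (`char_length > mid_max`)
#' classes. The three classes are disjoint and exhaustive.
#'
#' @param lexicon a lexicon data frame.
#' @param config a [refinement_config()].
#' @return A list with lexicons `short`, `mid`, `long`.
#' @export
categorize_by_length <- function(lexicon, config = refinement_config()) {
  len <- lexicon$char_length
  list(short = lexicon[len <= config$short_max, , drop = FALSE],
       mid = lexicon[len > config$short_max & len <= config$mid_max, , drop = FALSE],
       long = lexicon[len > config$mid_max, , drop = FALSE])
}

#' Corpus-occurrence filter for short names
#'
#' Very short names and abbreviations (APAP, ASA, HCTZ, ...) are kept only if
#' they actually occur in a reference corpus of drug-related text; names
#' never seen there are considered rare and removed. Occurrences are counted
#' with the token-sequence matcher ([count_occurrences()]), which for
#' single-token names reduces to comparing each document token against the
#' name.
#'
#' @param short_lexicon the short class from [categorize_by_length()].
#' @param corpus an [corpus()] data frame; required unless the class is empty
#'   or `min_corpus_occurrences` is 0.
#' @param config a [refinement_config()].
#' @return A list with `retained` and `removed` lexicons, each carrying an
#'   `occurrences` column.
#' @export
filter_short_names <- function(short_lexicon, corpus,
                               config = refinement_config()) {
  n <- nrow(short_lexicon)
  if (n == 0L || config$min_corpus_occurrences == 0L) {
    short_lexicon$occurrences <- if (n) NA_integer_ else integer()
    return(list(retained = short_lexicon,
                removed = short_lexicon[0, , drop = FALSE]))
  }
  if (missing(corpus) || is.null(corpus) || nrow(corpus) == 0L) {
    stop_data("short-name filtering needs a non-empty corpus; ",
              "set min_corpus_occurrences = 0 to disable the stage")
  }
  counts <- count_occurrences(short_lexicon$name, corpus)
  short_lexicon$occurrences <- as.integer(counts[short_lexicon$name])
  keep <- short_lexicon$occurrences >= config$min_corpus_occurrences
  list(retained = short_lexicon[keep, , drop = FALSE],
       removed = short_lexicon[!keep, , drop = FALSE])
}

#' Remove extremely long names
#'
#' Names longer than `mid_max` characters (200+ under defaults) virtually
#' never appear verbatim in free text and are removed wholesale.
#'
#' @param long_lexicon the long class from [categorize_by_length()].
#' @return A list with `removed` (all input rows).
#' @export
filter_long_names <- function(long_lexicon) {
  list(removed = long_lexicon)
}

# ---- report ----------------------------------------------------------------

#' Stage-by-stage refinement report
#'
#' Collects the retained/removed counts of every pipeline stage and their
#' percentages of the total extracted names (half-up rounding to two
#' decimals). The constructor enforces the conservation identities: the raw
#' total equals duplicates + administrative + short + mid + long, the short
#' and mid classes each split into retained + removed, and the refined total
#' is retained short + retained mid.
#'
#' @param total_extracted raw entry rows parsed from the RRF file.
#' @param duplicates_removed rows collapsed by deduplication.
#' @param non_drug_removed purely administrative names removed.
#' @param short_total,short_removed,short_retained short-class counts.
#' @param mid_total,mid_retained_distinct,mid_removed_containing mid-class
#'   counts (retained distinct names vs names removed for containing another
#'   name's words).
#' @param long_removed long names removed.
#' @return A list of class `refinement_report` with the counts,
#'   `refined_total`, and a `pct` vector of stage percentages.
#' @export
refinement_report <- function(total_extracted, duplicates_removed,
                              non_drug_removed, short_total, short_removed,
                              short_retained, mid_total, mid_retained_distinct,
                              mid_removed_containing, long_removed) {
  cnt <- vapply(list(total_extracted, duplicates_removed, non_drug_removed,
                     short_total, short_removed, short_retained, mid_total,
                     mid_retained_distinct, mid_removed_containing,
                     long_removed),
                function(x) { stopifnot(is_count(x)); as.integer(x) }, 0L)
  names(cnt) <- c("total_extracted", "duplicates_removed", "non_drug_removed",
                  "short_total", "short_removed", "short_retained",
                  "mid_total", "mid_retained_distinct",
                  "mid_removed_containing", "long_removed")
  refined_total <- cnt[["short_retained"]] + cnt[["mid_retained_distinct"]]
  if (cnt[["total_extracted"]] != cnt[["duplicates_removed"]] +
      cnt[["non_drug_removed"]] + cnt[["short_total"]] + cnt[["mid_total"]] +
      cnt[["long_removed"]]) {
    stop_data("report conservation violated: stage counts do not sum to the total")
  }
  if (cnt[["short_total"]] != cnt[["short_removed"]] + cnt[["short_retained"]]) {
    stop_data("short class does not partition into retained + removed")
  }
  if (cnt[["mid_total"]] != cnt[["mid_retained_distinct"]] +
      cnt[["mid_removed_containing"]]) {
    stop_data("mid class does not partition into retained + removed")
  }
  tot <- cnt[["total_extracted"]]
  pct_of <- function(x) if (tot == 0L) 0 else round_half_up(x / tot * 100, 2L)
  pct <- c(duplicates_removed = pct_of(cnt[["duplicates_removed"]]),
           non_drug_removed = pct_of(cnt[["non_drug_removed"]]),
           short_removed = pct_of(cnt[["short_removed"]]),
           mid_removed_containing = pct_of(cnt[["mid_removed_containing"]]),
           long_removed = pct_of(cnt[["long_removed"]]),
           refined_total = pct_of(refined_total))
  structure(c(as.list(cnt), list(refined_total = refined_total,
                                 pct = as.list(pct))),
            class = "refinement_report")
}

#' @export
print.refinement_report <- function(x, ...) {
  cat("Refinement report (", format(x$total_extracted, big.mark = ","),
      " raw names)\n", sep = "")
  rows <- rbind(
    c("duplicates removed", x$duplicates_removed, x$pct$duplicates_removed),
    c("administrative names removed", x$non_drug_removed, x$pct$non_drug_removed),
    c("short names removed (no corpus evidence)", x$short_removed, x$pct$short_removed),
    c("mid names removed (contain another name)", x$mid_removed_containing,
      x$pct$mid_removed_containing),
    c("long names removed", x$long_removed, x$pct$long_removed),
    c("refined lexicon retained", x$refined_total, x$pct$refined_total)
  )
  for (i in seq_len(nrow(rows))) {
    cat(sprintf("  %-42s %10s  (%6.2f%%)\n", rows[i, 1],
                format(as.integer(rows[i, 2]), big.mark = ","),
                as.numeric(rows[i, 3])))
  }
  invisible(x)
}
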