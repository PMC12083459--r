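# The end-to-end refinement pipeline and its result object.

#' Refine a drug-name lexicon
#'
#' Runs the full refinement pipeline over an RxNorm concept file (or an
#' already-parsed entry data frame): deduplication, administrative term-type
#' exclusion, length stratification, corpus-occurrence filtering of the short
#' class, word-set containment pruning of the mid class, and removal of the
#' long class. The refined lexicon is the union of retained short and
#' retained mid names.
#'
#' With the default `stage_order = "dedup_first"` the raw rows are first
#' collapsed to unique names and the term-type filter then removes names all
#' of whose term types are administrative. `stage_order = "tty_first"` drops
#' administrative rows from the raw stream before deduplication, for
#' extracts that follow that convention.
#'
#' @param x path to an RXNCONSO.RRF file, or a data frame of raw entries
#'   with columns `name`, `source`, `term_type`.
#' @param corpus an [corpus()] data frame used to screen short names; may be
#'   omitted when the short class is empty or the occurrence filter is
#'   disabled (`min_corpus_occurrences = 0`).
#' @param config a [refinement_config()].
#' @return An object of class `rx_refinement` with components:
#'   \describe{
#'     \item{lexicon}{the refined lexicon (retained short + retained mid),
#'       with `length_class` and `occurrences` columns.}
#'     \item{report}{a [refinement_report()].}
#'     \item{stages}{per-stage detail: removed administrative entries, the
#'       short retained/removed split with occurrence counts, the
#'       `containment_result` for the mid class, removed long entries.}
#'     \item{pre_lengths}{character lengths of all deduplicated names before
#'       filtering, kept for length-distribution comparisons.}
#'     \item{config, diagnostics, call}{run metadata.}
#'   }
#' @examples
#' entries <- data.frame(
#'   name = c("Aspirin", "Aspirin", "Aspirin 81 MG Oral Tablet", "Oral Tablet"),
#'   source = c("DB", "RXNORM", "RXNORM", "RXNORM"),
#'   term_type = c("IN", "IN", "SCD", "DF")
#' )
#' fit <- refine(entries, config = refinement_config(min_corpus_occurrences = 0))
#' fit$report$refined_total
#' @export
refine <- function(x, corpus = NULL, config = refinement_config()) {
  cl <- match.call()
  diagnostics <- NULL
  if (is.character(x)) {
    entries <- parse_rrf(x, languages = config$languages,
                         drop_suppressed = config$drop_suppressed)
    diagnostics <- rrf_diagnostics(entries)
  } else {
    stopifnot(is.data.frame(x),
              all(c("name", "source", "term_type") %in% names(x)))
    entries <- x
  }
  total_extracted <- nrow(entries)

  if (config$stage_order == "tty_first") {
    admin_rows <- entries$term_type %in% config$excluded_term_types
    non_drug_removed <- sum(admin_rows)
    bl <- build_lexicon(entries[!admin_rows, , drop = FALSE], config)
    lex <- bl$lexicon
    tt_removed <- lex[0, , drop = FALSE]
  } else {
    bl <- build_lexicon(entries, config)
    tt <- filter_term_types(bl$lexicon, config)
    lex <- tt$retained
    tt_removed <- tt$removed
    non_drug_removed <- nrow(tt_removed)
  }
  duplicates_removed <- bl$duplicates_removed
  pre_lengths <- c(bl$lexicon$char_length)

  classes <- categorize_by_length(lex, config)
  short <- filter_short_names(classes$short, corpus, config)

  # mid names that tokenize to nothing can never be matched; they are removed
  # at the containment stage with no witness
  mid <- classes$mid
  mid_empty <- vapply(mid$name,
                      function(n) length(tokenize_text(n)$tokens) == 0L, TRUE)
  mid_nonempty <- mid[!mid_empty, , drop = FALSE]
  reference <- if (config$containment_scope == "all_retained")
    short$retained$name else NULL
  cont <- filter_by_containment(mid_nonempty, reference = reference,
                                policy = config$equal_word_set_policy)
  if (any(mid_empty)) {
    extra <- mid$name[mid_empty]
    cont$removed <- sort_c(c(cont$removed, extra))
    cont$witness <- c(cont$witness,
                      stats::setNames(rep(NA_character_, length(extra)), extra))
    cont$witness <- cont$witness[cont$removed]
    cont$n_input <- cont$n_input + length(extra)
  }
  long <- filter_long_names(classes$long)

  report <- refinement_report(
    total_extracted = total_extracted,
    duplicates_removed = duplicates_removed,
    non_drug_removed = non_drug_removed,
    short_total = nrow(classes$short),
    short_removed = nrow(short$removed),
    short_retained = nrow(short$retained),
    mid_total = nrow(mid),
    mid_retained_distinct = length(cont$retained),
    mid_removed_containing = length(cont$removed),
    long_removed = nrow(long$removed)
  )

  short_ret <- short$retained
  mid_ret <- mid[mid$name %in% cont$retained, , drop = FALSE]
  if (nrow(mid_ret)) mid_ret$occurrences <- NA_integer_
  else mid_ret$occurrences <- integer()
  refined <- rbind(
    cbind(short_ret, length_class = rep("short", nrow(short_ret))),
    cbind(mid_ret, length_class = rep("mid", nrow(mid_ret)))
  )
  refined <- refined[order_c(refined$name), , drop = FALSE]
  rownames(refined) <- NULL
  class(refined) <- c("drug_lexicon", "data.frame")

  structure(list(
    lexicon = refined,
    report = report,
    stages = list(
      non_drug = tt_removed,
      short = short,
      containment = cont,
      mid_removed = mid[mid$name %in% cont$removed, , drop = FALSE],
      long = long$removed
    ),
    pre_lengths = pre_lengths,
    config = config,
    diagnostics = diagnostics,
    call = cl
  ), class = "rx_refinement")
}

#' @export
print.rx_refinement <- function(x, ...) {
  cat("Refined drug-name lexicon\n")
  cat("  raw entries:   ", format(x$report$total_extracted, big.mark = ","), "\n")
  cat("  refined names: ", format(x$report$refined_total, big.mark = ","),
      " (", x$report$short_retained, " short + ",
      x$report$mid_retained_distinct, " mid)\n", sep = "")
  cat("Use summary() for the stage-by-stage report.\n")
  invisible(x)
}

#' @export
summary.rx_refinement <- function(object, ...) object$report

#' Compare name-length distributions before and after refinement
#'
#' Draws the per-length name counts of the deduplicated input lexicon and of
#' the refined lexicon on one set of axes (log-scaled counts), the customary
#' way to show that long names are preferentially pruned.
#'
#' @param x an `rx_refinement` object.
#' @param max_char right edge of the length axis (default 250; longer names
#'   are pooled there).
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.rx_refinement <- function(x, max_char = 250L, ...) {
  h <- length_histogram(list(original = x$pre_lengths,
                             refined = x$lexicon$char_length),
                        max_char = max_char)
  plot(h, ...)
  invisible(x)
}
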