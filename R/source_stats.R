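# Provenance analytics: which source vocabularies contributed the names a
# refinement stage removed, and how name lengths are distributed.

#' The 14 source vocabularies aggregated by RxNorm
#'
#' ATC, CVX, DB (DrugBank), GS, MMSL, MMX, MSH, MTHCMS, MTHSPL, NDDF,
#' RXNORM, SNOMEDCT_US, USP, VANDF. Seeded for validation; unknown codes in
#' data are tolerated with a warning since releases evolve.
#'
#' @format Character vector of 14 SAB codes.
#' @export
rx_sab_codes <- c("ATC", "CVX", "DB", "GS", "MMSL", "MMX", "MSH", "MTHCMS",
                  "MTHSPL", "NDDF", "RXNORM", "SNOMEDCT_US", "USP", "VANDF")

#' Entries originating from exactly one source
#'
#' Names carried by a single source vocabulary lack corroboration from the
#' other RxNorm sources; the bulk of the names the pipeline removes turn out
#' to be single-sourced.
#'
#' @param lexicon a lexicon data frame (post [build_lexicon()], so sources
#'   are aggregated).
#' @return The subset of rows whose `sources` set has exactly one element.
#' @export
single_source_subset <- function(lexicon) {
  lexicon[lengths(lexicon$sources) == 1L, , drop = FALSE]
}

#' Per-source removal breakdown
#'
#' For each source vocabulary, how many names of `universe` carry it
#' ("provided"), how many of those were removed at a given stage, and the
#' removal rate as a percentage (half-up, one decimal). A multi-source name
#' counts toward every one of its sources. Also reports how many removed
#' names were single-sourced.
#'
#' @param removed lexicon of removed entries (must be a subset of
#'   `universe` by name).
#' @param universe lexicon of all entries at the stage of interest.
#' @return A list of class `source_breakdown`: `by_source` (data frame with
#'   `source`, `provided`, `removed`, `removal_rate`), `single_sourced_removed`,
#'   `total_removed`.
#' @export
source_breakdown <- function(removed, universe) {
  if (!all(removed$name %in% universe$name)) {
    stop_data("removed entries must be a subset of the universe")
  }
  prov_tab <- table(unlist(universe$sources, use.names = FALSE))
  rem_tab <- table(unlist(removed$sources, use.names = FALSE))
  sabs <- sort_c(names(prov_tab))
  unknown <- setdiff(sabs, rx_sab_codes)
  if (length(unknown)) {
    warning("unknown source codes: ", paste(unknown, collapse = ", "))
  }
  if (length(setdiff(names(rem_tab), sabs))) {
    stop_data("removed entries carry sources absent from the universe")
  }
  provided <- as.integer(prov_tab[sabs])
  rem <- as.integer(rem_tab[sabs])
  rem[is.na(rem)] <- 0L
  by_source <- data.frame(
    source = sabs,
    provided = provided,
    removed = rem,
    removal_rate = ifelse(provided > 0L,
                          round_half_up(rem / provided * 100, 1L), 0),
    stringsAsFactors = FALSE
  )
  structure(list(
    by_source = by_source,
    single_sourced_removed = nrow(single_source_subset(removed)),
    total_removed = nrow(removed)
  ), class = "source_breakdown")
}

#' @export
print.source_breakdown <- function(x, ...) {
  cat("Source breakdown (", x$single_sourced_removed, " of ", x$total_removed,
      " removed names single-sourced)\n", sep = "")
  df <- x$by_source
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-12s %8d provided %8d removed  (%5.1f%%)\n",
                df$source[i], df$provided[i], df$removed[i],
                df$removal_rate[i]))
  }
  invisible(x)
}

#' Write a source breakdown as JSON and TSV
#'
#' @param x a `source_breakdown`.
#' @param path_json,path_tsv output files (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_breakdown <- function(x, path_json = NULL, path_tsv = NULL) {
  if (!is.null(path_json)) {
    jsonlite::write_json(unclass(x), path_json, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  if (!is.null(path_tsv)) {
    utils::write.table(x$by_source, path_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(c(path_json, path_tsv))
}

#' Name-length histogram
#'
#' Counts names per character length with unit-width bins over
#' `[1, max_char]` and a terminal overflow bin; bin counts always sum to the
#' lexicon size.
#'
#' @param x a lexicon data frame, an integer vector of lengths, or a named
#'   list of either (to histogram several lexicons side by side).
#' @param max_char last regular bin (default 250).
#' @return A list of class `length_histogram`: `breaks` (1..max_char, `Inf`
#'   labels the overflow bin) and `counts`, an integer matrix with one column
#'   per input lexicon.
#' @export
length_histogram <- function(x, max_char = 250L) {
  max_char <- as.integer(max_char)
  stopifnot(is_count(max_char), max_char >= 1L)
  if (!is.list(x) || is.data.frame(x)) x <- list(lexicon = x)
  if (is.null(names(x))) names(x) <- paste0("lexicon", seq_along(x))
  lens <- lapply(x, function(el) {
    if (is.data.frame(el)) el$char_length else as.integer(el)
  })
  counts <- vapply(lens, function(L) {
    stopifnot(all(L >= 1L))
    main <- tabulate(L[L <= max_char], nbins = max_char)
    c(main, sum(L > max_char))
  }, integer(max_char + 1L))
  counts <- matrix(counts, ncol = length(lens),
                   dimnames = list(c(as.character(seq_len(max_char)),
                                     "overflow"), names(x)))
  structure(list(breaks = c(seq_len(max_char), Inf), counts = counts),
            class = "length_histogram")
}

#' @export
print.length_histogram <- function(x, ...) {
  tot <- colSums(x$counts)
  cat("Length histogram (", length(x$breaks) - 1L, " unit bins + overflow)\n",
      sep = "")
  for (nm in colnames(x$counts)) {
    nz <- which(x$counts[, nm] > 0L)
    cat(sprintf("  %-12s %8d names, lengths %s-%s\n", nm, tot[[nm]],
                if (length(nz)) min(nz) else "-",
                if (length(nz)) max(nz) else "-"))
  }
  invisible(x)
}

#' @export
plot.length_histogram <- function(x, ...) {
  n_bins <- nrow(x$counts)
  cols <- c("#2166ac", "#b2182b", "#4dac26", "#e08214")
  graphics::matplot(seq_len(n_bins), x$counts, type = "s", lty = 1,
                    col = cols[seq_len(ncol(x$counts))],
                    xlab = "name length (characters)",
                    ylab = "number of names", ...)
  graphics::legend("topright", legend = colnames(x$counts),
                   col = cols[seq_len(ncol(x$counts))], lty = 1, bty = "n")
  invisible(x)
}
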