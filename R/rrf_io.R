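# Reading RxNorm RRF concept files and free-text corpora; writing refined
# lexicons, reports and match tables.

#' Column layout of an RXNCONSO.RRF file
#'
#' RRF files are pipe-delimited and headerless; the standard RXNCONSO layout
#' places RXCUI first and the name string (STR) fifteenth. Positions are
#' 1-based and can be overridden for non-standard extracts.
#'
#' @param rxcui,lat,sab,tty,str,suppress 1-based column positions of the
#'   concept id, language, source abbreviation, term type, name string and
#'   suppression flag.
#' @return A named list of integer column positions.
#' @export
rrf_columns <- function(rxcui = 1L, lat = 2L, sab = 12L, tty = 13L,
                        str = 15L, suppress = 17L) {
  out <- list(rxcui = as.integer(rxcui), lat = as.integer(lat),
              sab = as.integer(sab), tty = as.integer(tty),
              str = as.integer(str), suppress = as.integer(suppress))
  stopifnot(all(vapply(out, function(i) is_count(i) && i >= 1L, TRUE)))
  out
}

#' Parse an RXNCONSO.RRF concept file
#'
#' Reads a pipe-delimited RRF file and extracts one raw entry per well-formed
#' line: the name string (STR), its term type (TTY), source vocabulary (SAB)
#' and concept id (RXCUI, kept for traceability only). Lines with too few
#' fields or an empty name/source/term type are skipped and counted in the
#' diagnostics; input order is preserved. Leading/trailing whitespace in the
#' name is trimmed so padding artifacts cannot create spurious unique names.
#' Bytes that are not valid UTF-8 are replaced and the affected lines counted.
#'
#' No language or suppression filtering is applied unless requested:
#' `languages = "ENG"` keeps only English rows, `drop_suppressed = TRUE`
#' drops rows whose suppression flag is "Y", "E" or "O".
#'
#' @param path path to an RRF file.
#' @param columns column layout, see [rrf_columns()].
#' @param languages optional character vector of LAT codes to keep.
#' @param drop_suppressed drop suppressed rows?
#' @return A data frame with columns `concept_id`, `source`, `term_type`,
#'   `name`, carrying a `"diagnostics"` attribute (see [rrf_diagnostics()]).
#' @export
parse_rrf <- function(path, columns = rrf_columns(), languages = NULL,
                      drop_suppressed = FALSE) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop_data("RRF file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  n_total <- length(lines)
  bad_enc <- !validUTF8(lines)
  if (any(bad_enc)) {
    lines[bad_enc] <- iconv(lines[bad_enc], "UTF-8", "UTF-8", sub = "?")
  }
  fields <- strsplit(lines, "|", fixed = TRUE)
  need <- max(columns$rxcui, columns$sab, columns$tty, columns$str)
  nf <- lengths(fields)
  long_enough <- nf >= need
  get_col <- function(i) {
    out <- rep(NA_character_, n_total)
    out[long_enough] <- vapply(fields[long_enough], `[[`, "", i)
    out
  }
  name <- trimws(get_col(columns$str))
  sab <- get_col(columns$sab)
  tty <- get_col(columns$tty)
  rxcui <- get_col(columns$rxcui)
  ok <- long_enough & nzchar(name) & nzchar(sab) & nzchar(tty)
  ok[is.na(ok)] <- FALSE

  diag <- list(
    total_lines = n_total,
    well_formed = sum(ok),
    skipped = n_total - sum(ok),
    skipped_short = sum(!long_enough),
    skipped_empty_field = sum(long_enough & !ok),
    repaired_encoding = sum(bad_enc),
    filtered_language = 0L,
    filtered_suppressed = 0L
  )

  keep <- ok
  if (!is.null(languages)) {
    lat <- get_col(columns$lat)
    drop <- keep & !(lat %in% languages)
    diag$filtered_language <- sum(drop)
    keep <- keep & !drop
  }
  if (isTRUE(drop_suppressed) && any(nf >= columns$suppress)) {
    supp <- rep(NA_character_, n_total)
    has <- nf >= columns$suppress
    supp[has] <- vapply(fields[has], `[[`, "", columns$suppress)
    drop <- keep & !is.na(supp) & supp %in% c("Y", "E", "O")
    diag$filtered_suppressed <- sum(drop)
    keep <- keep & !drop
  }
  if (diag$well_formed == 0L) {
    stop_data("no well-formed RRF lines in ", path,
              " (", diag$skipped, " of ", n_total, " lines skipped)")
  }
  entries <- data.frame(
    concept_id = rxcui[keep],
    source = sab[keep],
    term_type = tty[keep],
    name = name[keep],
    stringsAsFactors = FALSE
  )
  attr(entries, "diagnostics") <- diag
  entries
}

#' Parse diagnostics of an RRF read
#'
#' @param entries the data frame returned by [parse_rrf()].
#' @return A list of line counts: `total_lines`, `well_formed`, `skipped`
#'   (malformed), `skipped_short`, `skipped_empty_field`, `repaired_encoding`,
#'   `filtered_language`, `filtered_suppressed`. `well_formed + skipped`
#'   always equals `total_lines`.
#' @export
rrf_diagnostics <- function(entries) attr(entries, "diagnostics")

#' Construct a document corpus
#'
#' @param doc_id character vector of unique document ids.
#' @param text character vector of document bodies (may be empty strings).
#' @return A data frame of class `rx_corpus` with columns `doc_id`, `text`.
#' @export
corpus <- function(doc_id, text) {
  doc_id <- as.character(doc_id)
  text <- as.character(text)
  stopifnot(length(doc_id) == length(text))
  if (anyDuplicated(doc_id)) {
    stop_data("duplicate doc_id in corpus: ",
              paste(unique(doc_id[duplicated(doc_id)]), collapse = ", "))
  }
  text[is.na(text)] <- ""
  structure(
    data.frame(doc_id = doc_id, text = text, stringsAsFactors = FALSE),
    class = c("rx_corpus", "data.frame")
  )
}

#' Load a text corpus from disk
#'
#' Accepts either a directory of `*.txt` files (one document per file, the
#' file stem is the document id) or a JSON-lines file with one
#' `{"id": ..., "text": ...}` record per line.
#'
#' @param path directory or JSON-lines file.
#' @return An [corpus()] data frame.
#' @export
load_corpus <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop_data("corpus path not found: ", path)
  }
  if (dir.exists(path)) {
    files <- sort_c(list.files(path, pattern = "\\.txt$", full.names = FALSE))
    texts <- vapply(files, function(f) {
      paste(readLines(file.path(path, f), warn = FALSE, encoding = "UTF-8"),
            collapse = "\n")
    }, "")
    return(corpus(sub("\\.txt$", "", files), unname(texts)))
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON)
  ids <- vapply(recs, function(r) as.character(r$id %||% stop_data(
    "corpus record missing 'id' field")), "")
  txt <- vapply(recs, function(r) as.character(r$text %||% ""), "")
  corpus(ids, txt)
}

#' Write a corpus to disk
#'
#' @param x an [corpus()] data frame.
#' @param path output file (JSON-lines) or directory (`format = "dir"`).
#' @param format `"jsonl"` (default) or `"dir"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(x, path, format = c("jsonl", "dir")) {
  format <- match.arg(format)
  if (format == "dir") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(nrow(x))) {
      writeLines(x$text[i], file.path(path, paste0(x$doc_id[i], ".txt")),
                 useBytes = TRUE)
    }
  } else {
    con <- file(path, open = "wb")
    on.exit(close(con))
    for (i in seq_len(nrow(x))) {
      writeLines(jsonlite::toJSON(list(id = x$doc_id[i], text = x$text[i]),
                                  auto_unbox = TRUE), con, useBytes = TRUE)
    }
  }
  invisible(path)
}

# ---- lexicon and result writers -------------------------------------------

#' Write a refined lexicon as TSV
#'
#' Columns: `name`, `char_length`, `sources` (semicolon-joined), `term_types`
#' (semicolon-joined). Rows are sorted by name under C collation so identical
#' inputs always produce byte-identical files.
#'
#' @param lexicon a lexicon data frame (see [build_lexicon()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  df <- data.frame(
    name = lexicon$name,
    char_length = lexicon$char_length,
    sources = vapply(lexicon$sources, function(s) paste(sort_c(s), collapse = ";"), ""),
    term_types = vapply(lexicon$term_types, function(s) paste(sort_c(s), collapse = ";"), ""),
    stringsAsFactors = FALSE
  )
  df <- df[order_c(df$name), , drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = "\t"), con, useBytes = TRUE)
  if (nrow(df)) {
    writeLines(do.call(paste, c(unname(df), sep = "\t")), con, useBytes = TRUE)
  }
  invisible(path)
}

#' Read a lexicon TSV written by [write_lexicon()]
#'
#' @param path TSV file.
#' @return A lexicon data frame with list columns `sources`, `term_types`.
#' @export
read_lexicon <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          colClasses = c("character", "integer",
                                         "character", "character"))
  new_lexicon(df$name,
              sources = strsplit(df$sources, ";", fixed = TRUE),
              term_types = strsplit(df$term_types, ";", fixed = TRUE))
}

#' Write a match table as TSV
#'
#' Columns `doc_id`, `name`, `start_token`, `end_token`; rows sorted by
#' doc id, then start token, then span length, then name.
#'
#' @param matches data frame from [match_corpus()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_matches <- function(matches, path) {
  o <- order_c(matches$doc_id, matches$start_token,
               matches$end_token - matches$start_token, matches$name)
  df <- matches[o, c("doc_id", "name", "start_token", "end_token"), drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = "\t"), con, useBytes = TRUE)
  if (nrow(df)) {
    writeLines(do.call(paste, c(unname(df), sep = "\t")), con, useBytes = TRUE)
  }
  invisible(path)
}

#' Write a refinement report as JSON
#'
#' @param report a [refinement_report()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write the standard output bundle of a refinement run
#'
#' Writes the refined lexicon (`lexicon.tsv`), the stage report
#' (`report.json`) and, when supplied, a match table (`matches.tsv`) into
#' `out_dir`. All writers are deterministic: identical inputs produce
#' byte-identical files.
#'
#' @param lexicon lexicon data frame.
#' @param report [refinement_report()] object.
#' @param matches optional match table.
#' @param out_dir output directory (created if missing).
#' @return Named character vector of the files written, invisibly.
#' @export
write_outputs <- function(lexicon, report, matches = NULL, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    lexicon = write_lexicon(lexicon, file.path(out_dir, "lexicon.tsv")),
    report = write_report(report, file.path(out_dir, "report.json"))
  )
  if (!is.null(matches)) {
    files <- c(files,
               matches = write_matches(matches, file.path(out_dir, "matches.tsv")))
  }
  invisible(files)
}
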