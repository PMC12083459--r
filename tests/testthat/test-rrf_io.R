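# RRF parsing, corpus IO, and the deterministic writers.

make_rrf_line <- function(rxcui = "198440", sab = "RXNORM", tty = "SCD",
                          str = "Acetaminophen 325 MG Oral Tablet",
                          n_fields = 18L) {
  f <- rep("", n_fields)
  f[1] <- rxcui; f[2] <- "ENG"; f[12] <- sab; f[13] <- tty; f[15] <- str
  f[17] <- "N"
  paste0(paste(f, collapse = "|"), "|")
}

test_that("a standard RXNCONSO line yields one raw entry", {
  path <- withr::local_tempfile(fileext = ".rrf")
  writeLines(make_rrf_line(), path)
  e <- parse_rrf(path)
  expect_identical(nrow(e), 1L)
  expect_identical(e$name, "Acetaminophen 325 MG Oral Tablet")
  expect_identical(e$source, "RXNORM")
  expect_identical(e$term_type, "SCD")
  expect_identical(e$concept_id, "198440")
})

test_that("missing and empty files are fatal", {
  expect_error(parse_rrf(file.path(tempdir(), "no-such-file.rrf")),
               "not found")
  path <- withr::local_tempfile(fileext = ".rrf")
  file.create(path)
  expect_error(parse_rrf(path), "no well-formed")
})

test_that("malformed lines are skipped and audited against a field count", {
  set.seed(7)
  good <- vapply(1:40, function(i)
    make_rrf_line(rxcui = as.character(i), str = paste0("drug", i)), "")
  bad <- c(
    make_rrf_line(str = ""),                    # empty STR
    make_rrf_line(sab = ""),                    # empty SAB
    paste(rep("x", 5), collapse = "|"),         # too few fields
    "1|ENG|short",                              # too few fields
    make_rrf_line(str = "   ")                  # whitespace-only STR
  )
  lines <- sample(c(good, bad))
  path <- withr::local_tempfile(fileext = ".rrf")
  writeLines(lines, path)
  e <- parse_rrf(path)
  d <- rrf_diagnostics(e)

  # brute-force audit: split each line on the pipe and count usable fields
  audit_ok <- vapply(lines, function(l) {
    f <- strsplit(l, "|", fixed = TRUE)[[1]]
    length(f) >= 15 && nzchar(trimws(f[15])) && nzchar(f[12]) && nzchar(f[13])
  }, TRUE)
  expect_identical(nrow(e), sum(audit_ok))
  expect_identical(d$skipped, sum(!audit_ok))
  expect_identical(d$well_formed + d$skipped, d$total_lines)
  expect_identical(d$total_lines, length(lines))
})

test_that("STR whitespace is trimmed and input order preserved", {
  path <- withr::local_tempfile(fileext = ".rrf")
  writeLines(c(make_rrf_line(str = "  Aspirin  "),
               make_rrf_line(str = "Tylenol")), path)
  e <- parse_rrf(path)
  expect_identical(e$name, c("Aspirin", "Tylenol"))
})

test_that("column overrides, language and suppression filters work", {
  path <- withr::local_tempfile(fileext = ".rrf")
  # nonstandard 5-column layout: rxcui, lat, sab, tty, str
  writeLines(c("1|ENG|DB|IN|Aspirin|",
               "2|SPA|DB|IN|Aspirina|"), path)
  cols <- rrf_columns(rxcui = 1, lat = 2, sab = 3, tty = 4, str = 5,
                      suppress = 6)
  e <- parse_rrf(path, columns = cols)
  expect_identical(e$name, c("Aspirin", "Aspirina"))
  e_eng <- parse_rrf(path, columns = cols, languages = "ENG")
  expect_identical(e_eng$name, "Aspirin")
  expect_identical(rrf_diagnostics(e_eng)$filtered_language, 1L)

  path2 <- withr::local_tempfile(fileext = ".rrf")
  writeLines(c(make_rrf_line(str = "Keep me"),
               sub("\\|N\\|", "|Y|", make_rrf_line(str = "Suppress me"))),
             path2)
  e2 <- parse_rrf(path2, drop_suppressed = TRUE)
  expect_identical(e2$name, "Keep me")
})

test_that("generator-written RRF files are recovered exactly", {
  fx <- generate_fixture(fixture_config(seed = 11, n_base_names = 15L),
                         out_dir = withr::local_tempdir())
  e <- parse_rrf(fx$paths[["rrf"]])
  expect_identical(e$name, fx$entries$name)
  expect_identical(e$source, fx$entries$source)
  expect_identical(e$term_type, fx$entries$term_type)
  expect_identical(e$concept_id, fx$entries$concept_id)
  expect_identical(rrf_diagnostics(e)$skipped, 0L)
})

test_that("corpora load from directories and JSON-lines files", {
  d <- withr::local_tempdir()
  writeLines("APAP overdose", file.path(d, "a.txt"))
  file.create(file.path(d, "b.txt"))
  corp <- load_corpus(d)
  expect_identical(corp$doc_id, c("a", "b"))
  expect_identical(corp$text[1], "APAP overdose")
  expect_identical(nchar(corp$text[2]), 0L)

  f <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(corp, f)
  again <- load_corpus(f)
  expect_identical(as.data.frame(again), as.data.frame(corp))
  # byte-identical round trip of the serialized form
  f2 <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(again, f2)
  expect_identical(readBin(f, "raw", file.size(f)),
                   readBin(f2, "raw", file.size(f2)))

  expect_error(corpus(c("a", "a"), c("x", "y")), "duplicate doc_id")
})

test_that("lexicon TSV writing is deterministic and round-trips exactly", {
  lex <- new_lexicon(
    c("Aspirin", "apap", "Acetaminophen 325 MG Oral Tablet"),
    sources = list(c("DB", "RXNORM"), "MSH", "RXNORM"),
    term_types = list("IN", c("SY", "IN"), "SCD")
  )
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon(lex, f1)
  write_lexicon(lex[sample(nrow(lex)), , drop = FALSE], f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  back <- read_lexicon(f1)
  o <- order(lex$name, method = "radix")
  expect_identical(back$name, lex$name[o])
  expect_identical(back$char_length, lex$char_length[o])
  expect_identical(back$sources,
                   lapply(lex$sources[o], function(s) sort(s, method = "radix")))

  # empty lexicon: header-only file
  f3 <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon(lex[0, , drop = FALSE], f3)
  expect_identical(readLines(f3), "name\tchar_length\tsources\tterm_types")
})

test_that("the output bundle writes lexicon, report and matches", {
  wx <- worked_example_fixture()
  matches <- match_corpus(compile_matcher(wx$names), wx$corpus)
  rep <- refinement_report(4L, 1L, 1L, 0L, 0L, 0L, 2L, 1L, 1L, 0L)
  d <- withr::local_tempdir()
  lex <- new_lexicon(wx$names, sources = list("RXNORM", "RXNORM"),
                     term_types = list("IN", "SCD"))
  files <- write_outputs(lex, rep, matches, d)
  expect_true(all(file.exists(files)))
  got <- jsonlite::fromJSON(file.path(d, "report.json"))
  expect_identical(got$total_extracted, 4L)
  expect_identical(got$refined_total, 1L)
  m <- utils::read.delim(file.path(d, "matches.tsv"))
  expect_identical(nrow(m), 2L)
})
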