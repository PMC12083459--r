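# Deduplication, term-type filtering, length stratification, the short-name
# corpus filter, and the assembled pipeline report.

raw <- function(name, source = "RXNORM", term_type = "IN") {
  n <- length(name)
  data.frame(name = name, source = rep_len(source, n),
             term_type = rep_len(term_type, n), stringsAsFactors = FALSE)
}

test_that("deduplication merges identical strings and unions provenance", {
  e <- rbind(raw("Aspirin", "DB"), raw("Aspirin", "RXNORM", "SY"))
  bl <- build_lexicon(e)
  expect_identical(nrow(bl$lexicon), 1L)
  expect_identical(bl$duplicates_removed, 1L)
  expect_identical(bl$lexicon$sources[[1]], c("DB", "RXNORM"))
  expect_identical(bl$lexicon$term_types[[1]], c("IN", "SY"))

  # case sensitivity is configurable; trimming is not
  e2 <- rbind(raw("Aspirin"), raw("aspirin"), raw(" Aspirin "))
  expect_identical(nrow(build_lexicon(e2)$lexicon), 2L)
  cfg <- refinement_config(dedup_case_sensitive = FALSE)
  expect_identical(nrow(build_lexicon(e2, cfg)$lexicon), 1L)

  empty <- build_lexicon(raw(character()))
  expect_identical(nrow(empty$lexicon), 0L)
  expect_identical(empty$duplicates_removed, 0L)
})

test_that("distinct-name counts match a hash-set oracle on random multisets", {
  set.seed(23)
  for (rep in 1:20) {
    pool <- paste0("drug", seq_len(sample(5:40, 1)))
    nms <- sample(pool, sample(10:200, 1), replace = TRUE)
    bl <- build_lexicon(raw(nms))
    expect_identical(nrow(bl$lexicon), length(unique(nms)))
    expect_identical(bl$duplicates_removed,
                     length(nms) - length(unique(nms)))
    # sources of each entry = all sources seen for that string
    e <- raw(nms, source = sample(rx_sab_codes, length(nms), replace = TRUE))
    bl2 <- build_lexicon(e)
    for (i in seq_len(nrow(bl2$lexicon))) {
      nm <- bl2$lexicon$name[i]
      expect_identical(bl2$lexicon$sources[[i]],
                       sort(unique(e$source[e$name == nm]), method = "radix"))
    }
  }
})

test_that("only purely administrative entries are removed", {
  lex <- new_lexicon(c("Oral Tablet", "Daytrana", "Chewable Product"),
                     sources = list("RXNORM", "MMSL", "RXNORM"),
                     term_types = list("DF", c("BN", "DF"), "DFG"))
  ft <- filter_term_types(lex)
  expect_identical(ft$removed$name, c("Oral Tablet", "Chewable Product"))
  # a name that also carries a drug-specific TTY survives
  expect_identical(ft$retained$name, "Daytrana")

  # planted count on a fixture
  fx <- generate_fixture(fixture_config(seed = 5, n_admin_rows = 9L))
  bl <- build_lexicon(fx$entries)
  ft2 <- filter_term_types(bl$lexicon)
  expect_identical(nrow(ft2$removed), 9L)
})

test_that("length classes partition the lexicon at the configured bounds", {
  nm <- c("APAP", strrep("b", 5), strrep("c", 199), strrep("d", 200), "x")
  lex <- new_lexicon(nm, sources = as.list(rep("DB", 5)),
                     term_types = as.list(rep("IN", 5)))
  cl <- categorize_by_length(lex)
  expect_identical(cl$short$name, c("APAP", "x"))
  expect_identical(cl$mid$name, c(strrep("b", 5), strrep("c", 199)))
  expect_identical(cl$long$name, strrep("d", 200))

  set.seed(4)
  lens <- sample(1:260, 1000, replace = TRUE)
  nms <- unique(vapply(lens, function(L)
    paste0(sample(c(letters, 0:9), L, replace = TRUE), collapse = ""), ""))
  lex2 <- new_lexicon(nms, sources = as.list(rep("DB", length(nms))),
                      term_types = as.list(rep("IN", length(nms))))
  cl2 <- categorize_by_length(lex2)
  lens2 <- nchar(nms)
  expect_identical(nrow(cl2$short), sum(lens2 <= 4))
  expect_identical(nrow(cl2$mid), sum(lens2 > 4 & lens2 <= 199))
  expect_identical(nrow(cl2$long), sum(lens2 > 199))
  expect_identical(nrow(cl2$short) + nrow(cl2$mid) + nrow(cl2$long),
                   length(nms))
})

test_that("short names need corpus evidence to survive", {
  lex <- new_lexicon(c("apap", "QZXV"), sources = list("MSH", "DB"),
                     term_types = list("SY", "SY"))
  corp <- corpus("d1", "after APAP the patient improved")
  fs <- filter_short_names(lex, corp)
  expect_identical(fs$retained$name, "apap")
  expect_identical(fs$retained$occurrences, 1L)
  expect_identical(fs$removed$name, "QZXV")
  expect_identical(fs$removed$occurrences, 0L)

  expect_error(filter_short_names(lex, corpus(character(), character())),
               "non-empty corpus")
  # the stage can be disabled explicitly
  cfg0 <- refinement_config(min_corpus_occurrences = 0)
  fs0 <- filter_short_names(lex, NULL, cfg0)
  expect_identical(fs0$retained$name, c("apap", "QZXV"))
})

test_that("raising the occurrence threshold never grows the retained set", {
  fx <- generate_fixture(fixture_config(seed = 31))
  bl <- build_lexicon(fx$entries)
  cl <- categorize_by_length(filter_term_types(bl$lexicon)$retained)
  prev <- Inf
  for (thr in c(1L, 2L, 3L, 5L)) {
    cfg <- refinement_config(min_corpus_occurrences = thr)
    n_ret <- nrow(filter_short_names(cl$short, fx$corpus, cfg)$retained)
    expect_lte(n_ret, prev)
    prev <- n_ret
  }
})

test_that("the report constructor enforces the conservation identities", {
  rep <- refinement_report(100L, 20L, 5L, 10L, 4L, 6L, 60L, 15L, 45L, 5L)
  expect_identical(rep$refined_total, 21L)
  expect_error(refinement_report(99L, 20L, 5L, 10L, 4L, 6L, 60L, 15L, 45L, 5L),
               "conservation")
  expect_error(refinement_report(100L, 20L, 5L, 10L, 3L, 6L, 60L, 15L, 45L, 5L),
               "short class")
  expect_error(refinement_report(100L, 20L, 5L, 10L, 4L, 6L, 60L, 15L, 44L, 5L),
               "mid class")
})

test_that("report percentages use half-up rounding against the raw total", {
  # 269931 / 1143201 * 100 = 23.6118... -> 23.61 at two decimals
  expect_identical(rxlexr:::round_half_up(269931 / 1143201 * 100, 2), 23.61)
  expect_identical(rxlexr:::round_half_up(1009 / 1143201 * 100, 2), 0.09)
  expect_identical(rxlexr:::round_half_up(687 / 1143201 * 100, 2), 0.06)
  expect_identical(rxlexr:::round_half_up(751981 / 1143201 * 100, 2), 65.78)
  expect_identical(rxlexr:::round_half_up(17529 / 1143201 * 100, 2), 1.53)
  # half-up at the boundary, where round() would go to even
  expect_identical(rxlexr:::round_half_up(0.125, 2), 0.13)
  expect_identical(rxlexr:::round_half_up(12.345, 2), 12.35)
})

test_that("refine is idempotent on its own output", {
  fx <- generate_fixture(fixture_config(seed = 77))
  fit <- refine(fx$entries, fx$corpus)
  fit2 <- refine(entries_from_refined(fit), fx$corpus, fit$config)
  expect_identical(fit2$report$duplicates_removed, 0L)
  expect_identical(fit2$report$non_drug_removed, 0L)
  expect_identical(fit2$report$short_removed, 0L)
  expect_identical(fit2$report$mid_removed_containing, 0L)
  expect_identical(fit2$report$long_removed, 0L)
  expect_identical(sort(fit2$lexicon$name, method = "radix"),
                   sort(fit$lexicon$name, method = "radix"))
})

test_that("every refined entry is matchable-length and non-administrative", {
  fx <- generate_fixture(fixture_config(seed = 13))
  fit <- refine(fx$entries, fx$corpus)
  cfg <- fit$config
  expect_true(all(fit$lexicon$char_length >= 1 &
                    fit$lexicon$char_length <= cfg$mid_max))
  expect_true(all(vapply(fit$lexicon$term_types, function(t)
    length(setdiff(t, cfg$excluded_term_types)) > 0, TRUE)))
})

test_that("shrinking the mid range never grows the mid class", {
  fx <- generate_fixture(fixture_config(seed = 19))
  bl <- build_lexicon(fx$entries)
  lex <- filter_term_types(bl$lexicon)$retained
  prev <- Inf
  for (mm in c(199L, 60L, 30L, 12L)) {
    n_mid <- nrow(categorize_by_length(lex, refinement_config(mid_max = mm))$mid)
    expect_lte(n_mid, prev)
    prev <- n_mid
  }
})

test_that("the tty-first stage order filters raw rows before deduplication", {
  e <- rbind(raw("Oral Tablet", "RXNORM", "DF"),
             raw("Oral Tablet", "DB", "DF"),
             raw("Aspirin", "DB", "IN"))
  cfg <- refinement_config(min_corpus_occurrences = 0,
                           stage_order = "tty_first")
  fit <- refine(e, config = cfg)
  expect_identical(fit$report$non_drug_removed, 2L)  # rows, not names
  expect_identical(fit$report$duplicates_removed, 0L)
  expect_identical(fit$report$total_extracted, 3L)
  expect_identical(fit$lexicon$name, "Aspirin")
})
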