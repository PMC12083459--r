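# Synthetic fixture generation: RRF-like concept files, corpora with planted
# name occurrences, and a constructive ground-truth manifest. The manifest is
# computed from the generator's own bookkeeping while the data is built —
# never by running the refinement pipeline — so it is an independent oracle
# for end-to-end tests.

#' Discrete distribution specification
#'
#' @param values vector of possible values.
#' @param probs optional probabilities (uniform when omitted).
#' @return A list of class `dist_spec`.
#' @export
dist_spec <- function(values, probs = NULL) {
  if (!is.null(probs)) {
    stopifnot(length(probs) == length(values), all(probs >= 0),
              abs(sum(probs) - 1) < 1e-8)
  }
  structure(list(values = values, probs = probs), class = "dist_spec")
}

sample_dist <- function(spec, n) {
  if (length(spec$values) == 1L) return(rep(spec$values, n))
  sample(spec$values, n, replace = TRUE, prob = spec$probs)
}

#' Fixture generator configuration
#'
#' Controls the synthetic RxNorm-like dataset: how many base ingredient
#' names, how many sources and duplicate rows each name carries, how many
#' dose-form expansions word-contain each base, how many purely
#' administrative rows, ultra-long names and short abbreviations exist, and
#' how the evaluation corpus is built. Defaults mirror the structure of a
#' real release at bench scale: most names are single-sourced, dose-form
#' expansions dominate the mid-length class, and a bit under half of the
#' short abbreviations actually occur in drug-related text.
#'
#' @param seed integer RNG seed; a fixed seed yields byte-identical output.
#' @param n_base_names number of synthetic ingredient names (single words of
#'   6-14 characters, always in the mid class).
#' @param n_sources_per_name [dist_spec()] over 1..14 source counts.
#' @param dup_rows_per_name [dist_spec()] of extra duplicate rows per base.
#' @param n_dose_expansions_per_name [dist_spec()] of dose-form expansions
#'   per base (`"<base> <dose> <unit> [<form>]"`, strictly word-containing
#'   the base by construction).
#' @param n_admin_rows number of purely administrative (DF/DFG/SC) entries.
#' @param n_long_names number of names of 200+ characters.
#' @param n_short_abbrevs number of 2-4 character abbreviations.
#' @param plant_fraction fraction of abbreviations and base names planted
#'   into the corpus.
#' @param n_documents corpus size.
#' @param words_per_document [dist_spec()] of filler words per document.
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1L,
                           n_base_names = 60L,
                           n_sources_per_name = dist_spec(
                             1:14, c(0.80, 0.12, 0.05, 0.02, 0.005, 0.005,
                                     rep(0, 8))),
                           dup_rows_per_name = dist_spec(
                             0:3, c(0.75, 0.15, 0.07, 0.03)),
                           n_dose_expansions_per_name = dist_spec(
                             0:12, c(0.02, 0.02, 0.04, 0.06, 0.08, 0.10,
                                     0.12, 0.14, 0.12, 0.10, 0.08, 0.07,
                                     0.05)),
                           n_admin_rows = 6L,
                           n_long_names = 4L,
                           n_short_abbrevs = 14L,
                           plant_fraction = 0.45,
                           n_documents = 60L,
                           words_per_document = dist_spec(25:60)) {
  stopifnot(is_count(seed) || (is.numeric(seed) && seed == floor(seed)),
            is_count(n_base_names), is_count(n_admin_rows),
            is_count(n_long_names), is_count(n_short_abbrevs),
            is_count(n_documents),
            plant_fraction >= 0, plant_fraction <= 1,
            inherits(n_sources_per_name, "dist_spec"),
            inherits(dup_rows_per_name, "dist_spec"),
            inherits(n_dose_expansions_per_name, "dist_spec"),
            inherits(words_per_document, "dist_spec"))
  structure(list(
    seed = as.integer(seed),
    n_base_names = as.integer(n_base_names),
    n_sources_per_name = n_sources_per_name,
    dup_rows_per_name = dup_rows_per_name,
    n_dose_expansions_per_name = n_dose_expansions_per_name,
    n_admin_rows = as.integer(n_admin_rows),
    n_long_names = as.integer(n_long_names),
    n_short_abbrevs = as.integer(n_short_abbrevs),
    plant_fraction = plant_fraction,
    n_documents = as.integer(n_documents),
    words_per_document = words_per_document
  ), class = "fixture_config")
}

# pronounceable gibberish from consonant-vowel syllables
.gen_words <- function(n, n_syll_min, n_syll_max, avoid = character()) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  out <- character(0)
  avoid <- unique(avoid)
  guard <- 0L
  while (length(out) < n) {
    guard <- guard + 1L
    if (guard > 50000L) stop("fixture word generation failed to converge")
    k <- sample(n_syll_min:n_syll_max, 1L)
    w <- paste0(paste0(sample(cons, k, replace = TRUE),
                       sample(vow, k, replace = TRUE)), collapse = "")
    if (!(w %in% avoid) && !(w %in% out)) out <- c(out, w)
  }
  out
}

.admin_pool <- c("oral tablet", "chewable product", "medical supplies",
                 "prefilled syringe", "topical cream", "oral solution",
                 "dose pack", "inhalation powder", "injectable product",
                 "transdermal system", "ophthalmic irrigation",
                 "drug implant product")

.drug_ttys <- c("IN", "BN", "PIN", "SY", "SCD", "SBD", "SCDC")

.dose_vocab <- list(doses = c("5", "10", "25", "50", "100", "250", "325", "500"),
                    units = c("mg", "ml", "mcg"),
                    forms = list(c("oral", "tablet"), c("chewable", "tablet"),
                                 c("oral", "solution"),
                                 c("extended", "release", "capsule"),
                                 character(0)))

#' Generate a synthetic refinement fixture
#'
#' Builds an RRF-like concept file, a document corpus with planted name
#' occurrences, and a [`FixtureManifest`]-style ground-truth list, all
#' deterministically from `config$seed`. The synthetic dataset contains, in
#' known numbers: exact-duplicate rows contributed by multiple sources,
#' purely administrative DF/DFG/SC rows, dose-form-expanded names that
#' strictly word-contain their base ingredient, names of 200+ characters,
#' and 2-4 character abbreviations of which a known subset is planted into
#' the corpus. Document filler words are drawn from a vocabulary disjoint
#' from every name word, so planted occurrence counts are exact by
#' construction.
#'
#' @param config a [fixture_config()].
#' @param out_dir optional directory; when given, writes `rxnconso.rrf`,
#'   `corpus.jsonl` and `manifest.json` there.
#' @return A list with `entries` (raw entry data frame in RRF row order),
#'   `corpus` (an [corpus()]), `manifest` (see Details) and, when `out_dir`
#'   is given, `paths`. The manifest holds `report` (every expected
#'   refinement-report count and percentage), `plant_plan` (planted name ->
#'   per-document counts), `planted_short`/`unplanted_short`,
#'   `planted_base`, and `mid_source_plan` (per-source provided/removed
#'   counts over the mid class plus `single_sourced_removed`).
#' @export
generate_fixture <- function(config = fixture_config(), out_dir = NULL) {
  stopifnot(inherits(config, "fixture_config"))
  res <- with_seed(config$seed, .generate_fixture_impl(config))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    rrf_path <- file.path(out_dir, "rxnconso.rrf")
    .write_fixture_rrf(res$entries, rrf_path)
    corpus_path <- file.path(out_dir, "corpus.jsonl")
    write_corpus(res$corpus, corpus_path)
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(res$manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    res$paths <- c(rrf = rrf_path, corpus = corpus_path,
                   manifest = manifest_path)
  }
  res
}

.generate_fixture_impl <- function(config) {
  reserved <- unique(c(unlist(.dose_vocab$forms), .dose_vocab$units,
                       .dose_vocab$doses,
                       unlist(strsplit(.admin_pool, " ", fixed = TRUE))))

  base_names <- .gen_words(config$n_base_names, 3L, 7L, avoid = reserved)
  base_names <- base_names[nchar(base_names) >= 6L & nchar(base_names) <= 14L]
  while (length(base_names) < config$n_base_names) {
    more <- .gen_words(config$n_base_names - length(base_names), 3L, 7L,
                       avoid = c(reserved, base_names))
    base_names <- c(base_names, more[nchar(more) >= 6L & nchar(more) <= 14L])
  }

  # dose-form expansions: strict word-set supersets of their base
  combos <- expand.grid(d = seq_along(.dose_vocab$doses),
                        u = seq_along(.dose_vocab$units),
                        f = seq_along(.dose_vocab$forms))
  n_exp_per_base <- sample_dist(config$n_dose_expansions_per_name,
                                config$n_base_names)
  n_exp_per_base <- pmin(n_exp_per_base, nrow(combos))
  expansions <- character(0)
  exp_base <- character(0)
  for (b in seq_along(base_names)) {
    k <- n_exp_per_base[b]
    if (k == 0L) next
    pick <- combos[sample(nrow(combos), k), , drop = FALSE]
    for (j in seq_len(k)) {
      parts <- c(base_names[b], .dose_vocab$doses[pick$d[j]],
                 .dose_vocab$units[pick$u[j]],
                 .dose_vocab$forms[[pick$f[j]]])
      expansions <- c(expansions, paste(parts, collapse = " "))
      exp_base <- c(exp_base, base_names[b])
    }
  }

  stopifnot(config$n_admin_rows <= length(.admin_pool))
  admin_names <- if (config$n_admin_rows > 0L)
    sample(.admin_pool, config$n_admin_rows) else character(0)

  long_names <- character(0)
  while (length(long_names) < config$n_long_names) {
    w <- .gen_words(sample(28:40, 1L), 2L, 4L,
                    avoid = c(reserved, base_names))
    nm <- paste(w, collapse = " ")
    if (nchar(nm) >= 200L && !(nm %in% long_names)) {
      long_names <- c(long_names, nm)
    }
  }

  # abbreviations: unique lowercase forms, disjoint from every name word
  name_words <- unique(c(base_names, reserved,
                         unlist(strsplit(long_names, " ", fixed = TRUE))))
  abbrevs <- character(0)
  guard <- 0L
  while (length(abbrevs) < config$n_short_abbrevs) {
    guard <- guard + 1L
    if (guard > 50000L) stop("fixture abbreviation generation failed")
    a <- paste0(sample(LETTERS, sample(2:4, 1L), replace = TRUE),
                collapse = "")
    if (!(tolower(a) %in% name_words) &&
        !(tolower(a) %in% tolower(abbrevs))) {
      abbrevs <- c(abbrevs, a)
    }
  }

  # assemble raw rows with per-name source/term-type bookkeeping
  all_names <- c(base_names, expansions, admin_names, long_names, abbrevs)
  stopifnot(!anyDuplicated(all_names))
  kind <- rep(c("base", "expansion", "admin", "long", "abbrev"),
              c(length(base_names), length(expansions), length(admin_names),
                length(long_names), length(abbrevs)))
  n_names <- length(all_names)
  src_counts <- sample_dist(config$n_sources_per_name, n_names)
  src_counts[kind == "admin"] <- 1L
  src_counts[kind == "long"] <- 1L   # long names are single-sourced
  name_sources <- lapply(src_counts, function(k) sample(rx_sab_codes, k))
  dup_extra <- integer(n_names)
  dup_extra[kind == "base"] <- sample_dist(config$dup_rows_per_name,
                                           sum(kind == "base"))

  rows <- vector("list", n_names)
  for (i in seq_len(n_names)) {
    srcs <- c(name_sources[[i]],
              if (dup_extra[i] > 0L)
                sample(name_sources[[i]], dup_extra[i], replace = TRUE))
    tty <- if (kind[i] == "admin") sample(c("DF", "DFG", "SC"), 1L)
           else sample(.drug_ttys, 1L)
    rows[[i]] <- data.frame(
      concept_id = sprintf("C%06d", i),
      source = srcs,
      term_type = tty,
      name = all_names[i],
      stringsAsFactors = FALSE
    )
  }
  entries <- do.call(rbind, rows)
  entries <- entries[sample(nrow(entries)), , drop = FALSE]
  rownames(entries) <- NULL

  # corpus: filler vocabulary disjoint from every token of every name
  all_name_tokens <- unique(c(name_words, tolower(abbrevs)))
  filler <- .gen_words(120L, 2L, 4L, avoid = all_name_tokens)
  docs <- lapply(sample_dist(config$words_per_document, config$n_documents),
                 function(k) sample(filler, k, replace = TRUE))
  doc_ids <- sprintf("doc%03d", seq_len(config$n_documents))

  plantable <- c(abbrevs, base_names)
  planted <- plantable[stats::runif(length(plantable)) < config$plant_fraction]
  plant_plan <- list()
  for (nm in planted) {
    per_doc <- integer(0)
    for (occ in seq_len(sample(1:3, 1L))) {
      d <- sample(config$n_documents, 1L)
      pos <- sample(0:length(docs[[d]]), 1L)
      docs[[d]] <- append(docs[[d]], nm, after = pos)
      per_doc[doc_ids[d]] <- (if (doc_ids[d] %in% names(per_doc))
        per_doc[[doc_ids[d]]] else 0L) + 1L
    }
    plant_plan[[nm]] <- as.list(per_doc)
  }
  # random sentence-casing of filler exercises the lowercasing contract
  texts <- vapply(docs, function(tk) {
    if (length(tk) == 0L) return("")
    cap <- stats::runif(length(tk)) < 0.15
    tk[cap] <- paste0(toupper(substr(tk[cap], 1L, 1L)),
                      substring(tk[cap], 2L))
    paste0(paste(tk, collapse = " "), ".")
  }, "")
  corp <- corpus(doc_ids, texts)

  # constructive manifest ----------------------------------------------------
  planted_short <- intersect(abbrevs, planted)
  total <- nrow(entries)
  n_distinct <- n_names
  pct <- function(k) {
    if (total == 0L) 0 else floor(round(k / total * 100 * 100, 9) + 0.5) / 100
  }
  report <- list(
    total_extracted = total,
    duplicates_removed = total - n_distinct,
    non_drug_removed = length(admin_names),
    short_total = length(abbrevs),
    short_removed = length(abbrevs) - length(planted_short),
    short_retained = length(planted_short),
    mid_total = length(base_names) + length(expansions),
    mid_retained_distinct = length(base_names),
    mid_removed_containing = length(expansions),
    long_removed = length(long_names),
    refined_total = length(planted_short) + length(base_names),
    pct = list(
      duplicates_removed = pct(total - n_distinct),
      non_drug_removed = pct(length(admin_names)),
      short_removed = pct(length(abbrevs) - length(planted_short)),
      mid_removed_containing = pct(length(expansions)),
      long_removed = pct(length(long_names)),
      refined_total = pct(length(planted_short) + length(base_names))
    )
  )

  mid_idx <- which(kind %in% c("base", "expansion"))
  rem_idx <- which(kind == "expansion")
  prov <- table(unlist(name_sources[mid_idx]))
  remv <- table(unlist(name_sources[rem_idx]))
  mid_source_plan <- list(
    provided = as.list(prov),
    removed = as.list(remv),
    single_sourced_removed = sum(src_counts[rem_idx] == 1L)
  )

  list(entries = entries, corpus = corp,
       manifest = list(report = report,
                       plant_plan = plant_plan,
                       planted_short = planted_short,
                       unplanted_short = setdiff(abbrevs, planted_short),
                       planted_base = intersect(base_names, planted),
                       base_names = base_names,
                       expansions = expansions,
                       mid_source_plan = mid_source_plan))
}

# standard 18-column RXNCONSO layout with a trailing pipe
.write_fixture_rrf <- function(entries, path) {
  f <- matrix("", nrow = nrow(entries), ncol = 18L)
  f[, 1L] <- entries$concept_id
  f[, 2L] <- "ENG"
  f[, 12L] <- entries$source
  f[, 13L] <- entries$term_type
  f[, 15L] <- entries$name
  f[, 17L] <- "N"
  lines <- paste0(apply(f, 1L, paste, collapse = "|"), "|")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' The two-name worked example
#'
#' A minimal demonstration of the redundant-count problem: the unrefined
#' pair fires twice on the example sentence (once for the bare ingredient,
#' once for the dosed form), while the containment-refined lexicon fires
#' once.
#'
#' @return A list with `names` (the two lexicon entries) and `corpus` (a
#'   one-sentence, one-document corpus).
#' @examples
#' wx <- worked_example_fixture()
#' nrow(match_corpus(compile_matcher(wx$names), wx$corpus))          # 2
#' refined <- filter_by_containment(wx$names)$retained
#' nrow(match_corpus(compile_matcher(refined), wx$corpus))           # 1
#' @export
worked_example_fixture <- function() {
  list(
    names = c("Acetaminophen", "Acetaminophen 325 mg"),
    corpus = corpus("example-1",
                    "Acetaminophen 325 mg caused my mom's liver injury")
  )
}
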