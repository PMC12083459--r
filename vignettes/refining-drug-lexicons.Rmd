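---
title: "Refining drug-name lexicons for unstructured-text surveillance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining drug-name lexicons for unstructured-text surveillance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxlexr)
```

## The problem

Counting drug mentions in free text with a dictionary is only as good as
the dictionary. An RxNorm concept file (`RXNCONSO.RRF`) is the most
comprehensive drug-name inventory available, but it is built for clinical
interoperability, not for text mining. Four of its properties corrupt
text-derived occurrence counts:

* the same string appears on many rows, contributed by different source
  vocabularies;
* some term types (dose form DF, dose form group DFG, special category SC)
  label formulation concepts such as *oral tablet* — matching them tags
  text that mentions no drug;
* name lengths range from one character to thousands; one-to-four-character
  strings are mostly abbreviations of very uneven currency, and 200+
  character names never occur verbatim in prose;
* dose-expanded entries nest their base names, so one textual mention can
  fire several patterns and an adverse event gets counted more than once.

`rxlexr` addresses each property with one pipeline stage, and the package
exists to make that pipeline reproducible, auditable and testable.

## The pipeline

Let $N$ be the multiset of raw STR values parsed from the concept file.

1. **Deduplication.** Names are compared as exact strings after trimming
   leading/trailing whitespace. Comparison is case-sensitive by default:
   RxNorm lowercases nothing itself, and case variants of one name are
   legitimately distinct rows in the file (a case-insensitive switch is
   provided). Sources and term types of merged rows are unioned, so
   provenance survives deduplication.
2. **Administrative term types.** An entry is removed only if *all* of its
   term types are administrative. A string carrying both DF and a
   drug-specific type (e.g. a brand name that collides with a form word)
   is retained — deleting it would remove a true drug name. The excluded
   set `{DF, DFG, SC}` is configurable.
3. **Length stratification.** Short means ≤ 4 characters, mid 5–199, long
   ≥ 200 (`short_max`, `mid_max`). Characters are counted as encoded
   characters, spaces and punctuation included.
4. **Short names.** A short name survives iff its token-sequence occurrence
   count in a reference corpus is at least `min_corpus_occurrences`
   (default 1, i.e. only never-seen names are dropped). An empty corpus is
   an error rather than a silent no-op: the stage is undefined without
   evidence, and a caller who wants to skip it must say so
   (`min_corpus_occurrences = 0`).
5. **Containment.** Each mid name is lowercased and split into words on
   maximal runs of non-alphanumeric characters; the *word set* $W(x)$
   discards order and repeats. A name $a$ is removed iff some other name
   $b$ in scope satisfies $W(b) \subsetneq W(a)$. Because removal is
   defined by the global strict-inclusion relation, the result is
   independent of processing order, and the retained set is exactly the
   set of minimal word sets — an antichain: no retained pattern can start
   a match wherever another retained pattern also matches inside it. Long
   names are then removed wholesale.

The refined lexicon is the union of retained short and retained mid names.
The stage report preserves three identities on every run, enforced in the
report constructor itself:

* `total = duplicates + administrative + short_total + mid_total + long`;
* `short_total = short_retained + short_removed`, likewise for mid;
* `refined = short_retained + mid_retained`.

### Decisions where the procedure was genuinely open

* **Stage order.** Deduplication runs before the term-type filter, so the
  administrative count is a count of *names*, not rows. The opposite
  convention (filter raw rows first) changes both counts; it is available
  as `stage_order = "tty_first"` for comparing against extracts produced
  that way.
* **Class boundaries.** The short class is "four or fewer" characters and
  the long class "200 or more": with `short_max = 4` and `mid_max = 199`
  the three classes partition every lexicon, and boundary names (4, 5,
  199, 200 characters) land deterministically.
* **Equal word sets.** Two distinct strings can have identical word sets
  (*"acetaminophen 325 mg"* / *"325 mg acetaminophen"*). Mutual strict
  containment is false, but keeping both reintroduces double counting,
  and removing both silently deletes the drug from the lexicon. The
  default (`keep_canonical`) retains exactly one — the shortest string,
  ties broken lexicographically — and records it as the witness of the
  others; `remove_all` is available and marks its removals with an `NA`
  witness.
* **Containment scope.** By default mid names are compared only among
  themselves (`mid_only`). The alternative (`all_retained`) also checks
  them against retained short names, removing e.g. *"apap 500 mg"* when
  *apap* survived the corpus filter. Both semantics are useful; the
  default matches the convention of treating the mid class as a
  self-contained analysis.
* **Untokenizable names.** A name with no alphanumeric characters can
  never be matched; the pipeline removes mid-class cases at the
  containment stage with no witness, keeping the conservation identities
  intact.

## Matching

The tokenizer lowercases and emits maximal runs of Unicode letters and
digits; punctuation splits tokens, so hyphenated and apostrophized names
(*co-trimoxazole*, *mom's*) decompose identically in lexicon and text. The
same tokenizer is used on both sides by construction — most matcher bugs in
dictionary NER are tokenizer asymmetries.

`match_corpus()` reports **all** occurrences, including nested and
overlapping spans. That is deliberate: the redundant-count behaviour of an
unrefined lexicon is the phenomenon under study, and the refined lexicon's
single-firing property (an antichain cannot double-fire from one start
position) is a testable consequence rather than a matcher feature.
Patterns are indexed by first token; at each position only patterns sharing
that token are compared. `evaluate_lexicon()` summarizes the identified
fraction of a lexicon ("accuracy"), the character-length range of
identified names, and wall time — the latter recorded but never asserted
anywhere, since it is hardware-bound.

## The containment algorithm and its oracle

Quadratic all-pairs subset testing is impossible at vocabulary scale
(~10⁶ names). `filter_by_containment()` sweeps distinct word sets in
ascending size and maintains an inverted index from each *minimal* set's
rarest word (by global frequency) to the set. A candidate superset must
contain every word of the subset, in particular its rarest word, so
looking up the query's words in the index finds every minimal subset
without comparing against non-minimal ones; only minimal sets are ever
indexed, which keeps candidate lists short. `containment_oracle()` is the
brute-force all-pairs implementation, guarded to 5,000 names; the test
suite proves the two routes identical on randomized families (up to 500
names over a 30-word alphabet, 50 families per run) and validates the
witness map — every removed name word-contains its witness, and the
witness is retained.

## The synthetic data generator

`generate_fixture()` emulates the structures the pipeline exists to
remove, at bench scale, with a constructively computed manifest:

* base ingredient names — pronounceable consonant-vowel gibberish of 6–14
  characters, so they always fall in the mid class and can never collide
  with real words of the corpus vocabulary;
* per name, a source count drawn from a distribution concentrated on 1
  (80% single-sourced, echoing the provenance skew of a real release) and
  optional extra duplicate rows;
* dose-form expansions `"<base> <dose> <unit> [<form>]"` that strictly
  word-contain their base by construction, at roughly 7 per base so the
  mid class is dominated by removable names, as in a real release;
* purely administrative DF/DFG/SC rows, 200+-character names
  (single-sourced, as observed in practice), and 2–4-character
  abbreviations of which a known ~45% are planted into the corpus —
  about the corpus-attested fraction of short names in drug-related
  abstracts;
* a corpus whose filler vocabulary is generated disjoint from every name
  word, so the planted occurrence plan is exact: a planted name's count
  equals its insertions, an unplanted name's count is zero.

The manifest (expected value of every report field, the plant plan, and a
per-source removal plan for the mid class) is computed from the
generator's bookkeeping during construction and never by running the
pipeline — pipeline-vs-manifest agreement is therefore a genuine
end-to-end check, exercised over 50 random configurations per test run.

What the generator does **not** emulate: natural-language context (filler
is unstructured gibberish), polysemous short names that are also common
words, real RXCUI structure, and cross-name word sharing beyond the
dose-expansion pattern. Passing tests therefore demonstrate the
correctness of the mechanics — parsing, counting, set algebra, matching —
not the linguistic precision of any particular lexicon on real prose.

## Numerical conventions

* Report percentages are stage counts over the raw total, rounded
  **half-up** to 2 decimals (base `round()` is half-even); per-source
  removal rates use half-up at 1 decimal. Half-up reproduces the
  arithmetic of the published summary tables this report format follows.
* All string sorts use C-locale radix order, making every writer
  byte-deterministic across platforms and locales.
* Writers emit UTF-8 with `\n` line endings; RRF bytes that are not valid
  UTF-8 are replaced on ingest and counted in the parse diagnostics.

## Problem sizes in the test suite

The suite runs entirely offline on generated data: containment
equivalence on 50 families up to 500 names, matcher-vs-window-scan on
random corpora of tens of documents, and 50 end-to-end
fixture-vs-manifest runs with 8–30 base names each — sizes chosen so the
whole suite completes in well under a minute while still exercising every
code path, including the degenerate ones (empty classes, empty corpus,
untokenizable names, tied word sets). A full-release reproduction test
exists but requires the corresponding RxNorm download and reference
abstracts to be placed under `tests/testthat/rxnorm-full/`; at vocabulary
scale the containment sweep is the dominant cost and takes hours in pure
R, so that check is a deliberate opt-in.

## Limitations

The refinement inherits the limitations of its inputs: a corpus-attested
short name may still be a common word in other contexts; names absent
from RxNorm (street names, novel misspellings) cannot be recovered; and a
lexicon refined against one reference corpus reflects that corpus's
domain. Containment is exact set inclusion — no stemming, no unit
normalization (*mg* vs *milligram*), no similarity linking; those belong
to downstream normalization, not to this pipeline.
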