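# rxlexr

Dictionary-based drug identification in free text — PubMed abstracts,
clinical notes, social-media posts — needs a drug-name lexicon that is both
comprehensive and clean. RxNorm, the National Library of Medicine's drug
vocabulary, is the natural starting point: it aggregates names from 14
source vocabularies (DrugBank, MeSH, SNOMED CT, FDA Structured Product
Labeling, ...). Used raw, however, it inflates and distorts occurrence
counts in text: the same string is contributed by several sources; rows such
as *oral tablet* describe dose forms rather than drugs; names run from
single letters to over 2,000 characters; and dose-expanded entries nest
shorter ones, so the sentence *"Acetaminophen 325 mg caused my mom's liver
injury"* fires twice — once for *Acetaminophen* and once for
*Acetaminophen 325 mg* — double-counting one adverse event.

`rxlexr` builds a refined drug-name lexicon from an `RXNCONSO.RRF` concept
file with a five-stage pipeline:

1. **Deduplication** — one entry per distinct name string; source and
   term-type provenance is unioned over the merged rows.
2. **Administrative term types** — entries whose term types are all in
   {DF, DFG, SC} (dose form, dose form group, special category) are removed.
3. **Length stratification** — names of ≤ 4 characters (short), 5–199
   characters (mid), ≥ 200 characters (long).
4. **Short names** — retained only with corpus evidence: a short name or
   abbreviation (APAP, ASA, HCTZ) survives iff it occurs at least once in a
   reference corpus of drug-related text.
5. **Mid names** — *word-set containment* pruning. With
   `W(x)` the set of lowercase words of name `x`, a name `a` is removed iff
   there is another name `b` with `W(b) ⊂ W(a)` (strict inclusion). The
   retained set is an antichain under word-set inclusion — no retained name
   can fire redundantly inside another. Long names are removed wholesale.

Around the pipeline sit an exact token-sequence phrase matcher (all
occurrences reported, nested and overlapping spans included), provenance
analytics (per-source removal rates, single-source subsets, length
histograms), and a synthetic fixture generator that produces RRF files and
corpora with a constructively known ground truth for every stage count.

## Worked example

The package ships no RxNorm data; the fixture generator stands in for a
release at bench scale:

```r
library(rxlexr)

fx   <- generate_fixture(fixture_config(seed = 7), out_dir = tempfile())
corp <- load_corpus(fx$paths[["corpus"]])
fit  <- refine(fx$paths[["rrf"]], corp)
summary(fit)
#> Refinement report (656 raw names)
#>   duplicates removed                                171  ( 26.07%)
#>   administrative names removed                        6  (  0.91%)
#>   short names removed (no corpus evidence)            7  (  1.07%)
#>   mid names removed (contain another name)          401  ( 61.13%)
#>   long names removed                                  4  (  0.61%)
#>   refined lexicon retained                           67  ( 10.21%)
```

Each row is the count (and percentage of the 656 raw rows) removed at one
stage; the six percentages cover the whole input up to rounding. The
refined lexicon — 7 corpus-attested short names plus 60 "distinct" mid
names — equals the generator's constructive ground truth field by field
(`fx$manifest$report`).

The redundant-count motivation in two lines:

```r
wx <- worked_example_fixture()
match_corpus(compile_matcher(wx$names), wx$corpus)
#>      doc_id                 name start_token end_token
#> 1 example-1        Acetaminophen           1         1
#> 2 example-1 Acetaminophen 325 mg           1         3

filter_by_containment(wx$names)
#> Containment filter: 1 retained, 1 removed of 2 names
```

After containment pruning only *Acetaminophen* remains and the sentence
yields one match instead of two.

To run against a real release, point `refine()` at the `RXNCONSO.RRF` of an
RxNorm full release and pass a corpus (a directory of `.txt` files or a
JSON-lines file of `{"id", "text"}` records). A shell entry point with
subcommands `refine`, `match`, `stats` and `fixtures` is in `exec/rxlexr`
(see `rx_cli()`).

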