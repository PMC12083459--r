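Package: rxlexr
Title: Refining Drug-Name Lexicons for Text Mining in Drug Safety Surveillance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds refined drug-name lexicons from RxNorm concept files
    (RXNCONSO.RRF) for dictionary-based drug identification in free text.
    Implements a multi-stage refinement pipeline: removal of duplicate names
    contributed by multiple sources, exclusion of administrative term types
    (dose form, dose form group, special category), stratification of names by
    character length, corpus-occurrence filtering of very short names and
    abbreviations, word-set containment pruning of dose-form-expanded names,
    and removal of extremely long names. Also provides an exact token-sequence
    phrase matcher for evaluating lexicons against document corpora,
    source-attribution analytics, and a synthetic fixture generator with
    constructive ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
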