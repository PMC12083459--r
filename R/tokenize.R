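# Tokenization shared by the phrase matcher and the containment filter.
#
# Both drug names and documents are lowercased and reduced to maximal runs of
# alphanumeric characters. Using the same rule on both sides guarantees that a
# lexicon name tokenizes identically whether it appears in a pattern or in
# running text; punctuation (hyphens, apostrophes, periods) splits tokens, so
# "co-trimoxazole" is a 2-token pattern on both sides.

.token_pattern <- "[\\p{L}\\p{N}]+"

#' Tokenize a text string
#'
#' Lowercases the input and emits maximal runs of Unicode letters and digits
#' as tokens, discarding punctuation and whitespace. Character offsets of each
#' token in the original string are retained so matches can be mapped back.
#'
#' @param text a single character string (`NA` is treated as empty).
#' @return A list with components `tokens` (character vector of lowercase
#'   tokens) and `offsets` (integer vector of 1-based character start
#'   positions, strictly increasing). Empty text yields zero-length vectors.
#' @examples
#' tokenize_text("Acetaminophen 325 mg caused my mom's liver injury")$tokens
#' @export
tokenize_text <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(list(tokens = character(), offsets = integer()))
  }
  m <- gregexpr(.token_pattern, text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) {
    return(list(tokens = character(), offsets = integer()))
  }
  list(
    tokens = tolower(regmatches(text, list(m))[[1L]]),
    offsets = as.integer(m)
  )
}

#' Split a drug name into words
#'
#' Applies the package tokenizer to a name and returns both the ordered word
#' list and the deduplicated word set used by the containment filter. A name
#' with no alphanumeric characters yields an empty word set; such names can
#' never be matched in text and are flagged for removal by the pipeline.
#'
#' @param name a single non-empty character string.
#' @return A list with components `words` (ordered lowercase tokens, repeats
#'   kept), `set` (unique words), and `word_count` (`length(words)`).
#' @examples
#' split_words("Acetaminophen 325 MG Oral Tablet")
#' split_words("st. john's wort")$words
#' @export
split_words <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, !is.na(name), nzchar(name))
  tk <- tokenize_text(name)
  list(words = tk$tokens, set = unique(tk$tokens), word_count = length(tk$tokens))
}
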