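#' Built-in stimulus lexicon
#'
#' Returns the 16-noun / 16-verb Dutch lexicon used to build the sentence
#' pool: eight nouns denoting sports people, eight denoting musicians, eight
#' transitive contact verbs and eight transitive perception verbs (all
#' experiencer-subject). `length_chars` is the character count of the lemma.
#'
#' @return A data frame with columns `lemma`, `word_class` (`"noun"` or
#'   `"verb"`), `category` (`"sport"`/`"music"` for nouns,
#'   `"contact"`/`"perception"` for verbs), `gloss`, `length_chars` and
#'   `log_freq` (optional metadata, may be `NA`).
#' @export
#' @examples
#' lex <- default_lexicon()
#' table(lex$word_class, lex$category)
default_lexicon <- function() {
  path <- system.file("extdata", "lexicon.tsv", package = "sentencode",
                      mustWork = TRUE)
  read_lexicon(path)
}

#' Read a lexicon from a TSV file
#'
#' @param path Path to a tab-separated file with columns `lemma`,
#'   `word_class`, `category` and optionally `gloss` and `log_freq`.
#' @return A validated lexicon data frame (see [default_lexicon()]).
#' @export
read_lexicon <- function(path) {
  lex <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  validate_lexicon(lex)
}

validate_lexicon <- function(lex) {
  req <- c("lemma", "word_class", "category")
  if (!all(req %in% names(lex)))
    abort(paste("lexicon must have columns:", paste(req, collapse = ", ")),
          "invalid_lexicon")
  if (anyDuplicated(lex$lemma))
    abort("duplicate lemmas in lexicon", "invalid_lexicon")
  if (!all(lex$word_class %in% c("noun", "verb")))
    abort("word_class must be 'noun' or 'verb'", "invalid_lexicon")
  ok_cat <- ifelse(lex$word_class == "noun",
                   lex$category %in% c("sport", "music"),
                   lex$category %in% c("contact", "perception"))
  if (!all(ok_cat))
    abort("noun categories must be sport/music; verb categories contact/perception",
          "invalid_lexicon")
  lex$length_chars <- nchar(lex$lemma)
  if (is.null(lex$log_freq)) lex$log_freq <- NA_real_
  if (is.null(lex$gloss)) lex$gloss <- lex$lemma
  rownames(lex) <- NULL
  lex[, c("lemma", "word_class", "category", "gloss", "length_chars", "log_freq")]
}

## named category lookup for all lemmas in a lexicon
category_of <- function(lexicon) {
  stats::setNames(lexicon$category, lexicon$lemma)
}

lexicon_nouns <- function(lexicon) lexicon[lexicon$word_class == "noun", ]
lexicon_verbs <- function(lexicon) lexicon[lexicon$word_class == "verb", ]
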