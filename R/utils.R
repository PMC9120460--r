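# Shared helpers: name normalisation and tokenisation. Matching throughout
# the package is case-insensitive fixed-string on space-normalised text, so
# every name and every page goes through the same normalisation.

#' Normalise a scientific name for indexing and matching
#'
#' Lower-cases, strips parenthetical authority strings (e.g. "(Smith 1996)"),
#' removes any character that is not a Unicode letter, digit or space, and
#' collapses runs of whitespace to a single space. Authorities never appear
#' in shop text, so they are dropped before the name enters the search space.
#'
#' @param x Character vector of names.
#' @return Character vector of normalised names.
#' @examples
#' normalise_name("Haplopelma  lividum (Smith 1996)")
#' @export
normalise_name <- function(x) {
  x <- stringr::str_remove_all(x, "\\([^)]*\\)")
  x <- stringr::str_to_lower(x)
  x <- stringr::str_replace_all(x, "[^\\p{L}\\p{N} ]+", " ")
  x <- stringr::str_squish(x)
  x
}

# Split already-normalised text into its space-separated tokens.
tokenise <- function(text) {
  if (!nzchar(text)) return(character(0))
  strsplit(text, " ", fixed = TRUE)[[1]]
}

# Number of tokens in a (possibly un-normalised) name, authorities stripped.
name_rank <- function(x) {
  stringr::str_count(normalise_name(x), " ") + 1L
}
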