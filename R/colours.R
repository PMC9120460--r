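# Colour-term co-occurrence with genus mentions. Shop listings often append
# a colour (or a locality) instead of an epithet ("Chilobrachys sp Electric
# Blue"); counting colour words inside the 3-before/4-after context window
# of each genus mention surfaces that signal, a possible marker of
# undescribed diversity in trade.

#' Build a colour lexicon
#'
#' Reads a one-term-per-line colour list and an exclusion list of words that
#' are only ambiguously colour-related (e.g. "web", "jungle", "sea"), and
#' returns the set difference. Defaults are the packaged lists.
#'
#' @param colour_file Path to the colour list (one lower-case term per line).
#' @param exclusions_file Path to the exclusion list.
#' @return An object of class `colour_lexicon`: list with `colour_terms`
#'   and `ambiguous_exclusions` (both lower-cased character vectors).
#' @export
build_colour_lexicon <- function(
    colour_file = system.file("extdata", "colours.txt",
                              package = "arachnotrade"),
    exclusions_file = system.file("extdata", "colour_exclusions.txt",
                                  package = "arachnotrade")) {
  terms <- tolower(trimws(readLines(colour_file, encoding = "UTF-8")))
  terms <- unique(terms[nzchar(terms)])
  if (length(terms) == 0) {
    stop("colour list ", colour_file, " is empty", call. = FALSE)
  }
  excl <- tolower(trimws(readLines(exclusions_file, encoding = "UTF-8")))
  excl <- unique(excl[nzchar(excl)])
  absent <- setdiff(excl, terms)
  if (length(absent) > 0) {
    warning("exclusion term(s) not in the colour list (no-op): ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  structure(list(colour_terms = setdiff(terms, excl),
                 ambiguous_exclusions = excl),
            class = "colour_lexicon")
}

#' @export
print.colour_lexicon <- function(x, ...) {
  cat("<colour_lexicon> ", length(x$colour_terms), " terms (",
      length(x$ambiguous_exclusions), " ambiguous exclusions applied)\n",
      sep = "")
  invisible(x)
}

#' Packaged English stop-word list
#'
#' @return Lower-cased character vector.
#' @export
default_stopwords <- function() {
  readLines(system.file("extdata", "stopwords_en.txt",
                        package = "arachnotrade"), encoding = "UTF-8")
}

#' Count colour terms co-occurring with genus mentions
#'
#' Every detection row is one genus mention carrying its context window.
#' Per window, tokens are lower-cased, stop words removed, and the remainder
#' intersected with the colour lexicon. By default each distinct colour in a
#' window increments the (genus, colour) count by one ("red red" counts red
#' once); `multiplicity = TRUE` counts raw token occurrences instead.
#'
#' @param detections Detection tibble from [hierarchical_search()] at full
#'   multiplicity (do not collapse per page first).
#' @param lexicon A [build_colour_lexicon()] object.
#' @param stopwords Character vector (default [default_stopwords()]).
#' @param multiplicity Count raw token occurrences within a window.
#' @return A tibble `genus_token`, `colour_term`, `n` (rows with `n >= 1`
#'   only), with attribute `"summary"`: per-genus distinct-colour counts
#'   plus `mean_colours_per_genus` as attribute on that tibble.
#' @export
count_colour_cooccurrence <- function(detections, lexicon,
                                      stopwords = default_stopwords(),
                                      multiplicity = FALSE) {
  stopifnot(inherits(lexicon, "colour_lexicon"))
  stopwords <- tolower(stopwords)
  window_hits <- purrr::map2(
    detections$context_before, detections$context_after,
    function(b, a) {
      toks <- tolower(c(strsplit(b, "|", fixed = TRUE)[[1]],
                        strsplit(a, "|", fixed = TRUE)[[1]]))
      toks <- toks[nzchar(toks) & !toks %in% stopwords]
      toks <- toks[toks %in% lexicon$colour_terms]
      if (multiplicity) toks else unique(toks)
    })
  n_each <- lengths(window_hits)
  counts <- tibble(
    genus_token = rep(detections$genus_token, n_each),
    colour_term = unlist(window_hits)
  )
  counts <- if (nrow(counts) == 0) {
    tibble(genus_token = character(0), colour_term = character(0),
           n = integer(0))
  } else {
    counts |> count(.data$genus_token, .data$colour_term) |>
      arrange(.data$genus_token, dplyr::desc(.data$n))
  }
  summary <- counts |>
    group_by(.data$genus_token) |>
    summarise(n_colours = dplyr::n_distinct(.data$colour_term),
              n_mentions_with_colour = sum(.data$n)) |>
    ungroup()
  attr(summary, "mean_colours_per_genus") <-
    if (nrow(summary) == 0) NA_real_ else mean(summary$n_colours)
  attr(counts, "summary") <- summary
  counts
}

#' Bar chart of colour terms associated with each genus
#'
#' @param counts Output of [count_colour_cooccurrence()].
#' @param top_n Keep the `top_n` genera by total colour mentions.
#' @return A ggplot object.
#' @export
plot_colour_associations <- function(counts, top_n = 15) {
  keep <- counts |>
    group_by(.data$genus_token) |>
    summarise(total = sum(.data$n)) |>
    arrange(dplyr::desc(.data$total)) |>
    head(top_n) |> pull("genus_token")
  counts |>
    filter(.data$genus_token %in% keep) |>
    ggplot2::ggplot(ggplot2::aes(
      x = stats::reorder(.data$genus_token, .data$n, sum),
      y = .data$n, fill = .data$colour_term)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "colour mentions alongside genus",
                  fill = "colour") +
    ggplot2::theme_minimal()
}
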