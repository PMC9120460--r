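# Hierarchical genus-then-species keyword search. Pages are first scanned
# for genus tokens; only the full names ever housed in a mentioned genus are
# then searched on that page. Matching is case-insensitive fixed-string with
# a LEFT word boundary only: a genus token must be preceded by a space (or
# start of page) but may continue into a longer word ("Neon" matches
# "Neonate"). That one-sidedness is deliberate — the spurious-genus audit
# depends on it — and a strict both-boundary mode is available behind a flag.

#' Find genus mentions on a cleaned page
#'
#' Returns every token position where a genus token matches with a left word
#' boundary. In the default mode the right boundary is unconstrained, so a
#' genus can match the head of a longer word; `strict_boundary = TRUE`
#' requires the whole token to equal the genus.
#'
#' @param text Cleaned page text (see [clean_html()]).
#' @param genus_list Character vector of lower-cased genus tokens (e.g.
#'   `index$genus_list`).
#' @param strict_boundary Require the full token to equal the genus.
#' @return A tibble with columns `genus_token` and `position` (1-based token
#'   index).
#' @export
find_genus_mentions <- function(text, genus_list, strict_boundary = FALSE) {
  toks <- tolower(tokenise(text))
  if (length(toks) == 0 || length(genus_list) == 0) {
    return(tibble(genus_token = character(0), position = integer(0)))
  }
  hits <- purrr::map(genus_list, function(g) {
    pos <- if (strict_boundary) which(toks == g) else
      which(startsWith(toks, g))
    if (length(pos) == 0) NULL else tibble(genus_token = g, position = pos)
  })
  out <- bind_rows(hits)
  if (nrow(out) == 0) {
    return(tibble(genus_token = character(0), position = integer(0)))
  }
  arrange(out, .data$position, .data$genus_token)
}

#' Capture the context window around a genus mention
#'
#' Up to 3 tokens before and 4 after the given position, truncated at page
#' boundaries. Original casing is preserved.
#'
#' @param tokens Character vector of page tokens.
#' @param position 1-based token index of the genus mention.
#' @return A list with `before` and `after` character vectors.
#' @export
capture_context <- function(tokens, position) {
  n <- length(tokens)
  stopifnot(position >= 1, position <= n)
  list(
    before = tokens[seq_len(n) >= position - 3 & seq_len(n) < position],
    after = tokens[seq_len(n) > position & seq_len(n) <= position + 4]
  )
}

#' Hierarchical genus-then-species search over a corpus
#'
#' For every page: genus tokens are located with [find_genus_mentions()];
#' for each mentioned genus, every full name in that genus bucket (any name
#' a species ever carried) is searched page-wide as a case-insensitive
#' fixed string with a left word boundary. A species match is emitted as one
#' detection per occurrence (its `position` is the start of the full name,
#' which is itself a genus mention), with `match_kind` from
#' [resolve_names()]. A genus mention at a position where no species match
#' of that genus starts becomes a `genus_only` detection. Each detection
#' carries the 3-before/4-after context window at its position, so every row
#' is one genus mention — the unit the colour co-occurrence counts use.
#'
#' The genus pre-filter is an optimisation, not a semantics change: the
#' species-detection set is identical to a brute-force scan of every name
#' in the index against every page.
#'
#' @param pages Corpus tibble from [load_corpus()] (columns `site_id`,
#'   `page_id`, `snapshot_year`, `text`).
#' @param index A [build_name_index()] object.
#' @param strict_boundary Require both word boundaries (default `FALSE`).
#' @return A tibble with one row per detection: `site_id`, `page_id`,
#'   `snapshot_year`, `genus_token`, `matched_name`, `accepted_name`,
#'   `match_kind` (`exact_current`, `synonym`, `genus_only`), `position`,
#'   `context_before`, `context_after` (pipe-joined tokens), ordered by
#'   site, page, position.
#' @export
hierarchical_search <- function(pages, index, strict_boundary = FALSE) {
  buckets <- split(index$genus_buckets$name, index$genus_buckets$genus)
  per_page <- purrr::pmap(
    list(pages$site_id, pages$page_id, pages$snapshot_year, pages$text),
    function(site_id, page_id, snapshot_year, text) {
      search_page(site_id, page_id, snapshot_year, text, index, buckets,
                  strict_boundary)
    })
  out <- bind_rows(per_page)
  if (nrow(out) == 0) return(empty_detections())
  arrange(out, .data$site_id, .data$page_id, .data$position,
          .data$genus_token)
}

empty_detections <- function() {
  tibble(site_id = character(0), page_id = character(0),
         snapshot_year = integer(0), genus_token = character(0),
         matched_name = character(0), accepted_name = character(0),
         match_kind = character(0), position = integer(0),
         context_before = character(0), context_after = character(0))
}

search_page <- function(site_id, page_id, snapshot_year, text, index,
                        buckets, strict_boundary) {
  toks <- tokenise(text)
  low <- tolower(toks)
  gh <- find_genus_mentions(text, index$genus_list, strict_boundary)
  if (nrow(gh) == 0) return(NULL)

  species_rows <- purrr::map(unique(gh$genus_token), function(g) {
    nm <- buckets[[g]]
    if (is.null(nm)) return(NULL)
    purrr::map(nm, function(full) {
      parts <- tokenise(full)
      pos <- match_name_positions(low, parts, strict_boundary)
      if (length(pos) == 0) return(NULL)
      tibble(genus_token = g, matched_name = full, position = pos)
    }) |> bind_rows()
  }) |> bind_rows()

  if (nrow(species_rows) > 0) {
    res <- resolve_names(species_rows$matched_name, index)
    species_rows$accepted_name <- res$accepted_name
    species_rows$match_kind <- res$match_kind
    covered <- paste(species_rows$genus_token, species_rows$position)
  } else {
    covered <- character(0)
  }

  genus_rows <- gh |>
    filter(!paste(.data$genus_token, .data$position) %in% covered) |>
    mutate(matched_name = NA_character_, accepted_name = NA_character_,
           match_kind = "genus_only")

  out <- bind_rows(species_rows, genus_rows)
  ctx <- purrr::map(out$position, capture_context, tokens = toks)
  out |>
    mutate(site_id = site_id, page_id = page_id,
           snapshot_year = snapshot_year,
           context_before = purrr::map_chr(ctx, ~ paste(.x$before,
                                                        collapse = "|")),
           context_after = purrr::map_chr(ctx, ~ paste(.x$after,
                                                       collapse = "|"))) |>
    select("site_id", "page_id", "snapshot_year", "genus_token",
           "matched_name", "accepted_name", "match_kind", "position",
           "context_before", "context_after")
}

# Positions where a multi-token name matches: all tokens equal except the
# last, which is a prefix match unless strict. A fixed-string match of
# "genus epithet" inside space-normalised text is exactly this.
match_name_positions <- function(low_tokens, name_parts, strict_boundary) {
  k <- length(name_parts)
  n <- length(low_tokens)
  if (n < k || k == 0) return(integer(0))
  cand <- which(low_tokens == name_parts[1])
  cand <- cand[cand + k - 1 <= n]
  if (k == 1) return(cand)
  keep <- vapply(cand, function(i) {
    mid_ok <- k <= 2 ||
      all(low_tokens[i + seq_len(k - 2)] == name_parts[seq_len(k - 2) + 1])
    last <- low_tokens[i + k - 1]
    last_ok <- if (strict_boundary) last == name_parts[k] else
      startsWith(last, name_parts[k])
    mid_ok && last_ok
  }, logical(1))
  cand[keep]
}

#' Default blocklist of spurious genus tokens
#'
#' Short genus names that routinely match the start of ordinary words
#' (left-boundary-only matching) and that never had species-level hits; used
#' as the default in [filter_spurious()].
#'
#' @return Lower-cased character vector.
#' @export
default_genus_blocklist <- function() {
  tolower(readLines(system.file("extdata", "spurious_genera.txt",
                                package = "arachnotrade"),
                    encoding = "UTF-8"))
}

#' Remove spurious genus-only detections
#'
#' Drops `genus_only` detections whose genus token is on the blocklist.
#' Species-level detections are never removed; if a blocklisted genus has
#' species detections anywhere in the corpus a warning is raised, since the
#' rationale for removal (no species ever detected in the genus) would be
#' violated. The attached audit report lists every genus with at least one
#' genus-only hit and zero species hits corpus-wide, for manual review.
#'
#' @param detections Detection tibble from [hierarchical_search()].
#' @param blocklist Character vector of genus tokens (default
#'   [default_genus_blocklist()]).
#' @return The filtered detections, with attribute `"audit"` (tibble of
#'   review candidates: `genus_token`, `n_genus_only`).
#' @export
filter_spurious <- function(detections, blocklist = default_genus_blocklist()) {
  blocklist <- tolower(blocklist)
  has_species <- detections |>
    filter(.data$match_kind != "genus_only") |>
    pull("genus_token") |> unique()
  offenders <- intersect(blocklist, has_species)
  if (length(offenders) > 0) {
    warning("blocklisted genus token(s) with species detections retained: ",
            paste(offenders, collapse = ", "), call. = FALSE)
  }
  out <- filter(detections,
                !(.data$match_kind == "genus_only" &
                    .data$genus_token %in% blocklist))
  audit <- detections |>
    filter(.data$match_kind == "genus_only",
           !.data$genus_token %in% has_species) |>
    count(.data$genus_token, name = "n_genus_only") |>
    arrange(dplyr::desc(.data$n_genus_only))
  attr(out, "audit") <- audit
  out
}

#' Collapse detections to one row per page and species
#'
#' Species lists count presence, so multiple hits of one species on one page
#' collapse to a single row; colour counting keeps full multiplicity and
#' should use the uncollapsed detections.
#'
#' @param detections Detection tibble.
#' @return Detections with species rows deduplicated per
#'   (site, page, matched name); `genus_only` rows pass through untouched.
#' @export
distinct_species_detections <- function(detections) {
  sp <- detections |>
    filter(.data$match_kind != "genus_only") |>
    distinct(.data$site_id, .data$page_id, .data$matched_name,
             .keep_all = TRUE)
  bind_rows(sp, filter(detections, .data$match_kind == "genus_only")) |>
    arrange(.data$site_id, .data$page_id, .data$position)
}

#' Write detections as a tidy CSV
#'
#' One row per detection; context tokens stay pipe-joined.
#'
#' @param detections Detection tibble.
#' @param path Output CSV path.
#' @export
write_detections <- function(detections, path) {
  readr::write_csv(detections, path, progress = FALSE)
  invisible(path)
}
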