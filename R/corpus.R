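# Corpus ingestion: saved web pages (contemporary or archived snapshots)
# normalised into searchable plain text with site/page/year metadata.

#' Clean a raw HTML or text blob into searchable plain text
#'
#' Strips markup (including the contents of `<script>` and `<style>`
#' elements), replaces every character that is not a Unicode letter or digit
#' with a space, collapses runs of spaces, and trims. Casing is preserved —
#' matching downstream is case-insensitive, but context exports keep the
#' original casing. The operation is idempotent.
#'
#' @param raw A single character string (HTML or plain text).
#' @return The cleaned text (a single string; `""` for empty input).
#' @examples
#' clean_html("<b>Grammostola-pulchra!</b>")
#' @export
clean_html <- function(raw) {
  if (is.na(raw)) return("")
  txt <- raw
  if (grepl("<", raw, fixed = TRUE)) {
    doc <- tryCatch(xml2::read_html(raw), error = function(e) NULL)
    if (!is.null(doc)) {
      drop <- xml2::xml_find_all(doc, ".//script | .//style")
      xml2::xml_remove(drop)
      txt <- xml2::xml_text(doc)
    }
  }
  txt <- stringr::str_replace_all(txt, "[^\\p{L}\\p{N}]+", " ")
  stringr::str_squish(txt)
}

#' Load a saved-page corpus described by a manifest
#'
#' The manifest lists one row per saved page: `path` (relative to `root` or
#' absolute), `site_id`, `page_id` and `snapshot_year` (empty/NA marks the
#' contemporary snapshot, which carries no dated year). Every file is read,
#' cleaned with [clean_html()], and wrapped with its metadata. Pages that
#' clean to nothing are retained, flagged empty, with `n_chars = 0`.
#'
#' @param root Directory containing the page files.
#' @param manifest Path to the manifest CSV (or a data frame already read).
#' @return A tibble with columns `site_id`, `page_id`, `snapshot_year`,
#'   `text`, `n_chars`, `flag_empty`.
#' @export
load_corpus <- function(root, manifest) {
  man <- if (is.data.frame(manifest)) as_tibble(manifest) else
    readr::read_csv(manifest, show_col_types = FALSE, progress = FALSE)
  need <- c("path", "site_id", "page_id", "snapshot_year")
  missing_cols <- setdiff(need, names(man))
  if (length(missing_cols) > 0) {
    stop("corpus manifest is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", man$path), man$path,
                  file.path(root, man$path))
  gone <- !file.exists(paths)
  if (any(gone)) {
    stop("corpus manifest lists missing file(s): ",
         paste(paths[gone], collapse = ", "), call. = FALSE)
  }
  pages <- man |>
    mutate(
      site_id = as.character(.data$site_id),
      page_id = as.character(.data$page_id),
      snapshot_year = suppressWarnings(as.integer(.data$snapshot_year)),
      text = purrr::map_chr(paths, function(p) {
        raw <- readChar(p, file.size(p), useBytes = TRUE)
        Encoding(raw) <- "UTF-8"
        if (!validUTF8(raw)) raw <- iconv(raw, "UTF-8", "UTF-8", sub = " ")
        clean_html(raw)
      }),
      n_chars = nchar(.data$text),
      flag_empty = .data$n_chars == 0L
    ) |>
    select("site_id", "page_id", "snapshot_year", "text", "n_chars",
           "flag_empty")
  per_site <- count(pages, .data$site_id)
  message("load_corpus: ", nrow(pages), " page(s) from ", nrow(per_site),
          " site(s)")
  pages
}

#' Write / read a cleaned corpus as JSON-lines
#'
#' One `CleanPage` record per line, for reproducible reruns of the matcher
#' without re-cleaning raw files.
#'
#' @param pages A corpus tibble from [load_corpus()].
#' @param path Output (or input) `.jsonl` path.
#' @export
write_corpus <- function(pages, path) {
  lines <- purrr::map_chr(seq_len(nrow(pages)), function(i) {
    jsonlite::toJSON(as.list(pages[i, ]), auto_unbox = TRUE, na = "null")
  })
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  rows <- purrr::map(readLines(path, encoding = "UTF-8"), function(l) {
    x <- jsonlite::fromJSON(l)
    as_tibble(purrr::map(x, ~ .x %||% NA))
  })
  out <- bind_rows(rows)
  out$snapshot_year <- as.integer(out$snapshot_year)
  out
}
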