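# Shared fixtures and independent oracles.

# Brute-force species-search oracle: a name matches a page iff the padded
# lower-cased page contains " <name>" as a fixed substring (left word
# boundary; right boundary unconstrained). Deliberately character-based so
# it shares no tokenisation code with the matcher under test.
brute_force_species_set <- function(pages, index) {
  rows <- list()
  for (i in seq_len(nrow(pages))) {
    hay <- paste0(" ", tolower(pages$text[i]))
    hit <- vapply(index$names$name, function(nm) {
      grepl(paste0(" ", nm), hay, fixed = TRUE)
    }, logical(1))
    if (any(hit)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        site_id = pages$site_id[i], page_id = pages$page_id[i],
        matched_name = index$names$name[hit])
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(site_id = character(0), page_id = character(0),
                          matched_name = character(0))
  }
  dplyr::arrange(out, site_id, page_id, matched_name)
}

species_set <- function(detections) {
  detections |>
    dplyr::filter(match_kind != "genus_only") |>
    dplyr::distinct(site_id, page_id, matched_name) |>
    dplyr::arrange(site_id, page_id, matched_name)
}

# A hand-built registry in the shape load_checklist() returns.
make_registry <- function(rows) {
  tibble::tibble(
    accepted_name = paste(rows$genus, rows$epithet),
    genus = rows$genus, epithet = rows$epithet,
    family = rows$family %||% "Theraphosidae",
    group = rows$group %||% "spider",
    description_year = rows$year %||% 2000L,
    nomen_dubium = rows$nomen_dubium %||% FALSE,
    synonyms = rows$synonyms %||% rep(list(character(0)), length(rows$genus)),
    unrepaired = rep(list(character(0)), length(rows$genus))
  )
}

micro_registry <- function() {
  make_registry(list(
    genus = c("Grammostola", "Cyriopagopus", "Pandinus", "Neon",
              "Chilobrachys"),
    epithet = c("pulchra", "lividus", "imperator", "reticulatus",
                "fimbriatus"),
    family = c("Theraphosidae", "Theraphosidae", "Scorpionidae",
               "Salticidae", "Theraphosidae"),
    group = c("spider", "spider", "scorpion", "spider", "spider"),
    year = c(1921L, 1996L, 1841L, 1861L, 1899L),
    nomen_dubium = rep(FALSE, 5),
    synonyms = list(c("Grammostola spathulata", "Grammostola rosea"),
                    c("Haplopelma lividum"), character(0), character(0),
                    character(0))
  ))
}

make_pages <- function(texts, site_id = NULL, snapshot_year = NULL) {
  n <- length(texts)
  tibble::tibble(
    site_id = site_id %||% sprintf("s%02d", seq_len(n)),
    page_id = sprintf("p%02d", seq_len(n)),
    snapshot_year = snapshot_year %||% rep(NA_integer_, n),
    text = vapply(texts, clean_html, character(1), USE.NAMES = FALSE),
    n_chars = nchar(vapply(texts, clean_html, character(1),
                           USE.NAMES = FALSE)),
    flag_empty = FALSE
  )
}

`%||%` <- rlang::`%||%`

# Comparison helper: a bare data frame, stripped of ad-hoc attributes
# (audit trails, summaries, worklists) that are irrelevant to set equality.
plain <- function(x) {
  x <- as.data.frame(x)
  attributes(x) <- attributes(x)[c("names", "class", "row.names")]
  rownames(x) <- NULL
  x
}
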