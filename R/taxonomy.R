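# Taxonomy registry: read checklists with synonym histories, repair
# abbreviated-genus synonyms, and build the name index that drives all
# downstream matching and name reconciliation.

#' Read a taxonomic checklist into one row per accepted species
#'
#' Reads a delimited checklist export (one row per accepted species) and
#' returns a tidy registry. Rows whose name has more than two tokens
#' (subspecies/trinomials) are dropped. Synonyms may be packed into one cell
#' (separated by `syn_sep`); abbreviated-genus synonyms such as `"G. rosea"`
#' are repaired against the genera already seen in that species' listing
#' (accepted genus first, then synonym genera in listed order) via
#' [repair_abbreviated_synonym()].
#'
#' @param path Path to a CSV/TSV file.
#' @param group Taxonomic group label for every row: one of `"spider"`,
#'   `"scorpion"`, `"uropygi"`, `"amblypygi"`.
#' @param cols Named list mapping logical columns to file columns. Recognised
#'   entries: `genus`, `epithet` (or a single `name`), `family`, `year`,
#'   `synonyms`, `nomen_dubium`. Defaults match the synthetic generator's
#'   output (`genus`, `epithet`, `family`, `year`, `synonyms`,
#'   `nomen_dubium`).
#' @param syn_sep Separator between packed synonyms. Default `";"`.
#' @return A tibble with columns `accepted_name`, `genus`, `epithet`,
#'   `family`, `group`, `description_year`, `nomen_dubium`, and list-columns
#'   `synonyms` (repaired binomials) and `unrepaired` (abbreviations whose
#'   initial matched no candidate genus, passed through and flagged).
#' @export
load_checklist <- function(path, group = c("spider", "scorpion", "uropygi",
                                           "amblypygi"),
                           cols = list(), syn_sep = ";") {
  group <- match.arg(group)
  defaults <- list(genus = "genus", epithet = "epithet", family = "family",
                   year = "year", synonyms = "synonyms",
                   nomen_dubium = "nomen_dubium")
  cols <- utils::modifyList(defaults, cols)
  raw <- readr::read_delim(path, delim = guess_delim(path),
                           show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(.default = "c"))

  has <- function(key) !is.null(cols[[key]]) && cols[[key]] %in% names(raw)
  if (!is.null(cols$name) && cols$name %in% names(raw)) {
    full <- raw[[cols$name]]
    genus <- stringr::word(full, 1)
    epithet <- stringr::word(full, 2)
  } else {
    for (key in c("genus", "epithet")) {
      if (!has(key)) {
        stop("checklist ", path, " is missing required column '",
             cols[[key]] %||% key, "'", call. = FALSE)
      }
    }
    genus <- raw[[cols$genus]]
    epithet <- raw[[cols$epithet]]
    full <- paste(genus, epithet)
  }
  if (!has("family")) {
    stop("checklist ", path, " is missing required column '",
         cols$family %||% "family", "'", call. = FALSE)
  }

  year <- if (has("year")) suppressWarnings(as.integer(raw[[cols$year]]))
          else rep(NA_integer_, nrow(raw))
  if (has("year")) {
    bad <- !is.na(raw[[cols$year]]) & is.na(year)
    if (any(bad)) {
      warning(sum(bad), " checklist row(s) had unparseable years; set to NA",
              call. = FALSE)
    }
  }
  dubium <- if (has("nomen_dubium")) {
    tolower(trimws(raw[[cols$nomen_dubium]])) %in% c("true", "t", "1", "yes")
  } else rep(FALSE, nrow(raw))
  syn_raw <- if (has("synonyms")) raw[[cols$synonyms]] else
    rep(NA_character_, nrow(raw))

  out <- tibble(
    accepted_name = stringr::str_squish(full),
    genus = stringr::str_squish(genus),
    epithet = stringr::str_squish(epithet),
    family = raw[[cols$family]],
    group = group,
    description_year = year,
    nomen_dubium = dubium,
    syn_raw = syn_raw
  )

  # subspecies: any row whose full name is more than a binomial
  n_in <- nrow(out)
  out <- dplyr::filter(out, name_rank(.data$accepted_name) == 2L,
                       nzchar(.data$genus), nzchar(.data$epithet))
  n_tri <- n_in - nrow(out)

  repaired <- purrr::map2(out$syn_raw, out$genus, function(packed, gen) {
    if (is.na(packed) || !nzchar(trimws(packed))) {
      return(list(synonyms = character(0), unrepaired = character(0)))
    }
    syns <- stringr::str_squish(strsplit(packed, syn_sep, fixed = TRUE)[[1]])
    syns <- syns[nzchar(syns)]
    fixed <- character(0); flagged <- character(0)
    seen_genera <- gen
    for (s in syns) {
      if (is_abbreviated(s)) {
        r <- repair_abbreviated_synonym(s, seen_genera)
        if (attr(r, "repaired")) fixed <- c(fixed, r)
        else flagged <- c(flagged, s)
      } else {
        fixed <- c(fixed, s)
        seen_genera <- c(seen_genera, stringr::word(s, 1))
      }
    }
    list(synonyms = unique(fixed), unrepaired = flagged)
  })

  out$synonyms <- purrr::map(repaired, "synonyms")
  out$unrepaired <- purrr::map(repaired, "unrepaired")
  out$syn_raw <- NULL
  message("load_checklist: ", nrow(out), " ", group, " species from ",
          basename(path), " (", n_tri, " trinomial row(s) removed)")
  out
}

guess_delim <- function(path) {
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
}

is_abbreviated <- function(x) {
  grepl("^\\p{L}\\.\\s*\\S+$", x, perl = TRUE)
}

#' Repair an abbreviated-genus synonym
#'
#' Checklist synonym listings sometimes abbreviate the genus (`"G. rosea"`).
#' The repair substitutes the first candidate genus (in the order the genera
#' were encountered in the source listing) whose initial letter matches the
#' abbreviation, case-insensitively. If no candidate matches, the input is
#' returned unchanged with attribute `repaired = FALSE`.
#'
#' @param abbrev_name A string of the form `"G. epithet"`.
#' @param candidate_genera Character vector of genus names, in encounter
#'   order.
#' @return The repaired binomial (or the input unchanged), with a logical
#'   attribute `"repaired"`.
#' @examples
#' repair_abbreviated_synonym("G. rosea", c("Grammostola", "Phrixotrichus"))
#' @export
repair_abbreviated_synonym <- function(abbrev_name, candidate_genera) {
  initial <- tolower(substr(trimws(abbrev_name), 1, 1))
  epithet <- stringr::str_squish(sub("^\\S+\\.", "", trimws(abbrev_name)))
  hit <- which(tolower(substr(candidate_genera, 1, 1)) == initial)
  if (length(candidate_genera) == 0 || length(hit) == 0) {
    return(structure(abbrev_name, repaired = FALSE))
  }
  structure(paste(candidate_genera[hit[1]], epithet), repaired = TRUE)
}

#' Build the species/synonym name index
#'
#' Indexes every accepted name and every synonym of a registry (all names
#' normalised with [normalise_name()]) and buckets full names under each
#' distinct leading genus token ever used in any name. The genus buckets
#' drive the hierarchical search: if a species ever belonged to a genus, its
#' full names are searched whenever that genus is mentioned.
#'
#' A full name mapping to two accepted species is a homonym conflict (e.g.
#' the same historical name reused across the spider and scorpion
#' checklists): every candidate is kept in the `ambiguous` table and a
#' warning is raised; the resolution map retains the alphabetically first
#' candidate, flagged ambiguous, so downstream counts can surface rather
#' than silently drop these names.
#'
#' @param records Registry tibble from [load_checklist()] (several groups may
#'   be row-bound).
#' @param include_nomen_dubium Keep names of *nomen dubium* species in the
#'   search space (default `TRUE`; they are tagged either way).
#' @return An object of class `name_index`: a list with `names` (tibble:
#'   `name`, `accepted_name`, `kind`, `nomen_dubium`, `ambiguous`),
#'   `genus_buckets` (tibble: `genus`, `name`), `genus_list`, `species`
#'   (the registry), `ambiguous`, and `dubious` (names excluded when
#'   `include_nomen_dubium = FALSE`).
#' @export
build_name_index <- function(records, include_nomen_dubium = TRUE) {
  stopifnot(nrow(records) > 0)
  long <- records |>
    select("accepted_name", "group", "nomen_dubium", "synonyms") |>
    mutate(syn = purrr::map2(.data$accepted_name, .data$synonyms,
                             ~ c(.x, .y))) |>
    select(-"synonyms") |>
    tidyr::unnest_longer("syn", values_to = "raw_name") |>
    mutate(name = normalise_name(.data$raw_name),
           kind = if_else(.data$raw_name == .data$accepted_name,
                          "accepted", "synonym")) |>
    filter(nzchar(.data$name)) |>
    distinct(.data$name, .data$accepted_name, .keep_all = TRUE)

  dubious <- long |> filter(.data$nomen_dubium) |> pull("name") |> unique()
  if (!include_nomen_dubium) long <- filter(long, !.data$nomen_dubium)

  conflicts <- long |>
    group_by(.data$name) |>
    filter(dplyr::n_distinct(.data$accepted_name) > 1) |>
    ungroup()
  if (nrow(conflicts) > 0) {
    warning("name index: ", dplyr::n_distinct(conflicts$name),
            " homonym name(s) map to multiple accepted species; ",
            "kept all candidates in $ambiguous", call. = FALSE)
  }

  # resolution map: alphabetically first candidate, flagged when ambiguous
  resolved <- long |>
    group_by(.data$name) |>
    arrange(.data$accepted_name, .by_group = TRUE) |>
    mutate(ambiguous = dplyr::n_distinct(.data$accepted_name) > 1) |>
    dplyr::slice(1) |>
    ungroup() |>
    select("name", "accepted_name", "kind", "nomen_dubium", "ambiguous")

  buckets <- long |>
    mutate(genus = stringr::word(.data$name, 1)) |>
    distinct(.data$genus, .data$name) |>
    arrange(.data$genus, .data$name)

  structure(list(
    names = arrange(resolved, .data$name),
    genus_buckets = buckets,
    genus_list = sort(unique(buckets$genus)),
    species = records,
    ambiguous = conflicts |> select("name", "accepted_name", "group"),
    dubious = dubious
  ), class = "name_index")
}

#' @export
print.name_index <- function(x, ...) {
  cat("<name_index> ", nrow(x$species), " species, ", nrow(x$names),
      " names, ", length(x$genus_list), " genus tokens\n", sep = "")
  invisible(x)
}

#' @describeIn build_name_index Long tibble of all indexed names.
#' @param x A `name_index`.
#' @param ... Unused.
#' @export
tidy.name_index <- function(x, ...) x$names

#' @describeIn build_name_index One-row summary: species, name and genus
#'   counts and mean names per species.
#' @export
glance.name_index <- function(x, ...) {
  tibble(
    n_species = nrow(x$species),
    n_names = nrow(x$names),
    n_genus_tokens = length(x$genus_list),
    n_ambiguous = dplyr::n_distinct(x$ambiguous$name),
    mean_names_per_species = nrow(x$names) / nrow(x$species)
  )
}

#' Resolve names against a name index
#'
#' Case-insensitive lookup of each name. `match_kind` is `"exact_current"`
#' when the name equals an accepted name, `"synonym"` when it maps through a
#' historical name, and `"unknown"` otherwise (a value, not an error).
#'
#' @param names Character vector of names to resolve.
#' @param index A [build_name_index()] object.
#' @return A tibble with columns `name`, `accepted_name`, `match_kind`,
#'   `ambiguous`.
#' @examples
#' \dontrun{resolve_names(c("Haplopelma lividum"), index)}
#' @export
resolve_names <- function(names, index) {
  key <- normalise_name(names)
  hit <- match(key, index$names$name)
  tibble(
    name = names,
    accepted_name = index$names$accepted_name[hit],
    match_kind = dplyr::case_when(
      is.na(hit) ~ "unknown",
      index$names$kind[hit] == "accepted" ~ "exact_current",
      TRUE ~ "synonym"
    ),
    ambiguous = !is.na(hit) & index$names$ambiguous[hit]
  )
}

#' @rdname resolve_names
#' @param name A single name.
#' @export
resolve_name <- function(name, index) resolve_names(name, index)

#' Export / import a name index as JSON
#'
#' Serialises the name map, genus buckets and registry for reproducible
#' reruns without re-reading checklists.
#'
#' @param index A `name_index`.
#' @param path Output (or input) JSON path.
#' @return `write_name_index()` returns `path` invisibly; `read_name_index()`
#'   returns a `name_index`.
#' @export
write_name_index <- function(index, path) {
  payload <- list(
    names = index$names,
    genus_buckets = index$genus_buckets,
    species = index$species |>
      mutate(synonyms = purrr::map_chr(.data$synonyms, paste, collapse = ";"),
             unrepaired = purrr::map_chr(.data$unrepaired, paste,
                                         collapse = ";")),
    ambiguous = index$ambiguous,
    dubious = index$dubious
  )
  jsonlite::write_json(payload, path, dataframe = "columns", na = "null")
  invisible(path)
}

#' @rdname write_name_index
#' @export
read_name_index <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  unpack <- function(x) {
    purrr::map(x, ~ if (is.na(.x) || !nzchar(.x)) character(0) else
      strsplit(.x, ";", fixed = TRUE)[[1]])
  }
  species <- as_tibble(payload$species) |>
    mutate(synonyms = unpack(.data$synonyms),
           unrepaired = unpack(.data$unrepaired))
  structure(list(
    names = as_tibble(payload$names),
    genus_buckets = as_tibble(payload$genus_buckets),
    genus_list = sort(unique(payload$genus_buckets$genus)),
    species = species,
    ambiguous = as_tibble(payload$ambiguous),
    dubious = as.character(payload$dubious %||% character(0))
  ), class = "name_index")
}
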