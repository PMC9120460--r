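# LEMIS (US Fish & Wildlife import ledger) and CITES trade-database readers
# and the classification rules used for headline trade summaries.

# Whole-individual description codes: dead animal, live eggs, dead specimen,
# live specimen, specimen, whole skin, entire animal trophy.
WHOLE_INDIVIDUAL_CODES <- c("BOD", "EGL", "DEA", "LIV", "SPE", "SKI", "TRO")
CAPTIVE_SOURCE_CODES <- c("C", "F", "D", "R")
NON_COMMERCIAL_PURPOSES <- c("M", "S", "Y")

#' Read LEMIS records
#'
#' Reads a CSV in the column dialect of the public LEMIS compilation and
#' returns a tidy record table, filtered to the requested taxon class.
#' Missing quantities become 0 (logged); negative quantities are rejected
#' with a log entry.
#'
#' @param path CSV path.
#' @param col_map Named list mapping logical fields (`taxon_class`, `genus`,
#'   `species`, `quantity`, `description`, `disposition`, `purpose`,
#'   `source`, `country_origin`, `shipment_year`) to file columns; defaults
#'   match the compilation's column names (`class`, `genus`, `specific_name`,
#'   `quantity`, `description`, `disposition`, `purpose`, `source`,
#'   `country_origin`, `shipment_year`).
#' @param taxon_class Keep records of this class (default `"Arachnida"`;
#'   `NULL` keeps all).
#' @return Tibble with the logical field names above.
#' @export
read_lemis <- function(path, col_map = list(), taxon_class = "Arachnida") {
  defaults <- list(taxon_class = "class", genus = "genus",
                   species = "specific_name", quantity = "quantity",
                   description = "description", disposition = "disposition",
                   purpose = "purpose", source = "source",
                   country_origin = "country_origin",
                   shipment_year = "shipment_year")
  col_map <- utils::modifyList(defaults, col_map)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  missing_cols <- setdiff(unlist(col_map), names(raw))
  if (length(missing_cols) > 0) {
    stop("LEMIS file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble(
    taxon_class = raw[[col_map$taxon_class]],
    genus = raw[[col_map$genus]],
    species = raw[[col_map$species]],
    quantity = suppressWarnings(as.numeric(raw[[col_map$quantity]])),
    description = toupper(raw[[col_map$description]]),
    disposition = toupper(raw[[col_map$disposition]]),
    purpose = toupper(raw[[col_map$purpose]]),
    source = toupper(raw[[col_map$source]]),
    country_origin = raw[[col_map$country_origin]],
    shipment_year = suppressWarnings(as.integer(raw[[col_map$shipment_year]]))
  )
  if (!is.null(taxon_class)) {
    keep_class <- tolower(taxon_class)
    out <- filter(out, !is.na(.data$taxon_class),
                  tolower(.data$taxon_class) == keep_class)
  }
  n_na_qty <- sum(is.na(out$quantity))
  if (n_na_qty > 0) {
    message("read_lemis: ", n_na_qty, " record(s) had missing quantity, ",
            "treated as 0")
    out$quantity[is.na(out$quantity)] <- 0
  }
  neg <- out$quantity < 0
  if (any(neg)) {
    message("read_lemis: ", sum(neg), " record(s) with negative quantity ",
            "rejected")
    out <- out[!neg, ]
  }
  out
}

#' Keep records that plausibly represent whole individuals
#'
#' Restricts records to the description codes BOD, EGL, DEA, LIV, SPE, SKI,
#' TRO (dead animal, live eggs, dead specimen, live specimen, specimen,
#' whole skin, entire animal trophy). All headline individual counts are
#' computed after this filter.
#'
#' @param records LEMIS tibble from [read_lemis()].
#' @return Filtered tibble.
#' @export
filter_whole_individuals <- function(records) {
  filter(records, .data$description %in% WHOLE_INDIVIDUAL_CODES)
}

#' Classify a source code as wild, captive or other
#'
#' `W` (taken from the wild) is wild; `C`, `F` (bred in captivity), `D`
#' (commercially bred) and `R` (ranched) are captive; everything else
#' (including blank) is other.
#'
#' @param source Character vector of one-letter LEMIS source codes.
#' @return Character vector: `"wild"`, `"captive"`, `"other"`.
#' @export
classify_source <- function(source) {
  source <- toupper(trimws(ifelse(is.na(source), "", source)))
  dplyr::case_when(
    source == "W" ~ "wild",
    source %in% CAPTIVE_SOURCE_CODES ~ "captive",
    TRUE ~ "other"
  )
}

#' Classify a purpose code as commercial-or-other vs non-commercial
#'
#' Biomedical research (`M`), scientific (`S`) and reintroduction (`Y`) are
#' non-commercial; everything else is commercial-or-other.
#'
#' @param purpose Character vector of one-letter LEMIS purpose codes.
#' @return Character vector: `"non_commercial"` or `"commercial_or_other"`.
#' @export
classify_purpose <- function(purpose) {
  purpose <- toupper(trimws(ifelse(is.na(purpose), "", purpose)))
  if_else(purpose %in% NON_COMMERCIAL_PURPOSES,
          "non_commercial", "commercial_or_other")
}

#' Headline LEMIS trade summary
#'
#' Applies [filter_whole_individuals()] first (the filter order behind every
#' percentage), then computes quantity-weighted headline statistics, a
#' per-genus table with wild fractions (genera listed only as
#' `"Non-CITES entry"` or missing are excluded from the genus table), and a
#' per-origin-country table of wild-sourced totals.
#'
#' @param records LEMIS tibble.
#' @return An object of class `lemis_summary`: list with `totals` (one-row
#'   tibble: `total_individuals`, `pct_seized`, `pct_commercial`,
#'   `pct_wild`, `pct_captive`, `pct_other`), `per_genus` and
#'   `per_origin_country` tibbles, and `records` (the filtered records with
#'   `source_class`/`purpose_class` columns).
#' @export
summarise_lemis <- function(records) {
  recs <- filter_whole_individuals(records) |>
    mutate(source_class = classify_source(.data$source),
           purpose_class = classify_purpose(.data$purpose))
  total <- sum(recs$quantity)
  pct <- function(mask) {
    if (total == 0) return(NA_real_)
    100 * sum(recs$quantity[mask]) / total
  }
  totals <- tibble(
    total_individuals = total,
    pct_seized = pct(!is.na(recs$disposition) & recs$disposition == "S"),
    pct_commercial = pct(recs$purpose_class == "commercial_or_other"),
    pct_wild = pct(recs$source_class == "wild"),
    pct_captive = pct(recs$source_class == "captive"),
    pct_other = pct(recs$source_class == "other")
  )
  per_genus <- recs |>
    filter(!is.na(.data$genus), nzchar(.data$genus),
           tolower(.data$genus) != "non-cites entry") |>
    group_by(.data$genus) |>
    summarise(
      total_individuals = sum(.data$quantity),
      wild_individuals = sum(.data$quantity[.data$source_class == "wild"]),
      wild_fraction = if_else(.data$total_individuals > 0,
                              .data$wild_individuals /
                                .data$total_individuals, NA_real_)
    ) |>
    ungroup() |>
    arrange(dplyr::desc(.data$total_individuals))
  per_country <- recs |>
    filter(!is.na(.data$country_origin), nzchar(.data$country_origin)) |>
    group_by(.data$country_origin) |>
    summarise(
      total_individuals = sum(.data$quantity),
      wild_individuals = sum(.data$quantity[.data$source_class == "wild"])
    ) |>
    ungroup() |>
    arrange(dplyr::desc(.data$wild_individuals))
  structure(list(totals = totals, per_genus = per_genus,
                 per_origin_country = per_country, records = recs),
            class = "lemis_summary")
}

#' @export
print.lemis_summary <- function(x, ...) {
  cat("<lemis_summary> ", format(x$totals$total_individuals, big.mark = ","),
      " whole individuals; ", sprintf("%.1f%% wild, %.1f%% captive, ",
                                      x$totals$pct_wild,
                                      x$totals$pct_captive),
      sprintf("%.3f%% seized\n", x$totals$pct_seized), sep = "")
  invisible(x)
}

#' @describeIn summarise_lemis Per-genus tidy table.
#' @param x A `lemis_summary`.
#' @param ... Unused.
#' @export
tidy.lemis_summary <- function(x, ...) x$per_genus

#' @describeIn summarise_lemis One-row headline totals.
#' @export
glance.lemis_summary <- function(x, ...) x$totals

#' Wild-sourced exports from countries outside a species' native range
#'
#' For wild-sourced whole-individual records resolvable to an accepted
#' species with range data: per origin country, the total wild individuals
#' and the share from species not native to that country; per species, the
#' total wild individuals exported from non-native countries. Species with
#' no range data fall into an `unknown` bucket, never counted non-native.
#'
#' @param records LEMIS tibble.
#' @param ranges Species-to-country long tibble from
#'   [build_country_ranges()] (columns `accepted_name`, `country_id`).
#' @param index A [build_name_index()] object used to resolve LEMIS
#'   genus+species names (junior synonyms included).
#' @param country_table Country reference table whose `name`/`aliases`
#'   standardise LEMIS origin codes to `country_id`s.
#' @return List with `per_country` (tibble: `country_id`, `wild_total`,
#'   `wild_nonnative`, `wild_native`, `wild_unknown`, `pct_nonnative`) and
#'   `per_species` (tibble: `accepted_name`, `wild_nonnative`).
#' @export
nonnative_wild_exports <- function(records, ranges, index, country_table) {
  recs <- filter_whole_individuals(records) |>
    filter(classify_source(.data$source) == "wild",
           !is.na(.data$species), nzchar(.data$species))
  recs$accepted_name <-
    resolve_names(paste(recs$genus, recs$species), index)$accepted_name
  recs <- filter(recs, !is.na(.data$accepted_name))
  std <- standardise_country(recs$country_origin, country_table)
  recs$country_id <- std$country_id
  recs <- filter(recs, !is.na(.data$country_id))

  native <- ranges |> distinct(.data$accepted_name, .data$country_id)
  has_range <- unique(native$accepted_name)
  recs <- recs |>
    left_join(mutate(native, native = TRUE),
              by = c("accepted_name", "country_id")) |>
    mutate(status = dplyr::case_when(
      !.data$accepted_name %in% has_range ~ "unknown",
      is.na(.data$native) ~ "nonnative",
      TRUE ~ "native"
    ))
  per_country <- recs |>
    group_by(.data$country_id) |>
    summarise(
      wild_total = sum(.data$quantity),
      wild_nonnative = sum(.data$quantity[.data$status == "nonnative"]),
      wild_native = sum(.data$quantity[.data$status == "native"]),
      wild_unknown = sum(.data$quantity[.data$status == "unknown"]),
      pct_nonnative = if_else(.data$wild_total > 0,
                              100 * .data$wild_nonnative / .data$wild_total,
                              NA_real_)
    ) |>
    ungroup() |>
    arrange(dplyr::desc(.data$wild_nonnative))
  per_species <- recs |>
    filter(.data$status == "nonnative") |>
    group_by(.data$accepted_name) |>
    summarise(wild_nonnative = sum(.data$quantity)) |>
    ungroup() |>
    arrange(dplyr::desc(.data$wild_nonnative))
  list(per_country = per_country, per_species = per_species)
}

#' Read a CITES gross-imports export
#'
#' Reads the standard gross-imports layout (one `Taxon` column plus one
#' column per year), pivots to long form, restricts to the study years, and
#' resolves taxa through the name index. Unresolvable names are kept under
#' the raw name and flagged.
#'
#' @param gross_imports_csv Path to the gross-imports CSV.
#' @param index A [build_name_index()] object.
#' @param appendices_csv Optional CSV of CITES appendix listings with a
#'   `Taxon` column; listed taxa are resolved and returned in `appendix`.
#' @param years Inclusive year window (default 1975-2021).
#' @return List with `species` (tibble: `taxon_raw`, `accepted_name`,
#'   `match_kind`, `resolved`), `yearly` (tibble: `taxon_raw`,
#'   `accepted_name`, `year`, `quantity`), `appendix` (tibble or `NULL`).
#' @export
read_cites <- function(gross_imports_csv, index, appendices_csv = NULL,
                       years = c(1975, 2021)) {
  raw <- readr::read_csv(gross_imports_csv, show_col_types = FALSE,
                         progress = FALSE)
  taxon_col <- intersect(c("Taxon", "taxon"), names(raw))[1]
  if (is.na(taxon_col)) {
    stop("CITES gross-imports file has no 'Taxon' column", call. = FALSE)
  }
  year_cols <- names(raw)[grepl("^[0-9]{4}$", names(raw))]
  yearly <- raw |>
    select(taxon_raw = dplyr::all_of(taxon_col),
           dplyr::all_of(year_cols)) |>
    tidyr::pivot_longer(-"taxon_raw", names_to = "year",
                        values_to = "quantity") |>
    mutate(year = as.integer(.data$year),
           quantity = suppressWarnings(as.numeric(.data$quantity))) |>
    filter(.data$year >= years[1], .data$year <= years[2],
           !is.na(.data$quantity), .data$quantity > 0)
  species <- tibble(taxon_raw = unique(raw[[taxon_col]]))
  res <- resolve_names(species$taxon_raw, index)
  species$accepted_name <- res$accepted_name
  species$match_kind <- res$match_kind
  species$resolved <- res$match_kind != "unknown"
  yearly <- left_join(yearly, select(species, "taxon_raw", "accepted_name"),
                      by = "taxon_raw")
  appendix <- NULL
  if (!is.null(appendices_csv)) {
    app <- readr::read_csv(appendices_csv, show_col_types = FALSE,
                           progress = FALSE)
    tcol <- intersect(c("Taxon", "taxon"), names(app))[1]
    appendix <- tibble(taxon_raw = unique(app[[tcol]]))
    ares <- resolve_names(appendix$taxon_raw, index)
    appendix$accepted_name <- ares$accepted_name
    appendix$resolved <- ares$match_kind != "unknown"
  }
  list(species = species, yearly = yearly, appendix = appendix)
}
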