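# End-to-end orchestration: one validated configuration drives every stage
# in dependency order, all summaries are written as CSV, and a JSON run
# manifest records inputs, options and output hashes so identical runs are
# bit-identical and diffable.

#' Validate a pipeline configuration
#'
#' A configuration is a named list (or a YAML file path) with input paths
#' (`checklists` — named list group -> path, `corpus_root`,
#' `corpus_manifest`, `lemis`, `cites`, `country_table`, `region_map`,
#' `island_map`, `range_assertions`), options (`basis` `"any"`/`"exact"`,
#' `strict_boundary`, `colour_multiplicity`, `include_nomen_dubium`,
#' `lag_cutoff_year`) and `out_dir`. Every referenced input path must
#' exist. `lemis`, `cites` and the range inputs are optional; stages
#' without inputs are skipped.
#'
#' @param config Named list or YAML path.
#' @return The validated config (with defaults filled), invisibly usable by
#'   [run_pipeline()].
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(basis = "any", strict_boundary = FALSE,
                   colour_multiplicity = FALSE,
                   include_nomen_dubium = TRUE, lag_cutoff_year = 1999)
  config <- utils::modifyList(defaults, config)
  for (field in c("checklists", "corpus_root", "corpus_manifest",
                  "out_dir")) {
    if (is.null(config[[field]])) {
      stop("pipeline config is missing required field '", field, "'",
           call. = FALSE)
    }
  }
  paths <- c(unlist(config$checklists), config$corpus_manifest,
             config$lemis, config$cites, config$country_table,
             config$region_map, config$island_map,
             config$range_assertions)
  gone <- paths[!file.exists(paths)]
  if (length(gone) > 0) {
    stop("pipeline config references missing file(s): ",
         paste(gone, collapse = ", "), call. = FALSE)
  }
  if (!config$basis %in% c("any", "exact")) {
    stop("config field 'basis' must be \"any\" or \"exact\"",
         call. = FALSE)
  }
  config
}

#' Run the full trade-monitoring pipeline
#'
#' Stages, in dependency order: checklist loading and name-index build;
#' corpus loading and cleaning; hierarchical keyword search and
#' spurious-genus filtering; colour co-occurrence; LEMIS summary; CITES
#' reading; cross-source integration (profiles, overlaps, per-year trends,
#' description lags, per-site richness); range digitisation and per-country
#' trade summaries. Outputs are written to `config$out_dir` as CSVs plus a
#' `run_manifest.json` with the options in effect and an md5 per output.
#' The run is a pure function of (inputs, config).
#'
#' @param config A configuration list or YAML path (see
#'   [validate_config()]).
#' @return Invisibly, a named list of the in-memory results (`index`,
#'   `pages`, `detections`, `colour_counts`, `lemis`, `cites`, `profiles`,
#'   `overlaps`, `yearly`, `lags`, `richness`, `ranges`,
#'   `country_summary`, `manifest`).
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(x, name) {
    p <- file.path(config$out_dir, paste0(name, ".csv"))
    readr::write_csv(x, p, progress = FALSE, na = "")
    outputs <<- c(outputs, p)
  }

  registry <- bind_rows(purrr::imap(config$checklists, function(p, g) {
    load_checklist(p, group = g)
  }))
  index <- build_name_index(registry,
                            include_nomen_dubium =
                              config$include_nomen_dubium)

  pages <- load_corpus(config$corpus_root, config$corpus_manifest)
  detections <- hierarchical_search(pages, index,
                                    strict_boundary =
                                      config$strict_boundary)
  detections <- filter_spurious(detections)
  emit(detections, "detections")
  emit(attr(detections, "audit"), "spurious_genus_audit")

  lexicon <- build_colour_lexicon()
  colour_counts <- count_colour_cooccurrence(
    detections, lexicon, multiplicity = config$colour_multiplicity)
  emit(colour_counts, "colour_counts")
  emit(attr(colour_counts, "summary"), "colour_summary")

  lemis_sum <- NULL; lemis_records <- NULL
  if (!is.null(config$lemis)) {
    lemis_records <- read_lemis(config$lemis)
    lemis_sum <- summarise_lemis(lemis_records)
    emit(lemis_sum$totals, "lemis_totals")
    emit(lemis_sum$per_genus, "lemis_per_genus")
    emit(lemis_sum$per_origin_country, "lemis_per_origin")
  }
  cites <- NULL
  if (!is.null(config$cites)) {
    cites <- read_cites(config$cites, index)
    emit(cites$species, "cites_species")
  }

  profiles <- combine_sources(
    online = detections,
    lemis = lemis_records,
    cites = if (is.null(cites)) NULL else cites$yearly,
    index = index, basis = config$basis)
  overlaps <- count_source_overlap(profiles)
  yearly <- species_per_year(profiles)
  lags <- description_lag(profiles, cutoff_year = config$lag_cutoff_year)
  richness <- per_site_richness(
    filter(detections, is.na(.data$snapshot_year)),
    all_sites = unique(pages$site_id[is.na(pages$snapshot_year)]))
  emit(select(profiles, -"detection_years"), "species_profiles")
  emit(overlaps, "source_overlaps")
  emit(yearly, "species_per_year")
  emit(lags, "description_lags")
  emit(attr(lags, "summary"), "lag_summary")
  emit(richness, "site_richness")
  emit(attr(richness, "summary"), "site_richness_summary")

  ranges <- NULL; country_summary <- NULL
  if (!is.null(config$range_assertions) &&
      !is.null(config$country_table)) {
    tab <- read_country_table(config$country_table)
    rmap <- if (is.null(config$region_map)) NULL else
      readr::read_csv(config$region_map, show_col_types = FALSE,
                      progress = FALSE)
    imap <- if (is.null(config$island_map)) NULL else
      readr::read_csv(config$island_map, show_col_types = FALSE,
                      progress = FALSE)
    assertions <- readr::read_csv(config$range_assertions,
                                  show_col_types = FALSE, progress = FALSE)
    ranges <- build_country_ranges(assertions, tab, rmap, imap)
    country_summary <- country_trade_summary(ranges,
                                             profiles$accepted_name)
    emit(ranges, "species_country_ranges")
    emit(country_summary, "country_trade_summary")
    emit(endemism_summary(ranges), "endemism_summary")
  }

  manifest <- list(
    options = config[c("basis", "strict_boundary", "colour_multiplicity",
                       "include_nomen_dubium", "lag_cutoff_year")],
    inputs = config[c("checklists", "corpus_manifest", "lemis", "cites",
                      "country_table", "region_map", "island_map",
                      "range_assertions")],
    outputs = as.list(tools::md5sum(outputs))
  )
  manifest_path <- file.path(config$out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)

  invisible(list(index = index, pages = pages, detections = detections,
                 colour_counts = colour_counts, lemis = lemis_sum,
                 cites = cites, profiles = profiles, overlaps = overlaps,
                 yearly = yearly, lags = lags, richness = richness,
                 ranges = ranges, country_summary = country_summary,
                 manifest = manifest_path))
}
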