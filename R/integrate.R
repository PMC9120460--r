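# Cross-source integration: which species appear online, in LEMIS, in
# CITES; per-year trends and year-unique species; description-to-trade
# lags; per-site species richness.

#' Combine online, LEMIS and CITES species lists into trade profiles
#'
#' Builds one row per accepted species detected in any source, under the
#' chosen matching basis: `"any"` accepts matches through any historical
#' name (the basis used for broad summaries), `"exact"` keeps only exact
#' current-name matches. Detection years are pooled across sources; the
#' undated contemporary snapshot (online detections with `snapshot_year`
#' `NA`) is kept as its own class and never contributes a dated year.
#'
#' @param online Detection tibble from [hierarchical_search()] (species
#'   rows; `genus_only` rows are ignored).
#' @param lemis Tibble of LEMIS species observations with columns `genus`,
#'   `species`, `shipment_year` (a [read_lemis()] table; species membership
#'   uses every record, not just whole-individual rows — that filter is for
#'   individual counts), or `NULL`.
#' @param cites Tibble with columns `accepted_name` (or `taxon_raw`) and
#'   `year` (e.g. the `yearly` element of [read_cites()]), or `NULL`.
#' @param index A [build_name_index()] object.
#' @param basis `"any"` (default) or `"exact"`.
#' @return A tibble of class `trade_profiles`: `accepted_name`, `group`,
#'   `in_online`, `in_lemis`, `in_cites`, `n_sources`, `detection_years`
#'   (list-column of dated years), `first_year`, `snapshot_only`,
#'   `description_year`; attribute `"by_year"` holds the long
#'   (species, year, source) table behind the per-year summaries.
#' @export
combine_sources <- function(online, lemis = NULL, cites = NULL, index,
                            basis = c("any", "exact")) {
  basis <- match.arg(basis)
  keep_kind <- if (basis == "exact") "exact_current" else
    c("exact_current", "synonym")

  online_tbl <- online |>
    filter(.data$match_kind %in% keep_kind) |>
    distinct(accepted_name = .data$accepted_name,
             year = .data$snapshot_year) |>
    mutate(source = "online")

  lemis_tbl <- NULL
  if (!is.null(lemis) && nrow(lemis) > 0) {
    res <- resolve_names(paste(lemis$genus, lemis$species), index)
    lemis_tbl <- tibble(accepted_name = res$accepted_name,
                        match_kind = res$match_kind,
                        year = lemis$shipment_year) |>
      filter(!is.na(.data$accepted_name), .data$match_kind %in% keep_kind) |>
      distinct(.data$accepted_name, .data$year) |>
      mutate(source = "lemis")
  }
  cites_tbl <- NULL
  if (!is.null(cites) && nrow(cites) > 0) {
    nm <- if ("accepted_name" %in% names(cites)) cites$accepted_name else
      resolve_names(cites$taxon_raw, index)$accepted_name
    res <- resolve_names(nm, index)
    cites_tbl <- tibble(accepted_name = res$accepted_name,
                        match_kind = res$match_kind,
                        year = cites$year) |>
      filter(!is.na(.data$accepted_name), .data$match_kind %in% keep_kind) |>
      distinct(.data$accepted_name, .data$year) |>
      mutate(source = "cites")
  }
  by_year <- bind_rows(online_tbl, lemis_tbl, cites_tbl) |>
    mutate(year = as.integer(.data$year))

  meta <- index$species |>
    select("accepted_name", "group", "description_year")
  profiles <- by_year |>
    group_by(.data$accepted_name) |>
    summarise(
      in_online = any(.data$source == "online"),
      in_lemis = any(.data$source == "lemis"),
      in_cites = any(.data$source == "cites"),
      detection_years = list(sort(unique(
        .data$year[!is.na(.data$year)]))),
      .groups = "drop") |>
    mutate(
      n_sources = .data$in_online + .data$in_lemis + .data$in_cites,
      first_year = purrr::map_int(.data$detection_years,
                                  ~ if (length(.x) == 0) NA_integer_ else
                                    min(.x)),
      snapshot_only = lengths(.data$detection_years) == 0
    ) |>
    left_join(meta, by = "accepted_name") |>
    select("accepted_name", "group", "in_online", "in_lemis", "in_cites",
           "n_sources", "detection_years", "first_year", "snapshot_only",
           "description_year") |>
    arrange(.data$accepted_name)
  attr(profiles, "by_year") <- by_year
  class(profiles) <- c("trade_profiles", class(profiles))
  profiles
}

#' @describeIn combine_sources One-row totals: species per source, overlap
#'   share detected only online, and source counts.
#' @param x A `trade_profiles` tibble.
#' @param ... Unused.
#' @export
glance.trade_profiles <- function(x, ...) {
  tibble(
    n_species = nrow(x),
    n_online = sum(x$in_online),
    n_lemis = sum(x$in_lemis),
    n_cites = sum(x$in_cites),
    n_online_only = sum(x$in_online & !x$in_lemis & !x$in_cites),
    pct_online_only = 100 * sum(x$in_online & !x$in_lemis & !x$in_cites) /
      nrow(x),
    n_all_three = sum(x$in_online & x$in_lemis & x$in_cites)
  )
}

#' Count species in every source-membership combination
#'
#' UpSet-style counts over the seven non-empty combinations of
#' online/LEMIS/CITES membership; the combination counts partition the
#' species total.
#'
#' @param profiles A [combine_sources()] tibble.
#' @return Tibble with logical columns `online`, `lemis`, `cites` and `n`
#'   (all seven combinations present, zeros included).
#' @export
count_source_overlap <- function(profiles) {
  combos <- tidyr::expand_grid(online = c(TRUE, FALSE),
                               lemis = c(TRUE, FALSE),
                               cites = c(TRUE, FALSE)) |>
    filter(.data$online | .data$lemis | .data$cites)
  observed <- profiles |>
    count(online = .data$in_online, lemis = .data$in_lemis,
          cites = .data$in_cites)
  combos |>
    left_join(observed, by = c("online", "lemis", "cites")) |>
    mutate(n = tidyr::replace_na(.data$n, 0L)) |>
    arrange(dplyr::desc(.data$n))
}

#' Species per year and species unique to a year
#'
#' For every dated year, the number of species detected (any source) and
#' the number of species whose entire dated detection-year set is that
#' single year.
#'
#' @param profiles A [combine_sources()] tibble (its `"by_year"` attribute
#'   supplies the long table).
#' @return Tibble `year`, `n_species`, `n_unique`.
#' @export
species_per_year <- function(profiles) {
  by_year <- attr(profiles, "by_year")
  dated <- by_year |>
    filter(!is.na(.data$year)) |>
    distinct(.data$accepted_name, .data$year)
  singletons <- dated |>
    group_by(.data$accepted_name) |>
    filter(dplyr::n_distinct(.data$year) == 1) |>
    ungroup()
  dated |>
    count(.data$year, name = "n_species") |>
    left_join(count(singletons, .data$year, name = "n_unique"),
              by = "year") |>
    mutate(n_unique = tidyr::replace_na(.data$n_unique, 0L)) |>
    arrange(.data$year)
}

#' Lag between species description and first dated trade detection
#'
#' For species described after `cutoff_year`, the lag is the first dated
#' detection year minus the description year. Species seen only in the
#' undated contemporary snapshot have no first dated year: they are
#' excluded from the lag statistics and counted separately. Negative lags
#' (detection recorded before description) are retained and flagged.
#'
#' @param profiles A [combine_sources()] tibble.
#' @param cutoff_year Keep species with `description_year > cutoff_year`
#'   (default 1999).
#' @return Tibble of per-species lags (`accepted_name`, `group`,
#'   `description_year`, `first_year`, `lag`, `negative_lag`), with
#'   attribute `"summary"`: per-group and overall `n`, `mean_lag`, `sd_lag`,
#'   `n_snapshot_only`, `n_within_1yr`, `n_same_year`.
#' @export
description_lag <- function(profiles, cutoff_year = 1999) {
  cohort <- profiles |>
    filter(!is.na(.data$description_year),
           .data$description_year > cutoff_year)
  n_unknown <- sum(is.na(profiles$description_year))
  if (n_unknown > 0) {
    message("description_lag: ", n_unknown,
            " species with unknown description year excluded")
  }
  dated <- cohort |>
    filter(!.data$snapshot_only) |>
    mutate(lag = .data$first_year - .data$description_year,
           negative_lag = .data$lag < 0) |>
    select("accepted_name", "group", "description_year", "first_year",
           "lag", "negative_lag")
  summarise_block <- function(d, label) {
    tibble(group = label, n = nrow(d),
           mean_lag = if (nrow(d) > 0) mean(d$lag) else NA_real_,
           sd_lag = if (nrow(d) > 1) sd(d$lag) else NA_real_,
           n_within_1yr = sum(d$lag <= 1),
           n_same_year = sum(d$lag == 0))
  }
  summary <- bind_rows(
    summarise_block(dated, "all"),
    dated |> group_by(.data$group) |>
      dplyr::group_map(~ summarise_block(.x, .y$group)) |> bind_rows()
  ) |>
    mutate(n_snapshot_only = sum(cohort$snapshot_only))
  attr(dated, "summary") <- summary
  dated
}

#' Per-site species richness
#'
#' Distinct accepted species per site within one snapshot, with the
#' mean/SE/range computed over sites with at least one species detected
#' (SE = sample SD / sqrt(n)). The all-sites mean (zero-detection sites in
#' the denominator) is also reported when `all_sites` is given.
#'
#' @param detections Detection tibble restricted to the snapshot of
#'   interest (species rows only are counted).
#' @param all_sites Optional character vector of every sampled site id,
#'   used to count zero-detection sites.
#' @return Tibble `site_id`, `n_species`, with attribute `"summary"`
#'   (one row: `n_sites_detected`, `n_sites_zero`, `mean_species`,
#'   `se_species`, `min_species`, `max_species`, `mean_all_sites`).
#' @export
per_site_richness <- function(detections, all_sites = NULL) {
  per_site <- detections |>
    filter(.data$match_kind != "genus_only",
           !is.na(.data$accepted_name)) |>
    group_by(.data$site_id) |>
    summarise(n_species = dplyr::n_distinct(.data$accepted_name)) |>
    ungroup() |>
    arrange(dplyr::desc(.data$n_species))
  n_zero <- if (is.null(all_sites)) NA_integer_ else
    length(setdiff(all_sites, per_site$site_id))
  x <- per_site$n_species
  summary <- tibble(
    n_sites_detected = length(x),
    n_sites_zero = n_zero,
    mean_species = if (length(x) > 0) mean(x) else NA_real_,
    se_species = if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_,
    min_species = if (length(x) > 0) min(x) else NA_integer_,
    max_species = if (length(x) > 0) max(x) else NA_integer_,
    mean_all_sites = if (!is.null(all_sites) && length(all_sites) > 0)
      sum(x) / length(unique(c(all_sites, per_site$site_id)))
    else NA_real_
  )
  attr(per_site, "summary") <- summary
  per_site
}

#' Bar chart of source-overlap combination counts
#'
#' @param profiles A [combine_sources()] tibble.
#' @return A ggplot object.
#' @export
plot_source_overlap <- function(profiles) {
  count_source_overlap(profiles) |>
    mutate(combo = paste0(if_else(.data$online, "online+", ""),
                          if_else(.data$lemis, "lemis+", ""),
                          if_else(.data$cites, "cites+", "")),
           combo = sub("\\+$", "", .data$combo)) |>
    ggplot2::ggplot(ggplot2::aes(
      x = stats::reorder(.data$combo, -.data$n), y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "source combination", y = "species") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Line chart of species detected per year and year-unique species
#'
#' @param yearly Output of [species_per_year()].
#' @return A ggplot object.
#' @export
plot_species_per_year <- function(yearly) {
  yearly |>
    tidyr::pivot_longer(c("n_species", "n_unique"), names_to = "series",
                        values_to = "n") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$year, y = .data$n,
                                 colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(
      values = c(n_species = "grey25", n_unique = "firebrick"),
      labels = c(n_species = "species detected",
                 n_unique = "unique to year")) +
    ggplot2::labs(x = "year", y = "species", colour = NULL) +
    ggplot2::theme_minimal()
}
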