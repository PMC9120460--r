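# Range digitisation: textual range assertions (country, region, "A to B"
# span, island) are turned into standardised country-level presence, the
# basis for endemism and per-country trade-exposure summaries. Span
# assertions are expanded through the convex hull of the centroids of the
# listed areas: every country whose centroid falls inside or on the hull is
# added. This centroid-in-hull rule approximates polygon intersection and
# keeps the pipeline free of border geometry; coordinates are decimal
# degrees (lon, lat) on the raw plane, adequate at continental scale.

#' Read a country reference table
#'
#' @param path CSV with columns `country_id`, `name`, `aliases`
#'   (pipe-separated, may be empty), `lon`, `lat` (centroid, decimal
#'   degrees).
#' @return Tibble with those columns (aliases kept packed).
#' @export
read_country_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           country_id = "c", name = "c", aliases = "c",
                           lon = "d", lat = "d"))
  stopifnot(!anyDuplicated(tab$country_id),
            all(abs(tab$lon) <= 180), all(abs(tab$lat) <= 90))
  tab$aliases[is.na(tab$aliases)] <- ""
  tab
}

alias_lookup <- function(table) {
  long <- table |>
    mutate(alias = purrr::map2(.data$name, .data$aliases, function(n, a) {
      extra <- strsplit(a, "|", fixed = TRUE)[[1]]
      unique(c(n, extra[nzchar(extra)]))
    })) |>
    select("country_id", "alias") |>
    tidyr::unnest_longer("alias") |>
    mutate(alias = tolower(stringr::str_squish(.data$alias)))
  setNames(long$country_id, long$alias)
}

#' Standardise raw country names against the reference table
#'
#' Exact or alias match, case-insensitive. Unmatched names are returned in
#' a correction worklist (attribute `"worklist"`), never silently dropped:
#' an empty worklist is the endpoint of range digitisation.
#'
#' @param raw_names Character vector of raw country names.
#' @param table Country table from [read_country_table()].
#' @return Tibble `raw`, `country_id` (NA when unmatched), `matched`;
#'   attribute `"worklist"` lists distinct unmatched names.
#' @export
standardise_country <- function(raw_names, table) {
  lk <- alias_lookup(table)
  ids <- unname(lk[tolower(stringr::str_squish(raw_names))])
  out <- tibble(raw = raw_names, country_id = ids,
                matched = !is.na(ids))
  attr(out, "worklist") <- sort(unique(raw_names[is.na(ids)]))
  out
}

#' Expand a named region to its country set
#'
#' @param region_name Region name (case-insensitive).
#' @param region_map Tibble `region`, `country_id` (one row per member
#'   country) — a shipped, editable table.
#' @return Character vector of `country_id`s; unknown regions return an
#'   empty set with attribute `"worklist"` naming the region.
#' @export
expand_region <- function(region_name, region_map) {
  hit <- region_map$country_id[tolower(region_map$region) ==
                                 tolower(stringr::str_squish(region_name))]
  if (length(hit) == 0) {
    return(structure(character(0), worklist = region_name))
  }
  unique(hit)
}

# Point-in-convex-hull with boundary inclusion: the point is inside iff the
# cross products against every hull edge share a sign (zero = on an edge).
in_convex_hull <- function(px, py, hx, hy, tol = 1e-9) {
  n <- length(hx)
  nxt <- c(seq_len(n)[-1], 1L)
  cross <- (hx[nxt] - hx) * (py - hy) - (hy[nxt] - hy) * (px - hx)
  all(cross >= -tol) || all(cross <= tol)
}

#' Expand a "to" span through the convex hull of listed-area centroids
#'
#' Each listed area is resolved to countries (directly, or through the
#' region map); the convex hull of their centroids is computed and every
#' country of the reference table whose centroid lies inside or on the hull
#' is added to the listed countries. With fewer than three distinct
#' centroids, or collinear centroids, the hull degenerates and only the
#' listed countries are returned. Spans wider than 180 degrees of longitude
#' are geometrically ill-posed on the lon/lat plane and are returned as the
#' listed set, flagged with attribute `"antimeridian"`.
#'
#' @param listed_areas Character vector of country or region names.
#' @param table Country table.
#' @param region_map Region map tibble (optional).
#' @return Character vector of `country_id`s (always a superset of the
#'   resolvable listed countries); attribute `"worklist"` carries
#'   unresolvable areas, if any.
#' @export
expand_span <- function(listed_areas, table, region_map = NULL) {
  worklist <- character(0)
  ids <- unique(unlist(purrr::map(listed_areas, function(a) {
    std <- standardise_country(a, table)
    if (std$matched[1]) return(std$country_id[1])
    if (!is.null(region_map)) {
      r <- expand_region(a, region_map)
      if (length(r) > 0) return(r)
    }
    worklist <<- c(worklist, a)
    NULL
  })))
  if (length(ids) == 0) {
    return(structure(character(0), worklist = worklist, unmappable = TRUE))
  }
  pts <- table[match(ids, table$country_id), ]
  uniq <- distinct(pts, .data$lon, .data$lat)
  out <- ids
  if (nrow(uniq) >= 3 &&
      diff(range(uniq$lon)) < 180) {
    h <- grDevices::chull(uniq$lon, uniq$lat)
    if (length(h) >= 3) {
      hx <- uniq$lon[h]; hy <- uniq$lat[h]
      inside <- vapply(seq_len(nrow(table)), function(i) {
        in_convex_hull(table$lon[i], table$lat[i], hx, hy)
      }, logical(1))
      out <- unique(c(ids, table$country_id[inside]))
    }
  } else if (diff(range(uniq$lon)) >= 180) {
    attr(out, "antimeridian") <- TRUE
  }
  if (length(worklist) > 0) attr(out, "worklist") <- worklist
  out
}

#' Digitise range assertions into country-level presence
#'
#' Unions, per species, the countries from all four assertion kinds:
#' `country` (standardised directly), `region` (expanded through the region
#' map), `span` (hull-expanded with [expand_span()]; listed areas packed
#' with `";"` in `raw_text`), and `island` (replaced by its sovereign
#' country through the island map). Duplicates are removed; "introduced"
#' localities are assumed excluded upstream.
#'
#' @param assertions Tibble `accepted_name`, `kind` (one of `country`,
#'   `region`, `span`, `island`), `raw_text`.
#' @param table Country table from [read_country_table()].
#' @param region_map Tibble `region`, `country_id`.
#' @param island_map Tibble `island`, `country_id` (island name to
#'   sovereign country).
#' @return Long tibble `accepted_name`, `country_id`, `kind` (first kind
#'   that asserted the country), one row per species-country connection;
#'   attributes `"worklist"` (unmatched names), `"unmappable"` (species
#'   with zero mappable assertions) and `"n_connections"`.
#' @export
build_country_ranges <- function(assertions, table, region_map = NULL,
                                 island_map = NULL) {
  stopifnot(all(assertions$kind %in% c("country", "region", "span",
                                       "island")))
  worklist <- character(0)
  rows <- purrr::pmap(
    list(assertions$accepted_name, assertions$kind, assertions$raw_text),
    function(sp, kind, txt) {
      ids <- switch(
        kind,
        country = {
          std <- standardise_country(txt, table)
          worklist <<- c(worklist, attr(std, "worklist"))
          std$country_id[std$matched]
        },
        region = {
          r <- if (is.null(region_map)) character(0) else
            expand_region(txt, region_map)
          if (length(r) == 0) worklist <<- c(worklist, txt)
          r
        },
        span = {
          areas <- stringr::str_squish(
            strsplit(txt, ";", fixed = TRUE)[[1]])
          r <- expand_span(areas[nzchar(areas)], table, region_map)
          worklist <<- c(worklist, attr(r, "worklist"))
          as.character(r)
        },
        island = {
          hit <- if (is.null(island_map)) character(0) else
            island_map$country_id[tolower(island_map$island) ==
                                    tolower(stringr::str_squish(txt))]
          if (length(hit) == 0) worklist <<- c(worklist, txt)
          hit
        })
      if (length(ids) == 0) return(NULL)
      tibble(accepted_name = sp, country_id = ids, kind = kind)
    })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(accepted_name = character(0), country_id = character(0),
                  kind = character(0))
  }
  out <- out |>
    distinct(.data$accepted_name, .data$country_id, .keep_all = TRUE) |>
    arrange(.data$accepted_name, .data$country_id)
  unmappable <- setdiff(unique(assertions$accepted_name),
                        unique(out$accepted_name))
  attr(out, "worklist") <- sort(unique(worklist))
  attr(out, "unmappable") <- unmappable
  attr(out, "n_connections") <- nrow(out)
  message("build_country_ranges: ", nrow(out),
          " species-country connections (", length(unmappable),
          " unmappable species)")
  out
}

#' Per-country richness, trade exposure and endemism
#'
#' For every country: native species (from the digitised ranges), species
#' in trade, genera and traded genera, and single-country endemics in and
#' out of trade. A species is endemic when its whole digitised range is one
#' country. `min_traded_per_genus` optionally drops genera with that many
#' or fewer traded species before computing percentages (the
#' popular-groups variant).
#'
#' @param ranges Long tibble from [build_country_ranges()].
#' @param traded_species Character vector of accepted names in trade (e.g.
#'   `profiles$accepted_name` from [combine_sources()]).
#' @param min_traded_per_genus If not `NULL`, drop genera with `<=` this
#'   many traded species before computing the summary.
#' @return Tibble `country_id`, `n_species`, `n_traded`, `pct_traded`,
#'   `n_genera`, `n_genera_traded`, `n_endemic`, `n_endemic_traded`.
#' @export
country_trade_summary <- function(ranges, traded_species,
                                  min_traded_per_genus = NULL) {
  rng <- ranges |>
    mutate(genus = stringr::word(.data$accepted_name, 1),
           traded = .data$accepted_name %in% traded_species)
  if (!is.null(min_traded_per_genus)) {
    genus_traded <- rng |>
      distinct(.data$accepted_name, .data$genus, .data$traded) |>
      group_by(.data$genus) |>
      summarise(n_traded = sum(.data$traded)) |>
      filter(.data$n_traded > min_traded_per_genus)
    rng <- semi_join(rng, genus_traded, by = "genus")
  }
  endemics <- rng |>
    group_by(.data$accepted_name) |>
    filter(dplyr::n_distinct(.data$country_id) == 1) |>
    ungroup() |>
    pull("accepted_name") |> unique()
  rng |>
    group_by(.data$country_id) |>
    summarise(
      n_species = dplyr::n_distinct(.data$accepted_name),
      n_traded = dplyr::n_distinct(.data$accepted_name[.data$traded]),
      pct_traded = 100 * .data$n_traded / .data$n_species,
      n_genera = dplyr::n_distinct(.data$genus),
      n_genera_traded = dplyr::n_distinct(.data$genus[.data$traded]),
      n_endemic = dplyr::n_distinct(
        .data$accepted_name[.data$accepted_name %in% endemics]),
      n_endemic_traded = dplyr::n_distinct(
        .data$accepted_name[.data$accepted_name %in% endemics &
                              .data$traded])
    ) |>
    ungroup() |>
    arrange(dplyr::desc(.data$n_species))
}

#' Share of species whose digitised range is a single country
#'
#' @param ranges Long tibble from [build_country_ranges()].
#' @return One-row tibble `n_species`, `n_endemic`, `pct_endemic`.
#' @export
endemism_summary <- function(ranges) {
  per_sp <- ranges |>
    group_by(.data$accepted_name) |>
    summarise(n_countries = dplyr::n_distinct(.data$country_id)) |>
    ungroup()
  tibble(
    n_species = nrow(per_sp),
    n_endemic = sum(per_sp$n_countries == 1),
    pct_endemic = 100 * sum(per_sp$n_countries == 1) / nrow(per_sp),
    pct_under_5 = 100 * sum(per_sp$n_countries < 5) / nrow(per_sp)
  )
}

#' Scatter of per-country richness against trade exposure
#'
#' @param summary Output of [country_trade_summary()].
#' @return A ggplot object.
#' @export
plot_country_trade <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$n_species,
                                        y = .data$n_traded)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$pct_traded),
                        alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "native species (log)", y = "species in trade",
                  size = "% traded") +
    ggplot2::theme_minimal()
}
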