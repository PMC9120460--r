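# Seeded synthetic-data generators. Every generator records its ground
# truth, so each pipeline stage can be tested offline against planted
# values. Pseudo-names are built from syllable alphabets disjoint from real
# genera (and from the shipped blocklist): genus tokens use one alphabet,
# epithets another, so an epithet can never trigger a genus prefix match,
# and all tokens of one class have equal length, so no name is a proper
# prefix of another. Pages are laid out so that planted colour words fall
# inside exactly one genus context window.

SYL_GEN <- c("xan", "zel", "vor", "wix", "kru", "dru", "bly", "gof", "hax",
             "jil", "mev", "tyx", "quz", "fep", "rog", "sab", "nuv", "kel",
             "pim", "osk")
SYL_EP <- c("pax", "nid", "tor", "ful", "ges", "lim", "rop", "sul", "ven",
            "daz", "cob", "muh", "rik", "zet", "bol", "gur", "hiv", "jop",
            "lud", "nof")
DECOY_WORDS <- c("terrarium", "breeding", "adult", "juvenile", "female",
                 "male", "available", "stock", "price", "shipping",
                 "captive", "keeper", "enclosure", "cricket", "feeder",
                 "substrate", "moult", "hobby", "listing", "order")
LOCALITY_WORDS <- c("Northreach", "Eastvale", "Stonegate", "Riverbend",
                    "Highcliff")
PLANT_COLOURS <- c("blue", "red", "green", "black", "golden", "violet",
                   "orange", "ivory")

make_tokens <- function(n, syllables, parts) {
  grid <- do.call(expand.grid,
                  c(rep(list(syllables), parts),
                    list(stringsAsFactors = FALSE)))
  words <- do.call(paste0, grid)
  stopifnot(n <= length(words))
  sample(words, n)
}

cap <- function(x) paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))

#' Generate a synthetic taxonomic registry
#'
#' Produces a checklist (one row per accepted species) with synonym
#' histories including cross-genus moves and abbreviated-genus synonyms.
#' The number of synonyms per species is Poisson(`synonym_rate`), so the
#' mean number of names per species is about `1 + synonym_rate`; the
#' default 0.81 reproduces the observed mean of ~1.8 names per species in
#' real checklists with synonymy. Abbreviated synonyms always abbreviate
#' the accepted genus, so the first-initial repair recovers them exactly.
#'
#' @param n_species,n_genera Registry size (`n_species >= n_genera >= 1`).
#' @param synonym_rate Mean synonyms per species (`>= 0`).
#' @param abbrev_rate Probability a synonym is written with an abbreviated
#'   genus in the checklist file (in `[0, 1]`).
#' @param group Group label for the checklist.
#' @param seed Integer seed; runs are fully deterministic.
#' @param out_dir If not `NULL`, the checklist CSV is written here as
#'   `checklist_<group>.csv`.
#' @return List with `checklist` (the raw file tibble: `genus`, `epithet`,
#'   `family`, `year`, `synonyms` packed with `";"`, `nomen_dubium`),
#'   `truth` (tibble `accepted_name`, `name` — every name each species
#'   carries, post-repair, normalised — plus `kind`), and `path` (or
#'   `NULL`).
#' @export
gen_registry <- function(n_species = 120, n_genera = 25,
                         synonym_rate = 0.81, abbrev_rate = 0.1,
                         group = "spider", seed = 1, out_dir = NULL) {
  stopifnot(n_species >= n_genera, n_genera >= 1, synonym_rate >= 0,
            abbrev_rate >= 0, abbrev_rate <= 1)
  set.seed(seed)
  genera <- cap(make_tokens(n_genera + 5, SYL_GEN, 2))
  dead_genera <- genera[n_genera + seq_len(5)]  # only ever used in synonyms
  genera <- genera[seq_len(n_genera)]
  n_fam <- max(1L, ceiling(n_genera / 3))
  families <- paste0(cap(make_tokens(n_fam, SYL_GEN, 2)), "idae")
  genus_family <- setNames(sample(families, n_genera, replace = TRUE),
                           genera)
  epithet_pool <- make_tokens(n_species * 6 + 50, SYL_EP, 3)
  sp_epithets <- epithet_pool[seq_len(n_species)]
  syn_epithets <- epithet_pool[-seq_len(n_species)]
  sp_genus <- c(genera, sample(genera, n_species - n_genera,
                               replace = TRUE))

  used <- 0L
  rows <- purrr::map(seq_len(n_species), function(i) {
    accepted <- paste(sp_genus[i], sp_epithets[i])
    k <- stats::rpois(1, synonym_rate)
    syn_full <- character(0)
    if (k > 0) {
      for (j in seq_len(k)) {
        cross <- stats::runif(1) < 0.5
        g <- if (cross) sample(c(genera, dead_genera), 1) else sp_genus[i]
        e <- if (cross && stats::runif(1) < 0.5) sp_epithets[i] else {
          used <<- used + 1L
          syn_epithets[used]
        }
        syn_full <- c(syn_full, paste(g, e))
      }
      syn_full <- setdiff(unique(syn_full), accepted)
    }
    written <- syn_full
    if (length(written) > 0) {
      abbrev <- stats::runif(length(written)) < abbrev_rate &
        stringr::word(written, 1) == sp_genus[i]
      written[abbrev] <- paste0(substr(sp_genus[i], 1, 1), ". ",
                                stringr::word(written[abbrev], 2))
    }
    list(
      file_row = tibble(
        genus = sp_genus[i], epithet = sp_epithets[i],
        family = unname(genus_family[sp_genus[i]]),
        year = sample(1900:2021, 1),
        synonyms = paste(written, collapse = ";"),
        nomen_dubium = stats::runif(1) < 0.05
      ),
      truth = tibble(
        accepted_name = accepted,
        name = normalise_name(c(accepted, syn_full)),
        kind = c("accepted", rep("synonym", length(syn_full)))
      )
    )
  })
  checklist <- bind_rows(purrr::map(rows, "file_row"))
  truth <- bind_rows(purrr::map(rows, "truth"))
  path <- NULL
  if (!is.null(out_dir)) {
    path <- file.path(out_dir, paste0("checklist_", group, ".csv"))
    readr::write_csv(checklist, path, progress = FALSE)
  }
  list(checklist = checklist, truth = truth, path = path)
}

#' Generate a synthetic shop-page corpus with planted detections
#'
#' Writes HTML pages embedding planted binomials (accepted name or a
#' synonym, recorded which), colour words immediately after a planted name
#' with probability `colour_prob`, genus-plus-`"sp"`-plus-locality listings
#' with probability `locality_prob` per page, and decoy text. Listings are
#' spaced so each planted colour falls inside exactly one genus context
#' window. Adversarial mode adds left-boundary traps (a genus token
#' continued into a longer word, which the left-boundary matcher is meant
#' to hit as genus-only) and split binomials (genus and epithet separated
#' by another token) that must not be detected as species.
#'
#' Sites are archived with probability `archive_prob`; archived pages get
#' dated snapshot years from `year_range`, contemporary pages get `NA`.
#'
#' @param registry A [load_checklist()] registry tibble (or the `checklist`
#'   loaded through it).
#' @param n_sites,pages_per_site,species_per_page Corpus dimensions.
#' @param colour_prob,locality_prob,archive_prob Planting probabilities.
#' @param adversarial Add traps (default `FALSE`).
#' @param year_range Candidate years for archived pages.
#' @param seed Integer seed.
#' @param out_dir Directory for page files and `manifest.csv` (created if
#'   needed; required).
#' @return List with `manifest` (path), `truth` (list of tibbles:
#'   `detections` — `site_id`, `page_id`, `snapshot_year`, `accepted_name`,
#'   `used_name`, `kind`; `colours` — `genus_token`, `colour_term`, `n`;
#'   `genus_only` — planted locality/trap genus mentions).
#' @export
gen_corpus <- function(registry, n_sites = 8, pages_per_site = 4,
                       species_per_page = 4, colour_prob = 0.3,
                       locality_prob = 0.1, archive_prob = 0.4,
                       adversarial = FALSE, year_range = 2014:2020,
                       seed = 1, out_dir) {
  stopifnot(nrow(registry) >= species_per_page)
  set.seed(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  site_archived <- stats::runif(n_sites) < archive_prob
  det_rows <- list(); col_rows <- list(); gonly_rows <- list()
  man_rows <- list()
  for (s in seq_len(n_sites)) {
    site_id <- sprintf("site%02d", s)
    for (p in seq_len(pages_per_site)) {
      page_id <- sprintf("p%02d", p)
      year <- if (site_archived[s]) sample(year_range, 1) else NA_integer_
      toks <- sample(DECOY_WORDS, 2)
      # dated pages only list species already described by that year
      pool <- registry
      if (!is.na(year)) {
        eligible <- is.na(registry$description_year) |
          registry$description_year <= year
        if (sum(eligible) >= species_per_page) pool <- registry[eligible, ]
      }
      planted <- pool[sample(nrow(pool), species_per_page), ]
      for (i in seq_len(nrow(planted))) {
        syns <- planted$synonyms[[i]]
        use_syn <- length(syns) > 0 && stats::runif(1) < 0.3
        used <- if (use_syn) sample(syns, 1) else planted$accepted_name[i]
        parts <- tokenise(used)
        toks <- c(toks, cap(parts[1]), parts[2])
        colour <- NULL
        if (stats::runif(1) < colour_prob) {
          colour <- sample(PLANT_COLOURS, 1)
          toks <- c(toks, paste0("“", cap(colour), "”"))
          col_rows[[length(col_rows) + 1]] <-
            tibble(genus_token = tolower(parts[1]), colour_term = colour)
        }
        toks <- c(toks, sample(DECOY_WORDS, 4, replace = TRUE))
        det_rows[[length(det_rows) + 1]] <- tibble(
          site_id = site_id, page_id = page_id, snapshot_year = year,
          accepted_name = planted$accepted_name[i],
          used_name = normalise_name(used),
          kind = if (use_syn) "synonym" else "exact_current")
      }
      if (stats::runif(1) < locality_prob) {
        g <- sample(registry$genus, 1)
        toks <- c(toks, g, "sp.", sample(LOCALITY_WORDS, 1),
                  sample(DECOY_WORDS, 4, replace = TRUE))
        gonly_rows[[length(gonly_rows) + 1]] <-
          tibble(site_id = site_id, page_id = page_id,
                 genus_token = tolower(g), trap = "locality")
      }
      if (adversarial) {
        g1 <- sample(registry$genus, 1)
        toks <- c(toks, paste0(g1, "idae"),
                  sample(DECOY_WORDS, 4, replace = TRUE))
        gonly_rows[[length(gonly_rows) + 1]] <-
          tibble(site_id = site_id, page_id = page_id,
                 genus_token = tolower(g1), trap = "prefix")
        j <- sample(nrow(registry), 1)
        toks <- c(toks, registry$genus[j], sample(DECOY_WORDS, 1),
                  registry$epithet[j],
                  sample(DECOY_WORDS, 4, replace = TRUE))
        gonly_rows[[length(gonly_rows) + 1]] <-
          tibble(site_id = site_id, page_id = page_id,
                 genus_token = tolower(registry$genus[j]), trap = "split")
      }
      html <- paste0("<html><head><title>stock</title>",
                     "<script>var x = 1;</script></head><body><p>",
                     paste(toks, collapse = " "),
                     "</p></body></html>")
      fname <- sprintf("%s_%s.html", site_id, page_id)
      writeLines(html, file.path(out_dir, fname), useBytes = TRUE)
      man_rows[[length(man_rows) + 1]] <-
        tibble(path = fname, site_id = site_id, page_id = page_id,
               snapshot_year = year)
    }
  }
  manifest <- file.path(out_dir, "manifest.csv")
  readr::write_csv(bind_rows(man_rows), manifest, progress = FALSE)
  colours <- if (length(col_rows) == 0) {
    tibble(genus_token = character(0), colour_term = character(0),
           n = integer(0))
  } else {
    bind_rows(col_rows) |> count(.data$genus_token, .data$colour_term)
  }
  list(manifest = manifest,
       truth = list(detections = bind_rows(det_rows),
                    colours = colours,
                    genus_only = bind_rows(gonly_rows)))
}

#' Generate synthetic LEMIS-like import records
#'
#' Draws description/disposition/purpose/source codes and quantities from
#' configurable frequencies; defaults echo the code mix of real arachnid
#' import ledgers (live-specimen dominated, ~2/3 wild-sourced, seizures
#' rare, overwhelmingly commercial). When `per_genus_wild_fractions` names
#' a genus, its records draw source `W` with that probability and `C`
#' otherwise. About 8% of rows are genus-level only (blank species), and a
#' few carry the placeholder genus `"Non-CITES entry"`.
#'
#' @param registry Registry tibble.
#' @param n_records Number of records.
#' @param code_frequencies Named list of named probability vectors for
#'   `description`, `disposition`, `purpose`, `source`; each must sum to 1.
#' @param per_genus_wild_fractions Named numeric vector (genus -> wild
#'   probability), optional.
#' @param species_coverage Fraction of registry species that appear in the
#'   import ledger at all (default 0.25): import records cover a far
#'   narrower species pool than online listings, which is what makes
#'   online-only species the dominant overlap class.
#' @param countries Character vector of origin-country names to sample.
#' @param seed Integer seed.
#' @param out_dir If not `NULL`, writes `lemis.csv` in the public
#'   compilation's column dialect.
#' @return List with `records` (logical-field tibble as [read_lemis()]
#'   returns), `truth` (list: `totals` one-row tibble of realised
#'   quantity-weighted percentages computed directly from the drawn codes;
#'   `per_genus_wild` realised wild fractions), and `path`.
#' @export
gen_lemis <- function(registry, n_records = 10000,
                      code_frequencies = list(), per_genus_wild_fractions = NULL,
                      species_coverage = 0.25,
                      countries = paste0("Origin", 1:6), seed = 1,
                      out_dir = NULL) {
  defaults <- list(
    description = c(LIV = 0.7, SPE = 0.06, DEA = 0.04, BOD = 0.02,
                    EGL = 0.02, SKI = 0.02, TRO = 0.02, SHE = 0.06,
                    PRT = 0.06),
    disposition = c(C = 0.9766, S = 0.0034, I = 0.02),
    purpose = c(T = 0.90, P = 0.04, M = 0.02, S = 0.03, Y = 0.01),
    source = setNames(c(0.67, 0.20, 0.03, 0.05, 0.02, 0.02, 0.01),
                      c("W", "C", "F", "D", "R", "I", ""))
  )
  code_frequencies <- utils::modifyList(defaults, code_frequencies)
  for (fam in names(code_frequencies)) {
    if (abs(sum(code_frequencies[[fam]]) - 1) > 1e-8) {
      stop("code_frequencies$", fam, " must sum to 1", call. = FALSE)
    }
  }
  set.seed(seed)
  draw <- function(p, n) sample(names(p), n, replace = TRUE, prob = p)
  pool <- sample(nrow(registry),
                 max(1L, round(species_coverage * nrow(registry))))
  idx <- pool[sample.int(length(pool), n_records, replace = TRUE)]
  genus <- registry$genus[idx]
  species <- registry$epithet[idx]
  genus_only <- stats::runif(n_records) < 0.08
  species[genus_only] <- NA_character_
  placeholder <- stats::runif(n_records) < 0.01
  genus[placeholder] <- "Non-CITES entry"
  species[placeholder] <- NA_character_

  source <- draw(code_frequencies$source, n_records)
  if (!is.null(per_genus_wild_fractions)) {
    for (g in names(per_genus_wild_fractions)) {
      m <- genus == g
      source[m] <- if_else(
        stats::runif(sum(m)) < per_genus_wild_fractions[[g]], "W", "C")
    }
  }
  records <- tibble(
    taxon_class = "Arachnida",
    genus = genus, species = species,
    quantity = sample(1:100, n_records, replace = TRUE),
    description = draw(code_frequencies$description, n_records),
    disposition = draw(code_frequencies$disposition, n_records),
    purpose = draw(code_frequencies$purpose, n_records),
    source = source,
    country_origin = sample(countries, n_records, replace = TRUE),
    # a species is never shipped before its description year
    shipment_year = {
      dy <- registry$description_year[idx]
      lo <- pmax(2000L, ifelse(is.na(dy), 2000L, dy))
      as.integer(lo + floor(stats::runif(n_records) * (2022L - lo)))
    }
  )

  # realised truth, straight arithmetic on the drawn codes
  whole <- records$description %in% WHOLE_INDIVIDUAL_CODES
  q <- records$quantity
  tot <- sum(q[whole])
  totals <- tibble(
    total_individuals = tot,
    pct_seized = 100 * sum(q[whole & records$disposition == "S"]) / tot,
    pct_commercial = 100 * sum(q[whole & !records$purpose %in%
                                   NON_COMMERCIAL_PURPOSES]) / tot,
    pct_wild = 100 * sum(q[whole & records$source == "W"]) / tot,
    pct_captive = 100 * sum(q[whole & records$source %in%
                                CAPTIVE_SOURCE_CODES]) / tot,
    pct_other = 100 * sum(q[whole & records$source != "W" &
                              !records$source %in%
                                CAPTIVE_SOURCE_CODES]) / tot
  )
  wf <- records[whole & genus != "Non-CITES entry", ]
  per_genus_wild <- wf |>
    group_by(.data$genus) |>
    summarise(wild_fraction = sum(.data$quantity[.data$source == "W"]) /
                sum(.data$quantity)) |>
    ungroup()
  path <- NULL
  if (!is.null(out_dir)) {
    path <- file.path(out_dir, "lemis.csv")
    records |>
      rename(class = "taxon_class", specific_name = "species") |>
      readr::write_csv(path, progress = FALSE, na = "")
  }
  list(records = records,
       truth = list(totals = totals, per_genus_wild = per_genus_wild),
       path = path)
}

#' Generate a synthetic CITES gross-imports table
#'
#' Samples taxa from the registry (using a junior synonym for some, which
#' the reader must resolve) and spreads quantities over years.
#'
#' @param registry Registry tibble.
#' @param n_taxa Number of taxa in the export.
#' @param synonym_rate Probability a taxon is written under a synonym.
#' @param years Year columns to emit.
#' @param seed Integer seed.
#' @param out_dir If not `NULL`, writes `cites.csv`.
#' @return List with `table` (wide gross-imports tibble: `Taxon` + year
#'   columns), `truth` (tibble `taxon_raw`, `accepted_name`), `path`.
#' @export
gen_cites <- function(registry, n_taxa = 6, synonym_rate = 0.3,
                      years = 2005:2020, seed = 1, out_dir = NULL) {
  set.seed(seed)
  pick <- registry[sample(nrow(registry), min(n_taxa, nrow(registry))), ]
  taxon <- purrr::map2_chr(pick$accepted_name, pick$synonyms, function(a, s) {
    if (length(s) > 0 && stats::runif(1) < synonym_rate) sample(s, 1) else a
  })
  wide <- tibble(Taxon = cap(taxon))
  desc <- pick$description_year
  for (y in years) {
    q <- ifelse(stats::runif(nrow(wide)) < 0.4,
                sample(1:500, nrow(wide), replace = TRUE), NA_real_)
    # no imports recorded before a species was described
    q[!is.na(desc) & desc > y] <- NA_real_
    wide[[as.character(y)]] <- q
  }
  path <- NULL
  if (!is.null(out_dir)) {
    path <- file.path(out_dir, "cites.csv")
    readr::write_csv(wide, path, progress = FALSE, na = "")
  }
  list(table = wide,
       truth = tibble(taxon_raw = wide$Taxon,
                      accepted_name = pick$accepted_name),
       path = path)
}

#' Generate a synthetic world: country table, region map, island map
#'
#' Countries are placed in well-separated longitudinal clusters (each
#' cluster is one named region), so a convex hull over any one cluster's
#' centroids can never contain another cluster's centroid.
#'
#' @param n_clusters,countries_per_cluster World dimensions.
#' @param seed Integer seed.
#' @param out_dir If not `NULL`, writes `country_table.csv`,
#'   `region_map.csv`, `island_map.csv`.
#' @return List with `country_table`, `region_map`, `island_map` tibbles
#'   and `paths`.
#' @export
gen_world <- function(n_clusters = 5, countries_per_cluster = 4, seed = 1,
                      out_dir = NULL) {
  set.seed(seed)
  centers <- seq(-150, 150, length.out = n_clusters)
  rows <- purrr::map(seq_len(n_clusters), function(k) {
    ids <- sprintf("C%d%02d", k, seq_len(countries_per_cluster))
    tibble(
      country_id = ids,
      name = paste0("Country ", ids),
      aliases = paste0("Alias", ids),
      lon = centers[k] + stats::runif(countries_per_cluster, -8, 8),
      lat = stats::runif(countries_per_cluster, -40, 40),
      region = paste0("Region ", k)
    )
  })
  world <- bind_rows(rows)
  country_table <- select(world, "country_id", "name", "aliases", "lon",
                          "lat")
  region_map <- select(world, "region", "country_id")
  island_map <- world |>
    group_by(.data$region) |>
    dplyr::slice(1) |>
    ungroup() |>
    mutate(island = paste0("Isle of ", .data$country_id)) |>
    select("island", "country_id")
  paths <- NULL
  if (!is.null(out_dir)) {
    paths <- file.path(out_dir, c("country_table.csv", "region_map.csv",
                                  "island_map.csv"))
    readr::write_csv(country_table, paths[1], progress = FALSE)
    readr::write_csv(region_map, paths[2], progress = FALSE)
    readr::write_csv(island_map, paths[3], progress = FALSE)
  }
  list(country_table = country_table, region_map = region_map,
       island_map = island_map, paths = paths)
}

#' Generate synthetic range assertions with planted country sets
#'
#' Each species is endemic (single country) with probability
#' `endemism_rate`; its assertion is a plain country row or, sometimes, an
#' island row resolving to that country. Non-endemic species receive one
#' whole cluster as their range, asserted either as a region row (with
#' probability `region_use_rate`) or as a `"to"` span listing every country
#' of the cluster — because clusters are geographically separated, the
#' hull expansion of such a span adds nothing, so the planted set is exact
#' ground truth. A redundant country assertion is sometimes added to
#' exercise de-duplication.
#'
#' @param registry Registry tibble.
#' @param world A [gen_world()] list.
#' @param endemism_rate,region_use_rate Planting probabilities.
#' @param seed Integer seed.
#' @param out_dir If not `NULL`, writes `range_assertions.csv`.
#' @return List with `assertions` (tibble `accepted_name`, `kind`,
#'   `raw_text`), `truth` (tibble `accepted_name`, `country_id`), `path`.
#' @export
gen_ranges <- function(registry, world, endemism_rate = 0.5,
                       region_use_rate = 0.3, seed = 1, out_dir = NULL) {
  set.seed(seed)
  tab <- world$country_table
  rmap <- world$region_map
  imap <- world$island_map
  clusters <- split(rmap$country_id, rmap$region)
  a_rows <- list(); t_rows <- list()
  for (i in seq_len(nrow(registry))) {
    sp <- registry$accepted_name[i]
    if (stats::runif(1) < endemism_rate) {
      cid <- sample(tab$country_id, 1)
      isle <- imap$island[imap$country_id == cid]
      if (length(isle) == 1 && stats::runif(1) < 0.3) {
        a_rows[[length(a_rows) + 1]] <-
          tibble(accepted_name = sp, kind = "island", raw_text = isle)
      } else {
        nm <- if (stats::runif(1) < 0.5) tab$name[tab$country_id == cid]
              else tab$aliases[tab$country_id == cid]
        a_rows[[length(a_rows) + 1]] <-
          tibble(accepted_name = sp, kind = "country", raw_text = nm)
      }
      t_rows[[length(t_rows) + 1]] <- tibble(accepted_name = sp,
                                             country_id = cid)
    } else {
      k <- sample(names(clusters), 1)
      members <- clusters[[k]]
      if (stats::runif(1) < region_use_rate) {
        a_rows[[length(a_rows) + 1]] <-
          tibble(accepted_name = sp, kind = "region", raw_text = k)
      } else {
        a_rows[[length(a_rows) + 1]] <-
          tibble(accepted_name = sp, kind = "span",
                 raw_text = paste(tab$name[match(members, tab$country_id)],
                                  collapse = ";"))
      }
      if (stats::runif(1) < 0.3) {
        a_rows[[length(a_rows) + 1]] <-
          tibble(accepted_name = sp, kind = "country",
                 raw_text = tab$name[tab$country_id == members[1]])
      }
      t_rows[[length(t_rows) + 1]] <- tibble(accepted_name = sp,
                                             country_id = members)
    }
  }
  assertions <- bind_rows(a_rows)
  truth <- bind_rows(t_rows) |>
    distinct(.data$accepted_name, .data$country_id) |>
    arrange(.data$accepted_name, .data$country_id)
  path <- NULL
  if (!is.null(out_dir)) {
    path <- file.path(out_dir, "range_assertions.csv")
    readr::write_csv(assertions, path, progress = FALSE)
  }
  list(assertions = assertions, truth = truth, path = path)
}

#' Generate a complete synthetic study in one directory
#'
#' Runs all generators with one seed (each stage derives its own sub-seed)
#' and writes checklists, corpus + manifest, LEMIS, CITES, world tables and
#' range assertions, plus the combined ground truth as
#' `ground_truth.json`.
#'
#' @param out_dir Output directory (created).
#' @param seed Integer master seed.
#' @param n_species,n_genera,n_sites,pages_per_site,species_per_page,
#'   n_lemis_records Study dimensions.
#' @param colour_prob,locality_prob,endemism_rate Planting rates.
#' @param adversarial Adversarial corpus mode.
#' @return List of generator outputs (`registry`, `corpus`, `lemis`,
#'   `cites`, `world`, `ranges`) plus `config`, a ready-made
#'   [run_pipeline()] configuration list.
#' @export
generate_study <- function(out_dir, seed = 1, n_species = 120,
                           n_genera = 25, n_sites = 8, pages_per_site = 4,
                           species_per_page = 4, n_lemis_records = 10000,
                           colour_prob = 0.3, locality_prob = 0.1,
                           endemism_rate = 0.5, adversarial = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  reg <- gen_registry(n_species, n_genera, seed = seed + 1,
                      out_dir = out_dir)
  registry <- load_checklist(file.path(out_dir, "checklist_spider.csv"),
                             group = "spider")
  corpus_dir <- file.path(out_dir, "corpus")
  corp <- gen_corpus(registry, n_sites, pages_per_site, species_per_page,
                     colour_prob, locality_prob,
                     adversarial = adversarial, seed = seed + 2,
                     out_dir = corpus_dir)
  lem <- gen_lemis(registry, n_lemis_records, seed = seed + 3,
                   out_dir = out_dir)
  cit <- gen_cites(registry, seed = seed + 4, out_dir = out_dir)
  wld <- gen_world(seed = seed + 5, out_dir = out_dir)
  rng <- gen_ranges(registry, wld, endemism_rate = endemism_rate,
                    seed = seed + 6, out_dir = out_dir)
  truth_path <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(
    list(registry = reg$truth, detections = corp$truth$detections,
         colours = corp$truth$colours, lemis_totals = lem$truth$totals,
         per_genus_wild = lem$truth$per_genus_wild,
         cites = cit$truth, ranges = rng$truth),
    truth_path, dataframe = "columns", na = "null")
  config <- list(
    checklists = list(spider = file.path(out_dir, "checklist_spider.csv")),
    corpus_root = corpus_dir,
    corpus_manifest = corp$manifest,
    lemis = lem$path,
    cites = cit$path,
    country_table = wld$paths[1],
    region_map = wld$paths[2],
    island_map = wld$paths[3],
    range_assertions = rng$path,
    basis = "any",
    out_dir = file.path(out_dir, "results")
  )
  list(registry = reg, corpus = corp, lemis = lem, cites = cit,
       world = wld, ranges = rng, config = config,
       registry_loaded = registry)
}
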