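test_that("registry generator is deterministic and sized as asked", {
  a <- gen_registry(10, 3, synonym_rate = 0, abbrev_rate = 0, seed = 1)
  expect_equal(nrow(a$checklist), 10)
  expect_equal(nrow(a$truth), 10)  # no synonyms: one name per species
  b <- gen_registry(10, 3, synonym_rate = 0, abbrev_rate = 0, seed = 1)
  expect_identical(a$checklist, b$checklist)
  # byte-identical files on identical seeds
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  gen_registry(50, 10, seed = 4, out_dir = d1)
  gen_registry(50, 10, seed = 4, out_dir = d2)
  expect_identical(readLines(file.path(d1, "checklist_spider.csv")),
                   readLines(file.path(d2, "checklist_spider.csv")))
})

test_that("mean names per species tracks 1 + synonym_rate", {
  reg <- gen_registry(400, 30, synonym_rate = 0.81, seed = 2)
  m <- nrow(reg$truth) / 400
  expect_lt(abs(m - 1.81), 0.15)  # Poisson sampling tolerance at n=400
})

test_that("abbreviated synonyms in files are repaired on load", {
  reg <- gen_registry(80, 10, synonym_rate = 1.5, abbrev_rate = 0.5,
                      seed = 3)
  expect_true(any(grepl("\\. ", reg$checklist$synonyms)))
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(reg$checklist, f)
  loaded <- suppressMessages(load_checklist(f, "spider"))
  idx <- build_name_index(loaded)
  res <- resolve_names(reg$truth$name, idx)
  expect_equal(res$accepted_name, reg$truth$accepted_name)
})

test_that("corpus generator plants recoverable pages deterministically", {
  reg <- gen_registry(20, 5, seed = 7)
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(reg$checklist, f)
  loaded <- suppressMessages(load_checklist(f, "spider"))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  c1 <- gen_corpus(loaded, n_sites = 2, pages_per_site = 2,
                   species_per_page = 3, seed = 8, out_dir = d1)
  c2 <- gen_corpus(loaded, n_sites = 2, pages_per_site = 2,
                   species_per_page = 3, seed = 8, out_dir = d2)
  for (fn in list.files(d1)) {
    expect_identical(readLines(file.path(d1, fn)),
                     readLines(file.path(d2, fn)))
  }
  expect_equal(c1$truth$detections, c2$truth$detections)
  expect_equal(nrow(c1$truth$detections), 2 * 2 * 3)
})

test_that("adversarial traps appear as genus-only, never as species", {
  reg <- gen_registry(20, 5, seed = 9)
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(reg$checklist, f)
  loaded <- suppressMessages(load_checklist(f, "spider"))
  d <- withr::local_tempdir()
  corp <- gen_corpus(loaded, n_sites = 2, pages_per_site = 3,
                     species_per_page = 3, adversarial = TRUE, seed = 10,
                     out_dir = d)
  expect_true(all(c("prefix", "split") %in% corp$truth$genus_only$trap))
  pages <- suppressMessages(load_corpus(d, corp$manifest))
  det <- hierarchical_search(pages, build_name_index(loaded))
  got <- species_set(det)
  want <- corp$truth$detections |>
    dplyr::distinct(site_id, page_id, matched_name = used_name) |>
    dplyr::arrange(site_id, page_id, matched_name)
  # split binomials and prefix traps add no species detections
  expect_equal(plain(got), plain(want))
  # but the traps are visible as genus-only mentions
  tr <- corp$truth$genus_only[corp$truth$genus_only$trap == "prefix", ][1, ]
  expect_true(any(det$match_kind == "genus_only" &
                    det$site_id == tr$site_id &
                    det$page_id == tr$page_id &
                    det$genus_token == tr$genus_token))
})

test_that("LEMIS generator honours planted code frequencies and truth", {
  reg <- gen_registry(20, 5, seed = 11)
  lem <- gen_lemis(make_registry(list(genus = reg$checklist$genus,
                                      epithet = reg$checklist$epithet)),
                   n_records = 2000, seed = 12)
  s <- summarise_lemis(lem$records)
  expect_equal(s$totals, lem$truth$totals)
  # per-genus wild fraction 1 forced for one genus
  g <- reg$checklist$genus[1]
  lem1 <- gen_lemis(make_registry(list(genus = reg$checklist$genus,
                                       epithet = reg$checklist$epithet)),
                    n_records = 500, species_coverage = 1,
                    per_genus_wild_fractions = setNames(1, g), seed = 13)
  s1 <- summarise_lemis(lem1$records)
  expect_equal(s1$per_genus$wild_fraction[s1$per_genus$genus == g], 1)
  # all-seized dispositions give 100% seized
  lem_s <- gen_lemis(make_registry(list(genus = "Aaa", epithet = "bbb")),
                     n_records = 50,
                     code_frequencies = list(disposition = c(S = 1)),
                     seed = 14)
  expect_equal(summarise_lemis(lem_s$records)$totals$pct_seized, 100)
  # invalid frequencies are a configuration error
  expect_error(gen_lemis(make_registry(list(genus = "A", epithet = "b")),
                         10, code_frequencies = list(source = c(W = 0.5))),
               "sum to 1")
})

test_that("CITES generator emits resolvable taxa", {
  reg <- gen_registry(20, 5, synonym_rate = 1, seed = 15)
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(reg$checklist, f)
  loaded <- suppressMessages(load_checklist(f, "spider"))
  idx <- build_name_index(loaded)
  cit <- gen_cites(loaded, n_taxa = 5, seed = 16)
  res <- resolve_names(cit$truth$taxon_raw, idx)
  expect_equal(res$accepted_name, cit$truth$accepted_name)
})

test_that("world generator keeps clusters separated for hull safety", {
  world <- gen_world(n_clusters = 4, countries_per_cluster = 3, seed = 17)
  spread <- world$country_table |>
    dplyr::mutate(cluster = substr(country_id, 2, 2)) |>
    dplyr::group_by(cluster) |>
    dplyr::summarise(lo = min(lon), hi = max(lon))
  # cluster longitude envelopes never overlap
  ord <- dplyr::arrange(spread, lo)
  expect_true(all(ord$lo[-1] > ord$hi[-nrow(ord)]))
})
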