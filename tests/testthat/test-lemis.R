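lemis_row <- function(genus = "Pandinus", species = "imperator", qty = 10,
                      desc = "LIV", disp = "C", purp = "T", src = "W",
                      origin = "Ghana", year = 2010L) {
  tibble::tibble(taxon_class = "Arachnida", genus = genus,
                 species = species, quantity = qty, description = desc,
                 disposition = disp, purpose = purp, source = src,
                 country_origin = origin, shipment_year = year)
}

test_that("whole-individual filter admits exactly the seven codes", {
  codes <- c("BOD", "EGL", "DEA", "LIV", "SPE", "SKI", "TRO",
             "SHE", "PRT", "EGG", "SKP")
  recs <- dplyr::bind_rows(lapply(codes, function(cd) lemis_row(desc = cd)))
  kept <- filter_whole_individuals(recs)
  expect_setequal(kept$description,
                  c("BOD", "EGL", "DEA", "LIV", "SPE", "SKI", "TRO"))
  expect_false("SHE" %in% kept$description)
})

test_that("source codes partition into wild, captive and other", {
  expect_equal(classify_source(c("W", "C", "F", "D", "R", "I", "", NA)),
               c("wild", "captive", "captive", "captive", "captive",
                 "other", "other", "other"))
})

test_that("purposes M, S, Y are non-commercial; the rest commercial", {
  expect_equal(classify_purpose(c("M", "S", "Y", "T", "P", "", NA)),
               c(rep("non_commercial", 3), rep("commercial_or_other", 4)))
})

test_that("headline summary is quantity-weighted", {
  recs <- dplyr::bind_rows(lemis_row(qty = 70, src = "W"),
                           lemis_row(qty = 30, src = "C"))
  s <- summarise_lemis(recs)
  expect_equal(s$totals$pct_wild, 70)
  expect_equal(s$totals$pct_captive, 30)
  # 1 seized record of 10 equal-quantity records
  recs10 <- dplyr::bind_rows(lapply(1:10, function(i) {
    lemis_row(qty = 5, disp = if (i == 1) "S" else "C")
  }))
  expect_equal(summarise_lemis(recs10)$totals$pct_seized, 10)
})

test_that("source classes conserve the filtered total", {
  lem <- gen_lemis(micro_registry(), n_records = 500, seed = 3)
  s <- summarise_lemis(lem$records)
  expect_equal(s$totals$pct_wild + s$totals$pct_captive +
                 s$totals$pct_other, 100)
  by_class <- tapply(s$records$quantity, s$records$source_class, sum)
  expect_equal(sum(by_class), s$totals$total_individuals)
})

test_that("percentages are invariant to order and record splitting", {
  recs <- dplyr::bind_rows(lemis_row(qty = 70, src = "W"),
                           lemis_row(qty = 30, src = "C"))
  shuffled <- recs[2:1, ]
  split_up <- dplyr::bind_rows(lemis_row(qty = 40, src = "W"),
                               lemis_row(qty = 30, src = "W"),
                               lemis_row(qty = 30, src = "C"))
  expect_equal(summarise_lemis(shuffled)$totals,
               summarise_lemis(recs)$totals)
  expect_equal(summarise_lemis(split_up)$totals,
               summarise_lemis(recs)$totals)
})

test_that("per-genus table drops placeholder genera, fractions in [0,1]", {
  recs <- dplyr::bind_rows(
    lemis_row(qty = 80, src = "W"),
    lemis_row(qty = 20, src = "C"),
    lemis_row(genus = "Non-CITES entry", species = NA, qty = 50),
    lemis_row(genus = NA, species = NA, qty = 10))
  s <- summarise_lemis(recs)
  expect_equal(s$per_genus$genus, "Pandinus")
  expect_equal(s$per_genus$wild_fraction, 0.8)
  expect_true(all(s$per_genus$wild_fraction >= 0 &
                    s$per_genus$wild_fraction <= 1))
})

test_that("LEMIS reader maps columns, repairs quantities, filters class", {
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    class = c("Arachnida", "Arachnida", "Reptilia", "Arachnida"),
    genus = "Pandinus", specific_name = "imperator",
    quantity = c("10", "", "5", "-3"),
    description = "LIV", disposition = "C", purpose = "T", source = "W",
    country_origin = "Ghana", shipment_year = "2010"), f, na = "")
  recs <- suppressMessages(read_lemis(f))
  expect_equal(nrow(recs), 2)  # reptile and negative-quantity rows gone
  expect_equal(recs$quantity, c(10, 0))
})

test_that("wild exports from non-native countries are flagged per country", {
  world <- gen_world(n_clusters = 2, countries_per_cluster = 2, seed = 9)
  tab <- world$country_table
  reg <- micro_registry()
  idx <- build_name_index(reg)
  ranges <- tibble::tibble(accepted_name = "Cyriopagopus lividus",
                           country_id = "C101", kind = "country")
  recs <- dplyr::bind_rows(
    # synonym used in trade, exported from its native country
    lemis_row(genus = "Haplopelma", species = "lividum", qty = 40,
              origin = tab$name[1]),
    # same species wild-exported from a non-native country
    lemis_row(genus = "Haplopelma", species = "lividum", qty = 100,
              origin = tab$name[3]),
    # species with no range data: unknown, never non-native
    lemis_row(genus = "Pandinus", species = "imperator", qty = 7,
              origin = tab$name[3]))
  nn <- nonnative_wild_exports(recs, ranges, idx, tab)
  c3 <- nn$per_country[nn$per_country$country_id == tab$country_id[3], ]
  expect_equal(c3$wild_nonnative, 100)
  expect_equal(c3$wild_unknown, 7)
  c1 <- nn$per_country[nn$per_country$country_id == tab$country_id[1], ]
  expect_equal(c1$wild_nonnative, 0)
  expect_equal(nn$per_species$accepted_name, "Cyriopagopus lividus")
  expect_equal(nn$per_species$wild_nonnative, 100)
})

test_that("CITES reader resolves taxa and keeps the study years", {
  idx <- build_name_index(micro_registry())
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    Taxon = c("Haplopelma lividum", "Grammostola pulchra",
              "Unknownus taxon"),
    `1974` = c(5, NA, NA), `1980` = c(10, 2, NA), `2021` = c(NA, NA, 7)),
    f, na = "")
  cit <- read_cites(f, idx)
  expect_equal(nrow(cit$species), 3)
  expect_equal(sum(cit$species$resolved), 2)
  expect_equal(cit$species$accepted_name[1], "Cyriopagopus lividus")
  # 1974 is outside the 1975-2021 window
  expect_false(1974L %in% cit$yearly$year)
  expect_setequal(cit$yearly$year, c(1980L, 2021L))
})
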