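# A tiny hand-built world for geometric oracles: triangle A(0,0), B(10,0),
# C(0,10); D(2,2) lies strictly inside the hull, E(40,40) outside, and
# F(5,0) on an edge.
tiny_world <- function() {
  tibble::tibble(
    country_id = c("A", "B", "C", "D", "E", "F"),
    name = c("Aland", "Bland", "Cland", "Dland", "Eland", "Fland"),
    aliases = c("AL|United A", "", "", "", "", ""),
    lon = c(0, 10, 0, 2, 40, 5),
    lat = c(0, 0, 10, 2, 40, 0))
}

test_that("country standardisation matches names and aliases", {
  tab <- tiny_world()
  std <- standardise_country(c("Bland", "united a", "AL", "Nonsense"), tab)
  expect_equal(std$country_id, c("B", "A", "A", NA))
  expect_equal(attr(std, "worklist"), "Nonsense")
  all_ok <- standardise_country(c("Aland", "Bland"), tab)
  expect_length(attr(all_ok, "worklist"), 0)
})

test_that("regions expand through the shipped map", {
  rmap <- tibble::tibble(region = c("North", "North", "Solo"),
                         country_id = c("A", "B", "C"))
  expect_setequal(expand_region("north", rmap), c("A", "B"))
  expect_equal(expand_region("Solo", rmap), "C")
  unknown <- expand_region("Atlantis", rmap)
  expect_length(unknown, 0)
  expect_equal(attr(unknown, "worklist"), "Atlantis")
})

test_that("span expansion adds countries inside the centroid hull", {
  tab <- tiny_world()
  # degenerate: single listed country
  expect_equal(as.character(expand_span("Aland", tab)), "A")
  # 3-country hull contains D (inside) and F (on an edge), not E
  got <- expand_span(c("Aland", "Bland", "Cland"), tab)
  expect_setequal(as.character(got), c("A", "B", "C", "D", "F"))
  # hull never removes listed members
  expect_true(all(c("A", "B", "C") %in% got))
  # collinear centroids: listed set only
  coll <- expand_span(c("Aland", "Bland", "Fland"), tab)
  expect_setequal(as.character(coll), c("A", "B", "F"))
  # nothing resolvable: unmappable flag
  none <- expand_span("Atlantis", tab)
  expect_length(none, 0)
  expect_true(attr(none, "unmappable"))
})

test_that("range digitisation unions all four assertion kinds", {
  tab <- tiny_world()
  rmap <- tibble::tibble(region = c("Northish", "Northish"),
                         country_id = c("A", "B"))
  imap <- tibble::tibble(island = "Isle of A", country_id = "A")
  assertions <- tibble::tibble(
    accepted_name = c("Sp one", "Sp one", "Sp two", "Sp three", "Sp four"),
    kind = c("country", "region", "island", "span", "country"),
    raw_text = c("Aland", "Northish", "Isle of A",
                 "Aland;Bland;Cland", "Nonsense"))
  rng <- suppressMessages(build_country_ranges(assertions, tab, rmap, imap))
  one <- rng$country_id[rng$accepted_name == "Sp one"]
  expect_setequal(one, c("A", "B"))  # dedup absorbed the country row
  expect_equal(rng$country_id[rng$accepted_name == "Sp two"], "A")
  expect_setequal(rng$country_id[rng$accepted_name == "Sp three"],
                  c("A", "B", "C", "D", "F"))
  expect_equal(attr(rng, "unmappable"), "Sp four")
  expect_equal(attr(rng, "worklist"), "Nonsense")
  expect_equal(attr(rng, "n_connections"), nrow(rng))
})

test_that("country trade summary computes exposure and endemism", {
  ranges <- tibble::tibble(
    accepted_name = c(paste("Genus", letters[1:10]), "Genus a"),
    country_id = c(rep("X", 10), "Y"),
    kind = "country")
  traded <- paste("Genus", letters[1:3])
  cs <- country_trade_summary(ranges, traded)
  x <- cs[cs$country_id == "X", ]
  expect_equal(x$n_species, 10L)
  expect_equal(x$n_traded, 3L)
  expect_equal(x$pct_traded, 30)
  # "Genus a" spans X and Y, so 9 endemics in X
  expect_equal(x$n_endemic, 9L)
  expect_equal(x$n_endemic_traded, 2L)
})

test_that("the popular-groups filter drops sparsely traded genera", {
  ranges <- tibble::tibble(
    accepted_name = c(paste("Biggen", letters[1:6]),
                      paste("Smallgen", letters[1:4])),
    country_id = "X", kind = "country")
  traded <- c(paste("Biggen", letters[1:4]), "Smallgen a")
  full <- country_trade_summary(ranges, traded)
  popular <- country_trade_summary(ranges, traded,
                                   min_traded_per_genus = 2)
  expect_equal(full$n_species, 10L)
  expect_equal(popular$n_species, 6L)     # Smallgen dropped (1 traded)
  expect_equal(popular$pct_traded, 100 * 4 / 6)
})

test_that("synthetic ranges recover the planted sets and endemism rate", {
  reg <- suppressMessages(gen_registry(40, 8, seed = 31))
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(reg$checklist, f)
  loaded <- suppressMessages(load_checklist(f, "spider"))
  world <- gen_world(seed = 32)
  rng <- gen_ranges(loaded, world, endemism_rate = 0.4, seed = 33)
  got <- suppressMessages(build_country_ranges(
    rng$assertions, world$country_table, world$region_map,
    world$island_map)) |>
    dplyr::distinct(accepted_name, country_id) |>
    dplyr::arrange(accepted_name, country_id)
  expect_equal(plain(got), plain(rng$truth))
  # endemism measured on the output equals the planted rate
  es <- endemism_summary(got)
  planted <- rng$truth |>
    dplyr::count(accepted_name) |>
    dplyr::summarise(p = mean(n == 1)) |>
    dplyr::pull(p)
  expect_equal(es$pct_endemic, 100 * planted)
  # every species-country pair counts once in the connection total
  expect_equal(es$n_species, dplyr::n_distinct(rng$truth$accepted_name))
  # all species endemic at rate 1
  rng1 <- gen_ranges(loaded, world, endemism_rate = 1, seed = 34)
  expect_true(all(table(rng1$truth$accepted_name) == 1))
})

test_that("country trade plot builds", {
  ranges <- tibble::tibble(accepted_name = paste("G", 1:5),
                           country_id = "X", kind = "country")
  expect_s3_class(plot_country_trade(
    country_trade_summary(ranges, "G 1")), "ggplot")
})
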