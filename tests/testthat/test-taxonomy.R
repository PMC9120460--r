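test_that("load_checklist parses rows, drops trinomials and repairs years", {
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    genus = c("Grammostola", "Aphonopelma", rep("Xenogenus", 8)),
    epithet = c("pulchra", "seemanni ssp x", paste0("sp", 1:8)),
    family = "Theraphosidae",
    year = c("1921", "1897", 2001:2007, "twenty"),
    synonyms = "",
    nomen_dubium = FALSE
  ), f)
  expect_warning(reg <- suppressMessages(load_checklist(f, "spider")),
                 "unparseable")
  expect_equal(nrow(reg), 9)  # 10 rows minus 1 trinomial
  expect_false("Aphonopelma seemanni ssp x" %in% reg$accepted_name)
  gp <- reg[reg$accepted_name == "Grammostola pulchra", ]
  expect_equal(gp$description_year, 1921L)
  expect_true(is.na(reg$description_year[reg$epithet == "sp8"]))
})

test_that("load_checklist names the missing column in its error", {
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(genus = "A", epithet = "b"), f)
  expect_error(load_checklist(f, "spider"), "family")
})

test_that("abbreviated synonyms repair by first matching genus initial", {
  r <- repair_abbreviated_synonym("G. rosea",
                                  c("Grammostola", "Phrixotrichus"))
  expect_equal(as.character(r), "Grammostola rosea")
  expect_true(attr(r, "repaired"))

  # first-match rule over the ordered candidate list
  r2 <- repair_abbreviated_synonym("p. metallica",
                                   c("Poecilotheria", "Pterinochilus"))
  expect_equal(as.character(r2), "Poecilotheria metallica")

  # no initial-letter match / empty candidates: flagged pass-through
  r3 <- repair_abbreviated_synonym("X. alba", c("Grammostola"))
  expect_equal(as.character(r3), "X. alba")
  expect_false(attr(r3, "repaired"))
  expect_false(attr(repair_abbreviated_synonym("G. rosea", character(0)),
                    "repaired"))
})

test_that("name index holds every name and buckets every leading genus", {
  reg <- make_registry(list(genus = "Cyriopagopus", epithet = "lividus",
                            synonyms = list(c("Haplopelma lividum",
                                              "Melopoeus albostriatus",
                                              "Ornithoctonus andersoni"))))
  idx <- build_name_index(reg)
  expect_equal(nrow(idx$names), 4)  # accepted + 3 synonyms
  expect_setequal(idx$genus_list,
                  c("cyriopagopus", "haplopelma", "melopoeus",
                    "ornithoctonus"))
  expect_equal(
    idx$genus_buckets$name[idx$genus_buckets$genus == "haplopelma"],
    "haplopelma lividum")
})

test_that("resolve_names distinguishes exact, synonym and unknown", {
  idx <- build_name_index(micro_registry())
  res <- resolve_names(c("Haplopelma lividum", "Grammostola pulchra",
                         "Fakegenus nullus"), idx)
  expect_equal(res$accepted_name,
               c("Cyriopagopus lividus", "Grammostola pulchra", NA))
  expect_equal(res$match_kind, c("synonym", "exact_current", "unknown"))
  # case-insensitive with authority stripped
  expect_equal(
    resolve_names("HAPLOPELMA LIVIDUM (Smith 1996)", idx)$accepted_name,
    "Cyriopagopus lividus")
})

test_that("every accepted name resolves exact and synonyms round-trip", {
  reg <- suppressMessages(gen_registry(60, 12, synonym_rate = 1.2,
                                       seed = 11))
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(reg$checklist, f)
  loaded <- suppressMessages(load_checklist(f, "spider"))
  idx <- build_name_index(loaded)
  acc <- resolve_names(loaded$accepted_name, idx)
  expect_true(all(acc$match_kind == "exact_current"))
  expect_equal(acc$accepted_name, loaded$accepted_name)
  # round-trip: resolving every truth name reproduces the synonym map
  res <- resolve_names(reg$truth$name, idx)
  expect_equal(res$accepted_name, reg$truth$accepted_name)
  # index size equals count of distinct names
  expect_equal(nrow(idx$names), dplyr::n_distinct(reg$truth$name))
})

test_that("index is invariant to record order", {
  reg <- micro_registry()
  idx1 <- build_name_index(reg)
  idx2 <- build_name_index(reg[sample(nrow(reg)), ])
  expect_equal(idx1$names, idx2$names)
  expect_equal(idx1$genus_buckets, idx2$genus_buckets)
})

test_that("homonym names are surfaced, never silently dropped", {
  reg <- dplyr::bind_rows(
    make_registry(list(genus = "Alpha", epithet = "beta",
                       synonyms = list("Shared namus"))),
    make_registry(list(genus = "Gamma", epithet = "delta",
                       synonyms = list("Shared namus")))
  )
  expect_warning(idx <- build_name_index(reg), "homonym")
  expect_equal(nrow(idx$ambiguous), 2)
  res <- resolve_names("Shared namus", idx)
  expect_true(res$ambiguous)
  expect_equal(res$accepted_name, "Alpha beta")  # documented tie-break
})

test_that("nomen dubium names are tagged, excludable but reported", {
  reg <- micro_registry()
  reg$nomen_dubium[reg$genus == "Neon"] <- TRUE
  idx_in <- build_name_index(reg, include_nomen_dubium = TRUE)
  expect_equal(resolve_names("Neon reticulatus", idx_in)$match_kind,
               "exact_current")
  idx_out <- build_name_index(reg, include_nomen_dubium = FALSE)
  expect_equal(resolve_names("Neon reticulatus", idx_out)$match_kind,
               "unknown")
  expect_true("neon reticulatus" %in% idx_out$dubious)
})

test_that("JSON export/import preserves resolution behaviour", {
  idx <- build_name_index(micro_registry())
  f <- withr::local_tempfile(fileext = ".json")
  write_name_index(idx, f)
  idx2 <- read_name_index(f)
  nm <- c("Haplopelma lividum", "Neon reticulatus", "Nope nope")
  expect_equal(resolve_names(nm, idx2), resolve_names(nm, idx))
  expect_equal(idx2$genus_list, idx$genus_list)
})

test_that("glance and tidy summarise the index", {
  idx <- build_name_index(micro_registry())
  g <- glance(idx)
  expect_equal(g$n_species, 5)
  expect_equal(g$n_names, 8)
  expect_equal(g$mean_names_per_species, 8 / 5)
  expect_equal(nrow(tidy(idx)), 8)
})
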