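test_that("coverage rounds half-up in exact arithmetic", {
  expect_equal(coverage(354, 497), 71.2)
  expect_equal(coverage(0, 36568), 0)
  expect_equal(coverage(34788, 36568), 95.1)
  expect_equal(coverage(7087, 36568, decimals = 2), 19.38)
  # exact .5 boundaries round up, where round() would go half-to-even
  expect_equal(coverage(15, 1000, 0), 2)      # 1.5 -> 2
  expect_equal(coverage(25, 1000, 0), 3)      # 2.5 -> 3 (round() gives 2)
  expect_equal(coverage(1, 800), 0.1)         # 0.125 -> 0.1
  expect_equal(coverage(3, 800), 0.4)         # 0.375 -> 0.4
  expect_equal(coverage(36568, 36568), 100)
  expect_error(coverage(1, 0), "positive")
  expect_error(coverage(-1, 10), "non-negative")
  # vectorised and monotone in the numerator
  cov <- coverage(0:100, 100)
  expect_true(all(diff(cov) >= 0))
})

test_that("the BCG document profiles into the expected four rows", {
  d <- local_worked_example()
  corpus <- load_corpus(file.path(d, "spl"))
  tab <- profile_by_epc(corpus, DEN_NDFRT)
  rows <- tab$rows
  cell <- function(cat, col) rows[[col]][rows$category == cat]
  expect_equal(cell("EPC", "unique_concepts"), 2L)
  expect_equal(cell("EPC", "unique_setids"), 1L)
  # the ingredient shared by both EPC classes deduplicates to 2 unique NUIs
  expect_equal(cell("Chemical/Ingredient", "unique_concepts"), 2L)
  expect_equal(cell("PE", "unique_concepts"), 3L)
  expect_equal(cell("MoA", "unique_concepts"), 0L)
  expect_equal(cell("MoA", "unique_setids"), 0L)
  # totals: concept sum over disjoint role categories, setId union
  expect_equal(tab$total_row$unique_concepts, 7L)
  expect_equal(tab$total_row$unique_setids, 1L)
})

test_that("an empty corpus gives an all-zero table", {
  tab <- profile_by_epc(list(), DEN_NDFRT)
  expect_true(all(tab$rows$unique_concepts == 0))
  expect_true(all(tab$rows$unique_setids == 0))
  expect_equal(tab$total_row$unique_setids, 0L)
  expect_equal(tab$rows$setid_coverage, rep(0, 4))
})

test_that("NDF-RT profiling excludes untagged parents and keeps their children", {
  d <- local_worked_example()
  store <- fixture_store(d)
  tab <- profile_by_ndfrt(store, DEN_NDFRT)
  va_links <- tab$links[tab$links$category == "VA Product", ]
  expect_false("N0000147595" %in% tab$links$concept)   # Mesna, untagged
  expect_true("N0000156948" %in% va_links$concept)     # its tagged child
  # the three-category label appears in every row's setId set
  cavan <- "0f2053f1-fd94-4a4a-b803-bca391d9e032"
  for (cat in c("VA Product", "Chemical/Ingredient", "EPC"))
    expect_true(cavan %in% tab$links$setid[tab$links$category == cat])
  # ...but only once in the total union
  expect_equal(tab$total_row$unique_setids,
               length(unique(tab$links$setid)))
  # Famotidine: one RxCUI, two labeller setIds
  expect_equal(sum(tab$links$concept == "N0000006373"), 2L)
  expect_equal(setids_for_rxcui(store, "4278"),
               sort(c("3a6f1b22-8c4d-4e9a-9f10-5b7d2c8e4a01",
                      "9d4c7e55-1f2a-4b83-a6c9-0e8f3d5b7a12")))
})

test_that("TTY profiling unions overlapping synonym term types", {
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeLines(c(conso_line("10", "RXNORM", "IN", "10", "drug a"),
               conso_line("10", "RXNORM", "SY", "10", "Drug A"),
               conso_line("20", "RXNORM", "SCD", "20", "drug b 5mg"),
               conso_line("30", "RXNORM", "IN", "30", "unlinked")), f1)
  writeLines(c(sat_line("10", "SPL_SET_ID", "s1"),
               sat_line("10", "SPL_SET_ID", "s2"),
               sat_line("20", "SPL_SET_ID", "s2")), f2)
  tab <- profile_by_tty(rxnorm_store(f1, f2),
                        c(concept_total = 100, setid_total = 10))
  cell <- function(cat, col) tab$rows[[col]][tab$rows$category == cat]
  expect_equal(cell("IN", "unique_concepts"), 1L)   # rxcui 30 has no setId
  expect_equal(cell("IN", "unique_setids"), 2L)
  expect_equal(cell("SY", "unique_setids"), 2L)
  expect_equal(cell("SCD", "unique_setids"), 1L)
  # union, not sum: rxcui 10 counted once, setids {s1,s2} once
  expect_equal(tab$total_row$unique_concepts, 2L)
  expect_equal(tab$total_row$unique_setids, 2L)
})

test_that("a store without setId attributes profiles to all zeros", {
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeLines(conso_line("10", "RXNORM", "IN", "10", "drug"), f1)
  writeLines(sat_line("10", "OTHER", "zz"), f2)
  tab <- profile_by_tty(rxnorm_store(f1, f2),
                        c(concept_total = 100, setid_total = 10))
  expect_true(all(tab$rows$unique_concepts == 0))
  expect_equal(tab$total_row$unique_setids, 0L)
})

test_that("total-row unions obey the sum and max bounds on generated stores", {
  for (seed in c(2, 8, 21)) {
    fx <- local_fixture(fixture_spec(n_spl = 30, seed = seed))
    corpus <- load_corpus(file.path(fx$dir, "spl"))
    store <- fixture_store(fx$dir)
    for (tab in list(profile_by_epc(corpus, DEN_NDFRT),
                     profile_by_ndfrt(store, DEN_NDFRT),
                     profile_by_tty(store, DEN_RXNORM))) {
      expect_lte(tab$total_row$unique_setids, sum(tab$rows$unique_setids))
      expect_gte(tab$total_row$unique_setids, max(tab$rows$unique_setids))
    }
  }
})

test_that("duplicated input records never inflate counts", {
  fx <- local_fixture(fixture_spec(n_spl = 10, seed = 13))
  conso <- read_rrf(file.path(fx$dir, "RXNCONSO.RRF"), "RXNCONSO")
  sat <- read_rrf(file.path(fx$dir, "RXNSAT.RRF"), "RXNSAT")
  den <- DEN_NDFRT
  once <- profile_by_ndfrt(rxnorm_store(conso, sat), den)
  twice <- profile_by_ndfrt(rxnorm_store(rbind(conso, conso),
                                         rbind(sat, sat)), den)
  expect_equal(once$rows, twice$rows)
  expect_equal(once$total_row, twice$total_row)
})

test_that("TSV and JSON serializations carry the table and its link triples", {
  d <- local_worked_example()
  tab <- profile_by_ndfrt(fixture_store(d), DEN_NDFRT)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(tab, tsv)
  got <- utils::read.delim(tsv, comment.char = "#")
  expect_equal(got$category, c(tab$rows$category, "Total"))
  expect_equal(got$unique_setids,
               c(tab$rows$unique_setids, tab$total_row$unique_setids))
  js <- withr::local_tempfile(fileext = ".json")
  write_profile_json(tab, js)
  back <- read_profile_json(js)
  expect_equal(back$rows, tab$rows)
  expect_equal(back$total_row, tab$total_row)
  expect_equal(back$links, tab$links)
  expect_equal(back$concept_kind, tab$concept_kind)
})
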