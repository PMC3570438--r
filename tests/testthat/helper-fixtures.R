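# Shared helpers: standard denominators, fixture construction shortcuts,
# and comparison of a profile_table against a generator ground truth.

DEN_NDFRT <- c(concept_total = 47075, setid_total = 36568)
DEN_RXNORM <- c(concept_total = 965968, setid_total = 36568)

local_fixture <- function(spec, env = parent.frame()) {
  d <- withr::local_tempdir(.local_envir = env)
  truth <- generate_fixtures(spec, d)
  list(dir = d, truth = truth)
}

local_worked_example <- function(env = parent.frame()) {
  d <- withr::local_tempdir(.local_envir = env)
  worked_example_fixture(d)
  d
}

fixture_store <- function(dir, ...) {
  rxnorm_store(file.path(dir, "RXNCONSO.RRF"),
               file.path(dir, "RXNSAT.RRF"), ...)
}

# counts-only equality between a profile_table and a fixture_truth element
expect_matches_truth <- function(table, truth) {
  got <- as.data.frame(table$rows[, c("category", "unique_concepts",
                                      "unique_setids")])
  want <- as.data.frame(truth$rows)
  expect_equal(got, want, ignore_attr = TRUE)
  expect_identical(as.integer(table$total_row$unique_concepts),
                   as.integer(truth$total_concepts))
  expect_identical(as.integer(table$total_row$unique_setids),
                   as.integer(truth$total_setids))
}

# canonical row-order-independent form of a drug_network
network_key <- function(net) {
  n <- as.data.frame(net$nodes); e <- as.data.frame(net$edges)
  list(nodes = n[order(n$id), , drop = FALSE],
       edges = e[order(e$source, e$target, e$label), , drop = FALSE])
}

expect_same_network <- function(a, b) {
  expect_equal(network_key(a), network_key(b), ignore_attr = TRUE)
}

# small literal RRF line builders for targeted unit tests
conso_line <- function(rxcui, sab, tty, code, str) {
  paste0(paste(rxcui, "ENG", "", "", "", "", "Y", "1", "", "", "", sab,
               tty, code, str, "", "N", "", sep = "|"), "|")
}

sat_line <- function(rxcui, atn, atv, sab = "MTHSPL") {
  paste0(paste(rxcui, "", "", "", "CUI", "", "AT1", "", atn, sab, atv,
               "N", "", sep = "|"), "|")
}
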