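# Synthetic SPL / NDF-RT / RxNorm corpora with machine-readable ground
# truth. The generator emits exactly the dialects the readers consume
# (canonical SPL XML, NDF-RT TSV, RXNCONSO/RXNSAT RRF) with internally
# consistent cross-file identifiers, and returns the profile tables the
# corpus must produce -- computed from its own bookkeeping sets, not by the
# profilers. Identifier shapes mimic the real ones (NUIs "N" + 10 digits,
# setIds UUIDv4, RxCUIs short integers) so format handling is exercised.

#' Specification of a synthetic corpus
#'
#' @param n_spl Number of EPC-indexing SPL documents.
#' @param n_epc,n_chem,n_pe,n_moa,n_va NDF-RT concept pool sizes per
#'   category (EPC classes, chemical ingredients, physiologic effects,
#'   mechanisms of action, VA products).
#' @param n_untagged Number of untagged drug-class parents (each gets one
#'   VA-Product-tagged child product, the configuration under which an
#'   untagged parent must not be counted).
#' @param multi_category_fraction Fraction of setIds linked to one concept
#'   of each of the three NDF-RT table categories (VA Product,
#'   Chemical/Ingredient, EPC), emulating labels mapped to more than one
#'   category.
#' @param seed RNG seed; identical spec + seed reproduces identical bytes.
#' @return Named list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_spl = 20L, n_epc = 8L, n_chem = 12L, n_pe = 6L,
                         n_moa = 4L, n_va = 10L, n_untagged = 3L,
                         multi_category_fraction = 0.25, seed = 1L) {
  spec <- list(n_spl = as.integer(n_spl), n_epc = as.integer(n_epc),
               n_chem = as.integer(n_chem), n_pe = as.integer(n_pe),
               n_moa = as.integer(n_moa), n_va = as.integer(n_va),
               n_untagged = as.integer(n_untagged),
               multi_category_fraction = multi_category_fraction,
               seed = as.integer(seed))
  counts <- unlist(spec[1:7])
  if (any(counts < 0)) stop("all counts must be >= 0")
  if (multi_category_fraction < 0 || multi_category_fraction > 1)
    stop("multi_category_fraction must be in [0, 1]")
  if (spec$n_spl > 0 && spec$n_epc == 0)
    stop("an EPC-indexing corpus needs at least one EPC class (n_epc >= 1)")
  structure(spec, class = "fixture_spec")
}

make_nui <- function(base, i) sprintf("N%010d", base + i)

rand_uuid <- function(n) {
  if (n == 0L) return(character(0))
  hx <- function(k) matrix(sample(c(0:9, letters[1:6]), n * k,
                                  replace = TRUE), nrow = n)
  p <- function(m) apply(m, 1L, paste, collapse = "")
  # version nibble 4 / variant nibble 8-b, cosmetic UUIDv4 shape
  paste0(p(hx(8L)), "-", p(hx(4L)), "-4", p(hx(3L)), "-",
         sample(c("8", "9", "a", "b"), n, replace = TRUE), p(hx(3L)),
         "-", p(hx(12L)))
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

# One SPL document in the canonical dialect, as a character vector of lines.
# epcs: list of list(nui, name, links = data.frame(nui, name, role))
spl_xml_lines <- function(setid, epcs) {
  out <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
           "<document>",
           sprintf("  <setId root=\"%s\"/>", setid),
           "  <structuredBody>")
  for (e in epcs) {
    out <- c(out, "    <epcSection>",
             sprintf("      <code code=\"%s\" displayName=\"%s\"/>",
                     e$nui, xml_escape(e$name)))
    if (!is.null(e$links) && nrow(e$links)) {
      for (j in seq_len(nrow(e$links))) {
        out <- c(out,
          sprintf("      <relationship name=\"%s\">", e$links$role[j]),
          sprintf("        <code code=\"%s\" displayName=\"%s\"/>",
                  e$links$nui[j], xml_escape(e$links$name[j])),
          "      </relationship>")
      }
    }
    out <- c(out, "    </epcSection>")
  }
  c(out, "  </structuredBody>", "</document>")
}

blank_conso <- function(n) {
  cols <- rrf_schema("RXNCONSO")
  dt <- data.table::as.data.table(
    stats::setNames(rep(list(rep("", n)), length(cols)), cols))
  dt
}

conso_rows <- function(rxcui, sab, tty, code, str, rxaui_start = 1L) {
  n <- length(rxcui)
  dt <- blank_conso(n)
  if (n == 0L) return(dt)
  data.table::set(dt, j = "rxcui", value = rxcui)
  data.table::set(dt, j = "lat", value = rep("ENG", n))
  data.table::set(dt, j = "ispref", value = rep("Y", n))
  data.table::set(dt, j = "rxaui",
                  value = as.character(rxaui_start + seq_len(n) - 1L))
  data.table::set(dt, j = "sab", value = rep(sab, length.out = n))
  data.table::set(dt, j = "tty", value = rep(tty, length.out = n))
  data.table::set(dt, j = "code", value = code)
  data.table::set(dt, j = "str", value = str)
  data.table::set(dt, j = "suppress", value = rep("N", n))
  dt
}

sat_rows <- function(rxcui, setid, atn = "SPL_SET_ID") {
  n <- length(rxcui)
  cols <- rrf_schema("RXNSAT")
  dt <- data.table::as.data.table(
    stats::setNames(rep(list(rep("", n)), length(cols)), cols))
  if (n == 0L) return(dt)
  data.table::set(dt, j = "rxcui", value = rxcui)
  data.table::set(dt, j = "stype", value = rep("CUI", n))
  data.table::set(dt, j = "atui", value = sprintf("AT%08d", seq_len(n)))
  data.table::set(dt, j = "atn", value = rep(atn, n))
  data.table::set(dt, j = "sab", value = rep("MTHSPL", n))
  data.table::set(dt, j = "atv", value = setid)
  data.table::set(dt, j = "suppress", value = rep("N", n))
  dt
}

truth_table <- function(categories, concept_sets, setid_sets,
                        concept_total_rule = "sum") {
  rows <- data.table::data.table(
    category = categories,
    unique_concepts = vapply(concept_sets, function(s)
      length(unique(s)), 0L),
    unique_setids = vapply(setid_sets, function(s)
      length(unique(s)), 0L))
  list(rows = rows,
       total_concepts = if (concept_total_rule == "sum")
         sum(rows$unique_concepts) else
         length(unique(unlist(concept_sets))),
       total_setids = length(unique(unlist(setid_sets))))
}

#' Generate a synthetic SPL/NDF-RT/RxNorm corpus with ground truth
#'
#' Writes, under `outdir`: `spl/` (one canonical-dialect XML file per SPL
#' document), `ndfrt.tsv` (tabular NDF-RT serialization), `RXNCONSO.RRF`
#' and `RXNSAT.RRF`, and `ground_truth.json`. Every NUI referenced by an
#' SPL exists in the NDF-RT file and every setId in RXNSAT belongs to an
#' emitted SPL. The returned ground truth holds the EPC, NDF-RT-category
#' and TTY profile tables the corpus must produce, plus the expected
#' EPC-network node and edge counts, all derived from the generator's own
#' assignment sets.
#'
#' Structure emulated: each SPL maps to one or two EPC classes, each class
#' to 0-2 concepts per role; setIds link to VA Product / Chemical
#' Ingredient / EPC concepts through RxNorm with realistic marginal rates
#' (most labels resolve to a chemical ingredient, a majority to a product,
#' few directly to an EPC class); untagged drug-class parents and their
#' tagged child products share setIds; every setId-bearing RxCUI carries
#' one primary term type and synonym term types with moderate probability.
#'
#' @param spec A [fixture_spec()].
#' @param outdir Output directory (created; must be writable).
#' @return Invisibly, a list of class `fixture_truth`: elements `epc`,
#'   `ndfrt`, `tty` (each `rows` + `total_concepts` + `total_setids`),
#'   `network` (`nodes`, `edges` expected for the EPC-profile network) and
#'   `outdir`.
#' @export
generate_fixtures <- function(spec, outdir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(file.path(outdir, "spl"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  set.seed(spec$seed)

  pool <- function(n, base, fmt) {
    if (n == 0L) return(data.table::data.table(nui = character(0),
                                               name = character(0)))
    data.table::data.table(nui = make_nui(base, seq_len(n)),
                           name = sprintf(fmt, seq_len(n)))
  }
  epc  <- pool(spec$n_epc, 1000000L, "Example Class %d [EPC]")
  chem <- pool(spec$n_chem, 2000000L, "Example Ingredient %d [Chemical/Ingredient]")
  pe   <- pool(spec$n_pe, 3000000L, "Example Effect %d [PE]")
  moa  <- pool(spec$n_moa, 4000000L, "Example Mechanism %d [MoA]")
  va   <- pool(spec$n_va, 5000000L, "EXAMPLE DRUG %d 10MG TAB [VA Product]")
  untg <- pool(spec$n_untagged, 6000000L, "Parent Class %d")
  kids <- pool(spec$n_untagged, 7000000L, "PARENT CLASS %d 50MG INJ [VA Product]")

  setids <- sort(rand_uuid(spec$n_spl))

  # ---- SPL documents + EPC-profile bookkeeping -------------------------
  used <- list(epc = character(0), chem = character(0),
               pe = character(0), moa = character(0))
  docs_with <- list(chem = character(0), pe = character(0),
                    moa = character(0))
  epc_edges <- 0L   # distinct (concept, setid) pairs per doc, summed
  role_pick <- function(tab, mx = 2L) {
    if (nrow(tab) == 0L) return(tab[0L])
    k <- sample.int(min(mx, nrow(tab)) + 1L, 1L) - 1L
    if (k == 0L) return(tab[0L])
    tab[sample.int(nrow(tab), k)]
  }
  for (i in seq_len(spec$n_spl)) {
    k <- if (nrow(epc) > 1L && stats::runif(1) < 0.4) 2L else 1L
    picked <- epc[sample.int(nrow(epc), k)]
    doc_links <- list(epc = picked$nui, chem = character(0),
                      pe = character(0), moa = character(0))
    epcs <- vector("list", k)
    for (j in seq_len(k)) {
      lc <- role_pick(chem); lp <- role_pick(pe); lm <- role_pick(moa)
      links <- data.table::data.table(
        nui = c(lc$nui, lp$nui, lm$nui),
        name = c(lc$name, lp$name, lm$name),
        role = c(rep("has_Chemical_Structure", nrow(lc)),
                 rep("has_PE", nrow(lp)), rep("has_MoA", nrow(lm))))
      epcs[[j]] <- list(nui = picked$nui[j], name = picked$name[j],
                        links = links)
      doc_links$chem <- c(doc_links$chem, lc$nui)
      doc_links$pe <- c(doc_links$pe, lp$nui)
      doc_links$moa <- c(doc_links$moa, lm$nui)
    }
    writeLines(spl_xml_lines(setids[i], epcs),
               file.path(outdir, "spl", sprintf("spl_%05d.xml", i)))
    for (nm in names(used)) {
      doc_links[[nm]] <- unique(doc_links[[nm]])
      used[[nm]] <- c(used[[nm]], doc_links[[nm]])
      if (nm != "epc" && length(doc_links[[nm]]))
        docs_with[[nm]] <- c(docs_with[[nm]], setids[i])
      epc_edges <- epc_edges + length(doc_links[[nm]])
    }
  }
  epc_truth <- truth_table(
    c("EPC", "Chemical/Ingredient", "PE", "MoA"),
    list(used$epc, used$chem, used$pe, used$moa),
    list(if (spec$n_spl) setids else character(0),
         docs_with$chem, docs_with$pe, docs_with$moa))
  net_nodes <- length(unique(unlist(used))) +
    as.integer(spec$n_spl > 0) * spec$n_spl
  net_truth <- list(nodes = net_nodes, edges = epc_edges)

  # ---- NDF-RT file -----------------------------------------------------
  all_con <- rbind(epc, chem, pe, moa, va, untg, kids)
  tsv <- sprintf("%s\t%s\t\t\t", all_con$nui, all_con$name)
  # a few role assertions for structural realism (EPC class -> ingredient)
  if (nrow(epc) && nrow(chem)) {
    tgt <- chem$nui[1L + (seq_len(nrow(epc)) - 1L) %% nrow(chem)]
    tsv <- c(tsv, sprintf("%s\t\thas_Chemical_Structure\t%s\t",
                          epc$nui, tgt))
  }
  if (nrow(kids))
    tsv <- c(tsv, sprintf("%s\t\t\t\t%s", kids$nui, untg$nui))
  writeLines(tsv, file.path(outdir, "ndfrt.tsv"))

  # ---- RxNorm: conso NDFRT atoms, setId links, term types --------------
  rx_con <- data.table::copy(all_con)
  rx_con$rxcui <- as.character(1000L + seq_len(nrow(rx_con)))
  idx <- function(tab) rx_con[match(tab$nui, rx_con$nui)]

  n_multi <- floor(spec$multi_category_fraction * spec$n_spl)
  multi <- if (n_multi > 0) sort(sample.int(spec$n_spl, n_multi)) else
    integer(0)
  link <- list()  # per NDF-RT-category links: (nui, rxcui, setid)
  add_link <- function(tab, i_concept, s)
    data.table::data.table(nui = tab$nui[i_concept],
                           rxcui = idx(tab)$rxcui[i_concept], setid = s)
  for (i in seq_len(spec$n_spl)) {
    s <- setids[i]
    forced <- i %in% multi
    if (nrow(va) && (forced || stats::runif(1) < 0.7))
      link[[length(link) + 1L]] <- add_link(va, sample.int(nrow(va), 1L), s)
    if (nrow(chem) && (forced || stats::runif(1) < 0.85))
      link[[length(link) + 1L]] <- add_link(chem, sample.int(nrow(chem), 1L), s)
    if (nrow(epc) && (forced || stats::runif(1) < 0.05))
      link[[length(link) + 1L]] <- add_link(epc, sample.int(nrow(epc), 1L), s)
  }
  # untagged parents + their tagged children share a setId
  n_u <- min(spec$n_untagged, spec$n_spl)
  if (n_u > 0) {
    su <- sample.int(spec$n_spl, n_u)
    for (j in seq_len(n_u)) {
      link[[length(link) + 1L]] <- add_link(untg, j, setids[su[j]])
      link[[length(link) + 1L]] <- add_link(kids, j, setids[su[j]])
    }
  }
  links <- if (length(link)) unique(data.table::rbindlist(link)) else
    data.table::data.table(nui = character(0), rxcui = character(0),
                           setid = character(0))

  cat_of <- function(nui) {
    ifelse(nui %in% va$nui | nui %in% kids$nui, "VA Product",
    ifelse(nui %in% chem$nui, "Chemical/Ingredient",
    ifelse(nui %in% epc$nui, "EPC", "NONE")))
  }
  lcat <- cat_of(links$nui)
  ndfrt_truth <- truth_table(
    c("VA Product", "Chemical/Ingredient", "EPC"),
    list(links$nui[lcat == "VA Product"],
         links$nui[lcat == "Chemical/Ingredient"],
         links$nui[lcat == "EPC"]),
    list(links$setid[lcat == "VA Product"],
         links$setid[lcat == "Chemical/Ingredient"],
         links$setid[lcat == "EPC"]))

  bearing <- sort(unique(links$rxcui))
  primary_pool <- c("SBD", "SCD", "IN", "PIN", "BPCK", "GPCK", "BN", "MIN")
  wts <- c(0.20, 0.22, 0.25, 0.12, 0.06, 0.05, 0.05, 0.05)
  tty_of <- stats::setNames(vector("list", length(bearing)), bearing)
  for (r in bearing) {
    t <- sample(primary_pool, 1L, prob = wts)
    if (stats::runif(1) < 0.4) t <- c(t, "SY")
    if (stats::runif(1) < 0.1) t <- c(t, "TMSY")
    tty_of[[r]] <- t
  }
  setids_of <- split(links$setid, links$rxcui)
  tty_truth <- truth_table(
    TTY_ROWS,
    lapply(TTY_ROWS, function(t)
      bearing[vapply(tty_of[bearing], function(x) t %in% x, TRUE)]),
    lapply(TTY_ROWS, function(t)
      unlist(setids_of[bearing[vapply(tty_of[bearing],
                                      function(x) t %in% x, TRUE)]],
             use.names = FALSE)),
    concept_total_rule = "union")

  conso <- conso_rows(rx_con$rxcui, "NDFRT", "FN", rx_con$nui, rx_con$name,
                      rxaui_start = 1L)
  base_of <- parse_category_tag(rx_con$name)$base_name
  names(base_of) <- rx_con$nui
  mthspl <- conso_rows(bearing, "MTHSPL", "DP", bearing,
                       paste0(base_of[rx_con$nui[match(bearing, rx_con$rxcui)]],
                              " (product)"),
                       rxaui_start = 100000L)
  tty_flat <- data.table::data.table(
    rxcui = rep(bearing, lengths(tty_of[bearing])),
    tty = unlist(tty_of[bearing], use.names = FALSE))
  rxnorm <- conso_rows(tty_flat$rxcui, "RXNORM", tty_flat$tty,
                       tty_flat$rxcui,
                       base_of[rx_con$nui[match(tty_flat$rxcui,
                                                rx_con$rxcui)]],
                       rxaui_start = 200000L)
  write_rrf(rbind(conso, mthspl, rxnorm),
            file.path(outdir, "RXNCONSO.RRF"))
  write_rrf(sat_rows(links$rxcui, links$setid),
            file.path(outdir, "RXNSAT.RRF"))

  truth <- structure(list(epc = epc_truth, ndfrt = ndfrt_truth,
                          tty = tty_truth, network = net_truth,
                          outdir = outdir),
                     class = "fixture_truth")
  jsonlite::write_json(
    list(epc = epc_truth, ndfrt = ndfrt_truth, tty = tty_truth,
         network = net_truth),
    file.path(outdir, "ground_truth.json"),
    dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(truth)
}

#' The packaged worked-example corpus
#'
#' Emits a small fixed corpus transcribing the published worked examples of
#' the crosswalk: the BCG vaccine label mapped to two EPC classes (one
#' carrying one PE and two Chemical/Ingredient links, the other two PE and
#' the same two Chemical/Ingredient links, so the shared ingredients
#' deduplicate to two unique NUIs); the Famotidine NDFRT atom (RxCUI 4278,
#' NUI N0000006373); the untagged drug-class parent Mesna (N0000147595)
#' with its VA-Product-tagged child MESNA 100MG/ML INJ (N0000156948), which
#' must be excluded from / included in the VA Product row respectively; and
#' the Cavan-EC SOD DHA label (setId 0f2053f1-fd94-4a4a-b803-bca391d9e032)
#' linked to one concept in each of the three NDF-RT table categories
#' (N0000006244 Chemical/Ingredient, N000158434 VA Product, N0000175583
#' EPC). Identifiers not published (the BCG setId/NUIs, the Famotidine and
#' Mesna setIds) are synthetic placeholders with realistic shapes.
#'
#' @param outdir Output directory (default: fresh temp directory).
#' @return `outdir`, with the same file layout as [generate_fixtures()]
#'   (`spl/`, `ndfrt.tsv`, `RXNCONSO.RRF`, `RXNSAT.RRF`).
#' @export
worked_example_fixture <- function(outdir = tempfile("worked_example_")) {
  dir.create(file.path(outdir, "spl"), recursive = TRUE,
             showWarnings = FALSE)
  chem2 <- data.table::data.table(
    nui = c("N0000190201", "N0000190202"),
    name = c("Vaccines, Attenuated [Chemical/Ingredient]",
             "BCG Vaccine [Chemical/Ingredient]"),
    role = "has_Chemical_Structure")
  epc1 <- list(
    nui = "N0000190001",
    name = "Live Attenuated Bacillus Calmette-Guerin Vaccine [EPC]",
    links = rbind(data.table::data.table(
      nui = "N0000190101", name = "Actively Acquired Immunity [PE]",
      role = "has_PE"), chem2))
  epc2 <- list(
    nui = "N0000190002",
    name = "Live Attenuated Intravesical Bacillus Calmette-Guerin Vaccine [EPC]",
    links = rbind(data.table::data.table(
      nui = c("N0000190102", "N0000190103"),
      name = c("Increased Macrophage Proliferation [PE]",
               "Increased Immunologically Active Molecule Activity [PE]"),
      role = "has_PE"), chem2))
  bcg_setid <- "7c2e94d1-63a8-4f0b-b8a5-12d9c0e4f871"  # synthetic
  writeLines(spl_xml_lines(bcg_setid, list(epc1, epc2)),
             file.path(outdir, "spl", "bcg.xml"))

  con <- data.table::data.table(
    nui = c("N0000190001", "N0000190002", "N0000190101", "N0000190102",
            "N0000190103", "N0000190201", "N0000190202",
            "N0000006373", "N0000147595", "N0000156948",
            "N0000006244", "N000158434", "N0000175583"),
    name = c(epc1$name, epc2$name,
             "Actively Acquired Immunity [PE]",
             "Increased Macrophage Proliferation [PE]",
             "Increased Immunologically Active Molecule Activity [PE]",
             "Vaccines, Attenuated [Chemical/Ingredient]",
             "BCG Vaccine [Chemical/Ingredient]",
             "Famotidine [Chemical/Ingredient]",
             "Mesna",
             "MESNA 100MG/ML INJ [VA Product]",
             "Fatty Acids, Omega-3 [Chemical/Ingredient]",
             "SILICON DIOXIDE [VA Product]",
             "Omega-3 Fatty Acid [EPC]"),
    parent = c(rep("", 9L), "N0000147595", "", "", ""))
  writeLines(sprintf("%s\t%s\t\t\t%s", con$nui, con$name, con$parent),
             file.path(outdir, "ndfrt.tsv"))

  rx <- data.table::data.table(
    rxcui = c("4278", "44", "45", "46", "47", "48"),
    nui = c("N0000006373", "N0000147595", "N0000156948",
            "N0000006244", "N000158434", "N0000175583"))
  rx$name <- con$name[match(rx$nui, con$nui)]
  conso <- conso_rows(rx$rxcui, "NDFRT", "FN", rx$nui, rx$name)
  extra <- conso_rows(c("4278", "4278", "47"), "RXNORM",
                      c("IN", "SY", "SCD"), c("4278", "4278", "47"),
                      c("Famotidine", "famotidine", "SILICON DIOXIDE tablet"),
                      rxaui_start = 500L)
  write_rrf(rbind(conso, extra), file.path(outdir, "RXNCONSO.RRF"))

  cavan <- "0f2053f1-fd94-4a4a-b803-bca391d9e032"
  fam <- c("3a6f1b22-8c4d-4e9a-9f10-5b7d2c8e4a01",   # synthetic labellers
           "9d4c7e55-1f2a-4b83-a6c9-0e8f3d5b7a12")
  mesna_sid <- "b1e8d3c6-4a2f-4d97-8e5b-6c0a9f1d2e83" # synthetic
  sat <- sat_rows(c("4278", "4278", "46", "47", "48", "44", "45"),
                  c(fam, cavan, cavan, cavan, mesna_sid, mesna_sid))
  write_rrf(sat, file.path(outdir, "RXNSAT.RRF"))
  outdir
}
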