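# The three profiling procedures and the coverage arithmetic behind the
# crosswalk tables: (1) EPC-indexing SPL documents classified by role
# relationship, (2) NDF-RT category profiling through the RxNorm NDFRT
# source, (3) term-type (TTY) profiling through the RxNorm MTHSPL source.
# Every count is over sets: duplicated input records never inflate a cell.

TTY_ROWS <- c("SBD", "SCD", "IN", "PIN", "BPCK", "GPCK", "BN", "MIN",
              "SY", "TMSY")

#' Coverage percentage with exact half-up rounding
#'
#' `100 * count / total`, rounded half-up to `decimals` places. Rounding is
#' done in integer arithmetic on the rational `count/total`, so a cell that
#' is mathematically on the `.5` boundary always rounds up (base `round()`
#' rounds half to even and would disagree with printed tables).
#'
#' @param count Non-negative integer(s).
#' @param total Positive integer denominator.
#' @param decimals Decimal places (default 1).
#' @return Numeric percentage(s) in `[0, 100]`.
#' @examples
#' coverage(354, 497)          # 71.2
#' coverage(7087, 36568, 2)    # 19.38
#' @export
coverage <- function(count, total, decimals = 1L) {
  if (length(total) != 1L || is.na(total) || total <= 0)
    stop("total must be a single positive number")
  if (any(count < 0)) stop("count must be non-negative")
  scale <- 10^decimals
  num <- count * 100 * scale
  base <- num %/% total
  rem <- num %% total
  (base + (2 * rem >= total)) / scale
}

# Assemble a profile_table from per-category link triples.
#
# links: data.table(concept, concept_name, setid, category); one row per
# distinct (concept, setid, category) triple after dedup.
# concept_total_rule: "sum" (categories disjoint by construction) or
# "union" (overlaps expected, e.g. TTY synonym rows).
make_profile_table <- function(links, row_categories, denominators,
                               concept_kind,
                               concept_total_rule = c("sum", "union"),
                               decimals = 1L) {
  concept_total_rule <- match.arg(concept_total_rule)
  links <- unique(links[, c("concept", "concept_name", "setid", "category")])
  main <- links[links$category %in% row_categories, ]
  other <- links[!links$category %in% row_categories, ]
  per_row <- function(cat) {
    sub <- main[main$category == cat, ]
    list(unique_concepts = length(unique(sub$concept)),
         unique_setids = length(unique(sub$setid[nzchar(sub$setid)])))
  }
  cells <- lapply(row_categories, per_row)
  rows <- data.table::data.table(
    category = row_categories,
    unique_concepts = vapply(cells, `[[`, 0L, "unique_concepts"),
    unique_setids = vapply(cells, `[[`, 0L, "unique_setids"))
  total_concepts <- if (concept_total_rule == "sum")
    sum(rows$unique_concepts) else length(unique(main$concept))
  total_setids <- length(unique(main$setid[nzchar(main$setid)]))
  ct <- denominators[["concept_total"]]
  st <- denominators[["setid_total"]]
  rows$concept_coverage <- coverage(rows$unique_concepts, ct, decimals)
  rows$setid_coverage <- coverage(rows$unique_setids, st, decimals)
  total_row <- data.table::data.table(
    category = "Total",
    unique_concepts = total_concepts,
    unique_setids = total_setids,
    concept_coverage = coverage(total_concepts, ct, decimals),
    setid_coverage = coverage(total_setids, st, decimals))
  other_row <- if (nrow(other)) data.table::data.table(
    category = "(other)",
    unique_concepts = length(unique(other$concept)),
    unique_setids = length(unique(other$setid[nzchar(other$setid)])),
    concept_coverage = NA_real_, setid_coverage = NA_real_) else NULL
  structure(list(rows = rows, total_row = total_row, other_row = other_row,
                 denominators = c(concept_total = ct, setid_total = st),
                 links = main, other_links = other,
                 concept_kind = concept_kind, decimals = decimals),
            class = "profile_table")
}

#' @export
print.profile_table <- function(x, ...) {
  df <- rbind(x$rows, x$total_row)
  df$concept_coverage <- sprintf(paste0("%.", x$decimals, "f%%"),
                                 df$concept_coverage)
  df$setid_coverage <- sprintf(paste0("%.", x$decimals, "f%%"),
                               df$setid_coverage)
  cat("<profile_table> denominators: concepts =",
      x$denominators[["concept_total"]], ", setIds =",
      x$denominators[["setid_total"]], "\n")
  print(as.data.frame(df), row.names = FALSE)
  if (!is.null(x$other_row))
    cat("(other, outside fixed rows):", x$other_row$unique_concepts,
        "concepts,", x$other_row$unique_setids, "setIds\n")
  invisible(x)
}

#' Profile a corpus by EPC classes and role relationships
#'
#' Classifies an EPC-indexing SPL corpus into four rows: `EPC` (concepts
#' reached as EPC class memberships), `Chemical/Ingredient`
#' (`has_Chemical_Structure` links), `PE` (`has_PE`) and `MoA` (`has_MoA`).
#' Each row counts the distinct NUIs and the distinct setIds contributing at
#' least one link of that relationship. A concept appearing under several
#' EPC classes of one document (common for shared chemical ingredients)
#' counts once. The total row sums concepts across the four rows (the
#' role-derived categories are disjoint by construction) and takes the
#' distinct union of setIds.
#'
#' @param corpus List of `spl_document` from [load_corpus()]/[parse_spl()].
#' @param denominators Named vector/list with `concept_total` (NDF-RT
#'   concept universe size) and `setid_total` (SPL label universe size).
#' @param decimals Rounding for coverage cells.
#' @return A `profile_table` whose `links` carry the underlying
#'   (NUI, setId, category) triples for network building.
#' @export
profile_by_epc <- function(corpus, denominators, decimals = 1L) {
  rel_to_cat <- c(EPC_MEMBERSHIP = "EPC",
                  HAS_CHEMICAL_STRUCTURE = "Chemical/Ingredient",
                  HAS_PE = "PE", HAS_MOA = "MoA")
  triples <- lapply(corpus, function(d) {
    epc <- data.table::data.table(concept = d$epc_classes$nui,
                                  concept_name = d$epc_classes$display_name,
                                  setid = d$set_id, category = "EPC")
    if (nrow(d$role_links)) {
      rl <- data.table::data.table(
        concept = d$role_links$nui,
        concept_name = d$role_links$display_name,
        setid = d$set_id,
        category = unname(rel_to_cat[d$role_links$relationship]))
      rbind(epc, rl)
    } else epc
  })
  links <- if (length(triples)) data.table::rbindlist(triples) else
    data.table::data.table(concept = character(0),
                           concept_name = character(0),
                           setid = character(0), category = character(0))
  make_profile_table(links, unname(rel_to_cat), denominators,
                     concept_kind = "nui", concept_total_rule = "sum",
                     decimals = decimals)
}

#' Profile SPL labels by NDF-RT category through RxNorm
#'
#' Restricts RXNCONSO to `SAB = "NDFRT"`; each record supplies an RxCUI, a
#' NUI (the `code` field) and a preferred name whose trailing bracketed tag
#' carries the category. Only the categories `VA Product`,
#' `Chemical/Ingredient` and `EPC` form table rows; a concept whose name has
#' no recognized tag is excluded from every category count (an untagged
#' drug-class parent such as "Mesna" is not counted as a VA Product even
#' when its child products are). RxCUIs are linked to SPL setIds through the
#' RXNSAT setId attribute, and only concepts linked to at least one setId
#' enter the table. Tagged categories outside the three rows (PE, MoA) are
#' reported in a separate "(other)" bucket, never silently dropped.
#'
#' @param store An [rxnorm_store()].
#' @inheritParams profile_by_epc
#' @return A `profile_table` (concept identifiers are NUIs).
#' @export
profile_by_ndfrt <- function(store, denominators, decimals = 1L) {
  ndfrt <- filter_by_sab(store, "NDFRT")
  empty <- data.table::data.table(concept = character(0),
                                  concept_name = character(0),
                                  setid = character(0),
                                  category = character(0))
  if (nrow(ndfrt) == 0L)
    return(make_profile_table(empty,
                              c("VA Product", "Chemical/Ingredient", "EPC"),
                              denominators, "nui", "sum", decimals))
  con <- unique(data.table::data.table(rxcui = ndfrt$rxcui,
                                       nui = ndfrt$code,
                                       name = ndfrt$str))
  tags <- parse_category_tag(con$name)
  con$category <- unname(NDFRT_CATEGORIES[tags$category])
  con$base_name <- tags$base_name
  con <- con[!is.na(con$category), ]          # the untagged-parent rule
  pairs <- setid_pairs(store, con$rxcui)
  merged <- merge(con, pairs, by = "rxcui", allow.cartesian = TRUE)
  links <- data.table::data.table(concept = merged$nui,
                                  concept_name = merged$name,
                                  setid = merged$atv,
                                  category = merged$category)
  make_profile_table(links, c("VA Product", "Chemical/Ingredient", "EPC"),
                     denominators, concept_kind = "nui",
                     concept_total_rule = "sum", decimals = decimals)
}

#' Profile SPL labels by RxNorm term type
#'
#' Identifies the setId-bearing RxCUIs (those with at least one setId
#' attribute in RXNSAT), collects each one's term types from all RXNCONSO
#' records sharing the RxCUI (the SPL-derived atom itself usually carries a
#' source-specific TTY, while the normalized-form TTYs live on RXNORM atoms
#' of the same concept), and tabulates the ten term types `SBD, SCD, IN,
#' PIN, BPCK, GPCK, BN, MIN, SY, TMSY`. Synonym rows (`SY`, `TMSY`) overlap
#' with the others by definition, so the total row takes distinct unions of
#' RxCUIs and setIds rather than sums. TTYs outside the ten land in the
#' "(other)" bucket.
#'
#' @param store An [rxnorm_store()].
#' @param tty_sab Optional source restriction for the TTY lookup (e.g.
#'   `"RXNORM"`); default `NULL` spans all sources.
#' @inheritParams profile_by_epc
#' @return A `profile_table` (concept identifiers are RxCUIs).
#' @export
profile_by_tty <- function(store, denominators, tty_sab = NULL,
                           decimals = 1L) {
  pairs <- store$setid_map                     # all (rxcui, setid) links
  empty <- data.table::data.table(concept = character(0),
                                  concept_name = character(0),
                                  setid = character(0),
                                  category = character(0))
  if (nrow(pairs) == 0L)
    return(make_profile_table(empty, TTY_ROWS, denominators, "rxcui",
                              "union", decimals))
  conso <- store$conso
  if (!is.null(tty_sab)) conso <- conso[conso$sab %in% tty_sab, ]
  ttys <- unique(data.table::data.table(rxcui = conso$rxcui,
                                        tty = conso$tty,
                                        name = conso$str))
  ttys <- ttys[nzchar(ttys$tty) & ttys$rxcui %in% pairs$rxcui, ]
  ttys <- unique(ttys, by = c("rxcui", "tty"))
  merged <- merge(ttys, pairs, by = "rxcui", allow.cartesian = TRUE)
  links <- data.table::data.table(concept = merged$rxcui,
                                  concept_name = merged$name,
                                  setid = merged$atv,
                                  category = merged$tty)
  make_profile_table(links, TTY_ROWS, denominators, concept_kind = "rxcui",
                     concept_total_rule = "union", decimals = decimals)
}

#' Write a profile table as TSV
#'
#' Column layout: category, unique concepts, concept coverage, unique
#' setIds, setId coverage; rows then the total row; the "(other)" bucket,
#' when present, as a trailing comment line.
#'
#' @param table A `profile_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(table, path) {
  stopifnot(inherits(table, "profile_table"))
  df <- rbind(table$rows, table$total_row)
  out <- data.frame(category = df$category,
                    unique_concepts = df$unique_concepts,
                    concept_coverage = sprintf(
                      paste0("%.", table$decimals, "f%%"),
                      df$concept_coverage),
                    unique_setids = df$unique_setids,
                    setid_coverage = sprintf(
                      paste0("%.", table$decimals, "f%%"),
                      df$setid_coverage))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(table$other_row))
    cat(sprintf("# other\t%d\t\t%d\t\n", table$other_row$unique_concepts,
                table$other_row$unique_setids),
        file = path, append = TRUE)
  invisible(path)
}

#' Serialize a profile table to JSON (with its link triples)
#'
#' The JSON form carries the underlying (concept, setId, category) triples
#' so a network can be built downstream without re-running the profiler.
#'
#' @param table A `profile_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_json <- function(table, path) {
  stopifnot(inherits(table, "profile_table"))
  obj <- list(concept_kind = table$concept_kind,
              decimals = table$decimals,
              denominators = as.list(table$denominators),
              rows = table$rows,
              total_row = table$total_row,
              other_row = table$other_row,
              links = table$links,
              other_links = table$other_links)
  jsonlite::write_json(obj, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a profile table back from its JSON serialization
#'
#' @param path A file written by [write_profile_json()].
#' @return A `profile_table`.
#' @export
read_profile_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_links <- function(x) {
    if (is.null(x) || length(x) == 0L)
      return(data.table::data.table(concept = character(0),
                                    concept_name = character(0),
                                    setid = character(0),
                                    category = character(0)))
    data.table::as.data.table(lapply(x, as.character))
  }
  structure(list(rows = data.table::as.data.table(obj$rows),
                 total_row = data.table::as.data.table(obj$total_row),
                 other_row = if (is.null(obj$other_row)) NULL else
                   data.table::as.data.table(obj$other_row),
                 denominators = unlist(obj$denominators),
                 links = as_links(obj$links),
                 other_links = as_links(obj$other_links),
                 concept_kind = obj$concept_kind,
                 decimals = obj$decimals),
            class = "profile_table")
}
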