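# NDF-RT concept store. NDF-RT embeds a concept's category in its preferred
# name as a trailing bracketed tag -- "Famotidine [Chemical/Ingredient]",
# "Androgen Receptor Inhibitor [EPC]" -- and the profiler classifies by that
# tag. The store also keeps role relationships and parent links so the drug
# hierarchy can be traversed (e.g. all descendants of a VA drug class).

NDFRT_CATEGORIES <- c(EPC = "EPC",
                      CHEMICAL_INGREDIENT = "Chemical/Ingredient",
                      PE = "PE",
                      MOA = "MoA",
                      VA_PRODUCT = "VA Product")

#' Parse the category tag of an NDF-RT preferred name
#'
#' Splits a display string on its final `[...]` suffix. The tag text is
#' matched case-sensitively (after trimming whitespace inside the brackets)
#' against the five categories `EPC`, `Chemical/Ingredient`, `PE`, `MoA`
#' and `VA Product`. A name with no trailing bracketed suffix, or with an
#' unrecognized tag (e.g. `[Disease/Finding]`), gets category `"NONE"` and
#' keeps the full input as base name.
#'
#' @param display_name Character vector of non-empty preferred names.
#' @return data.table with columns `base_name` and `category` (one of
#'   `"EPC"`, `"CHEMICAL_INGREDIENT"`, `"PE"`, `"MOA"`, `"VA_PRODUCT"`,
#'   `"NONE"`), one row per input.
#' @examples
#' parse_category_tag("Famotidine [Chemical/Ingredient]")
#' parse_category_tag("Mesna")
#' @export
parse_category_tag <- function(display_name) {
  if (length(display_name) == 0L)
    return(data.table::data.table(base_name = character(0),
                                  category = character(0)))
  if (any(is.na(display_name)) || any(!nzchar(display_name)))
    stop("display names must be non-empty strings")
  m <- regmatches(display_name,
                  regexpr("\\s*\\[[^][]*\\]\\s*$", display_name))
  has_tag <- grepl("\\[[^][]*\\]\\s*$", display_name)
  base <- display_name
  tag_txt <- rep(NA_character_, length(display_name))
  if (any(has_tag)) {
    raw <- regmatches(display_name[has_tag],
                      regexpr("\\[[^][]*\\]\\s*$", display_name[has_tag]))
    tag_txt[has_tag] <- trimws(sub("^\\[", "", sub("\\]\\s*$", "", raw)))
  }
  recognized <- tag_txt %in% unname(NDFRT_CATEGORIES)
  cat <- rep("NONE", length(display_name))
  cat[recognized] <- names(NDFRT_CATEGORIES)[match(tag_txt[recognized],
                                                   NDFRT_CATEGORIES)]
  strip <- has_tag & recognized
  base[strip] <- trimws(sub("\\s*\\[[^][]*\\]\\s*$", "", display_name[strip]))
  data.table::data.table(base_name = base, category = cat)
}

#' Load an NDF-RT concept file
#'
#' Ingests NDF-RT as asserted facts (no OWL reasoning): concepts with NUIs
#' and preferred names, role relationships, and parent links. Two
#' serializations are supported:
#'
#' * `"tabular"`: TSV with columns `nui`, `preferred_name`, `role_type`,
#'   `target_nui`, `parent_nui` (no header). A concept may span several rows
#'   (one per role/parent); role and parent columns may be empty.
#' * `"triples"`: N-Triples-style lines `<subject> <predicate> object .`
#'   where the preferred-name predicate has a literal object and role/parent
#'   predicates have IRI objects; the NUI is the final path segment of a
#'   concept IRI. Predicate IRIs are configurable through `predicates`;
#'   any predicate other than the name and parent predicates whose object is
#'   an IRI is treated as a role, named by its final path segment.
#'
#' Role or parent targets that name no loaded concept are kept but flagged
#' with a warning (dangling links). Hierarchy cycles are detected by
#' [descendants()] and broken with a warning.
#'
#' @param path Input file.
#' @param format `"tabular"` or `"triples"`.
#' @param predicates For `"triples"`: named list with elements
#'   `preferred_name` and `parent` giving full predicate IRIs.
#' @return Object of class `ndfrt_store`: list of data.tables `concepts`
#'   (`nui`, `preferred_name`, `base_name`, `category`), `roles`
#'   (`nui`, `role`, `target_nui`) and `parents` (`nui`, `parent_nui`).
#' @export
load_ndfrt <- function(path, format = c("tabular", "triples"),
                       predicates = list(
                         preferred_name = "http://purl.example.org/ndfrt#preferredName",
                         parent = "http://purl.example.org/ndfrt#isa")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read NDF-RT file: ", path)
  if (format == "tabular") {
    cols <- c("nui", "preferred_name", "role_type", "target_nui", "parent_nui")
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) {
      rows <- data.table::as.data.table(
        stats::setNames(rep(list(character(0)), 5L), cols))
    } else {
      parts <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
      if (length(parts) > 5L)
        stop("NDF-RT tabular file has more than 5 columns: ", path)
      parts <- c(parts, rep(list(rep("", length(lines))),
                            5L - length(parts)))
      rows <- data.table::as.data.table(stats::setNames(parts, cols))
      for (cc in cols) data.table::set(rows, j = cc,
                                       value = ifelse(is.na(rows[[cc]]), "", rows[[cc]]))
    }
    first <- rows[nzchar(rows$preferred_name),
                  c("nui", "preferred_name")]
    concepts <- unique(first, by = "nui")
    roles <- rows[nzchar(rows$role_type) & nzchar(rows$target_nui),
                  list(nui = nui, role = role_type, target_nui = target_nui)]
    parents <- rows[nzchar(rows$parent_nui),
                    list(nui = nui, parent_nui = parent_nui)]
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    pat <- "^<([^>]+)>\\s+<([^>]+)>\\s+(.+?)\\s*\\.$"
    ok <- grepl(pat, lines)
    if (any(!ok)) stop("unparseable triple line(s): ",
                       paste(utils::head(lines[!ok], 3L), collapse = " ; "))
    subj <- iri_local(sub(pat, "\\1", lines))
    pred <- sub(pat, "\\2", lines)
    obj <- sub(pat, "\\3", lines)
    is_name <- pred == predicates$preferred_name
    is_parent <- pred == predicates$parent
    is_iri_obj <- grepl("^<.+>$", obj)
    lit <- sub("\"\\s*(@[A-Za-z-]+)?$", "", sub("^\"", "", obj))
    concepts <- unique(data.table::data.table(
      nui = subj[is_name], preferred_name = lit[is_name]), by = "nui")
    parents <- data.table::data.table(
      nui = subj[is_parent & is_iri_obj],
      parent_nui = iri_local(gsub("^<|>$", "", obj[is_parent & is_iri_obj])))
    is_role <- !is_name & !is_parent & is_iri_obj
    roles <- data.table::data.table(
      nui = subj[is_role],
      role = iri_local(pred[is_role]),
      target_nui = iri_local(gsub("^<|>$", "", obj[is_role])))
  }
  if (nrow(concepts)) {
    tags <- parse_category_tag(concepts$preferred_name)
    concepts <- cbind(concepts, tags)
  } else {
    concepts <- data.table::data.table(nui = character(0),
                                       preferred_name = character(0),
                                       base_name = character(0),
                                       category = character(0))
  }
  dangling <- setdiff(c(roles$target_nui, parents$parent_nui), concepts$nui)
  if (length(dangling))
    warning("NDF-RT links point at ", length(dangling),
            " concept(s) not defined in the file (kept, dangling): ",
            paste(utils::head(dangling, 5L), collapse = ", "))
  structure(list(concepts = concepts, roles = roles, parents = parents),
            class = "ndfrt_store")
}

iri_local <- function(x) sub("^.*[/#]", "", x)

#' @export
print.ndfrt_store <- function(x, ...) {
  cat("<ndfrt_store>\n")
  cat("  concepts:", nrow(x$concepts), "\n")
  tab <- table(x$concepts$category)
  for (nm in names(tab)) cat("    ", nm, ":", tab[[nm]], "\n")
  cat("  roles:", nrow(x$roles), " parents:", nrow(x$parents), "\n")
  invisible(x)
}

#' Transitive descendants of an NDF-RT concept
#'
#' Breadth-first closure over child links (the inverse of the stored parent
#' links), excluding the starting concept itself. Cycle-safe: a cycle is
#' traversed once and reported with a warning.
#'
#' @param store An `ndfrt_store`.
#' @param nui Concept identifier present in the store.
#' @return Character vector of descendant NUIs (unsorted set).
#' @export
descendants <- function(store, nui) {
  stopifnot(inherits(store, "ndfrt_store"))
  if (!nui %in% store$concepts$nui && !nui %in% store$parents$parent_nui)
    stop("unknown NUI: ", nui)
  children <- split(store$parents$nui, store$parents$parent_nui)
  # depth-first with an on-stack marker: a back edge (child still on the
  # current path) is a true cycle, while a re-visit off the path is just a
  # diamond in the DAG and is fine.
  seen <- new.env(parent = emptyenv())
  onstack <- new.env(parent = emptyenv())
  cycle <- FALSE
  visit <- function(node) {
    assign(node, TRUE, envir = onstack)
    for (k in children[[node]]) {
      if (isTRUE(get0(k, envir = onstack))) { cycle <<- TRUE; next }
      if (is.null(get0(k, envir = seen))) {
        assign(k, TRUE, envir = seen)
        visit(k)
      }
    }
    assign(node, FALSE, envir = onstack)
  }
  visit(nui)
  if (cycle) warning("hierarchy cycle detected under ", nui,
                     "; traversed once")
  setdiff(ls(seen), nui)
}
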