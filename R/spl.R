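# Parser for EPC-indexing SPL documents. An EPC indexing label carries the
# SPL setId plus one or more External Pharmacologic Class (EPC) concepts;
# each EPC class is further linked to NDF-RT concepts through the role
# relationships has_Chemical_Structure, has_MoA and has_PE. The exact HL7
# element paths vary across releases, so every path the parser touches is
# configuration (a "dialect"), with a documented canonical default that the
# packaged fixture generator also emits.

SPL_RELATIONSHIPS <- c("EPC_MEMBERSHIP", "HAS_CHEMICAL_STRUCTURE",
                       "HAS_MOA", "HAS_PE")

ROLE_NAME_MAP <- c(has_Chemical_Structure = "HAS_CHEMICAL_STRUCTURE",
                   has_MoA = "HAS_MOA",
                   has_PE  = "HAS_PE")

#' SPL dialect configuration
#'
#' Element paths used by [parse_spl()]. The canonical dialect expects
#' ```
#' <document>
#'   <setId root="UUID"/>
#'   <structuredBody>
#'     <epcSection>
#'       <code code="NUI" displayName="... [EPC]"/>
#'       <relationship name="has_PE">
#'         <code code="NUI" displayName="... [PE]"/>
#'       </relationship>
#'     </epcSection>
#'   </structuredBody>
#' </document>
#' ```
#' Real DailyMed indexing files can be mapped by overriding the XPaths and
#' attribute names, either via arguments or a YAML file (see
#' [read_spl_dialect()]).
#'
#' @param setid_xpath XPath (from the root) of the element carrying the setId.
#' @param setid_attr Attribute of that element holding the identifier.
#' @param epc_xpath XPath (from the root) selecting one node per EPC class.
#' @param epc_code_xpath XPath (from an EPC node) of its concept-code element.
#' @param link_xpath XPath (from an EPC node) selecting role-relationship
#'   elements nested under it.
#' @param role_attr Attribute of a relationship element naming the role.
#' @param link_code_xpath XPath (from a relationship element) of the linked
#'   concept-code element.
#' @param code_attr,name_attr Attributes of a concept-code element holding
#'   the NUI and the tagged display name.
#' @return Named list of class `spl_dialect`.
#' @export
spl_dialect <- function(setid_xpath = "./setId",
                        setid_attr = "root",
                        epc_xpath = ".//epcSection",
                        epc_code_xpath = "./code",
                        link_xpath = "./relationship",
                        role_attr = "name",
                        link_code_xpath = "./code",
                        code_attr = "code",
                        name_attr = "displayName") {
  structure(list(setid_xpath = setid_xpath, setid_attr = setid_attr,
                 epc_xpath = epc_xpath, epc_code_xpath = epc_code_xpath,
                 link_xpath = link_xpath, role_attr = role_attr,
                 link_code_xpath = link_code_xpath,
                 code_attr = code_attr, name_attr = name_attr),
            class = "spl_dialect")
}

#' Read an SPL dialect from a YAML file
#'
#' Keys absent from the file keep their canonical defaults.
#'
#' @param path YAML file of dialect keys (see [spl_dialect()]).
#' @return An `spl_dialect` object.
#' @export
read_spl_dialect <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(spl_dialect))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    warning("ignoring unknown dialect keys: ", paste(unknown, collapse = ", "))
  do.call(spl_dialect, cfg[intersect(names(cfg), known)])
}

# setIds are UUID-style: compare case-insensitively after trimming.
normalize_setid <- function(x) tolower(trimws(x))

#' Parse one EPC-indexing SPL document
#'
#' Extracts the setId, every EPC class, and every role-linked NDF-RT concept
#' (NUI, display name, relationship), attributing each link to the EPC class
#' element it is nested in. Role names are mapped
#' `has_Chemical_Structure` -> `HAS_CHEMICAL_STRUCTURE`, `has_MoA` ->
#' `HAS_MOA`, `has_PE` -> `HAS_PE`; a link with an unrecognized role name is
#' skipped with a warning.
#'
#' @param path Path to a well-formed SPL XML file.
#' @param dialect An [spl_dialect()] (or path handling is up to the caller).
#' @return An object of class `spl_document`: a list with `set_id`
#'   (normalized), `epc_classes` (data.table: `nui`, `display_name`) and
#'   `role_links` (data.table: `epc_nui`, `nui`, `display_name`,
#'   `relationship`).
#' @export
parse_spl <- function(path, dialect = spl_dialect()) {
  stopifnot(inherits(dialect, "spl_dialect"))
  doc <- xml2::read_xml(path)
  sid_node <- xml2::xml_find_first(doc, dialect$setid_xpath)
  sid <- if (inherits(sid_node, "xml_missing")) NA_character_ else
    xml2::xml_attr(sid_node, dialect$setid_attr)
  if (is.na(sid) || !nzchar(trimws(sid)))
    stop("SPL document has no setId: ", path)
  sid <- normalize_setid(sid)

  epc_nodes <- xml2::xml_find_all(doc, dialect$epc_xpath)
  if (length(epc_nodes) == 0L)
    stop("EPC-indexing SPL without any EPC class: ", path)

  epc <- list(); links <- list()
  for (i in seq_along(epc_nodes)) {
    node <- epc_nodes[[i]]
    code_node <- xml2::xml_find_first(node, dialect$epc_code_xpath)
    epc_nui <- xml2::xml_attr(code_node, dialect$code_attr)
    epc_name <- xml2::xml_attr(code_node, dialect$name_attr)
    if (is.na(epc_nui) || !nzchar(epc_nui))
      stop("EPC class without a concept code in ", path)
    epc[[i]] <- data.table::data.table(nui = epc_nui,
                                       display_name = epc_name)
    rel_nodes <- xml2::xml_find_all(node, dialect$link_xpath)
    if (length(rel_nodes) == 0L) next
    role_raw <- xml2::xml_attr(rel_nodes, dialect$role_attr)
    rel <- unname(ROLE_NAME_MAP[role_raw])
    unknown <- is.na(rel)
    if (any(unknown)) {
      warning("skipping link(s) with unknown role name ",
              paste(unique(role_raw[unknown]), collapse = ", "),
              " in ", path)
      rel_nodes <- rel_nodes[!unknown]; rel <- rel[!unknown]
    }
    if (length(rel_nodes) == 0L) next
    tgt <- lapply(rel_nodes, xml2::xml_find_first, dialect$link_code_xpath)
    links[[length(links) + 1L]] <- data.table::data.table(
      epc_nui = epc_nui,
      nui = vapply(tgt, xml2::xml_attr, "", attr = dialect$code_attr),
      display_name = vapply(tgt, xml2::xml_attr, "",
                            attr = dialect$name_attr),
      relationship = rel)
  }
  empty_links <- data.table::data.table(epc_nui = character(0),
                                        nui = character(0),
                                        display_name = character(0),
                                        relationship = character(0))
  structure(list(set_id = sid,
                 epc_classes = data.table::rbindlist(epc),
                 role_links = if (length(links))
                   data.table::rbindlist(links) else empty_links),
            class = "spl_document")
}

#' @export
print.spl_document <- function(x, ...) {
  cat("<spl_document> setId:", x$set_id, "\n")
  cat("  EPC classes:", nrow(x$epc_classes), "| role links:",
      nrow(x$role_links), "\n")
  invisible(x)
}

#' Load a directory of EPC-indexing SPL documents
#'
#' Parses every `.xml` file in `dir`. Files sharing a setId (after UUID
#' normalization) collapse to one logical document holding the union of
#' their EPC classes and role links, with a warning. Files that fail to
#' parse are reported together at the end; the remainder still load.
#'
#' @param dir Directory containing `.xml` files.
#' @param dialect An [spl_dialect()].
#' @return List of `spl_document`, ordered by first appearance.
#' @export
load_corpus <- function(dir, dialect = spl_dialect()) {
  files <- sort(list.files(dir, pattern = "\\.xml$", full.names = TRUE))
  docs <- list(); failures <- character(0)
  for (f in files) {
    d <- tryCatch(parse_spl(f, dialect), error = function(e) e)
    if (inherits(d, "error")) {
      failures <- c(failures, paste0(basename(f), ": ", conditionMessage(d)))
      next
    }
    if (!is.null(docs[[d$set_id]])) {
      warning("duplicate setId ", d$set_id, " (", basename(f),
              "); merging into one document")
      old <- docs[[d$set_id]]
      old$epc_classes <- unique(rbind(old$epc_classes, d$epc_classes))
      old$role_links <- unique(rbind(old$role_links, d$role_links))
      docs[[d$set_id]] <- old
    } else docs[[d$set_id]] <- d
  }
  if (length(failures))
    warning(length(failures), " file(s) failed to parse:\n  ",
            paste(failures, collapse = "\n  "))
  unname(docs)
}
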