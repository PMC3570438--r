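# RxNorm Rich Release Format (RRF) reader/writer and the indexed store used
# by the profiling procedures. RRF files are pipe-delimited, one record per
# line, no header, with a trailing "|" closing the last field.

#' RRF column layouts
#'
#' Named column layouts for the two RxNorm release files the profiler
#' consumes. Layouts are declared data, not code, so a dialect change (a
#' future release adding a column) is configuration.
#'
#' @param layout Layout name, `"RXNCONSO"` (18 columns) or `"RXNSAT"`
#'   (13 columns), per the public RxNorm technical documentation.
#' @return Character vector of lower-case column names, in file order.
#' @examples
#' rrf_schema("RXNCONSO")
#' @export
rrf_schema <- function(layout = c("RXNCONSO", "RXNSAT")) {
  layout <- match.arg(layout)
  switch(layout,
    RXNCONSO = c("rxcui", "lat", "ts", "lui", "stt", "sui", "ispref",
                 "rxaui", "saui", "scui", "sdui", "sab", "tty", "code",
                 "str", "srl", "suppress", "cvf"),
    RXNSAT   = c("rxcui", "lui", "sui", "rxaui", "stype", "code", "atui",
                 "satui", "atn", "sab", "atv", "suppress", "cvf"))
}

# Split one RRF line into fields. A single trailing "|" is the RRF line
# terminator and is consumed; embedded empty fields are preserved. The
# sentinel trick is needed because strsplit() drops a trailing empty piece.
split_rrf_line <- function(line) {
  parts <- strsplit(paste0(line, "\x01"), "|", fixed = TRUE)[[1L]]
  n <- length(parts)
  if (parts[n] == "\x01") parts[-n] else {
    parts[n] <- sub("\x01$", "", parts[n])
    parts
  }
}

#' Read an RxNorm RRF file
#'
#' Strict reader: every line must have exactly the field count of the
#' declared layout (after consuming the RRF trailing `|`). Malformed lines
#' are collected and reported with their line numbers.
#'
#' @param path Path to a pipe-delimited RRF file (UTF-8, no header).
#' @param layout Layout name passed to [rrf_schema()].
#' @param on_error `"stop"` (default) aborts on the first malformed line;
#'   `"warn"` skips malformed lines with one warning naming them all.
#' @return A [data.table::data.table] with one row per record, columns named
#'   by the layout, all character, in file order.
#' @examples
#' f <- tempfile(fileext = ".RRF")
#' writeLines("4278|ENG||||||1||||NDFRT|FN|N0000006373|Famotidine [Chemical/Ingredient]||N||",
#'            f)
#' read_rrf(f, "RXNCONSO")[, .(rxcui, sab, code, str)]
#' @export
read_rrf <- function(path, layout = c("RXNCONSO", "RXNSAT"),
                     on_error = c("stop", "warn")) {
  layout <- match.arg(layout)
  on_error <- match.arg(on_error)
  if (!file.exists(path)) stop("cannot read RRF file: ", path)
  cols <- rrf_schema(layout)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- data.table::as.data.table(
      stats::setNames(rep(list(character(0)), length(cols)), cols))
    return(out)
  }
  fields <- lapply(lines, split_rrf_line)
  nf <- lengths(fields)
  bad <- which(nf != length(cols))
  if (length(bad)) {
    msg <- sprintf("line %d: expected %d fields, found %d",
                   bad, length(cols), nf[bad])
    if (on_error == "stop")
      stop("malformed ", layout, " record(s) in ", path, ":\n  ",
           paste(utils::head(msg, 10L), collapse = "\n  "))
    warning("skipping malformed ", layout, " record(s) in ", path, ": ",
            paste(msg, collapse = "; "))
    fields <- fields[-bad]
  }
  m <- matrix(unlist(fields, use.names = FALSE),
              ncol = length(cols), byrow = TRUE)
  out <- data.table::as.data.table(m)
  data.table::setnames(out, cols)
  out[]
}

#' Write records back to RRF
#'
#' Inverse of [read_rrf()]: emits pipe-delimited lines with the RRF trailing
#' `|`. `write_rrf(read_rrf(f))` reproduces a well-formed `f` byte for byte.
#'
#' @param records A data.table/data.frame whose columns are the layout fields.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rrf <- function(records, path) {
  records <- data.table::as.data.table(records)
  lines <- if (nrow(records) == 0L) character(0) else
    do.call(paste, c(as.list(records), list(sep = "|", collapse = NULL)))
  if (length(lines)) lines <- paste0(lines, "|")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Load RXNCONSO/RXNSAT into an indexed store
#'
#' Reads the two release files and builds the keyed indexes the profiling
#' procedures query (by source vocabulary `sab`, by concept `rxcui`, and
#' `rxcui` to SPL `setId`). The store answers those lookups without
#' rescanning files; it plays the role of the relational database a
#' production deployment would use.
#'
#' @param conso Path to RXNCONSO.RRF, or a data.table already read with
#'   [read_rrf()].
#' @param sat Path to RXNSAT.RRF, or a data.table. May be `NULL` when only
#'   concept records are needed.
#' @param setid_attr Name of the RXNSAT attribute (`ATN`) that carries the
#'   SPL setId. Default `"SPL_SET_ID"`, matching the released RxNorm
#'   attribute vocabulary; override if a release names it differently.
#' @return An object of class `rxnorm_store`.
#' @export
rxnorm_store <- function(conso, sat = NULL, setid_attr = "SPL_SET_ID") {
  if (is.character(conso)) conso <- read_rrf(conso, "RXNCONSO")
  conso <- data.table::as.data.table(conso)
  if (is.null(sat)) {
    sat <- data.table::as.data.table(
      stats::setNames(rep(list(character(0)), length(rrf_schema("RXNSAT"))),
                      rrf_schema("RXNSAT")))
  } else if (is.character(sat)) {
    sat <- read_rrf(sat, "RXNSAT")
  } else sat <- data.table::as.data.table(sat)
  stopifnot(all(nzchar(conso$rxcui)), all(nzchar(conso$sab)))
  data.table::setkey(conso, sab)
  # setId lookup table: rxcui -> atv for the configured attribute
  setid_map <- sat[sat$atn == setid_attr, c("rxcui", "atv")]
  setid_map <- unique(setid_map)
  data.table::setkey(setid_map, rxcui)
  structure(list(conso = conso, sat = sat, setid_map = setid_map,
                 setid_attr = setid_attr),
            class = "rxnorm_store")
}

#' @export
print.rxnorm_store <- function(x, ...) {
  cat("<rxnorm_store>\n")
  cat("  conso records:", nrow(x$conso),
      " (SABs:", paste(sort(unique(x$conso$sab)), collapse = ", "), ")\n")
  cat("  sat records:  ", nrow(x$sat), "\n")
  cat("  setId attribute:", x$setid_attr,
      " (", nrow(x$setid_map), "rxcui-setId links )\n")
  invisible(x)
}

#' Filter concept records by source vocabulary
#'
#' @param store An `rxnorm_store`.
#' @param sab Source abbreviation, matched case-sensitively (e.g. `"MTHSPL"`
#'   for SPL-derived atoms, `"NDFRT"` for NDF-RT-derived atoms). An unknown
#'   `sab` yields an empty result, not an error.
#' @return data.table of the matching RXNCONSO records, in file order.
#' @export
filter_by_sab <- function(store, sab) {
  stopifnot(inherits(store, "rxnorm_store"), is.character(sab))
  rows <- which(store$conso[["sab"]] == sab)   # value, not NSE: the bare
  store$conso[rows]                            # name would hit the column
}

#' SPL setIds attached to an RxNorm concept
#'
#' Looks up the distinct setId attribute values recorded for one RxCUI.
#' One RxCUI frequently maps to several SPL documents because different
#' labellers file separate labels for the same product, so the result is a
#' set, possibly empty.
#'
#' @param store An `rxnorm_store`.
#' @param rxcui Concept identifier (character scalar).
#' @return Character vector of distinct setIds (possibly empty), sorted.
#' @export
setids_for_rxcui <- function(store, rxcui) {
  stopifnot(inherits(store, "rxnorm_store"))
  key <- as.character(rxcui)
  hit <- store$setid_map[list(key), on = "rxcui", nomatch = NULL]
  sort(unique(hit$atv))
}

# Vectorised internal form: distinct (rxcui, setid) pairs for a set of rxcuis.
setid_pairs <- function(store, rxcuis) {
  hit <- store$setid_map[list(unique(as.character(rxcuis))), on = "rxcui",
                         nomatch = NULL]
  unique(hit)
}
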