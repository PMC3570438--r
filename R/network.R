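# Drug / drug-class network: terminology concepts (NDF-RT NUIs, RxNorm
# RxCUIs) as source nodes, SPL labels as target nodes, category information
# on the edges. Node identifiers are namespaced ("nui:", "rxcui:",
# "setid:") so the three identifier spaces cannot collide.

NODE_TYPES <- c(nui = "NDFRT_CONCEPT", rxcui = "RXNORM_CONCEPT",
                setid = "SPL_LABEL")

empty_network <- function() {
  structure(list(
    nodes = data.table::data.table(id = character(0),
                                   node_type = character(0),
                                   display_name = character(0)),
    edges = data.table::data.table(source = character(0),
                                   target = character(0),
                                   label = character(0))),
    class = "drug_network")
}

#' Build a drug/drug-class network from profile tables
#'
#' One node per distinct concept and per distinct setId, one labeled edge
#' per distinct (concept, setId, category) triple, directed concept ->
#' label. Edges deduplicate on the full triple; self-loops cannot arise
#' because concept and label identifier spaces are namespaced apart.
#' Isolated nodes are not emitted.
#'
#' @param profiles A `profile_table` or list of them (their `links` supply
#'   the triples; the table's `concept_kind` decides the concept namespace).
#' @return Object of class `drug_network` with `nodes` (`id`, `node_type`,
#'   `display_name`) and `edges` (`source`, `target`, `label`) data.tables.
#' @export
build_network <- function(profiles) {
  if (inherits(profiles, "profile_table")) profiles <- list(profiles)
  stopifnot(all(vapply(profiles, inherits, TRUE, "profile_table")))
  parts <- lapply(profiles, function(p) {
    l <- p$links[nzchar(p$links$setid), ]
    if (nrow(l) == 0L) return(NULL)
    data.table::data.table(
      source = paste0(p$concept_kind, ":", l$concept),
      target = paste0("setid:", l$setid),
      label = l$category,
      source_type = NODE_TYPES[[p$concept_kind]],
      display_name = ifelse(is.na(l$concept_name) | !nzchar(l$concept_name),
                            l$concept, l$concept_name))
  })
  parts <- parts[!vapply(parts, is.null, TRUE)]
  if (length(parts) == 0L) return(empty_network())
  all_links <- unique(data.table::rbindlist(parts),
                      by = c("source", "target", "label"))
  concept_nodes <- unique(data.table::data.table(
    id = all_links$source, node_type = all_links$source_type,
    display_name = all_links$display_name), by = "id")
  label_nodes <- unique(data.table::data.table(
    id = all_links$target, node_type = NODE_TYPES[["setid"]],
    display_name = sub("^setid:", "", all_links$target)), by = "id")
  structure(list(nodes = rbind(concept_nodes, label_nodes),
                 edges = all_links[, c("source", "target", "label")]),
            class = "drug_network")
}

#' @export
print.drug_network <- function(x, ...) {
  cat("<drug_network>", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  if (nrow(x$edges))
    cat("  edge labels:",
        paste(sort(unique(x$edges$label)), collapse = ", "), "\n")
  invisible(x)
}

#' Extract the sub-network carrying one edge label
#'
#' Keeps the edges with the requested category label plus their endpoint
#' nodes only (e.g. the EPC sub-network: NDF-RT EPC concepts as sources,
#' SPL labels as targets). Unknown labels yield an empty network.
#' Idempotent: extracting the same label twice returns the same network.
#'
#' @param net A `drug_network`.
#' @param edge_label Category label to keep.
#' @return A `drug_network`.
#' @export
extract_subnetwork <- function(net, edge_label) {
  stopifnot(inherits(net, "drug_network"))
  edges <- net$edges[net$edges$label == edge_label, ]
  if (nrow(edges) == 0L) return(empty_network())
  keep <- unique(c(edges$source, edges$target))
  structure(list(nodes = net$nodes[net$nodes$id %in% keep, ],
                 edges = edges),
            class = "drug_network")
}

#' Export a network for Cytoscape
#'
#' `"sif"` writes the Simple Interaction Format, one line per edge
#' (`source<TAB>label<TAB>target`). `"graphml"` writes GraphML with
#' `node_type` and `display_name` node attributes and the `label` edge
#' attribute; GraphML is the lossless archival format
#' (see [import_graphml()]).
#'
#' @param net A `drug_network`.
#' @param path Output file path.
#' @param format `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("sif", "graphml")) {
  stopifnot(inherits(net, "drug_network"))
  format <- match.arg(format)
  if (format == "sif") {
    lines <- if (nrow(net$edges)) paste(net$edges$source, net$edges$label,
                                        net$edges$target, sep = "\t")
             else character(0)
    writeLines(lines, path)
  } else {
    g <- igraph::graph_from_data_frame(
      d = as.data.frame(net$edges[, c("source", "target", "label")]),
      directed = TRUE,
      vertices = as.data.frame(net$nodes))
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Re-import a GraphML export
#'
#' Round-trip inverse of `export_network(..., format = "graphml")`.
#'
#' @param path A GraphML file written by [export_network()].
#' @return A `drug_network`.
#' @export
import_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if (igraph::vcount(g) == 0L) return(empty_network())
  nodes <- data.table::data.table(
    id = igraph::vertex_attr(g, "name"),
    node_type = igraph::vertex_attr(g, "node_type"),
    display_name = igraph::vertex_attr(g, "display_name"))
  el <- igraph::as_edgelist(g, names = TRUE)
  edges <- data.table::data.table(
    source = el[, 1], target = el[, 2],
    label = if (igraph::ecount(g)) igraph::edge_attr(g, "label")
            else character(0))
  structure(list(nodes = nodes, edges = edges), class = "drug_network")
}
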