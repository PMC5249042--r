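#' Construct a pathway graph of multi-gene KEGG-style nodes
#'
#' A pathway is a set of nodes, each potentially mapping to several genes
#' (KEGG nodes frequently represent multiple genes/isoforms), plus
#' optional relation edges used for export. A gene may belong to more than
#' one node; membership lists may be empty (unmeasured nodes).
#'
#' @param pathway_id Pathway label.
#' @param nodes data.frame with columns `node_id` (unique) and `label`.
#' @param members Named list (names = node ids) of character vectors of
#'   member gene ids; gene ids are treated as opaque strings.
#' @param edges data.frame with columns `from`, `to`, `relation`
#'   (optional; defaults to no edges).
#' @return An object of class `pathway_graph`.
#' @export
pathway_graph <- function(pathway_id, nodes, members,
                          edges = data.frame(from = character(0),
                                             to = character(0),
                                             relation = character(0))) {
  if (is.null(pathway_id) || !nzchar(pathway_id)) {
    stop_param("pathway_id must be a non-empty label")
  }
  stopifnot(is.data.frame(nodes), all(c("node_id", "label") %in% names(nodes)))
  if (anyDuplicated(nodes$node_id)) {
    stop_param("duplicate node id: %s",
               nodes$node_id[duplicated(nodes$node_id)][1L])
  }
  if (!setequal(names(members), nodes$node_id)) {
    stop_param("members must be a named list covering exactly the node ids")
  }
  members <- members[nodes$node_id]  # align order
  nodes$node_id <- as.character(nodes$node_id)
  nodes$label <- as.character(nodes$label)
  structure(list(pathway_id = pathway_id,
                 nodes = nodes[c("node_id", "label")],
                 members = members,
                 edges = edges[c("from", "to", "relation")]),
            class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("<pathway_graph> %s: %d nodes (%d genes), %d edges\n",
              x$pathway_id, nrow(x$nodes),
              length(unique(unlist(x$members))), nrow(x$edges)))
  invisible(x)
}

#' Read a pathway from a KGML document
#'
#' Parses the subset of KEGG Markup Language needed for node scoring:
#' `entry` elements of type `"gene"` become nodes whose membership is the
#' whitespace-separated identifier list in the entry's `name` attribute;
#' entries of any other type become empty-membership nodes; `relation`
#' elements become edges. Graphics coordinates are ignored.
#'
#' @param source Path to a KGML file, or an `xml2` document.
#' @return A [pathway_graph()].
#' @export
read_kgml <- function(source) {
  doc <- if (inherits(source, "xml_document")) source else xml2::read_xml(source)
  root <- xml2::xml_find_first(doc, "/pathway")
  if (inherits(root, "xml_missing")) {
    stop_param("document has no <pathway> root element")
  }
  pid <- xml2::xml_attr(root, "name")
  if (is.na(pid) || !nzchar(pid)) {
    stop_param("KGML pathway element lacks the required name attribute")
  }
  entries <- xml2::xml_find_all(root, "entry")
  ids <- xml2::xml_attr(entries, "id")
  types <- xml2::xml_attr(entries, "type")
  names_attr <- xml2::xml_attr(entries, "name")
  labels <- vapply(entries, function(e) {
    g <- xml2::xml_find_first(e, "graphics")
    lab <- if (inherits(g, "xml_missing")) NA_character_ else xml2::xml_attr(g, "name")
    if (is.na(lab)) xml2::xml_attr(e, "name") else lab
  }, character(1))
  members <- lapply(seq_along(entries), function(i) {
    if (identical(types[i], "gene")) {
      strsplit(trimws(names_attr[i]), "\\s+")[[1L]]
    } else {
      character(0)
    }
  })
  names(members) <- ids
  rels <- xml2::xml_find_all(root, "relation")
  edges <- data.frame(
    from = xml2::xml_attr(rels, "entry1"),
    to = xml2::xml_attr(rels, "entry2"),
    relation = vapply(rels, function(r) {
      s <- xml2::xml_find_first(r, "subtype")
      lab <- if (inherits(s, "xml_missing")) NA_character_ else xml2::xml_attr(s, "name")
      if (is.na(lab)) xml2::xml_attr(r, "type") else lab
    }, character(1)))
  pathway_graph(pid,
                nodes = data.frame(node_id = ids, label = labels),
                members = members, edges = edges)
}

#' Write a pathway graph as a KGML document
#'
#' Emits the same KGML subset [read_kgml()] consumes (entries with
#' whitespace-separated gene lists, graphics labels, relations), so
#' writing and re-reading a graph is lossless.
#'
#' @param graph A [pathway_graph()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_kgml <- function(graph, path) {
  stopifnot(inherits(graph, "pathway_graph"))
  doc <- xml2::xml_new_root("pathway", name = graph$pathway_id)
  for (i in seq_len(nrow(graph$nodes))) {
    nid <- graph$nodes$node_id[i]
    mem <- graph$members[[nid]]
    e <- xml2::xml_add_child(doc, "entry",
                             id = nid,
                             name = paste(mem, collapse = " "),
                             type = if (length(mem)) "gene" else "map")
    xml2::xml_add_child(e, "graphics", name = graph$nodes$label[i])
  }
  for (i in seq_len(nrow(graph$edges))) {
    r <- xml2::xml_add_child(doc, "relation",
                             entry1 = graph$edges$from[i],
                             entry2 = graph$edges$to[i],
                             type = "PPrel")
    xml2::xml_add_child(r, "subtype", name = graph$edges$relation[i],
                        value = "")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a pathway from a node-map TSV
#'
#' Simplified tabular alternative to KGML: one row per node with columns
#' `node_id`, `gene_ids` (comma-separated, possibly empty) and an
#' optional `label`. The resulting graph has no edges.
#'
#' @param path Input TSV path.
#' @param pathway_id Pathway label (default: file name without
#'   extension).
#' @return A [pathway_graph()].
#' @export
read_node_map <- function(path, pathway_id = NULL) {
  if (is.null(pathway_id)) {
    pathway_id <- tools::file_path_sans_ext(basename(path))
  }
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character", na.strings = NULL)
  need <- c("node_id", "gene_ids")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop_param("node-map TSV is missing required column(s): %s",
               paste(miss, collapse = ", "))
  }
  if (anyDuplicated(tab$node_id)) {
    stop_param("duplicate node_id row: %s",
               tab$node_id[duplicated(tab$node_id)][1L])
  }
  if (is.null(tab$label)) tab$label <- tab$node_id
  members <- lapply(tab$gene_ids, function(s) {
    if (!nzchar(s)) character(0) else strsplit(s, ",", fixed = TRUE)[[1L]]
  })
  names(members) <- tab$node_id
  pathway_graph(pathway_id,
                nodes = data.frame(node_id = tab$node_id, label = tab$label),
                members = members)
}

#' Write a pathway graph as a node-map TSV
#'
#' @param graph A [pathway_graph()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_node_map <- function(graph, path) {
  stopifnot(inherits(graph, "pathway_graph"))
  tab <- data.frame(
    node_id = graph$nodes$node_id,
    gene_ids = vapply(graph$members, paste, character(1), collapse = ","),
    label = graph$nodes$label)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
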