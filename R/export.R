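#' Export a network for Cytoscape
#'
#' Writes the assembled network in the lowest-common-denominator Cytoscape
#' interchange formats plus a lossless GraphML:
#' \itemize{
#'   \item `<prefix>.sif` — one line per edge, `geneA co geneB`; isolated
#'     nodes are listed on their own line so they survive import;
#'   \item `<prefix>_edge_attrs.tsv` — `gene_a`, `interaction`, `gene_b`,
#'     `occurrence_count`;
#'   \item `<prefix>_node_attrs.tsv` — `gene`, `role` (hit/connector),
#'     `delta`;
#'   \item `<prefix>.graphml` — nodes, roles, deltas and edge weights in one
#'     file; [read_graphml_network()] reconstructs an identical network.
#' }
#' All files are byte-deterministic for a given network (lexicographic node
#' and edge order).
#'
#' @param net A `coreg_network` from [assemble_network()].
#' @param out_prefix Path prefix for the output files.
#' @param graphml Write the GraphML file too (default `TRUE`).
#' @return Named character vector of written paths, invisibly.
#' @export
export_cytoscape <- function(net, out_prefix, graphml = TRUE) {
  stopifnot(inherits(net, "coreg_network"))
  out_dir <- dirname(out_prefix)
  if (!dir.exists(out_dir)) {
    stop("output directory does not exist: ", out_dir, call. = FALSE)
  }
  nodes <- net$nodes[order(net$nodes$gene, method = "radix"), , drop = FALSE]
  edges <- net$edges[order(net$edges$gene_a, net$edges$gene_b,
                           method = "radix"), , drop = FALSE]
  paths <- c(sif = paste0(out_prefix, ".sif"),
             edge_attrs = paste0(out_prefix, "_edge_attrs.tsv"),
             node_attrs = paste0(out_prefix, "_node_attrs.tsv"))

  connected <- unique(c(edges$gene_a, edges$gene_b))
  isolated <- setdiff(nodes$gene, connected)
  writeLines(c(sprintf("%s\tco\t%s", edges$gene_a, edges$gene_b), isolated),
             paths[["sif"]], useBytes = TRUE)

  writeLines(c("gene_a\tinteraction\tgene_b\toccurrence_count",
               sprintf("%s\tco\t%s\t%d", edges$gene_a, edges$gene_b,
                       edges$weight)),
             paths[["edge_attrs"]], useBytes = TRUE)

  fmt_delta <- function(d) ifelse(is.na(d), "NA",
                                  format(d, digits = 15, trim = TRUE,
                                         scientific = FALSE))
  writeLines(c("gene\trole\tdelta",
               sprintf("%s\t%s\t%s", nodes$gene, nodes$role,
                       fmt_delta(nodes$delta))),
             paths[["node_attrs"]], useBytes = TRUE)

  if (graphml) {
    paths <- c(paths, graphml = paste0(out_prefix, ".graphml"))
    .write_graphml(nodes, edges, net$direction, paths[["graphml"]])
  }
  invisible(paths)
}

# Hand-rolled GraphML writer: xml2 serialization does not guarantee stable
# attribute ordering across versions, and the schema here is tiny.
#' @keywords internal
#' @noRd
.write_graphml <- function(nodes, edges, direction, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  node_lines <- unlist(lapply(seq_len(nrow(nodes)), function(i) {
    d <- nodes$delta[[i]]
    c(sprintf('    <node id="%s">', esc(nodes$gene[[i]])),
      sprintf('      <data key="role">%s</data>', nodes$role[[i]]),
      if (!is.na(d)) sprintf('      <data key="delta">%s</data>',
                             format(d, digits = 15, trim = TRUE,
                                    scientific = FALSE)),
      "    </node>")
  }), use.names = FALSE)
  edge_lines <- unlist(lapply(seq_len(nrow(edges)), function(i) {
    c(sprintf('    <edge source="%s" target="%s">',
              esc(edges$gene_a[[i]]), esc(edges$gene_b[[i]])),
      sprintf('      <data key="weight">%d</data>', edges$weight[[i]]),
      "    </edge>")
  }), use.names = FALSE)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="role" for="node" attr.name="role" attr.type="string"/>',
    '  <key id="delta" for="node" attr.name="delta" attr.type="double"/>',
    '  <key id="weight" for="edge" attr.name="weight" attr.type="int"/>',
    sprintf('  <graph id="%s" edgedefault="undirected">', esc(direction)),
    node_lines,
    edge_lines,
    "  </graph>",
    "</graphml>"
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a network back from GraphML
#'
#' Inverse of the GraphML export of [export_cytoscape()]; reconstructs the
#' `coreg_network` with identical nodes, roles, deltas and edge weights.
#'
#' @param path Path to a GraphML file written by this package.
#' @return A `coreg_network`.
#' @export
read_graphml_network <- function(path) {
  if (!file.exists(path)) stop("GraphML file not found: ", path,
                               call. = FALSE)
  doc <- xml2::read_xml(path)
  ns <- c(g = "http://graphml.graphdrawing.org/xmlns")
  graph <- xml2::xml_find_first(doc, ".//g:graph", ns)
  direction <- xml2::xml_attr(graph, "id")
  node_xml <- xml2::xml_find_all(graph, "g:node", ns)
  get_data <- function(node, key) {
    d <- xml2::xml_find_first(node, sprintf("g:data[@key='%s']", key), ns)
    if (inherits(d, "xml_missing")) NA_character_ else xml2::xml_text(d)
  }
  nodes <- data.frame(
    gene = xml2::xml_attr(node_xml, "id"),
    role = vapply(node_xml, get_data, character(1L), key = "role"),
    delta = as.numeric(vapply(node_xml, get_data, character(1L),
                              key = "delta")),
    stringsAsFactors = FALSE
  )
  edge_xml <- xml2::xml_find_all(graph, "g:edge", ns)
  edges <- data.frame(
    gene_a = xml2::xml_attr(edge_xml, "source"),
    gene_b = xml2::xml_attr(edge_xml, "target"),
    weight = as.integer(vapply(edge_xml, get_data, character(1L),
                               key = "weight")),
    stringsAsFactors = FALSE
  )
  nodes <- nodes[order(nodes$gene, method = "radix"), , drop = FALSE]
  rownames(nodes) <- NULL
  edges <- edges[order(edges$gene_a, edges$gene_b, method = "radix"), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 direction = if (is.na(direction)) "up" else direction),
            class = "coreg_network")
}
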