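.net_formats <- c("graphml", "tsv", "sif")

.check_format <- function(format) {
  if (length(format) != 1 || !format %in% .net_formats)
    stop("unknown network format '", paste(format, collapse = ","),
         "'; supported formats: ", paste(.net_formats, collapse = ", "))
  format
}

.nodes_sidecar <- function(path) paste0(path, ".nodes")

#' Write a CT/CTP network to disk
#'
#' Three formats are supported. `graphml` is self-contained: node attributes
#' `layer`, `weight`, `n_publications` and edge attributes `type` (and
#' `score`, when present) are embedded, numerics at full double precision.
#' `tsv` writes a three-column edge list (`source`, `target`, `edge_type`)
#' and `sif` writes Cytoscape SIF lines (`A ct B`, `A pp B`, isolated nodes
#' as single-token lines); both also write a `<path>.nodes` sidecar table
#' carrying the node attributes so that a round trip preserves the network
#' exactly.
#'
#' @param net network from [build_ct_network()] / [merge_ctp()].
#' @param path output path.
#' @param format one of `"graphml"`, `"tsv"`, `"sif"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("graphml", "tsv", "sif")) {
  if (identical(format, c("graphml", "tsv", "sif"))) format <- "graphml"
  .check_format(format)
  tab <- network_tables(net)
  switch(format,
         graphml = .write_graphml(tab, path),
         tsv = .write_tsv_net(tab, path),
         sif = .write_sif_net(tab, path))
  invisible(path)
}

#' Read a CT/CTP network from disk
#'
#' Counterpart of [write_network()]. For `tsv` and `sif` the `<path>.nodes`
#' sidecar is read back when present; without it node layers are inferred
#' from the edge types (`ct` source = component, everything else = target),
#' weights default to 1.
#'
#' @param path file path.
#' @param format one of `"graphml"`, `"tsv"`, `"sif"`.
#' @return an undirected `igraph` network.
#' @export
read_network <- function(path, format = c("graphml", "tsv", "sif")) {
  if (identical(format, c("graphml", "tsv", "sif"))) format <- "graphml"
  .check_format(format)
  if (!file.exists(path)) stop("network file not found: ", path)
  switch(format,
         graphml = .read_graphml(path),
         tsv = .read_tsv_net(path),
         sif = .read_sif_net(path))
}

# ---- tsv ------------------------------------------------------------------

.write_nodes_sidecar <- function(nodes, path) {
  out <- nodes
  out$weight <- .fmt_num(nodes$weight)
  out$n_publications <- .fmt_num(nodes$n_publications)
  utils::write.table(out, .nodes_sidecar(path), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

.read_nodes_sidecar <- function(path) {
  f <- .nodes_sidecar(path)
  if (!file.exists(f)) return(NULL)
  nodes <- utils::read.delim(f, colClasses = c("character", "character",
                                               "numeric", "numeric"))
  names(nodes) <- c("name", "layer", "weight", "n_publications")
  nodes
}

.infer_nodes <- function(edges) {
  comp <- unique(edges$from[edges$type == "ct"])
  prot <- setdiff(unique(c(edges$to, edges$from)), comp)
  data.frame(name = c(comp, prot),
             layer = c(rep("component", length(comp)), rep("target", length(prot))),
             weight = 1, n_publications = 0, stringsAsFactors = FALSE)
}

.write_tsv_net <- function(tab, path) {
  edges <- data.frame(source = tab$edges$from, target = tab$edges$to,
                      edge_type = tab$edges$type, stringsAsFactors = FALSE)
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  .write_nodes_sidecar(tab$nodes, path)
}

.read_tsv_net <- function(path) {
  edges <- utils::read.delim(path, colClasses = "character")
  if (ncol(edges) < 2) stop("edge-list TSV needs at least two columns")
  names(edges)[1:2] <- c("from", "to")
  edges$type <- if (ncol(edges) >= 3) edges[[3]] else "pp"
  edges <- edges[, c("from", "to", "type")]
  nodes <- .read_nodes_sidecar(path) %||% .infer_nodes(edges)
  .make_ctp(nodes, edges)
}

# ---- sif ------------------------------------------------------------------

.write_sif_net <- function(tab, path) {
  con_deg <- c(tab$edges$from, tab$edges$to)
  isolated <- setdiff(tab$nodes$name, con_deg)
  lines <- c(paste(tab$edges$from, tab$edges$type, tab$edges$to), isolated)
  writeLines(lines, path)
  .write_nodes_sidecar(tab$nodes, path)
}

.read_sif_net <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  singles <- vapply(parts, length, 0L) == 1
  if (any(vapply(parts, length, 0L) == 2))
    stop("malformed SIF line: expected 'source relation target'")
  edges <- do.call(rbind, lapply(parts[!singles], function(p) {
    # SIF permits one source with several targets on a line
    data.frame(from = p[1], to = p[-(1:2)], type = p[2],
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(from = character(0), to = character(0),
                        type = character(0), stringsAsFactors = FALSE)
  iso <- unlist(parts[singles])
  nodes <- .read_nodes_sidecar(path)
  if (is.null(nodes)) {
    nodes <- .infer_nodes(edges)
    if (length(iso))
      nodes <- rbind(nodes, data.frame(name = setdiff(iso, nodes$name),
                                       layer = "target", weight = 1,
                                       n_publications = 0,
                                       stringsAsFactors = FALSE))
  }
  .make_ctp(nodes, edges)
}

# ---- graphml --------------------------------------------------------------
# Hand-rolled writer/reader so node weights survive the round trip at full
# double precision.

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

.write_graphml <- function(tab, path) {
  nodes <- tab$nodes
  edges <- tab$edges
  has_score <- "score" %in% names(edges) && any(!is.na(edges$score))
  head <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="layer" for="node" attr.name="layer" attr.type="string"/>',
    '  <key id="weight" for="node" attr.name="weight" attr.type="double"/>',
    '  <key id="n_publications" for="node" attr.name="n_publications" attr.type="double"/>',
    '  <key id="type" for="edge" attr.name="type" attr.type="string"/>',
    if (has_score)
      '  <key id="score" for="edge" attr.name="score" attr.type="double"/>',
    '  <graph id="G" edgedefault="undirected">')
  node_lines <- sprintf(
    '    <node id="%s"><data key="layer">%s</data><data key="weight">%s</data><data key="n_publications">%s</data></node>',
    .xml_escape(nodes$name), .xml_escape(nodes$layer),
    .fmt_num(nodes$weight), .fmt_num(nodes$n_publications))
  if (nrow(edges)) {
    score_part <- if (has_score) {
      ifelse(is.na(edges$score), "",
             sprintf('<data key="score">%s</data>', .fmt_num(edges$score)))
    } else ""
    edge_lines <- sprintf(
      '    <edge source="%s" target="%s"><data key="type">%s</data>%s</edge>',
      .xml_escape(edges$from), .xml_escape(edges$to),
      .xml_escape(edges$type), score_part)
  } else edge_lines <- character(0)
  writeLines(c(head, node_lines, edge_lines, "  </graph>", "</graphml>"), path)
}

.read_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  node_els <- xml2::xml_find_all(doc, ".//graph/node")
  get_data <- function(els, key) {
    vapply(els, function(e) {
      d <- xml2::xml_find_first(e, sprintf(".//data[@key='%s']", key))
      if (inherits(d, "xml_missing")) NA_character_ else xml2::xml_text(d)
    }, character(1))
  }
  nodes <- data.frame(
    name = xml2::xml_attr(node_els, "id"),
    layer = get_data(node_els, "layer"),
    weight = as.numeric(get_data(node_els, "weight")),
    n_publications = as.numeric(get_data(node_els, "n_publications")),
    stringsAsFactors = FALSE)
  nodes$layer[is.na(nodes$layer)] <- "target"
  nodes$weight[is.na(nodes$weight)] <- 1
  nodes$n_publications[is.na(nodes$n_publications)] <- 0
  edge_els <- xml2::xml_find_all(doc, ".//graph/edge")
  edges <- data.frame(
    from = xml2::xml_attr(edge_els, "source"),
    to = xml2::xml_attr(edge_els, "target"),
    type = get_data(edge_els, "type"),
    stringsAsFactors = FALSE)
  edges$type[is.na(edges$type)] <- "pp"
  score <- as.numeric(get_data(edge_els, "score"))
  if (any(!is.na(score))) edges$score <- score
  .make_ctp(nodes, edges)
}
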