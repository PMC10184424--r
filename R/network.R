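#' @importFrom igraph V E vcount ecount degree
NULL

# Canonical edge form: protein-protein edges get their endpoints sorted,
# component-target edges keep the component first; duplicates collapse and
# rows are sorted so graph construction is order-insensitive.
.canonical_edges <- function(edges, layer_of) {
  if (!nrow(edges)) {
    edges <- edges[, intersect(c("from", "to", "type", "score"), names(edges)),
                   drop = FALSE]
    return(edges)
  }
  is_pp <- edges$type == "pp"
  sw <- is_pp & edges$from > edges$to
  if (!missing(layer_of) && length(layer_of)) {
    sw_ct <- edges$type == "ct" &
      !is.na(layer_of[edges$to]) & layer_of[edges$to] == "component"
    sw <- sw | sw_ct
  }
  tmp <- edges$from[sw]
  edges$from[sw] <- edges$to[sw]
  edges$to[sw] <- tmp
  key <- paste(edges$type, edges$from, edges$to)
  edges <- edges[!duplicated(key), , drop = FALSE]
  edges <- edges[order(edges$type, edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

.make_ctp <- function(nodes, edges) {
  nodes <- nodes[order(nodes$name), , drop = FALSE]
  rownames(nodes) <- NULL
  layer_of <- stats::setNames(nodes$layer, nodes$name)
  edges <- .canonical_edges(edges, layer_of)
  bad <- c(setdiff(edges$from, nodes$name), setdiff(edges$to, nodes$name))
  if (length(bad))
    stop("edge endpoint not among nodes: ", paste(unique(bad), collapse = ", "))
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

#' Build the component-target (CT) network
#'
#' Constructs the simple bipartite graph of components and their predicted
#' protein targets. Duplicate edges (e.g. the same pair reported by several
#' target predictors) collapse to one; targets never mentioned in an edge do
#' not enter the graph. Pass only the components that should appear in the
#' network (typically the active subset from
#' [select_active_components()]) -- every listed component becomes a node even
#' if it has no predicted target.
#'
#' @param components component table (only `component_id` is required).
#' @param ct_edges a two-column `data.frame` (component id, target gene
#'   symbol). Target symbols are upper-cased at ingest.
#' @return an undirected `igraph` graph with vertex attributes `layer`
#'   (`"component"`/`"target"`), `weight` (1) and `n_publications` (0), and
#'   edge attribute `type = "ct"`.
#' @export
build_ct_network <- function(components, ct_edges) {
  stopifnot(is.data.frame(ct_edges), ncol(ct_edges) >= 2)
  cid <- trimws(as.character(ct_edges[[1]]))
  tgt <- .norm_symbol(ct_edges[[2]])
  known <- components$component_id
  unknown <- setdiff(unique(cid), known)
  if (length(unknown))
    stop("CT edges reference unknown components: ",
         paste(utils::head(unknown, 10), collapse = ", "))
  clash <- intersect(unique(tgt), known)
  if (length(clash))
    stop("target symbols collide with component ids: ",
         paste(utils::head(clash, 10), collapse = ", "))

  edges <- data.frame(from = cid, to = tgt, type = "ct",
                      stringsAsFactors = FALSE)
  targets <- sort(unique(tgt))
  nodes <- data.frame(
    name = c(known, targets),
    layer = c(rep("component", length(known)), rep("target", length(targets))),
    weight = 1,
    n_publications = 0,
    stringsAsFactors = FALSE)
  .make_ctp(nodes, edges)
}

#' Per-layer degree statistics
#'
#' Mean degree and node count for the component, target and pathogenic layers
#' of a CT or CTP network, plus total node and edge counts. Nodes carrying
#' both the target and pathogenic annotation count towards both layers. An
#' empty layer is reported with count 0 and mean `NA` rather than 0.
#'
#' @param net a network from [build_ct_network()] or [merge_ctp()].
#' @return a list with elements `layers` (a `data.frame` of `layer`,
#'   `n_nodes`, `mean_degree`), `n_nodes` and `n_edges`.
#' @export
layer_degree_stats <- function(net) {
  if (igraph::vcount(net) == 0) stop("network is empty")
  lay <- V(net)$layer
  deg <- igraph::degree(net)
  members <- list(component = lay == "component",
                  target = grepl("target", lay, fixed = TRUE),
                  pathogenic = grepl("pathogenic", lay, fixed = TRUE))
  layers <- data.frame(
    layer = names(members),
    n_nodes = vapply(members, sum, 0L),
    mean_degree = vapply(members, function(m) {
      if (!any(m)) NA_real_ else mean(deg[m])
    }, 0),
    stringsAsFactors = FALSE)
  rownames(layers) <- NULL
  list(layers = layers, n_nodes = igraph::vcount(net), n_edges = igraph::ecount(net))
}

#' Merge the CT network with PPI and weighted pathogenic-gene layers
#'
#' Builds the full component-target-pathogenic (CTP) network: the union of
#' the bipartite CT graph, an undirected protein-protein interaction edge
#' list, and a table of disease genes weighted by their number of supporting
#' publications. A protein that is both a predicted target and a pathogenic
#' gene carries the dual layer label `"target|pathogenic"`. Pathogenic nodes
#' receive weight `1 + ln(1 + n_publications)`; all other nodes weight 1.
#' PPI self-loops are dropped (with a message); pathogenic genes with no edge
#' at all are retained as isolated weighted nodes, since dropping them would
#' silently shift the median importance threshold downstream.
#'
#' @param ct CT network from [build_ct_network()].
#' @param ppi_edges `data.frame` whose first two columns are interacting gene
#'   symbols; an optional third numeric column (e.g. a STRING combined score)
#'   is kept as edge attribute `score` but never used for filtering.
#' @param pathogenic `data.frame` with columns `symbol` and `n_publications`
#'   (each >= 1).
#' @return the merged undirected `igraph` CTP network.
#' @export
merge_ctp <- function(ct, ppi_edges, pathogenic) {
  stopifnot(is.data.frame(ppi_edges), ncol(ppi_edges) >= 2,
            is.data.frame(pathogenic),
            all(c("symbol", "n_publications") %in% names(pathogenic)))

  a <- .norm_symbol(ppi_edges[[1]])
  b <- .norm_symbol(ppi_edges[[2]])
  score <- if (ncol(ppi_edges) >= 3 && is.numeric(ppi_edges[[3]]))
    ppi_edges[[3]] else NULL
  self <- a == b
  if (any(self)) {
    message("dropped ", sum(self), " PPI self-loop(s)")
    a <- a[!self]; b <- b[!self]
    if (!is.null(score)) score <- score[!self]
  }

  psym <- .norm_symbol(pathogenic$symbol)
  if (anyDuplicated(psym))
    stop("duplicate pathogenic gene symbols: ",
         paste(unique(psym[duplicated(psym)]), collapse = ", "))
  npub <- pathogenic$n_publications
  if (any(is.na(npub)) || any(npub < 1))
    stop("n_publications must be >= 1 for every pathogenic gene")
  pweight <- 1 + log(1 + npub)

  ct_nodes <- data.frame(name = V(ct)$name, layer = V(ct)$layer,
                         stringsAsFactors = FALSE)
  comp_ids <- ct_nodes$name[ct_nodes$layer == "component"]
  ct_targets <- ct_nodes$name[ct_nodes$layer != "component"]
  ppi_nodes <- unique(c(a, b))
  clash <- intersect(comp_ids, c(ppi_nodes, psym))
  if (length(clash))
    stop("protein symbols collide with component ids: ",
         paste(utils::head(clash, 10), collapse = ", "))

  proteins <- sort(unique(c(ct_targets, ppi_nodes, psym)))
  is_path <- proteins %in% psym
  # the target layer holds every non-pathogenic protein (predicted targets
  # and any extra PPI proteins supplied by the user)
  is_target <- proteins %in% ct_targets | (!is_path & proteins %in% ppi_nodes)
  layer <- ifelse(is_target & is_path, "target|pathogenic",
                  ifelse(is_path, "pathogenic", "target"))

  idx <- match(proteins, psym)
  weight <- ifelse(is_path, pweight[idx], 1)
  n_publications <- ifelse(is_path, npub[idx], 0)

  isolated <- setdiff(psym, c(ct_targets, ppi_nodes))
  if (length(isolated))
    message("retained ", length(isolated),
            " isolated pathogenic gene(s) with no interaction")

  nodes <- rbind(
    data.frame(name = comp_ids, layer = "component", weight = 1,
               n_publications = 0, stringsAsFactors = FALSE),
    data.frame(name = proteins, layer = layer, weight = weight,
               n_publications = n_publications, stringsAsFactors = FALSE))

  ct_el <- igraph::as_data_frame(ct, what = "edges")
  edges <- data.frame(from = c(ct_el$from, a), to = c(ct_el$to, b),
                      type = c(rep("ct", nrow(ct_el)), rep("pp", length(a))),
                      stringsAsFactors = FALSE)
  if (!is.null(score))
    edges$score <- c(rep(NA_real_, nrow(ct_el)), score)
  .make_ctp(nodes, edges)
}

#' Canonical node and edge tables of a network
#'
#' Returns the network as two sorted data frames (nodes with layer, weight
#' and publication count; canonicalized edges with type). Two networks are
#' identical in the round-trip sense exactly when their tables are equal.
#'
#' @param net a CT/CTP `igraph` network.
#' @return `list(nodes =, edges =)`.
#' @export
network_tables <- function(net) {
  nodes <- data.frame(
    name = V(net)$name,
    layer = V(net)$layer %||% rep(NA_character_, igraph::vcount(net)),
    weight = V(net)$weight %||% rep(1, igraph::vcount(net)),
    n_publications = V(net)$n_publications %||% rep(0, igraph::vcount(net)),
    stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$name), , drop = FALSE]
  rownames(nodes) <- NULL
  edges <- igraph::as_data_frame(net, what = "edges")
  if (!"type" %in% names(edges)) edges$type <- rep("pp", nrow(edges))
  layer_of <- stats::setNames(nodes$layer, nodes$name)
  edges <- .canonical_edges(edges[, intersect(c("from", "to", "type", "score"),
                                              names(edges)), drop = FALSE],
                            layer_of)
  list(nodes = nodes, edges = edges)
}
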