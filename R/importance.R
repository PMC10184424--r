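#' Damped weight-propagating node importance
#'
#' The importance of a node `v` combines the probability that it is connected
#' to others with its influence over the nodes it can reach:
#' \deqn{score(v) = \frac{deg(v)}{N-1} \sum_{u \ne v,\ d(v,u) \le D} w(u)\,\alpha^{d(v,u)}}
#' where `d(v,u)` is the shortest-path distance, `D = max_depth` truncates the
#' propagation, `alpha` damps influence with distance, and `w(u)` is the node
#' weight -- `1 + ln(1 + n_publications)` for pathogenic genes, 1 for every
#' other node (taken from the vertex attribute `weight`). Isolated nodes
#' score 0; unreachable pairs contribute nothing.
#'
#' @param net CT/CTP network (`igraph`), node weights in the vertex attribute
#'   `weight` (defaults to 1 if absent).
#' @param alpha damping factor, strictly inside (0, 1).
#' @param max_depth propagation horizon in hops (default 3).
#' @return named numeric vector of scores, one per node.
#' @export
novel_importance <- function(net, alpha = 0.5, max_depth = 3) {
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly inside (0, 1)")
  if (!is.numeric(max_depth) || length(max_depth) != 1 || max_depth < 1)
    stop("max_depth must be a positive number of hops")
  n <- igraph::vcount(net)
  nm <- V(net)$name %||% as.character(seq_len(n))
  if (n == 0) return(stats::setNames(numeric(0), character(0)))
  if (n == 1) return(stats::setNames(0, nm))
  w <- V(net)$weight %||% rep(1, n)
  deg <- igraph::degree(net)
  score <- numeric(n)
  chunk <- 512L  # bounds the distance-matrix slab on large networks
  for (start in seq(1L, n, by = chunk)) {
    end <- min(n, start + chunk - 1L)
    d <- igraph::distances(net, v = V(net)[start:end], algorithm = "unweighted")
    a <- alpha^d
    a[d == 0 | d > max_depth | is.infinite(d)] <- 0
    score[start:end] <- deg[start:end] / (n - 1) * as.numeric(a %*% w)
  }
  stats::setNames(score, nm)
}

#' Classical baseline centralities
#'
#' The six baselines the importance model is compared against, with their
#' textbook definitions. Distance-based measures are computed per connected
#' component of size `n_c`:
#' \itemize{
#'   \item `degree`: number of incident edges.
#'   \item `closeness`: \eqn{(n_c - 1) / \sum_u d(v, u)}.
#'   \item `radiality`: \eqn{\sum_{u \ne v} (diam_c + 1 - d(v, u)) / (n_c - 1)}
#'     with the component diameter `diam_c`.
#'   \item `clustering_coefficient`: local clustering coefficient (0 for
#'     nodes with fewer than two neighbours).
#'   \item `neighborhood_connectivity`: mean degree of the neighbours (0 for
#'     isolated nodes).
#'   \item `avg_shortest_path`: \eqn{\sum_u d(v, u) / (n_c - 1)}; lower means
#'     more central, so the ranking is inverted before key-network extraction
#'     (singletons get `Inf`).
#' }
#'
#' @param net an undirected `igraph` network.
#' @param method one of the six names above.
#' @return named numeric vector of centralities.
#' @export
baseline_centrality <- function(net, method) {
  methods <- c("degree", "closeness", "radiality", "clustering_coefficient",
               "neighborhood_connectivity", "avg_shortest_path")
  if (length(method) != 1 || !method %in% methods)
    stop("unknown centrality method '", paste(method, collapse = ","),
         "'; available methods: ", paste(methods, collapse = ", "))
  n <- igraph::vcount(net)
  nm <- V(net)$name %||% as.character(seq_len(n))
  deg <- igraph::degree(net)

  out <- switch(method,
    degree = as.numeric(deg),
    clustering_coefficient = {
      cc <- igraph::transitivity(net, type = "local")
      cc[is.na(cc) | is.nan(cc)] <- 0
      cc
    },
    neighborhood_connectivity = {
      adj <- igraph::as_adj_list(net)
      vapply(seq_len(n), function(i) {
        nb <- as.integer(adj[[i]])
        if (!length(nb)) 0 else mean(deg[nb])
      }, 0)
    },
    {
      memb <- igraph::components(net)$membership
      res <- numeric(n)
      for (cmp in unique(memb)) {
        idx <- which(memb == cmp)
        nc <- length(idx)
        if (nc == 1) {
          res[idx] <- if (method == "avg_shortest_path") Inf else 0
          next
        }
        dc <- igraph::distances(net, v = V(net)[idx], to = V(net)[idx],
                                algorithm = "unweighted")
        tot <- rowSums(dc)
        res[idx] <- switch(method,
          closeness = (nc - 1) / tot,
          radiality = {
            diam <- max(dc)
            (rowSums(diam + 1 - dc) - (diam + 1)) / (nc - 1)
          },
          avg_shortest_path = tot / (nc - 1))
      }
      res
    })
  stats::setNames(as.numeric(out), nm)
}

#' Extract the key functional network by median thresholding
#'
#' Nodes whose score strictly exceeds the median score of *all* nodes (one
#' joint median across layers, not per layer) are retained, together with the
#' edges among them, as the key functional network. Retained nodes that end
#' up isolated are kept (and counted in a message). When every score is
#' identical the key set is empty and a warning is raised.
#'
#' @param net the scored network.
#' @param scores named numeric vector covering every node of `net`, larger =
#'   more important.
#' @param method label stored on the result.
#' @return an object of class `importance_result`: a list with `method`,
#'   `scores`, `median`, `key_nodes` and `key_network` (induced `igraph`
#'   subgraph).
#' @export
extract_key_network <- function(net, scores, method = "custom") {
  nm <- V(net)$name %||% as.character(seq_len(igraph::vcount(net)))
  if (!all(nm %in% names(scores)))
    stop("scores must cover every node of the network")
  s <- scores[nm]
  med <- stats::median(s)
  if (length(s) && length(unique(s)) == 1L) {
    warning("all scores are identical; the key network is empty")
    key <- character(0)
  } else {
    key <- nm[s > med]
  }
  sub <- igraph::induced_subgraph(net, key)
  iso <- sum(igraph::degree(sub) == 0)
  if (iso > 0)
    message(iso, " retained node(s) are isolated within the key network")
  structure(list(method = method, scores = s, median = med,
                 key_nodes = key, key_network = sub),
            class = "importance_result")
}

#' Score a network and extract its key functional network
#'
#' Convenience wrapper: computes either the damped-influence importance
#' (`method = "novel"`) or one of the six baseline centralities, orients the
#' scores so that larger always means more central (average shortest path is
#' negated), and applies the strict-median threshold of
#' [extract_key_network()].
#'
#' @param net CT/CTP network.
#' @param method `"novel"` or a [baseline_centrality()] method name.
#' @param alpha,max_depth passed to [novel_importance()].
#' @return an `importance_result`.
#' @export
key_functional_network <- function(net, method = "novel", alpha = 0.5,
                                   max_depth = 3) {
  s <- if (identical(method, "novel")) {
    novel_importance(net, alpha = alpha, max_depth = max_depth)
  } else {
    baseline_centrality(net, method)
  }
  if (identical(method, "avg_shortest_path")) s <- -s
  extract_key_network(net, s, method = method)
}

#' Gene symbols of a key functional network
#'
#' The non-component node names of the key network of an
#' [extract_key_network()] result -- the query set for enrichment-based
#' method comparison.
#'
#' @param result an `importance_result`.
#' @return character vector of gene symbols.
#' @export
key_network_genes <- function(result) {
  stopifnot(inherits(result, "importance_result"))
  g <- result$key_network
  V(g)$name[V(g)$layer != "component"]
}

#' @export
print.importance_result <- function(x, ...) {
  cat("Key functional network (method: ", x$method, ")\n", sep = "")
  cat("  scored nodes : ", length(x$scores), "\n", sep = "")
  cat("  median score : ", format(x$median), "\n", sep = "")
  cat("  key nodes    : ", length(x$key_nodes), "\n", sep = "")
  cat("  key edges    : ", igraph::ecount(x$key_network), "\n", sep = "")
  invisible(x)
}
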