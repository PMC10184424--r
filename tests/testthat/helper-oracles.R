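# Independent brute-force oracles used to check the package implementations.
# Everything here works from a plain adjacency matrix and deliberately avoids
# igraph and stats::phyper.

# all-pairs shortest-path distances by hand-rolled BFS
bf_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (u in which(adj[v, ] > 0)) {
          if (d[s, u] > depth) {
            d[s, u] <- depth
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  d
}

bf_novel <- function(adj, w, alpha = 0.5, max_depth = 3) {
  n <- nrow(adj)
  if (n == 1) return(0)
  d <- bf_distances(adj)
  sapply(seq_len(n), function(v) {
    total <- 0
    for (u in seq_len(n)) {
      if (u != v && is.finite(d[v, u]) && d[v, u] <= max_depth)
        total <- total + w[u] * alpha^d[v, u]
    }
    sum(adj[v, ]) / (n - 1) * total
  })
}

bf_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in which(adj[v, ] > 0)) {
        if (is.na(comp[u])) { comp[u] <- cur; queue <- c(queue, u) }
      }
    }
  }
  comp
}

bf_centrality <- function(adj, method) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  if (method == "degree") return(deg)
  if (method == "neighborhood_connectivity") {
    return(sapply(seq_len(n), function(v) {
      nb <- which(adj[v, ] > 0)
      if (!length(nb)) 0 else mean(deg[nb])
    }))
  }
  if (method == "clustering_coefficient") {
    return(sapply(seq_len(n), function(v) {
      nb <- which(adj[v, ] > 0)
      k <- length(nb)
      if (k < 2) return(0)
      links <- sum(adj[nb, nb]) / 2
      2 * links / (k * (k - 1))
    }))
  }
  d <- bf_distances(adj)
  comp <- bf_components(adj)
  out <- numeric(n)
  for (cm in unique(comp)) {
    idx <- which(comp == cm)
    nc <- length(idx)
    if (nc == 1) {
      out[idx] <- if (method == "avg_shortest_path") Inf else 0
      next
    }
    dc <- d[idx, idx, drop = FALSE]
    diam <- max(dc)
    for (i in seq_along(idx)) {
      tot <- sum(dc[i, ])
      out[idx[i]] <- switch(method,
        closeness = (nc - 1) / tot,
        radiality = sum(diam + 1 - dc[i, -i]) / (nc - 1),
        avg_shortest_path = tot / (nc - 1))
    }
  }
  out
}

# upper-tail hypergeometric by direct log-factorial summation
bf_hyper_upper <- function(k, K, n, N) {
  hi <- min(n, K)
  if (k > hi) return(0)
  terms <- vapply(k:hi, function(i) {
    exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n))
  }, 0)
  sum(terms)
}

# random undirected graph as an igraph object with CTP-style attributes,
# plus its adjacency matrix for the oracles
random_attr_graph <- function(n, p = 0.12, weighted = TRUE) {
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  adj <- adj + t(adj)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- sprintf("V%03d", seq_len(n))
  igraph::V(g)$layer <- sample(c("target", "pathogenic"), n, replace = TRUE)
  igraph::V(g)$weight <- if (weighted) round(stats::runif(n, 1, 5), 3) else rep(1, n)
  igraph::V(g)$n_publications <- 0
  list(graph = g, adj = adj, w = igraph::V(g)$weight)
}

# random CT/CTP-shaped network for round-trip and CDR tests
random_ctp_network <- function(n_comp = 4, n_prot = 10, p_ct = 0.4, p_pp = 0.2) {
  comps <- sprintf("CMP%02d", seq_len(n_comp))
  prots <- sprintf("PR%02d", seq_len(n_prot))
  ct <- expand.grid(from = comps, to = prots, stringsAsFactors = FALSE)
  ct <- ct[stats::runif(nrow(ct)) < p_ct, , drop = FALSE]
  pp <- t(utils::combn(prots, 2))
  pp <- pp[stats::runif(nrow(pp)) < p_pp, , drop = FALSE]
  is_path <- stats::runif(n_prot) < 0.4
  npub <- ifelse(is_path, 1L + stats::rgeom(n_prot, 0.5), 0L)
  nodes <- data.frame(
    name = c(comps, prots),
    layer = c(rep("component", n_comp),
              ifelse(is_path, "target|pathogenic", "target")),
    weight = c(rep(1, n_comp), ifelse(is_path, 1 + log(1 + npub), 1)),
    n_publications = c(rep(0, n_comp), npub),
    stringsAsFactors = FALSE)
  edges <- rbind(
    if (nrow(ct)) data.frame(from = ct$from, to = ct$to, type = "ct",
                             stringsAsFactors = FALSE),
    if (nrow(pp)) data.frame(from = pp[, 1], to = pp[, 2], type = "pp",
                             stringsAsFactors = FALSE))
  if (is.null(edges))
    edges <- data.frame(from = character(0), to = character(0),
                        type = character(0), stringsAsFactors = FALSE)
  kfcnet:::.make_ctp(nodes, edges)
}

# a reduced synthetic study specification for fast end-to-end tests
small_spec <- function(seed, ...) {
  args <- list(n_components = 80, n_targets = 180, n_pathogenic = 300,
               mean_component_degree = 15, n_validated = 3, n_planted = 5,
               module_size = 30, n_decoy_cliques = 30, n_null_genes = 1200,
               n_signal_terms = 10, n_decoy_terms = 15, term_size = 60,
               seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(synthetic_spec, args)
}

expect_same_network <- function(a, b) {
  expect_equal(network_tables(a), network_tables(b))
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
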