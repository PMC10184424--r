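path_graph_abc <- function() {
  g <- igraph::make_graph(~ A - B, B - C)
  igraph::V(g)$weight <- 1
  g
}

test_that("the damped influence score matches hand-evaluated path-graph values", {
  s <- novel_importance(path_graph_abc(), alpha = 0.5, max_depth = 3)
  # centre: p = 2/2, influence = 0.5 + 0.5; leaf: p = 1/2, influence = 0.5 + 0.25
  expect_equal(unname(s["B"]), 1.0)
  expect_equal(unname(s["A"]), 0.375)
  expect_equal(unname(s["C"]), 0.375)
})

test_that("isolated nodes score zero and invalid damping is rejected", {
  g <- igraph::make_graph(~ A - B) + igraph::vertex("Z")
  igraph::V(g)$weight <- 1
  s <- novel_importance(g)
  expect_equal(unname(s["Z"]), 0)
  expect_error(novel_importance(g, alpha = 0), "alpha")
  expect_error(novel_importance(g, alpha = 1), "alpha")
  expect_error(novel_importance(g, alpha = 1.5), "alpha")
})

test_that("max_depth truncates influence and weights propagate", {
  # path A-B-C-D-E from A: depths 1..4
  g <- igraph::make_graph(~ A - B, B - C, C - D, D - E)
  igraph::V(g)$weight <- c(1, 1, 1, 1, 10)[match(c("A","B","C","D","E"),
                                                 igraph::V(g)$name)]
  s2 <- novel_importance(g, alpha = 0.5, max_depth = 2)
  expect_equal(unname(s2["A"]), (1 / 4) * (0.5 + 0.25))
  s4 <- novel_importance(g, alpha = 0.5, max_depth = 4)
  expect_equal(unname(s4["A"]), (1 / 4) * (0.5 + 0.25 + 0.125 + 10 * 0.0625))
})

test_that("trivial baseline facts: triangle clustering and star connectivity", {
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("a", "b", "c")
  expect_equal(unname(baseline_centrality(tri, "clustering_coefficient")),
               rep(1, 3))
  expect_equal(unname(baseline_centrality(tri, "degree")), rep(2, 3))
  star <- igraph::make_star(5, mode = "undirected")
  igraph::V(star)$name <- paste0("s", 1:5)
  nc <- baseline_centrality(star, "neighborhood_connectivity")
  expect_equal(unname(nc[1]), 1)       # centre's neighbours are all leaves
  expect_equal(unname(nc[2:5]), rep(4, 4))
  expect_error(baseline_centrality(star, "pagerank"), "available methods")
})

test_that("all centralities and the novel score match brute-force oracles", {
  withr::with_seed(2024, {
    for (rep in 1:20) {
      n <- sample(8:40, 1)
      rg <- random_attr_graph(n, p = stats::runif(1, 0.05, 0.3))
      for (m in c("degree", "closeness", "radiality", "clustering_coefficient",
                  "neighborhood_connectivity", "avg_shortest_path")) {
        expect_equal(unname(baseline_centrality(rg$graph, m)),
                     bf_centrality(rg$adj, m), info = m)
      }
      expect_equal(unname(novel_importance(rg$graph)),
                   bf_novel(rg$adj, rg$w))
      a2 <- stats::runif(1, 0.1, 0.9)
      d2 <- sample(1:4, 1)
      expect_equal(unname(novel_importance(rg$graph, alpha = a2, max_depth = d2)),
                   bf_novel(rg$adj, rg$w, alpha = a2, max_depth = d2))
    }
  })
})

test_that("adding an edge never decreases the endpoint's novel score", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      rg <- random_attr_graph(15, p = 0.15)
      g <- rg$graph
      non_edges <- which(rg$adj == 0 & upper.tri(rg$adj), arr.ind = TRUE)
      if (!nrow(non_edges)) next
      pick <- non_edges[sample(nrow(non_edges), 1), ]
      g2 <- igraph::add_edges(g, igraph::V(g)$name[pick])
      s1 <- novel_importance(g)
      s2 <- novel_importance(g2)
      expect_gte(s2[pick[1]], s1[pick[1]])
      expect_gte(s2[pick[2]], s1[pick[2]])
    }
  })
})

test_that("median thresholding is strict and keeps isolated survivors", {
  g <- igraph::make_ring(5)
  igraph::V(g)$name <- letters[1:5]
  igraph::V(g)$layer <- "target"
  s <- setNames(c(1, 2, 3, 4, 5), letters[1:5])
  res <- extract_key_network(g, s)
  expect_equal(res$median, 3)
  expect_setequal(res$key_nodes, c("d", "e"))     # strictly above the median
  expect_s3_class(res, "importance_result")
  expect_lte(length(res$key_nodes), ceiling(igraph::vcount(g) / 2))

  # all-equal scores: empty key network plus a warning
  expect_warning(res0 <- extract_key_network(g, setNames(rep(2, 5), letters[1:5])),
                 "identical")
  expect_length(res0$key_nodes, 0)
  expect_error(extract_key_network(g, s[1:3]), "cover")
})

test_that("key sets equal a sort-based oracle on random score maps", {
  withr::with_seed(77, {
    for (rep in 1:40) {
      n <- sample(4:30, 1)
      g <- igraph::make_ring(n)
      igraph::V(g)$name <- sprintf("n%02d", 1:n)
      igraph::V(g)$layer <- "target"
      s <- setNames(sample(100, n, replace = TRUE), igraph::V(g)$name)
      res <- if (length(unique(s)) == 1) {
        suppressWarnings(extract_key_network(g, s))
      } else extract_key_network(g, s)
      med <- sort(s)[ceiling(n / 2)]  # independent of stats::median for odd n
      oracle <- names(s)[s > stats::median(s)]
      expect_setequal(res$key_nodes, oracle)
      if (length(unique(s)) > 1)
        expect_lte(length(res$key_nodes), ceiling(n / 2))
    }
  })
})

test_that("avg-shortest-path ranking is inverted before thresholding", {
  # path graph: centre has the smallest mean distance, so it must be key
  g <- igraph::make_graph(~ A - B, B - C, C - D, D - E)
  igraph::V(g)$layer <- "target"
  igraph::V(g)$weight <- 1
  res <- suppressMessages(key_functional_network(g, "avg_shortest_path"))
  expect_true("C" %in% res$key_nodes)
  expect_false("A" %in% res$key_nodes)
})
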