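test_that("the generator is fully determined by its seed", {
  d1 <- generate_ctp_data(small_spec(42))
  d2 <- generate_ctp_data(small_spec(42))
  expect_identical(d1, d2)
  dir1 <- file.path(tempfile(), "a"); dir2 <- file.path(tempfile(), "b")
  write_synthetic_dataset(d1, dir1)
  write_synthetic_dataset(d2, dir2)
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), info = f)
  }
  d3 <- generate_ctp_data(small_spec(43))
  expect_false(identical(d1$ct_edges, d3$ct_edges))
})

test_that("infeasible degree demands and bad parameters are rejected", {
  expect_error(synthetic_spec(n_components = 10, n_targets = 20,
                              mean_component_degree = 25),
               "infeasible")
  expect_error(synthetic_spec(planting_strength = 0.5), "planting_strength")
  d <- small_spec(1)
  d$n_planted <- 75L  # more planted than active components
  expect_error(generate_ctp_data(d), "exceeds")
})

test_that("a zero-planting spec has empty truth and recovery is undefined", {
  d <- generate_ctp_data(small_spec(5, n_planted = 0))
  expect_length(d$truth, 0)
  rk <- data.frame(rank = 1, component_id = "C001", marginal = 1, cumulative = 1)
  class(rk) <- c("cdr_ranking", "data.frame")
  expect_error(recovery_metrics(rk, d$truth), "undefined")
})

test_that("publication counts follow the stated long-tailed law", {
  frac1 <- sapply(1:6, function(s) {
    d <- generate_ctp_data(synthetic_spec(seed = s, n_components = 40,
                                          n_targets = 150,
                                          mean_component_degree = 12,
                                          n_pathogenic = 1500, n_planted = 0,
                                          module_size = 50,
                                          n_decoy_cliques = 20,
                                          n_null_genes = 500))
    mean(d$pathogenic$n_publications == 1)
  })
  expect_true(all(frac1 > 0.5))            # most genes: one publication
  d <- generate_ctp_data(synthetic_spec(seed = 9, n_components = 40,
                                        n_targets = 150,
                                        mean_component_degree = 12,
                                        n_pathogenic = 2973, n_planted = 0,
                                        module_size = 50, n_decoy_cliques = 20,
                                        n_null_genes = 500))
  expect_gt(sum(d$pathogenic$n_publications > 40), 5)  # a rare heavy tail
})

test_that("paper-scale CT degree means land within 10% of the specification", {
  stats <- sapply(1:4, function(s) {
    d <- generate_ctp_data(synthetic_spec(seed = s))
    v <- suppressMessages(select_active_components(d$components))
    active <- d$components[d$components$component_id %in%
                             v$component_id[v$active], ]
    st <- layer_degree_stats(build_ct_network(active, d$ct_edges))
    st$layers$mean_degree[1:2]
  })
  expect_lt(abs(mean(stats[1, ]) - 40.5) / 40.5, 0.10)
  expect_lt(abs(mean(stats[2, ]) - 9.42) / 9.42, 0.10)
})

test_that("planted components sit within two PPI hops of top-decile genes", {
  d <- generate_ctp_data(small_spec(8))
  g <- igraph::graph_from_data_frame(d$ppi_edges, directed = FALSE)
  hot_near <- unique(c(d$hot_genes,
                       names(unlist(igraph::ego(g, 2,
                         intersect(d$hot_genes, igraph::V(g)$name))))))
  for (cid in d$truth) {
    tg <- d$ct_edges$target_symbol[d$ct_edges$component_id == cid]
    expect_true(any(tg %in% hot_near), info = cid)
  }
})

test_that("recovery metrics equal hand-computed overlaps", {
  rk <- data.frame(rank = 1:5, component_id = paste0("c", 1:5),
                   marginal = rep(0.2, 5), cumulative = seq(0.2, 1, 0.2))
  class(rk) <- c("cdr_ranking", "data.frame")
  truth <- c("c2", "c4", "c9")
  expect_equal(recovery_metrics(rk, truth, k = 3),
               c(precision = 1 / 3, recall = 1 / 3))
  expect_equal(unname(recovery_metrics(rk, paste0("c", 1:3), k = 3)["recall"]), 1)
  expect_equal(unname(recovery_metrics(rk, c("c5"), k = 2)["precision"]), 0)
  expect_error(recovery_metrics(rk, truth, k = 9), "k must")
})

test_that("weight-aware scoring ranks the planted module above its degree rank", {
  # study-scale networks: the planted module is a weight signal, not a degree
  # signal, so the damped-influence score should place it higher than degree
  # centrality does in at least 80% of replicates
  wins <- sapply(1:5, function(s) {
    d <- generate_ctp_data(synthetic_spec(seed = s))
    v <- suppressMessages(select_active_components(d$components))
    active <- d$components[d$components$component_id %in%
                             v$component_id[v$active], ]
    net <- suppressMessages(merge_ctp(build_ct_network(active, d$ct_edges),
                                      d$ppi_edges, d$pathogenic))
    sn <- novel_importance(net)
    sd_ <- baseline_centrality(net, "degree")
    mod <- intersect(d$module, names(sn))
    mean(rank(-sn)[mod]) < mean(rank(-sd_)[mod])
  })
  expect_gte(mean(wins), 0.8)
})

test_that("weight-aware key networks recover planted truth at least as well as degree", {
  recalls <- sapply(1:6, function(s) {
    d <- generate_ctp_data(synthetic_spec(seed = s))
    v <- suppressMessages(select_active_components(d$components))
    active <- d$components[d$components$component_id %in%
                             v$component_id[v$active], ]
    net <- suppressMessages(merge_ctp(build_ct_network(active, d$ct_edges),
                                      d$ppi_edges, d$pathogenic))
    sapply(c("novel", "degree"), function(m) {
      res <- suppressMessages(suppressWarnings(key_functional_network(net, m)))
      rk <- rank_cdr(res$key_network)
      unname(recovery_metrics(rk, d$truth)["recall"])
    })
  })
  expect_gte(mean(recalls["novel", ]), mean(recalls["degree", ]))
})
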