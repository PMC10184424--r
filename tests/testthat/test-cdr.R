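key_net_from_sets <- function(sets, extra_targets = character(0)) {
  comps <- names(sets)
  targets <- unique(c(unlist(sets), extra_targets))
  edges <- do.call(rbind, lapply(comps, function(cid) {
    if (!length(sets[[cid]])) return(NULL)
    data.frame(from = cid, to = sets[[cid]], type = "ct",
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(from = character(0), to = character(0),
                        type = character(0))
  nodes <- data.frame(name = c(comps, targets),
                      layer = c(rep("component", length(comps)),
                                rep("target", length(targets))),
                      weight = 1, n_publications = 0, stringsAsFactors = FALSE)
  kfcnet:::.make_ctp(nodes, edges)
}

test_that("coverage has the right endpoints and rejects unknown ids", {
  net <- key_net_from_sets(list(a = c("t1", "t2"), b = "t2", c = "t3"))
  expect_equal(component_coverage(character(0), net), 0)
  expect_equal(component_coverage(c("a", "b", "c"), net), 1)
  expect_equal(component_coverage("a", net), 2 / 3)
  expect_error(component_coverage(c("a", "zz"), net), "unknown component.*zz")
  no_comps <- key_net_from_sets(list(), extra_targets = c("t1", "t2"))
  expect_error(rank_cdr(no_comps), "no component nodes")
})

test_that("greedy CDR reproduces the exhaustively traced toy example", {
  net <- key_net_from_sets(list(a = c("t1", "t2"), b = "t2", c = "t3"))
  rk <- rank_cdr(net)
  expect_equal(rk$component_id, c("a", "c", "b"))
  expect_equal(rk$marginal, c(2 / 3, 1 / 3, 0))
  expect_equal(rk$cumulative, c(2 / 3, 1, 1))
  # single component covers its whole universe
  solo <- key_net_from_sets(list(only = c("t1", "t2")))
  expect_equal(rank_cdr(solo)$marginal, 1)
})

test_that("ties break by key-network degree then id, deterministically", {
  # x and y both add 1 fresh target; y has higher degree via overlap edges
  net <- key_net_from_sets(list(x = "t1", y = c("t2", "t3"), z = c("t1", "t2")))
  rk <- rank_cdr(net)
  expect_equal(rk$component_id[1], "y")     # largest gain first
  # equal gain, equal degree -> lexicographic
  net2 <- key_net_from_sets(list(b = "t1", a = "t2"))
  expect_equal(rank_cdr(net2)$component_id, c("a", "b"))
})

test_that("coverage equals a set-union oracle and is monotone", {
  withr::with_seed(404, {
    for (rep in 1:15) {
      sets <- lapply(setNames(seq_len(6), paste0("c", 1:6)), function(i)
        sample(paste0("t", 1:12), sample(0:6, 1)))
      sets <- sets[lengths(sets) > 0]
      if (length(sets) < 2) next
      net <- key_net_from_sets(sets)
      u <- unique(unlist(sets))
      ids <- sample(names(sets), sample(length(sets), 1))
      expect_equal(component_coverage(ids, net),
                   length(unique(unlist(sets[ids]))) / length(u))
      # monotone: S subset T
      sub <- ids[seq_len(max(1, length(ids) - 1))]
      expect_lte(component_coverage(sub, net), component_coverage(ids, net))
    }
  })
})

test_that("greedy marginals never increase and sum to the final coverage", {
  withr::with_seed(505, {
    for (rep in 1:10) {
      sets <- lapply(setNames(seq_len(8), paste0("c", 1:8)), function(i)
        sample(paste0("t", 1:15), sample(1:8, 1)))
      rk <- rank_cdr(key_net_from_sets(sets))
      expect_true(all(diff(rk$marginal) <= 1e-12))
      expect_true(all(diff(rk$cumulative) >= -1e-12))
      expect_equal(sum(rk$marginal), rk$cumulative[nrow(rk)])
      expect_lte(rk$cumulative[nrow(rk)], 1 + 1e-12)
    }
  })
})

test_that("greedy prefixes reach (1 - 1/e) of the exhaustive optimum", {
  withr::with_seed(606, {
    bound <- 1 - exp(-1)
    for (rep in 1:12) {
      n_comp <- sample(5:9, 1)
      sets <- lapply(setNames(seq_len(n_comp), paste0("c", 1:n_comp)),
                     function(i) sample(paste0("t", 1:14), sample(1:7, 1)))
      net <- key_net_from_sets(sets)
      rk <- rank_cdr(net)
      u <- length(unique(unlist(sets)))
      for (k in seq_len(n_comp)) {
        best <- max(utils::combn(names(sets), k, function(ids)
          length(unique(unlist(sets[ids]))), simplify = TRUE))
        expect_gte(rk$cumulative[k] + 1e-12, bound * best / u)
      }
    }
  })
})

test_that("greedy equals the optimum exactly when target sets are disjoint", {
  withr::with_seed(707, {
    pool <- paste0("t", 1:24)
    sizes <- c(6, 5, 4, 3, 2)
    sets <- list()
    off <- 0
    for (i in seq_along(sizes)) {
      sets[[paste0("c", i)]] <- pool[(off + 1):(off + sizes[i])]
      off <- off + sizes[i]
    }
    rk <- rank_cdr(key_net_from_sets(sets))
    expect_equal(rk$component_id, paste0("c", 1:5))  # by size = by optimum
    expect_equal(rk$cumulative, cumsum(sizes) / sum(sizes))
  })
})

test_that("KFC selection takes the shortest threshold-reaching prefix", {
  # cumulative 0.5, 0.8, 0.92, 0.95
  sets <- list(a = paste0("t", 1:50), b = paste0("t", 51:80),
               c = paste0("t", 81:92), d = paste0("t", 93:95))
  extra <- character(0)
  net <- key_net_from_sets(c(sets, list(e = paste0("t", 96:100))))
  rk <- rank_cdr(net)
  expect_equal(select_kfc(rk, 0.90), c("a", "b", "c"))
  expect_equal(select_kfc(rk, 0.5), "a")
  expect_error(select_kfc(rk, 0), "threshold")

  # unreachable threshold: t99/t100 touch no ranked component once e is gone
  net2 <- key_net_from_sets(list(a = paste0("t", 1:8)),
                            extra_targets = "t9")
  # t9 is isolated, so it is not in the coverage universe; full coverage = 1
  rk2 <- rank_cdr(net2)
  expect_equal(rk2$cumulative, 1)
})

test_that("an unreachable threshold warns and returns the positive prefix", {
  # a ranking whose components cannot reach the threshold (e.g. computed on a
  # restricted component subset)
  rk <- data.frame(rank = 1:3, component_id = c("a", "b", "c"),
                   marginal = c(0.5, 0.2, 0), cumulative = c(0.5, 0.7, 0.7))
  class(rk) <- c("cdr_ranking", "data.frame")
  attr(rk, "universe_size") <- 10L
  expect_warning(kfc <- select_kfc(rk, 0.9), "unreachable")
  expect_equal(kfc, c("a", "b"))
  expect_silent(select_kfc(rk, 0.7))
})

test_that("the edge universe counts component-incident edges", {
  net <- key_net_from_sets(list(a = c("t1", "t2"), b = "t1"))
  rk <- rank_cdr(net, universe = "edges")
  expect_equal(attr(rk, "universe_size"), 3L)
  expect_equal(rk$component_id[1], "a")
  expect_equal(rk$cumulative[2], 1)
})

test_that("static ordering ranks by individual coverage without re-evaluation", {
  sets <- list(a = c("t1", "t2", "t3"), b = c("t1", "t2"), c = c("t4", "t5"))
  rk <- rank_cdr(key_net_from_sets(sets), order = "static")
  expect_equal(rk$component_id, c("a", "b", "c"))
  expect_equal(rk$marginal, c(3, 0, 2) / 5)
})
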