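# Coverage sets of a key functional network: one set of coverable items per
# component. With the node universe (default) a component covers its
# non-component neighbours; with the edge universe it covers its incident
# edges. The universe is everything coverable by at least one component.
.cdr_sets <- function(key_net, universe = c("nodes", "edges")) {
  universe <- match.arg(universe)
  lay <- V(key_net)$layer
  nm <- V(key_net)$name
  comp <- nm[lay == "component"]
  if (!length(comp))
    stop("key network contains no component nodes")
  if (universe == "nodes") {
    adj <- igraph::adjacent_vertices(key_net, comp)
    sets <- lapply(adj, function(v) setdiff(unique(nm[as.integer(v)]), comp))
  } else {
    inc <- igraph::incident_edges(key_net, comp)
    sets <- lapply(inc, function(e) {
      if (!length(e)) return(character(0))
      ends <- igraph::ends(key_net, e, names = TRUE)
      lo <- pmin(ends[, 1], ends[, 2]); hi <- pmax(ends[, 1], ends[, 2])
      unique(paste(lo, hi, sep = "--"))
    })
  }
  names(sets) <- comp
  u <- unique(unlist(sets, use.names = FALSE))
  if (!length(u))
    stop("no coverable ", universe, ": every component is isolated in the key network")
  list(components = comp, sets = sets, universe = u)
}

#' Coverage of the key functional network by a component set
#'
#' Fraction of the coverage universe -- the non-component key-network nodes
#' adjacent to at least one component (or, with `universe = "edges"`, the
#' component-incident edges) -- that is reached by the components in `ids`.
#' `component_coverage(character(0), net)` is 0 and the full component set
#' covers 1 by construction.
#'
#' @param ids character vector of component ids (may be empty).
#' @param key_net key functional network containing at least one component.
#' @param universe `"nodes"` (default) or `"edges"`.
#' @return a fraction in `[0, 1]`.
#' @export
component_coverage <- function(ids, key_net, universe = c("nodes", "edges")) {
  cs <- .cdr_sets(key_net, universe)
  ids <- unique(as.character(ids))
  unknown <- setdiff(ids, cs$components)
  if (length(unknown))
    stop("unknown component id(s): ", paste(unknown, collapse = ", "))
  if (!length(ids)) return(0)
  covered <- unique(unlist(cs$sets[ids], use.names = FALSE))
  length(covered) / length(cs$universe)
}

#' Rank components by contribution decision rate (CDR)
#'
#' Greedy maximum-coverage ranking: at every step the component adding the
#' largest number of still-uncovered universe items is appended; its CDR is
#' that marginal gain as a fraction of the universe. Ties break
#' deterministically by higher key-network degree, then lexicographic id.
#' Components that can add nothing are appended with marginal 0 in the same
#' tie-break order, so the ranking always lists every component. The greedy
#' order makes marginal gains non-increasing and guarantees the classical
#' `1 - 1/e` approximation of the optimal coverage at every prefix size.
#'
#' `order = "static"` instead ranks components once by their individual
#' coverage (no re-evaluation) and reports marginals along that fixed order.
#'
#' @param key_net key functional network.
#' @param order `"greedy"` (default) or `"static"`.
#' @param universe `"nodes"` (default) or `"edges"`, see
#'   [component_coverage()].
#' @return a `data.frame` of class `cdr_ranking` with columns `rank`,
#'   `component_id`, `marginal` and `cumulative` (fractions of the universe);
#'   attributes `universe_size` and `universe`.
#' @export
rank_cdr <- function(key_net, order = c("greedy", "static"),
                     universe = c("nodes", "edges")) {
  order <- match.arg(order)
  universe <- match.arg(universe)
  cs <- .cdr_sets(key_net, universe)
  comp <- cs$components
  sets <- cs$sets
  nu <- length(cs$universe)
  deg <- igraph::degree(key_net)[comp]

  tie_rank <- base::order(-deg, comp)  # degree desc, then id asc
  picked <- character(0)
  marginal <- numeric(0)

  if (order == "static") {
    sizes <- lengths(sets)
    seq_ids <- comp[base::order(-sizes, -deg, comp)]
    covered <- character(0)
    for (id in seq_ids) {
      gain <- length(setdiff(sets[[id]], covered))
      covered <- union(covered, sets[[id]])
      picked <- c(picked, id)
      marginal <- c(marginal, gain / nu)
    }
  } else {
    remaining <- comp[tie_rank]  # pre-sorted by the tie-break order
    covered <- character(0)
    gains <- lengths(sets)[remaining]
    while (length(remaining)) {
      if (max(gains) == 0L) {  # nothing left to gain: append in tie-break order
        picked <- c(picked, remaining)
        marginal <- c(marginal, numeric(length(remaining)))
        break
      }
      best <- which.max(gains)  # first max = best gain, ties already ordered
      id <- remaining[best]
      picked <- c(picked, id)
      marginal <- c(marginal, gains[best] / nu)
      covered <- c(covered, setdiff(sets[[id]], covered))
      remaining <- remaining[-best]
      gains <- vapply(remaining, function(r) length(setdiff(sets[[r]], covered)), 0L)
    }
  }

  out <- data.frame(rank = seq_along(picked), component_id = picked,
                    marginal = marginal, cumulative = cumsum(marginal),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "universe_size") <- nu
  attr(out, "universe") <- universe
  class(out) <- c("cdr_ranking", "data.frame")
  out
}

#' Select key functional components (KFC)
#'
#' The KFC are the shortest ranking prefix whose cumulative coverage reaches
#' the threshold. If the threshold is unreachable (some universe items touch
#' no ranked component), the full positive-contribution prefix is returned
#' with a warning.
#'
#' @param ranking a `cdr_ranking` from [rank_cdr()].
#' @param threshold coverage fraction in (0, 1], default 0.90.
#' @return ordered character vector of component ids.
#' @export
select_kfc <- function(ranking, threshold = 0.90) {
  stopifnot(inherits(ranking, "cdr_ranking"),
            is.numeric(threshold), length(threshold) == 1,
            threshold > 0, threshold <= 1)
  cum <- ranking$cumulative
  hit <- which(cum >= threshold - 1e-12)
  if (!length(hit)) {
    warning("coverage threshold ", threshold, " unreachable (maximum ",
            format(max(cum), digits = 4),
            "); returning all positive-contribution components")
    return(ranking$component_id[ranking$marginal > 0])
  }
  ranking$component_id[seq_len(hit[1])]
}

#' @export
print.cdr_ranking <- function(x, n = 10, ...) {
  cat("CDR ranking over ", attr(x, "universe_size"), " coverable ",
      attr(x, "universe"), " (", nrow(x), " components)\n", sep = "")
  print.data.frame(utils::head(x, n))
  if (nrow(x) > n) cat("... ", nrow(x) - n, " more rows\n", sep = "")
  invisible(x)
}
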