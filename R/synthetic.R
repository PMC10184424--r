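#' Specification of a synthetic CTP study
#'
#' Describes a synthetic multi-herb formula dataset with known ground truth:
#' a component table with ADMET descriptors calibrated so that roughly
#' `active_fraction` of components pass the all-rules filter, a heavy-tailed
#' bipartite component-target layer, a preferential-attachment PPI layer in
#' which the top weight decile of pathogenic genes is concentrated into a
#' module by degree-preserving rewiring, publication counts with a long right
#' tail (most genes a single supporting publication, a few above 40), a
#' planted set of key components preferentially wired towards targets
#' adjacent to high-weight pathogenic genes, and a GMT of signal terms (drawn
#' from the hot neighbourhood) plus random decoys.
#'
#' @param n_herbs number of herbs in the formula.
#' @param n_components number of chemical components.
#' @param n_targets number of predictable protein targets; defaults to
#'   `active_fraction * n_components * mean_component_degree /
#'   mean_target_degree` so both layer degree means come out as requested.
#' @param n_pathogenic number of disease genes.
#' @param mean_component_degree mean number of targets per active component.
#' @param mean_target_degree intended mean target degree (used only to derive
#'   the default `n_targets`).
#' @param component_degree_sdlog log-normal spread of component degrees.
#' @param target_popularity_sdlog log-normal spread of target popularity
#'   (heavier = more skewed target degrees).
#' @param active_fraction fraction of components drawn drug-like.
#' @param n_validated components flagged as experimentally validated
#'   (active regardless of their ADMET draw).
#' @param ob_missing_fraction fraction of drug-like components with missing
#'   oral bioavailability.
#' @param pathogenic_target_overlap fraction of pathogenic genes that are
#'   also predicted targets.
#' @param ppi_edges_per_node preferential-attachment edges per node.
#' @param ppi_isolated_fraction fraction of proteins left out of the PPI.
#' @param module_size number of top-weight pathogenic genes forming the
#'   disease-core module.
#' @param module_rewire_fraction fraction of module-gene PPI edge endpoints
#'   redirected inside the module (degree-preserving, so degree-based
#'   centralities cannot see the module).
#' @param pub_geom_p geometric parameter of the bulk publication-count law;
#'   counts are `1 + Geom(p)`, so `P(count = 1) = p`.
#' @param pub_heavy_fraction,pub_heavy_geom_p mixture weight and geometric
#'   parameter of the heavy tail producing the rare high-publication genes.
#' @param n_planted number of planted key components.
#' @param planting_strength sampling-weight multiplier pulling planted
#'   components' CT edges towards hot targets.
#' @param planted_degree_multiplier factor on the planted components' target
#'   degree (key components are broad-acting as well as disease-focused).
#' @param n_decoy_cliques,decoy_clique_size small protein complexes added at
#'   random in the PPI, so triangle-rich neighbourhoods are not unique to the
#'   disease module.
#' @param n_signal_terms,n_decoy_terms,term_size GMT composition.
#' @param signal_pathogenic_fraction,signal_target_fraction fraction of a
#'   signal term drawn from hot pathogenic genes and hot targets.
#' @param n_null_genes annotation-only genes padding the enrichment
#'   background (genes that never enter the network).
#' @param seed integer seed; the generator is fully determined by it.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_herbs = 7L,
                           n_components = 523L,
                           n_targets = NULL,
                           n_pathogenic = 2973L,
                           mean_component_degree = 40.5,
                           mean_target_degree = 9.42,
                           component_degree_sdlog = 0.5,
                           target_popularity_sdlog = 1,
                           active_fraction = 0.55,
                           n_validated = 9L,
                           ob_missing_fraction = 0.1,
                           pathogenic_target_overlap = 0.25,
                           ppi_edges_per_node = 2L,
                           ppi_isolated_fraction = 0.03,
                           module_size = 150L,
                           module_rewire_fraction = 0.55,
                           pub_geom_p = 0.55,
                           pub_heavy_fraction = 0.03,
                           pub_heavy_geom_p = 0.03,
                           n_planted = 15L,
                           planting_strength = 3,
                           planted_degree_multiplier = 4.5,
                           n_decoy_cliques = 300L,
                           decoy_clique_size = 5L,
                           n_signal_terms = 30L,
                           n_decoy_terms = 40L,
                           term_size = 100L,
                           signal_pathogenic_fraction = 0.45,
                           signal_target_fraction = 0.18,
                           n_null_genes = 14000L,
                           seed = 1L) {
  if (is.null(n_targets))
    n_targets <- as.integer(round(active_fraction * n_components *
                                    mean_component_degree / mean_target_degree))
  spec <- list(n_herbs = as.integer(n_herbs),
               n_components = as.integer(n_components),
               n_targets = as.integer(n_targets),
               n_pathogenic = as.integer(n_pathogenic),
               mean_component_degree = mean_component_degree,
               mean_target_degree = mean_target_degree,
               component_degree_sdlog = component_degree_sdlog,
               target_popularity_sdlog = target_popularity_sdlog,
               active_fraction = active_fraction,
               n_validated = as.integer(n_validated),
               ob_missing_fraction = ob_missing_fraction,
               pathogenic_target_overlap = pathogenic_target_overlap,
               ppi_edges_per_node = as.integer(ppi_edges_per_node),
               ppi_isolated_fraction = ppi_isolated_fraction,
               module_size = as.integer(module_size),
               module_rewire_fraction = module_rewire_fraction,
               pub_geom_p = pub_geom_p,
               pub_heavy_fraction = pub_heavy_fraction,
               pub_heavy_geom_p = pub_heavy_geom_p,
               n_planted = as.integer(n_planted),
               planting_strength = planting_strength,
               planted_degree_multiplier = planted_degree_multiplier,
               n_decoy_cliques = as.integer(n_decoy_cliques),
               decoy_clique_size = as.integer(decoy_clique_size),
               n_signal_terms = as.integer(n_signal_terms),
               n_decoy_terms = as.integer(n_decoy_terms),
               term_size = as.integer(term_size),
               signal_pathogenic_fraction = signal_pathogenic_fraction,
               signal_target_fraction = signal_target_fraction,
               n_null_genes = as.integer(n_null_genes),
               seed = as.integer(seed))
  with(spec, {
    stopifnot(n_herbs >= 1, n_components >= 1, n_targets >= 1,
              n_pathogenic >= 1, n_planted >= 0, n_validated >= 0,
              mean_component_degree > 0,
              active_fraction > 0, active_fraction <= 1,
              pathogenic_target_overlap >= 0, pathogenic_target_overlap <= 1,
              module_rewire_fraction >= 0, module_rewire_fraction <= 1,
              pub_geom_p > 0, pub_geom_p <= 1,
              pub_heavy_fraction >= 0, pub_heavy_fraction <= 1,
              pub_heavy_geom_p > 0, pub_heavy_geom_p <= 1,
              planting_strength >= 1, planted_degree_multiplier >= 1,
              n_decoy_cliques >= 0, decoy_clique_size >= 3, term_size >= 3)
  })
  if (spec$mean_component_degree >= spec$n_targets)
    stop("infeasible degrees: mean_component_degree (",
         spec$mean_component_degree, ") must be below n_targets (",
         spec$n_targets, ")")
  class(spec) <- "synthetic_spec"
  spec
}

#' Generate a synthetic CTP dataset
#'
#' Draws a complete dataset from a [synthetic_spec()]: the same seed always
#' yields an identical dataset. See the spec documentation for the generative
#' model.
#'
#' @param spec a `synthetic_spec`.
#' @return a list with `components` (component table), `ct_edges`,
#'   `ppi_edges`, `pathogenic` (symbol, n_publications), `gene_sets` (GMT
#'   list), `background`, `truth` (planted component ids), `hot_genes`,
#'   `hot_targets` and the `spec` itself.
#' @export
generate_ctp_data <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, .generate_impl(spec))
}

.generate_impl <- function(spec) {
  n <- spec$n_components

  ## --- component table with synthetic ADMET -------------------------------
  herbs_all <- sprintf("HERB%02d", seq_len(spec$n_herbs))
  comp_id <- sprintf("C%03d", seq_len(n))
  n_herb_each <- sample(1:2, n, replace = TRUE, prob = c(0.7, 0.3))
  herbs <- lapply(n_herb_each, function(k) sort(sample(herbs_all, k)))

  druglike <- stats::runif(n) < spec$active_fraction
  validated <- rep(FALSE, n)
  if (spec$n_validated > 0)
    validated[sample.int(n, min(spec$n_validated, n))] <- TRUE

  mw   <- stats::runif(n, 150, 500)
  logp <- stats::runif(n, -2, 5)
  hbd  <- sample(0:5, n, replace = TRUE)
  hba  <- sample(0:9, n, replace = TRUE)
  rotb <- sample(0:9, n, replace = TRUE)
  ob   <- stats::runif(n, 30, 100)
  gi   <- rep("high", n)
  # non-drug-like components violate exactly one randomly chosen rule
  viol <- sample(7L, n, replace = TRUE)
  for (i in which(!druglike)) {
    switch(viol[i],
           mw[i]   <- stats::runif(1, 500.5, 900),
           logp[i] <- stats::runif(1, 5.1, 9),
           hbd[i]  <- sample(6:9, 1),
           hba[i]  <- sample(10:14, 1),
           rotb[i] <- sample(10:15, 1),
           ob[i]   <- stats::runif(1, 0, 29.5),
           gi[i]   <- "low")
  }
  ob_miss <- druglike & stats::runif(n) < spec$ob_missing_fraction
  ob[ob_miss] <- NA
  active <- druglike | validated
  components <- data.frame(component_id = comp_id,
                           name = paste0("compound_", sprintf("%03d", seq_len(n))),
                           mw = mw, logp = logp, hbd = hbd, hba = hba,
                           rotatable_bonds = rotb, ob_percent = ob,
                           gi_class = gi, validated = validated,
                           stringsAsFactors = FALSE)
  components$herbs <- herbs

  ## --- pathogenic genes with long-tailed publication counts ---------------
  targets <- sprintf("G%04d", seq_len(spec$n_targets))
  n_ov <- round(spec$pathogenic_target_overlap * spec$n_pathogenic)
  n_ov <- min(n_ov, spec$n_targets)
  psym <- c(sample(targets, n_ov),
            sprintf("P%04d", seq_len(spec$n_pathogenic - n_ov)))
  heavy <- stats::runif(spec$n_pathogenic) < spec$pub_heavy_fraction
  bulk_counts <- 1L + stats::rgeom(spec$n_pathogenic, spec$pub_geom_p)
  heavy_counts <- 1L + stats::rgeom(spec$n_pathogenic, spec$pub_heavy_geom_p)
  npub <- ifelse(heavy, heavy_counts, bulk_counts)
  pathogenic <- data.frame(symbol = psym, n_publications = as.integer(npub),
                           stringsAsFactors = FALSE)
  pweight <- 1 + log(1 + npub)
  by_weight <- psym[base::order(-pweight, psym)]
  # hot pool: top weight decile; disease-core module: its highest-weight head
  hot_genes <- by_weight[seq_len(ceiling(spec$n_pathogenic / 10))]
  module <- by_weight[seq_len(min(spec$module_size, length(hot_genes)))]

  ## --- PPI: preferential attachment + hot-module rewiring -----------------
  proteins <- sort(unique(c(targets, psym)))
  n_iso <- round(spec$ppi_isolated_fraction * length(proteins))
  iso <- if (n_iso > 0) sample(setdiff(proteins, hot_genes), n_iso) else character(0)
  connected <- setdiff(proteins, iso)
  g_pa <- igraph::sample_pa(length(connected), power = 1,
                            m = spec$ppi_edges_per_node, directed = FALSE)
  igraph::V(g_pa)$name <- sample(connected)
  el <- igraph::as_edgelist(g_pa, names = TRUE)
  el <- .rewire_hot_module(el, module, spec$module_rewire_fraction)

  ## module halo: PPI neighbours of the disease core. Hot targets are the
  ## predicted targets inside the module or its halo, so planted components
  ## sit <= 2 PPI hops from top-weight-decile pathogenic genes.
  inc <- el[, 1] %in% module | el[, 2] %in% module
  halo <- setdiff(unique(c(el[inc, 1], el[inc, 2])), module)
  hot_targets <- intersect(targets, c(module, halo))
  halo_pathogenic <- intersect(psym, c(module, halo))

  ## decoy complexes avoid the hot pool and the module halo: triangle-rich
  ## neighbourhoods occur everywhere in the interactome, not just around the
  ## disease core
  el <- .add_decoy_cliques(el, setdiff(connected, c(hot_genes, module, halo)),
                           spec$n_decoy_cliques, spec$decoy_clique_size)
  ppi_edges <- data.frame(protein_a = el[, 1], protein_b = el[, 2],
                          stringsAsFactors = FALSE)

  ## --- CT layer with planted key components -------------------------------
  active_ids <- comp_id[active]
  if (spec$n_planted > length(active_ids))
    stop("n_planted (", spec$n_planted, ") exceeds the number of active components (",
         length(active_ids), ")")
  planted <- if (spec$n_planted > 0) sort(sample(active_ids, spec$n_planted))
             else character(0)

  ## base degree mean is deflated so the planted multiplier leaves the
  ## overall mean component degree at its requested value
  f_planted <- length(planted) / max(1L, length(active_ids))
  base_mean <- spec$mean_component_degree /
    (1 + f_planted * (spec$planted_degree_multiplier - 1))
  meanlog <- log(base_mean) - spec$component_degree_sdlog^2 / 2
  deg_draw <- stats::rlnorm(length(active_ids), meanlog, spec$component_degree_sdlog)
  deg_draw[active_ids %in% planted] <-
    deg_draw[active_ids %in% planted] * spec$planted_degree_multiplier
  comp_deg <- pmin(spec$n_targets, pmax(1L, as.integer(round(deg_draw))))
  popularity <- stats::rlnorm(spec$n_targets, 0, spec$target_popularity_sdlog)
  is_hot_target <- targets %in% hot_targets

  ct_list <- vector("list", length(active_ids))
  for (i in seq_along(active_ids)) {
    w <- popularity
    if (active_ids[i] %in% planted && any(is_hot_target))
      w <- w * ifelse(is_hot_target, spec$planting_strength, 1)
    tg <- sample(targets, comp_deg[i], prob = w)
    if (active_ids[i] %in% planted && any(is_hot_target) &&
        !any(tg %in% hot_targets))
      tg[1] <- sample(hot_targets, 1)  # planting guarantee, virtually never hit
    ct_list[[i]] <- data.frame(component_id = active_ids[i],
                               target_symbol = tg, stringsAsFactors = FALSE)
  }
  ct_edges <- do.call(rbind, ct_list)
  rownames(ct_edges) <- NULL

  ## --- GMT: signal terms around the hot neighbourhood, plus decoys --------
  ## Term sizes and hot-gene shares vary term to term, giving the signal
  ## terms a difficulty gradient (as real annotation terms have) rather than
  ## an all-or-nothing detection boundary.
  null_genes <- sprintf("N%05d", seq_len(spec$n_null_genes))
  pool <- c(proteins, null_genes)
  gene_sets <- list()
  sig_path_pool <- unique(halo_pathogenic)  # module + pathogenic halo
  sizes <- round(stats::runif(spec$n_signal_terms,
                              0.6 * spec$term_size, 1.4 * spec$term_size))
  p_share <- stats::runif(spec$n_signal_terms,
                          0.75 * spec$signal_pathogenic_fraction,
                          1.25 * spec$signal_pathogenic_fraction)
  t_share <- stats::runif(spec$n_signal_terms,
                          0.75 * spec$signal_target_fraction,
                          1.25 * spec$signal_target_fraction)
  for (j in seq_len(spec$n_signal_terms)) {
    n_hp <- round(p_share[j] * sizes[j])
    n_ht <- round(t_share[j] * sizes[j])
    genes <- unique(c(
      sample(sig_path_pool, min(n_hp, length(sig_path_pool))),
      if (length(hot_targets)) sample(hot_targets, min(n_ht, length(hot_targets))),
      sample(null_genes, max(0L, sizes[j] - n_hp - n_ht))))
    gene_sets[[sprintf("SIG%02d", j)]] <- sort(genes)
  }
  d_sizes <- round(stats::runif(spec$n_decoy_terms,
                                0.4 * spec$term_size, 1.6 * spec$term_size))
  for (j in seq_len(spec$n_decoy_terms)) {
    gene_sets[[sprintf("DECOY%02d", j)]] <- sort(sample(pool, d_sizes[j]))
  }
  attr(gene_sets, "description") <- stats::setNames(
    c(rep("planted signal term", spec$n_signal_terms),
      rep("random decoy term", spec$n_decoy_terms)),
    names(gene_sets))

  list(components = components, ct_edges = ct_edges, ppi_edges = ppi_edges,
       pathogenic = pathogenic, gene_sets = gene_sets,
       background = pool, truth = planted,
       hot_genes = hot_genes, module = module, hot_targets = hot_targets,
       spec = spec)
}

# Degree-preserving rewiring: repeatedly take two edges that each join a hot
# gene to a cold node and swap partners, creating one hot-hot and one
# cold-cold edge. Degrees are untouched, so degree centrality stays blind to
# the module while weight-aware scores see it.
.rewire_hot_module <- function(el, hot, fraction) {
  if (fraction <= 0 || length(hot) < 2) return(el)
  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  keys <- new.env(hash = TRUE)
  for (k in edge_key(el[, 1], el[, 2])) assign(k, TRUE, envir = keys)
  a_hot <- el[, 1] %in% hot
  b_hot <- el[, 2] %in% hot
  # orient mixed edges as (hot, cold)
  mixed <- xor(a_hot, b_hot)
  swap <- mixed & b_hot
  tmp <- el[swap, 1]; el[swap, 1] <- el[swap, 2]; el[swap, 2] <- tmp
  n_mixed <- sum(mixed)
  target_swaps <- floor(fraction * n_mixed / 2)
  attempts <- 0L
  done <- 0L
  max_attempts <- 60L * max(1L, target_swaps)
  while (done < target_swaps && attempts < max_attempts) {
    attempts <- attempts + 1L
    cand <- which(xor(el[, 1] %in% hot, el[, 2] %in% hot) & el[, 1] %in% hot)
    if (length(cand) < 2) break
    ij <- sample(cand, 2)
    h1 <- el[ij[1], 1]; x1 <- el[ij[1], 2]
    h2 <- el[ij[2], 1]; x2 <- el[ij[2], 2]
    if (h1 == h2 || x1 == x2) next
    k_hh <- edge_key(h1, h2); k_xx <- edge_key(x1, x2)
    if (exists(k_hh, envir = keys) || exists(k_xx, envir = keys)) next
    rm(list = c(edge_key(h1, x1), edge_key(h2, x2)), envir = keys)
    assign(k_hh, TRUE, envir = keys); assign(k_xx, TRUE, envir = keys)
    el[ij[1], ] <- c(h1, h2)
    el[ij[2], ] <- c(x1, x2)
    done <- done + 1L
  }
  el
}

# Random small complexes (cliques) among cold proteins. Adds edges that are
# not already present; keeps the PPI's triangle structure from being a
# signature of the disease module alone.
.add_decoy_cliques <- function(el, cold, n_cliques, size) {
  if (n_cliques <= 0 || length(cold) < size) return(el)
  keys <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  extra <- list()
  for (j in seq_len(n_cliques)) {
    members <- sample(cold, size)
    pairs <- utils::combn(sort(members), 2)
    extra[[j]] <- cbind(pairs[1, ], pairs[2, ])
  }
  extra <- do.call(rbind, extra)
  ek <- paste(pmin(extra[, 1], extra[, 2]), pmax(extra[, 1], extra[, 2]))
  keep <- !duplicated(ek) & !(ek %in% keys)
  rbind(el, extra[keep, , drop = FALSE])
}

#' Precision and recall of a CDR ranking against planted truth
#'
#' @param ranking a `cdr_ranking`.
#' @param truth character vector of planted component ids (non-empty).
#' @param k prefix size (default `length(truth)`).
#' @return named numeric vector `c(precision =, recall =)`.
#' @export
recovery_metrics <- function(ranking, truth, k = length(truth)) {
  if (!length(truth)) stop("truth set is empty; recovery is undefined")
  if (k < 1 || k > nrow(ranking))
    stop("k must lie in [1, ", nrow(ranking), "]")
  top <- ranking$component_id[seq_len(k)]
  hits <- length(intersect(top, truth))
  c(precision = hits / k, recall = hits / length(truth))
}

#' Write a synthetic dataset as pipeline input files
#'
#' Emits the same plain-text formats the analysis pipeline ingests:
#' `components.tsv`, `ct_edges.tsv`, `ppi_edges.tsv`, `pathogenic_genes.tsv`,
#' `gene_sets.gmt` and `truth.txt`.
#'
#' @param data result of [generate_ctp_data()].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_synthetic_dataset <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(components = file.path(dir, "components.tsv"),
             ct_edges = file.path(dir, "ct_edges.tsv"),
             ppi_edges = file.path(dir, "ppi_edges.tsv"),
             pathogenic = file.path(dir, "pathogenic_genes.tsv"),
             gene_sets = file.path(dir, "gene_sets.gmt"),
             truth = file.path(dir, "truth.txt"))
  write_component_table(data$components, paths["components"])
  utils::write.table(data$ct_edges, paths["ct_edges"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data$ppi_edges, paths["ppi_edges"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data$pathogenic, paths["pathogenic"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(data$gene_sets, paths["gene_sets"])
  writeLines(data$truth, paths["truth"])
  invisible(paths)
}
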