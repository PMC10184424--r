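.pipeline_defaults <- function() {
  list(
    inputs = list(components = NULL, ct_edges = NULL, ppi = NULL,
                  disease_genes = NULL, gene_sets = NULL),
    admet = list(ob_threshold = 30, combine = "all"),
    importance = list(method = "novel", alpha = 0.5, max_depth = 3),
    cdr = list(threshold = 0.9, order = "greedy", universe = "nodes"),
    enrichment = list(alpha = 0.05, adjusted = FALSE, compare_methods = FALSE),
    outdir = NULL,
    seed = 1L)
}

#' Read and validate a pipeline configuration
#'
#' Accepts a YAML file path or a nested list with the sections `inputs`
#' (`components`, `ct_edges`, `ppi`, `disease_genes`, optional `gene_sets`),
#' `admet`, `importance`, `cdr`, `enrichment`, plus `outdir` and `seed`.
#' Unknown keys anywhere are rejected; missing options are filled with
#' defaults; required input files must exist.
#'
#' @param config path to a YAML file, or a list.
#' @return the resolved configuration list.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- .pipeline_defaults()

  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (section in c("inputs", "admet", "importance", "cdr", "enrichment")) {
    extra <- setdiff(names(config[[section]]), names(defaults[[section]]))
    if (length(extra))
      stop("unknown key(s) in '", section, "': ", paste(extra, collapse = ", "))
    defaults[[section]][names(config[[section]])] <- config[[section]]
  }
  defaults$outdir <- config$outdir %||% defaults$outdir
  defaults$seed <- as.integer(config$seed %||% defaults$seed)

  if (is.null(defaults$outdir)) stop("configuration must set 'outdir'")
  required <- c("components", "ct_edges", "ppi", "disease_genes")
  for (inp in required) {
    p <- defaults$inputs[[inp]]
    if (is.null(p)) stop("configuration must set inputs$", inp)
    if (!file.exists(p)) stop("input file for '", inp, "' not found: ", p)
  }
  if (!is.null(defaults$inputs$gene_sets) &&
      !file.exists(defaults$inputs$gene_sets))
    stop("input file for 'gene_sets' not found: ", defaults$inputs$gene_sets)
  defaults
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full key-functional-component pipeline
#'
#' Executes the complete workflow: ADMET filtering, CT network construction
#' from the active components, merging with the PPI and weighted
#' pathogenic-gene layers, importance scoring, median-threshold key-network
#' extraction, CDR ranking with KFC selection and (when gene sets are
#' supplied) effective-term enrichment, optionally comparing all seven
#' importance methods. Every artifact is written under `outdir` together with
#' a machine-readable `report.json` and a `manifest.json` of input hashes and
#' parameters; rerunning an identical configuration reproduces every output
#' byte for byte.
#'
#' @param config YAML path or list, see [read_pipeline_config()].
#' @return the report list, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- read_pipeline_config(config)
  outdir <- cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(name) {
    written[length(written) + 1L] <<- file.path(outdir, name)
    file.path(outdir, name)
  }

  comps <- .stage("read components",
                  read_component_table(cfg$inputs$components))
  verdicts <- .stage("admet filter", select_active_components(
    comps, ob_threshold = cfg$admet$ob_threshold, combine = cfg$admet$combine))
  utils::write.table(verdicts, emit("admet_verdicts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  active_ids <- verdicts$component_id[verdicts$active]
  active <- comps[comps$component_id %in% active_ids, , drop = FALSE]

  ct_edges <- .stage("read CT edges", {
    e <- utils::read.delim(cfg$inputs$ct_edges, colClasses = "character")
    if (ncol(e) < 2) stop("CT edge list needs two columns")
    e
  })
  n_raw <- nrow(ct_edges)
  ct_edges <- ct_edges[ct_edges[[1]] %in% active_ids, , drop = FALSE]
  if (nrow(ct_edges) < n_raw)
    message("dropped ", n_raw - nrow(ct_edges),
            " CT edge(s) of filtered-out components")
  ct <- .stage("build CT network", build_ct_network(active, ct_edges))
  ct_stats <- layer_degree_stats(ct)

  ppi <- .stage("read PPI edges", utils::read.delim(cfg$inputs$ppi))
  disease <- .stage("read disease genes", {
    d <- utils::read.delim(cfg$inputs$disease_genes)
    if (!all(c("symbol", "n_publications") %in% names(d)))
      stop("disease gene table needs columns symbol, n_publications")
    d
  })
  net <- .stage("merge CTP network", merge_ctp(ct, ppi, disease))
  write_network(net, emit("ctp_network.graphml"), format = "graphml")

  res <- .stage("importance scoring", key_functional_network(
    net, method = cfg$importance$method, alpha = cfg$importance$alpha,
    max_depth = cfg$importance$max_depth))
  scores <- data.frame(node = names(res$scores),
                       layer = V(net)$layer[match(names(res$scores), V(net)$name)],
                       score = .fmt_num(unname(res$scores)),
                       key = names(res$scores) %in% res$key_nodes,
                       stringsAsFactors = FALSE)
  scores <- scores[base::order(scores$node), , drop = FALSE]
  utils::write.table(scores, emit("importance_scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_network(res$key_network, emit("key_network.graphml"), format = "graphml")

  ranking <- .stage("CDR ranking", rank_cdr(
    res$key_network, order = cfg$cdr$order, universe = cfg$cdr$universe))
  rk <- as.data.frame(ranking)
  rk$marginal <- .fmt_num(rk$marginal)
  rk$cumulative <- .fmt_num(rk$cumulative)
  utils::write.table(rk, emit("cdr_ranking.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  kfc <- .stage("KFC selection", select_kfc(ranking, cfg$cdr$threshold))
  writeLines(kfc, emit("kfc.txt"))

  report <- list(
    n_components = nrow(comps),
    n_active = length(active_ids),
    ct_network = list(n_nodes = ct_stats$n_nodes, n_edges = ct_stats$n_edges,
                      mean_component_degree = ct_stats$layers$mean_degree[1],
                      mean_target_degree = ct_stats$layers$mean_degree[2]),
    ctp_network = list(n_nodes = igraph::vcount(net),
                       n_edges = igraph::ecount(net)),
    importance = list(method = res$method, median = res$median,
                      n_key_nodes = length(res$key_nodes),
                      n_key_edges = igraph::ecount(res$key_network)),
    cdr = list(n_ranked = nrow(ranking),
               universe_size = attr(ranking, "universe_size"),
               n_kfc = length(kfc),
               kfc_coverage = ranking$cumulative[length(kfc)],
               threshold = cfg$cdr$threshold))

  if (!is.null(cfg$inputs$gene_sets)) {
    gmt <- .stage("read gene sets", read_gmt(cfg$inputs$gene_sets))
    bg <- unique(.norm_symbol(unlist(gmt, use.names = FALSE)))
    lay <- V(net)$layer
    target_genes <- V(net)$name[grepl("target", lay, fixed = TRUE)]
    path_genes <- V(net)$name[grepl("pathogenic", lay, fixed = TRUE)]
    eff <- .stage("effective terms", suppressMessages(effective_terms(
      target_genes, path_genes, gmt, bg,
      alpha = cfg$enrichment$alpha, adjusted = cfg$enrichment$adjusted)))
    writeLines(eff, emit("effective_terms.txt"))
    report$enrichment <- list(n_effective_terms = length(eff))
    if (isTRUE(cfg$enrichment$compare_methods) && length(eff)) {
      methods <- c("novel", "degree", "closeness", "radiality",
                   "clustering_coefficient", "neighborhood_connectivity",
                   "avg_shortest_path")
      results <- .stage("method comparison", {
        rs <- lapply(methods, function(m) suppressMessages(
          key_functional_network(net, method = m,
                                 alpha = cfg$importance$alpha,
                                 max_depth = cfg$importance$max_depth)))
        names(rs) <- methods
        rs
      })
      cov <- suppressMessages(method_coverage(
        results, eff, gmt, bg,
        alpha = cfg$enrichment$alpha, adjusted = cfg$enrichment$adjusted))
      cov_df <- data.frame(method = names(cov),
                           effective_term_coverage = .fmt_num(unname(cov)),
                           stringsAsFactors = FALSE)
      utils::write.table(cov_df, emit("method_coverage.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      report$enrichment$method_coverage <- as.list(cov)
    }
  }

  jsonlite::write_json(report, emit("report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  # resolved config carries machine-specific paths, so it is written for the
  # record but stays outside the manifest's reproducibility hashes
  yaml::write_yaml(cfg, file.path(outdir, "config_resolved.yaml"))

  inputs <- Filter(Negate(is.null), cfg$inputs)
  manifest <- list(
    inputs = lapply(inputs, function(p) unname(tools::md5sum(p))),
    parameters = cfg[c("admet", "importance", "cdr", "enrichment", "seed")],
    outputs = lapply(stats::setNames(written, basename(written)),
                     function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(report)
}
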