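#' Read gene sets from a GMT file
#'
#' One term per line: term id, description, then the member genes, all
#' tab-separated. Gene symbols are upper-cased at ingest.
#'
#' @param path GMT file path.
#' @return named list of character vectors; the term descriptions are kept in
#'   the `"description"` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate GMT term ids: ", paste(dup, collapse = ", "))
  desc <- vapply(parts, function(p) if (length(p) >= 2) p[2] else "", character(1))
  sets <- lapply(parts, function(p) {
    if (length(p) < 3) character(0) else unique(.norm_symbol(p[-(1:2)]))
  })
  names(sets) <- ids
  attr(sets, "description") <- stats::setNames(desc, ids)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of term descriptions
#'   (defaults to the `"description"` attribute, else `"na"`).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% attr(gene_sets, "description") %||%
    rep("na", length(gene_sets))
  lines <- vapply(seq_along(gene_sets), function(i) {
    paste(c(names(gene_sets)[i], descriptions[i], gene_sets[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' For each term with `K` annotated genes in a background of `N` genes and a
#' query of `n` genes overlapping the term in `k` genes, the upper-tail
#' hypergeometric probability `P(X >= k)` is computed, followed by
#' Benjamini-Hochberg adjustment across the tested terms. Query genes outside
#' the background are dropped (with a message); terms with no background gene
#' are skipped. Significance is called on the raw p-value (< `alpha`,
#' default 0.05) unless `adjusted = TRUE`.
#'
#' @param query character vector of gene symbols.
#' @param gene_sets named list of gene sets (see [read_gmt()]).
#' @param background gene universe; defaults to all genes appearing in
#'   `gene_sets`.
#' @param alpha significance cutoff (default 0.05).
#' @param adjusted call significance on BH-adjusted p-values instead of raw.
#' @return a `data.frame` of class `enrichment_result` with columns
#'   `term_id`, `k`, `n`, `K`, `N`, `p_value`, `p_adjusted`, ordered by
#'   p-value; the significant term ids are in [significant_terms()].
#' @export
ora <- function(query, gene_sets, background = NULL, alpha = 0.05,
                adjusted = FALSE) {
  if (!length(gene_sets)) stop("no gene sets supplied")
  bg <- unique(.norm_symbol(background %||% unlist(gene_sets, use.names = FALSE)))
  q0 <- unique(.norm_symbol(query))
  q <- intersect(q0, bg)
  dropped <- length(q0) - length(q)
  if (dropped > 0)
    message("dropped ", dropped, " query gene(s) outside the background")
  if (!length(q))
    stop("query is empty after intersection with the background")

  sets_bg <- lapply(gene_sets, function(s) intersect(.norm_symbol(s), bg))
  K <- lengths(sets_bg)
  keep <- K > 0
  if (!any(keep)) stop("no gene set overlaps the background")
  sets_bg <- sets_bg[keep]
  K <- K[keep]
  N <- length(bg)
  n <- length(q)
  k <- vapply(sets_bg, function(s) length(intersect(q, s)), 0L)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  padj <- stats::p.adjust(p, method = "BH")

  res <- data.frame(term_id = names(sets_bg), k = k, n = n, K = as.integer(K),
                    N = N, p_value = p, p_adjusted = padj,
                    stringsAsFactors = FALSE)
  res <- res[base::order(res$p_value, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  sig <- res$term_id[if (adjusted) res$p_adjusted < alpha else res$p_value < alpha]
  attr(res, "significant") <- sig
  attr(res, "alpha") <- alpha
  attr(res, "adjusted") <- adjusted
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Significant terms of an enrichment result
#'
#' @param x an `enrichment_result` from [ora()].
#' @return character vector of significant term ids.
#' @export
significant_terms <- function(x) {
  stopifnot(inherits(x, "enrichment_result"))
  attr(x, "significant")
}

#' Effective terms: shared enrichment of drug targets and disease genes
#'
#' Terms significantly enriched in *both* the target gene set and the
#' pathogenic gene set. This intersection serves as the reference against
#' which key-network extraction methods are compared.
#'
#' @param target_genes predicted target symbols.
#' @param pathogenic_genes disease gene symbols.
#' @param gene_sets,background,alpha,adjusted passed to [ora()].
#' @return character vector of effective term ids.
#' @export
effective_terms <- function(target_genes, pathogenic_genes, gene_sets,
                            background = NULL, alpha = 0.05, adjusted = FALSE) {
  if (!length(target_genes) || !length(pathogenic_genes))
    stop("both gene sets must be non-empty")
  st <- significant_terms(ora(target_genes, gene_sets, background, alpha, adjusted))
  sp <- significant_terms(ora(pathogenic_genes, gene_sets, background, alpha, adjusted))
  intersect(st, sp)
}

#' Effective-term coverage of importance methods
#'
#' For each importance method, the genes of its key functional network are
#' tested for over-representation and the fraction of effective terms that
#' come out significant is reported. A method whose key network contains no
#' background gene covers 0.
#'
#' @param method_results named list of `importance_result` objects.
#' @param effective character vector of effective term ids (non-empty).
#' @param gene_sets,background,alpha,adjusted passed to [ora()].
#' @return named numeric vector of coverage fractions in `[0, 1]`.
#' @export
method_coverage <- function(method_results, effective, gene_sets,
                            background = NULL, alpha = 0.05, adjusted = FALSE) {
  if (!length(effective))
    stop("effective term set is empty; the comparison is undefined")
  bg <- unique(.norm_symbol(background %||% unlist(gene_sets, use.names = FALSE)))
  vapply(method_results, function(r) {
    genes <- intersect(.norm_symbol(key_network_genes(r)), bg)
    if (!length(genes)) return(0)
    sig <- significant_terms(suppressMessages(
      ora(genes, gene_sets, bg, alpha, adjusted)))
    length(intersect(sig, effective)) / length(effective)
  }, 0)
}
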