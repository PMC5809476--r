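# Hypergeometric over-representation of target genes in term annotations.

#' Hypergeometric term enrichment
#'
#' For each term with at least one target gene, the upper-tail probability
#' `P(X >= k)` with `X ~ Hypergeometric(N, K, n)`: `k` target genes carry
#' the term, `K` background genes carry it, `n` is the target-set size and
#' `N` the background (genome) size.
#'
#' @param target_genes character vector (must be a subset of the background).
#' @param background_genes the gene universe.
#' @param term_map data.frame: gene_id, term_id, term_name, category.
#' @return data.frame, one row per term with `k >= 1`.
#' @export
hypergeom_enrich <- function(target_genes, background_genes, term_map) {
  target_genes <- unique(target_genes)
  background_genes <- unique(background_genes)
  missing <- setdiff(target_genes, background_genes)
  if (length(missing))
    stopf("target gene(s) absent from background: %s",
          paste(missing, collapse = ", "))
  N <- length(background_genes)
  n <- length(target_genes)
  tm <- term_map[term_map$gene_id %in% background_genes, , drop = FALSE]
  out <- lapply(split(tm, tm$term_id), function(g) {
    genes <- unique(g$gene_id)
    K <- length(genes)
    k <- length(intersect(genes, target_genes))
    if (k == 0L) return(NULL)
    data.frame(term_id = g$term_id[1], term_name = g$term_name[1],
               category = g$category[1], k = k, K = K, n = n, N = N,
               p_value = stats::phyper(k - 1L, K, N - K, n,
                                       lower.tail = FALSE))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(term_id = character(0), term_name = character(0),
                      category = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_value = numeric(0))
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Multiple-testing correction for enrichment results
#'
#' Bonferroni (`min(1, m p)`) by default for consistency with the
#' differential-expression stage; Benjamini-Hochberg step-up selectable.
#' Significance is `p_corrected <= alpha`.
#'
#' @param results output of [hypergeom_enrich()].
#' @param method "bonferroni" or "benjamini_hochberg".
#' @param alpha significance threshold (0.05).
#' @return `results` with `p_corrected` and `significant`.
#' @export
correct_terms <- function(results, method = c("bonferroni",
                                              "benjamini_hochberg"),
                          alpha = 0.05) {
  method <- match.arg(method)
  if (!nrow(results)) {
    results$p_corrected <- numeric(0)
    results$significant <- logical(0)
    return(results)
  }
  results$p_corrected <- stats::p.adjust(
    results$p_value, method = if (method == "bonferroni") "bonferroni" else "BH")
  results$significant <- results$p_corrected <= alpha
  results
}

#' Category classification table for a gene set
#'
#' Counts, per annotation category (or per term), the genes of the set
#' carrying at least one term of that category; a gene may count in several
#' categories, once each. Sorted descending.
#'
#' @param genes character vector of gene ids.
#' @param term_map data.frame: gene_id, term_id, term_name, category.
#' @param by "category" or "term".
#' @return data.frame: class, n_genes.
#' @export
classification_table <- function(genes, term_map, by = c("category", "term")) {
  by <- match.arg(by)
  key <- if (by == "category") term_map$category else term_map$term_name
  lv <- unique(key)
  genes <- unique(genes)
  counts <- vapply(lv, function(cl) {
    length(intersect(genes, term_map$gene_id[key == cl]))
  }, integer(1))
  out <- data.frame(class = lv, n_genes = counts)
  out <- out[order(-out$n_genes, out$class), , drop = FALSE]
  rownames(out) <- NULL
  out
}
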