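#' Fisher's exact over-representation test
#'
#' For each term, tests whether the query gene set carries the term more often
#' than expected from the background universe: the one-sided upper
#' hypergeometric tail P(X >= k) for a 2x2 table with k query carriers, K
#' background carriers, query size n and background size N. This is the
#' one-sided Fisher's exact test used both for GO-term profiling of pathways
#' and for disease-to-pathway mapping.
#'
#' Term gene sets are intersected with the background before testing; terms
#' with no background carriers after restriction are skipped, and only terms
#' with at least one query hit are reported.
#'
#' @param query Character vector of query genes (must lie in `background`).
#' @param term_to_genes Named list mapping term id -> character vector of
#'   carrier genes (see [term_to_genes()]).
#' @param background Character vector: the gene universe.
#' @return Tibble with columns `term`, `k`, `K`, `n`, `N`, `p`, sorted by
#'   ascending `p` (ties by term id). No multiplicity correction is applied
#'   here; see [bh_adjust()].
#' @export
fisher_enrichment <- function(query, term_to_genes, background) {
  background <- unique(background)
  query <- unique(query)
  if (length(query) == 0L) rlang::abort("query gene set is empty")
  if (length(setdiff(query, background))) {
    rlang::abort("query contains genes absent from the background")
  }
  N <- length(background)
  n <- length(query)
  K <- vapply(term_to_genes,
              function(g) length(intersect(g, background)), integer(1))
  k <- vapply(term_to_genes,
              function(g) length(intersect(g, query)), integer(1))
  keep <- K > 0L & k > 0L
  terms <- names(term_to_genes)[keep]
  K <- unname(K[keep]); k <- unname(k[keep])
  # upper tail P(X >= k) of Hypergeometric(N, K, n)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- tibble::tibble(term = terms, k = k, K = K, n = n, N = N,
                        p = pmin(p, 1))
  dplyr::arrange(out, .data$p, .data$term)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a family of p-values, with
#' enforced monotonicity and capping at 1.
#'
#' @param pvalues Numeric vector of raw p-values in (0, 1].
#' @return Numeric vector of adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    rlang::abort("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Enriched-term functional profiles for a pathway set
#'
#' Runs [fisher_enrichment()] for every pathway's annotated gene set against
#' the shared background (the union of annotated genes across the set), then
#' keeps terms whose BH-adjusted p-value (within the pathway's own test
#' family) falls below `alpha`. Pathways with no enriched term cannot be
#' linked into the network and are flagged for removal.
#'
#' @param ps A [pathway_set()] carrying the `annotated` list-column from
#'   [filter_annotation_coverage()].
#' @param table A filtered, propagated [annotation_table()].
#' @param alpha Adjusted-p threshold for calling a term enriched
#'   (default 0.01).
#' @param background Optional explicit gene universe; defaults to the union
#'   of annotated genes over all pathways in `ps`.
#' @return Tibble of class `functional_profiles`, one row per (pathway, term)
#'   with columns `pathway`, `term`, `k`, `K`, `n`, `N`, `p`, `p_adj`.
#'   Pathways with zero enriched terms are absent; the attribute
#'   `unprofiled` lists their ids.
#' @export
profile_pathways <- function(ps, table, alpha = 0.01, background = NULL) {
  stopifnot(inherits(ps, "pathway_set"), inherits(table, "annotation_table"))
  if (!is_propagated(table)) rlang::abort("annotation table must be propagated")
  if (!"annotated" %in% names(ps)) {
    rlang::abort("run filter_annotation_coverage() first")
  }
  t2g <- term_to_genes(table)
  if (is.null(background)) {
    background <- sort(unique(unlist(ps$annotated, use.names = FALSE)))
  }
  t2g <- lapply(t2g, function(g) intersect(g, background))
  t2g <- t2g[lengths(t2g) > 0L]
  res <- purrr::map2(ps$id, ps$annotated, function(id, genes) {
    genes <- intersect(genes, background)
    if (length(genes) == 0L) return(NULL)
    er <- fisher_enrichment(genes, t2g, background)
    er$p_adj <- bh_adjust(er$p)
    er <- dplyr::filter(er, .data$p_adj < alpha)
    if (nrow(er) == 0L) return(NULL)
    dplyr::bind_cols(tibble::tibble(pathway = id), er)
  })
  out <- dplyr::bind_rows(res)
  profiled <- unique(out$pathway)
  structure(out,
            class = c("functional_profiles", class(tibble::tibble())),
            unprofiled = setdiff(ps$id, profiled),
            alpha = alpha,
            background = background)
}

#' Pathways that failed to yield any enriched term
#'
#' @param profiles A `functional_profiles` tibble from [profile_pathways()].
#' @return Character vector of pathway ids.
#' @export
unprofiled_pathways <- function(profiles) {
  attr(profiles, "unprofiled")
}
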