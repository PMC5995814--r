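#' Minimize a pathway's enriched-term profile
#'
#' Greedy set cover over a pathway's annotated genes using its enriched terms
#' as candidate sets: at each step the most significant (smallest-p) term
#' that still covers at least one uncovered gene is selected; ties are broken
#' toward the term covering more uncovered genes, then by lexicographic term
#' id. Terms describing the same genes at lower significance are thereby
#' discarded, leaving a minimal, most-specific functional profile.
#'
#' Genes carried by none of the enriched terms can never be covered and are
#' excluded from the cover target; they are reported in the `uncovered`
#' attribute.
#'
#' @param pathway_genes Character vector: the pathway's annotated genes.
#' @param enriched Data frame with columns `term`, `p` and a `carriers`
#'   list-column holding each term's carrier genes *within this pathway*
#'   (i.e. already intersected with `pathway_genes`).
#' @return Tibble with columns `term`, `p`, `new_genes` (genes first covered
#'   by that term), in selection order; attribute `uncovered` holds genes no
#'   enriched term covers.
#' @export
minimize_profile <- function(pathway_genes, enriched) {
  enriched <- tibble::as_tibble(enriched)
  stopifnot(all(c("term", "p", "carriers") %in% names(enriched)))
  if (nrow(enriched) == 0L) {
    rlang::abort("no enriched terms: pathway should have been removed upstream")
  }
  carriers <- lapply(enriched$carriers, function(g) {
    intersect(unique(g), pathway_genes)
  })
  coverable <- sort(unique(unlist(carriers, use.names = FALSE)))
  uncovered <- coverable
  sel <- integer(0)
  new_sets <- list()
  while (length(uncovered)) {
    gain <- vapply(carriers, function(g) length(intersect(g, uncovered)),
                   integer(1))
    cand <- which(gain > 0L)
    if (!length(cand)) break
    ord <- order(enriched$p[cand], -gain[cand], enriched$term[cand])
    pick <- cand[ord[1]]
    newly <- intersect(carriers[[pick]], uncovered)
    sel <- c(sel, pick)
    new_sets[[length(new_sets) + 1L]] <- sort(newly)
    uncovered <- setdiff(uncovered, newly)
    carriers[[pick]] <- character(0)
  }
  # Every selected term covered >= 1 gene not covered by the (more
  # significant) terms selected before it, so no selection is subsumed by
  # more significant ones. A later, more general term may subsume an earlier
  # specific pick's genes; the specific term is retained regardless — the
  # point of the minimization is to keep the most significant description of
  # each gene, not the smallest possible cover.
  structure(
    tibble::tibble(term = enriched$term[sel], p = enriched$p[sel],
                   new_genes = new_sets),
    uncovered = setdiff(sort(unique(pathway_genes)), coverable),
    class = c("minimal_profile", class(tibble::tibble()))
  )
}

#' Minimize every pathway's functional profile
#'
#' Applies [minimize_profile()] to each pathway in a `functional_profiles`
#' table, using each enriched term's query carriers as its cover set.
#'
#' @param profiles Output of [profile_pathways()].
#' @param table The propagated [annotation_table()] used for profiling.
#' @param ps The [pathway_set()] that was profiled (supplies the annotated
#'   gene sets).
#' @return Tibble with columns `pathway`, `term`, `p`, `p_adj`, `order` (the
#'   greedy selection rank within the pathway).
#' @export
minimize_profiles <- function(profiles, table, ps) {
  stopifnot(inherits(table, "annotation_table"), inherits(ps, "pathway_set"))
  t2g <- term_to_genes(table)
  by_pathway <- split(seq_len(nrow(profiles)), profiles$pathway)
  res <- purrr::imap(by_pathway, function(rows, pid) {
    genes <- ps$annotated[[match(pid, ps$id)]]
    enriched <- tibble::tibble(
      term = profiles$term[rows],
      p = profiles$p[rows],
      p_adj = profiles$p_adj[rows],
      carriers = lapply(profiles$term[rows],
                        function(t) intersect(t2g[[t]], genes))
    )
    mp <- minimize_profile(genes, enriched)
    tibble::tibble(pathway = pid, term = mp$term, p = mp$p,
                   p_adj = enriched$p_adj[match(mp$term, enriched$term)],
                   order = seq_len(nrow(mp)))
  })
  dplyr::bind_rows(res)
}

#' Proportional greedy set cover over pathways
#'
#' Selects a reduced-redundancy subset of pathways covering a required
#' fraction of the gene universe. Each iteration picks the pathway with the
#' most still-uncovered genes; among ties, the pathway whose total size is
#' closest to `target_size` (by absolute difference), with residual ties
#' broken by lexicographic id. Selection stops as soon as the covered
#' fraction reaches `coverage_fraction`, which lets very large, unspecific
#' pathways be skipped near the end of the cover.
#'
#' @param ps A [pathway_set()].
#' @param target_size Preferred pathway size for tie-breaking; default is the
#'   median pathway size of `ps`, computed from the data.
#' @param coverage_fraction Fraction of the gene universe that must be
#'   covered before stopping (default 0.9995).
#' @return A [pathway_set()] of the selected pathways in selection order,
#'   with attribute `selection_trace` (tibble: `iteration`, `id`,
#'   `new_genes`, `covered_fraction`) and `uncovered_genes` (character).
#' @export
proportional_set_cover <- function(ps, target_size = NULL,
                                   coverage_fraction = 0.9995) {
  stopifnot(inherits(ps, "pathway_set"))
  if (!(coverage_fraction > 0 && coverage_fraction <= 1)) {
    rlang::abort("coverage_fraction must lie in (0, 1]")
  }
  sizes <- lengths(ps$genes)
  if (is.null(target_size)) target_size <- stats::median(sizes)
  if (target_size <= 0) rlang::abort("target_size must be positive")
  universe <- gene_universe(ps)
  need <- ceiling(coverage_fraction * length(universe))
  uncovered <- universe
  remaining <- seq_len(nrow(ps))
  picked <- integer(0)
  trace <- list()
  covered <- 0L
  while (covered < need && length(remaining)) {
    gain <- vapply(remaining, function(i) {
      length(intersect(ps$genes[[i]], uncovered))
    }, integer(1))
    if (max(gain) == 0L) break
    ord <- order(-gain, abs(sizes[remaining] - target_size), ps$id[remaining])
    pick <- remaining[ord[1]]
    newly <- intersect(ps$genes[[pick]], uncovered)
    covered <- covered + length(newly)
    uncovered <- setdiff(uncovered, newly)
    picked <- c(picked, pick)
    remaining <- setdiff(remaining, pick)
    trace[[length(trace) + 1L]] <- tibble::tibble(
      iteration = length(picked), id = ps$id[pick],
      new_genes = length(newly),
      covered_fraction = covered / length(universe))
  }
  if (covered < need) {
    rlang::abort(sprintf(
      "coverage fraction %.4f unreachable; maximum achievable is %.4f",
      coverage_fraction, covered / length(universe)))
  }
  out <- ps[picked, ]
  out <- pathway_set(out, curation_log(ps))
  out <- log_stage(out, "proportional_set_cover", nrow(ps) - length(picked),
                   "redundant (not selected by set cover)")
  attr(out, "selection_trace") <- dplyr::bind_rows(trace)
  attr(out, "uncovered_genes") <- uncovered
  out
}

#' Per-gene pathway-membership counts
#'
#' How many pathways each gene of the set's universe belongs to — the
#' redundancy profile the proportional set cover is designed to flatten.
#'
#' @param ps A [pathway_set()].
#' @return Tibble with columns `gene` and `memberships`, one row per gene,
#'   plus attributes `mean` and `median` of the membership counts.
#' @export
redundancy_histogram <- function(ps) {
  stopifnot(inherits(ps, "pathway_set"))
  counts <- table(unlist(ps$genes, use.names = FALSE))
  out <- tibble::tibble(gene = names(counts),
                        memberships = as.integer(counts))
  out <- dplyr::arrange(out, .data$gene)
  structure(out, mean = mean(out$memberships),
            median = stats::median(out$memberships))
}
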