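#' Pathway sets
#'
#' A `pathway_set` is a tibble with one row per pathway: `id`, `name`, a
#' `genes` list-column of unique gene symbols, and a `source` provenance
#' label. A curation log (tibble attribute `curation_log`) accumulates one row
#' per curation stage recording how many pathways that stage removed, so the
#' full accounting from raw collection to network node set can be audited.
#'
#' @param pathways Data frame with columns `id`, `name`, `genes` (list of
#'   character vectors) and optionally `source`.
#' @param curation_log Optional existing log tibble (`stage`, `removed`,
#'   `reason`).
#' @return A tibble of class `pathway_set`.
#' @export
pathway_set <- function(pathways, curation_log = NULL) {
  pathways <- tibble::as_tibble(pathways)
  stopifnot(all(c("id", "name", "genes") %in% names(pathways)))
  if (!"source" %in% names(pathways)) pathways$source <- NA_character_
  if (anyDuplicated(pathways$id)) rlang::abort("duplicate pathway ids")
  if (nrow(pathways) && any(lengths(pathways$genes) == 0L)) {
    rlang::abort("pathways must have non-empty gene sets")
  }
  pathways$genes <- lapply(pathways$genes, function(g) sort(unique(g)))
  if (is.null(curation_log)) {
    curation_log <- tibble::tibble(stage = character(), removed = integer(),
                                   reason = character())
  }
  structure(pathways,
            class = c("pathway_set", class(tibble::tibble())),
            curation_log = curation_log)
}

#' @export
print.pathway_set <- function(x, ...) {
  cat(sprintf("<pathway_set> %d pathways, %d genes in universe\n",
              nrow(x), length(gene_universe(x))))
  NextMethod()
}

#' Curation log of a pathway set
#'
#' @param ps A [pathway_set()].
#' @return Tibble with columns `stage`, `removed`, `reason`.
#' @export
curation_log <- function(ps) {
  stopifnot(inherits(ps, "pathway_set"))
  attr(ps, "curation_log")
}

log_stage <- function(ps, stage, removed, reason) {
  log <- dplyr::bind_rows(
    attr(ps, "curation_log"),
    tibble::tibble(stage = stage, removed = as.integer(removed),
                   reason = reason))
  attr(ps, "curation_log") <- log
  ps
}

#' Union of genes across a pathway set
#'
#' @param ps A [pathway_set()].
#' @return Sorted character vector.
#' @export
gene_universe <- function(ps) {
  stopifnot(inherits(ps, "pathway_set"))
  sort(unique(unlist(ps$genes, use.names = FALSE)))
}

#' Read gene sets from a GMT file
#'
#' One pathway per line: id, name/description, then one gene symbol per
#' remaining tab-separated field. Duplicate symbols within a line are
#' collapsed.
#'
#' @param file Path to a GMT file, or a character vector of its lines.
#' @param source Provenance label stored on every pathway.
#' @return A [pathway_set()].
#' @export
read_gmt <- function(file, source = NA_character_) {
  lines <- input_lines(file)
  keep <- nzchar(trimws(lines))
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- which(nf < 3L)[1]
    rlang::abort(sprintf(
      "line %d: GMT lines need >= 3 tab-separated fields, found %d",
      idx[bad], nf[bad]))
  }
  pathway_set(tibble::tibble(
    id = purrr::map_chr(fields, 1),
    name = purrr::map_chr(fields, 2),
    genes = purrr::map(fields, ~ unique(.x[-(1:2)])),
    source = source
  ))
}

#' Write a pathway set to GMT text
#'
#' @param ps A [pathway_set()].
#' @param file Optional path; if `NULL` the GMT lines are returned invisibly.
#' @return Character vector of GMT lines, invisibly.
#' @export
write_gmt <- function(ps, file = NULL) {
  stopifnot(inherits(ps, "pathway_set"))
  lines <- purrr::pmap_chr(list(ps$id, ps$name, ps$genes), function(id, nm, g) {
    paste(c(id, nm, g), collapse = "\t")
  })
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Remove pathways with identical gene sets
#'
#' Among pathways whose gene sets are exactly equal, the one with the
#' lexicographically smallest id is retained; the removal count is logged.
#'
#' @param ps A [pathway_set()].
#' @return A deduplicated [pathway_set()].
#' @export
deduplicate_pathways <- function(ps) {
  stopifnot(inherits(ps, "pathway_set"))
  key <- purrr::map_chr(ps$genes, ~ paste(.x, collapse = "\r"))
  ord <- order(key, ps$id)
  keep_ids <- ps$id[ord][!duplicated(key[ord])]
  out <- dplyr::filter(ps, .data$id %in% keep_ids)
  out <- pathway_set(out, curation_log(ps))
  log_stage(out, "deduplicate", nrow(ps) - nrow(out), "identical gene sets")
}

#' Remove pathways whose names match disease/drug/addiction terms
#'
#' Pathways depicting disease perturbations, drug metabolism or addiction show
#' the cell in an altered state and are excluded from a network of normal
#' function. Matching is case-insensitive substring search of each term
#' against the pathway name; per-category removals are logged separately.
#'
#' @param ps A [pathway_set()].
#' @param term_lists Named list of character vectors of search terms, e.g.
#'   `list(disease = c("cancer", ...), drug = ..., addiction = ...)`.
#' @return A filtered [pathway_set()].
#' @export
filter_by_name <- function(ps, term_lists = default_exclusion_terms()) {
  stopifnot(inherits(ps, "pathway_set"), length(term_lists) > 0)
  if (any(lengths(term_lists) == 0L)) {
    rlang::abort("every term-list category must be non-empty")
  }
  lower_names <- tolower(ps$name)
  matched <- rep(FALSE, nrow(ps))
  out <- ps
  removed_counts <- integer(length(term_lists))
  for (i in seq_along(term_lists)) {
    hits <- Reduce(`|`, lapply(tolower(term_lists[[i]]), function(tm) {
      stringr::str_detect(lower_names, stringr::fixed(tm))
    }), accumulate = FALSE)
    # a name matching several categories is counted in the first that hits it
    new_hits <- hits & !matched
    removed_counts[i] <- sum(new_hits)
    matched <- matched | hits
  }
  kept <- pathway_set(dplyr::filter(ps, !matched), curation_log(ps))
  for (i in seq_along(term_lists)) {
    kept <- log_stage(kept, paste0("filter_name_", names(term_lists)[i]),
                      removed_counts[i],
                      paste0("name matches ", names(term_lists)[i], " term"))
  }
  kept
}

#' Default name-exclusion term lists
#'
#' A configurable starting point for [filter_by_name()]: users analysing a
#' real pathway collection should supply the full curated term lists for
#' their database release.
#'
#' @return Named list with `disease`, `drug` and `addiction` categories.
#' @export
default_exclusion_terms <- function() {
  list(
    disease = c("cancer", "carcinoma", "sarcoma", "melanoma", "leukemia",
                "lymphoma", "asthma", "infection", "disease", "diabetes"),
    drug = c("doxorubicin", "statin", "metabolism of drug", "drug metabolism"),
    addiction = c("addiction", "dependence", "alcoholism")
  )
}

#' Remove pathways with too few annotated genes
#'
#' Enrichment analysis needs a minimum number of annotated genes per query;
#' pathways below the floor are removed. Each surviving pathway records the
#' subset of its genes that carry annotations (list-column `annotated`), which
#' is the query set enrichment uses.
#'
#' @param ps A [pathway_set()].
#' @param table A filtered, propagated [annotation_table()].
#' @param min_annotated Minimum number of annotated genes (default 4).
#' @return A filtered [pathway_set()] with an `annotated` list-column.
#' @export
filter_annotation_coverage <- function(ps, table, min_annotated = 4L) {
  stopifnot(inherits(ps, "pathway_set"), inherits(table, "annotation_table"))
  if (!is_propagated(table)) {
    rlang::abort("annotation table must be filtered and propagated first")
  }
  known <- annotated_genes(table)
  annotated <- purrr::map(ps$genes, ~ intersect(.x, known))
  keep <- lengths(annotated) >= min_annotated
  out <- dplyr::filter(dplyr::mutate(ps, annotated = annotated), keep)
  out <- pathway_set(out, curation_log(ps))
  log_stage(out, "filter_annotation_coverage", sum(!keep),
            sprintf("fewer than %d annotated genes", min_annotated))
}
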