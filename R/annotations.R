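#' Gene-to-term annotation tables
#'
#' An `annotation_table` is a tibble with one row per (gene, term, evidence
#' class) assignment. Evidence is binary: `"IEA"` for electronically inferred
#' annotations and `"curated"` for everything else — the only evidence
#' distinction the pipeline acts on, since IEA annotations are of lower
#' confidence and are discarded before enrichment.
#'
#' @param entries Data frame with columns `gene`, `term`, `evidence`
#'   (`"curated"` or `"IEA"`).
#' @param propagated Logical; whether terms have been closed over ancestors.
#' @return A tibble of class `annotation_table` with attribute `propagated`.
#' @export
annotation_table <- function(entries, propagated = FALSE) {
  entries <- tibble::as_tibble(entries)
  stopifnot(all(c("gene", "term", "evidence") %in% names(entries)))
  bad <- setdiff(unique(entries$evidence), c("curated", "IEA"))
  if (length(bad)) {
    rlang::abort(paste0("unknown evidence class: ", paste(bad, collapse = ", ")))
  }
  entries <- dplyr::arrange(
    dplyr::distinct(entries, .data$gene, .data$term, .data$evidence),
    .data$gene, .data$term)
  structure(entries,
            class = c("annotation_table", class(tibble::tibble())),
            propagated = propagated)
}

#' @export
print.annotation_table <- function(x, ...) {
  cat(sprintf("<annotation_table> %d entries, %d genes, %d terms%s\n",
              nrow(x), dplyr::n_distinct(x$gene), dplyr::n_distinct(x$term),
              if (isTRUE(attr(x, "propagated"))) ", propagated" else ""))
  NextMethod()
}

is_propagated <- function(table) isTRUE(attr(table, "propagated"))

#' Read gene annotations from a GAF file
#'
#' Parses the GAF 2.x tab-delimited layout (comment lines start with `!`).
#' Rows are restricted to the requested aspect (`"P"` = Biological Process),
#' `NOT`-qualified rows are dropped, and the evidence-code column is collapsed
#' to the binary curated/IEA classification.
#'
#' @param file Path to a GAF file, or a character vector of its lines.
#' @param aspect Single-letter GO aspect to retain (default `"P"`).
#' @return An [annotation_table()] (not yet evidence-filtered or propagated).
#' @export
read_gaf <- function(file, aspect = "P") {
  lines <- input_lines(file)
  keep <- !grepl("^!", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 15L)) {
    bad <- idx[which(nf < 15L)[1]]
    rlang::abort(sprintf(
      "line %d: expected >= 15 tab-separated GAF columns, found %d",
      bad, nf[which(nf < 15L)[1]]))
  }
  rows <- tibble::tibble(
    gene = purrr::map_chr(fields, 3),
    qualifier = purrr::map_chr(fields, 4),
    term = purrr::map_chr(fields, 5),
    evidence_code = purrr::map_chr(fields, 7),
    aspect = purrr::map_chr(fields, 9)
  )
  rows <- dplyr::filter(rows,
                        .data$aspect == !!aspect,
                        !grepl("(^|\\|)NOT($|\\|)", .data$qualifier))
  annotation_table(tibble::tibble(
    gene = rows$gene,
    term = rows$term,
    evidence = ifelse(rows$evidence_code == "IEA", "IEA", "curated")
  ))
}

#' Drop electronically inferred (IEA) annotations
#'
#' Genes left with no annotations at all are removed from the table entirely,
#' so downstream coverage counts see only genes with at least one curated
#' Biological Process term.
#'
#' @param table An unpropagated [annotation_table()].
#' @return An [annotation_table()] containing only curated entries.
#' @export
filter_evidence <- function(table) {
  stopifnot(inherits(table, "annotation_table"))
  if (is_propagated(table)) {
    rlang::abort("evidence filtering must precede ancestor propagation")
  }
  annotation_table(dplyr::filter(table, .data$evidence == "curated"))
}

#' Propagate annotations over ontology ancestors
#'
#' Applies the true-path rule: each gene's term set is replaced by its closure
#' over all ancestors (both `is_a` and `part_of`), so any gene annotated to a
#' term is also annotated to every ancestor of that term. Idempotent.
#'
#' @param table A filtered [annotation_table()].
#' @param dag The [ontology_dag()] the terms belong to.
#' @return A propagated [annotation_table()].
#' @export
propagate_annotations <- function(table, dag) {
  stopifnot(inherits(table, "annotation_table"), inherits(dag, "ontology_dag"))
  missing <- setdiff(unique(table$term), dag$terms$id)
  if (length(missing)) {
    g <- table$gene[match(missing[1], table$term)]
    rlang::abort(sprintf("term '%s' (gene '%s') not present in the ontology",
                         missing[1], g))
  }
  anc <- dag$ancestors
  closed <- dplyr::bind_rows(purrr::map2(table$gene, table$term, function(g, t) {
    tibble::tibble(gene = g, term = c(t, anc[[t]]))
  }))
  closed$evidence <- "curated"
  annotation_table(closed, propagated = TRUE)
}

#' Invert an annotation table to term -> gene sets
#'
#' @param table An [annotation_table()].
#' @return Named list mapping each term id to the sorted character vector of
#'   genes annotated with it. After propagation the parent's gene set is a
#'   superset of every child's.
#' @export
term_to_genes <- function(table) {
  stopifnot(inherits(table, "annotation_table"))
  lapply(split(table$gene, table$term), function(g) sort(unique(g)))
}

#' Genes carrying at least one annotation
#'
#' @param table An [annotation_table()].
#' @return Sorted character vector of gene symbols.
#' @export
annotated_genes <- function(table) {
  sort(unique(table$gene))
}
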