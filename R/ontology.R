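#' Ontology DAGs
#'
#' An `ontology_dag` holds the terms of one sub-ontology (e.g. the Gene
#' Ontology's Biological Process namespace) together with its typed parent
#' edges. Only `is_a` and `part_of` relations are retained: these are the two
#' relation classes the Wang similarity measure defines decay weights for.
#' Edges are oriented child -> parent, so the root(s) have no outgoing edges.
#'
#' @param terms A data frame with columns `id` and `name`, one row per term.
#' @param edges A data frame with columns `child`, `parent`, `relation`
#'   (`"is_a"` or `"part_of"`).
#' @param namespace Label of the sub-ontology the terms belong to.
#' @param alt_ids Named character vector mapping alternate ids to canonical
#'   term ids (may be empty).
#'
#' @return An object of class `ontology_dag`: a list with elements `terms`
#'   (tibble), `edges` (tibble), `namespace`, `alt_ids`, `roots` (terms with
#'   no parents) and `ancestors` (named list giving, for every term, the
#'   sorted character vector of all its ancestors over both relation types).
#' @export
ontology_dag <- function(terms, edges, namespace = "biological_process",
                         alt_ids = character()) {
  terms <- tibble::as_tibble(terms)
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("id", "name") %in% names(terms)),
            all(c("child", "parent", "relation") %in% names(edges)))
  if (anyDuplicated(terms$id)) {
    rlang::abort("duplicate term ids in ontology")
  }
  bad_rel <- setdiff(unique(edges$relation), c("is_a", "part_of"))
  if (length(bad_rel)) {
    rlang::abort(paste0("unsupported edge relation(s): ",
                        paste(bad_rel, collapse = ", ")))
  }
  missing_ref <- setdiff(unique(c(edges$child, edges$parent)), terms$id)
  if (length(missing_ref)) {
    rlang::abort(paste0("edges reference unknown term(s): ",
                        paste(utils::head(missing_ref, 5), collapse = ", ")))
  }
  edges <- dplyr::distinct(edges, .data$child, .data$parent, .data$relation)
  anc <- compute_ancestors(terms$id, edges)
  roots <- setdiff(terms$id, unique(edges$child))
  structure(
    list(terms = terms, edges = edges, namespace = namespace,
         alt_ids = alt_ids, roots = sort(roots), ancestors = anc),
    class = "ontology_dag"
  )
}

#' @export
print.ontology_dag <- function(x, ...) {
  rel <- table(factor(x$edges$relation, levels = c("is_a", "part_of")))
  cat(sprintf(
    "<ontology_dag> %d terms, %d edges (is_a %d, part_of %d), namespace '%s'\n",
    nrow(x$terms), nrow(x$edges), rel[["is_a"]], rel[["part_of"]],
    x$namespace))
  invisible(x)
}

# Kahn topological sort; on a cycle, abort naming one cycle found by DFS.
# Returns the full ancestor closure as a named list, computed in topological
# order so each term's closure is parents plus their (already final) closures.
compute_ancestors <- function(ids, edges) {
  parents <- split(edges$parent, factor(edges$child, levels = ids))
  # Kahn from the roots downward: a term is ready once all its parents are.
  out_count <- vapply(parents, length, integer(1)) # edges toward parents
  queue <- ids[out_count == 0L]
  remaining <- out_count
  children_of <- split(edges$child, factor(edges$parent, levels = ids))
  order <- character(0)
  while (length(queue)) {
    t <- queue[[1]]; queue <- queue[-1]
    order <- c(order, t)
    for (ch in children_of[[t]]) {
      remaining[[ch]] <- remaining[[ch]] - 1L
      if (remaining[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < length(ids)) {
    cyc <- find_cycle(ids[!(ids %in% order)], parents)
    rlang::abort(paste0("ontology edges contain a cycle: ",
                        paste(cyc, collapse = " -> ")))
  }
  anc <- stats::setNames(vector("list", length(ids)), ids)
  for (t in order) {
    ps <- parents[[t]]
    anc[[t]] <- if (length(ps)) {
      sort(unique(c(ps, unlist(anc[ps], use.names = FALSE))))
    } else character(0)
  }
  anc
}

find_cycle <- function(start_ids, parents) {
  for (s in start_ids) {
    path <- character(0)
    t <- s
    seen <- character(0)
    while (TRUE) {
      if (t %in% path) {
        i <- match(t, path)
        return(c(path[i:length(path)], t))
      }
      path <- c(path, t)
      ps <- parents[[t]]
      ps <- ps[!(ps %in% seen)]
      if (!length(ps)) break
      t <- ps[[1]]
    }
  }
  start_ids[1]
}

#' Read an OBO ontology file
#'
#' Parses the OBO 1.2 subset used by Gene Ontology releases: `[Term]` stanzas
#' with `id`, `name`, `namespace`, `is_a`, `relationship: part_of`,
#' `is_obsolete` and `alt_id` tags. Obsolete terms are dropped, all
#' relationship types other than `part_of` are ignored, and `alt_id`s are
#' resolved to their canonical term at load so downstream code never sees an
#' alternate id.
#'
#' @param file Path to an OBO file, or a character vector of its lines.
#' @param namespace Sub-ontology to retain (terms in other namespaces are
#'   dropped; terms with no namespace tag are kept).
#' @return An [ontology_dag()].
#' @export
read_obo <- function(file, namespace = "biological_process") {
  lines <- input_lines(file)
  lines <- sub("\\s*!.*$", "", lines) # strip OBO comments
  in_term <- FALSE
  cur <- NULL
  stanzas <- list()
  flush <- function(cur) if (!is.null(cur)) stanzas[[length(stanzas) + 1L]] <<- cur
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "") next
    if (grepl("^\\[", ln)) {
      flush(cur); cur <- NULL
      in_term <- identical(ln, "[Term]")
      if (!in_term && !ln %in% c("[Typedef]", "[Instance]")) {
        rlang::abort(sprintf("line %d: unknown stanza header '%s'", i, ln))
      }
      if (in_term) cur <- list(line = i)
      next
    }
    if (!in_term) next
    if (!grepl("^[A-Za-z_]+:", ln)) {
      rlang::abort(sprintf("line %d: malformed tag line '%s'", i, ln))
    }
    tag <- sub(":.*$", "", ln)
    val <- trimws(sub("^[A-Za-z_]+:\\s*", "", ln))
    cur[[tag]] <- c(cur[[tag]], val)
  }
  flush(cur)

  recs <- purrr::keep(stanzas, ~ !is.null(.x$id))
  if (length(recs) < length(stanzas)) {
    bad <- purrr::detect(stanzas, ~ is.null(.x$id))
    rlang::abort(sprintf("line %d: [Term] stanza without an id tag", bad$line))
  }
  keep <- purrr::keep(recs, function(r) {
    ns_ok <- is.null(r$namespace) || r$namespace[[1]] == namespace
    obs <- !is.null(r$is_obsolete) && tolower(r$is_obsolete[[1]]) == "true"
    ns_ok && !obs
  })
  ids <- purrr::map_chr(keep, ~ .x$id[[1]])
  terms <- tibble::tibble(
    id = ids,
    name = purrr::map_chr(keep, ~ if (is.null(.x$name)) .x$id[[1]] else .x$name[[1]])
  )
  alt_ids <- unlist(purrr::map(keep, function(r) {
    if (is.null(r$alt_id)) return(NULL)
    stats::setNames(rep(r$id[[1]], length(r$alt_id)), r$alt_id)
  }))
  if (is.null(alt_ids)) alt_ids <- character()

  edge_rows <- purrr::map(keep, function(r) {
    isa <- if (is.null(r$is_a)) character() else sub("\\s.*$", "", r$is_a)
    po <- character()
    if (!is.null(r$relationship)) {
      rel <- strsplit(trimws(r$relationship), "\\s+")
      po <- purrr::map_chr(purrr::keep(rel, ~ .x[[1]] == "part_of"), 2)
    }
    tibble::tibble(
      child = r$id[[1]],
      parent = c(isa, po),
      relation = c(rep("is_a", length(isa)), rep("part_of", length(po)))
    )
  })
  edges <- dplyr::bind_rows(edge_rows)
  # resolve alt_id references, drop edges leaving the namespace
  if (nrow(edges)) {
    edges$parent <- ifelse(edges$parent %in% names(alt_ids),
                           unname(alt_ids[edges$parent]), edges$parent)
    edges <- dplyr::filter(edges, .data$parent %in% ids)
  }
  ontology_dag(terms, edges, namespace = namespace, alt_ids = alt_ids)
}

#' Ancestors of ontology terms
#'
#' Transitive closure over both `is_a` and `part_of` edges, excluding the
#' query term itself (the true-path rule propagates annotations over both
#' relation types).
#'
#' @param dag An [ontology_dag()].
#' @param term A term id (single string).
#' @return Sorted character vector of ancestor term ids; empty for a root.
#' @export
term_ancestors <- function(dag, term) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (!term %in% dag$terms$id) {
    rlang::abort(sprintf("unknown term '%s'", term))
  }
  dag$ancestors[[term]]
}

#' Direct parents of a term, with edge relations
#'
#' @inheritParams term_ancestors
#' @return Tibble with columns `parent`, `relation`.
#' @export
term_parents <- function(dag, term) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (!term %in% dag$terms$id) rlang::abort(sprintf("unknown term '%s'", term))
  dplyr::select(dplyr::filter(dag$edges, .data$child == term),
                "parent", "relation")
}
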