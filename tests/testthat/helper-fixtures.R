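# In-code fixtures and independent oracles shared across the test files.

# --- standard fixture cache --------------------------------------------------

.pipeline_cache <- new.env()

std_study <- function() {
  if (is.null(.pipeline_cache$study)) {
    .pipeline_cache$study <- generate_study(synth_config(seed = 17))
  }
  .pipeline_cache$study
}

std_result <- function() {
  if (is.null(.pipeline_cache$result)) {
    st <- std_study()
    .pipeline_cache$result <- run_pipeline(st$obo, st$gaf, st$gmt,
                                           st$diseases,
                                           pipeline_config(seed = 17))
  }
  .pipeline_cache$result
}

# --- tiny ontologies ---------------------------------------------------------

obo_lines <- function(...) {
  c("format-version: 1.2", "", ...)
}

term_stanza <- function(id, name = id, is_a = character(), part_of = character(),
                        obsolete = FALSE, alt_id = character(),
                        namespace = "biological_process") {
  c("[Term]",
    paste0("id: ", id),
    paste0("name: ", name),
    paste0("namespace: ", namespace),
    vapply(alt_id, function(a) paste0("alt_id: ", a), character(1)),
    vapply(is_a, function(p) paste0("is_a: ", p), character(1)),
    vapply(part_of, function(p) paste0("relationship: part_of ", p),
           character(1)),
    if (obsolete) "is_obsolete: true" else character(0),
    "")
}

# A is_a B is_a ROOT
chain_obo <- function() {
  obo_lines(term_stanza("T:ROOT"),
            term_stanza("T:B", is_a = "T:ROOT"),
            term_stanza("T:A", is_a = "T:B"))
}

# diamond: A -> {B, C} -> D (D the root)
diamond_obo <- function() {
  obo_lines(term_stanza("T:D"),
            term_stanza("T:B", is_a = "T:D"),
            term_stanza("T:C", is_a = "T:D"),
            term_stanza("T:A", is_a = c("T:B", "T:C")))
}

# 10 terms, hand-counted 9 is_a + 2 part_of edges
ten_term_obo <- function() {
  obo_lines(
    term_stanza("T:00"),
    term_stanza("T:01", is_a = "T:00"),
    term_stanza("T:02", is_a = "T:00"),
    term_stanza("T:03", is_a = "T:01"),
    term_stanza("T:04", is_a = "T:01", part_of = "T:02"),
    term_stanza("T:05", is_a = "T:02"),
    term_stanza("T:06", is_a = "T:03"),
    term_stanza("T:07", is_a = "T:03", part_of = "T:05"),
    term_stanza("T:08", is_a = "T:05"),
    term_stanza("T:09", is_a = "T:06"))
}

# random rooted DAG as an ontology_dag, for property tests
random_dag <- function(n, extra_prob = 0.15) {
  ids <- sprintf("T:%03d", seq_len(n))
  child <- integer(0); parent <- integer(0)
  for (i in 2:n) {
    p <- sample.int(i - 1L, 1L)
    child <- c(child, i); parent <- c(parent, p)
    if (stats::runif(1) < extra_prob && i > 2L) {
      p2 <- sample(setdiff(seq_len(i - 1L), p), 1L)
      child <- c(child, i); parent <- c(parent, p2)
    }
  }
  rel <- sample(c("is_a", "part_of"), length(child), replace = TRUE,
                prob = c(0.8, 0.2))
  ontology_dag(data.frame(id = ids, name = ids),
               data.frame(child = ids[child], parent = ids[parent],
                          relation = rel))
}

# brute-force ancestor closure by repeated expansion (independent of the
# memoized topological-order implementation)
bfs_ancestors <- function(dag, term) {
  parents <- split(dag$edges$parent, dag$edges$child)
  seen <- character(0)
  frontier <- term
  while (length(frontier)) {
    ps <- unique(unlist(parents[frontier], use.names = FALSE))
    ps <- setdiff(ps, seen)
    seen <- union(seen, ps)
    frontier <- ps
  }
  sort(seen)
}

# --- GAF / GMT / disease text ------------------------------------------------

gaf_line <- function(gene, term, evidence = "EXP", aspect = "P",
                     qualifier = "") {
  paste("DB", gene, gene, qualifier, term, "REF:1", evidence, "",
        aspect, "", "", "protein", "taxon:9606", "20240101", "DB",
        sep = "\t")
}

gmt_line <- function(id, name, genes) paste(c(id, name, genes), collapse = "\t")

disease_line <- function(id, name, gene, kind = "disease") {
  paste(id, name, gene, kind, sep = "\t")
}

# --- semantic-similarity oracles --------------------------------------------

# all directed child->parent paths from `from` up to `to`
all_paths_up <- function(dag, from, to) {
  edges <- dag$edges
  out <- list()
  walk <- function(node, path) {
    if (node == to) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    rows <- which(edges$child == node)
    for (r in rows) walk(edges$parent[r], c(path, r))
  }
  walk(from, integer(0))
  out
}

# Wang S-value of ancestor t for anchor a: max over paths of the product of
# edge weights along the path (1 for t == a)
oracle_svalue <- function(dag, a, t, weights = c(is_a = 0.8, part_of = 0.6)) {
  if (a == t) return(1)
  paths <- all_paths_up(dag, a, t)
  if (!length(paths)) return(0)
  max(vapply(paths, function(rows) {
    prod(weights[dag$edges$relation[rows]])
  }, numeric(1)))
}

oracle_wang_similarity <- function(dag, a, b,
                                   weights = c(is_a = 0.8, part_of = 0.6)) {
  ta <- c(a, bfs_ancestors(dag, a))
  tb <- c(b, bfs_ancestors(dag, b))
  shared <- intersect(ta, tb)
  sva <- vapply(ta, function(t) oracle_svalue(dag, a, t, weights), numeric(1))
  svb <- vapply(tb, function(t) oracle_svalue(dag, b, t, weights), numeric(1))
  names(sva) <- ta; names(svb) <- tb
  sum(sva[shared] + svb[shared]) / (sum(sva) + sum(svb))
}

# exhaustive hypergeometric upper tail by direct summation
oracle_hyper_tail <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# BFS all-pairs shortest paths on an edge list (hop counts)
oracle_bfs_paths <- function(edges, nodes) {
  adj <- lapply(stats::setNames(nodes, nodes), function(x) character(0))
  for (i in seq_len(nrow(edges))) {
    adj[[edges$u[i]]] <- c(adj[[edges$u[i]]], edges$v[i])
    adj[[edges$v[i]]] <- c(adj[[edges$v[i]]], edges$u[i])
  }
  dist_from <- function(s) {
    d <- stats::setNames(rep(Inf, length(nodes)), nodes)
    d[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- character(0)
      for (f in frontier) {
        for (nb in adj[[f]]) if (!is.finite(d[nb])) {
          d[nb] <- d[f] + 1
          nxt <- c(nxt, nb)
        }
      }
      frontier <- nxt
    }
    d
  }
  vapply(nodes, dist_from, numeric(length(nodes)))
}

# exhaustive minimum set cover size (for instances with <= 12 candidates)
oracle_min_cover_size <- function(universe, sets) {
  n <- length(sets)
  for (size in 1:n) {
    combos <- utils::combn(n, size, simplify = FALSE)
    for (cmb in combos) {
      if (all(universe %in% unlist(sets[cmb]))) return(size)
    }
  }
  Inf
}

# a small pathway_set built from plain lists
make_ps <- function(sets) {
  pathway_set(tibble::tibble(
    id = names(sets),
    name = names(sets),
    genes = unname(sets)))
}
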