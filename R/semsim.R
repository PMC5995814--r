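#' Wang semantic-contribution S-values for a term
#'
#' The Wang measure scores a term A by the weighted contributions of its
#' ancestor subgraph: S_A(A) = 1 and, walking upward, S_A(t) is the best
#' (maximum) product of per-edge decay weights along any path from A to t,
#' with `is_a` edges decaying less (default weight 0.8) than `part_of` edges
#' (0.6). SV(A) is the sum of S-values over A's ancestor-closed subgraph.
#'
#' @param dag An [ontology_dag()].
#' @param term Term id.
#' @param weights Named numeric decay weights for the two relations; both in
#'   (0,1) with `is_a > part_of`.
#' @return Named numeric vector of S-values over `{term} U ancestors(term)`
#'   (names sorted), with attribute `SV` (their sum).
#' @export
wang_svalues <- function(dag, term, weights = c(is_a = 0.8, part_of = 0.6)) {
  stopifnot(inherits(dag, "ontology_dag"))
  check_wang_weights(weights)
  if (!term %in% dag$terms$id) rlang::abort(sprintf("unknown term '%s'", term))
  sub <- c(term, dag$ancestors[[term]])
  edges <- dplyr::filter(dag$edges, .data$child %in% sub, .data$parent %in% sub)
  s <- stats::setNames(rep(0, length(sub)), sub)
  s[[term]] <- 1
  # relax child->parent edges until the max-product S-values stabilize; the
  # subgraph is a DAG, so |sub| sweeps suffice
  w <- weights[edges$relation]
  for (iter in seq_along(sub)) {
    prop <- s[edges$child] * w
    upd <- tapply(prop, edges$parent, max)
    changed <- FALSE
    for (p in names(upd)) {
      if (upd[[p]] > s[[p]] + 1e-15) { s[[p]] <- upd[[p]]; changed <- TRUE }
    }
    if (!changed) break
  }
  s <- s[order(names(s))]
  structure(s, SV = sum(s))
}

check_wang_weights <- function(weights) {
  if (!all(c("is_a", "part_of") %in% names(weights)) ||
      any(weights <= 0) || any(weights >= 1) ||
      weights[["is_a"]] <= weights[["part_of"]]) {
    rlang::abort("weights must lie in (0,1) with is_a > part_of")
  }
}

#' Wang similarity between two ontology terms
#'
#' The shared ancestors' S-value contributions from both terms, relative to
#' the terms' total semantic values:
#' sim(a,b) = sum over t in T_a intersect T_b of (S_a(t) + S_b(t)) /
#' (SV(a) + SV(b)). Symmetric, in (0, 1], and 1 for identical terms.
#'
#' @inheritParams wang_svalues
#' @param a,b Term ids.
#' @return Similarity in \[0, 1\].
#' @export
wang_similarity <- function(dag, a, b, weights = c(is_a = 0.8, part_of = 0.6)) {
  sa <- wang_svalues(dag, a, weights)
  sb <- wang_svalues(dag, b, weights)
  shared <- intersect(names(sa), names(sb))
  sum(sa[shared] + sb[shared]) / (attr(sa, "SV") + attr(sb, "SV"))
}

#' Information-content map from annotation counts
#'
#' For each ontology term with at least one annotated gene (after ancestor
#' propagation), p(t) is the fraction of annotated genes carrying t and
#' IC(t) = -log p(t). The root carries every gene, so IC(root) = 0; the
#' corpus maximum IC over informative terms is stored for normalization.
#'
#' @param table A propagated [annotation_table()].
#' @param dag An [ontology_dag()] (used only to validate terms).
#' @return Tibble of class `ic_map` with columns `term`, `n_genes`, `p`,
#'   `ic`; attribute `max_ic`.
#' @export
ic_map <- function(table, dag = NULL) {
  stopifnot(inherits(table, "annotation_table"))
  if (!is_propagated(table)) {
    rlang::abort("information content requires a propagated annotation table")
  }
  if (!is.null(dag)) {
    missing <- setdiff(unique(table$term), dag$terms$id)
    if (length(missing)) {
      rlang::abort(sprintf("term '%s' not in ontology", missing[1]))
    }
  }
  n_total <- length(unique(table$gene))
  counts <- table(table$term) # propagated: one row per (gene, term)
  out <- tibble::tibble(term = names(counts),
                        n_genes = as.integer(counts),
                        p = as.integer(counts) / n_total)
  out$ic <- -log(out$p)
  out <- dplyr::arrange(out, .data$term)
  structure(out, max_ic = max(out$ic),
            class = c("ic_map", class(tibble::tibble())))
}

#' Resnik similarity between two ontology terms
#'
#' The information content of the most informative common ancestor (MICA) of
#' the two terms — the lowest common ancestor in annotation-probability
#' terms — normalized by the corpus maximum IC so that scores share the
#' \[0, 1\] scale of the Wang measure. Common-ancestor sets include the terms
#' themselves, so the self-similarity of the rarest term is 1.
#'
#' @param dag An [ontology_dag()].
#' @param ic An `ic_map` from [ic_map()].
#' @param a,b Term ids present in `ic`.
#' @return Similarity in \[0, 1\].
#' @export
resnik_similarity <- function(dag, ic, a, b) {
  stopifnot(inherits(dag, "ontology_dag"), inherits(ic, "ic_map"))
  for (t in c(a, b)) {
    if (!t %in% dag$terms$id) rlang::abort(sprintf("unknown term '%s'", t))
    if (!t %in% ic$term) {
      rlang::abort(sprintf(
        "term '%s' has no annotated genes; IC undefined", t))
    }
  }
  common <- intersect(c(a, dag$ancestors[[a]]), c(b, dag$ancestors[[b]]))
  common <- intersect(common, ic$term)
  if (!length(common)) return(0)
  raw <- max(ic$ic[match(common, ic$term)])
  max_ic <- attr(ic, "max_ic")
  if (max_ic <= 0) return(0)
  min(max(raw / max_ic, 0), 1)
}

#' Term-pair similarity matrix
#'
#' Tabulates [wang_similarity()] or [resnik_similarity()] over all pairs of
#' the given terms; the symmetric matrix is the cached `termsim` input the
#' set-level aggregations consume.
#'
#' @param dag An [ontology_dag()].
#' @param terms Character vector of term ids.
#' @param method `"wang"` or `"resnik"`.
#' @param ic An `ic_map`, required for `method = "resnik"`.
#' @param weights Wang decay weights.
#' @return Symmetric numeric matrix with `terms` as dimnames.
#' @export
term_similarity_matrix <- function(dag, terms, method = c("wang", "resnik"),
                                   ic = NULL,
                                   weights = c(is_a = 0.8, part_of = 0.6)) {
  method <- match.arg(method)
  terms <- unique(terms)
  n <- length(terms)
  m <- matrix(0, n, n, dimnames = list(terms, terms))
  if (method == "wang") {
    sv <- lapply(terms, function(t) wang_svalues(dag, t, weights))
    names(sv) <- terms
    for (i in seq_len(n)) {
      for (j in i:n) {
        sa <- sv[[i]]; sb <- sv[[j]]
        shared <- intersect(names(sa), names(sb))
        val <- sum(sa[shared] + sb[shared]) /
          (attr(sa, "SV") + attr(sb, "SV"))
        m[i, j] <- m[j, i] <- val
      }
    }
  } else {
    if (is.null(ic)) rlang::abort("resnik similarity needs an ic_map")
    for (i in seq_len(n)) {
      for (j in i:n) {
        m[i, j] <- m[j, i] <- resnik_similarity(dag, ic, terms[i], terms[j])
      }
    }
  }
  m
}

as_termsim_fun <- function(termsim) {
  if (is.function(termsim)) return(termsim)
  if (is.matrix(termsim)) {
    return(function(a, b) termsim[a, b])
  }
  rlang::abort("termsim must be a function or a named symmetric matrix")
}

#' Pairwise-average similarity between two term sets
#'
#' The mean term similarity over the full cross product A x B. Note that for
#' a set compared against itself this averages in the off-diagonal pairs, so
#' two pathways annotated with the same two unrelated terms score only 0.5.
#'
#' @param A,B Character vectors of term ids (non-empty).
#' @param termsim A symmetric term-similarity matrix with term-id dimnames,
#'   or a function of two term ids.
#' @return Similarity in \[0, 1\]; symmetric in A and B.
#' @export
pairwise_average <- function(A, B, termsim) {
  A <- unique(A); B <- unique(B)
  if (!length(A) || !length(B)) rlang::abort("term sets must be non-empty")
  f <- as_termsim_fun(termsim)
  vals <- outer(A, B, Vectorize(f))
  mean(vals)
}

#' Best-match-average similarity between two term sets
#'
#' Each term in A is matched to its most similar term in B and vice versa;
#' the score is the mean of the |A| + |B| best-match similarities. Identical
#' sets always score 1, making this the aggregation that tolerates pathways
#' enriched with several semantically unrelated functions.
#'
#' @inheritParams pairwise_average
#' @return Similarity in \[0, 1\]; symmetric in A and B.
#' @export
best_match_average <- function(A, B, termsim) {
  A <- unique(A); B <- unique(B)
  if (!length(A) || !length(B)) rlang::abort("term sets must be non-empty")
  f <- as_termsim_fun(termsim)
  vals <- outer(A, B, Vectorize(f))
  (sum(apply(vals, 1, max)) + sum(apply(vals, 2, max))) /
    (length(A) + length(B))
}

#' Pathway-pathway similarity from minimal functional profiles
#'
#' Computes the set-level semantic similarity between every pair of pathways,
#' aggregating a term-level measure (Wang or Resnik) over the pathways'
#' minimal enriched-term profiles.
#'
#' @param minimal Tibble from [minimize_profiles()] (columns `pathway`,
#'   `term`).
#' @param dag An [ontology_dag()].
#' @param method `"wang"` or `"resnik"`.
#' @param aggregation `"bma"` (best-match average) or `"pairwise"`.
#' @param ic `ic_map`, required for Resnik.
#' @param weights Wang decay weights.
#' @return Tibble with columns `u`, `v` (`u < v`) and `weight`, one row per
#'   unordered pathway pair.
#' @export
pathway_similarity <- function(minimal, dag,
                               method = c("wang", "resnik"),
                               aggregation = c("bma", "pairwise"),
                               ic = NULL,
                               weights = c(is_a = 0.8, part_of = 0.6)) {
  method <- match.arg(method)
  aggregation <- match.arg(aggregation)
  profiles <- lapply(split(minimal$term, minimal$pathway), unique)
  ids <- sort(names(profiles))
  all_terms <- unique(unlist(profiles, use.names = FALSE))
  tsm <- term_similarity_matrix(dag, all_terms, method, ic = ic,
                                weights = weights)
  agg <- if (aggregation == "bma") best_match_average else pairwise_average
  pairs <- utils::combn(ids, 2)
  weight <- vapply(seq_len(ncol(pairs)), function(i) {
    agg(profiles[[pairs[1, i]]], profiles[[pairs[2, i]]], tsm)
  }, numeric(1))
  tibble::tibble(u = pairs[1, ], v = pairs[2, ], weight = weight)
}

#' Within- vs between-pathway similarity separation
#'
#' For each combination of term measure (Resnik, Wang) and level (individual
#' term pairs, pairwise average, best-match average), contrasts the
#' distribution of similarities within pathways' profiles against those
#' between different pathways, summarizing the separation as a difference of
#' means and a two-sample Kolmogorov-Smirnov statistic. A good configuration
#' puts within-pathway similarities well above between-pathway ones.
#'
#' @param minimal Tibble from [minimize_profiles()].
#' @param dag An [ontology_dag()].
#' @param ic `ic_map` for the Resnik measure.
#' @param weights Wang decay weights.
#' @return List of class `separation_report`: `stats` (tibble: `method`,
#'   `level`, `mean_within`, `mean_between`, `delta`, `ks`) and `values`
#'   (tibble of the raw similarity values with `method`, `level`, `where`).
#' @export
separation_report <- function(minimal, dag, ic,
                              weights = c(is_a = 0.8, part_of = 0.6)) {
  profiles <- lapply(split(minimal$term, minimal$pathway), unique)
  if (length(profiles) < 2L) rlang::abort("need at least two profiles")
  all_terms <- unique(unlist(profiles, use.names = FALSE))
  ids <- names(profiles)
  pairs <- utils::combn(ids, 2)
  rows <- list()
  vals <- list()
  for (method in c("resnik", "wang")) {
    tsm <- term_similarity_matrix(dag, all_terms, method, ic = ic,
                                  weights = weights)
    # term level: similarities of term pairs within one profile vs term pairs
    # drawn from two different profiles
    term_within <- unlist(lapply(profiles, function(ts) {
      if (length(ts) < 2L) return(numeric(0))
      tsm[t(utils::combn(ts, 2))]
    }), use.names = FALSE)
    term_between <- unlist(lapply(seq_len(ncol(pairs)), function(i) {
      as.vector(tsm[profiles[[pairs[1, i]]], profiles[[pairs[2, i]]],
                    drop = FALSE])
    }), use.names = FALSE)
    pw_within <- vapply(profiles, function(ts) pairwise_average(ts, ts, tsm),
                        numeric(1))
    pw_between <- vapply(seq_len(ncol(pairs)), function(i) {
      pairwise_average(profiles[[pairs[1, i]]], profiles[[pairs[2, i]]], tsm)
    }, numeric(1))
    bma_within <- vapply(profiles,
                         function(ts) best_match_average(ts, ts, tsm),
                         numeric(1))
    bma_between <- vapply(seq_len(ncol(pairs)), function(i) {
      best_match_average(profiles[[pairs[1, i]]], profiles[[pairs[2, i]]], tsm)
    }, numeric(1))
    sets <- list(term = list(term_within, term_between),
                 pairwise = list(pw_within, pw_between),
                 bma = list(bma_within, bma_between))
    for (level in names(sets)) {
      w <- sets[[level]][[1]]; b <- sets[[level]][[2]]
      ks <- if (length(w) && length(b)) {
        suppressWarnings(stats::ks.test(w, b)$statistic)
      } else NA_real_
      rows[[length(rows) + 1L]] <- tibble::tibble(
        method = method, level = level,
        mean_within = mean(w), mean_between = mean(b),
        delta = mean(w) - mean(b), ks = unname(ks))
      vals[[length(vals) + 1L]] <- tibble::tibble(
        method = method, level = level,
        where = rep(c("within", "between"), c(length(w), length(b))),
        similarity = c(w, b))
    }
  }
  structure(list(stats = dplyr::bind_rows(rows),
                 values = dplyr::bind_rows(vals)),
            class = "separation_report")
}

#' @export
print.separation_report <- function(x, ...) {
  cat("<separation_report>\n")
  print(x$stats)
  invisible(x)
}

#' Plot a separation report
#'
#' Histograms of within- vs between-pathway similarities for each measure
#' and aggregation level.
#'
#' @param object A [separation_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.separation_report <- function(object, ...) {
  ggplot2::ggplot(object$values,
                  ggplot2::aes(x = .data$similarity, fill = .data$where)) +
    ggplot2::geom_histogram(position = "identity", alpha = 0.5, bins = 30) +
    ggplot2::facet_grid(ggplot2::vars(.data$method),
                        ggplot2::vars(.data$level)) +
    ggplot2::labs(x = "semantic similarity", y = "pairs", fill = NULL)
}
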