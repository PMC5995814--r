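#' Read a disease-gene annotation table
#'
#' Tab-delimited, one row per (disease, gene): disease id, disease name, gene
#' symbol, and optionally a kind column (`disease` or `phenotype`). Rows are
#' grouped into one record per disease.
#'
#' @param file Path to a TSV file, or a character vector of its lines.
#' @param min_genes Diseases with fewer distinct genes are dropped
#'   (default 4, the floor for meaningful enrichment).
#' @return Tibble of class `disease_set`: columns `disease_id`, `disease_name`,
#'   `kind`, `genes` (list-column).
#' @export
read_disease_table <- function(file, min_genes = 4L) {
  lines <- input_lines(file)
  keep <- nzchar(trimws(lines)) & !grepl("^#", lines)
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- which(nf < 3L)[1]
    rlang::abort(sprintf(
      "line %d: disease tables need >= 3 tab-separated fields, found %d",
      idx[bad], nf[bad]))
  }
  rows <- tibble::tibble(
    disease_id = purrr::map_chr(fields, 1),
    disease_name = purrr::map_chr(fields, 2),
    gene = purrr::map_chr(fields, 3),
    kind = purrr::map_chr(fields, ~ if (length(.x) >= 4) .x[[4]] else "disease")
  )
  disease_set(rows, min_genes = min_genes)
}

#' Group per-gene disease rows into disease gene sets
#'
#' @param rows Tibble with columns `disease_id`, `disease_name`, `gene` and
#'   optionally `kind`.
#' @param min_genes Minimum distinct genes per retained disease.
#' @return Tibble of class `disease_set`.
#' @export
disease_set <- function(rows, min_genes = 4L) {
  rows <- tibble::as_tibble(rows)
  stopifnot(all(c("disease_id", "disease_name", "gene") %in% names(rows)))
  if (!"kind" %in% names(rows)) rows$kind <- "disease"
  out <- dplyr::summarise(
    dplyr::group_by(rows, .data$disease_id),
    disease_name = dplyr::first(.data$disease_name),
    kind = dplyr::first(.data$kind),
    genes = list(sort(unique(.data$gene))),
    .groups = "drop")
  out <- dplyr::filter(out, lengths(.data$genes) >= min_genes)
  out <- dplyr::arrange(out, .data$disease_id)
  structure(out, class = c("disease_set", class(tibble::tibble())))
}

#' Map disease gene sets onto pathway nodes by enrichment
#'
#' A pathway is associated with a disease when the one-sided Fisher's exact
#' test of the overlap between the disease's genes and the pathway's genes
#' (against the annotated gene background) gives raw p below `alpha`. No
#' multiple-testing correction is applied at this stage.
#'
#' @param diseases A [disease_set()].
#' @param ps A [pathway_set()] (the network's node set).
#' @param background Character vector: the gene universe used for enrichment.
#' @param alpha Raw p-value threshold (default 0.01).
#' @return Tibble with columns `disease_id`, `pathway`, `k`, `K`, `n`, `N`,
#'   `p`; attribute `skipped` lists diseases with no background overlap.
#' @export
map_diseases <- function(diseases, ps, background, alpha = 0.01) {
  stopifnot(inherits(diseases, "disease_set"), inherits(ps, "pathway_set"))
  background <- unique(background)
  p2g <- stats::setNames(ps$genes, ps$id)
  skipped <- character(0)
  res <- purrr::map2(diseases$disease_id, diseases$genes, function(id, genes) {
    query <- intersect(genes, background)
    if (length(query) == 0L) {
      skipped <<- c(skipped, id)
      return(NULL)
    }
    er <- fisher_enrichment(query, p2g, background)
    er <- dplyr::filter(er, .data$p < alpha)
    if (nrow(er) == 0L) return(NULL)
    tibble::tibble(disease_id = id, pathway = er$term, k = er$k, K = er$K,
                   n = er$n, N = er$N, p = er$p)
  })
  structure(dplyr::bind_rows(res), skipped = skipped)
}

#' Select diseases whose names match search terms
#'
#' Case-insensitive substring match of each term against the disease names;
#' the union of matches is returned. Used to assemble disease-system sets
#' (all cancers, immune disorders, ...) from name searches.
#'
#' @param diseases A [disease_set()].
#' @param terms Character vector of search terms (non-empty).
#' @return The matching subset, still a `disease_set`.
#' @export
select_by_terms <- function(diseases, terms) {
  stopifnot(inherits(diseases, "disease_set"), length(terms) > 0)
  lower <- tolower(diseases$disease_name)
  hit <- Reduce(`|`, lapply(tolower(terms), function(tm) {
    stringr::str_detect(lower, stringr::fixed(tm))
  }))
  structure(diseases[hit, ], class = class(diseases))
}

#' Cancer-system search terms
#'
#' The name-search terms used to pull cancer annotations out of a disease
#' set.
#'
#' @return Character vector.
#' @export
cancer_terms <- function() {
  c("cancer", "tumor", "tumour", "melanoma", "carcinoma", "leukemia",
    "lymphoma", "sarcoma")
}

#' Shortest-path length distribution within a node set
#'
#' Unweighted (hop-count) shortest-path lengths between every unordered pair
#' of the given nodes that share a connected component of the pruned network;
#' pairs split across components are excluded and counted separately rather
#' than being assigned infinite distance.
#'
#' @param net A `pathway_network`.
#' @param node_set Character vector of node ids, length >= 2.
#' @return List of class `path_distribution`: `lengths` (integer vector, one
#'   per within-component pair) and `n_excluded` (cross-component pairs).
#' @export
shortest_path_distribution <- function(net, node_set) {
  stopifnot(inherits(net, "pathway_network"))
  node_set <- unique(node_set)
  if (length(node_set) < 2L) rlang::abort("need at least two nodes")
  missing <- setdiff(node_set, net$nodes$id)
  if (length(missing)) {
    rlang::abort(sprintf("node '%s' not in network", missing[1]))
  }
  # weights = NA: hop counts, not similarity-weighted sums
  d <- igraph::distances(net$graph, v = node_set, to = node_set, weights = NA)
  vals <- d[upper.tri(d)]
  structure(list(lengths = as.integer(vals[is.finite(vals)]),
                 n_excluded = sum(!is.finite(vals))),
            class = "path_distribution")
}

#' Pooled shortest-path null from random node sets
#'
#' Draws `reps` uniform samples of `k` distinct nodes from the network and
#' pools their within-component shortest-path lengths — the permutation null
#' against which a disease module's path distribution is compared.
#'
#' @param net A `pathway_network`.
#' @param k Node-set size (matched to the disease's node count).
#' @param reps Number of random replicates (default 100).
#' @param seed Optional integer seed.
#' @return `path_distribution` with the pooled lengths and total excluded
#'   pairs.
#' @export
random_node_null <- function(net, k, reps = 100L, seed = NULL) {
  stopifnot(inherits(net, "pathway_network"), reps >= 1L)
  ids <- net$nodes$id
  if (k < 2L) rlang::abort("k must be at least 2")
  if (k > length(ids)) rlang::abort("k exceeds the number of network nodes")
  if (!is.null(seed)) set.seed(seed)
  pooled <- vector("list", reps)
  excluded <- 0L
  # one distance computation over all sampled nodes per replicate would still
  # repeat BFS work; with desk-scale networks per-replicate distances() is fine
  for (r in seq_len(reps)) {
    pick <- sample(ids, k)
    pd <- shortest_path_distribution(net, pick)
    pooled[[r]] <- pd$lengths
    excluded <- excluded + pd$n_excluded
  }
  structure(list(lengths = unlist(pooled, use.names = FALSE),
                 n_excluded = excluded),
            class = "path_distribution")
}

#' Kolmogorov-Smirnov clustering test for a disease module
#'
#' Two-sample KS test of the observed path-length distribution against the
#' pooled permutation null. A significant result with observed mean below the
#' null mean indicates the disease's pathway nodes sit closer together in the
#' network than random same-size node sets — a disease module.
#'
#' @param observed A `path_distribution` for the disease's nodes.
#' @param null A pooled `path_distribution` from [random_node_null()].
#' @return Tibble with `ks_stat`, `p`, `observed_mean`, `null_mean`,
#'   `clustered` (observed mean < null mean).
#' @export
ks_cluster_test <- function(observed, null) {
  pull_lengths <- function(x) {
    if (is.list(x) && !is.null(x$lengths)) x$lengths else x
  }
  obs <- pull_lengths(observed)
  nul <- pull_lengths(null)
  if (!length(obs) || !length(nul)) {
    rlang::abort("both path-length samples must be non-empty")
  }
  kt <- suppressWarnings(stats::ks.test(obs, nul))
  tibble::tibble(ks_stat = unname(kt$statistic), p = kt$p.value,
                 observed_mean = mean(obs), null_mean = mean(nul),
                 clustered = mean(obs) < mean(nul))
}

#' Disease-module clustering tests across a disease mapping
#'
#' For every disease with at least two mapped pathway nodes, compares the
#' within-module shortest-path distribution against a pooled random-node null
#' of equal set size and reports the KS clustering test.
#'
#' @param net A `pathway_network`.
#' @param mapping Output of [map_diseases()].
#' @param reps Random replicates per disease (default 100).
#' @param seed Integer seed; per-disease seeds are derived from it.
#' @return Tibble of class `disease_module_test`: `disease_id`, `n_nodes`,
#'   `n_pairs`, `n_excluded`, `ks_stat`, `p`, `observed_mean`, `null_mean`,
#'   `clustered`.
#' @export
disease_module_test <- function(net, mapping, reps = 100L, seed = 1L) {
  stopifnot(inherits(net, "pathway_network"))
  mapping <- dplyr::filter(tibble::as_tibble(mapping),
                           .data$pathway %in% net$nodes$id)
  by_disease <- split(mapping$pathway, mapping$disease_id)
  by_disease <- by_disease[lengths(by_disease) >= 2L]
  res <- purrr::imap(by_disease, function(nodes, id) {
    pd <- shortest_path_distribution(net, nodes)
    if (!length(pd$lengths)) return(NULL)
    null <- random_node_null(net, length(unique(nodes)), reps = reps,
                             seed = derive_seed(seed, id))
    kt <- ks_cluster_test(pd, null)
    dplyr::bind_cols(
      tibble::tibble(disease_id = id, n_nodes = length(unique(nodes)),
                     n_pairs = length(pd$lengths),
                     n_excluded = pd$n_excluded),
      kt)
  })
  out <- dplyr::bind_rows(res)
  structure(out, class = c("disease_module_test", class(tibble::tibble())))
}

# deterministic 31-bit seed from a master seed and a stage/disease label
derive_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(paste0(label, ":", seed))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

#' @export
glance.disease_module_test <- function(x, ...) {
  tibble::tibble(
    n_diseases = nrow(x),
    n_clustered_p01 = sum(x$p < 0.01 & x$clustered),
    mean_observed = mean(x$observed_mean),
    mean_null = mean(x$null_mean))
}

#' Plot disease-module path distributions
#'
#' Observed vs pooled-null shortest-path histograms for the given diseases.
#'
#' @param net A `pathway_network`.
#' @param mapping Output of [map_diseases()].
#' @param disease_ids Diseases to plot.
#' @param reps,seed Passed to [random_node_null()].
#' @return A ggplot object.
#' @export
plot_disease_paths <- function(net, mapping, disease_ids, reps = 100L,
                               seed = 1L) {
  rows <- purrr::map(disease_ids, function(id) {
    nodes <- unique(mapping$pathway[mapping$disease_id == id])
    pd <- shortest_path_distribution(net, nodes)
    null <- random_node_null(net, length(nodes), reps = reps,
                             seed = derive_seed(seed, id))
    tibble::tibble(
      disease_id = id,
      where = rep(c("observed", "null"),
                  c(length(pd$lengths), length(null$lengths))),
      length = c(pd$lengths, null$lengths))
  })
  df <- dplyr::bind_rows(rows)
  ggplot2::ggplot(df, ggplot2::aes(.data$length,
                                   ggplot2::after_stat(.data$density),
                                   fill = .data$where)) +
    ggplot2::geom_histogram(position = "identity", alpha = 0.5, binwidth = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$disease_id)) +
    ggplot2::labs(x = "shortest-path length", y = "proportion of pairs",
                  fill = NULL)
}
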