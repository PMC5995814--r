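#' Edge-weight threshold scan
#'
#' Evaluates a grid of candidate edge-weight cut-offs strictly inside (0, 1)
#' (the default 50 thresholds are k/51, k = 1..50) and, for each, the
#' fraction of nodes retaining at least one incident edge and the fraction of
#' edges retained. The chosen threshold maximizes nodeFrac - edgeFrac — the
#' cut that links the most nodes with the fewest edges; ties go to the larger
#' threshold.
#'
#' @param weights Tibble with columns `u`, `v`, `weight` — all pairwise
#'   similarities (see [pathway_similarity()]).
#' @param n_thresholds Number of evenly spaced candidate thresholds
#'   (default 50).
#' @return List of class `threshold_scan`: `threshold` (chosen value) and
#'   `scan` (tibble: `threshold`, `node_frac`, `edge_frac`, `score`).
#' @export
threshold_scan <- function(weights, n_thresholds = 50L) {
  weights <- tibble::as_tibble(weights)
  stopifnot(all(c("u", "v", "weight") %in% names(weights)),
            n_thresholds >= 2L)
  if (!any(weights$weight > 0)) rlang::abort("all edge weights are zero")
  nodes <- unique(c(weights$u, weights$v))
  n_nodes <- length(nodes)
  n_edges <- nrow(weights)
  grid <- seq_len(n_thresholds) / (n_thresholds + 1)
  scan <- purrr::map_dfr(grid, function(theta) {
    keep <- weights$weight >= theta
    tibble::tibble(
      threshold = theta,
      node_frac = length(unique(c(weights$u[keep], weights$v[keep]))) / n_nodes,
      edge_frac = sum(keep) / n_edges)
  })
  scan$score <- scan$node_frac - scan$edge_frac
  # a cut that empties the edge set is useless whatever its score
  usable <- which(scan$edge_frac > 0)
  if (!length(usable)) usable <- 1L
  best <- usable[scan$score[usable] == max(scan$score[usable])]
  chosen <- grid[max(best)] # ties toward the larger threshold
  structure(list(threshold = chosen, scan = scan), class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  i <- match(x$threshold, x$scan$threshold)
  cat(sprintf(
    "<threshold_scan> chosen threshold %.4f (nodeFrac %.3f, edgeFrac %.3f)\n",
    x$threshold, x$scan$node_frac[i], x$scan$edge_frac[i]))
  invisible(x)
}

#' Plot a threshold scan
#'
#' Node and edge retention fractions and their difference across the
#' candidate thresholds, with the chosen cut-off marked.
#'
#' @param object A [threshold_scan()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.threshold_scan <- function(object, ...) {
  long <- tidyr::pivot_longer(object$scan, c("node_frac", "edge_frac", "score"),
                              names_to = "quantity")
  ggplot2::ggplot(long, ggplot2::aes(.data$threshold, .data$value,
                                     colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = 2) +
    ggplot2::labs(x = "edge-weight threshold", y = NULL, colour = NULL)
}

#' Prune weighted edges into a pathway network
#'
#' Retains edges with weight at or above the threshold. All nodes stay in the
#' node table; nodes left without any edge are flagged `isolated`.
#'
#' @param weights Tibble with columns `u`, `v`, `weight`.
#' @param threshold Edge-weight cut-off in (0, 1), typically from
#'   [threshold_scan()].
#' @return Object of class `pathway_network`: list with `nodes` (tibble:
#'   `id`, `isolated`), `edges` (tibble: `u`, `v`, `weight`, with `u < v`),
#'   `threshold`, and `graph` (the corresponding [igraph][igraph::graph] on
#'   the non-isolated edge set, with all nodes as vertices).
#' @export
prune_network <- function(weights, threshold) {
  weights <- tibble::as_tibble(weights)
  stopifnot(all(c("u", "v", "weight") %in% names(weights)))
  if (!(threshold > 0 && threshold < 1)) {
    rlang::abort("threshold must lie in (0, 1)")
  }
  swap <- weights$u > weights$v
  tmp <- weights$u[swap]; weights$u[swap] <- weights$v[swap]
  weights$v[swap] <- tmp
  weights <- dplyr::filter(weights, .data$u != .data$v)
  nodes <- sort(unique(c(weights$u, weights$v)))
  edges <- dplyr::arrange(
    dplyr::filter(weights, .data$weight >= threshold),
    .data$u, .data$v)
  connected <- unique(c(edges$u, edges$v))
  g <- igraph::graph_from_data_frame(
    edges[, c("u", "v", "weight")], directed = FALSE,
    vertices = data.frame(name = nodes))
  structure(
    list(nodes = tibble::tibble(id = nodes,
                                isolated = !(nodes %in% connected)),
         edges = edges,
         threshold = threshold,
         graph = g),
    class = "pathway_network")
}

#' @export
print.pathway_network <- function(x, ...) {
  cat(sprintf(
    "<pathway_network> %d nodes (%d connected), %d edges, threshold %.4f\n",
    nrow(x$nodes), sum(!x$nodes$isolated), nrow(x$edges), x$threshold))
  invisible(x)
}

#' @export
tidy.pathway_network <- function(x, ...) {
  x$edges
}

#' @export
glance.pathway_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_connected = sum(!x$nodes$isolated),
    n_edges = nrow(x$edges),
    threshold = x$threshold,
    clustering = clustering_coefficient(x))
}

#' Average clustering coefficient
#'
#' The Watts-Strogatz network clustering coefficient: the mean over all nodes
#' of the local clustering coefficient (triangles over connected triples),
#' with nodes of degree < 2 contributing 0. Triangles are counted on the
#' unweighted pruned graph.
#'
#' @param net A [prune_network()] result (or an igraph graph).
#' @return Value in \[0, 1\].
#' @export
clustering_coefficient <- function(net) {
  g <- if (inherits(net, "pathway_network")) net$graph else net
  if (igraph::vcount(g) == 0L) rlang::abort("network has no nodes")
  local <- igraph::transitivity(g, type = "local", isolates = "zero")
  mean(local)
}

#' Degree-preserving network randomization
#'
#' Rewires the network by repeated double-edge swaps, preserving every node's
#' degree exactly while destroying higher-order structure; the standard null
#' model for judging whether the observed clustering coefficient exceeds
#' chance. No self-loops or multi-edges are introduced.
#'
#' @param net A `pathway_network`.
#' @param n_swaps Number of attempted swaps (default 10x the edge count).
#' @param seed Optional integer seed for reproducibility.
#' @return A `pathway_network` with the same nodes, degree sequence and
#'   threshold; edge weights are dropped (set to `NA`).
#' @export
degree_preserving_randomize <- function(net, n_swaps = NULL, seed = NULL) {
  stopifnot(inherits(net, "pathway_network"))
  if (nrow(net$edges) < 2L) {
    rlang::warn("too few edges to swap; returning the input network")
    return(net)
  }
  if (is.null(n_swaps)) n_swaps <- 10L * nrow(net$edges)
  if (!is.null(seed)) set.seed(seed)
  g <- igraph::rewire(net$graph,
                      igraph::keeping_degseq(loops = FALSE, niter = n_swaps))
  el <- igraph::as_data_frame(g, what = "edges")
  u <- pmin(el$from, el$to); v <- pmax(el$from, el$to)
  edges <- dplyr::arrange(
    tibble::tibble(u = u, v = v, weight = NA_real_), .data$u, .data$v)
  connected <- unique(c(edges$u, edges$v))
  structure(
    list(nodes = tibble::tibble(id = net$nodes$id,
                                isolated = !(net$nodes$id %in% connected)),
         edges = edges, threshold = net$threshold, graph = g),
    class = "pathway_network")
}

#' Discrete power-law fit of a degree distribution
#'
#' Fits a discrete power law to the degree sequence by maximum likelihood
#' with the lower cut-off chosen by Kolmogorov-Smirnov minimization
#' (Clauset-Shalizi-Newman, via [igraph::fit_power_law()]), and reports the
#' goodness-of-fit p-value: small p rejects the power-law hypothesis.
#'
#' @param degrees Integer vector of node degrees (nodes with degree 0 are
#'   dropped; at least 10 positive degrees required).
#' @param xmin Optional fixed lower cut-off. The default (`NULL`) estimates
#'   it by KS minimization; note that a freely estimated cut-off can always
#'   retreat to an extreme tail that fits, so testing whether the *whole*
#'   distribution is power-law requires fixing `xmin` at the minimum degree.
#' @return Tibble with columns `alpha`, `xmin`, `ks_stat`, `p`.
#' @export
power_law_test <- function(degrees, xmin = NULL) {
  degrees <- degrees[degrees > 0]
  if (length(degrees) < 10L) {
    rlang::abort("need at least 10 nodes with degree >= 1")
  }
  if (length(unique(degrees)) == 1L) {
    rlang::abort("degenerate degree sequence: all degrees equal")
  }
  fit <- igraph::fit_power_law(degrees, xmin = xmin,
                               implementation = "plfit")
  n_tail <- sum(degrees >= fit$xmin)
  p <- if (!is.null(fit$KS.p)) {
    fit$KS.p
  } else {
    kolmogorov_p(fit$KS.stat, n_tail)
  }
  tibble::tibble(alpha = fit$alpha, xmin = fit$xmin,
                 ks_stat = fit$KS.stat, p = p)
}

# asymptotic Kolmogorov distribution upper tail for the one-sample KS
# statistic D over n tail observations
kolmogorov_p <- function(d, n) {
  lambda <- (sqrt(n) + 0.12 + 0.11 / sqrt(n)) * d
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}
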