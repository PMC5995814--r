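pair_weights <- function(mat) {
  # full symmetric matrix -> tibble of unordered pairs
  ids <- rownames(mat)
  pairs <- utils::combn(ids, 2)
  tibble::tibble(u = pairs[1, ], v = pairs[2, ],
                 weight = mat[t(pairs)])
}

test_that("threshold scan keeps hub nodes and prefers larger ties", {
  # star-like: each node has one heavy edge, many light ones
  set.seed(71)
  ids <- sprintf("N%02d", 1:10)
  m <- matrix(runif(100, 0.05, 0.15), 10, dimnames = list(ids, ids))
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  for (i in seq(1, 9, 2)) m[i, i + 1] <- m[i + 1, i] <- 0.9
  scan <- threshold_scan(pair_weights(m))
  expect_gt(scan$threshold, 0.15)
  i <- match(scan$threshold, scan$scan$threshold)
  expect_equal(scan$scan$node_frac[i], 1)

  # all weights equal: every theta <= w scores identically; largest wins
  eq <- pair_weights(matrix(0.5, 4, 4, dimnames = list(letters[1:4],
                                                       letters[1:4])))
  sc <- threshold_scan(eq)
  grid <- sc$scan$threshold
  expect_equal(sc$threshold, max(grid[grid <= 0.5]))

  expect_error(threshold_scan(tibble::tibble(u = "a", v = "b", weight = 0)),
               "zero")
})

test_that("threshold scan equals exhaustive evaluation on random weights", {
  set.seed(72)
  ids <- sprintf("N%02d", 1:20)
  m <- matrix(runif(400), 20, dimnames = list(ids, ids))
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  w <- pair_weights(m)
  scan <- threshold_scan(w, n_thresholds = 50)
  grid <- seq_len(50) / 51
  brute <- vapply(grid, function(theta) {
    keep <- w$weight >= theta
    nf <- length(unique(c(w$u[keep], w$v[keep]))) / 20
    ef <- sum(keep) / nrow(w)
    nf - ef
  }, numeric(1))
  best <- max(grid[brute == max(brute)])
  expect_equal(scan$threshold, best)
  expect_equal(scan$scan$score, brute, tolerance = 1e-12)
  # retention fractions are non-increasing in theta
  expect_true(all(diff(scan$scan$node_frac) <= 1e-12))
  expect_true(all(diff(scan$scan$edge_frac) <= 1e-12))
  i <- match(scan$threshold, grid)
  expect_lte(scan$scan$edge_frac[i], scan$scan$node_frac[i])
})

test_that("pruning keeps all nodes, flags isolates, and counts edges", {
  set.seed(73)
  ids <- sprintf("N%02d", 1:8)
  m <- matrix(runif(64), 8, dimnames = list(ids, ids))
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  w <- pair_weights(m)

  none <- prune_network(w, 0.99999)
  expect_equal(nrow(none$edges), 0L)
  expect_true(all(none$nodes$isolated))
  expect_equal(nrow(none$nodes), 8L)

  all_kept <- prune_network(w, 1e-6)
  expect_equal(nrow(all_kept$edges), nrow(w))

  at56 <- prune_network(w, 0.56)
  expect_equal(nrow(at56$edges), sum(w$weight >= 0.56))
  # idempotence: rescanning the pruned edges with the same cut changes nothing
  expect_equal(nrow(prune_network(at56$edges, 0.56)$edges),
               nrow(at56$edges))
  expect_error(prune_network(w, 1.2), "0, 1")
})

test_that("clustering coefficient matches exhaustive triangle counting", {
  tri <- tibble::tibble(u = c("a", "a", "b"), v = c("b", "c", "c"),
                        weight = 1)
  expect_equal(clustering_coefficient(prune_network(tri, 0.5)), 1)

  star <- tibble::tibble(u = rep("hub", 4), v = sprintf("s%d", 1:4),
                         weight = 1)
  expect_equal(clustering_coefficient(prune_network(star, 0.5)), 0)

  set.seed(74)
  ids <- sprintf("N%02d", 1:12)
  m <- matrix(runif(144), 12, dimnames = list(ids, ids))
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  net <- prune_network(pair_weights(m), 0.6)
  adj <- matrix(0L, 12, 12, dimnames = list(ids, ids))
  for (i in seq_len(nrow(net$edges))) {
    adj[net$edges$u[i], net$edges$v[i]] <- 1L
    adj[net$edges$v[i], net$edges$u[i]] <- 1L
  }
  local <- vapply(ids, function(v) {
    nb <- ids[adj[v, ] == 1L]
    k <- length(nb)
    if (k < 2) return(0)
    sum(adj[nb, nb]) / 2 / choose(k, 2)
  }, numeric(1))
  expect_equal(clustering_coefficient(net), mean(local), tolerance = 1e-12)
})

test_that("degree-preserving randomization keeps the degree sequence exactly", {
  set.seed(75)
  ids <- sprintf("N%02d", 1:15)
  m <- matrix(runif(225), 15, dimnames = list(ids, ids))
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  net <- prune_network(pair_weights(m), 0.55)
  degs <- function(x) {
    d <- table(factor(c(x$edges$u, x$edges$v), levels = ids))
    as.integer(d)
  }
  r1 <- degree_preserving_randomize(net, seed = 5)
  expect_identical(degs(r1), degs(net))
  expect_equal(nrow(r1$edges), nrow(net$edges))
  expect_false(any(r1$edges$u == r1$edges$v))
  expect_false(any(duplicated(paste(r1$edges$u, r1$edges$v))))
  r2 <- degree_preserving_randomize(net, seed = 5)
  expect_identical(r1$edges, r2$edges)
})

test_that("community structure collapses under randomization", {
  # two 6-cliques joined by one edge: high clustering by construction
  cl <- function(prefix) {
    ids <- paste0(prefix, 1:6)
    pairs <- utils::combn(ids, 2)
    tibble::tibble(u = pairs[1, ], v = pairs[2, ], weight = 1)
  }
  w <- dplyr::bind_rows(cl("a"), cl("b"),
                        tibble::tibble(u = "a1", v = "b1", weight = 1))
  net <- prune_network(w, 0.5)
  obs <- clustering_coefficient(net)
  rand <- vapply(1:10, function(i) {
    clustering_coefficient(degree_preserving_randomize(net, seed = i))
  }, numeric(1))
  expect_gt(obs, mean(rand))
})

test_that("power-law testing separates heavy-tailed from Poisson degrees", {
  set.seed(76)
  # discrete power law via inverse-CDF sampling (alpha ~ 2.5)
  xs <- 1:1000
  pmf <- xs^-2.5 / sum(xs^-2.5)
  pl <- sample(xs, 500, replace = TRUE, prob = pmf)
  fit <- power_law_test(pl)
  expect_gt(fit$p, 0.05)
  expect_gt(fit$alpha, 1.5)

  # the free cut-off can always retreat to a fitting extreme tail, so the
  # whole-distribution alternative is tested with the cut-off fixed
  pois <- stats::rpois(500, lambda = 8)
  fit2 <- power_law_test(pois[pois > 0], xmin = 1)
  expect_lt(fit2$p, 0.05)

  expect_error(power_law_test(rep(3L, 50)), "degenerate")
  expect_error(power_law_test(integer(0)), "at least 10")
})

test_that("network glance and tidy expose the edge table and summary", {
  set.seed(77)
  ids <- letters[1:6]
  m <- matrix(runif(36), 6, dimnames = list(ids, ids))
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  net <- prune_network(pair_weights(m), 0.5)
  expect_identical(tidy(net), net$edges)
  g <- glance(net)
  expect_equal(g$n_nodes, 6L)
  expect_equal(g$n_edges, nrow(net$edges))
  expect_equal(g$threshold, 0.5)
})
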