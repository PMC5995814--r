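ring_network <- function() {
  # path graph a-b-c-d-e plus isolated node f
  w <- tibble::tibble(
    u = c("a", "b", "c", "d", "a"),
    v = c("b", "c", "d", "e", "f"),
    weight = c(1, 1, 1, 1, 0.1))
  prune_network(w, 0.5)
}

test_that("disease tables load, group and apply the 4-gene floor", {
  lines <- c(
    disease_line("D1", "synthetic carcinoma", "G1"),
    disease_line("D1", "synthetic carcinoma", "G2"),
    disease_line("D1", "synthetic carcinoma", "G3"),
    disease_line("D1", "synthetic carcinoma", "G4"),
    disease_line("D2", "small disorder", "G1"),
    disease_line("D2", "small disorder", "G2"))
  ds <- read_disease_table(lines)
  expect_identical(ds$disease_id, "D1") # D2 below the floor
  expect_length(ds$genes[[1]], 4L)
  expect_error(read_disease_table("one\tfield-only"), "line 1")
})

test_that("name-based system selection is substring and case-insensitive", {
  rows <- tibble::tibble(
    disease_id = sprintf("D%02d", 1:12),
    disease_name = c("Duodenal adenocarcinoma", "Familial hemiplegic migraine",
                     "acute LEUKEMIA", "chronic asthma", "sarcoma of soft tissue",
                     "gastric cancer", "diabetes type 2", "melanoma, familial",
                     "Burkitt lymphoma", "epilepsy", "hypertension",
                     "colorectal tumor"),
    gene = "G1")
  rows <- rows[rep(1:12, each = 4), ]
  rows$gene <- sprintf("G%d", seq_len(nrow(rows)))
  ds <- disease_set(rows)
  hit <- select_by_terms(ds, cancer_terms())
  expect_setequal(hit$disease_name,
                  c("Duodenal adenocarcinoma", "acute LEUKEMIA",
                    "sarcoma of soft tissue", "gastric cancer",
                    "melanoma, familial", "Burkitt lymphoma",
                    "colorectal tumor"))
  # idempotent and order-independent
  expect_identical(select_by_terms(hit, cancer_terms()), hit)
})

test_that("shortest-path distributions are hop counts with exclusions", {
  net <- ring_network()
  expect_identical(shortest_path_distribution(net, c("a", "b"))$lengths, 1L)

  apart <- shortest_path_distribution(net, c("a", "e"))
  expect_identical(apart$lengths, 4L)

  # f is isolated at this threshold: cross-component pair excluded
  split <- shortest_path_distribution(net, c("a", "f"))
  expect_length(split$lengths, 0L)
  expect_equal(split$n_excluded, 1L)

  expect_error(shortest_path_distribution(net, "a"), "at least two")
  expect_error(shortest_path_distribution(net, c("a", "zz")), "not in network")
})

test_that("path distributions match brute-force BFS on the path graph", {
  net <- ring_network()
  nodes <- c("a", "b", "c", "d", "e")
  d <- oracle_bfs_paths(net$edges, nodes)
  expected <- sort(as.integer(d[upper.tri(d)][is.finite(d[upper.tri(d)])]))
  got <- sort(shortest_path_distribution(net, nodes)$lengths)
  expect_identical(got, expected)
  # permutation invariance
  got2 <- sort(shortest_path_distribution(net, rev(nodes))$lengths)
  expect_identical(got2, expected)
})

test_that("random node nulls are seed-reproducible and size-consistent", {
  net <- ring_network()
  full <- random_node_null(net, k = nrow(net$nodes), reps = 3, seed = 1)
  one <- shortest_path_distribution(net, net$nodes$id)
  expect_identical(sort(full$lengths), sort(rep(one$lengths, 3)))
  expect_equal(full$n_excluded, 3 * one$n_excluded)

  n1 <- random_node_null(net, 3, reps = 10, seed = 42)
  n2 <- random_node_null(net, 3, reps = 10, seed = 42)
  expect_identical(n1$lengths, n2$lengths)
  expect_error(random_node_null(net, 50, reps = 2, seed = 1), "exceeds")
  expect_error(random_node_null(net, 1, reps = 2, seed = 1), "at least 2")
})

test_that("planted modules sit closer than the random-node null", {
  # two 8-cliques bridged by a chain: the clique is the planted module
  clique <- function(prefix) {
    ids <- paste0(prefix, 1:8)
    pairs <- utils::combn(ids, 2)
    tibble::tibble(u = pairs[1, ], v = pairs[2, ], weight = 1)
  }
  w <- dplyr::bind_rows(
    clique("a"), clique("b"),
    tibble::tibble(u = c("a1", "m"), v = c("m", "b1"), weight = 1))
  net <- prune_network(w, 0.5)
  module <- sprintf("a%d", 1:5)
  obs <- shortest_path_distribution(net, module)
  null <- random_node_null(net, 5, reps = 100, seed = 9)
  expect_lt(mean(obs$lengths), mean(null$lengths))
  kt <- ks_cluster_test(obs, null)
  expect_true(kt$clustered)
  expect_lt(kt$p, 0.01)
})

test_that("KS cluster test flags extreme separation and validates input", {
  obs <- list(lengths = rep(1L, 20), n_excluded = 0L)
  null <- list(lengths = rep(4L, 400), n_excluded = 0L)
  class(obs) <- class(null) <- "path_distribution"
  kt <- ks_cluster_test(obs, null)
  expect_lt(kt$p, 1e-6)
  expect_true(kt$clustered)
  expect_error(ks_cluster_test(list(lengths = integer(0)), null), "non-empty")
})

test_that("disease mapping associates pathways by one-sided Fisher overlap", {
  bg <- sprintf("G%03d", 1:100)
  ps <- make_ps(list(
    PW1 = bg[1:20], PW2 = bg[21:40], PW3 = bg[41:60], PW4 = bg[61:80]))
  rows <- unlist(lapply(bg[1:20], function(g) {
    disease_line("D1", "planted one", g)
  }))
  rows <- c(rows, unlist(lapply(c("X1", "X2", "X3", "X4"), function(g) {
    disease_line("D2", "no overlap", g)
  })))
  ds <- read_disease_table(rows)
  m <- map_diseases(ds, ps, bg)
  expect_identical(m$pathway[m$disease_id == "D1"], "PW1")
  expect_equal(m$p[1], 1 / choose(100, 20), tolerance = 1e-9)
  expect_identical(attr(m, "skipped"), "D2")
})

test_that("null diseases produce few associations at the nominal rate", {
  set.seed(78)
  bg <- sprintf("G%03d", 1:200)
  sets <- lapply(1:20, function(i) sample(bg, 25))
  names(sets) <- sprintf("PW%02d", 1:20)
  ps <- make_ps(sets)
  n_assoc <- 0L; n_tests <- 0L
  for (d in 1:50) {
    genes <- sample(bg, 20)
    rows <- vapply(genes, function(g) disease_line(paste0("D", d), "null", g),
                   character(1))
    m <- map_diseases(read_disease_table(rows), ps, bg, alpha = 0.01)
    n_assoc <- n_assoc + nrow(m)
    n_tests <- n_tests + length(sets)
  }
  rate <- n_assoc / n_tests
  expect_lt(rate, 0.01 + 3 * sqrt(0.01 * 0.99 / n_tests))
})

test_that("disease_module_test summarizes per-disease clustering", {
  net <- ring_network()
  mapping <- tibble::tibble(
    disease_id = c("D1", "D1", "D1", "D2"),
    pathway = c("a", "b", "c", "d"))
  out <- disease_module_test(net, mapping, reps = 20, seed = 3)
  expect_identical(out$disease_id, "D1") # D2 has < 2 nodes
  expect_equal(out$n_nodes, 3L)
  expect_equal(out$n_pairs, 3L)
  g <- glance(out)
  expect_equal(g$n_diseases, 1L)
})
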