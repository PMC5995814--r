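test_that("Wang S-values follow the decay recurrence on hand-traced chains", {
  dag <- read_obo(chain_obo())
  s_root <- wang_svalues(dag, "T:ROOT")
  expect_equal(unname(s_root["T:ROOT"]), 1)
  expect_equal(attr(s_root, "SV"), 1)

  s_a <- wang_svalues(dag, "T:A")
  expect_equal(unname(s_a[c("T:A", "T:B", "T:ROOT")]), c(1, 0.8, 0.64))
  expect_equal(attr(s_a, "SV"), 2.44)

  expect_error(wang_svalues(dag, "T:NOPE"), "unknown")
  expect_error(wang_svalues(dag, "T:A", c(is_a = 0.5, part_of = 0.7)),
               "is_a > part_of")
})

test_that("S-values equal the brute-force max-over-paths oracle", {
  # mixed-relation diamond exercises max over alternative paths
  mixed <- obo_lines(
    term_stanza("T:R"),
    term_stanza("T:B", is_a = "T:R"),
    term_stanza("T:C", is_a = "T:R"),
    term_stanza("T:A", is_a = "T:B", part_of = "T:C"))
  dag <- read_obo(mixed)
  s <- wang_svalues(dag, "T:A")
  for (t in names(s)) {
    expect_equal(unname(s[t]), oracle_svalue(dag, "T:A", t), tolerance = 1e-12)
  }
  # S_A(R) = max(0.8*0.8 via B, 0.6*0.8 via C) = 0.64
  expect_equal(unname(s["T:R"]), 0.64)

  set.seed(61)
  for (rep in 1:5) {
    rdag <- random_dag(15)
    anchor <- sample(rdag$terms$id, 1)
    sv <- wang_svalues(rdag, anchor)
    for (t in names(sv)) {
      expect_equal(unname(sv[t]), oracle_svalue(rdag, anchor, t),
                   tolerance = 1e-12)
    }
  }
})

test_that("Wang similarity matches hand values and the path oracle", {
  dag <- read_obo(diamond_obo())
  expect_equal(wang_similarity(dag, "T:A", "T:A"), 1)

  # two depth-2 leaves sharing only the root
  two_leaves <- obo_lines(
    term_stanza("T:R"),
    term_stanza("T:B1", is_a = "T:R"), term_stanza("T:B2", is_a = "T:R"),
    term_stanza("T:L1", is_a = "T:B1"), term_stanza("T:L2", is_a = "T:B2"))
  dag2 <- read_obo(two_leaves)
  expect_equal(wang_similarity(dag2, "T:L1", "T:L2"),
               (0.64 + 0.64) / (2.44 + 2.44))

  set.seed(62)
  rdag <- random_dag(12)
  ids <- rdag$terms$id
  for (rep in 1:10) {
    ab <- sample(ids, 2)
    got <- wang_similarity(rdag, ab[1], ab[2])
    expect_equal(got, oracle_wang_similarity(rdag, ab[1], ab[2]),
                 tolerance = 1e-12)
    expect_equal(got, wang_similarity(rdag, ab[2], ab[1]))
  }
})

test_that("siblings are more similar than distant cousins; chains decay", {
  eight <- obo_lines(
    term_stanza("T:R"),
    term_stanza("T:X", is_a = "T:R"), term_stanza("T:Y", is_a = "T:R"),
    term_stanza("T:X1", is_a = "T:X"), term_stanza("T:X2", is_a = "T:X"),
    term_stanza("T:Y1", is_a = "T:Y"),
    term_stanza("T:X1a", is_a = "T:X1"), term_stanza("T:Y1a", is_a = "T:Y1"))
  dag <- read_obo(eight)
  expect_gt(wang_similarity(dag, "T:X1", "T:X2"),
            wang_similarity(dag, "T:X1a", "T:Y1a"))
  # similarity decreases walking up a pure is_a chain
  chain <- read_obo(chain_obo())
  expect_gt(wang_similarity(chain, "T:A", "T:B"),
            wang_similarity(chain, "T:A", "T:ROOT"))
})

make_ic_fixture <- function() {
  # 5-term DAG with hand-assigned annotation counts
  lines <- obo_lines(
    term_stanza("T:R"),
    term_stanza("T:M1", is_a = "T:R"), term_stanza("T:M2", is_a = "T:R"),
    term_stanza("T:L1", is_a = "T:M1"), term_stanza("T:L2", is_a = "T:M2"))
  dag <- read_obo(lines)
  # direct annotations: L1 x2 genes, L2 x4, M2 x2 extra
  rows <- c(
    gaf_line("g1", "T:L1"), gaf_line("g2", "T:L1"),
    gaf_line("g3", "T:L2"), gaf_line("g4", "T:L2"),
    gaf_line("g5", "T:L2"), gaf_line("g6", "T:L2"),
    gaf_line("g7", "T:M2"), gaf_line("g8", "T:M2"))
  tab <- propagate_annotations(filter_evidence(read_gaf(rows)), dag)
  list(dag = dag, tab = tab, ic = ic_map(tab, dag))
}

test_that("information content reflects annotation frequencies", {
  fx <- make_ic_fixture()
  ic <- fx$ic
  # hand counts after propagation: R:8, M1:2, M2:6, L1:2, L2:4 of 8 genes
  expect_equal(ic$p[ic$term == "T:R"], 1)
  expect_equal(ic$ic[ic$term == "T:R"], 0)
  expect_equal(ic$p[ic$term == "T:M2"], 6 / 8)
  expect_equal(attr(ic, "max_ic"), -log(2 / 8))
  # IC non-decreasing child vs parent
  for (i in seq_len(nrow(fx$dag$edges))) {
    ch <- fx$dag$edges$child[i]; pa <- fx$dag$edges$parent[i]
    expect_gte(ic$ic[ic$term == ch], ic$ic[ic$term == pa])
  }
})

test_that("Resnik similarity is the normalized MICA information content", {
  fx <- make_ic_fixture()
  # L1 vs L2: only common ancestor is the root -> 0
  expect_equal(resnik_similarity(fx$dag, fx$ic, "T:L1", "T:L2"), 0)
  # rarest term against itself -> 1 (L1 ties max IC)
  expect_equal(resnik_similarity(fx$dag, fx$ic, "T:L1", "T:L1"), 1)
  # L2 vs M2: MICA = M2 with p=6/8, normalized by max IC
  expect_equal(resnik_similarity(fx$dag, fx$ic, "T:L2", "T:M2"),
               -log(6 / 8) / -log(2 / 8))
  expect_equal(resnik_similarity(fx$dag, fx$ic, "T:L2", "T:M2"),
               resnik_similarity(fx$dag, fx$ic, "T:M2", "T:L2"))
  expect_error(resnik_similarity(fx$dag, fx$ic, "T:L1", "T:NOPE"), "unknown")
})

test_that("Resnik scores are invariant to duplicating every gene", {
  fx <- make_ic_fixture()
  doubled <- annotation_table(dplyr::bind_rows(
    fx$tab,
    dplyr::mutate(tibble::as_tibble(fx$tab),
                  gene = paste0(.data$gene, "_copy"))),
    propagated = TRUE)
  ic2 <- ic_map(doubled, fx$dag)
  for (pair in list(c("T:L2", "T:M2"), c("T:L1", "T:M1"), c("T:L1", "T:L2"))) {
    expect_equal(resnik_similarity(fx$dag, fx$ic, pair[1], pair[2]),
                 resnik_similarity(fx$dag, ic2, pair[1], pair[2]))
  }
})

test_that("pairwise average and best-match average match their definitions", {
  tsm <- matrix(c(1, 0, 0, 1), 2, dimnames = list(c("t1", "t2"),
                                                  c("t1", "t2")))
  A <- c("t1", "t2")
  # identically annotated pathways with unrelated terms:
  expect_equal(pairwise_average(A, A, tsm), 0.5)
  expect_equal(best_match_average(A, A, tsm), 1)

  expect_equal(pairwise_average("t1", "t1", tsm), 1)
  expect_equal(best_match_average("t1", "t2", tsm), 0)

  set.seed(63)
  terms <- sprintf("x%d", 1:7)
  m <- matrix(runif(49), 7, dimnames = list(terms, terms))
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 1
  A <- terms[1:3]; B <- terms[4:7]
  vals <- outer(A, B, Vectorize(function(a, b) m[a, b]))
  expect_equal(pairwise_average(A, B, m), mean(vals))
  expect_equal(best_match_average(A, B, m),
               (sum(apply(vals, 1, max)) + sum(apply(vals, 2, max))) / 7)
  expect_equal(pairwise_average(A, B, m), pairwise_average(B, A, m))
  expect_equal(best_match_average(A, B, m), best_match_average(B, A, m))
  expect_error(pairwise_average(character(0), B, m), "non-empty")
})

test_that("BMA dominates the pairwise average and is 1 on identical sets", {
  set.seed(64)
  terms <- sprintf("x%d", 1:10)
  m <- matrix(runif(100), 10, dimnames = list(terms, terms))
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 1
  for (rep in 1:20) {
    A <- sample(terms, sample(1:5, 1))
    B <- sample(terms, sample(1:5, 1))
    expect_gte(best_match_average(A, B, m) + 1e-12,
               pairwise_average(A, B, m))
    expect_equal(best_match_average(A, A, m), 1)
    expect_lte(pairwise_average(A, A, m), 1)
  }
})

test_that("pathway similarity and the separation report use the term cache", {
  dag <- read_obo(ten_term_obo())
  minimal <- tibble::tibble(
    pathway = c("P1", "P1", "P2", "P3"),
    term = c("T:06", "T:09", "T:07", "T:05"))
  sims <- pathway_similarity(minimal, dag, method = "wang")
  expect_equal(nrow(sims), 3L)
  expect_true(all(sims$weight >= 0 & sims$weight <= 1))
  # order independence: the same pairs from a reshuffled table
  sims2 <- pathway_similarity(minimal[c(4, 2, 3, 1), ], dag, method = "wang")
  expect_equal(dplyr::arrange(sims, u, v), dplyr::arrange(sims2, u, v))

  rows <- unlist(lapply(sprintf("g%d", 1:12), function(g) {
    gaf_line(g, sample(c("T:06", "T:07", "T:08", "T:09"), 1))
  }))
  set.seed(65)
  tab <- propagate_annotations(filter_evidence(read_gaf(rows)), dag)
  rep <- separation_report(minimal, dag, ic_map(tab, dag))
  expect_s3_class(rep, "separation_report")
  expect_equal(nrow(rep$stats), 6L)
  expect_setequal(unique(rep$stats$method), c("resnik", "wang"))

  # identical profiles: within and between distributions coincide
  same <- tibble::tibble(pathway = c("A", "A", "B", "B"),
                         term = c("T:06", "T:07", "T:06", "T:07"))
  rep2 <- separation_report(same, dag, ic_map(tab, dag))
  pw <- rep2$stats[rep2$stats$level == "pairwise", ]
  expect_equal(pw$mean_within, pw$mean_between, tolerance = 1e-12)
})
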