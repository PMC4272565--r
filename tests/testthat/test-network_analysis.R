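# Hubs, betweenness centrality, annotation agreement, term co-occurrence and
# reachability.

test_that("degree ranking orders hubs with lexicographic tie-breaks", {
  leaves <- sprintf("L%d", 1:5)
  star <- interaction_graph(cbind("HUB", leaves))
  r <- degree_ranking(star, 3)
  expect_equal(r$id[1], "HUB")
  expect_equal(r$degree[1], 5)
  expect_equal(r$id[2:3], c("L1", "L2"))  # all ties at degree 1
  expect_equal(nrow(degree_ranking(star, 100)), 6)
  expect_equal(sum(graph_degrees(star)), 2 * nrow(star$edges))
})

test_that("betweenness matches hand-derived values on canonical graphs", {
  path3 <- interaction_graph(rbind(c("a", "b"), c("b", "c")))
  bc <- betweenness_centrality(path3)
  expect_equal(unname(bc[c("a", "b", "c")]), c(0, 1, 0))

  star4 <- interaction_graph(cbind("c0", c("l1", "l2", "l3", "l4")))
  expect_equal(unname(betweenness_centrality(star4)["c0"]), 6)  # C(4,2) pairs

  cyc4 <- interaction_graph(rbind(c("a", "b"), c("b", "c"), c("c", "d"),
                                  c("d", "a")))
  expect_equal(unname(betweenness_centrality(cyc4)), rep(0.5, 4))
})

test_that("betweenness matches path enumeration on every small connected graph", {
  # exhaustive over all labeled graphs with 3-5 vertices
  for (n in 3:5) {
    ids <- sprintf("v%d", seq_len(n))
    prs <- t(utils::combn(ids, 2))
    npr <- nrow(prs)
    masks <- if (n <= 4) seq_len(2^npr - 1) else {
      set.seed(123)  # n = 5: a large random subset of the 1023 graphs
      sample(seq_len(2^npr - 1), 300)
    }
    for (mask in masks) {
      sel <- bitwAnd(mask, 2^(seq_len(npr) - 1)) > 0
      g <- interaction_graph(prs[sel, , drop = FALSE], vertices = ids)
      expect_equal(betweenness_centrality(g), oracle_betweenness_paths(g))
    }
  }
})

test_that("betweenness matches the sigma-product oracle and igraph on random graphs", {
  skip_if_not_installed("igraph")
  for (s in 1:50) {
    g <- random_graph_gnp(10, 0.4, seed = 1000 + s)
    bc <- betweenness_centrality(g)
    expect_equal(bc, oracle_betweenness_sigma(g), tolerance = 1e-10)
    ig <- igraph::graph_from_edgelist(g$edges, directed = FALSE)
    bi <- igraph::betweenness(ig, directed = FALSE)
    expect_equal(unname(bc[names(bi)]), unname(bi), tolerance = 1e-10)
  }
})

ann_fixture <- function() {
  annotation_table(data.frame(
    protein_id = c("A", "A", "A", "B", "B", "B", "C", "C", "D"),
    namespace  = c("CC", "MF", "BP", "CC", "MF", "BP", "CC", "MF", "CC"),
    term       = c("nucleus", "binding", "transcription",
                   "nucleus", "binding", "transcription",
                   "membrane", "kinase", "nucleus"),
    stringsAsFactors = FALSE))
}

test_that("shared-annotation fractions respect namespace eligibility", {
  ann <- ann_fixture()
  # A-B share all three; A-C share none; A-D only CC-eligible and share
  st <- shared_annotation_stats(rbind(c("A", "B"), c("A", "C"), c("A", "D")),
                                ann)
  expect_equal(st[["CC"]], 2 / 3)       # A-B, A-D share; A-C does not
  expect_equal(st[["MF"]], 1 / 2)       # among A-B, A-C
  expect_equal(st[["BP"]], 1 / 1)       # only A-B eligible
  expect_equal(st[["all3"]], 1)         # only A-B eligible in all three
  # on a fully annotated universe the denominators coincide, so the
  # conjunction can never exceed any single-namespace fraction
  full_ann <- annotation_table(data.frame(
    protein_id = rep(c("A", "B", "C"), each = 3),
    namespace = rep(c("CC", "MF", "BP"), 3),
    term = c("n", "b", "t", "n", "b", "x", "n", "k", "t"),
    stringsAsFactors = FALSE))
  st2 <- shared_annotation_stats(rbind(c("A", "B"), c("A", "C"), c("B", "C")),
                                 full_ann)
  expect_true(all(st2[["all3"]] <= st2[c("CC", "MF", "BP")]))
})

test_that("common-neighbor fractions count third-party partners", {
  path3 <- interaction_graph(rbind(c("a", "b"), c("b", "c")))
  expect_equal(common_neighbor_fraction(rbind(c("a", "c")), path3), 1)
  expect_equal(common_neighbor_fraction(rbind(c("a", "b")), path3), 0)
  tri <- interaction_graph(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  expect_equal(common_neighbor_fraction(rbind(c("a", "b")), tri), 1)
  iso <- interaction_graph(rbind(c("a", "b")), vertices = c("a", "b", "x", "y"))
  expect_equal(common_neighbor_fraction(rbind(c("x", "y")), iso), 0)
})

test_that("term-pair co-occurrence normalizes by possible pairs and is symmetric", {
  ann <- ann_fixture()
  # CC carriers: nucleus {A,B,D}, membrane {C}
  pairs <- rbind(c("A", "B"), c("A", "C"))
  m <- term_pair_cooccurrence(pairs, ann, "CC")
  expect_equal(m["nucleus", "nucleus"], 1 / 3)   # 1 observed / C(3,2) possible
  expect_equal(m["nucleus", "membrane"], 1 / 3)  # 1 observed / 3*1 possible
  expect_equal(m, t(m))
  # all possible pairs observed -> entry 1
  m2 <- term_pair_cooccurrence(rbind(c("A", "B"), c("A", "D"), c("B", "D")),
                               ann, "CC")
  expect_equal(m2["nucleus", "nucleus"], 1)
  # no pairs -> all zero (where defined)
  m0 <- term_pair_cooccurrence(pairs[0, , drop = FALSE], ann, "CC")
  expect_true(all(m0 == 0, na.rm = TRUE))
})

test_that("reachability grows with the intermediary allowance", {
  chain <- interaction_graph(rbind(c("bait", "x"), c("x", "y"), c("y", "prey")))
  r0 <- reachability_overlap("bait", "prey", chain, max_intermediaries = 0)
  expect_equal(r0$reachable, "x")
  expect_equal(r0$recall, 0)
  r1 <- reachability_overlap("bait", "prey", chain, max_intermediaries = 1)
  expect_equal(r1$recall, 0)
  r2 <- reachability_overlap("bait", "prey", chain, max_intermediaries = 2)
  expect_equal(r2$recall, 1)
  expect_true(all(r0$reachable %in% r1$reachable),
              all(r1$reachable %in% r2$reachable))
  # bait adjacent to every prey: recall 1, precision |prey|/|reachable|
  star <- interaction_graph(cbind("bait", c("p1", "p2", "q")))
  rs <- reachability_overlap("bait", c("p1", "p2"), star, 0)
  expect_equal(rs$recall, 1)
  expect_equal(rs$precision, 2 / 3)
  expect_true(is.na(reachability_overlap("bait", character(0), star)$recall))
})
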