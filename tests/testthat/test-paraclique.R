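# Maximal cliques, merge/glom stages, the full decomposition, and enrichment.

test_that("maximal cliques are exact on canonical graphs", {
  tri <- interaction_graph(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  cs <- maximal_cliques(tri, 3)
  expect_equal(cs$clusters, list(c("a", "b", "c")))

  # K4 minus one edge: two triangles
  k4m <- interaction_graph(rbind(c("a", "b"), c("a", "c"), c("a", "d"),
                                 c("b", "c"), c("c", "d")))
  cs2 <- maximal_cliques(k4m, 3)
  expect_equal(cs2$clusters, list(c("a", "b", "c"), c("a", "c", "d")))

  # edgeless graph has no cliques of size >= 3
  empty <- interaction_graph(matrix(character(0), 0, 2),
                             vertices = c("a", "b"))
  expect_length(maximal_cliques(empty, 3), 0)
})

test_that("maximal cliques match exhaustive subset enumeration on random graphs", {
  for (s in 1:30) {
    g <- random_graph_gnp(10, 0.5, seed = 3000 + s)
    for (ms in c(1, 3)) {
      got <- maximal_cliques(g, ms)$clusters
      want <- oracle_maximal_cliques(g, ms)
      expect_identical(got, want)
    }
  }
})

test_that("overlap proportion uses the smaller cluster as denominator", {
  expect_equal(overlap_proportion(c("a", "b", "c"), c("a", "b", "c")), 1)
  expect_equal(overlap_proportion(c("a", "b"), c("x", "y")), 0)
  expect_equal(overlap_proportion(c("a", "b", "c"), c("b", "c", "d")), 2 / 3)
  expect_equal(overlap_proportion(c("a", "b"), c("a", "b", "c", "d")), 1)
  expect_equal(overlap_proportion(c("a", "b", "c"), c("b", "c", "d"),
                                  method = "jaccard"), 1 / 2)
})

test_that("merge steps act only above the threshold and union the best pair", {
  cl <- list(c("a", "b", "c"), c("b", "c", "d"), c("x", "y", "z"))
  r1 <- merge_step(cl, m = 0.5)
  expect_true(r1$merged)
  expect_equal(r1$clusters$clusters[[r1$new_index]], c("a", "b", "c", "d"))
  expect_length(r1$clusters, 2)
  r2 <- merge_step(cl, m = 0.7)     # 2/3 overlap is not > 0.7
  expect_false(r2$merged)
  expect_length(r2$clusters, 3)
  r3 <- merge_step(list(c("a", "b")), m = 0.1)
  expect_false(r3$merged)
})

test_that("approximate merging honors its inclusive threshold and stop count", {
  cl <- list(c("a", "b", "c"), c("x", "y", "z"), c("p", "q", "r"))
  expect_equal(approx_merge(cl, a = 0.5)$clusters, lapply(cl, sort))
  same <- rep(list(c("m", "n", "o")), 5)
  # identical clusters dedup to one on construction, so build shifted copies
  shifted <- list(c("a", "b", "c"), c("b", "c", "d"), c("c", "d", "e"),
                  c("d", "e", "f"), c("e", "f", "g"))
  merged <- approx_merge(shifted, a = 2 / 3, stop_count = 2)
  expect_length(merged, 2)
  all_merged <- approx_merge(shifted, a = 2 / 3, stop_count = 1)
  expect_gte(length(all_merged), 1)
  # inclusive >= : overlap exactly a merges
  two <- list(c("a", "b", "c"), c("b", "c", "d"))
  expect_length(approx_merge(two, a = 2 / 3), 1)
})

test_that("glom absorbs vertices above the connectivity proportion, strictly", {
  g <- interaction_graph(rbind(c("a", "b"), c("b", "c"), c("a", "c"),
                               c("v", "a"), c("v", "b"),
                               c("w", "a")))
  # v is adjacent to 2/3 of {a,b,c}, w to 1/3
  expect_equal(glom_step(c("a", "b", "c"), g, 0.5), c("a", "b", "c", "v"))
  expect_equal(glom_step(c("a", "b", "c"), g, 2 / 3), c("a", "b", "c"))
  # g = 1 can never absorb (strict >)
  full <- interaction_graph(rbind(c("z", "a"), c("z", "b"), c("z", "c"),
                                  c("a", "b"), c("b", "c"), c("a", "c")))
  expect_equal(glom_step(c("a", "b", "c"), full, 1), c("a", "b", "c"))
  expect_equal(glom_step(c("a", "b", "c"), full, 0.99),
               c("a", "b", "c", "z"))
})

test_that("decomposition recovers disjoint triangles exactly and reaches a fixed point", {
  tris <- rbind(c("a1", "a2"), c("a2", "a3"), c("a1", "a3"),
                c("b1", "b2"), c("b2", "b3"), c("b1", "b3"),
                c("c1", "c2"), c("c2", "c3"), c("c1", "c3"))
  g <- interaction_graph(tris)
  cs <- decompose(g, paraclique_params(m = 0.5, g = 0.5))
  expect_length(cs, 3)
  expect_setequal(vapply(cs$clusters, paste, "", collapse = ","),
                  c("a1,a2,a3", "b1,b2,b3", "c1,c2,c3"))
  # fixed point: a further merge step changes nothing
  again <- merge_step(cs, m = 0.5)
  expect_false(again$merged)
  # empty-edge graph yields an empty decomposition
  e <- interaction_graph(matrix(character(0), 0, 2), vertices = c("u", "v"))
  expect_length(decompose(e), 0)
})

test_that("decomposition recovers planted communities", {
  for (s in 1:3) {
    sim <- gen_clustered_graph(2, 8, p_in = 0.9, p_out = 0.05, seed = 500 + s)
    cs <- decompose(sim$graph, paraclique_params(m = 0.5, g = 0.5))
    comm <- split(names(sim$truth$communities), sim$truth$communities)
    for (cm in comm) {
      best <- max(vapply(cs$clusters, function(cl) {
        length(intersect(cl, cm)) / length(cm)
      }, numeric(1)))
      expect_gte(best, 0.9)
    }
  }
})

test_that("approximate merging never under-merges relative to exact merging", {
  set.seed(99)
  cl <- lapply(1:8, function(i) {
    sort(sample(sprintf("v%02d", 1:14), 5))
  })
  exact <- cl
  repeat {
    st <- merge_step(exact, m = 0.5)
    if (!st$merged) break
    exact <- st$clusters$clusters
  }
  approx <- approx_merge(cl, a = 0.5, stop_count = 1)
  expect_lte(length(approx), length(exact))
})

test_that("cluster enrichment reproduces the closed-form hypergeometric tail", {
  ann <- stats::setNames(rep(list("T"), 3), c("p1", "p2", "p3"))
  bg <- sprintf("p%d", 1:20)
  e <- cluster_enrichment(c("p1", "p2", "p3"), ann, bg)
  expect_equal(e$p[e$term == "T"], 1 / 1140)  # C(3,3)C(17,0)/C(20,3)
  # cluster = background: every term has P = 1
  e2 <- cluster_enrichment(bg, c(ann, stats::setNames(list("U"), "p5")), bg)
  expect_true(all(e2$p == 1))
  # unannotated cluster: empty result
  e3 <- cluster_enrichment(c("p10", "p11"), ann, bg)
  expect_equal(nrow(e3), 0)
  expect_error(cluster_enrichment(c("zz"), ann, bg), "background")
})
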