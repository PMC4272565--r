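# The PIPE engine: windows, fragment similarity, candidate expansion,
# landscapes, the modified median filter, scores and decisions.

test_that("window enumeration covers every offset exactly once", {
  wins <- enumerate_windows("ACDEFG", 3)
  expect_equal(wins$start, 0:3)
  expect_equal(wins$fragment, c("ACD", "CDE", "DEF", "EFG"))
  expect_equal(nrow(enumerate_windows("ACD", 3)), 1)
  expect_warning(w0 <- enumerate_windows("AC", 3), "shorter")
  expect_equal(nrow(w0), 0)
})

test_that("window scores are sums of matrix entries and symmetric", {
  S <- PAM120
  expect_equal(window_score("AAA", "AAA", S), 3L * subst_score(S, "A", "A"))
  expect_equal(window_score("A", "R", S), -3L)  # read from the matrix
  set.seed(42)
  for (i in 1:20) {
    f <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 6, TRUE),
               collapse = "")
    g <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 6, TRUE),
               collapse = "")
    expect_equal(window_score(f, g, S), window_score(g, f, S))
    expect_equal(window_score(f, g, S), oracle_window_score(f, g, S))
  }
  expect_error(window_score("AC", "ACD", S), "length")
})

test_that("match positions agree with brute-force rescoring of every offset", {
  S <- PAM120
  set.seed(7)
  for (i in 1:10) {
    frag <- paste(sample(.canonical(), 5, TRUE), collapse = "")
    prot <- paste(sample(.canonical(), 40, TRUE), collapse = "")
    for (theta in c(-10L, 0L, 10L)) {
      expect_equal(protein_match_positions(frag, prot, S, theta),
                   oracle_match_starts(frag, prot, theta, S))
    }
  }
  # fragment planted uniquely, threshold below self-score
  prot <- paste0(paste(rep("A", 10), collapse = ""), "WWWWW",
                 paste(rep("A", 10), collapse = ""))
  self <- window_score("WWWWW", "WWWWW", S)
  expect_true(10 %in% protein_match_positions("WWWWW", prot, S, self - 1L))
  # an unattainably large threshold yields no matches
  expect_length(protein_match_positions("WWWWW", prot, S, 10000L), 0)
})

test_that("candidate lists union the neighbors of matching proteins", {
  S <- PAM120
  # X1 and X2 contain the probe motif; isolated protein Z also contains it
  prot <- proteome(c("X1", "X2", "Y", "W", "Z"),
                   c("AAAAAWWWWWCCCCC", "CCCCCWWWWWAAAAA",
                     "DDDDDDDDDDDDDDD", "EEEEEEEEEEEEEEE",
                     "WWWWWDDDDDDDDDD"))
  g <- interaction_graph(rbind(c("X1", "Y"), c("X2", "Y"), c("X2", "W")),
                         vertices = prot$ids)
  theta <- window_score("WWWWW", "WWWWW", S) - 1L
  expect_equal(candidate_neighbors("WWWWW", prot, g, S, theta), c("W", "Y"))
  # a fragment found only in an isolated protein contributes nothing
  g2 <- interaction_graph(rbind(c("Y", "W")), vertices = prot$ids)
  expect_length(candidate_neighbors("WWWWW", prot, g2, S, theta), 0)
})

test_that("landscapes match the brute-force triple loop, both count modes", {
  set.seed(101)
  for (trial in 1:4) {
    prot <- gen_proteome(6, c(22, 30), seed = 100 + trial)
    ids <- prot$ids
    g <- random_graph_gnp(6, 0.5, seed = 200 + trial)
    # rename gnp vertices onto the proteome ids
    edges <- matrix(ids[match(as.vector(g$edges), g$vertices)], ncol = 2)
    g <- interaction_graph(edges, vertices = ids)
    theta <- if (trial %% 2 == 0) 2L else 8L
    for (mode in c("per_edge", "per_occurrence")) {
      params <- pipe_params(w = 4, theta_sim = theta, count_mode = mode)
      H <- build_landscape(ids[1], ids[2], prot, g, params)
      expect_false(H$skipped)
      expect_identical(
        H$H, oracle_landscape(ids[1], ids[2], prot, g, 4, theta, mode))
    }
  }
})

test_that("per-edge landscapes transpose under query swap and stay bounded", {
  prot <- gen_proteome(8, c(25, 35), seed = 5)
  db <- random_graph_gnp(8, 0.5, seed = 6)
  edges <- matrix(prot$ids[match(as.vector(db$edges), db$vertices)], ncol = 2)
  g <- interaction_graph(edges, vertices = prot$ids)
  params <- pipe_params(w = 4, theta_sim = 6)
  H_ab <- build_landscape(prot$ids[1], prot$ids[2], prot, g, params)
  H_ba <- build_landscape(prot$ids[2], prot$ids[1], prot, g, params)
  expect_identical(H_ab$H, t(H_ba$H))
  # both orientations of each edge are considered, so 2|E| bounds every cell
  expect_true(all(H_ab$H <= 2 * nrow(g$edges)))
  # with no edges the landscape is identically zero
  g0 <- interaction_graph(matrix(character(0), 0, 2), vertices = prot$ids)
  expect_true(all(build_landscape(prot$ids[1], prot$ids[2], prot, g0,
                                  params)$H == 0))
})

test_that("lowering the similarity threshold or adding edges never shrinks cells", {
  prot <- gen_proteome(6, c(25, 30), seed = 9)
  db <- random_graph_gnp(6, 0.6, seed = 10)
  edges <- matrix(prot$ids[match(as.vector(db$edges), db$vertices)], ncol = 2)
  g <- interaction_graph(edges, vertices = prot$ids)
  H_hi <- build_landscape(prot$ids[1], prot$ids[2], prot, g,
                          pipe_params(w = 4, theta_sim = 10))$H
  H_lo <- build_landscape(prot$ids[1], prot$ids[2], prot, g,
                          pipe_params(w = 4, theta_sim = 2))$H
  expect_true(all(H_lo >= H_hi))
  e <- g$edges[1, ]
  H_less <- build_landscape(prot$ids[1], prot$ids[2], prot,
                            remove_edge(g, e[1], e[2]),
                            pipe_params(w = 4, theta_sim = 10))$H
  expect_true(all(H_less <= H_hi))
})

test_that("the modified median filter applies a strict neighbor majority", {
  expect_true(all(median_filter(matrix(0, 5, 5)) == 0))
  expect_true(all(median_filter(matrix(7, 5, 5)) == 1))
  # a single positive cell convinces no neighborhood
  H <- matrix(0, 5, 5); H[3, 3] <- 10
  expect_true(all(median_filter(H, 1) == 0))
  # corner cell: all 3 in-bounds neighbors positive -> strict majority -> 1
  H2 <- rbind(c(0, 1, 0), c(1, 1, 0), c(0, 0, 0))
  F2 <- median_filter(H2, 1)
  expect_equal(F2[1, 1], 1L)
  expect_true(all(F2 %in% c(0L, 1L)))
})

test_that("scores are cell means and decisions use a strict threshold", {
  expect_equal(pipe_score(matrix(1, 3, 3)), 1)
  expect_equal(pipe_score(matrix(0, 3, 3)), 0)
  expect_equal(pipe_score(matrix(c(1, 0), 4, 4)), 0.5)
  expect_equal(pipe_score(matrix(0, 0, 0)), 0)

  prot <- gen_proteome(6, c(30, 30), seed = 20)
  db <- plant_interactions(prot, n_motif_pairs = 1, motif_len = 6,
                           n_edges = 4, seed = 21, block = c(2, 2))
  params1 <- pipe_params(w = 6, theta_sim = 20, theta_dec = 1.0)
  e <- db$graph$edges[1, ]
  p <- predict_pair(e[1], e[2], db$proteome, db$graph, params1)
  expect_false(p$interacts)  # score <= 1 and the comparison is strict
  # identical inputs give identical predictions
  p2 <- predict_pair(e[1], e[2], db$proteome, db$graph, params1)
  expect_equal(p$score, p2$score)
})

test_that("short queries are skipped with a zero, non-interacting sentinel", {
  prot <- proteome(c("S1", "S2", "L1"), c("ACD", "WYH", "ACDEFGHIKL"))
  g <- interaction_graph(rbind(c("S1", "L1")), vertices = prot$ids)
  params <- pipe_params(w = 5, theta_sim = 10)
  expect_warning(p <- predict_pair("S1", "S2", prot, g, params), "skipped")
  expect_true(p$skipped)
  expect_equal(p$score, 0)
  expect_false(p$interacts)
})
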