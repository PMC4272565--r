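# Seeded generators: random proteomes, motif-planted interaction databases,
# labeled benchmark pairs, and planted-partition graphs. Every generator is a
# pure function of its arguments including the seed.

#' Generate a random proteome
#'
#' Residues are drawn i.i.d. uniformly over the 20 canonical amino-acid
#' letters (the simplest null model; no composition bias), lengths uniformly
#' over `length_range`. Ids follow the pattern `SYN00001, SYN00002, ...`.
#'
#' @param n Number of proteins.
#' @param length_range Integer vector `c(min, max)` of sequence lengths
#'   (default `c(100, 150)`).
#' @param seed Integer seed.
#' @return A [proteome].
#' @export
gen_proteome <- function(n, length_range = c(100L, 150L), seed) {
  stopifnot(n >= 1, length(length_range) == 2, length_range[1] >= 1)
  .with_seed(seed, {
    lens <- length_range[1] +
      sample.int(length_range[2] - length_range[1] + 1L, n, replace = TRUE) - 1L
    seqs <- vapply(lens, function(L) {
      paste(sample(.CANONICAL_AA, L, replace = TRUE), collapse = "")
    }, character(1))
    proteome(sprintf("SYN%05d", seq_len(n)), seqs)
  })
}

#' Plant a motif-mediated interaction database into a proteome
#'
#' Emulates the premise that a subset of physical interactions is mediated
#' by short linear sequence motifs. `n_motif_pairs` motif pairs
#' `(motif_s, motif_t)` are drawn at random; each is planted as a complete
#' bipartite block of interactions: `block[1]` proteins receive `motif_s`
#' and `block[2]` proteins receive `motif_t` (overwritten at a random
#' position, so lengths are unchanged), and *all* s-side x t-side pairs
#' become true edges. Planting whole blocks keeps the ground truth coherent:
#' a pair of proteins carries a complementary motif pair if and only if it
#' is a true edge, so sampled negatives never contain hidden positives, and
#' each edge retains co-occurrence support from its block under
#' leave-one-out removal.
#'
#' Proteins are assigned to at most one block (sampled without replacement),
#' so `n_motif_pairs * sum(block)` must not exceed the proteome size.
#'
#' @param proteome A [proteome] (e.g. from [gen_proteome()]).
#' @param n_motif_pairs Number of motif pairs / bipartite blocks (default 10).
#' @param motif_len Motif length in residues; downstream prediction expects
#'   this to equal the window length `w` (default 20).
#' @param n_edges Total number of true edges; must equal
#'   `n_motif_pairs * block[1] * block[2]` (default 40).
#' @param seed Integer seed.
#' @param block Bipartite block shape `c(n_s, n_t)` (default `c(2, 2)`,
#'   i.e. 4 edges per motif pair).
#' @return List with elements `proteome` (motifs planted), `graph` (an
#'   [interaction_graph] of exactly the true edges) and `truth` (list:
#'   `motifs` data frame, `edges`, `positions` data frame of planted
#'   occurrences).
#' @export
plant_interactions <- function(proteome, n_motif_pairs = 10L, motif_len = 20L,
                               n_edges = 40L, seed, block = c(2L, 2L)) {
  stopifnot(inherits(proteome, "proteome"))
  min_len <- min(nchar(proteome$seqs))
  if (motif_len > min_len) stop("motif_len exceeds the shortest protein")
  if (n_edges != n_motif_pairs * block[1] * block[2]) {
    stop("n_edges must equal n_motif_pairs * block[1] * block[2] (= ",
         n_motif_pairs * block[1] * block[2], ")")
  }
  slots <- n_motif_pairs * sum(block)
  if (slots > length(proteome$ids)) {
    stop("need ", slots, " proteins for ", n_motif_pairs,
         " blocks but the proteome has ", length(proteome$ids))
  }
  if (n_edges > choose(length(proteome$ids), 2)) {
    stop("more edges requested than protein pairs available")
  }
  .with_seed(seed, {
    seqs <- proteome$seqs
    carriers <- sample(proteome$ids, slots)
    motifs <- data.frame(
      pair = seq_len(n_motif_pairs),
      motif_s = vapply(seq_len(n_motif_pairs), function(i)
        paste(sample(.CANONICAL_AA, motif_len, replace = TRUE), collapse = ""),
        character(1)),
      motif_t = vapply(seq_len(n_motif_pairs), function(i)
        paste(sample(.CANONICAL_AA, motif_len, replace = TRUE), collapse = ""),
        character(1)),
      stringsAsFactors = FALSE)
    edges <- NULL
    positions <- NULL
    k <- 0
    for (p in seq_len(n_motif_pairs)) {
      s_ids <- carriers[k + seq_len(block[1])]; k <- k + block[1]
      t_ids <- carriers[k + seq_len(block[2])]; k <- k + block[2]
      for (id in s_ids) {
        pos <- sample.int(nchar(seqs[[id]]) - motif_len + 1L, 1)
        substr(seqs[[id]], pos, pos + motif_len - 1L) <- motifs$motif_s[p]
        positions <- rbind(positions,
                           data.frame(id = id, pair = p, side = "s", start = pos))
      }
      for (id in t_ids) {
        pos <- sample.int(nchar(seqs[[id]]) - motif_len + 1L, 1)
        substr(seqs[[id]], pos, pos + motif_len - 1L) <- motifs$motif_t[p]
        positions <- rbind(positions,
                           data.frame(id = id, pair = p, side = "t", start = pos))
      }
      edges <- rbind(edges, as.matrix(expand.grid(id_a = s_ids, id_b = t_ids,
                                                  stringsAsFactors = FALSE)))
    }
    prot2 <- proteome(proteome$ids, seqs)
    graph <- if (is.null(edges)) {
      interaction_graph(matrix(character(0), 0, 2), vertices = proteome$ids)
    } else {
      interaction_graph(edges, vertices = proteome$ids)
    }
    list(proteome = prot2, graph = graph,
         truth = list(motifs = motifs, edges = edges, positions = positions))
  })
}

#' Build a labeled benchmark from a planted database
#'
#' Positives are a seeded sample of the true edges (`holdout_fraction` of
#' them); negatives are drawn by [sample_negatives()] and are therefore
#' disjoint from the edge set.
#'
#' @param graph An [interaction_graph] of true edges.
#' @param proteome The matching [proteome].
#' @param holdout_fraction Fraction of edges used as positives, in `(0, 1]`.
#' @param n_negatives Number of negative pairs.
#' @param seed Integer seed.
#' @return List with `positives` and `negatives` (two-column matrices).
#' @export
gen_benchmark <- function(graph, proteome, holdout_fraction = 1, n_negatives,
                          seed) {
  stopifnot(holdout_fraction > 0, holdout_fraction <= 1)
  n_hold <- max(1L, round(holdout_fraction * nrow(graph$edges)))
  positives <- .with_seed(seed, {
    graph$edges[sample.int(nrow(graph$edges), n_hold), , drop = FALSE]
  })
  negatives <- sample_negatives(proteome, graph, n_negatives, seed = seed + 1L)
  list(positives = positives, negatives = negatives)
}

#' Generate a planted-partition (community) graph
#'
#' Vertices are split into `k_communities` blocks of the given sizes; each
#' within-community pair becomes an edge with probability `p_in`, each
#' between-community pair with probability `p_out`.
#'
#' @param k_communities Number of communities.
#' @param sizes Integer vector of community sizes (recycled to length
#'   `k_communities`).
#' @param p_in,p_out Edge probabilities, `0 <= p_out < p_in <= 1`.
#' @param seed Integer seed.
#' @return List with `graph` (an [interaction_graph]) and `truth` (list with
#'   `communities`: named membership vector id -> community index).
#' @export
gen_clustered_graph <- function(k_communities, sizes, p_in, p_out, seed) {
  stopifnot(p_out >= 0, p_out < p_in, p_in <= 1)
  sizes <- rep_len(sizes, k_communities)
  n <- sum(sizes)
  ids <- sprintf("V%04d", seq_len(n))
  membership <- rep(seq_len(k_communities), sizes)
  names(membership) <- ids
  .with_seed(seed, {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    same <- membership[pairs[, 1]] == membership[pairs[, 2]]
    p <- ifelse(same, p_in, p_out)
    keep <- runif(nrow(pairs)) < p
    edges <- cbind(ids[pairs[keep, 1]], ids[pairs[keep, 2]])
    graph <- interaction_graph(edges, vertices = ids)
    list(graph = graph, truth = list(communities = membership))
  })
}
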