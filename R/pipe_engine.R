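# The sequential PIPE algorithm: sliding windows, PAM120 fragment similarity,
# candidate-neighbor expansion, the co-occurrence landscape H, the modified
# median filter, and the per-pair score/decision.

#' Parameters of the PIPE engine
#'
#' @param w Window (fragment) length in residues. Default 20, the value used
#'   throughout the PIPE lineage.
#' @param theta_sim Integer similarity threshold: two windows "match" when
#'   their summed PAM120 score is strictly greater than this. Default 35.
#' @param filter_radius Moore-neighborhood radius of the modified median
#'   filter, in cells. Default 1 (the 3x3 neighborhood).
#' @param theta_dec Decision threshold on the mean filtered cell value; a
#'   pair is called interacting when its score is strictly greater. In
#'   practice the threshold is chosen at an operating point (see
#'   [operating_point()]); the default 0.005 is a conservative standalone
#'   value.
#' @param count_mode `"per_edge"` (default): a landscape cell counts the
#'   number of database edges across which the two fragments co-occur.
#'   `"per_occurrence"`: every pair of matching windows contributes 1,
#'   retained for sensitivity analysis.
#' @param allow_self Allow homodimer pairs/edges (default FALSE).
#' @param submat A [load_substitution_matrix()] result; defaults to the
#'   bundled PAM120.
#' @return An object of class `pipe_params`.
#' @export
pipe_params <- function(w = 20L, theta_sim = 35L, filter_radius = 1L,
                        theta_dec = 0.005, count_mode = c("per_edge", "per_occurrence"),
                        allow_self = FALSE, submat = NULL) {
  count_mode <- match.arg(count_mode)
  stopifnot(w >= 1, filter_radius >= 1, theta_dec >= 0, theta_dec <= 1)
  if (is.null(submat)) submat <- load_substitution_matrix("PAM120")
  structure(list(w = as.integer(w), theta_sim = as.integer(theta_sim),
                 filter_radius = as.integer(filter_radius),
                 theta_dec = theta_dec, count_mode = count_mode,
                 allow_self = isTRUE(allow_self), submat = submat),
            class = "pipe_params")
}

#' Enumerate overlapping sequence windows
#'
#' Splits a sequence into its `|s| - w + 1` overlapping length-`w` fragments.
#'
#' @param sequence Amino-acid sequence (character scalar).
#' @param w Window length.
#' @return Data frame with columns `start` (0-based offset) and `fragment`.
#'   Empty (with a warning) when the sequence is shorter than `w`.
#' @examples
#' enumerate_windows("ACDEFG", 3)
#' @export
enumerate_windows <- function(sequence, w) {
  sequence <- toupper(sequence)
  n <- nchar(sequence) - w + 1
  if (n < 1) {
    warning("sequence shorter than window length ", w, "; no windows")
    return(data.frame(start = integer(0), fragment = character(0)))
  }
  starts <- seq_len(n) - 1L
  data.frame(start = starts,
             fragment = substring(sequence, starts + 1L, starts + w),
             stringsAsFactors = FALSE)
}

#' Score a pair of equal-length fragments
#'
#' Sum of substitution-matrix scores over aligned positions; symmetric in
#' its fragment arguments because the matrix is symmetric.
#'
#' @param frag1,frag2 Equal-length amino-acid fragments.
#' @param S A [load_substitution_matrix()] result.
#' @return Integer score.
#' @export
window_score <- function(frag1, frag2, S) {
  if (nchar(frag1) != nchar(frag2)) {
    stop("fragments differ in length (", nchar(frag1), " vs ", nchar(frag2), ")")
  }
  window_score_cpp(encode_sequence(toupper(frag1)),
                   encode_sequence(toupper(frag2)), S$full)
}

#' Window starts of a protein matching a query fragment
#'
#' @param fragment Query fragment.
#' @param protein Protein sequence (character scalar) or a proteome record
#'   given as `list(id =, sequence =)`.
#' @param S Substitution matrix.
#' @param theta_sim Similarity threshold (strict `>`).
#' @return Integer vector of 0-based window starts in the protein whose
#'   windows score above `theta_sim` against the fragment; empty when the
#'   protein is shorter than the fragment.
#' @export
protein_match_positions <- function(fragment, protein, S, theta_sim) {
  seqc <- if (is.list(protein)) protein$sequence else protein
  seqc <- toupper(seqc)
  w <- nchar(fragment)
  n <- nchar(seqc) - w + 1
  if (n < 1) return(integer(0))
  fenc <- encode_sequence(toupper(fragment))
  penc <- encode_sequence(seqc)
  scores <- vapply(seq_len(n), function(s) {
    window_score_cpp(fenc, penc[s:(s + w - 1)], S$full)
  }, integer(1))
  which(scores > theta_sim) - 1L
}

#' Candidate neighbor set for one query fragment
#'
#' For each database protein containing a window similar to the fragment,
#' all of that protein's graph neighbors are collected; the union is the
#' candidate list R for this fragment. The list is computed fresh per
#' fragment.
#'
#' @param fragment Query fragment.
#' @param proteome A [proteome].
#' @param graph An [interaction_graph] over (a subset of) the proteome ids.
#' @param S Substitution matrix.
#' @param theta_sim Similarity threshold.
#' @return Character vector of candidate protein ids (possibly empty).
#' @export
candidate_neighbors <- function(fragment, proteome, graph, S, theta_sim) {
  unmatched <- setdiff(graph$vertices, proteome$ids)
  if (length(unmatched) > 0) {
    warning(length(unmatched), " graph vertex/vertices absent from the proteome; skipped")
  }
  w <- nchar(fragment)
  fenc <- encode_sequence(toupper(fragment))
  ids <- intersect(proteome$ids, names(which(graph_degrees(graph) > 0)))
  hits <- vapply(ids, function(id) {
    enc <- proteome$enc[[id]]
    if (length(enc) < w) return(FALSE)
    cnt <- match_count_table_cpp(fenc, w, list(enc), S$full, S_theta(theta_sim))
    any(cnt > 0)
  }, logical(1))
  sort(unique(unlist(graph$adjacency[ids[hits]], use.names = FALSE)))
}

# integer coercion guard for thresholds passed to compiled code
S_theta <- function(theta_sim) as.integer(theta_sim)

# Resolve a query argument (proteome id or list(id=, sequence=)) to an
# encoded record.
.resolve_query <- function(x, proteome) {
  if (is.character(x) && length(x) == 1) {
    if (!(x %in% proteome$ids)) stop("query id '", x, "' not in proteome")
    return(list(id = x, enc = proteome$enc[[x]]))
  }
  if (is.list(x) && !is.null(x$sequence)) {
    id <- if (!is.null(x$id)) x$id else "query"
    sq <- toupper(x$sequence)
    .check_residues(sq, id)
    return(list(id = id, enc = encode_sequence(sq)))
  }
  stop("query must be a proteome id or list(id =, sequence =)")
}

#' Build the co-occurrence landscape of a query pair
#'
#' The result matrix H has one row per window of A and one column per window
#' of B. In `per_edge` mode, cell (i, j) counts the undirected database edges
#' (X, Y) such that fragment a_i matches some window of X and fragment b_j
#' matches some window of Y; both orientations of every edge are considered,
#' which makes `H(A, B) = t(H(B, A))`. In `per_occurrence` mode every pair of
#' matching windows contributes 1 (so a cell sums, over edges, the product of
#' matching-window counts at the two endpoints).
#'
#' In a leave-one-out context the caller must have removed the edge (A, B)
#' from the graph first; see [loo_scores()].
#'
#' @param A,B Query proteins: proteome ids or `list(id =, sequence =)`.
#' @param proteome A [proteome] (the database sequences).
#' @param graph An [interaction_graph] of known interactions.
#' @param params A [pipe_params] object.
#' @return An object of class `result_matrix`: list with the integer matrix
#'   `H`, `id_a`, `id_b`, `w`, and a `skipped` flag (TRUE with an empty `H`
#'   when a query is shorter than `w`).
#' @export
build_landscape <- function(A, B, proteome, graph, params) {
  stopifnot(inherits(params, "pipe_params"))
  qa <- .resolve_query(A, proteome)
  qb <- .resolve_query(B, proteome)
  w <- params$w
  empty <- structure(list(H = matrix(0L, 0, 0), id_a = qa$id, id_b = qb$id,
                          w = w, skipped = TRUE), class = "result_matrix")
  if (length(qa$enc) < w || length(qb$enc) < w) {
    warning("query shorter than window length; pair (", qa$id, ", ", qb$id,
            ") skipped")
    return(empty)
  }
  na <- length(qa$enc) - w + 1L
  nb <- length(qb$enc) - w + 1L
  H <- matrix(0L, na, nb)

  edges <- graph$edges
  in_prot <- edges[, 1] %in% proteome$ids & edges[, 2] %in% proteome$ids
  if (any(!in_prot)) {
    warning(sum(!in_prot), " edge(s) with vertices absent from the proteome skipped")
    edges <- edges[in_prot, , drop = FALSE]
  }
  if (nrow(edges) > 0) {
    Smat <- params$submat$full
    cntA <- match_count_table_cpp(qa$enc, w, proteome$enc, Smat, params$theta_sim)
    cntB <- match_count_table_cpp(qb$enc, w, proteome$enc, Smat, params$theta_sim)
    if (params$count_mode == "per_edge") {
      cntA <- (cntA > 0) + 0
      cntB <- (cntB > 0) + 0
    } else {
      storage.mode(cntA) <- "double"
      storage.mode(cntB) <- "double"
    }
    e1 <- match(edges[, 1], proteome$ids)
    e2 <- match(edges[, 2], proteome$ids)
    hetero <- e1 != e2
    if (any(hetero)) {
      h1 <- e1[hetero]; h2 <- e2[hetero]
      H <- H + cntA[, h1, drop = FALSE] %*% t(cntB[, h2, drop = FALSE]) +
        cntA[, h2, drop = FALSE] %*% t(cntB[, h1, drop = FALSE])
    }
    if (any(!hetero)) {  # homodimer edges: the two orientations coincide
      s1 <- e1[!hetero]
      H <- H + cntA[, s1, drop = FALSE] %*% t(cntB[, s1, drop = FALSE])
    }
    storage.mode(H) <- "integer"
  }
  structure(list(H = H, id_a = qa$id, id_b = qb$id, w = w, skipped = FALSE),
            class = "result_matrix")
}

#' @export
print.result_matrix <- function(x, ...) {
  cat("result_matrix (", x$id_a, " x ", x$id_b, "): ",
      nrow(x$H), " x ", ncol(x$H), " windows of w = ", x$w,
      if (x$skipped) " [skipped]", "\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.result_matrix <- function(x, ...) x$H

#' Modified median filter of a landscape
#'
#' Sets a cell to 1 when strictly more than half of its in-bounds Moore
#' neighbors (the `(2 radius + 1)^2 - 1` surrounding cells, center excluded)
#' hold a value greater than zero, and to 0 otherwise. Border cells are
#' judged against their in-bounds neighbors only.
#'
#' @param H A `result_matrix` or a plain numeric matrix.
#' @param radius Neighborhood radius in cells (default 1).
#' @return Binary integer matrix of the same shape.
#' @export
median_filter <- function(H, radius = 1L) {
  m <- if (inherits(H, "result_matrix")) H$H else H
  if (length(m) == 0) return(matrix(0L, nrow(m), ncol(m)))
  stopifnot(radius >= 1)
  P <- m > 0
  nr <- nrow(P); nc <- ncol(P)
  pos <- matrix(0L, nr, nc)
  tot <- matrix(0L, nr, nc)
  for (di in -radius:radius) {
    ri <- max(1, 1 - di):min(nr, nr - di)
    if (length(ri) == 0 || ri[1] > ri[length(ri)]) next
    for (dj in -radius:radius) {
      if (di == 0 && dj == 0) next
      ci <- max(1, 1 - dj):min(nc, nc - dj)
      if (length(ci) == 0 || ci[1] > ci[length(ci)]) next
      pos[ri, ci] <- pos[ri, ci] + P[ri + di, ci + dj, drop = FALSE]
      tot[ri, ci] <- tot[ri, ci] + 1L
    }
  }
  F <- (pos > tot / 2)
  storage.mode(F) <- "integer"
  F
}

#' PIPE score of a filtered landscape
#'
#' The arithmetic mean of the binary filtered cells: the fraction of the
#' landscape covered by co-occurrence signal, in `[0, 1]`.
#'
#' @param F Binary matrix from [median_filter()] (an empty matrix scores 0).
#' @return Numeric scalar in `[0, 1]`.
#' @export
pipe_score <- function(F) {
  if (length(F) == 0) return(0)
  mean(F)
}

#' Predict whether a protein pair interacts
#'
#' Runs the full per-pair PIPE pipeline: landscape, modified median filter,
#' mean-cell score, and the strict-threshold decision
#' `interacts = score > theta_dec`.
#'
#' @inheritParams build_landscape
#' @return One-row data frame with columns `id_a`, `id_b`, `score`,
#'   `interacts`, `threshold_used`, `runtime_s`, `skipped`.
#' @export
predict_pair <- function(A, B, proteome, graph, params) {
  t0 <- proc.time()[["elapsed"]]
  H <- build_landscape(A, B, proteome, graph, params)
  if (H$skipped) {
    score <- 0
  } else {
    score <- pipe_score(median_filter(H, params$filter_radius))
  }
  rt <- proc.time()[["elapsed"]] - t0
  data.frame(id_a = H$id_a, id_b = H$id_b, score = score,
             interacts = !H$skipped && score > params$theta_dec,
             threshold_used = params$theta_dec, runtime_s = rt,
             skipped = H$skipped, stringsAsFactors = FALSE)
}
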