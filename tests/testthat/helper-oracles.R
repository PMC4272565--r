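# Independent brute-force oracles used to validate the implementation paths.
# These deliberately share no code with the package internals beyond the
# substitution-matrix data itself.

PAM120 <- load_substitution_matrix("PAM120")

.canonical <- function() strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# plain R lookup-and-sum fragment score
oracle_window_score <- function(f1, f2, S = PAM120) {
  a <- strsplit(f1, "")[[1]]
  b <- strsplit(f2, "")[[1]]
  sum(S$full[cbind(a, b)])
}

# 0-based starts of windows of `seqc` scoring > theta against `frag`
oracle_match_starts <- function(frag, seqc, theta, S = PAM120) {
  w <- nchar(frag)
  n <- nchar(seqc) - w + 1
  if (n < 1) return(integer(0))
  hits <- vapply(seq_len(n), function(s) {
    oracle_window_score(frag, substr(seqc, s, s + w - 1), S) > theta
  }, logical(1))
  which(hits) - 1L
}

# triple loop over (window of A, window of B, edges): the reference landscape
oracle_landscape <- function(id_a, id_b, prot, graph, w, theta,
                             mode = c("per_edge", "per_occurrence"),
                             S = PAM120) {
  mode <- match.arg(mode)
  A <- prot$seqs[[id_a]]; B <- prot$seqs[[id_b]]
  na <- nchar(A) - w + 1; nb <- nchar(B) - w + 1
  frag_a <- vapply(seq_len(na), function(i) substr(A, i, i + w - 1), "")
  frag_b <- vapply(seq_len(nb), function(j) substr(B, j, j + w - 1), "")
  # per protein: matching window starts for each fragment
  m_a <- lapply(frag_a, function(f) {
    lapply(prot$seqs, function(sq) oracle_match_starts(f, sq, theta, S))
  })
  m_b <- lapply(frag_b, function(f) {
    lapply(prot$seqs, function(sq) oracle_match_starts(f, sq, theta, S))
  })
  H <- matrix(0L, na, nb)
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    tot <- 0L
    for (e in seq_len(nrow(graph$edges))) {
      X <- graph$edges[e, 1]; Y <- graph$edges[e, 2]
      # both orientations of the undirected edge
      orientations <- if (X == Y) list(c(X, Y)) else list(c(X, Y), c(Y, X))
      for (o in orientations) {
        ca <- length(m_a[[i]][[o[1]]])
        cb <- length(m_b[[j]][[o[2]]])
        if (mode == "per_edge") {
          tot <- tot + as.integer(ca > 0 && cb > 0)
        } else {
          tot <- tot + ca * cb
        }
      }
    }
    H[i, j] <- tot
  }
  H
}

# --- betweenness oracles ----------------------------------------------------

# oracle 1: enumerate ALL simple paths between every pair by DFS, keep the
# shortest, count pass-throughs (tiny graphs only)
oracle_betweenness_paths <- function(graph) {
  ids <- graph$vertices
  n <- length(ids)
  bc <- stats::setNames(numeric(n), ids)
  adj <- graph$adjacency
  all_paths <- function(a, b) {
    res <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == b) { res[[length(res) + 1]] <<- path; return() }
      for (u in adj[[v]]) if (!(u %in% path)) walk(c(path, u))
    }
    walk(a)
    res
  }
  if (n < 3) return(bc)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    paths <- all_paths(ids[i], ids[j])
    if (length(paths) == 0) next
    lens <- lengths(paths)
    sp <- paths[lens == min(lens)]
    sigma <- length(sp)
    inner <- unlist(lapply(sp, function(p) p[-c(1, length(p))]))
    if (length(inner) > 0) {
      cnt <- table(inner)
      bc[names(cnt)] <- bc[names(cnt)] + as.numeric(cnt) / sigma
    }
  }
  bc
}

# oracle 2: BFS shortest-path counts sigma_av; sigma_ab(v) = sigma_av *
# sigma_vb when d(a,v) + d(v,b) = d(a,b)
oracle_betweenness_sigma <- function(graph) {
  ids <- graph$vertices
  n <- length(ids)
  adj <- lapply(graph$adjacency[ids], function(nb) match(nb, ids))
  dist <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist[s, s] <- 0; sigma[s, s] <- 1
    queue <- s; qh <- 1
    while (qh <= length(queue)) {
      v <- queue[qh]; qh <- qh + 1
      for (u in adj[[v]]) {
        if (!is.finite(dist[s, u])) {
          dist[s, u] <- dist[s, v] + 1
          queue <- c(queue, u)
        }
        if (dist[s, u] == dist[s, v] + 1) sigma[s, u] <- sigma[s, u] + sigma[s, v]
      }
    }
  }
  bc <- stats::setNames(numeric(n), ids)
  for (a in 1:(n - 1)) for (b in (a + 1):n) {
    if (!is.finite(dist[a, b])) next
    for (v in seq_len(n)) {
      if (v == a || v == b) next
      if (is.finite(dist[a, v]) && is.finite(dist[v, b]) &&
          dist[a, v] + dist[v, b] == dist[a, b]) {
        bc[v] <- bc[v] + sigma[a, v] * sigma[v, b] / sigma[a, b]
      }
    }
  }
  bc
}

# --- clique oracle -----------------------------------------------------------

# exhaustive subset enumeration (|V| <= ~12)
oracle_maximal_cliques <- function(graph, min_size = 1) {
  ids <- graph$vertices
  n <- length(ids)
  is_clique <- function(members) {
    if (length(members) < 2) return(TRUE)
    prs <- utils::combn(members, 2)
    all(vapply(seq_len(ncol(prs)), function(k) {
      has_edge(graph, prs[1, k], prs[2, k])
    }, logical(1)))
  }
  cliques <- list()
  for (mask in 1:(2^n - 1)) {
    members <- ids[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    if (!is_clique(members)) next
    extendable <- any(vapply(setdiff(ids, members), function(v) {
      is_clique(c(members, v))
    }, logical(1)))
    if (!extendable && length(members) >= min_size) {
      cliques[[length(cliques) + 1]] <- sort(members)
    }
  }
  keys <- vapply(cliques, paste, character(1), collapse = "\r")
  cliques[order(keys)]
}

# --- misc fixture helpers ----------------------------------------------------

random_graph_gnp <- function(n, p, seed, prefix = "N") {
  set.seed(seed)
  ids <- sprintf("%s%02d", prefix, seq_len(n))
  prs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(prs)) < p
  interaction_graph(cbind(ids[prs[keep, 1]], ids[prs[keep, 2]]),
                    vertices = ids)
}

tmp_file <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
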