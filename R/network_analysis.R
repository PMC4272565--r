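# Topology and annotation analyses of a PPI network: hub ranking, betweenness
# centrality, shared-annotation agreement, term-pair co-occurrence, and
# reachability-based concordance with pull-down experiments.

#' Top-k hub proteins by degree
#'
#' @param graph An [interaction_graph].
#' @param k Number of hubs to report.
#' @return Data frame with columns `id`, `degree`, sorted by degree
#'   descending, ties broken lexicographically by id.
#' @export
degree_ranking <- function(graph, k) {
  stopifnot(k >= 1)
  deg <- graph_degrees(graph)
  ord <- order(-deg, names(deg))
  out <- data.frame(id = names(deg)[ord], degree = unname(deg[ord]),
                    stringsAsFactors = FALSE)
  head(out, k)
}

#' Betweenness centrality of every vertex
#'
#' For a vertex v, `B(v) = sum over unordered pairs {a, b}, a != v != b, of
#' sigma_ab(v) / sigma_ab`, where `sigma_ab` is the number of shortest paths
#' between a and b and `sigma_ab(v)` the number of those passing through v.
#' Endpoints are excluded and no normalization is applied; pairs in
#' different components contribute 0. Computed with Brandes' accumulation
#' algorithm (BFS; unweighted, undirected).
#'
#' @param graph An [interaction_graph].
#' @return Named numeric vector of betweenness values.
#' @export
betweenness_centrality <- function(graph) {
  ids <- graph$vertices
  n <- length(ids)
  bc <- numeric(n)
  names(bc) <- ids
  if (n == 0) return(bc)
  adj <- lapply(graph$adjacency[ids], function(nb) match(nb, ids))
  for (s in seq_len(n)) {
    # single-source shortest-path counts
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    stack <- integer(0)
    preds <- vector("list", n)
    queue <- c(s); qh <- 1L
    while (qh <= length(queue)) {
      v <- queue[qh]; qh <- qh + 1L
      stack <- c(stack, v)
      for (wv in adj[[v]]) {
        if (dist[wv] < 0) {
          dist[wv] <- dist[v] + 1L
          queue <- c(queue, wv)
        }
        if (dist[wv] == dist[v] + 1L) {
          sigma[wv] <- sigma[wv] + sigma[v]
          preds[[wv]] <- c(preds[[wv]], v)
        }
      }
    }
    delta <- numeric(n)
    for (v in rev(stack)) {
      for (p in preds[[v]]) {
        delta[p] <- delta[p] + sigma[p] / sigma[v] * (1 + delta[v])
      }
      if (v != s) bc[v] <- bc[v] + delta[v]
    }
  }
  # each unordered pair was accumulated from both endpoints
  bc / 2
}

#' Fractions of pairs sharing an annotation term
#'
#' For each namespace (CC, MF, BP): among the pairs whose *both* partners
#' carry at least one term in that namespace, the fraction sharing at least
#' one term. The conjunction column (`all3`) restricts to pairs annotated in
#' all three namespaces at both partners and requires a shared term in each.
#'
#' @param pairs Two-column matrix/data frame of protein id pairs.
#' @param annotations An [annotation_table()].
#' @return Named numeric vector `c(CC =, MF =, BP =, all3 =)`; a column with
#'   no eligible pair is `NA`.
#' @export
shared_annotation_stats <- function(pairs, annotations) {
  stopifnot(inherits(annotations, "annotation_table"))
  pairs <- as.matrix(pairs)
  if (nrow(pairs) == 0) {
    return(c(CC = NA_real_, MF = NA_real_, BP = NA_real_, all3 = NA_real_))
  }
  ns_names <- c("CC", "MF", "BP")
  share <- sapply(ns_names, function(ns) {
    tab <- annotations[[ns]]
    apply(pairs, 1, function(pr) {
      ta <- tab[[pr[1]]]; tb <- tab[[pr[2]]]
      if (is.null(ta) || is.null(tb)) return(NA)
      length(intersect(ta, tb)) > 0
    })
  })
  share <- matrix(share, nrow = nrow(pairs))
  frac <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  all3_elig <- rowSums(is.na(share)) == 0
  all3 <- if (!any(all3_elig)) NA_real_ else mean(rowSums(share[all3_elig, , drop = FALSE]) == 3)
  c(CC = frac(share[, 1]), MF = frac(share[, 2]), BP = frac(share[, 3]),
    all3 = all3)
}

#' Fraction of pairs with a common interaction partner
#'
#' A pair (A, B) counts when some third protein interacts with both A and B.
#'
#' @param pairs Two-column matrix/data frame of id pairs.
#' @param graph An [interaction_graph].
#' @return Numeric fraction in `[0, 1]`.
#' @export
common_neighbor_fraction <- function(pairs, graph) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs) == 0) return(NA_real_)
  hit <- apply(pairs, 1, function(pr) {
    na <- graph$adjacency[[pr[1]]]; nb <- graph$adjacency[[pr[2]]]
    if (is.null(na) || is.null(nb)) return(FALSE)
    length(setdiff(intersect(na, nb), pr)) > 0
  })
  mean(hit)
}

#' Term-pair co-occurrence matrix
#'
#' Entry (s, t) is the number of input pairs in which one partner carries
#' term s and the other carries term t, divided by the number of possible
#' protein pairs (over all proteins annotated in the namespace) with that
#' term assignment. Symmetric; entries with zero possible pairs are `NA`.
#'
#' @param pairs Two-column matrix/data frame of id pairs.
#' @param annotations An [annotation_table()].
#' @param namespace One of `"CC"`, `"MF"`, `"BP"`.
#' @return Symmetric numeric matrix with term dimnames.
#' @export
term_pair_cooccurrence <- function(pairs, annotations, namespace = c("CC", "MF", "BP")) {
  namespace <- match.arg(namespace)
  tab <- annotations[[namespace]]
  pairs <- as.matrix(pairs)
  terms <- sort(unique(unlist(tab, use.names = FALSE)))
  nt <- length(terms)
  obs <- matrix(0, nt, nt, dimnames = list(terms, terms))
  for (i in seq_len(nrow(pairs))) {
    ta <- tab[[pairs[i, 1]]]; tb <- tab[[pairs[i, 2]]]
    if (is.null(ta) || is.null(tb)) next
    for (s in ta) for (t in tb) {
      obs[s, t] <- obs[s, t] + 1
      if (s != t) obs[t, s] <- obs[t, s] + 1
    }
  }
  # possible pairs per (s, t): |S||T| - |S & T| - choose(|S & T|, 2)
  carriers <- lapply(terms, function(t) names(tab)[vapply(tab, function(x) t %in% x, logical(1))])
  names(carriers) <- terms
  possible <- outer(seq_len(nt), seq_len(nt), Vectorize(function(i, j) {
    ns <- length(carriers[[i]]); ntj <- length(carriers[[j]])
    nb <- length(intersect(carriers[[i]], carriers[[j]]))
    ns * ntj - nb - choose(nb, 2)
  }))
  out <- ifelse(possible > 0, obs / possible, NA_real_)
  dimnames(out) <- list(terms, terms)
  out
}

#' Reachability overlap of a bait with its co-purifying prey
#'
#' Reachable proteins are the vertices within graph distance
#' `max_intermediaries + 1` of the bait (the bait itself excluded), i.e.
#' proteins interacting directly or through at most that many intermediary
#' proteins. Recall is `|reachable & prey| / |prey|`, precision
#' `|reachable & prey| / |reachable|`. The graph should already be
#' restricted to the detectable-protein universe by the caller.
#'
#' @param bait Bait protein id (must be a graph vertex).
#' @param prey Character vector of prey ids.
#' @param graph An [interaction_graph].
#' @param max_intermediaries Maximum intermediary proteins (default 2).
#' @return List with `reachable` (character vector), `reached` (prey
#'   reached), `recall`, `precision` (NA when the denominator is empty).
#' @export
reachability_overlap <- function(bait, prey, graph, max_intermediaries = 2L) {
  if (!(bait %in% graph$vertices)) stop("bait '", bait, "' not in graph")
  maxd <- max_intermediaries + 1L
  # BFS out to depth maxd
  dist <- c(stats::setNames(0L, bait))
  frontier <- bait
  for (d in seq_len(maxd)) {
    nxt <- setdiff(unique(unlist(graph$adjacency[frontier], use.names = FALSE)),
                   names(dist))
    if (length(nxt) == 0) break
    dist <- c(dist, stats::setNames(rep(d, length(nxt)), nxt))
    frontier <- nxt
  }
  reachable <- setdiff(names(dist), bait)
  reached <- intersect(reachable, prey)
  list(reachable = reachable, reached = reached,
       recall = if (length(prey) == 0) NA_real_ else length(reached) / length(prey),
       precision = if (length(reachable) == 0) NA_real_ else length(reached) / length(reachable))
}
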