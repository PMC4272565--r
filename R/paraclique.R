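# Paraclique decomposition: Bron-Kerbosch maximal-clique initialization,
# exact and approximate merge stages, the glom stage, loop control, and
# per-cluster hypergeometric term enrichment.

#' Parameters of the paraclique decomposition
#'
#' @param m Exact-merge overlap threshold in `(0, 1]`: a merge happens only
#'   when some pair of clusters overlaps by a proportion strictly greater
#'   than `m`.
#' @param g Glom connectivity threshold in `(0, 1]`: an outside vertex is
#'   absorbed when it is adjacent to strictly more than `g` of the cluster.
#' @param a Approximate-merge overlap threshold in `(0, 1]`: while many
#'   clusters remain, the first pair encountered with overlap at least `a`
#'   is merged (note `>=` here versus strict `>` for `m`).
#' @param switch_count Cluster count at which approximate merging hands
#'   over to exact merging (default 20000).
#' @param target_count Stop once this many clusters remain; 0 (default)
#'   runs to the fixed point.
#' @param min_clique_size Smallest initial clique kept (default 3; a
#'   "complex" of two proteins is just an edge).
#' @return An object of class `paraclique_params`.
#' @export
paraclique_params <- function(m = 0.5, g = 0.5, a = 0.5,
                              switch_count = 20000L, target_count = 0L,
                              min_clique_size = 3L) {
  stopifnot(m > 0, m <= 1, g > 0, g <= 1, a > 0, a <= 1,
            min_clique_size >= 2)
  structure(list(m = m, g = g, a = a,
                 switch_count = as.integer(switch_count),
                 target_count = as.integer(target_count),
                 min_clique_size = as.integer(min_clique_size)),
            class = "paraclique_params")
}

#' Cluster-set container
#'
#' @param clusters List of character vectors of member ids.
#' @param provenance Character vector, one flag per cluster
#'   (`"clique"`, `"merged"`, `"glommed"`).
#' @return An object of class `cluster_set`.
#' @export
cluster_set <- function(clusters, provenance = rep("clique", length(clusters))) {
  stopifnot(length(clusters) == length(provenance))
  if (any(lengths(clusters) == 0)) stop("empty cluster")
  clusters <- lapply(clusters, function(x) sort(unique(x)))
  keys <- vapply(clusters, paste, character(1), collapse = "\r")
  if (anyDuplicated(keys)) stop("duplicated cluster")
  structure(list(clusters = clusters, provenance = provenance),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("cluster_set:", length(x$clusters), "clusters, sizes",
      if (length(x$clusters)) paste(range(lengths(x$clusters)), collapse = "-")
      else "-", "\n")
  invisible(x)
}

#' @export
length.cluster_set <- function(x) length(x$clusters)

#' Enumerate maximal cliques
#'
#' Bron-Kerbosch with pivoting, degeneracy vertex ordering and bitset
#' adjacency (compiled). Returns exactly the maximal cliques with at least
#' `min_clique_size` members: every returned set is a clique, and none is a
#' subset of another.
#'
#' @param graph An [interaction_graph].
#' @param min_clique_size Smallest clique size reported (default 3).
#' @return A [cluster_set()] (clusters in a deterministic order: sorted by
#'   their member ids).
#' @export
maximal_cliques <- function(graph, min_clique_size = 3L) {
  ids <- graph$vertices
  if (length(ids) == 0 || nrow(graph$edges) == 0) {
    # only singleton "cliques" exist; report none unless min size is 1
    if (min_clique_size <= 1 && length(ids) > 0) {
      return(cluster_set(as.list(ids)))
    }
    return(cluster_set(list(), character(0)))
  }
  eidx <- cbind(match(graph$edges[, 1], ids), match(graph$edges[, 2], ids))
  storage.mode(eidx) <- "integer"
  raw <- maximal_cliques_cpp(eidx, length(ids), as.integer(min_clique_size))
  cl <- lapply(raw, function(ix) ids[ix])
  keys <- vapply(cl, paste, character(1), collapse = "\r")
  cl <- cl[order(keys)]
  cluster_set(cl)
}

#' Overlap proportion of two clusters
#'
#' `|c1 & c2| / min(|c1|, |c2|)` by default — the containment-style reading
#' of overlap used by the merge stages; `method = "jaccard"` divides by the
#' union size instead.
#'
#' @param c1,c2 Nonempty character vectors of member ids.
#' @param method `"min"` (default) or `"jaccard"`.
#' @return Numeric in `[0, 1]`.
#' @export
overlap_proportion <- function(c1, c2, method = c("min", "jaccard")) {
  method <- match.arg(method)
  stopifnot(length(c1) > 0, length(c2) > 0)
  i <- length(intersect(c1, c2))
  den <- if (method == "min") min(length(c1), length(c2))
         else length(union(c1, c2))
  i / den
}

#' One exact merge step
#'
#' Finds the pair of clusters with the highest overlap proportion; if that
#' overlap is strictly greater than `m`, the pair is replaced by its union
#' (ties broken toward the lexicographically smallest pair of cluster
#' indices). Otherwise nothing changes.
#'
#' @param clusters A [cluster_set()] or plain list of member vectors.
#' @param m Merge threshold.
#' @param method Overlap flavor, see [overlap_proportion()].
#' @return List with `clusters` (a `cluster_set`), `merged` (logical) and
#'   `new_index` (index of the union cluster, or NA).
#' @export
merge_step <- function(clusters, m, method = "min") {
  cs <- .as_cluster_list(clusters)
  n <- length(cs$clusters)
  if (n < 2) return(list(clusters = .rebuild(cs), merged = FALSE, new_index = NA))
  best <- 0; bi <- 0; bj <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ov <- overlap_proportion(cs$clusters[[i]], cs$clusters[[j]], method)
    if (ov > best) { best <- ov; bi <- i; bj <- j }
  }
  if (best <= m) return(list(clusters = .rebuild(cs), merged = FALSE, new_index = NA))
  res <- .do_merge(cs, bi, bj)
  list(clusters = .rebuild(res$clusters), merged = TRUE,
       new_index = res$new_index)
}

#' Approximate merging until a cluster-count target
#'
#' Repeatedly merges the first pair encountered (fixed index scan order)
#' whose overlap is at least `a`, until no such pair remains or the cluster
#' count reaches `stop_count`.
#'
#' @param clusters A [cluster_set()] or plain list.
#' @param a Approximation overlap threshold (inclusive `>=`).
#' @param stop_count Stop merging at this many clusters.
#' @param method Overlap flavor.
#' @return A [cluster_set()].
#' @export
approx_merge <- function(clusters, a, stop_count = 0L, method = "min") {
  cs <- .as_cluster_list(clusters)
  repeat {
    if (length(cs$clusters) <= max(stop_count, 1L)) break
    hit <- .first_pair_at_least(cs$clusters, a, method)
    if (is.null(hit)) break
    cs <- .do_merge(cs, hit[1], hit[2])$clusters
    cs <- list(clusters = cs$clusters, provenance = cs$provenance)
  }
  .rebuild(cs)
}

#' One glom step
#'
#' Every vertex outside the cluster whose adjacency covers strictly more
#' than proportion `g` of the *original* cluster members is absorbed, in a
#' single pass against the pre-glom membership.
#'
#' @param cluster Character vector of member ids.
#' @param graph An [interaction_graph].
#' @param g Glom factor.
#' @return The (possibly grown) cluster, sorted.
#' @export
glom_step <- function(cluster, graph, g) {
  stopifnot(length(cluster) > 0)
  outside <- setdiff(graph$vertices, cluster)
  if (length(outside) == 0) return(sort(cluster))
  conn <- vapply(outside, function(v) {
    length(intersect(graph$adjacency[[v]], cluster)) / length(cluster)
  }, numeric(1))
  sort(c(cluster, outside[conn > g]))
}

#' Full paraclique decomposition
#'
#' Initializes with the maximal cliques, gloms every initial cluster once,
#' then alternates merge (approximate while more than `switch_count`
#' clusters remain, exact afterwards) with a glom of the newly created
#' cluster, until `target_count` clusters remain or neither stage changes
#' anything. Deterministic: all scan orders and tie-breaks follow cluster
#' creation order.
#'
#' @param graph An [interaction_graph].
#' @param params A [paraclique_params()].
#' @param overlap_method Overlap flavor, see [overlap_proportion()].
#' @return A [cluster_set()] of (possibly overlapping) paracliques.
#' @export
decompose <- function(graph, params = paraclique_params(),
                      overlap_method = "min") {
  stopifnot(inherits(params, "paraclique_params"))
  cs0 <- maximal_cliques(graph, params$min_clique_size)
  if (length(cs0) == 0) return(cs0)
  clusters <- lapply(cs0$clusters, glom_step, graph = graph, g = params$g)
  prov <- rep("glommed", length(clusters))
  cs <- .dedup(list(clusters = clusters, provenance = prov))
  repeat {
    if (params$target_count > 0 && length(cs$clusters) <= params$target_count) break
    if (length(cs$clusters) < 2) break
    if (length(cs$clusters) > params$switch_count) {
      hit <- .first_pair_at_least(cs$clusters, params$a, overlap_method)
    } else {
      hit <- .best_pair_above(cs$clusters, params$m, overlap_method)
    }
    if (is.null(hit)) break
    merged <- .do_merge(cs, hit[1], hit[2])
    cs <- list(clusters = merged$clusters$clusters,
               provenance = merged$clusters$provenance)
    ni <- merged$new_index
    cs$clusters[[ni]] <- glom_step(cs$clusters[[ni]], graph, params$g)
    cs$provenance[ni] <- "glommed"
    cs <- .dedup(cs)
  }
  .rebuild(cs)
}

#' Hypergeometric term enrichment of one cluster
#'
#' For each term carried by at least one cluster member: the upper-tail
#' hypergeometric probability of observing at least `k` annotated members
#' in a cluster of size `n` drawn from a background of size `N` containing
#' `K` carriers of the term. Raw P-values by default (one term reported per
#' cluster in practice); set `correct = TRUE` for Benjamini-Hochberg
#' adjustment across the cluster's terms.
#'
#' @param cluster Character vector of member ids.
#' @param annotations Either a named list (protein id -> character vector of
#'   terms) or an [annotation_table()] with `namespace` naming the table to
#'   use.
#' @param background Character vector of background protein ids
#'   (must contain the cluster).
#' @param namespace Namespace when `annotations` is an `annotation_table`.
#' @param correct Apply Benjamini-Hochberg correction (default FALSE).
#' @return Data frame with columns `term`, `k` (cluster carriers), `K`
#'   (background carriers), `p`, ranked by ascending `p`, ties by term id.
#'   Empty for an unannotated cluster.
#' @export
cluster_enrichment <- function(cluster, annotations, background,
                               namespace = "BP", correct = FALSE) {
  if (inherits(annotations, "annotation_table")) {
    annotations <- annotation_namespace(annotations, namespace)
  }
  if (!all(cluster %in% background)) {
    stop("background must contain every cluster member")
  }
  terms <- sort(unique(unlist(annotations[intersect(cluster, names(annotations))],
                              use.names = FALSE)))
  if (length(terms) == 0) {
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      p = numeric(0)))
  }
  N <- length(background)
  n <- length(cluster)
  rows <- lapply(terms, function(t) {
    carriers <- names(annotations)[vapply(annotations, function(x) t %in% x,
                                          logical(1))]
    K <- length(intersect(carriers, background))
    k <- length(intersect(carriers, cluster))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = t, k = k, K = K, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (correct) out$p <- p.adjust(out$p, method = "BH")
  out[order(out$p, out$term), , drop = FALSE]
}

# ---- internal helpers -------------------------------------------------------

.as_cluster_list <- function(x) {
  if (inherits(x, "cluster_set")) list(clusters = x$clusters, provenance = x$provenance)
  else list(clusters = lapply(x, function(c) sort(unique(c))),
            provenance = rep("clique", length(x)))
}

.rebuild <- function(cs) cluster_set(cs$clusters, cs$provenance)

# merge clusters i < j: the union replaces position i, j is dropped
.do_merge <- function(cs, i, j) {
  un <- sort(union(cs$clusters[[i]], cs$clusters[[j]]))
  cs$clusters[[i]] <- un
  cs$provenance[i] <- "merged"
  cs$clusters[[j]] <- NULL
  cs$provenance <- cs$provenance[-j]
  list(clusters = list(clusters = cs$clusters, provenance = cs$provenance),
       new_index = i)
}

.first_pair_at_least <- function(clusters, a, method) {
  n <- length(clusters)
  if (n < 2) return(NULL)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (overlap_proportion(clusters[[i]], clusters[[j]], method) >= a) {
      return(c(i, j))
    }
  }
  NULL
}

.best_pair_above <- function(clusters, m, method) {
  n <- length(clusters)
  if (n < 2) return(NULL)
  best <- 0; bi <- 0; bj <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ov <- overlap_proportion(clusters[[i]], clusters[[j]], method)
    if (ov > best) { best <- ov; bi <- i; bj <- j }
  }
  if (best > m) c(bi, bj) else NULL
}

.dedup <- function(cs) {
  keys <- vapply(cs$clusters, paste, character(1), collapse = "\r")
  keep <- !duplicated(keys)
  list(clusters = cs$clusters[keep], provenance = cs$provenance[keep])
}
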