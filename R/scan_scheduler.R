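# Desk-scale realization of the two-level scheduler/worker scan: dynamic
# packet distribution over a single read-only database, with per-pair runtime
# bookkeeping and long-pair offload accounting.

#' Enumerate all-vs-all protein pairs
#'
#' Pairs are enumerated in lexicographic order with `id_a < id_b`;
#' self-pairs are included only when `allow_self = TRUE`.
#'
#' @param ids Character vector of protein ids (or a [proteome]).
#' @param allow_self Include homodimer pairs (default FALSE).
#' @return Two-column character matrix of pairs.
#' @export
all_pairs <- function(ids, allow_self = FALSE) {
  if (inherits(ids, "proteome")) ids <- ids$ids
  ids <- sort(ids)
  n <- length(ids)
  if (n < 2 && !allow_self) return(matrix(character(0), 0, 2,
                                          dimnames = list(NULL, c("id_a", "id_b"))))
  idx <- which(upper.tri(matrix(0, n, n), diag = allow_self), arr.ind = TRUE)
  # upper.tri(diag=TRUE) includes the diagonal for self pairs
  ord <- order(idx[, 1], idx[, 2])
  out <- cbind(id_a = ids[idx[ord, 1]], id_b = ids[idx[ord, 2]])
  out
}

#' Number of all-vs-all pairs
#'
#' @param n_proteins Number of proteins.
#' @param allow_self Include homodimer pairs.
#' @return `choose(n, 2)` (plus `n` when self-pairs are allowed).
#' @examples
#' n_pairs(22513)  # 253406328
#' @export
n_pairs <- function(n_proteins, allow_self = FALSE) {
  choose(n_proteins, 2) + if (allow_self) n_proteins else 0
}

#' Partition a pair list into work packets
#'
#' @param pairs Two-column matrix/data frame of id pairs.
#' @param packet_size Maximum pairs per packet (default 64, balancing
#'   scheduler communication overhead against work imbalance).
#' @return List of packets, each `list(packet_id =, pairs =)`; their
#'   concatenation reproduces the input order exactly.
#' @export
partition_pairs <- function(pairs, packet_size = 64L) {
  stopifnot(packet_size >= 1)
  pairs <- as.matrix(pairs)
  n <- nrow(pairs)
  if (n == 0) return(list())
  starts <- seq(1L, n, by = packet_size)
  lapply(seq_along(starts), function(k) {
    rows <- starts[k]:min(starts[k] + packet_size - 1L, n)
    list(packet_id = k, pairs = pairs[rows, , drop = FALSE])
  })
}

#' Run a (desk-scale) scheduled scan over protein pairs
#'
#' Simulates the pull-based scheduler/worker architecture in a single
#' process: pairs are split into packets, workers pull the next packet as
#' they finish (next-packet-to-first-free-worker over the measured per-pair
#' runtimes), and all workers share one read-only copy of the database
#' (proteome, graph, substitution matrix). The prediction set is identical
#' for every combination of `n_workers` and `packet_size`; only the
#' simulated wall-clock accounting changes.
#'
#' Pairs whose prediction exceeds `time_budget_s` are recorded as offloaded
#' and excluded from the prediction set, mirroring the off-loading of
#' extreme pairs to a separate cluster. A failing packet is re-queued once,
#' then raises an error naming the packet.
#'
#' @param pairs Two-column matrix/data frame of id pairs.
#' @param proteome A [proteome].
#' @param graph An [interaction_graph].
#' @param params A [pipe_params].
#' @param n_workers Number of simulated workers (default 1).
#' @param packet_size Pairs per packet (default 64).
#' @param time_budget_s Per-pair runtime budget in seconds (default `Inf`).
#' @param checkpoint Optional path of a checkpoint file recording completed
#'   packet ids; on rerun, completed packets are skipped.
#' @param verbose Log per-packet progress to stderr.
#' @return An object of class `scan_report`: list with `predictions` (data
#'   frame as from [predict_pair()]), `offloaded` (pair matrix),
#'   `wall_seconds` (simulated), `pairs_done`, `n_workers`, `packet_size`.
#' @export
run_scan <- function(pairs, proteome, graph, params, n_workers = 1L,
                     packet_size = 64L, time_budget_s = Inf,
                     checkpoint = NULL, verbose = FALSE) {
  stopifnot(n_workers >= 1)
  pairs <- as.matrix(pairs)
  packets <- partition_pairs(pairs, packet_size)
  done_ids <- integer(0)
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done_ids <- as.integer(readLines(checkpoint))
  }
  worker_free <- numeric(n_workers)  # simulated time each worker frees up
  results <- vector("list", length(packets))
  for (pk in packets) {
    if (pk$packet_id %in% done_ids) next
    res <- NULL
    for (attempt in 1:2) {
      res <- tryCatch(
        do.call(rbind, lapply(seq_len(nrow(pk$pairs)), function(i) {
          predict_pair(pk$pairs[i, 1], pk$pairs[i, 2], proteome, graph, params)
        })),
        error = function(e) e
      )
      if (!inherits(res, "error")) break
    }
    if (inherits(res, "error")) {
      stop("packet ", pk$packet_id, " failed twice: ", conditionMessage(res))
    }
    results[[pk$packet_id]] <- res
    # pull-based schedule: this packet goes to the worker that frees first
    wk <- which.min(worker_free)
    worker_free[wk] <- worker_free[wk] + sum(res$runtime_s)
    if (verbose) {
      message("packet ", pk$packet_id, "/", length(packets), ": ",
              nrow(res), " pairs, ", sum(res$interacts), " predicted positive")
    }
    if (!is.null(checkpoint)) {
      cat(pk$packet_id, "\n", file = checkpoint, append = TRUE)
    }
  }
  preds <- do.call(rbind, results)
  if (is.null(preds)) {
    preds <- data.frame(id_a = character(0), id_b = character(0),
                        score = numeric(0), interacts = logical(0),
                        threshold_used = numeric(0), runtime_s = numeric(0),
                        skipped = logical(0))
  }
  over <- preds$runtime_s > time_budget_s
  offloaded <- cbind(id_a = preds$id_a[over], id_b = preds$id_b[over])
  preds <- preds[!over, , drop = FALSE]
  rownames(preds) <- NULL
  structure(list(predictions = preds, offloaded = offloaded,
                 wall_seconds = max(c(0, worker_free)),
                 pairs_done = nrow(preds),
                 n_workers = n_workers, packet_size = packet_size),
            class = "scan_report")
}

#' @export
print.scan_report <- function(x, ...) {
  cat("scan_report:", x$pairs_done, "pairs done,", nrow(x$offloaded),
      "offloaded;", x$n_workers, "worker(s), packet size", x$packet_size,
      ", simulated wall", round(x$wall_seconds, 3), "s\n")
  invisible(x)
}
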