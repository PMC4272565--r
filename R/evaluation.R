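# Leave-one-out benchmarking, prevalence-adjusted confusion matrices, the
# six-metric battery, precision-recall sweeps and operating-point selection.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Sample random negative (assumed non-interacting) pairs
#'
#' Draws `n` distinct unordered protein pairs uniformly without replacement
#' from the pairs *not* present in the graph — the conservative negative set
#' of random pairs not previously reported to interact.
#'
#' @param proteome A [proteome] (or character vector of ids).
#' @param graph An [interaction_graph].
#' @param n Number of negative pairs.
#' @param seed Integer seed; the same seed reproduces the same sample.
#' @param allow_self Permit homodimer pairs (default FALSE).
#' @return Two-column character matrix of pairs (`id_a < id_b`).
#' @export
sample_negatives <- function(proteome, graph, n, seed, allow_self = FALSE) {
  ids <- if (inherits(proteome, "proteome")) proteome$ids else proteome
  ids <- sort(ids)
  nv <- length(ids)
  avail <- n_pairs(nv, allow_self) - nrow(graph$edges)
  if (n > avail) {
    stop("requested ", n, " negatives but only ", avail, " non-edges exist")
  }
  if (n == 0) return(matrix(character(0), 0, 2,
                            dimnames = list(NULL, c("id_a", "id_b"))))
  .with_seed(seed, {
    if (n_pairs(nv, allow_self) <= 2e6) {
      cand <- all_pairs(ids, allow_self = allow_self)
      is_edge <- vapply(seq_len(nrow(cand)),
                        function(i) has_edge(graph, cand[i, 1], cand[i, 2]),
                        logical(1))
      cand <- cand[!is_edge, , drop = FALSE]
      sel <- sample.int(nrow(cand), n)
      out <- cand[sel, , drop = FALSE]
    } else {
      # rejection sampling for large id universes
      seen <- character(0)
      out <- matrix(character(0), 0, 2)
      while (nrow(out) < n) {
        need <- n - nrow(out)
        i <- sample.int(nv, 2 * need, replace = TRUE)
        j <- sample.int(nv, 2 * need, replace = TRUE)
        ok <- if (allow_self) i <= j else i < j
        a <- ids[pmin(i, j)[ok]]; b <- ids[pmax(i, j)[ok]]
        key <- paste(a, b, sep = "\r")
        fresh <- !duplicated(key) & !(key %in% seen)
        is_edge <- mapply(function(x, y) has_edge(graph, x, y), a, b)
        keep <- which(fresh & !is_edge)
        keep <- head(keep, need)
        out <- rbind(out, cbind(a[keep], b[keep]))
        seen <- c(seen, key[keep])
      }
    }
    colnames(out) <- c("id_a", "id_b")
    out
  })
}

#' Leave-one-out scoring of labeled pairs
#'
#' Each positive pair (a known edge) is scored with exactly that edge
#' removed from the database, then restored; negatives are scored against
#' the full graph. Deterministic for fixed inputs.
#'
#' @param positives Two-column matrix/data frame of known interacting pairs;
#'   every row must be an edge of `graph`.
#' @param negatives Two-column matrix/data frame of assumed non-interacting
#'   pairs (none may be a graph edge); may have zero rows.
#' @param proteome A [proteome].
#' @param graph An [interaction_graph].
#' @param params A [pipe_params].
#' @param verbose Log progress every 50 pairs.
#' @return Data frame with columns `id_a`, `id_b`, `score`, `label`
#'   (`"positive"`/`"negative"`).
#' @export
loo_scores <- function(positives, negatives, proteome, graph, params,
                       verbose = FALSE) {
  positives <- as.matrix(positives)
  negatives <- as.matrix(negatives)
  for (i in seq_len(nrow(positives))) {
    if (!has_edge(graph, positives[i, 1], positives[i, 2])) {
      stop("positive pair (", positives[i, 1], ", ", positives[i, 2],
           ") is not an edge of the graph")
    }
  }
  if (nrow(negatives) > 0) {
    is_edge <- vapply(seq_len(nrow(negatives)),
                      function(i) has_edge(graph, negatives[i, 1], negatives[i, 2]),
                      logical(1))
    if (any(is_edge)) stop("negative pair(s) present in the graph")
  }
  score_one <- function(a, b, g) predict_pair(a, b, proteome, g, params)$score
  pos_scores <- vapply(seq_len(nrow(positives)), function(i) {
    g2 <- remove_edge(graph, positives[i, 1], positives[i, 2])
    if (verbose && i %% 50 == 0) message("LOO positive ", i, "/", nrow(positives))
    score_one(positives[i, 1], positives[i, 2], g2)
  }, numeric(1))
  neg_scores <- vapply(seq_len(nrow(negatives)), function(i) {
    if (verbose && i %% 50 == 0) message("negative ", i, "/", nrow(negatives))
    score_one(negatives[i, 1], negatives[i, 2], graph)
  }, numeric(1))
  data.frame(
    id_a = c(positives[, 1], negatives[, 1]),
    id_b = c(positives[, 2], negatives[, 2]),
    score = c(pos_scores, neg_scores),
    label = rep(c("positive", "negative"),
                c(nrow(positives), nrow(negatives))),
    stringsAsFactors = FALSE)
}

#' Confusion matrix at a decision threshold
#'
#' Pairs scoring strictly above the threshold are called positive.
#'
#' @param scores Data frame as from [loo_scores()] (columns `score`, `label`).
#' @param threshold Decision threshold.
#' @return An object of class `confusion_matrix`: list with integer-valued
#'   `TP`, `FP`, `FN`, `TN`.
#' @export
confusion_at <- function(scores, threshold) {
  pos <- scores$label == "positive"
  call_pos <- scores$score > threshold
  confusion_matrix(TP = sum(pos & call_pos), FP = sum(!pos & call_pos),
                   FN = sum(pos & !call_pos), TN = sum(!pos & !call_pos))
}

#' Construct a confusion matrix
#'
#' @param TP,FP,FN,TN Nonnegative counts (reals allowed after prevalence
#'   adjustment, before rounding).
#' @return An object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(TP, FP, FN, TN) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0, TN >= 0)
  structure(list(TP = TP, FP = FP, FN = FN, TN = TN),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2,
              dimnames = list(c("predicted +", "predicted -"),
                              c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Adjust a confusion matrix to an assumed class prevalence
#'
#' Evaluation sets rarely reflect the true scarcity of interacting pairs. To
#' report realistic figures, the negative column is rescaled so that the
#' evaluated negatives represent `target_ratio` non-interacting pairs per
#' interacting pair (default 100): FP and TN are each multiplied by
#' `target_ratio * n_pos / n_neg` and rounded to the nearest integer; the
#' positive column is untouched, so recall is invariant.
#'
#' @param cm A [confusion_matrix()].
#' @param n_pos,n_neg Numbers of positive and negative pairs evaluated.
#' @param target_ratio Assumed non-interacting:interacting ratio (default 100).
#' @return The adjusted `confusion_matrix`.
#' @examples
#' cm <- confusion_matrix(TP = 9586, FP = 50, FN = 32092, TN = 99950)
#' prevalence_adjust(cm, n_pos = 41678, n_neg = 100000)  # FP 2084, TN 4165716
#' @export
prevalence_adjust <- function(cm, n_pos, n_neg, target_ratio = 100) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (n_neg <= 0 || n_pos <= 0) stop("n_pos and n_neg must be positive")
  f <- target_ratio * n_pos / n_neg
  confusion_matrix(TP = cm$TP, FN = cm$FN,
                   FP = round(cm$FP * f), TN = round(cm$TN * f))
}

#' The six-statistic performance battery
#'
#' Specificity `TN/(FP+TN)`, recall `TP/(TP+FN)`, precision `TP/(TP+FP)`,
#' accuracy `(TP+TN)/total`, F1 `2TP/(2TP+FP+FN)`, and the Matthews
#' correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' A metric whose denominator is zero is reported as `NA`.
#'
#' @param cm A [confusion_matrix()] (typically prevalence-adjusted).
#' @return Named numeric vector with elements `specificity`, `recall`,
#'   `precision`, `accuracy`, `f1`, `mcc`.
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  TP <- cm$TP; FP <- cm$FP; FN <- cm$FN; TN <- cm$TN
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  c(specificity = div(TN, FP + TN),
    recall = div(TP, TP + FN),
    precision = div(TP, TP + FP),
    accuracy = div(TP + TN, TP + FP + FN + TN),
    f1 = div(2 * TP, 2 * TP + FP + FN),
    mcc = if (mcc_den == 0) NA_real_ else (TP * TN - FP * FN) / mcc_den)
}

#' Prevalence-adjusted precision-recall curve
#'
#' One point per distinct score value used as the strict decision threshold.
#' Precision is computed from the prevalence-adjusted confusion matrix (see
#' [prevalence_adjust()]); recall is non-increasing as the threshold rises.
#'
#' @param scores Data frame as from [loo_scores()].
#' @param target_ratio Assumed negative:positive prevalence (default 100).
#' @return Data frame with columns `threshold`, `precision` (adjusted),
#'   `recall`, ordered by increasing threshold.
#' @export
pr_curve <- function(scores, target_ratio = 100) {
  n_pos <- sum(scores$label == "positive")
  n_neg <- sum(scores$label == "negative")
  if (n_pos == 0 || n_neg == 0) {
    stop("pr_curve needs at least one positive and one negative")
  }
  thresholds <- sort(unique(scores$score))
  rows <- lapply(thresholds, function(th) {
    cm <- prevalence_adjust(confusion_at(scores, th), n_pos, n_neg, target_ratio)
    mt <- metrics(cm)
    data.frame(threshold = th, precision = mt[["precision"]],
               recall = mt[["recall"]])
  })
  do.call(rbind, rows)
}

#' Choose the decision threshold at a target specificity
#'
#' Returns the smallest threshold (over the distinct score values) whose
#' specificity is at least `target_specificity`; among qualifying
#' thresholds the smallest maximizes recall. The conservative default,
#' 99.95% specificity, minimizes the false-positive rate under the assumed
#' 1:100 prevalence.
#'
#' @param scores Data frame as from [loo_scores()] (negatives required).
#' @param target_specificity Required specificity (default 0.9995).
#' @return Numeric threshold.
#' @export
operating_point <- function(scores, target_specificity = 0.9995) {
  n_neg <- sum(scores$label == "negative")
  if (n_neg == 0) stop("operating_point needs negative pairs")
  thresholds <- sort(unique(scores$score))
  neg <- scores$score[scores$label == "negative"]
  for (th in thresholds) {
    spec <- sum(neg <= th) / n_neg
    if (spec >= target_specificity) return(th)
  }
  warning("target specificity ", target_specificity,
          " unattainable; returning the highest threshold")
  thresholds[length(thresholds)]
}
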