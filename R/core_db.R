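# Data model: proteomes, interaction graphs, predictions, and their readers
# and writers.

#' Construct a proteome from id and sequence vectors
#'
#' A proteome is an ordered collection of protein records with unique,
#' non-empty identifiers. Sequences are uppercased on ingestion and must be
#' drawn from the 20 canonical amino-acid letters plus the ambiguity codes
#' `B, Z, X, U, O, *`. Integer encodings used by the scoring kernels are
#' precomputed once here.
#'
#' @param ids Character vector of protein accessions.
#' @param sequences Character vector of amino-acid sequences, same length.
#' @return An object of class `proteome` with elements `ids`, `seqs`
#'   (named character vector) and `enc` (named list of integer codes).
#' @examples
#' p <- proteome(c("P1", "P2"), c("ACDE", "wyyh"))
#' p$seqs[["P2"]]  # "WYYH"
#' @export
proteome <- function(ids, sequences) {
  ids <- as.character(ids)
  sequences <- toupper(as.character(sequences))
  if (length(ids) != length(sequences)) {
    stop("ids and sequences must have the same length")
  }
  if (length(ids) < 1) stop("a proteome needs at least one record")
  if (any(!nzchar(ids))) stop("empty protein id")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate protein id(s): ", paste(unique(dup), collapse = ", "))
  }
  empty <- ids[!nzchar(sequences)]
  if (length(empty) > 0) {
    stop("empty sequence for protein(s): ", paste(empty, collapse = ", "))
  }
  for (i in seq_along(ids)) .check_residues(sequences[i], ids[i])
  names(sequences) <- ids
  enc <- lapply(sequences, encode_sequence)
  structure(list(ids = ids, seqs = sequences, enc = enc), class = "proteome")
}

#' @export
print.proteome <- function(x, ...) {
  cat("proteome:", length(x$ids), "proteins, lengths",
      min(nchar(x$seqs)), "-", max(nchar(x$seqs)), "\n")
  invisible(x)
}

#' @export
length.proteome <- function(x) length(x$ids)

#' Read a FASTA file into a proteome
#'
#' Parsing is delegated to [Biostrings::readAAStringSet()]; ingestion then
#' enforces the proteome invariants: unique non-empty ids (the first
#' whitespace-delimited token of each header), non-empty uppercase sequences
#' over the allowed alphabet, file order preserved.
#'
#' @param path Path to a FASTA file.
#' @return A [proteome] object.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aa <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop("failed to parse FASTA '", path, "': ",
                             conditionMessage(e))
  )
  if (length(aa) == 0) stop("no FASTA records in ", path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1)
  proteome(ids, as.character(aa))
}

#' Write a proteome to FASTA
#'
#' @param x A [proteome].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(inherits(x, "proteome"))
  writeLines(rbind(paste0(">", x$ids), unname(x$seqs)), path)
  invisible(path)
}

#' Construct an undirected interaction graph
#'
#' The known-PPI "database": vertices are protein ids, edges are unordered,
#' deduplicated id pairs. Self-loops (homodimers) are dropped with a warning
#' unless `allow_self = TRUE`.
#'
#' @param edges Two-column character matrix or data frame of id pairs.
#' @param vertices Optional character vector of vertex ids; defaults to the
#'   ids appearing in `edges`. Extra ids become isolated vertices.
#' @param allow_self Keep self-loop rows as homodimer edges (default FALSE).
#' @return An object of class `interaction_graph` with elements `vertices`,
#'   `edges` (two-column character matrix, each row in sorted order, unique)
#'   and `adjacency` (named list: id -> character vector of neighbors).
#' @export
interaction_graph <- function(edges, vertices = NULL, allow_self = FALSE) {
  edges <- as.matrix(edges)
  if (length(edges) == 0) {
    edges <- matrix(character(0), ncol = 2)
  }
  storage.mode(edges) <- "character"
  if (ncol(edges) < 2) stop("edges need two columns")
  edges <- edges[, 1:2, drop = FALSE]
  self <- edges[, 1] == edges[, 2]
  if (any(self) && !allow_self) {
    warning(sum(self), " self-loop row(s) dropped (set allow_self = TRUE to keep)")
    edges <- edges[!self, , drop = FALSE]
  }
  # canonical unordered storage: (min, max) per row
  if (nrow(edges) > 0) {
    a <- pmin(edges[, 1], edges[, 2])
    b <- pmax(edges[, 1], edges[, 2])
    keep <- !duplicated(paste(a, b, sep = "\r"))
    a <- a[keep]; b <- b[keep]
    ord <- order(a, b)  # canonical row order: storage independent of input order
    edges <- cbind(a[ord], b[ord])
  }
  vertices <- sort(unique(c(vertices, as.vector(edges))))
  adjacency <- rep(list(character(0)), length(vertices))
  names(adjacency) <- vertices
  if (nrow(edges) > 0) {
    nb1 <- split(edges[, 2], edges[, 1])
    nb2 <- split(edges[, 1], edges[, 2])
    for (v in names(nb1)) adjacency[[v]] <- c(adjacency[[v]], nb1[[v]])
    for (v in names(nb2)) adjacency[[v]] <- c(adjacency[[v]], nb2[[v]])
    adjacency <- lapply(adjacency, function(x) sort(unique(x)))
  }
  colnames(edges) <- c("id_a", "id_b")
  structure(list(vertices = vertices, edges = edges, adjacency = adjacency),
            class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat("interaction_graph:", length(x$vertices), "vertices,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Vertex degrees of an interaction graph
#'
#' @param graph An [interaction_graph].
#' @return Named integer vector of degrees (self-loops count 1).
#' @export
graph_degrees <- function(graph) {
  stopifnot(inherits(graph, "interaction_graph"))
  vapply(graph$adjacency, length, integer(1))
}

#' Test for edge membership
#'
#' @param graph An [interaction_graph].
#' @param id_a,id_b Protein ids.
#' @return Logical scalar.
#' @export
has_edge <- function(graph, id_a, id_b) {
  nb <- graph$adjacency[[id_a]]
  !is.null(nb) && id_b %in% nb
}

#' Remove one undirected edge from a graph
#'
#' Used by the leave-one-out protocol: the held-out known pair is removed
#' from the database before that same pair is scored.
#'
#' @param graph An [interaction_graph].
#' @param id_a,id_b Endpoints of the edge to remove.
#' @return A new `interaction_graph` without the edge (vertices retained).
#' @export
remove_edge <- function(graph, id_a, id_b) {
  if (!has_edge(graph, id_a, id_b)) {
    stop("edge (", id_a, ", ", id_b, ") not present in graph")
  }
  a <- min(id_a, id_b); b <- max(id_a, id_b)
  drop <- graph$edges[, 1] == a & graph$edges[, 2] == b
  graph$edges <- graph$edges[!drop, , drop = FALSE]
  graph$adjacency[[id_a]] <- setdiff(graph$adjacency[[id_a]], id_b)
  graph$adjacency[[id_b]] <- setdiff(graph$adjacency[[id_b]], id_a)
  graph
}

#' Read a TSV edge list into an interaction graph
#'
#' Expects two or more tab-separated columns of protein ids; only the first
#' two columns are used. Lines starting with `#` are ignored; an optional
#' header row whose first field begins with "id" (case-insensitive) is
#' skipped. Reversed and repeated rows collapse to a single undirected edge.
#'
#' @param path Path to the TSV file.
#' @param proteome Optional [proteome] to resolve ids against.
#' @param skip_unknown If TRUE (default), rows whose ids are absent from
#'   `proteome` are skipped with a warning; if FALSE such rows are an error.
#' @param allow_self Keep homodimer rows (default FALSE, dropped with warning).
#' @return An [interaction_graph]. When `proteome` is given, its full id set
#'   forms the vertex set, so unconnected proteins appear as isolated
#'   vertices.
#' @export
read_edges <- function(path, proteome = NULL, skip_unknown = TRUE,
                       allow_self = FALSE) {
  if (!file.exists(path)) stop("edge file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0) stop("no usable edges in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2)) {
    bad <- which(lengths(fields) < 2)[1]
    stop("line ", bad, " of ", path, " has fewer than 2 columns")
  }
  mat <- t(vapply(fields, function(f) f[1:2], character(2)))
  if (grepl("^id", mat[1, 1], ignore.case = TRUE)) {
    mat <- mat[-1, , drop = FALSE]
  }
  vertices <- NULL
  if (!is.null(proteome)) {
    known <- mat[, 1] %in% proteome$ids & mat[, 2] %in% proteome$ids
    if (any(!known)) {
      if (!skip_unknown) {
        stop(sum(!known), " edge row(s) reference ids absent from the proteome")
      }
      warning(sum(!known), " edge row(s) skipped: ids absent from the proteome")
      mat <- mat[known, , drop = FALSE]
    }
    vertices <- proteome$ids
  }
  if (nrow(mat) == 0) stop("zero usable edges in ", path)
  g <- interaction_graph(mat, vertices = vertices, allow_self = allow_self)
  if (nrow(g$edges) == 0) stop("zero usable edges in ", path)
  g
}

#' Write predictions to a TSV file
#'
#' Columns `id_a, id_b, score, interacts`, ordered by score descending
#' (higher score = higher confidence), ties broken lexicographically by
#' `(id_a, id_b)` so output files are bit-reproducible.
#'
#' @param predictions Data frame with columns `id_a`, `id_b`, `score`,
#'   `interacts` (extra columns are preserved).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  need <- c("id_a", "id_b", "score", "interacts")
  if (!all(need %in% names(predictions))) {
    stop("predictions must have columns: ", paste(need, collapse = ", "))
  }
  ord <- order(-predictions$score, predictions$id_a, predictions$id_b)
  out <- predictions[ord, , drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a prediction TSV written by [write_predictions()]
#'
#' @param path Path to the prediction TSV.
#' @return Data frame with columns `id_a`, `id_b`, `score`, `interacts`.
#' @export
read_predictions <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = NA, stringsAsFactors = FALSE)
  df$id_a <- as.character(df$id_a)
  df$id_b <- as.character(df$id_b)
  df
}

#' Write a cluster set to TSV
#'
#' One cluster per line: cluster id, size, then the tab-separated member ids.
#'
#' @param clusters A [cluster_set] or plain list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  members <- if (inherits(clusters, "cluster_set")) clusters$clusters else clusters
  lines <- vapply(seq_along(members), function(i) {
    paste(c(i, length(members[[i]]), sort(members[[i]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
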