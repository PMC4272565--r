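# Substitution matrices: the bundled PAM120 and NCBI-format text files.

#' Load a substitution matrix
#'
#' Resolves either the bundled matrix name `"PAM120"` (the `PAM120` data
#' matrix distributed with Biostrings) or the path of an NCBI-format
#' substitution matrix text file (a header row of residue letters followed
#' by one labelled score row per letter; `#` comment lines ignored).
#'
#' The source matrix must be symmetric and complete over its own alphabet;
#' both are verified on load. Letter pairs absent from the source (e.g. the
#' rare residues U and O, which PAM120 does not cover) score a configurable
#' constant penalty, `ambiguity_score`, whose default of -8 is in line with
#' the worst PAM120 mismatch scores.
#'
#' @param path_or_name Matrix name (`"PAM120"`) or path to an NCBI-format file.
#' @param ambiguity_score Integer score for letter pairs absent from the
#'   source matrix (default -8).
#' @return An object of class `substitution_matrix`: list with `alphabet`
#'   (letters present in the source), `scores` (named integer matrix over
#'   the source alphabet) and `full` (27 x 27 integer matrix over `A..Z, *`
#'   used by the scoring kernels).
#' @examples
#' S <- load_substitution_matrix("PAM120")
#' subst_score(S, "A", "A")
#' @export
load_substitution_matrix <- function(path_or_name = "PAM120",
                                     ambiguity_score = -8L) {
  if (file.exists(path_or_name)) {
    m <- .parse_ncbi_matrix(path_or_name)
  } else if (toupper(path_or_name) == "PAM120") {
    env <- new.env()
    utils::data("PAM120", package = "Biostrings", envir = env)
    m <- env$PAM120
  } else {
    stop("substitution matrix not found: '", path_or_name,
         "' is neither a file nor a bundled matrix name")
  }
  storage.mode(m) <- "integer"
  alphabet <- colnames(m)
  if (is.null(alphabet) || !identical(alphabet, rownames(m))) {
    stop("matrix rows and columns must carry the same letter labels")
  }
  if (any(is.na(m))) stop("substitution matrix has missing letter pairs")
  if (!isTRUE(all.equal(m, t(m)))) {
    bad <- which(m != t(m), arr.ind = TRUE)[1, ]
    stop("asymmetric substitution matrix: S(", alphabet[bad[1]], ",",
         alphabet[bad[2]], ") != S(", alphabet[bad[2]], ",", alphabet[bad[1]], ")")
  }
  full <- matrix(as.integer(ambiguity_score), 27, 27,
                 dimnames = list(.CODE_LETTERS, .CODE_LETTERS))
  keep <- intersect(alphabet, .CODE_LETTERS)
  full[keep, keep] <- m[keep, keep]
  structure(list(alphabet = alphabet, scores = m, full = full,
                 ambiguity_score = as.integer(ambiguity_score),
                 source = path_or_name),
            class = "substitution_matrix")
}

# NCBI-format parser: optional '#' comments, a header row of letters, then one
# row per letter beginning with its label.
.parse_ncbi_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) < 2) stop("not an NCBI-format matrix: ", path)
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- length(header)
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  labels <- vapply(rows, `[`, character(1), 1)
  if (length(rows) < n || !all(header %in% labels)) {
    missing <- setdiff(header, labels)
    stop("matrix file ", path, " is missing row(s): ",
         paste(missing, collapse = ", "))
  }
  m <- matrix(NA_integer_, n, n, dimnames = list(header, header))
  for (r in rows) {
    if (!(r[1] %in% header)) next
    vals <- suppressWarnings(as.integer(r[-1]))
    if (length(vals) != n || any(is.na(vals))) {
      stop("malformed matrix row for letter '", r[1], "' in ", path)
    }
    m[r[1], ] <- vals
  }
  m
}

#' Look up substitution scores
#'
#' @param S A [load_substitution_matrix()] result.
#' @param x,y Single residue letters (vectorized).
#' @return Integer score(s).
#' @export
subst_score <- function(S, x, y) {
  stopifnot(inherits(S, "substitution_matrix"))
  S$full[cbind(encode_sequence(paste(x, collapse = "")),
               encode_sequence(paste(y, collapse = "")))]
}

#' @export
print.substitution_matrix <- function(x, ...) {
  cat("substitution_matrix (", x$source, "): ", length(x$alphabet),
      " letters, ambiguity score ", x$ambiguity_score, "\n", sep = "")
  invisible(x)
}
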