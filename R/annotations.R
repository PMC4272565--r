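# Protein -> annotation-term tables, one namespace among CC / MF / BP.

#' Construct an annotation table
#'
#' @param df Data frame with columns `protein_id`, `namespace` (one of
#'   `"CC"`, `"MF"`, `"BP"`) and `term`, one row per assignment.
#' @return An object of class `annotation_table`: list with elements `CC`,
#'   `MF`, `BP`, each a named list mapping protein id to a character vector
#'   of terms. Proteins absent from a namespace are simply unannotated there.
#' @export
annotation_table <- function(df) {
  need <- c("protein_id", "namespace", "term")
  if (!all(need %in% names(df))) {
    stop("annotation data needs columns: ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(df$namespace), c("CC", "MF", "BP"))
  if (length(bad) > 0) {
    stop("unknown annotation namespace(s): ", paste(bad, collapse = ", "))
  }
  out <- lapply(c(CC = "CC", MF = "MF", BP = "BP"), function(ns) {
    sub <- df[df$namespace == ns, , drop = FALSE]
    if (nrow(sub) == 0) return(list())
    lapply(split(as.character(sub$term), as.character(sub$protein_id)), unique)
  })
  structure(out, class = "annotation_table")
}

#' Read an annotation TSV
#'
#' Expects three tab-separated columns `protein_id`, `namespace`, `term`
#' (header optional, `#` comments ignored), one row per term assignment.
#'
#' @param path Path to the TSV file.
#' @return An [annotation_table()].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3)) stop("annotation rows need 3 columns")
  mat <- t(vapply(fields, function(f) f[1:3], character(3)))
  if (grepl("^protein", mat[1, 1], ignore.case = TRUE)) {
    mat <- mat[-1, , drop = FALSE]
  }
  annotation_table(data.frame(protein_id = mat[, 1], namespace = mat[, 2],
                              term = mat[, 3], stringsAsFactors = FALSE))
}

#' Flatten one namespace of an annotation table
#'
#' @param annotations An [annotation_table()].
#' @param namespace One of `"CC"`, `"MF"`, `"BP"`.
#' @return Named list: protein id -> character vector of terms.
#' @export
annotation_namespace <- function(annotations, namespace = c("CC", "MF", "BP")) {
  namespace <- match.arg(namespace)
  annotations[[namespace]]
}
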