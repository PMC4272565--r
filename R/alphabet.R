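# Residue alphabet and integer encoding shared by the scoring kernels.
#
# Sequences are encoded as 1-based codes over A..Z plus '*' (code 27); the
# substitution matrix is expanded onto this 27-letter code space so kernel
# lookups never branch on ambiguity codes.

.CODE_LETTERS <- c(LETTERS, "*")

# the 20 canonical amino acids
.CANONICAL_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# ambiguity / non-canonical codes accepted in input sequences
.AMBIGUITY_AA <- c("B", "Z", "X", "U", "O", "*")

.ALLOWED_AA <- c(.CANONICAL_AA, .AMBIGUITY_AA)

#' Encode a protein sequence as integer residue codes
#'
#' Maps an uppercase amino-acid string onto 1-based codes over `A..Z` plus
#' `*`, the code space used by the compiled scoring kernels.
#'
#' @param sequence Character scalar, uppercase amino-acid sequence.
#' @return Integer vector of residue codes, one per residue.
#' @keywords internal
encode_sequence <- function(sequence) {
  codes <- utf8ToInt(sequence)
  out <- integer(length(codes))
  alpha <- codes >= 65L & codes <= 90L
  out[alpha] <- codes[alpha] - 64L
  out[codes == 42L] <- 27L
  if (any(out == 0L)) {
    bad <- intToUtf8(codes[out == 0L][1], multiple = TRUE)
    stop("sequence contains unencodable character '", bad, "'")
  }
  out
}

# validate residue letters against the allowed alphabet (design: sequences are
# uppercased on ingest and anything outside alphabet + ambiguity codes is an error)
.check_residues <- function(sequence, id) {
  letters_seen <- unique(strsplit(sequence, "")[[1]])
  bad <- setdiff(letters_seen, .ALLOWED_AA)
  if (length(bad) > 0) {
    stop("protein '", id, "' contains invalid residue letter(s): ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}
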