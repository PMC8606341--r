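#' The standard amino-acid alphabet
#'
#' Returns the 20 standard amino acids in the fixed order used throughout the
#' package: `A R N D C Q E G H I L K M F P S T W Y V`. This order is the one
#' used in profile (PSSM) files, sparse one-hot context encodings, and
#' emission tables; `match(symbol, aa_alphabet())` is a bijection onto 1..20.
#'
#' Non-alphabet characters (X, B, Z, U, O, ...) are handled by the
#' zero-block policy: they map to `NA` residue indices, encode as an all-zero
#' block in context vectors, and are flagged per position.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' Map residue characters to alphabet indices
#'
#' @param chars character vector of single residue characters.
#' @param alphabet ordered character vector of alphabet symbols.
#' @return Integer vector of the same length; `NA` for characters outside the
#'   alphabet (the zero-block unknown policy).
#' @export
match_residues <- function(chars, alphabet = aa_alphabet()) {
  stopifnot(!anyDuplicated(alphabet))
  match(toupper(chars), alphabet)
}
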