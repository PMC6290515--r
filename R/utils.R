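# Internal helpers shared across modules.

# Standard residue alphabet accepted on input: 20 amino acids plus the
# ambiguity/rare codes X, B, Z, U.
AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA_ACCEPTED <- c(AA_STANDARD, "X", "B", "Z", "U")

clamp01 <- function(x) pmin(1, pmax(0, x))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' BLOSUM62 substitution matrix extended with a zero-scoring U row
#'
#' Returns the BLOSUM62 matrix shipped with Biostrings, extended so that
#' selenocysteine (U) — absent from the published matrix — scores 0 against
#' every residue. Ambiguity codes B, Z and X keep their published rows.
#' Tolerates rare residues without rewarding ambiguity.
#'
#' @return An integer substitution matrix with row/column names covering
#'   the accepted residue alphabet.
#' @export
substitution_matrix <- function() {
  mat <- get_blosum62()
  extra <- setdiff(AA_ACCEPTED, rownames(mat))
  if (length(extra) > 0) {
    m2 <- matrix(0L, nrow(mat) + length(extra), ncol(mat) + length(extra),
                 dimnames = list(c(rownames(mat), extra),
                                 c(colnames(mat), extra)))
    m2[rownames(mat), colnames(mat)] <- mat
    mat <- m2
  }
  mat
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})
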