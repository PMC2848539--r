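#' Load a substitution matrix
#'
#' Returns the named substitution matrix as a symmetric integer matrix over
#' the amino-acid alphabet. BLOSUM62 (the default and the matrix used for
#' all identity/similarity statistics here) is taken from Biostrings.
#' Columns involving "X" or any residue outside the matrix alphabet are
#' treated by the metric functions as never identical and never positive.
#'
#' @param name matrix name; currently "BLOSUM62", "BLOSUM45", "BLOSUM80",
#'   "BLOSUM100", "PAM30", "PAM70", "PAM250" (anything shipped as a data set
#'   by Biostrings).
#' @return integer matrix with row/column names.
#' @export
substitution_matrix <- function(name = "BLOSUM62") {
  e <- new.env()
  ok <- tryCatch({
    utils::data(list = name, package = "Biostrings", envir = e)
    TRUE
  }, warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok || !exists(name, envir = e))
    stop("unknown substitution matrix: ", name, call. = FALSE)
  m <- get(name, envir = e)
  if (!isTRUE(all.equal(m, t(m))))
    stop("substitution matrix must be symmetric", call. = FALSE)
  m
}

# score of aligned residue pair under the matrix; NA when either character
# is outside the matrix alphabet
pair_score <- function(matrix, a, b) {
  ok <- a %in% rownames(matrix) & b %in% colnames(matrix)
  s <- rep(NA_real_, length(a))
  if (any(ok)) s[ok] <- matrix[cbind(a[ok], b[ok])]
  s
}
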