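#' @keywords internal
"_PACKAGE"

# Evaluate expr with a local RNG seed, restoring global RNG state afterwards.
# Keeps every generator seedable without touching global state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Three-letter -> one-letter amino acid code; unknown -> "X"
AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
         GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
         LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
         SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
AA1 <- names(AA3)
names(AA1) <- unname(AA3)

aa3_to_1 <- function(resname) {
  out <- AA3[toupper(resname)]
  out[is.na(out)] <- "X"
  unname(out)
}

aa1_to_3 <- function(code) {
  out <- AA1[toupper(code)]
  out[is.na(out)] <- "UNK"
  unname(out)
}

# residue key: author number + insertion code, unique within a chain
res_key <- function(resnum, inscode = "") {
  inscode[is.na(inscode)] <- ""
  paste0(resnum, inscode)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
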