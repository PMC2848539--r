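#' Read a two-chain protein complex from a PDB file
#'
#' Parses ATOM records (HETATM ignored by default), keeps the two requested
#' chains, drops hydrogens, and for alternate-location atoms keeps the
#' highest-occupancy conformer (ties: first encountered). Residue identity is
#' (chain, author number, insertion code); one-letter sequences are derived
#' from residue names in record order, non-standard residues mapping to "X".
#'
#' @param path PDB-format text file.
#' @param chains character vector of the two chain identifiers to keep, or a
#'   single two-character string such as `"AB"`.
#' @param id complex identifier; defaults to the file base name.
#' @param keep_hetatm also parse HETATM records (default FALSE).
#' @return an object of class `complex_structure` with elements `id`,
#'   `chains` (named list; each chain a data.frame of atoms with columns
#'   `resnum`, `inscode`, `resname`, `atom`, `element`, `x`, `y`, `z`) and
#'   `sequences` (named character vector of one-letter sequences).
#' @seealso [write_pdb()], [assign_interface()]
#' @export
read_pdb <- function(path, chains, id = NULL, keep_hetatm = FALSE) {
  lines <- readLines(path, warn = FALSE)
  recs <- substring(lines, 1, 6)
  sel <- recs == "ATOM  " | (keep_hetatm & recs == "HETATM")
  lines <- lines[sel]
  if (length(lines) == 0L) stop("no ATOM records in ", path, call. = FALSE)
  if (length(chains) == 1L && nchar(chains) == 2L)
    chains <- strsplit(chains, "")[[1]]
  if (length(chains) != 2L)
    stop("exactly two chain identifiers must be selected", call. = FALSE)

  atoms <- data.frame(
    chain   = substring(lines, 22, 22),
    resnum  = as.integer(substring(lines, 23, 26)),
    inscode = trimws(substring(lines, 27, 27)),
    resname = trimws(substring(lines, 18, 20)),
    atom    = trimws(substring(lines, 13, 16)),
    altloc  = trimws(substring(lines, 17, 17)),
    occ     = suppressWarnings(as.numeric(substring(lines, 55, 60))),
    element = trimws(substring(lines, 77, 78)),
    x = as.numeric(substring(lines, 31, 38)),
    y = as.numeric(substring(lines, 39, 46)),
    z = as.numeric(substring(lines, 47, 54)),
    stringsAsFactors = FALSE)
  atoms$occ[is.na(atoms$occ)] <- 1
  # element column may be blank in older files: fall back to the atom name
  blank <- atoms$element == ""
  atoms$element[blank] <- guess_element(atoms$atom[blank])
  atoms$element <- toupper(atoms$element)

  avail <- unique(atoms$chain)
  missing <- setdiff(chains, avail)
  if (length(missing) > 0L)
    stop("chain(s) ", paste(missing, collapse = ","),
         " not found; available chains: ", paste(avail, collapse = ","),
         call. = FALSE)
  atoms <- atoms[atoms$chain %in% chains, , drop = FALSE]
  atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]

  # altLoc: keep the highest-occupancy copy of each (chain,res,atom); ties ->
  # first in file order
  key <- paste(atoms$chain, atoms$resnum, atoms$inscode, atoms$atom, sep = "\r")
  ord <- order(factor(key, levels = unique(key)), -atoms$occ)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resnum, atoms$inscode,
                                   atoms$atom, sep = "\r")), , drop = FALSE]
  atoms$altloc <- NULL
  atoms$occ <- NULL

  ch <- lapply(chains, function(cid) {
    a <- atoms[atoms$chain == cid, , drop = FALSE]
    a$chain <- NULL
    rownames(a) <- NULL
    a
  })
  names(ch) <- chains
  if (!all(vapply(ch, nrow, 1L) > 0))
    stop("selected chain has no atoms", call. = FALSE)
  complex_structure(id %||% sub("\\.[^.]*$", "", basename(path)), ch)
}

#' Construct a complex_structure from per-chain atom tables
#'
#' @param id complex identifier.
#' @param chains named list of exactly two atom data.frames (columns
#'   `resnum`, `inscode`, `resname`, `atom`, `element`, `x`, `y`, `z`).
#' @return a `complex_structure`.
#' @export
complex_structure <- function(id, chains) {
  if (length(chains) != 2L || is.null(names(chains)))
    stop("a complex must have exactly two named chains", call. = FALSE)
  for (cid in names(chains)) {
    a <- chains[[cid]]
    if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
      stop("non-finite coordinates in chain ", cid, call. = FALSE)
    if (is.null(a$inscode)) chains[[cid]]$inscode <- ""
  }
  seqs <- vapply(chains, function(a) {
    k <- res_key(a$resnum, a$inscode)
    first <- !duplicated(k)
    if (anyDuplicated(paste(k[first])))
      stop("duplicate residue identifiers within a chain", call. = FALSE)
    paste(aa3_to_1(a$resname[first]), collapse = "")
  }, character(1))
  structure(list(id = id, chains = chains, sequences = seqs),
            class = "complex_structure")
}

# residue-level view of one chain: keys in order of first appearance
chain_residues <- function(chain_atoms) {
  k <- res_key(chain_atoms$resnum, chain_atoms$inscode)
  first <- !duplicated(k)
  data.frame(key = k[first], resnum = chain_atoms$resnum[first],
             inscode = chain_atoms$inscode[first],
             resname = chain_atoms$resname[first], stringsAsFactors = FALSE)
}

guess_element <- function(atom_names) {
  # PDB atom names: element is the first alphabetic character for protein
  # heavy atoms (C,N,O,S,P); 2-char elements do not occur in standard AAs
  el <- sub("^[0-9']*", "", atom_names)
  toupper(substring(el, 1, 1))
}

#' Write a complex to a PDB-format file
#'
#' Emits standard fixed-column ATOM records plus TER/END. Writing then
#' re-reading a structure reproduces the residue and atom inventory exactly;
#' coordinates are kept to 3 decimals as per the PDB format.
#'
#' @param complex a `complex_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(complex, path) {
  stopifnot(inherits(complex, "complex_structure"))
  out <- character(0)
  serial <- 0L
  for (cid in names(complex$chains)) {
    a <- complex$chains[[cid]]
    for (i in seq_len(nrow(a))) {
      serial <- serial + 1L
      nm <- a$atom[i]
      # standard alignment: 1-3 char names start in column 14
      nm_fmt <- if (nchar(nm) < 4L) sprintf(" %-3s", nm) else nm
      out <- c(out, sprintf(
        "ATOM  %5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, nm_fmt, a$resname[i], cid, a$resnum[i],
        ifelse(a$inscode[i] == "", " ", a$inscode[i]),
        a$x[i], a$y[i], a$z[i], 1, 0, a$element[i]))
    }
    out <- c(out, sprintf("TER   %5d      %-3s %1s%4d", serial + 1L,
                          a$resname[nrow(a)], cid, a$resnum[nrow(a)]))
    serial <- serial + 1L
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' @export
print.complex_structure <- function(x, ...) {
  cat("complex", x$id, "| chains:",
      paste(sprintf("%s (%d res, %d atoms)", names(x$chains),
                    nchar(x$sequences),
                    vapply(x$chains, nrow, 1L)), collapse = ", "), "\n")
  invisible(x)
}
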