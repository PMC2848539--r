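#' Construct a pairwise local alignment record
#'
#' The exchange unit of the whole package: one local target-template
#' alignment with its aligned strings (gap character "-"), 1-based inclusive
#' coordinates on both full sequences, and the e-value reported by the
#' search program.
#'
#' @param target_id,template_id sequence identifiers.
#' @param e_value alignment expectation value.
#' @param target_aln,template_aln equal-length aligned strings.
#' @param target_start,target_end 1-based inclusive coordinates of the
#'   aligned region on the full target sequence.
#' @param template_start,template_end same for the template.
#' @param target_full_length,template_full_length full sequence lengths.
#' @param ... extra metadata fields (e.g. `complex_id`, `chain`,
#'   `interface`) carried along untouched.
#' @return a list of class `pairwise_alignment`.
#' @export
pairwise_alignment <- function(target_id, template_id, e_value,
                               target_aln, template_aln,
                               target_start, target_end,
                               template_start, template_end,
                               target_full_length, template_full_length,
                               ...) {
  aln <- c(list(target_id = target_id, template_id = template_id,
                e_value = as.numeric(e_value),
                target_aln = target_aln, template_aln = template_aln,
                target_start = as.integer(target_start),
                target_end = as.integer(target_end),
                template_start = as.integer(template_start),
                template_end = as.integer(template_end),
                target_full_length = as.integer(target_full_length),
                template_full_length = as.integer(template_full_length)),
           list(...))
  class(aln) <- "pairwise_alignment"
  validate_alignment(aln)
  aln
}

#' Validate a pairwise alignment record
#'
#' Checks the structural invariants: equal string lengths, no column gapped
#' on both sides, and agreement between the non-gap target count and the
#' stated coordinates.
#'
#' @param aln a `pairwise_alignment` (or any list with the same fields).
#' @return `aln`, invisibly; errors on violation.
#' @export
validate_alignment <- function(aln) {
  tc <- strsplit(aln$target_aln, "")[[1]]
  pc <- strsplit(aln$template_aln, "")[[1]]
  if (length(tc) != length(pc))
    stop("aligned strings differ in length for ", aln$target_id, "/",
         aln$template_id, call. = FALSE)
  if (any(tc == "-" & pc == "-"))
    stop("column gapped on both sides", call. = FALSE)
  n_ali <- sum(tc != "-")
  if (n_ali != aln$target_end - aln$target_start + 1L)
    stop("target coordinates inconsistent with aligned string (N_ali=",
         n_ali, ", coords give ",
         aln$target_end - aln$target_start + 1L, ")", call. = FALSE)
  if (sum(pc != "-") != aln$template_end - aln$template_start + 1L)
    stop("template coordinates inconsistent with aligned string",
         call. = FALSE)
  if (aln$target_full_length < n_ali)
    stop("target_full_length smaller than aligned residue count",
         call. = FALSE)
  invisible(aln)
}

aln_chars <- function(aln)
  list(t = strsplit(aln$target_aln, "")[[1]],
       p = strsplit(aln$template_aln, "")[[1]])

# columns of the alignment indexed by target sequence position (NA at
# target-gap columns)
target_positions_by_column <- function(aln) {
  tc <- strsplit(aln$target_aln, "")[[1]]
  pos <- rep(NA_integer_, length(tc))
  pos[tc != "-"] <- seq(aln$target_start, aln$target_end)
  pos
}

ALN_TSV_COLS <- c("target_id", "template_id", "e_value",
                  "target_start", "target_end", "template_start",
                  "template_end", "target_aln", "template_aln",
                  "target_full_length", "template_full_length")

#' Read / write alignment pools in the TSV exchange format
#'
#' Tab-separated with a header row; the required columns are
#' target_id, template_id, e_value, target_start, target_end,
#' template_start, template_end, target_aln, template_aln,
#' target_full_length, template_full_length. Extra columns (ground-truth
#' annotations from the synthetic generator, complex ids, ...) round-trip
#' unchanged.
#'
#' @param path file path.
#' @return `read_alignment_tsv`: a data.frame, one alignment per row.
#' @export
read_alignment_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(ALN_TSV_COLS, names(df))
  if (length(miss) > 0L)
    stop("alignment TSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}

#' @rdname read_alignment_tsv
#' @param pool data.frame of alignments.
#' @export
write_alignment_tsv <- function(pool, path) {
  utils::write.table(pool, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# one row of an alignment pool as a pairwise_alignment
pool_row <- function(pool, i) {
  aln <- as.list(pool[i, , drop = FALSE])
  aln <- lapply(aln, function(x) x[[1]])
  class(aln) <- "pairwise_alignment"
  aln
}

#' Parse local alignments from BLAST XML
#'
#' Reads NCBI BLAST XML (one `<Hsp>` per alignment record). Coordinates are
#' already 1-based inclusive in the format and are preserved; e-values are
#' taken from `Hsp_evalue`. The full target length is taken from
#' `Iteration_query-len`, or, if absent, from `target_full_lengths`.
#'
#' @param path BLAST XML file.
#' @param target_full_lengths optional named integer vector giving the full
#'   target sequence length per query id; required for queries whose length
#'   the XML does not state.
#' @return data.frame of alignments in the exchange-format columns.
#' @export
parse_blast_xml <- function(path, target_full_lengths = NULL) {
  doc <- xml2::read_xml(path)
  iters <- xml2::xml_find_all(doc, ".//Iteration")
  if (length(iters) == 0L) stop("no <Iteration> records in ", path,
                                call. = FALSE)
  out <- list()
  for (it in iters) {
    qid <- xml2::xml_text(xml2::xml_find_first(it, "./Iteration_query-def"))
    qlen <- xml2::xml_text(xml2::xml_find_first(it, "./Iteration_query-len"))
    qlen <- if (is.na(qlen) || qlen == "") {
      if (is.null(target_full_lengths) || is.na(target_full_lengths[qid]))
        stop("full length unknown for target ", qid, call. = FALSE)
      as.integer(target_full_lengths[qid])
    } else as.integer(qlen)
    hits <- xml2::xml_find_all(it, ".//Hit")
    for (h in hits) {
      tid <- xml2::xml_text(xml2::xml_find_first(h, "./Hit_def"))
      tlen <- as.integer(xml2::xml_text(xml2::xml_find_first(h, "./Hit_len")))
      hsps <- xml2::xml_find_all(h, ".//Hsp")
      for (hs in hsps) {
        g <- function(tag) xml2::xml_text(xml2::xml_find_first(
          hs, paste0("./", tag)))
        rec <- tryCatch(data.frame(
          target_id = qid, template_id = tid,
          e_value = as.numeric(g("Hsp_evalue")),
          target_start = as.integer(g("Hsp_query-from")),
          target_end = as.integer(g("Hsp_query-to")),
          template_start = as.integer(g("Hsp_hit-from")),
          template_end = as.integer(g("Hsp_hit-to")),
          target_aln = g("Hsp_qseq"), template_aln = g("Hsp_hseq"),
          target_full_length = qlen, template_full_length = tlen,
          stringsAsFactors = FALSE),
          error = function(e) stop("malformed HSP (record ",
                                   length(out) + 1L, "): ",
                                   conditionMessage(e), call. = FALSE))
        out[[length(out) + 1L]] <- rec
      }
    }
  }
  if (length(out) == 0L)
    return(stats::setNames(data.frame(matrix(ncol = length(ALN_TSV_COLS),
                                             nrow = 0)), ALN_TSV_COLS))
  do.call(rbind, out)
}

#' Write an alignment pool as minimal BLAST XML
#'
#' Emits one `<Iteration>` per target id with one `<Hit>`/`<Hsp>` per
#' alignment; [parse_blast_xml()] reads the result back losslessly (for the
#' exchange-format columns).
#'
#' @param pool alignment data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_blast_xml <- function(pool, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  lines <- c("<?xml version=\"1.0\"?>", "<BlastOutput>",
             "<BlastOutput_iterations>")
  # one <Iteration> per record: synthetic pools may reuse a target id with
  # differing full lengths, which a shared per-query header cannot express
  for (i in seq_len(nrow(pool))) {
    sub <- pool[i, , drop = FALSE]
    lines <- c(lines, "<Iteration>",
               paste0("<Iteration_query-def>", esc(sub$target_id),
                      "</Iteration_query-def>"),
               paste0("<Iteration_query-len>", sub$target_full_length,
                      "</Iteration_query-len>"),
               "<Iteration_hits>")
    lines <- c(lines, "<Hit>",
      paste0("<Hit_def>", esc(sub$template_id), "</Hit_def>"),
      paste0("<Hit_len>", sub$template_full_length, "</Hit_len>"),
      "<Hit_hsps><Hsp>",
      paste0("<Hsp_evalue>", format(sub$e_value, digits = 17),
             "</Hsp_evalue>"),
      paste0("<Hsp_query-from>", sub$target_start, "</Hsp_query-from>"),
      paste0("<Hsp_query-to>", sub$target_end, "</Hsp_query-to>"),
      paste0("<Hsp_hit-from>", sub$template_start, "</Hsp_hit-from>"),
      paste0("<Hsp_hit-to>", sub$template_end, "</Hsp_hit-to>"),
      paste0("<Hsp_qseq>", sub$target_aln, "</Hsp_qseq>"),
      paste0("<Hsp_hseq>", sub$template_aln, "</Hsp_hseq>"),
      "</Hsp></Hit_hsps>", "</Hit>",
      "</Iteration_hits>", "</Iteration>")
  }
  writeLines(c(lines, "</BlastOutput_iterations>", "</BlastOutput>"), path)
  invisible(path)
}

#' Read full-length sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  s <- Biostrings::readAAStringSet(path)
  out <- as.character(s)
  names(out) <- sub("\\s.*$", "", names(s))
  out
}
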