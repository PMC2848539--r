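#' Target sequence coverage of a local alignment
#'
#' q = 100 * N_ali / N_tot, where N_ali is the number of target residues in
#' the alignment (non-gap characters of the aligned target string) and
#' N_tot the full target sequence length.
#'
#' @param aln a `pairwise_alignment` (or one pool row, see [pool_row()]).
#' @return coverage percent in (0, 100].
#' @export
target_coverage <- function(aln) {
  if (aln$target_full_length == 0L)
    stop("target_full_length is zero", call. = FALSE)
  n_ali <- sum(strsplit(aln$target_aln, "")[[1]] != "-")
  100 * n_ali / aln$target_full_length
}

#' Interface coverage of a local alignment
#'
#' q_int = 100 * N_int_ali / N_int_tot: the fraction of the target's
#' interface residues whose sequence position is covered by a non-gap
#' target column of the alignment.
#'
#' @param aln a `pairwise_alignment`.
#' @param interface integer vector of interface residue positions on the
#'   full target sequence (1-based).
#' @return list with `q_int` (percent) and `missing` (N_int_tot - N_int_ali).
#' @export
interface_coverage <- function(aln, interface) {
  interface <- unique(as.integer(interface))
  if (length(interface) == 0L)
    stop("empty interface: complexes without interface residues are excluded upstream",
         call. = FALSE)
  covered <- interface >= aln$target_start & interface <= aln$target_end
  list(q_int = 100 * sum(covered) / length(interface),
       missing = sum(!covered))
}

#' Full-interface-coverage (FIC) classification
#'
#' An alignment is FIC when at most `tolerance` target interface residues
#' are missing from it (default tolerance: one residue).
#'
#' @param missing_interface_count number of interface residues not covered.
#' @param tolerance maximum number of missing residues still counted as
#'   full coverage (default 1).
#' @return logical.
#' @export
classify_fic <- function(missing_interface_count, tolerance = 1L) {
  if (any(missing_interface_count < 0)) stop("missing count must be >= 0",
                                             call. = FALSE)
  missing_interface_count <= tolerance
}

#' Alignment identity and similarity
#'
#' a_iden = 100 * N_iden / L_ali and a_sim = 100 * N_pos / L_ali, with
#' L_ali the alignment length counted as target residues in the alignment
#' plus gaps in the aligned target string (i.e. the full column count),
#' N_iden the number of identically aligned residue pairs, and N_pos the
#' number of aligned pairs with a positive substitution-matrix score.
#' Columns containing "X" or characters outside the matrix alphabet are
#' never identical and never positive; gap columns on either side never
#' contribute to the numerators.
#'
#' @param aln a `pairwise_alignment`.
#' @param matrix substitution matrix from [substitution_matrix()].
#' @return list with `a_iden`, `a_sim` (percent) and the raw counts
#'   `l_ali`, `n_iden`, `n_pos`.
#' @examples
#' aln <- pairwise_alignment("t", "p", 1e-3, "KRDE", "RRDS", 1, 4, 1, 4, 4, 4)
#' alignment_identity_similarity(aln)  # 50% identity, 75% similarity
#' @export
alignment_identity_similarity <- function(aln,
                                          matrix = substitution_matrix()) {
  ch <- aln_chars(aln)
  ok_t <- c("-", "X", rownames(matrix))
  ok_p <- c("-", "X", colnames(matrix))
  bad <- !(ch$t %in% ok_t) | !(ch$p %in% ok_p)
  if (any(bad))
    stop("character outside alphabet at column ", which(bad)[1],
         call. = FALSE)
  l_ali <- length(ch$t)
  counts <- column_counts(ch$t, ch$p, matrix)
  list(a_iden = 100 * counts$n_iden / l_ali,
       a_sim = 100 * counts$n_pos / l_ali,
       l_ali = l_ali, n_iden = counts$n_iden, n_pos = counts$n_pos)
}

# shared column accounting for Eq. 3/4: identity and positivity per column
column_counts <- function(tc, pc, matrix) {
  both <- tc != "-" & pc != "-"
  known <- both & tc != "X" & pc != "X"
  iden <- known & tc == pc
  s <- rep(NA_real_, length(tc))
  if (any(known)) s[known] <- pair_score(matrix, tc[known], pc[known])
  pos <- !is.na(s) & s > 0
  list(iden = iden, pos = pos,
       n_iden = sum(iden), n_pos = sum(pos))
}

#' Interface identity and similarity
#'
#' Same ratios as [alignment_identity_similarity()] but restricted to
#' columns whose target residue belongs to the target complex interface;
#' the denominator is the number of interface target residues present in
#' the alignment (N_int_ali). Defined for FIC alignments, where (nearly)
#' all interface residues are inside the alignment.
#'
#' @inheritParams alignment_identity_similarity
#' @param interface integer vector of interface positions on the full
#'   target sequence.
#' @return list with `i_iden`, `i_sim` (percent) and `n_int_ali`.
#' @export
interface_identity_similarity <- function(aln, interface,
                                          matrix = substitution_matrix()) {
  ch <- aln_chars(aln)
  pos <- target_positions_by_column(aln)
  on_iface <- !is.na(pos) & pos %in% as.integer(interface)
  n_int_ali <- sum(on_iface)
  if (n_int_ali == 0L)
    stop("no interface residues inside the alignment", call. = FALSE)
  counts <- column_counts(ch$t, ch$p, matrix)
  list(i_iden = 100 * sum(counts$iden & on_iface) / n_int_ali,
       i_sim = 100 * sum(counts$pos & on_iface) / n_int_ali,
       n_int_ali = n_int_ali)
}

#' Domain coverage
#'
#' Coverage of a user-supplied domain: percentage of domain positions
#' covered by the aligned target region.
#'
#' @param aln a `pairwise_alignment`.
#' @param domain_range integer vector of target positions forming the
#'   domain (need not be contiguous).
#' @return percent in [0, 100].
#' @export
domain_coverage <- function(aln, domain_range) {
  domain_range <- unique(as.integer(domain_range))
  if (length(domain_range) == 0L) stop("empty domain", call. = FALSE)
  covered <- domain_range >= aln$target_start & domain_range <= aln$target_end
  100 * sum(covered) / length(domain_range)
}

#' Filter an alignment pool
#'
#' Applies the two pool-level exclusion rules: (a) statistically
#' insignificant alignments with e-value strictly greater than
#' `max_evalue`; (b) near-identical target/template pairs, where the
#' difference between the two sequences - substituted aligned positions
#' plus unaligned target residues plus unaligned template residues - is
#' below `min_difference` residues. Rule (b) removes a protein aligned to
#' itself or to a close mutant.
#'
#' @param pool alignment data.frame (exchange-format columns).
#' @param max_evalue e-value cutoff, kept when `e <= max_evalue` (default 1).
#' @param min_difference minimum target/template difference in residues
#'   (default 10); pairs with difference `< min_difference` are excluded.
#' @return list with `kept` (data.frame) and `excluded` (data.frame with an
#'   extra `reason` column, "evalue" or "near-identical").
#' @export
filter_pool <- function(pool, max_evalue = 1, min_difference = 10L) {
  n <- nrow(pool)
  reason <- rep(NA_character_, n)
  reason[pool$e_value > max_evalue] <- "evalue"
  todo <- which(is.na(reason))
  for (i in todo) {
    if (sequence_difference(pool_row(pool, i)) < min_difference)
      reason[i] <- "near-identical"
  }
  kept <- pool[is.na(reason), , drop = FALSE]
  excluded <- pool[!is.na(reason), , drop = FALSE]
  if (nrow(excluded) > 0L) excluded$reason <- reason[!is.na(reason)]
  else excluded$reason <- character(0)
  rownames(kept) <- rownames(excluded) <- NULL
  list(kept = kept, excluded = excluded)
}

# operational target/template difference: substituted aligned positions +
# unaligned target residues + unaligned template residues
sequence_difference <- function(aln) {
  ch <- aln_chars(aln)
  both <- ch$t != "-" & ch$p != "-"
  subs <- sum(both & ch$t != ch$p)
  unaligned_target <- aln$target_full_length - sum(ch$t != "-")
  unaligned_template <- aln$template_full_length - sum(ch$p != "-")
  subs + unaligned_target + unaligned_template
}

#' Subgroup a pool by maximal target coverage
#'
#' Returns the alignments with target sequence coverage `q <= q_max`.
#'
#' @param pool alignment data.frame; if a `q` column is absent it is
#'   computed on the fly.
#' @param q_max coverage upper bound in percent, in (0, 100].
#' @return the sub-pool data.frame.
#' @export
subset_by_qmax <- function(pool, q_max) {
  if (q_max <= 0 || q_max > 100) stop("q_max must be in (0,100]",
                                      call. = FALSE)
  q <- pool$q
  if (is.null(q))
    q <- vapply(seq_len(nrow(pool)),
                function(i) target_coverage(pool_row(pool, i)), numeric(1))
  out <- pool[q <= q_max, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compute all per-alignment metrics for a pool
#'
#' For each alignment: target coverage q, interface coverage q_int with
#' missing-residue count, FIC flag, alignment identity/similarity
#' (a_iden/a_sim), and, for FIC alignments only, interface
#' identity/similarity (i_iden/i_sim; NA otherwise, since these are
#' ill-defined when the interface is largely absent from the alignment).
#' Optional domain coverage q_dom.
#'
#' @param pool alignment data.frame. Interface positions are taken from the
#'   `interfaces` argument keyed by `target_id`, or from a per-row
#'   `interface` column of comma-separated positions.
#' @param interfaces named list (by target_id) of integer position vectors.
#' @param matrix substitution matrix.
#' @param fic_tolerance FIC tolerance in missing residues (default 1).
#' @param domains optional named list (by target_id) of domain position
#'   vectors; adds a `q_dom` column (NA for targets without a domain).
#' @return data.frame: target_id, template_id, e_value, plus metric columns
#'   q, q_int, missing, is_fic, a_iden, a_sim, i_iden, i_sim, q_dom and any
#'   `complex_id`/`chain` columns present in the pool.
#' @export
compute_alignment_metrics <- function(pool, interfaces = NULL,
                                      matrix = substitution_matrix(),
                                      fic_tolerance = 1L, domains = NULL) {
  n <- nrow(pool)
  get_iface <- function(aln) {
    if (!is.null(interfaces) && !is.null(interfaces[[aln$target_id]]))
      return(interfaces[[aln$target_id]])
    if (!is.null(aln$interface))
      return(as.integer(strsplit(as.character(aln$interface), ",")[[1]]))
    stop("no interface definition for target ", aln$target_id,
         call. = FALSE)
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    aln <- pool_row(pool, i)
    validate_alignment(aln)
    iface <- get_iface(aln)
    q <- target_coverage(aln)
    cov <- interface_coverage(aln, iface)
    fic <- classify_fic(cov$missing, fic_tolerance)
    ais <- alignment_identity_similarity(aln, matrix)
    if (fic && cov$missing < length(iface)) {
      iis <- interface_identity_similarity(aln, iface, matrix)
      i_iden <- iis$i_iden; i_sim <- iis$i_sim
    } else { i_iden <- NA_real_; i_sim <- NA_real_ }
    q_dom <- NA_real_
    if (!is.null(domains) && !is.null(domains[[aln$target_id]]))
      q_dom <- domain_coverage(aln, domains[[aln$target_id]])
    rows[[i]] <- data.frame(
      target_id = aln$target_id, template_id = aln$template_id,
      complex_id = aln$complex_id %||% NA_character_,
      chain = aln$chain %||% NA_character_,
      e_value = aln$e_value, q = q, q_int = cov$q_int,
      missing = cov$missing, is_fic = fic,
      a_iden = ais$a_iden, a_sim = ais$a_sim,
      i_iden = i_iden, i_sim = i_sim, q_dom = q_dom,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
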