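mk_aln <- function(taln, paln, tstart = 1, tfull = NULL, pstart = 1,
                   pfull = NULL, e = 1e-5, ...) {
  nt <- sum(strsplit(taln, "")[[1]] != "-")
  np <- sum(strsplit(paln, "")[[1]] != "-")
  pairwise_alignment("tgt", "tpl", e, taln, paln,
                     tstart, tstart + nt - 1, pstart, pstart + np - 1,
                     tfull %||% (tstart + nt - 1),
                     pfull %||% (pstart + np - 1), ...)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("target coverage is N_ali / N_tot", {
  expect_equal(target_coverage(mk_aln("ACDEF", "ACDEF", tfull = 5)), 100)
  aln <- mk_aln(strrep("A", 40), strrep("C", 40), tfull = 100)
  expect_equal(target_coverage(aln), 40)
  # gaps in the target string do not count as covered residues
  expect_equal(target_coverage(mk_aln("AC-EF", "ACDEF", tfull = 8)),
               100 * 4 / 8)
})

test_that("interface coverage counts covered interface positions", {
  aln <- mk_aln(strrep("K", 20), strrep("R", 20), tstart = 11, tfull = 50)
  all_in <- interface_coverage(aln, 11:20)
  expect_equal(all_in$q_int, 100); expect_equal(all_in$missing, 0)
  some <- interface_coverage(aln, c(11:18, 40, 45))
  expect_equal(some$q_int, 80); expect_equal(some$missing, 2)
  expect_error(interface_coverage(aln, integer(0)), "empty interface")
})

test_that("FIC tolerance boundaries", {
  expect_true(classify_fic(0))
  expect_true(classify_fic(1))
  expect_false(classify_fic(2))
  expect_false(classify_fic(1, tolerance = 0))
  expect_error(classify_fic(-1), ">= 0")
})

test_that("identity/similarity worked example under BLOSUM62", {
  res <- alignment_identity_similarity(mk_aln("KRDE", "RRDS"))
  expect_equal(res$a_iden, 50)   # R/R, D/D identical
  expect_equal(res$a_sim, 75)    # K/R=2, R/R=5, D/D=6 positive; E/S=0 not
  perfect <- alignment_identity_similarity(mk_aln("ACDEFG", "ACDEFG"))
  expect_equal(perfect$a_iden, 100); expect_equal(perfect$a_sim, 100)
})

test_that("gap columns enter L_ali but never the numerators", {
  # 4 target residues + 2 target-side gaps: L_ali = 6
  res <- alignment_identity_similarity(mk_aln("KR-D-E", "RRDDSE"))
  expect_equal(res$l_ali, 6)
  expect_equal(res$a_iden, 100 * 3 / 6)  # R/R, D/D, E/E
  # template-side gap: target residue counts toward L_ali only
  res2 <- alignment_identity_similarity(mk_aln("KRDE", "RR-S"))
  expect_equal(res2$l_ali, 4)
  expect_equal(res2$a_iden, 100 * 1 / 4)
})

test_that("X columns are never identical and never positive", {
  res <- alignment_identity_similarity(mk_aln("XKXK", "XKKK"))
  expect_equal(res$n_iden, 2)  # only the K/K pairs
  expect_equal(res$n_pos, 2)
  expect_error(alignment_identity_similarity(mk_aln("K1DE", "RRDS")),
               "column 2")
})

test_that("interface identity/similarity restricts to interface columns", {
  aln <- mk_aln("KRDE", "RRDS", tfull = 10)
  res <- interface_identity_similarity(aln, interface = c(2, 3))
  expect_equal(res$i_iden, 100)  # R/R and D/D
  expect_equal(res$i_sim, 100)
  # conserved-but-not-identical binding site: i_iden 0, i_sim 100
  # (K/R=2, D/E=2, E/D=2: all positive, none identical)
  res2 <- interface_identity_similarity(mk_aln("KDEK", "REDK"), c(1, 2, 3))
  expect_equal(res2$i_iden, 0)
  expect_equal(res2$i_sim, 100)
  expect_error(interface_identity_similarity(aln, interface = c(9, 10)),
               "no interface residues")
})

test_that("domain coverage", {
  aln <- mk_aln(strrep("A", 45), strrep("G", 45), tstart = 1, tfull = 100)
  expect_equal(domain_coverage(aln, 1:45), 100)
  expect_equal(domain_coverage(aln, 1:50), 90)
  expect_error(domain_coverage(aln, integer(0)), "empty domain")
})

test_that("metrics equal the column-scan oracle on random pools", {
  pool <- make_alignment_pool(planted_curve(rep(0.5, 20)), 300, seed = 31)
  mat <- substitution_matrix()
  m <- compute_alignment_metrics(pool, matrix = mat)
  for (i in seq_len(nrow(pool))) {
    aln <- pool_row_for_test(pool, i)
    iface <- as.integer(strsplit(aln$interface, ",")[[1]])
    o <- oracle_metrics(aln, iface, mat)
    expect_equal(m$q[i], o$q, tolerance = 1e-12)
    expect_equal(m$q_int[i], o$q_int, tolerance = 1e-12)
    expect_identical(as.integer(m$missing[i]), as.integer(o$missing))
    expect_equal(m$a_iden[i], o$a_iden, tolerance = 1e-12)
    expect_equal(m$a_sim[i], o$a_sim, tolerance = 1e-12)
    if (m$is_fic[i]) {
      expect_equal(m$i_iden[i], o$i_iden, tolerance = 1e-12)
      expect_equal(m$i_sim[i], o$i_sim, tolerance = 1e-12)
    }
  }
  expect_true(all(m$a_iden <= m$a_sim + 1e-12))
  fic <- m$is_fic & !is.na(m$i_iden)
  expect_true(all(m$i_iden[fic] <= m$i_sim[fic] + 1e-12))
})

test_that("pool filters: e-value strict at 1, near-identical by difference", {
  base <- mk_aln(strrep("K", 30), strrep("K", 30), tfull = 33, pfull = 33)
  pool <- do.call(rbind, lapply(c(2.0, 1.0, 0.5), function(e) {
    r <- as.data.frame(unclass(base), stringsAsFactors = FALSE)
    r$e_value <- e
    r
  }))
  out <- filter_pool(pool)
  # e = 2.0 excluded by the e-value rule; e = 1.0 passes it (strict >) but
  # both remaining rows then fall to the near-identical rule:
  # difference = 0 subs + 3 + 3 unaligned = 6 < 10
  expect_identical(out$excluded$reason[out$excluded$e_value == 2.0],
                   "evalue")
  expect_identical(out$excluded$reason[out$excluded$e_value <= 1.0],
                   c("near-identical", "near-identical"))
  expect_identical(nrow(out$kept), 0L)
  expect_identical(nrow(out$excluded), 3L)
})

test_that("near-identical rule uses substitutions + unaligned residues", {
  taln <- strrep("K", 30)
  paln <- paste0("RRR", strrep("K", 27))  # 3 substitutions
  r3 <- as.data.frame(unclass(mk_aln(taln, paln, tfull = 30, pfull = 30)),
                      stringsAsFactors = FALSE)
  out <- filter_pool(r3)
  expect_identical(out$excluded$reason, "near-identical")  # 3 < 10
  paln2 <- paste0(strrep("R", 10), strrep("K", 20))  # 10 substitutions
  r10 <- as.data.frame(unclass(mk_aln(taln, paln2, tfull = 30, pfull = 30)),
                       stringsAsFactors = FALSE)
  expect_identical(nrow(filter_pool(r10)$kept), 1L)
})

test_that("q_max subgrouping", {
  pool <- make_alignment_pool(planted_curve(rep(0.5, 20)), 100, seed = 13)
  q <- vapply(seq_len(nrow(pool)), function(i)
    target_coverage(pool_row_for_test(pool, i)), numeric(1))
  expect_identical(nrow(subset_by_qmax(pool, 100)), nrow(pool))
  for (qm in c(40, 60, 80)) {
    sub <- subset_by_qmax(pool, qm)
    expect_identical(nrow(sub), sum(q <= qm))
  }
  all50 <- pool[q > 40 & q <= 100, , drop = FALSE]
  expect_identical(nrow(subset_by_qmax(all50, 40)), 0L)
  expect_error(subset_by_qmax(pool, 0), "q_max")
})

test_that("alignment TSV and BLAST XML round-trip the pool", {
  pool <- make_alignment_pool(planted_curve(rep(0.4, 20)), 40, seed = 17)
  tsv <- tempfile(fileext = ".tsv")
  write_alignment_tsv(pool, tsv)
  back <- read_alignment_tsv(tsv)
  expect_equal(back$target_aln, pool$target_aln)
  expect_equal(back$e_value, pool$e_value, tolerance = 1e-12)
  m1 <- compute_alignment_metrics(pool)
  m2 <- compute_alignment_metrics(back)
  expect_equal(m1[, -(1:4)], m2[, -(1:4)], tolerance = 1e-12)

  xml <- tempfile(fileext = ".xml")
  write_blast_xml(pool, xml)
  px <- parse_blast_xml(xml)
  expect_identical(nrow(px), nrow(pool))
  key <- function(d) paste(d$template_id, d$target_aln, d$template_aln,
                           d$target_start, d$template_start)
  px <- px[match(key(pool), key(px)), ]
  m3 <- compute_alignment_metrics(
    px, interfaces = setNames(
      lapply(seq_len(nrow(pool)),
             function(i) as.integer(strsplit(pool$interface[i], ",")[[1]])),
      pool$target_id))
  expect_equal(m3$a_iden, m1$a_iden, tolerance = 1e-12)
})

test_that("parse_blast_xml handles multiple HSPs and missing lengths", {
  xml <- tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>', "<BlastOutput><BlastOutput_iterations>",
    "<Iteration><Iteration_query-def>q1</Iteration_query-def>",
    "<Iteration_hits><Hit><Hit_def>h1</Hit_def><Hit_len>50</Hit_len>",
    "<Hit_hsps>",
    "<Hsp><Hsp_evalue>0.01</Hsp_evalue><Hsp_query-from>1</Hsp_query-from>",
    "<Hsp_query-to>4</Hsp_query-to><Hsp_hit-from>3</Hsp_hit-from>",
    "<Hsp_hit-to>6</Hsp_hit-to><Hsp_qseq>KRDE</Hsp_qseq>",
    "<Hsp_hseq>RRDS</Hsp_hseq></Hsp>",
    "<Hsp><Hsp_evalue>0.5</Hsp_evalue><Hsp_query-from>10</Hsp_query-from>",
    "<Hsp_query-to>12</Hsp_query-to><Hsp_hit-from>1</Hsp_hit-from>",
    "<Hsp_hit-to>3</Hsp_hit-to><Hsp_qseq>ACD</Hsp_qseq>",
    "<Hsp_hseq>ACD</Hsp_hseq></Hsp>",
    "</Hit_hsps></Hit></Iteration_hits></Iteration>",
    "</BlastOutput_iterations></BlastOutput>"), xml)
  expect_error(parse_blast_xml(xml), "full length unknown")
  recs <- parse_blast_xml(xml, c(q1 = 40L))
  expect_identical(nrow(recs), 2L)
  expect_equal(recs$e_value, c(0.01, 0.5))
  res <- alignment_identity_similarity(pool_row_for_test(recs, 1))
  expect_equal(res$a_iden, 50)
})

test_that("alignment validation catches inconsistent records", {
  expect_error(pairwise_alignment("t", "p", 1, "KRD", "KR", 1, 3, 1, 2, 3, 2),
               "differ in length")
  expect_error(pairwise_alignment("t", "p", 1, "K-D", "K-D", 1, 2, 1, 2, 2, 2),
               "both sides")
  expect_error(pairwise_alignment("t", "p", 1, "KRD", "KRD", 1, 5, 1, 3, 5, 3),
               "inconsistent")
})
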