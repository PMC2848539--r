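#' Specification of a synthetic two-chain complex
#'
#' Describes a toy two-chain complex with a geometrically controlled
#' contact patch. The default "two-helix" geometry builds two ideal
#' alpha-helices (rise 1.5 A per residue, backbone radius 2.3 A, 100
#' degrees per residue); the first `contact_size` residues of each chain
#' face each other closely, and chain B then retreats laterally so that
#' later residues drop out of contact. The "random-walk" geometry builds a
#' 3.8 A-step C-alpha random walk per chain with the chains started close
#' together. Neither is physically realistic; both give exactly
#' reproducible structures with a non-trivial interface.
#'
#' @param chain_lengths integer vector of two residue counts, each >= 5.
#' @param contact_size number of residue pairs placed in contact,
#'   `1 <= contact_size <= min(chain_lengths)`. The realised interface is
#'   determined afterwards by the exhaustive distance-criterion oracle and
#'   covers at least `contact_size` residues per chain for the two-helix
#'   geometry.
#' @param geometry "two-helix" (default) or "random-walk".
#' @param seed RNG seed; identical spec + seed give bit-identical output.
#' @return a `synthetic_complex_spec`.
#' @export
synthetic_complex_spec <- function(chain_lengths, contact_size,
                                   geometry = c("two-helix", "random-walk"),
                                   seed = 1L) {
  geometry <- match.arg(geometry)
  chain_lengths <- as.integer(chain_lengths)
  if (length(chain_lengths) != 2L || any(chain_lengths < 5L))
    stop("two chain lengths >= 5 required", call. = FALSE)
  if (contact_size < 1L || contact_size > min(chain_lengths))
    stop("contact_size must be in [1, min(chain_lengths)]", call. = FALSE)
  structure(list(chain_lengths = chain_lengths,
                 contact_size = as.integer(contact_size),
                 geometry = geometry, seed = as.integer(seed)),
            class = "synthetic_complex_spec")
}

# ideal helix C-alpha trace: rise 1.5 A/res, radius 2.3 A, 100 deg/res
helix_ca <- function(n, origin = c(0, 0, 0)) {
  i <- seq_len(n) - 1
  th <- i * 100 * pi / 180
  cbind(2.3 * cos(th) + origin[1], 2.3 * sin(th) + origin[2],
        1.5 * i + origin[3])
}

# backbone-only residue atoms (N, CA, C, O, CB) laid out around each CA;
# offsets are fixed in a per-residue frame so shapes are reproducible
residue_atoms <- function(ca, resname, resnum) {
  axial <- c(0, 0, 1)
  radial <- c(ca[1], ca[2], 0)
  nr <- sqrt(sum(radial^2))
  radial <- if (nr > 1e-9) radial / nr else c(1, 0, 0)
  tangent <- c(-radial[2], radial[1], 0)
  pos <- rbind(N  = ca - 1.2 * tangent - 0.5 * axial,
               CA = ca,
               C  = ca + 1.2 * tangent + 0.5 * axial,
               O  = ca + 1.2 * tangent + 1.7 * axial,
               CB = ca + 1.5 * radial)
  atoms <- rownames(pos)
  if (resname == "GLY") { pos <- pos[1:4, , drop = FALSE]; atoms <- atoms[1:4] }
  data.frame(resnum = resnum, inscode = "", resname = resname,
             atom = atoms, element = substring(atoms, 1, 1),
             x = pos[, 1], y = pos[, 2], z = pos[, 3],
             stringsAsFactors = FALSE, row.names = NULL)
}

build_chain <- function(ca_trace, resnames) {
  do.call(rbind, lapply(seq_len(nrow(ca_trace)), function(i)
    residue_atoms(ca_trace[i, ], resnames[i], i)))
}

#' Generate a synthetic two-chain complex with ground-truth interface
#'
#' Builds the structure demanded by the spec and determines the true
#' interface by the exhaustive all-atom-pair distance criterion (an
#' independent brute-force scan, not [assign_interface()]'s vectorised
#' path), so downstream interface extraction can be validated against it.
#'
#' @param spec a [synthetic_complex_spec()].
#' @param vdw [vdw_table()] used for the ground-truth criterion.
#' @param path optional file path; when given, the structure is also
#'   written as a PDB file.
#' @param id complex identifier (default "SYN1").
#' @return list with `structure` (a `complex_structure`), `interface` (the
#'   ground-truth `interface_map`) and `path` (or NULL).
#' @export
make_complex <- function(spec, vdw = vdw_table(), path = NULL, id = "SYN1") {
  stopifnot(inherits(spec, "synthetic_complex_spec"))
  nA <- spec$chain_lengths[1]; nB <- spec$chain_lengths[2]
  k <- spec$contact_size
  chains <- with_seed(spec$seed, {
    rnA <- aa1_to_3(sample(unname(AA3), nA, replace = TRUE))
    rnB <- aa1_to_3(sample(unname(AA3), nB, replace = TRUE))
    if (spec$geometry == "two-helix") {
      caA <- helix_ca(nA)
      caB <- helix_ca(nB, origin = c(5.0, 0, 0))
      # retreat after the contact window so later residues leave contact
      off <- pmax(0, seq_len(nB) - k) * 4.0
      caB[, 1] <- caB[, 1] + off
    } else {
      caA <- random_walk_ca(nA, start = c(0, 0, 0))
      caB <- random_walk_ca(nB, start = c(5.0, 0, 0))
    }
    list(A = build_chain(caA, rnA), B = build_chain(caB, rnB))
  })
  cx <- complex_structure(id, chains)
  imap <- brute_force_interface(cx, vdw)
  if (!is.null(path)) write_pdb(cx, path)
  list(structure = cx, interface = imap, path = path)
}

random_walk_ca <- function(n, start) {
  dirs <- matrix(stats::rnorm(3 * (n - 1)), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  rbind(start, start + apply(dirs * 3.8, 2, cumsum))
}

#' Brute-force interface assignment (reference oracle)
#'
#' Plain double loop over residues and atom pairs applying the distance
#' criterion literally. Used to label synthetic ground truth and as the
#' reference against which [assign_interface()] is tested; deliberately
#' naive and independent of the vectorised implementation.
#'
#' @inheritParams assign_interface
#' @return an `interface_map`.
#' @export
brute_force_interface <- function(complex, vdw = vdw_table()) {
  cids <- names(complex$chains)
  a <- complex$chains[[cids[1]]]; b <- complex$chains[[cids[2]]]
  ra <- vdw_radii_for(vdw, a$element); rb <- vdw_radii_for(vdw, b$element)
  w <- vdw$water_diameter
  ka <- res_key(a$resnum, a$inscode); kb <- res_key(b$resnum, b$inscode)
  hit_a <- character(0); hit_b <- character(0)
  pairs <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    dx <- a$x[i] - b$x[j]; dy <- a$y[i] - b$y[j]; dz <- a$z[i] - b$z[j]
    thr <- ra[i] + rb[j] + w
    if (dx * dx + dy * dy + dz * dz < thr * thr) {
      hit_a <- c(hit_a, ka[i]); hit_b <- c(hit_b, kb[j])
      pairs[[length(pairs) + 1L]] <- data.frame(key_a = ka[i], key_b = kb[j],
                                                stringsAsFactors = FALSE)
    }
  }
  res_a <- chain_residues(a); res_b <- chain_residues(b)
  ia <- res_a[res_a$key %in% unique(hit_a), , drop = FALSE]
  ib <- res_b[res_b$key %in% unique(hit_b), , drop = FALSE]
  rownames(ia) <- rownames(ib) <- NULL
  res <- list(ia, ib); names(res) <- cids
  n <- c(nrow(ia), nrow(ib)); names(n) <- cids
  pr <- if (length(pairs)) unique(do.call(rbind, pairs)) else
    data.frame(key_a = character(0), key_b = character(0))
  rownames(pr) <- NULL
  structure(list(complex_id = complex$id, residues = res, n_int_tot = n,
                 pairs = pr),
            class = "interface_map")
}

#' Build a perturbed / truncated model of one chain
#'
#' Emulates a partial homology model: keeps the residues of `keep_range`,
#' perturbs every atom coordinate with i.i.d. Gaussian noise of standard
#' deviation `noise_sigma`, and preserves the residue numbering so that
#' model and native residues are matchable by author number.
#'
#' @param native a `complex_structure`.
#' @param chain chain identifier within `native`.
#' @param noise_sigma noise standard deviation per coordinate, in Angstrom.
#' @param keep_range length-2 integer vector, inclusive residue-number
#'   interval kept in the model; default keeps the full chain.
#' @param seed RNG seed.
#' @return a `model_structure`: list with `target_id`, `chain_id` and
#'   `atoms` (same columns as a chain of a `complex_structure`).
#' @export
make_model <- function(native, chain, noise_sigma = 0, keep_range = NULL,
                       seed = 1L) {
  stopifnot(inherits(native, "complex_structure"))
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  a <- native$chains[[chain]]
  if (is.null(a)) stop("chain ", chain, " not in complex", call. = FALSE)
  if (is.null(keep_range)) keep_range <- range(a$resnum)
  keep <- a$resnum >= keep_range[1] & a$resnum <= keep_range[2]
  if (!any(keep)) stop("empty keep_range", call. = FALSE)
  a <- a[keep, , drop = FALSE]
  if (noise_sigma > 0) {
    noise <- with_seed(seed,
                       matrix(stats::rnorm(3 * nrow(a), sd = noise_sigma),
                              ncol = 3))
    a$x <- a$x + noise[, 1]; a$y <- a$y + noise[, 2]; a$z <- a$z + noise[, 3]
  }
  rownames(a) <- NULL
  structure(list(target_id = native$id, chain_id = chain, atoms = a),
            class = "model_structure")
}

#' Planted FIC-probability curve
#'
#' The stand-in ground truth for the empirical probability of full
#' interface coverage as a function of alignment identity: per 5%-wide
#' identity bin over [0, 100], the probability that a generated alignment
#' is FIC.
#'
#' @param p_fic numeric vector of per-bin probabilities in [0, 1]; its
#'   length fixes the number of bins.
#' @param bin_edges bin boundaries, contiguous and covering [0, 100]
#'   (default `seq(0, 100, length.out = length(p_fic) + 1)`).
#' @return a `planted_curve`.
#' @export
planted_curve <- function(p_fic,
                          bin_edges = seq(0, 100,
                                          length.out = length(p_fic) + 1)) {
  if (any(p_fic < 0 | p_fic > 1)) stop("p_fic must be in [0,1]",
                                       call. = FALSE)
  if (length(bin_edges) != length(p_fic) + 1L ||
      bin_edges[1] != 0 || bin_edges[length(bin_edges)] != 100 ||
      any(diff(bin_edges) <= 0))
    stop("bin_edges must increase from 0 to 100 with one bin per p_fic",
         call. = FALSE)
  structure(list(bin_edges = bin_edges, p_fic = p_fic),
            class = "planted_curve")
}

#' Generate an alignment pool with planted FIC labels
#'
#' Constructs `n` local alignments whose recomputed alignment identity
#' falls in a chosen bin of the planted curve and whose FIC status is drawn
#' Bernoulli from that bin's probability. For FIC = TRUE all interface
#' positions lie inside the aligned region (0 missing); for FIC = FALSE at
#' least two lie outside, so the label is unambiguous under the default
#' one-missing-residue tolerance. Aligned strings contain exactly the
#' planted number of identical columns, so recomputing a_iden from the
#' strings reproduces the planted bin.
#'
#' @param curve a [planted_curve()].
#' @param n number of alignments (>= 1).
#' @param interface_sizes pool of interface sizes to sample from
#'   (default 5:15).
#' @param coverage_range target-coverage interval in percent (default
#'   c(40, 100)).
#' @param seed RNG seed.
#' @param n_complexes number of synthetic target complexes the alignments
#'   are attributed to (two chains each); default `max(1, n %/% 50)`.
#' @return data.frame in the TSV exchange format plus ground-truth columns
#'   `complex_id`, `chain`, `interface` (comma-separated target positions),
#'   `planted_bin`, `planted_iden`, `planted_fic`.
#' @export
make_alignment_pool <- function(curve, n, interface_sizes = 5:15,
                                coverage_range = c(40, 100), seed = 1L,
                                n_complexes = max(1L, n %/% 50L)) {
  stopifnot(inherits(curve, "planted_curve"))
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (coverage_range[1] <= 0 || coverage_range[2] > 100 ||
      coverage_range[1] > coverage_range[2])
    stop("coverage_range must be within (0,100]", call. = FALSE)
  nbin <- length(curve$p_fic)
  aa <- unname(AA3)  # one-letter alphabet
  with_seed(seed, {
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      b <- sample.int(nbin, 1L)
      lo <- curve$bin_edges[b]; hi <- curve$bin_edges[b + 1L]
      fic <- stats::runif(1) < curve$p_fic[b]
      n_int <- sample(rep(interface_sizes, 2L), 1L)
      n_tot <- sample(80:300, 1L)
      q_want <- stats::runif(1, coverage_range[1], coverage_range[2])
      n_ali <- max(25L, min(n_tot, round(q_want * n_tot / 100)))
      if (!fic) n_ali <- min(n_ali, n_tot - 2L)
      if (fic && n_ali < n_int)
        stop("coverage too small to contain the interface for a FIC alignment",
             call. = FALSE)
      # target-side gap columns (template insertions); omitted in the top
      # bins where they could make the planted identity unreachable
      n_gap <- if (lo < 80 && stats::runif(1) < 0.3) sample.int(5L, 1L) else 0L
      l_ali <- n_ali + n_gap
      # identical-column count realising the planted bin
      u <- stats::runif(1, lo, hi)
      n_iden <- round(u * l_ali / 100)
      while (100 * n_iden / l_ali < lo) n_iden <- n_iden + 1L
      while (100 * n_iden / l_ali >= hi && hi < 100) n_iden <- n_iden - 1L
      if (100 * n_iden / l_ali < lo || n_iden < 0L || n_iden > n_ali)
        stop("identity bin [", lo, ",", hi,
             ") not representable at alignment length ", l_ali,
             call. = FALSE)

      t_start <- sample.int(n_tot - n_ali + 1L, 1L)
      t_end <- t_start + n_ali - 1L
      covered <- t_start:t_end
      outside <- setdiff(seq_len(n_tot), covered)
      iface <- if (fic) sort(sample(covered, n_int)) else {
        k_max <- min(n_int, length(outside))
        k_out <- if (k_max <= 2L) 2L else sample(2:k_max, 1L)
        if (n_int - k_out > length(covered))
          stop("interface too large for the aligned region", call. = FALSE)
        inside <- if (n_int > k_out) sample(covered, n_int - k_out)
          else integer(0)
        sort(c(sample(outside, k_out), inside))
      }

      tgt <- sample(aa, n_ali, replace = TRUE)
      tpl <- vapply(tgt, function(x) sample(setdiff(aa, x), 1L), "a")
      iden_cols <- sample.int(n_ali, n_iden)
      tpl[iden_cols] <- tgt[iden_cols]
      # some non-identity columns become template-side gaps
      non_iden <- setdiff(seq_len(n_ali), iden_cols)
      if (length(non_iden) > 0L) {
        gsel <- non_iden[stats::runif(length(non_iden)) < 0.05]
        tpl[gsel] <- "-"
      }
      tcol <- tgt; pcol <- tpl
      if (n_gap > 0L) {
        ins <- sort(sample.int(n_ali + n_gap, n_gap))
        full_t <- character(l_ali); full_p <- character(l_ali)
        full_t[ins] <- "-"
        full_p[ins] <- sample(aa, n_gap, replace = TRUE)
        full_t[-ins] <- tgt; full_p[-ins] <- tpl
        tcol <- full_t; pcol <- full_p
      }
      n_tpl <- sum(pcol != "-")
      p_full <- n_tpl + sample(20:120, 1L)
      p_start <- sample.int(p_full - n_tpl + 1L, 1L)
      cid <- sprintf("CPLX%04d", sample.int(n_complexes, 1L))
      chn <- sample(c("A", "B"), 1L)
      rows[[i]] <- data.frame(
        target_id = paste0(cid, chn), template_id = sprintf("TMPL%05d", i),
        e_value = 10^stats::runif(1, -50, 0),
        target_start = t_start, target_end = t_end,
        template_start = p_start, template_end = p_start + n_tpl - 1L,
        target_aln = paste(tcol, collapse = ""),
        template_aln = paste(pcol, collapse = ""),
        target_full_length = n_tot, template_full_length = p_full,
        complex_id = cid, chain = chn,
        interface = paste(iface, collapse = ","),
        planted_bin = b, planted_iden = 100 * n_iden / l_ali,
        planted_fic = fic, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
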