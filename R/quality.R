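# C-alpha coordinate matrix keyed by residue for one chain / model
ca_coords <- function(atoms) {
  ca <- atoms[atoms$atom == "CA", , drop = FALSE]
  m <- cbind(ca$x, ca$y, ca$z)
  rownames(m) <- res_key(ca$resnum, ca$inscode)
  m
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Superimposes a model chain onto the native chain over C-alpha atoms
#' matched by residue number (and insertion code), minimising the RMSD of
#' the matched set. A proper rotation (det = +1) is enforced via the
#' standard sign correction of the Kabsch algorithm.
#'
#' @param native_chain atom data.frame of the native chain (one element of
#'   `complex_structure$chains`).
#' @param model a `model_structure` (see [make_model()]) or an atom
#'   data.frame.
#' @param scope "all" (default): superpose over all shared C-alpha atoms;
#'   "interface": superpose over interface residues only (requires
#'   `interface`).
#' @param interface data.frame of interface residues for this chain (the
#'   chain's element of `interface_map$residues`), needed when
#'   `scope = "interface"`.
#' @return a `superposition_result`: list with `rotation` (3x3, applied on
#'   the right to row-vector coordinates), `translation` (length-3),
#'   `matched_residue_count` and `rmsd_all_matched`. Model coordinates map
#'   onto the native frame as `x %*% rotation + translation`.
#' @export
superimpose <- function(native_chain, model, scope = c("all", "interface"),
                        interface = NULL) {
  scope <- match.arg(scope)
  matoms <- if (inherits(model, "model_structure")) model$atoms else model
  P <- ca_coords(matoms)          # model
  Q <- ca_coords(native_chain)    # native
  shared <- intersect(rownames(P), rownames(Q))
  if (scope == "interface") {
    if (is.null(interface)) stop("interface required for interface scope",
                                 call. = FALSE)
    shared <- intersect(shared, res_key(interface$resnum,
                                        interface$inscode))
  }
  if (length(shared) < 3L)
    stop("need at least 3 matched C-alpha atoms (have ", length(shared),
         ")", call. = FALSE)
  P <- P[shared, , drop = FALSE]; Q <- Q[shared, , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  H <- t(P0) %*% Q0
  sv <- svd(H)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-300))
    stop("degenerate (collinear) coordinates: superposition not unique",
         call. = FALSE)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)   # right-multiplication rotation
  moved <- P0 %*% R
  rmsd <- sqrt(mean(rowSums((moved - Q0)^2)))
  structure(list(rotation = R, translation = as.numeric(cq - cp %*% R),
                 matched_residue_count = length(shared),
                 rmsd_all_matched = rmsd),
            class = "superposition_result")
}

#' Interface RMSD of a partial model
#'
#' RMSD over the C-alpha atoms of the interface residues between the model
#' and the native chain, after rigid superposition. The superposition is
#' computed over the chosen scope (all shared C-alpha atoms by default, or
#' the interface only); the RMSD is always evaluated over the interface
#' C-alpha set.
#'
#' @inheritParams superimpose
#' @param interface data.frame of interface residues for this chain.
#' @return interface RMSD in Angstrom (a single number, attribute
#'   `superposition` carries the `superposition_result`).
#' @export
interface_rmsd <- function(native_chain, model, interface,
                           scope = c("all", "interface")) {
  scope <- match.arg(scope)
  matoms <- if (inherits(model, "model_structure")) model$atoms else model
  keys <- res_key(interface$resnum, interface$inscode)
  P <- ca_coords(matoms); Q <- ca_coords(native_chain)
  absent <- setdiff(keys, rownames(P))
  if (length(absent) > 0L)
    stop("interface residue(s) missing C-alpha in the model: ",
         paste(absent, collapse = ", "), call. = FALSE)
  absent_nat <- setdiff(keys, rownames(Q))
  if (length(absent_nat) > 0L)
    stop("interface residue(s) missing C-alpha in the native chain: ",
         paste(absent_nat, collapse = ", "), call. = FALSE)
  sup <- superimpose(native_chain, model, scope = scope,
                     interface = interface)
  Pm <- sweep(P[keys, , drop = FALSE] %*% sup$rotation, 2,
              sup$translation, "+")
  d2 <- rowSums((Pm - Q[keys, , drop = FALSE])^2)
  out <- sqrt(mean(d2))
  attr(out, "superposition") <- sup
  out
}

#' Model quality class from interface RMSD
#'
#' good: interface RMSD <= 5.0 A (the accuracy needed for meaningful
#' template-free docking); acceptable: (5, 10] A (within the docking
#' funnel); incorrect: > 10 A. The 5.0 A boundary is inclusive.
#'
#' @param rmsd numeric vector of interface RMSD values (>= 0).
#' @return factor with levels good, acceptable, incorrect.
#' @export
classify_quality <- function(rmsd) {
  if (any(rmsd < 0, na.rm = TRUE)) stop("rmsd must be >= 0", call. = FALSE)
  cut(rmsd, breaks = c(-Inf, 5, 10, Inf),
      labels = c("good", "acceptable", "incorrect"), right = TRUE)
}

#' Select the top model of a target
#'
#' The top model is the one built from the alignment with the highest
#' sequence identity (a_iden); ties are broken by lower e-value, then by
#' lexicographic template id, so selection is deterministic.
#'
#' @param records data.frame of model records for one target with columns
#'   `a_iden`, `e_value`, `template_id`.
#' @return `records` with a logical `is_top` column (exactly one TRUE).
#' @export
select_top_model <- function(records) {
  if (nrow(records) == 0L) stop("no model records", call. = FALSE)
  ord <- order(-records$a_iden, records$e_value, records$template_id)
  records$is_top <- seq_len(nrow(records)) == ord[1]
  records
}

#' Select the best model of a target
#'
#' The best model is the one with the lowest interface RMSD; ties are
#' broken by lexicographic template id.
#'
#' @param records data.frame with columns `interface_rmsd`, `template_id`.
#' @return `records` with a logical `is_best` column (exactly one TRUE).
#' @export
select_best_model <- function(records) {
  if (nrow(records) == 0L || all(is.na(records$interface_rmsd)))
    stop("no model records with interface_rmsd", call. = FALSE)
  ord <- order(records$interface_rmsd, records$template_id)
  records$is_best <- seq_len(nrow(records)) == ord[1]
  records
}

#' Assess a batch of models against their native chains
#'
#' Computes interface RMSD and quality class for each model, then flags the
#' top (highest alignment identity) and best (lowest interface RMSD) model
#' per target.
#'
#' @param models list of `model_structure` objects.
#' @param natives named list of native `complex_structure`s keyed by
#'   target id.
#' @param interfaces named list of `interface_map`s keyed by target id.
#' @param records data.frame with one row per model: `target_id`,
#'   `template_id`, `a_iden`, `e_value` (alignment provenance).
#' @param scope superposition scope, "all" or "interface".
#' @return data.frame of `model_quality_record`s: target_id, template_id,
#'   a_iden, e_value, interface_rmsd, quality_class, is_top, is_best.
#' @export
assess_models <- function(models, natives, interfaces, records,
                          scope = "all") {
  stopifnot(length(models) == nrow(records))
  rmsd <- vapply(seq_along(models), function(i) {
    m <- models[[i]]
    tid <- records$target_id[i]
    native <- natives[[m$target_id %||% tid]]
    imap <- interfaces[[m$target_id %||% tid]]
    as.numeric(interface_rmsd(native$chains[[m$chain_id]], m,
                              imap$residues[[m$chain_id]], scope = scope))
  }, numeric(1))
  out <- cbind(records, interface_rmsd = rmsd,
               quality_class = classify_quality(rmsd))
  parts <- lapply(split(out, out$target_id), function(s)
    select_best_model(select_top_model(s)))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
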