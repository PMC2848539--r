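# Independent reference implementations used to cross-check the package.
# These deliberately use different algorithms / code paths than the
# functions they validate.

# exhaustive per-residue interface scan, written against the criterion text
oracle_interface_keys <- function(cx, radii = c(C = 1.70, N = 1.55,
                                                O = 1.52, S = 1.80,
                                                P = 1.80),
                                  water = 2.8) {
  cids <- names(cx$chains)
  a <- cx$chains[[cids[1]]]; b <- cx$chains[[cids[2]]]
  ka <- paste0(a$resnum, a$inscode); kb <- paste0(b$resnum, b$inscode)
  in_a <- character(0); in_b <- character(0)
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 +
                  (a$z[i] - b$z[j])^2)
      if (d < radii[[a$element[i]]] + radii[[b$element[j]]] + water) {
        in_a <- union(in_a, ka[i]); in_b <- union(in_b, kb[j])
      }
    }
  }
  out <- list(sort(in_a), sort(in_b))
  names(out) <- cids
  out
}

# column-by-column recomputation of every alignment statistic
oracle_metrics <- function(aln, interface, matrix) {
  tc <- strsplit(aln$target_aln, "")[[1]]
  pc <- strsplit(aln$template_aln, "")[[1]]
  pos <- aln$target_start - 1L
  n_iden <- 0L; n_pos <- 0L
  int_in <- 0L; int_iden <- 0L; int_pos <- 0L
  for (k in seq_along(tc)) {
    t <- tc[k]; p <- pc[k]
    if (t != "-") pos <- pos + 1L
    iden <- FALSE; positive <- FALSE
    if (t != "-" && p != "-" && t != "X" && p != "X" &&
        t %in% rownames(matrix) && p %in% colnames(matrix)) {
      iden <- t == p
      positive <- matrix[t, p] > 0
    }
    n_iden <- n_iden + iden; n_pos <- n_pos + positive
    if (t != "-" && pos %in% interface) {
      int_in <- int_in + 1L
      int_iden <- int_iden + iden; int_pos <- int_pos + positive
    }
  }
  n_ali <- sum(tc != "-")
  l_ali <- length(tc)
  list(q = 100 * n_ali / aln$target_full_length,
       q_int = 100 * int_in / length(interface),
       missing = length(interface) - int_in,
       a_iden = 100 * n_iden / l_ali, a_sim = 100 * n_pos / l_ali,
       i_iden = if (int_in > 0) 100 * int_iden / int_in else NA_real_,
       i_sim = if (int_in > 0) 100 * int_pos / int_in else NA_real_)
}

# Horn's quaternion absolute-orientation method: independent of the SVD
# Kabsch used by superimpose()
oracle_quaternion_rmsd <- function(P, Q) {
  P0 <- sweep(P, 2, colMeans(P)); Q0 <- sweep(Q, 2, colMeans(Q))
  S <- t(P0) %*% Q0
  K <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2], S[3,1]-S[1,3], S[1,2]-S[2,1],
    S[2,3]-S[3,2], S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1], S[3,1]+S[1,3],
    S[3,1]-S[1,3], S[1,2]+S[2,1], -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1], S[3,1]+S[1,3], S[2,3]+S[3,2], -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  ev <- eigen(K, symmetric = TRUE)
  q <- ev$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1-2*(y^2+z^2), 2*(x*y-w*z), 2*(x*z+w*y),
    2*(x*y+w*z), 1-2*(x^2+z^2), 2*(y*z-w*x),
    2*(x*z-w*y), 2*(y*z+w*x), 1-2*(x^2+y^2)), 3, 3, byrow = TRUE)
  moved <- P0 %*% t(R)
  sqrt(mean(rowSums((moved - Q0)^2)))
}

# quaternion superposition over all shared CAs, rmsd over interface CAs
oracle_iface_rmsd <- function(P, Q, iface_keys) {
  shared <- intersect(rownames(P), rownames(Q))
  Ps <- P[shared, , drop = FALSE]; Qs <- Q[shared, , drop = FALSE]
  cp <- colMeans(Ps); cq <- colMeans(Qs)
  P0 <- sweep(Ps, 2, cp); Q0 <- sweep(Qs, 2, cq)
  S <- t(P0) %*% Q0
  K <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2], S[3,1]-S[1,3], S[1,2]-S[2,1],
    S[2,3]-S[3,2], S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1], S[3,1]+S[1,3],
    S[3,1]-S[1,3], S[1,2]+S[2,1], -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1], S[3,1]+S[1,3], S[2,3]+S[3,2], -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  q <- eigen(K, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1-2*(y^2+z^2), 2*(x*y-w*z), 2*(x*z+w*y),
    2*(x*y+w*z), 1-2*(x^2+z^2), 2*(y*z-w*x),
    2*(x*z-w*y), 2*(y*z+w*x), 1-2*(x^2+y^2)), 3, 3, byrow = TRUE)
  Pt <- sweep(P %*% t(R), 2, cq - drop(R %*% cp), "+")
  d2 <- rowSums((Pt[iface_keys, , drop = FALSE] -
                   Q[iface_keys, , drop = FALSE])^2)
  sqrt(mean(d2))
}

# weighted polynomial least squares by explicit normal equations
oracle_polyfit <- function(x, y, w, degree) {
  X <- outer(x, 0:degree, "^")
  solve(t(X) %*% (w * X), t(X) %*% (w * y))[, 1]
}

random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

apply_rigid_complex <- function(cx, R, t) {
  for (cid in names(cx$chains)) {
    a <- cx$chains[[cid]]
    xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
    xyz <- sweep(xyz, 2, t, "+")
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
    cx$chains[[cid]] <- a
  }
  cx
}

apply_rigid_model <- function(model, R, t) {
  a <- model$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, t, "+")
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  model$atoms <- a
  model
}

iface_keys <- function(imap) lapply(imap$residues, function(r) sort(r$key))

pool_row_for_test <- function(pool, i) {
  aln <- lapply(as.list(pool[i, , drop = FALSE]), function(x) x[[1]])
  class(aln) <- "pairwise_alignment"
  aln
}

random_spec <- function(seed) {
  synthetic_complex_spec(
    chain_lengths = sample(6:16, 2, replace = TRUE),
    contact_size = sample(3:5, 1),
    geometry = sample(c("two-helix", "random-walk"), 1),
    seed = seed)
}
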