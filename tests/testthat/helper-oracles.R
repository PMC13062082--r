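# Independent brute-force oracles and small fixture builders shared by the
# tests. These deliberately avoid the package's computational paths.

# Random proper rotation matrix (QR of a Gaussian matrix, det corrected).
random_rotation <- function() {
  qr_dec <- qr(matrix(rnorm(9), 3L))
  q <- qr.Q(qr_dec)
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# Horn quaternion superposition oracle: optimal proper rotation mapping B
# onto A via the largest eigenvector of the 4x4 key matrix.
quaternion_superpose_oracle <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2L, ca); Bc <- sweep(B, 2L, cb)
  S <- t(Bc) %*% Ac
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz
  ), 4L, 4L, byrow = TRUE)
  ev <- eigen(K, symmetric = TRUE)
  q <- ev$vectors[, 1L]
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3L, 3L, byrow = TRUE)
  moved <- sweep(Bc %*% t(R), 2L, ca, FUN = "+")
  sqrt(mean(rowSums((moved - A)^2)))
}

# Dense-cone oracle for the idealised hydroxyl hydrogen: minimum O-H...N
# linearity deviation over the cone dihedral, sampled at `step` degrees.
cone_hbond_oracle <- function(Ogamma, Cbeta, N_acceptor,
                              oh = 0.96, ang = 108.5, step = 0.5) {
  u <- (Cbeta - Ogamma); u <- u / sqrt(sum(u^2))
  ref <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w1 <- ref - sum(ref * u) * u; w1 <- w1 / sqrt(sum(w1^2))
  w2 <- c(u[2L] * w1[3L] - u[3L] * w1[2L],
          u[3L] * w1[1L] - u[1L] * w1[3L],
          u[1L] * w1[2L] - u[2L] * w1[1L])
  th <- ang * pi / 180
  ts <- seq(0, 360 - step, by = step) * pi / 180
  base <- Ogamma + oh * cos(th) * u
  Hm <- sweep((oh * sin(th)) * (outer(cos(ts), w1) + outer(sin(ts), w2)),
              2L, base, FUN = "+")
  H <- t(Hm)  # 3 x m; deviation per column
  vo <- Ogamma - H
  vn <- N_acceptor - H
  cosang <- colSums(vo * vn) / sqrt(colSums(vo^2) * colSums(vn^2))
  devs <- 180 - acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  min(devs)
}

# Brute-force circular distance (minimum over winding numbers).
circ_dist_oracle <- function(a, b) {
  min(abs(a - b + c(-720, -360, 0, 360, 720)))
}

# Minimal C-alpha-only chain ensemble spelling a given one-letter sequence.
make_ca_chain <- function(seq1, chain = "A", start_resno = 1L) {
  letters1 <- strsplit(seq1, "")[[1L]]
  res3 <- bio3d::aa123(letters1)
  n <- length(letters1)
  topo <- data.frame(atom_name = "CA", element = "C", resid = res3,
                     resno = start_resno + seq_len(n) - 1L, insert = "",
                     chain = chain, alt = "", occupancy = 1,
                     stringsAsFactors = FALSE)
  t <- seq_len(n)
  xyz <- cbind(2.3 * cos(t), 2.3 * sin(t), 1.5 * t)
  conformer_ensemble(topo, xyz, source = "synthetic CA chain")
}

# Drop the imidazole ring of residue 910 and rename it ARG, turning an
# HLS fixture into an RLS-motif chain.
as_rls_chain <- function(ensemble) {
  topo <- ensemble$topology
  drop <- topo$resno == 910L & topo$atom_name %in% c("ND1", "CD2", "CE1", "NE2")
  topo <- topo[!drop, , drop = FALSE]
  topo$resid[topo$resno == 910L] <- "ARG"
  frames <- lapply(seq_len(n_frames(ensemble)), function(f)
    frame_coords(ensemble, f)[!drop, , drop = FALSE])
  conformer_ensemble(topo, frames, source = "synthetic RLS chain")
}
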