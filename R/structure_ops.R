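# Structure editing (rotamer what-ifs) and comparison (Kabsch superposition,
# sequence-based C-alpha pairing, outlier-trimmed RMSD).

.backbone_names <- c("N", "CA", "C", "O", "OXT", "H", "H1", "H2", "H3",
                     "HN", "HA", "HA2", "HA3")

# Atom rows of one residue, as topology indices.
.residue_atoms <- function(ensemble, chain, resno, insert = "") {
  topo <- ensemble$topology
  idx <- which(topo$chain == chain & topo$resno == resno & topo$insert == insert)
  if (!length(idx)) stop("residue ", resno, insert, " not found in chain ", chain)
  idx
}

# First gamma-position heavy atom of a side chain (chi-1 fourth atom).
.gamma_atom <- function(names) {
  for (nm in c("CG", "CG1", "OG", "OG1", "SG", "CG2")) {
    if (nm %in% names) return(nm)
  }
  NA_character_
}

#' Set the chi-1 torsion of one residue
#'
#' Rigidly rotates everything distal to CB (the whole side chain beyond the
#' CA-CB bond, including CB-attached hydrogens) about the CA-CB axis so the
#' resulting chi-1 equals `target_chi1`. Bond lengths and angles within the
#' rotated group are untouched; no atom outside the edited side chain
#' moves. Applied to every frame of the ensemble.
#'
#' @param ensemble a [conformer_ensemble].
#' @param chain,resno,insert residue to edit (author numbering).
#' @param target_chi1 target chi-1 torsion in degrees.
#' @return The modified ensemble.
#' @export
set_chi1 <- function(ensemble, chain, resno, target_chi1, insert = "") {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  idx <- .residue_atoms(ensemble, chain, resno, insert)
  nm <- ensemble$topology$atom_name[idx]
  for (need in c("N", "CA", "CB")) {
    if (!need %in% nm) stop("residue lacks pivot atom ", need)
  }
  gam <- .gamma_atom(nm)
  if (is.na(gam)) stop("residue has no side-chain atom beyond CB")
  rot_idx <- idx[!nm %in% c(.backbone_names, "CB")]
  if (!length(rot_idx)) stop("no atoms distal to CB to rotate")
  iN <- idx[match("N", nm)]; iCA <- idx[match("CA", nm)]
  iCB <- idx[match("CB", nm)]; iG <- idx[match(gam, nm)]
  for (f in seq_len(n_frames(ensemble))) {
    xyz <- frame_coords(ensemble, f)
    cur <- dihedral(xyz[iN, ], xyz[iCA, ], xyz[iCB, ], xyz[iG, ])
    delta <- .wrap180(target_chi1 - cur)
    # rotating right-handedly about CB->CA advances the N-CA-CB-X torsion
    xyz[rot_idx, ] <- .rotate_points(xyz[rot_idx, , drop = FALSE],
                                     xyz[iCA, ], xyz[iCA, ] - xyz[iCB, ], delta)
    ensemble$frames[, , f] <- xyz
  }
  ensemble
}

#' Flip a histidine imidazole ring
#'
#' Rotates the ring atoms (ND1, CD2, CE1, NE2 and their hydrogens) by 180
#' degrees about the CB-CG axis, the physical chi-2 flip that exchanges the
#' ring nitrogen positions while keeping a (possibly non-ideal) ring
#' geometry intact. Applying the flip twice restores the input.
#'
#' @inheritParams set_chi1
#' @return The modified ensemble.
#' @export
flip_imidazole <- function(ensemble, chain, resno, insert = "") {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  idx <- .residue_atoms(ensemble, chain, resno, insert)
  nm <- ensemble$topology$atom_name[idx]
  ring <- c("ND1", "CD2", "CE1", "NE2", "HD1", "HD2", "HE1", "HE2")
  for (need in c("CB", "CG", "ND1", "CD2", "CE1", "NE2")) {
    if (!need %in% nm) stop("imidazole atom ", need, " missing")
  }
  rot_idx <- idx[nm %in% ring]
  iCB <- idx[match("CB", nm)]; iCG <- idx[match("CG", nm)]
  for (f in seq_len(n_frames(ensemble))) {
    xyz <- frame_coords(ensemble, f)
    xyz[rot_idx, ] <- .rotate_points(xyz[rot_idx, , drop = FALSE],
                                     xyz[iCG, ], xyz[iCG, ] - xyz[iCB, ], 180)
    ensemble$frames[, , f] <- xyz
  }
  ensemble
}

#' Least-squares superposition (Kabsch)
#'
#' Optimal proper rotation and translation mapping `coordsB` onto
#' `coordsA` in the least-squares sense, via singular value decomposition
#' of the cross-covariance matrix with the usual reflection correction.
#'
#' @param coordsA,coordsB paired `n x 3` coordinate matrices (n >= 3,
#'   non-collinear).
#' @return Object of class `superposition`: `rotation` (3x3, det +1),
#'   `translation` (length 3), `rmsd` (Angstrom, over the pairs after
#'   transformation), `n_pairs`. The transform maps a mobile point x to
#'   `rotation %*% x + translation`.
#' @export
kabsch_superpose <- function(coordsA, coordsB) {
  coordsA <- as.matrix(coordsA); coordsB <- as.matrix(coordsB)
  if (!all(dim(coordsA) == dim(coordsB)) || ncol(coordsA) != 3L)
    stop("coordsA and coordsB must be paired n x 3 matrices")
  n <- nrow(coordsA)
  if (n < 3L) stop("need at least 3 point pairs")
  ca <- colMeans(coordsA); cb <- colMeans(coordsB)
  Ac <- sweep(coordsA, 2L, ca); Bc <- sweep(coordsB, 2L, cb)
  if (qr(Ac)$rank < 2L || qr(Bc)$rank < 2L)
    stop("degenerate point set: collinear or coincident points")
  H <- t(Bc) %*% Ac
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.vector(ca - R %*% cb)
  moved <- sweep(coordsB %*% t(R), 2L, tr, FUN = "+")
  rmsd <- sqrt(mean(rowSums((moved - coordsA)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd, n_pairs = n),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> %d pairs, rmsd %.3f A\n", x$n_pairs, x$rmsd))
  invisible(x)
}

#' Apply a superposition transform to coordinates
#'
#' @param sup a `superposition`.
#' @param coords `n x 3` matrix of mobile-frame coordinates.
#' @return Transformed `n x 3` matrix.
#' @export
apply_superposition <- function(sup, coords) {
  stopifnot(inherits(sup, "superposition"))
  sweep(as.matrix(coords) %*% t(sup$rotation), 2L, sup$translation, FUN = "+")
}

#' Pair common C-alpha atoms of two chains by sequence alignment
#'
#' Extracts the one-letter sequences of the two chains from their resolved
#' residues, aligns them globally (default scores: match +1, mismatch -1,
#' gap -2 per residue; a custom substitution matrix may be supplied) and
#' returns the C-alpha pairs of aligned, non-gap columns where both
#' C-alpha atoms are resolved. Residues missing from either model (e.g.
#' disordered loops) are therefore absent from the pairing.
#'
#' @param ensembleA,ensembleB [conformer_ensemble] objects.
#' @param chainA,chainB chain identifiers.
#' @param match,mismatch,gap alignment scores.
#' @param substitution_matrix optional full substitution matrix overriding
#'   `match`/`mismatch`.
#' @return data frame with one row per pair: residue keys of both chains
#'   and the C-alpha topology indices `idx_a`, `idx_b`.
#' @export
pair_common_calpha <- function(ensembleA, ensembleB, chainA, chainB,
                               match = 1, mismatch = -1, gap = -2,
                               substitution_matrix = NULL) {
  sa <- .chain_sequence(ensembleA, chainA)
  sb <- .chain_sequence(ensembleB, chainB)
  if (!nzchar(sa$seq) || !nzchar(sb$seq)) stop("empty chain sequence")
  if (is.null(substitution_matrix)) {
    letters20 <- strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1L]]
    substitution_matrix <- matrix(mismatch, length(letters20), length(letters20),
                                  dimnames = list(letters20, letters20))
    diag(substitution_matrix) <- match
  }
  al <- Biostrings::pairwiseAlignment(sa$seq, sb$seq, type = "global",
                                      substitutionMatrix = substitution_matrix,
                                      gapOpening = 0, gapExtension = abs(gap))
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1L]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1L]]
  ia <- 0L; ib <- 0L
  rows <- vector("list", length(pa))
  for (k in seq_along(pa)) {
    ga <- pa[k] == "-"; gb <- pb[k] == "-"
    if (!ga) ia <- ia + 1L
    if (!gb) ib <- ib + 1L
    if (ga || gb) next
    ra <- sa$residues[ia, ]; rb <- sb$residues[ib, ]
    ka <- .atom_index(ensembleA, chainA, ra$resno, ra$insert, "CA")
    kb <- .atom_index(ensembleB, chainB, rb$resno, rb$insert, "CA")
    if (is.na(ka) || is.na(kb)) next
    rows[[k]] <- data.frame(resno_a = ra$resno, insert_a = ra$insert,
                            resid_a = ra$resid, resno_b = rb$resno,
                            insert_b = rb$insert, resid_b = rb$resid,
                            idx_a = ka, idx_b = kb,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(out)) stop("no common C-alpha pairs")
  rownames(out) <- NULL
  out
}

#' Iteratively trimmed superposition
#'
#' Superposes, removes pairs deviating by more than `threshold` Angstrom,
#' and repeats until no pair is removed. The per-iteration RMSD is
#' non-increasing; the returned object carries the retained pair indices
#' as attribute `"kept"`.
#'
#' @param coordsA,coordsB paired `n x 3` coordinate matrices.
#' @param threshold per-pair deviation cutoff in Angstrom (default 3.5, a
#'   standard core-superposition choice).
#' @param max_iter safety bound on iterations.
#' @return A `superposition` over the retained pairs.
#' @export
rmsd_outlier_trim <- function(coordsA, coordsB, threshold = 3.5,
                              max_iter = 50L) {
  coordsA <- as.matrix(coordsA); coordsB <- as.matrix(coordsB)
  keep <- seq_len(nrow(coordsA))
  sup <- kabsch_superpose(coordsA, coordsB)
  for (it in seq_len(max_iter)) {
    sup <- kabsch_superpose(coordsA[keep, , drop = FALSE],
                            coordsB[keep, , drop = FALSE])
    moved <- apply_superposition(sup, coordsB[keep, , drop = FALSE])
    dev <- sqrt(rowSums((moved - coordsA[keep, , drop = FALSE])^2))
    bad <- dev > threshold
    if (!any(bad)) break
    keep <- keep[!bad]
    if (length(keep) < 3L) stop("fewer than 3 pairs remain after trimming")
  }
  attr(sup, "kept") <- keep
  sup
}

#' Superpose two chains on their common C-alpha atoms
#'
#' Convenience wrapper chaining [pair_common_calpha] and
#' [kabsch_superpose] (optionally [rmsd_outlier_trim]) on the first frame
#' of each ensemble.
#'
#' @inheritParams pair_common_calpha
#' @param trim optional deviation threshold in Angstrom; when given, the
#'   superposition is outlier-trimmed.
#' @return A `superposition` (with attribute `"pairs"` holding the pairing
#'   table).
#' @export
superpose_common_calpha <- function(ensembleA, ensembleB, chainA, chainB,
                                    trim = NULL) {
  pairs <- pair_common_calpha(ensembleA, ensembleB, chainA, chainB)
  xa <- frame_coords(ensembleA, 1L)[pairs$idx_a, , drop = FALSE]
  xb <- frame_coords(ensembleB, 1L)[pairs$idx_b, , drop = FALSE]
  sup <- if (is.null(trim)) kabsch_superpose(xa, xb)
  else rmsd_outlier_trim(xa, xb, threshold = trim)
  attr(sup, "pairs") <- pairs
  sup
}
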