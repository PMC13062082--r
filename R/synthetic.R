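# Seeded synthetic-data generators with planted ground truth for every
# analysis stage: GPS tripeptide conformer ensembles with prescribed
# geometry, exponential cleavage time series, and alignments with known
# column profiles. Fixtures are geometric, not chemical: when a prescribed
# nucleophile placement (attack angles + distance) is requested, the
# serine O-gamma is positioned by explicit spherical construction in the
# attack frame, overriding its covalent geometry.

# Idealised bond lengths (Angstrom) and angles (degrees)
.geo <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
  ca_cb = 1.530,
  ang_c_n_ca = 121.7, ang_n_ca_c = 111.0, ang_ca_c_n = 116.2,
  ang_ca_c_o = 120.8, ang_n_ca_cb = 110.5,
  # His side chain / imidazole
  cb_cg = 1.497, ang_ca_cb_cg = 113.8,
  cg_nd1 = 1.371, ang_cb_cg_nd1 = 122.7,
  cg_cd2 = 1.356, ang_cb_cg_cd2 = 131.0,
  nd1_ce1 = 1.319, ang_cg_nd1_ce1 = 109.3,
  cd2_ne2 = 1.374, ang_cg_cd2_ne2 = 107.2,
  # Ser side chain
  cb_og = 1.417, ang_ca_cb_og = 110.8,
  # Leu side chain
  ang_ca_cb_cg_leu = 116.3, cg_cd = 1.521, ang_cb_cg_cd = 110.5
)

#' Build an idealised GPS tripeptide model
#'
#' Constructs a single-conformer His-Leu-Ser tripeptide (standard bond
#' lengths and angles, author numbering 910-912 on chain A) with full
#' control over the backbone torsions, the scissile omega, and the side
#' chain torsions. The serine O-gamma may be placed covalently (from
#' `chi1_nu`) or by explicit spherical construction at prescribed attack
#' angles `(theta_x, theta_y)` and distance `d_attack` in the attack frame
#' of the scissile carbonyl (see [build_attack_frame]); the spherical
#' placement takes the +z (peptide-plane normal) side.
#'
#' When `d_no` is given, the imidazole chi-2 is tuned (by root finding on
#' the ND1...O-gamma distance as a function of the ring rotation) so the
#' planted hydrogen-bond distance is met exactly; among candidate ring
#' rotations the one with the smallest O-H...N linearity deviation is
#' chosen. An error reports the achievable distance range when the target
#' cannot be met.
#'
#' @param phi,psi named numeric vectors (degrees) with elements `his`,
#'   `x`, `nu` for the three residues.
#' @param omega numeric length-2: the His-Leu and the scissile Leu-Ser
#'   omega torsions (degrees).
#' @param chi1_his,chi2_his His side-chain torsions (degrees).
#' @param chi1_nu Ser chi-1 (degrees); ignored for the O-gamma position
#'   when `theta_x`/`theta_y` are given.
#' @param theta_x,theta_y optional prescribed attack angles (degrees);
#'   must satisfy `cos^2 + cos^2 <= 1`.
#' @param d_attack O-gamma to carbonyl-carbon distance for the spherical
#'   placement (Angstrom).
#' @param d_no optional planted ND1...O-gamma distance (Angstrom),
#'   realised by tuning chi-2.
#' @param add_next_n append the backbone nitrogen of a following (913)
#'   glycine, placed by `psi["nu"]`, so the GPS.+1 psi torsion is
#'   measurable.
#' @return A one-frame [conformer_ensemble].
#' @export
build_gps_model <- function(phi = c(his = -120, x = -120, nu = -120),
                            psi = c(his = 130, x = 130, nu = 130),
                            omega = c(180, 180),
                            chi1_his = 180, chi2_his = -70,
                            chi1_nu = -60,
                            theta_x = NULL, theta_y = NULL, d_attack = 3.0,
                            d_no = NULL, add_next_n = TRUE) {
  g <- .geo
  atoms <- list()
  add <- function(resno, resid, name, xyz, element = substr(name, 1L, 1L)) {
    atoms[[length(atoms) + 1L]] <<- list(resno = resno, resid = resid,
                                         name = name, xyz = xyz,
                                         element = element)
  }

  # residue 910 (His) backbone, in a canonical lab frame
  N1 <- c(0, 0, 0)
  CA1 <- c(g$n_ca, 0, 0)
  C1 <- CA1 + g$ca_c * c(-cos(g$ang_n_ca_c * pi / 180),
                         sin(g$ang_n_ca_c * pi / 180), 0)
  resids <- c("HIS", "LEU", "SER")
  resnos <- c(910L, 911L, 912L)
  N <- list(N1); CA <- list(CA1); C <- list(C1)
  for (i in 2:3) {
    N[[i]] <- place_atom(N[[i - 1]], CA[[i - 1]], C[[i - 1]],
                         g$c_n, g$ang_ca_c_n, psi[[i - 1]])
    CA[[i]] <- place_atom(CA[[i - 1]], C[[i - 1]], N[[i]],
                          g$n_ca, g$ang_c_n_ca, omega[[i - 1]])
    C[[i]] <- place_atom(C[[i - 1]], N[[i]], CA[[i]],
                         g$ca_c, g$ang_n_ca_c, phi[[i]])
  }
  O <- lapply(1:3, function(i)
    place_atom(N[[i]], CA[[i]], C[[i]], g$c_o, g$ang_ca_c_o, psi[[i]] + 180))

  # His side chain + imidazole (planar, atom by atom)
  cb1 <- .place_cb(N[[1]], C[[1]], CA[[1]])
  cg1 <- place_atom(N[[1]], CA[[1]], cb1, g$cb_cg, g$ang_ca_cb_cg, chi1_his)
  ring <- .build_imidazole(CA[[1]], cb1, cg1, chi2_his)

  # Leu side chain (fixed rotamer; only the backbone carbonyl matters)
  cb2 <- .place_cb(N[[2]], C[[2]], CA[[2]])
  cg2 <- place_atom(N[[2]], CA[[2]], cb2, 1.530, g$ang_ca_cb_cg_leu, -60)
  cd1 <- place_atom(CA[[2]], cb2, cg2, g$cg_cd, g$ang_cb_cg_cd, 65)
  cd2 <- place_atom(CA[[2]], cb2, cg2, g$cg_cd, g$ang_cb_cg_cd, -172)

  # Ser side chain
  cb3 <- .place_cb(N[[3]], C[[3]], CA[[3]])
  if (is.null(theta_x) != is.null(theta_y))
    stop("give both theta_x and theta_y, or neither")
  if (!is.null(theta_x)) {
    cx <- cos(theta_x * pi / 180)
    cy <- cos(theta_y * pi / 180)
    rem <- 1 - cx^2 - cy^2
    if (rem < -1e-9)
      stop(sprintf("infeasible attack angles (%g, %g): cos^2 sum exceeds 1",
                   theta_x, theta_y))
    fr <- build_attack_frame(C[[2]], O[[2]], N[[3]])
    og3 <- fr$origin + d_attack * (cx * fr$x_axis + cy * fr$y_axis +
                                     sqrt(max(rem, 0)) * fr$z_axis)
    if (.vnorm(og3 - C[[2]]) < 1e-6)
      stop("requested O-gamma placement coincides with the carbonyl carbon")
  } else {
    og3 <- place_atom(N[[3]], CA[[3]], cb3, g$cb_og, g$ang_ca_cb_og, chi1_nu)
  }

  if (!is.null(d_no)) {
    ring <- .tune_ring_distance(CA[[1]], cb1, cg1, ring, og3, cb3, d_no)
  }

  for (i in 1:3) {
    add(resnos[i], resids[i], "N", N[[i]], "N")
    add(resnos[i], resids[i], "CA", CA[[i]])
    add(resnos[i], resids[i], "C", C[[i]])
    add(resnos[i], resids[i], "O", O[[i]], "O")
    if (i == 1L) {
      add(910L, "HIS", "CB", cb1)
      add(910L, "HIS", "CG", cg1)
      add(910L, "HIS", "ND1", ring$nd1, "N")
      add(910L, "HIS", "CD2", ring$cd2)
      add(910L, "HIS", "CE1", ring$ce1)
      add(910L, "HIS", "NE2", ring$ne2, "N")
    } else if (i == 2L) {
      add(911L, "LEU", "CB", cb2)
      add(911L, "LEU", "CG", cg2)
      add(911L, "LEU", "CD1", cd1)
      add(911L, "LEU", "CD2", cd2)
    } else {
      add(912L, "SER", "CB", cb3)
      add(912L, "SER", "OG", og3, "O")
    }
  }

  if (add_next_n) {
    add(913L, "GLY", "N",
        place_atom(N[[3]], CA[[3]], C[[3]], g$c_n, g$ang_ca_c_n, psi[["nu"]]),
        "N")
  }

  topo <- data.frame(
    atom_name = vapply(atoms, `[[`, character(1L), "name"),
    element = vapply(atoms, `[[`, character(1L), "element"),
    resid = vapply(atoms, `[[`, character(1L), "resid"),
    resno = vapply(atoms, function(a) as.integer(a$resno), integer(1L)),
    insert = "",
    chain = "A",
    alt = "",
    occupancy = 1,
    stringsAsFactors = FALSE)
  xyz <- do.call(rbind, lapply(atoms, `[[`, "xyz"))
  conformer_ensemble(topo, xyz, source = "synthetic GPS tripeptide")
}

# C-beta from the L-amino-acid improper torsion N-C-CA-CB = -122.5 deg.
.place_cb <- function(n, c, ca) {
  place_atom(n, c, ca, .geo$ca_cb, 110.1, -122.5)
}

# Imidazole ring atoms for a given chi2 (planar construction).
.build_imidazole <- function(ca, cb, cg, chi2) {
  g <- .geo
  nd1 <- place_atom(ca, cb, cg, g$cg_nd1, g$ang_cb_cg_nd1, chi2)
  cd2 <- place_atom(ca, cb, cg, g$cg_cd2, g$ang_cb_cg_cd2, chi2 + 180)
  ce1 <- place_atom(cb, cg, nd1, g$nd1_ce1, g$ang_cg_nd1_ce1, 180)
  ne2 <- place_atom(cb, cg, cd2, g$cd2_ne2, g$ang_cg_cd2_ne2, 180)
  list(nd1 = nd1, cd2 = cd2, ce1 = ce1, ne2 = ne2)
}

# Rotate the ring about the CB-CG axis so that |ND1 - Og| = target.
# ND1 moves on a circle, so the squared distance to Og is
# K + R*cos(delta - delta0): the (up to two) solutions are closed-form;
# the one with the smaller idealised O-H...N linearity deviation is kept.
.tune_ring_distance <- function(ca, cb, cg, ring, og, ser_cb, target) {
  u <- .unit(cg - cb)
  p <- ring$nd1
  c0 <- cg + sum((p - cg) * u) * u
  v <- p - c0
  w <- .cross(u, v)
  a <- c0 - og
  K <- sum(a * a) + sum(v * v)
  B <- 2 * sum(a * v)
  C <- 2 * sum(a * w)
  R <- sqrt(B^2 + C^2)
  if (R < 1e-12) {
    if (abs(K - target^2) > 1e-6)
      stop(sprintf(
        "planted N-delta...O-gamma distance %.2f A unreachable (fixed at %.2f A)",
        target, sqrt(K)))
    deltas <- 0
  } else {
    cosval <- (target^2 - K) / R
    if (abs(cosval) > 1) {
      lo <- sqrt(max(K - R, 0)); hi <- sqrt(K + R)
      stop(sprintf(
        "planted N-delta...O-gamma distance %.2f A unreachable (range %.2f-%.2f A)",
        target, lo, hi))
    }
    d0 <- atan2(C, B)
    deltas <- (c(d0 + acos(cosval), d0 - acos(cosval))) * 180 / pi
  }
  devs <- vapply(deltas, function(delta) {
    nd1 <- .rotate_points(matrix(ring$nd1, 1L), cg, cg - cb, delta)[1L, ]
    hbond_geometry(og, Cbeta = ser_cb, N_acceptor = nd1)$linearity_dev
  }, numeric(1L))
  best <- deltas[which.min(devs)]
  ring_xyz <- do.call(rbind, ring)
  rot <- .rotate_points(ring_xyz, cg, cg - cb, best)
  list(nd1 = rot[1L, ], cd2 = rot[2L, ], ce1 = rot[3L, ], ne2 = rot[4L, ])
}

#' Generate a GPS conformer ensemble with planted ground truth
#'
#' Builds `n_frames` idealised His-Leu-Ser conformers. For each frame the
#' requested targets (attack angles, attack distance, His chi-1, scissile
#' omega, and optionally the ND1...O-gamma distance) are jittered with
#' independent Gaussian noise (wrapped on each angle's circle), the
#' conformer is constructed to realise the jittered values exactly, and
#' the realised values are recorded in the `truth` table together with the
#' rotamer bins and condition flags derived from them (theta window
#' \[60, 120\] inclusive; favourable H-bond `d <= 3.2` Angstrom with
#' idealised-hydrogen linearity deviation `< 30` degrees; strain
#' `> 25` degrees). Infeasible jittered angle pairs
#' (`cos^2 + cos^2 > 1`) are redrawn.
#'
#' The same seed reproduces the ensemble and truth table bit-exactly.
#'
#' @param n_frames number of conformers.
#' @param theta_x,theta_y target attack angles (degrees); the pair must be
#'   jointly feasible (`cos^2 + cos^2 <= 1`).
#' @param theta_jitter angular jitter s.d. (degrees) per attack angle,
#'   wrapped on the angle's circle; jointly infeasible draws are redrawn.
#' @param d_attack target O-gamma...C distance (Angstrom).
#' @param d_attack_jitter jitter s.d. (Angstrom).
#' @param chi1_his,chi1_his_jitter His chi-1 target and jitter (degrees).
#' @param chi2_his His chi-2 (degrees; overridden per frame when `d_no` is
#'   planted).
#' @param omega,omega_jitter scissile omega target and jitter (degrees).
#' @param d_no,d_no_jitter optional ND1...O-gamma distance target and
#'   jitter (Angstrom).
#' @param phi,psi backbone torsions passed to [build_gps_model].
#' @param seed integer seed fixing the whole output.
#' @return Object of class `gps_fixture`: `ensemble` (a
#'   [conformer_ensemble]) and `truth` (data frame of realised per-frame
#'   values, bins and flags).
#' @export
build_gps_fixture <- function(n_frames, theta_x = 90, theta_y = 90,
                              theta_jitter = 0,
                              d_attack = 3.0, d_attack_jitter = 0,
                              chi1_his = 180, chi1_his_jitter = 0,
                              chi2_his = -70,
                              omega = 180, omega_jitter = 0,
                              d_no = NULL, d_no_jitter = 0,
                              phi = c(his = -120, x = -120, nu = -120),
                              psi = c(his = 130, x = 130, nu = 130),
                              seed = 1L) {
  stopifnot(n_frames >= 1L, theta_jitter >= 0, d_attack_jitter >= 0,
            chi1_his_jitter >= 0, omega_jitter >= 0, d_no_jitter >= 0)
  .with_seed(seed, {
    frames <- vector("list", n_frames)
    truth <- vector("list", n_frames)
    topo <- NULL
    if (1 - cos(theta_x * pi / 180)^2 - cos(theta_y * pi / 180)^2 < -1e-9)
      stop(sprintf("infeasible attack-angle targets (%g, %g)",
                   theta_x, theta_y))
    for (i in seq_len(n_frames)) {
      # per-angle wrapped Gaussian jitter; jointly infeasible draws are
      # rejected and redrawn, which truncates the tails without moving
      # the interior mode
      for (try in 1:200) {
        tx <- abs(.wrap180(theta_x + stats::rnorm(1L, 0, theta_jitter)))
        ty <- abs(.wrap180(theta_y + stats::rnorm(1L, 0, theta_jitter)))
        if (cos(tx * pi / 180)^2 + cos(ty * pi / 180)^2 <= 1) break
        if (try == 200L) stop("could not draw feasible attack angles")
      }
      da <- max(d_attack + stats::rnorm(1L, 0, d_attack_jitter), 0.5)
      c1h <- .wrap180(chi1_his + stats::rnorm(1L, 0, chi1_his_jitter))
      om <- .wrap180(omega + stats::rnorm(1L, 0, omega_jitter))
      dn <- if (is.null(d_no)) NULL
      else max(d_no + stats::rnorm(1L, 0, d_no_jitter), 1.5)

      mod <- build_gps_model(phi = phi, psi = psi, omega = c(180, om),
                             chi1_his = c1h, chi2_his = chi2_his,
                             theta_x = tx, theta_y = ty, d_attack = da,
                             d_no = dn)
      if (is.null(topo)) topo <- mod$topology
      frames[[i]] <- frame_coords(mod, 1L)

      # realised hydrogen-bond geometry from the constructed coordinates
      iog <- which(topo$atom_name == "OG")
      ind1 <- which(topo$atom_name == "ND1")
      icb <- which(topo$atom_name == "CB" & topo$resno == 912L)
      hb <- hbond_geometry(frames[[i]][iog, ], Cbeta = frames[[i]][icb, ],
                           N_acceptor = frames[[i]][ind1, ])
      om_dev <- min(circular_distance(om, 180), circular_distance(om, 0))
      th_ok <- tx >= 60 & tx <= 120 & ty >= 60 & ty <= 120
      hb_ok <- hb$d_NO <= 3.2 & hb$linearity_dev < 30
      truth[[i]] <- data.frame(
        frame_index = i, theta_x = tx, theta_y = ty, d_attack = da,
        chi1_his = c1h, omega = om, d_NO = hb$d_NO,
        hbond_linearity_dev = hb$linearity_dev,
        chi1_his_bin = classify_chi1(c1h),
        omega_planarity_dev = om_dev,
        flag_theta_window = th_ok, flag_hbond = hb_ok,
        flag_active = th_ok & hb_ok, flag_strained = om_dev > 25,
        stringsAsFactors = FALSE)
    }
    structure(list(ensemble = conformer_ensemble(
      topo, frames, source = sprintf("synthetic GPS fixture (seed %d)", seed)),
      truth = do.call(rbind, truth), seed = seed),
      class = "gps_fixture")
  })
}

#' @export
print.gps_fixture <- function(x, ...) {
  cat(sprintf("<gps_fixture> %d frames (seed %d), %d planted active\n",
              n_frames(x$ensemble), x$seed, sum(x$truth$flag_active)))
  invisible(x)
}

#' Concatenate GPS fixtures
#'
#' Binds the frames and truth tables of fixtures sharing one topology
#' (e.g. an active and an inactive population forming a planted mixture);
#' truth frame indices are renumbered consecutively.
#'
#' @param ... `gps_fixture` objects.
#' @return A combined `gps_fixture`.
#' @export
bind_fixtures <- function(...) {
  fx <- list(...)
  stopifnot(length(fx) >= 1L,
            all(vapply(fx, inherits, logical(1L), "gps_fixture")))
  topo <- fx[[1L]]$ensemble$topology
  for (f in fx[-1L]) {
    if (!identical(f$ensemble$topology$atom_name, topo$atom_name))
      stop("fixtures have different topologies")
  }
  all_frames <- do.call(c, lapply(fx, function(f)
    lapply(seq_len(n_frames(f$ensemble)), function(i)
      frame_coords(f$ensemble, i))))
  truth <- do.call(rbind, lapply(fx, `[[`, "truth"))
  truth$frame_index <- seq_len(nrow(truth))
  structure(list(ensemble = conformer_ensemble(topo, all_frames,
                                               source = "synthetic GPS fixture (mixture)"),
                 truth = truth, seed = fx[[1L]]$seed),
            class = "gps_fixture")
}

#' Simulate a cleavage time course
#'
#' Draws cleavage fractions from the one-phase decay
#' `f(t) = 100 + (f0 - 100) * exp(-k t)` with additive Gaussian noise,
#' optionally truncated to \[0, 100\] percent.
#'
#' @param k rate constant (per day, > 0).
#' @param f0 cleavage at t = 0 (percent).
#' @param sigma noise s.d. (percent).
#' @param times sampling times in days (default: the 0-14 day design).
#' @param n_replicates replicate series per timepoint.
#' @param truncate clamp noisy values into \[0, 100\].
#' @param seed integer seed.
#' @return data frame with columns `time_days`, `fraction_percent`,
#'   `replicate`; attributes record the generating parameters.
#' @export
synth_kinetics <- function(k, f0 = 0, sigma = 0,
                           times = c(0, 1, 2, 4, 7, 10, 14),
                           n_replicates = 1L, truncate = TRUE, seed = 1L) {
  stopifnot(k > 0, sigma >= 0, n_replicates >= 1L)
  .with_seed(seed, {
    t_all <- rep(times, times = n_replicates)
    rep_id <- rep(seq_len(n_replicates), each = length(times))
    mu <- 100 + (f0 - 100) * exp(-k * t_all)
    y <- mu + stats::rnorm(length(t_all), 0, sigma)
    if (truncate) y <- pmin(pmax(y, 0), 100)
    out <- data.frame(time_days = t_all, fraction_percent = y,
                      replicate = rep_id)
    attr(out, "params") <- list(k = k, f0 = f0, sigma = sigma, seed = seed)
    out
  })
}

#' Sample an alignment from known column profiles
#'
#' Draws `n_rows` sequences column-independently from the given residue
#' profiles (named frequency vectors over the 20 amino acids, optionally
#' including `-`), yielding an alignment whose expected column
#' compositions are the planted profiles.
#'
#' @param profiles list of named frequency vectors (each summing to 1), or
#'   [column_profile] objects.
#' @param n_rows number of sequences.
#' @param seed integer seed.
#' @return An `aa_alignment`.
#' @export
synth_alignment <- function(profiles, n_rows, seed = 1L) {
  stopifnot(n_rows >= 1L, length(profiles) >= 1L)
  probs <- lapply(profiles, function(p) {
    if (inherits(p, "column_profile")) p <- p$frequencies
    if (is.null(names(p))) stop("profiles must be named frequency vectors")
    if (any(p < 0) || abs(sum(p) - 1) > 1e-6)
      stop("profile frequencies must be nonnegative and sum to 1")
    p
  })
  .with_seed(seed, {
    cols <- lapply(probs, function(p)
      sample(names(p), n_rows, replace = TRUE, prob = p))
    rows <- do.call(paste0, cols)
    names(rows) <- sprintf("synth%04d", seq_len(n_rows))
    aa_alignment(rows)
  })
}
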