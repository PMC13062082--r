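# Per-conformer catalytic-competence descriptors at the GPS.
#
# Geometry conventions:
#  * attack frame: origin at the scissile carbonyl carbon C; x along C->N
#    (leaving nitrogen), z along the peptide-plane normal (O-C x N-C),
#    y = z x x. Perpendicular attack of the nucleophile then gives
#    theta_x = theta_y = 90 degrees.
#  * boundary semantics follow the defining criteria literally:
#    theta window inclusive [60, 120]; H-bond distance inclusive (<= 3.2 A);
#    H-bond linearity strict (< 30 deg); chi1 bins strict (< 30 deg);
#    omega strain strict (> 25 deg).

.theta_lo <- 60
.theta_hi <- 120
.hbond_dmax <- 3.2
.hbond_devmax <- 30
.chi1_halfwidth <- 30
.omega_strain <- 25

#' Local reference frame of the scissile carbonyl
#'
#' Builds the orthonormal frame used to measure the nucleophile attack
#' angles: origin at the carbonyl carbon `C`, `x_axis` along C->N (towards
#' the leaving nitrogen), `z_axis` along the peptide-plane normal
#' (`(O-C) x (N-C)`), `y_axis = z_axis x x_axis` (in-plane). A nucleophile
#' approaching along the plane normal has both attack angles at 90 degrees.
#'
#' @param C,O,N coordinates of the scissile carbonyl carbon and oxygen and
#'   of the leaving (amide) nitrogen.
#' @return An object of class `attack_frame` with fields `origin`,
#'   `x_axis`, `y_axis`, `z_axis`.
#' @export
build_attack_frame <- function(C, O, N) {
  zraw <- .cross(O - C, N - C)
  if (.vnorm(zraw) < 1e-9) stop("C, O, N are collinear; no peptide plane")
  z <- .unit(zraw)
  x <- .unit(N - C)
  y <- .cross(z, x)
  structure(list(origin = C, x_axis = x, y_axis = y, z_axis = z),
            class = "attack_frame")
}

#' Nucleophile attack angles
#'
#' Angles between the C->Ogamma direction and the in-plane axes of an
#' [build_attack_frame] frame. `theta_x` is measured against the C->N axis
#' and `theta_y` against the in-plane orthogonal axis; both lie in
#' \[0, 180\]. Because the axes are orthogonal,
#' `cos^2(theta_x) + cos^2(theta_y) <= 1` always holds.
#'
#' @param frame an `attack_frame`.
#' @param Ogamma coordinate of the attacking hydroxyl oxygen.
#' @return Named numeric vector `c(theta_x, theta_y)` in degrees.
#' @export
attack_angles <- function(frame, Ogamma) {
  stopifnot(inherits(frame, "attack_frame"))
  u <- Ogamma - frame$origin
  if (.vnorm(u) < 1e-9) stop("nucleophile coincides with the carbonyl carbon")
  c(theta_x = vec_angle(u, frame$x_axis),
    theta_y = vec_angle(u, frame$y_axis))
}

#' Hydrogen-bond geometry between nucleophile hydroxyl and acceptor nitrogen
#'
#' Returns the heavy-atom distance `d_NO` between the acceptor nitrogen and
#' the hydroxyl oxygen, and the deviation of the O-H...N angle from
#' linearity. With an explicit hydroxyl hydrogen `H` the deviation is
#' `180 - angle(Ogamma, H, N)`. Without one, the hydrogen is idealised on
#' the cone with |O-H| = 0.96 Angstrom and angle(Cbeta, O, H) = 108.5
#' degrees, at the cone position minimising the deviation (the in-plane
#' position towards the acceptor); the minimised deviation is returned.
#'
#' A favourable geometry in the Table-1 sense is `d_NO <= 3.2` Angstrom
#' together with a deviation `< 30` degrees; the flag itself is computed by
#' [frame_descriptors].
#'
#' @param Ogamma,Cbeta coordinates of the hydroxyl oxygen and its carbon.
#' @param H optional explicit hydroxyl hydrogen coordinate.
#' @param N_acceptor acceptor nitrogen coordinate.
#' @param oh_bond,coh_angle idealisation constants (Angstrom, degrees).
#' @return list with `d_NO` (Angstrom) and `linearity_dev` (degrees).
#' @export
hbond_geometry <- function(Ogamma, Cbeta = NULL, H = NULL, N_acceptor,
                           oh_bond = 0.96, coh_angle = 108.5) {
  d_NO <- .vnorm(N_acceptor - Ogamma)
  if (d_NO < 1e-9) stop("acceptor nitrogen coincides with Ogamma")
  if (!is.null(H)) {
    dev <- 180 - vec_angle(Ogamma - H, N_acceptor - H)
    return(list(d_NO = d_NO, linearity_dev = dev))
  }
  if (is.null(Cbeta))
    stop("Cbeta is required to idealise the hydroxyl hydrogen")
  u <- .unit(Cbeta - Ogamma)
  a <- N_acceptor - Ogamma
  aperp <- a - sum(a * u) * u
  if (.vnorm(aperp) < 1e-9) {
    # acceptor on the C-O axis: every cone position is equivalent
    w <- .unit(.cross(u, if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
  } else {
    w <- .unit(aperp)
  }
  th <- coh_angle * pi / 180
  dev_at <- function(s) {
    H <- Ogamma + oh_bond * (cos(th) * u + s * sin(th) * w)
    180 - vec_angle(Ogamma - H, N_acceptor - H)
  }
  # the extrema of the deviation over the cone dihedral lie in the
  # (Cbeta, Ogamma, N) plane; evaluate both in-plane positions
  list(d_NO = d_NO, linearity_dev = min(dev_at(1), dev_at(-1)))
}

#' Classify a chi-1 torsion into canonical rotamer bins
#'
#' Assigns the side-chain torsion to the +60 (p), -60 (m) or 180 (t) bin
#' when its circular distance to the canonical value is strictly below 30
#' degrees; otherwise `"unassigned"`. The 180 bin wraps across +/-180.
#'
#' @param chi1 torsion angle(s) in degrees, in (-180, 180].
#' @return character vector over `{"+60", "-60", "180", "unassigned"}`.
#' @examples
#' classify_chi1(c(61, -65, -175, 95))
#' @export
classify_chi1 <- function(chi1) {
  vapply(chi1, function(x) {
    if (is.na(x)) return(NA_character_)
    d <- circular_distance(x, c(60, -60, 180))
    i <- which(d < .chi1_halfwidth)
    if (length(i)) c("+60", "-60", "180")[i[1L]] else "unassigned"
  }, character(1L))
}

#' Peptide-bond planarity strain
#'
#' Deviation of the omega torsion from planarity, i.e. the smaller of the
#' circular distances to 180 (trans) and 0 (cis) degrees, in \[0, 90\].
#' A peptide bond is called strained when the deviation exceeds 25 degrees
#' (strictly).
#'
#' @param omega omega torsion(s) in degrees, in (-180, 180].
#' @return data frame with columns `deviation` (degrees) and `strained`
#'   (logical).
#' @examples
#' omega_planarity(c(180, 150, -170, 25))
#' @export
omega_planarity <- function(omega) {
  dev <- pmin(circular_distance(omega, 180), circular_distance(omega, 0))
  data.frame(deviation = dev, strained = dev > .omega_strain)
}

# Resolve the acceptor nitrogen topology index for one policy.
.acceptor_index <- function(site, xyz, policy) {
  nd1 <- site$atoms[["his_ND1"]]
  ne2 <- site$atoms[["his_NE2"]]
  if (policy %in% c("ND1", "NE2")) {
    i <- if (policy == "ND1") nd1 else ne2
    if (is.na(i)) stop("acceptor atom ", policy, " not present in site")
    return(i)
  }
  if (is.na(nd1) || is.na(ne2)) return(NA_integer_)
  if (policy == "auto_tautomer") {
    return(switch(site$tautomer,
                  HSE = nd1,   # proton on N-epsilon, N-delta accepts
                  HSD = ne2,
                  stop("tautomer is '", site$tautomer,
                       "'; use acceptor_policy 'best', 'ND1' or 'NE2'")))
  }
  # policy "best": the nitrogen closer to Ogamma
  og <- xyz[site$atoms[["nu_OG"]], ]
  if (.vnorm(xyz[nd1, ] - og) <= .vnorm(xyz[ne2, ] - og)) nd1 else ne2
}

#' Catalytic-competence descriptors of one conformer
#'
#' Computes, for one frame of an ensemble, the full per-conformer record:
#' attack angles `theta_x`/`theta_y` of the hydroxyl nucleophile, the
#' His...Ogamma hydrogen-bond geometry (`d_NO`, linearity deviation), the
#' chi-1 torsions and rotamer bins of the base and the nucleophile, the
#' scissile omega torsion and its planarity deviation, the backbone phi/psi
#' of the GPS.+1 residue, and the derived flags:
#' `flag_theta_window` (both thetas within 90 +/- 30 degrees, inclusive),
#' `flag_hbond` (`d_NO <= 3.2` Angstrom and linearity deviation `< 30`
#' degrees), `flag_active` (= both), and `flag_strained` (omega deviation
#' `> 25` degrees).
#'
#' Undefined quantities (missing atoms, no tautomer-resolvable acceptor,
#' chain-terminal psi) propagate as `NA`, never as sentinel numbers.
#'
#' @param ensemble a [conformer_ensemble].
#' @param site a `gps_site` from [locate_gps].
#' @param frame_index frame to analyse (1-based).
#' @param acceptor_policy how to choose the acceptor imidazole nitrogen:
#'   `"auto_tautomer"` (N-delta for HSE, N-epsilon for HSD; error for
#'   HSP/unknown), `"ND1"`, `"NE2"`, or `"best"` (smaller `d_NO`).
#' @param use_explicit_h use the explicit hydroxyl hydrogen for the
#'   linearity deviation when present (default); otherwise idealise.
#' @return One-row data frame (see Details for columns).
#' @export
frame_descriptors <- function(ensemble, site, frame_index = 1L,
                              acceptor_policy = c("auto_tautomer", "ND1",
                                                  "NE2", "best"),
                              use_explicit_h = TRUE) {
  stopifnot(inherits(ensemble, "conformer_ensemble"), inherits(site, "gps_site"))
  acceptor_policy <- match.arg(acceptor_policy)
  xyz <- frame_coords(ensemble, frame_index)
  at <- function(nm) {
    i <- site$atoms[[nm]]
    if (is.na(i)) stop("site atom ", nm, " missing from topology")
    xyz[i, ]
  }

  fr <- build_attack_frame(at("x_C"), at("x_O"), at("nu_N"))
  th <- attack_angles(fr, at("nu_OG"))

  chi1_his <- tryCatch(
    dihedral(at("his_N"), at("his_CA"), at("his_CB"), at("his_CG")),
    error = function(e) NA_real_)
  chi1_nu <- dihedral(at("nu_N"), at("nu_CA"), at("nu_CB"), at("nu_OG"))

  omega <- dihedral(at("x_CA"), at("x_C"), at("nu_N"), at("nu_CA"))
  om <- omega_planarity(omega)

  phi <- dihedral(at("x_C"), at("nu_N"), at("nu_CA"), at("nu_C"))
  psi <- if (!is.na(site$atoms[["next_N"]]))
    dihedral(at("nu_N"), at("nu_CA"), at("nu_C"), xyz[site$atoms[["next_N"]], ])
  else NA_real_

  acc <- .acceptor_index(site, xyz, acceptor_policy)
  if (is.na(acc)) {
    d_NO <- NA_real_
    lin <- NA_real_
  } else {
    hxyz <- if (use_explicit_h && !is.na(site$atoms[["nu_HG"]]))
      xyz[site$atoms[["nu_HG"]], ] else NULL
    hb <- hbond_geometry(at("nu_OG"), Cbeta = at("nu_CB"), H = hxyz,
                         N_acceptor = xyz[acc, ])
    d_NO <- hb$d_NO
    lin <- hb$linearity_dev
  }

  flag_theta <- th[["theta_x"]] >= .theta_lo & th[["theta_x"]] <= .theta_hi &
    th[["theta_y"]] >= .theta_lo & th[["theta_y"]] <= .theta_hi
  flag_hbond <- if (is.na(d_NO)) NA else (d_NO <= .hbond_dmax & lin < .hbond_devmax)

  data.frame(frame_index = frame_index,
             theta_x = th[["theta_x"]],
             theta_y = th[["theta_y"]],
             d_NO = d_NO,
             hbond_linearity_dev = lin,
             chi1_his = chi1_his,
             chi1_nu = chi1_nu,
             chi1_his_bin = classify_chi1(chi1_his),
             chi1_nu_bin = classify_chi1(chi1_nu),
             omega_scissile = omega,
             omega_planarity_dev = om$deviation,
             phi_nu = phi,
             psi_nu = psi,
             flag_theta_window = flag_theta,
             flag_hbond = flag_hbond,
             flag_active = flag_theta & flag_hbond,
             flag_strained = om$strained,
             stringsAsFactors = FALSE)
}

#' Descriptor table over all frames of an ensemble
#'
#' Applies [frame_descriptors] to every frame (or a subset) and binds the
#' records into one data frame, one row per conformer.
#'
#' @inheritParams frame_descriptors
#' @param frames integer vector of frame indices (default: all frames).
#' @return data frame of per-frame descriptor records.
#' @export
descriptor_table <- function(ensemble, site, frames = NULL,
                             acceptor_policy = c("auto_tautomer", "ND1",
                                                 "NE2", "best"),
                             use_explicit_h = TRUE) {
  acceptor_policy <- match.arg(acceptor_policy)
  if (is.null(frames)) frames <- seq_len(n_frames(ensemble))
  do.call(rbind, lapply(frames, function(f)
    frame_descriptors(ensemble, site, f, acceptor_policy, use_explicit_h)))
}

.descriptor_columns <- c("frame_index", "theta_x", "theta_y", "d_NO",
                         "hbond_linearity_dev", "chi1_his", "chi1_nu",
                         "chi1_his_bin", "chi1_nu_bin", "omega_scissile",
                         "omega_planarity_dev", "phi_nu", "psi_nu",
                         "flag_theta_window", "flag_hbond", "flag_active",
                         "flag_strained")

#' Write / read a per-frame descriptor table
#'
#' Plain CSV with a fixed column order (one row per frame, angles in
#' degrees, distances in Angstrom, flags as 0/1).
#'
#' @param records data frame as produced by [descriptor_table].
#' @param path file path.
#' @return `write_descriptor_table` invisibly returns `path`;
#'   `read_descriptor_table` returns the records with flags restored to
#'   logical.
#' @export
write_descriptor_table <- function(records, path) {
  if (is.null(records) || nrow(records) == 0L)
    stop("no descriptor records to write")
  missing_cols <- setdiff(.descriptor_columns, names(records))
  if (length(missing_cols))
    stop("records lack columns: ", paste(missing_cols, collapse = ", "))
  out <- records[, .descriptor_columns]
  for (fl in c("flag_theta_window", "flag_hbond", "flag_active", "flag_strained"))
    out[[fl]] <- as.integer(out[[fl]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_descriptor_table
#' @export
read_descriptor_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(chi1_his_bin = "character",
                                        chi1_nu_bin = "character"))
  for (fl in c("flag_theta_window", "flag_hbond", "flag_active", "flag_strained"))
    if (fl %in% names(out)) out[[fl]] <- as.logical(out[[fl]])
  out
}
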