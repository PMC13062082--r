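#' Locate the GPS catalytic triad in a structure
#'
#' Resolves the His/X/Ser-Thr triad of the GPCR proteolysis site (GPS) and
#' the atoms needed for all downstream descriptors: the base imidazole
#' nitrogens, the scissile carbonyl (C, O) of the GPS.-1 residue, the leaving
#' nitrogen and the hydroxyl oxygen (OG for Ser, OG1 for Thr) of the GPS.+1
#' residue. Either give the author residue number of the nucleophile
#' (GPS.+1), or set `scan = TRUE` to search the chain sequence for the
#' canonical H-X-\[ST\] motif (plus R-X-\[ST\] when
#' `allow_noncanonical_base = TRUE`, as in the ADGRB1/B3 RLS motif); the
#' scan must find exactly one match.
#'
#' The histidine tautomer is set from explicit hydrogens when present
#' (HD1 only: HSD; HE2 only: HSE; both: HSP) and is `"unknown"` otherwise.
#'
#' @param ensemble a [conformer_ensemble].
#' @param chain chain identifier.
#' @param nucleophile_residue author residue number of the Ser/Thr (GPS.+1).
#' @param insert insertion code of the nucleophile residue (default none).
#' @param scan search the chain for the motif instead.
#' @param allow_noncanonical_base also accept Arg at the base (GPS.-2)
#'   position.
#' @return An object of class `gps_site`: residue keys for GPS.-2/-1/+1,
#'   a named vector `atoms` of topology indices (NA where an optional atom
#'   is absent), the histidine `tautomer`, and the `base_type`
#'   (`"His"`/`"Arg"`).
#' @export
locate_gps <- function(ensemble, chain, nucleophile_residue = NULL,
                       insert = "", scan = FALSE,
                       allow_noncanonical_base = FALSE) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  info <- .chain_sequence(ensemble, chain)
  res <- info$residues

  if (is.null(nucleophile_residue)) {
    if (!isTRUE(scan))
      stop("give 'nucleophile_residue' or set scan = TRUE")
    s <- strsplit(info$seq, "")[[1L]]
    bases <- c("H", if (allow_noncanonical_base) "R")
    hits <- which(seq_along(s) <= length(s) - 2L &
                    s %in% bases &
                    c(s[-(1:2)], "", "")[seq_along(s)] %in% c("S", "T"))
    if (length(hits) == 0L)
      stop("no ", paste(bases, collapse = "/"), "-X-[ST] motif found in chain ", chain)
    if (length(hits) > 1L)
      stop("ambiguous GPS: ", length(hits), " motif matches in chain ", chain,
           " (give 'nucleophile_residue' explicitly)")
    ipos <- hits + 2L
  } else {
    ipos <- which(res$resno == nucleophile_residue & res$insert == insert)
    if (length(ipos) != 1L)
      stop("residue ", nucleophile_residue, insert, " not found in chain ", chain)
    if (ipos < 3L)
      stop("GPS.+1 residue has fewer than two preceding residues in chain ", chain)
  }

  nu <- res[ipos, ]
  xres <- res[ipos - 1L, ]
  base <- res[ipos - 2L, ]

  if (!nu$resid %in% c("SER", "THR"))
    stop("GPS.+1 residue ", nu$resno, " is ", nu$resid, ", not Ser/Thr")
  base_type <- switch(base$resid,
                      HIS = "His",
                      ARG = if (allow_noncanonical_base) "Arg" else
                        stop("GPS.-2 residue is ARG; set allow_noncanonical_base = TRUE"),
                      stop("GPS.-2 residue ", base$resno, " is ", base$resid,
                           ", not His", if (allow_noncanonical_base) "/Arg"))

  ai <- function(r, nm) .atom_index(ensemble, chain, r$resno, r$insert, nm)
  og_name <- if (nu$resid == "SER") "OG" else "OG1"
  hg_name <- if (nu$resid == "SER") c("HG", "HG1") else c("HG1", "HG")

  atoms <- c(
    his_N   = ai(base, "N"),
    his_CA  = ai(base, "CA"),
    his_CB  = ai(base, "CB"),
    his_CG  = ai(base, "CG"),
    his_ND1 = if (base_type == "His") ai(base, "ND1") else NA_integer_,
    his_NE2 = if (base_type == "His") ai(base, "NE2") else NA_integer_,
    x_CA    = ai(xres, "CA"),
    x_C     = ai(xres, "C"),
    x_O     = ai(xres, "O"),
    nu_N    = ai(nu, "N"),
    nu_CA   = ai(nu, "CA"),
    nu_CB   = ai(nu, "CB"),
    nu_OG   = ai(nu, og_name),
    nu_C    = ai(nu, "C"),
    nu_HG   = ai(nu, hg_name),
    next_N  = if (ipos + 1L <= nrow(res)) ai(res[ipos + 1L, ], "N")
              else NA_integer_
  )
  required <- setdiff(names(atoms), c("nu_HG", "next_N",
    if (base_type == "Arg") c("his_ND1", "his_NE2")))
  if (anyNA(atoms[required]))
    stop("missing required GPS atoms: ",
         paste(required[is.na(atoms[required])], collapse = ", "))

  tautomer <- "unknown"
  if (base_type == "His") {
    hd1 <- ai(base, "HD1")
    he2 <- ai(base, "HE2")
    if (!is.na(hd1) && !is.na(he2)) tautomer <- "HSP"
    else if (!is.na(hd1)) tautomer <- "HSD"
    else if (!is.na(he2)) tautomer <- "HSE"
  }

  key <- function(r) list(resno = r$resno, insert = r$insert, resid = r$resid)
  structure(list(chain = chain,
                 his_residue = key(base),
                 x_residue = key(xres),
                 nu_residue = key(nu),
                 atoms = atoms,
                 tautomer = tautomer,
                 base_type = base_type),
            class = "gps_site")
}

#' @export
print.gps_site <- function(x, ...) {
  fmt <- function(k) sprintf("%s%d%s", k$resid, k$resno, k$insert)
  cat(sprintf("<gps_site> chain %s: %s / %s / %s (tautomer %s)\n",
              x$chain, fmt(x$his_residue), fmt(x$x_residue),
              fmt(x$nu_residue), x$tautomer))
  invisible(x)
}

#' Set the histidine tautomer of a GPS site
#'
#' Overrides the tautomer assignment (e.g. for trajectories stripped of
#' hydrogens where the simulated protonation state is known).
#'
#' @param site a `gps_site`.
#' @param tautomer one of `"HSE"`, `"HSD"`, `"HSP"`, `"unknown"`.
#' @return The modified `gps_site`.
#' @export
set_tautomer <- function(site, tautomer = c("HSE", "HSD", "HSP", "unknown")) {
  stopifnot(inherits(site, "gps_site"))
  site$tautomer <- match.arg(tautomer)
  site
}
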