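#' Conformer ensembles
#'
#' A `conformer_ensemble` holds one atom topology shared by an ordered set of
#' conformers: a crystallographic model, a predicted model, or trajectory
#' frames written as a multi-model PDB. The topology is a data frame with one
#' row per atom (columns `atom_name`, `element`, `resid`, `resno`, `insert`,
#' `chain`, `alt`, `occupancy`); coordinates live in a separate
#' `n_atoms x 3 x n_frames` array so that every downstream operation can index
#' atoms identically in every frame.
#'
#' @param topology data frame describing the atoms (see Details).
#' @param frames numeric array `n_atoms x 3 x n_frames`, or a list of
#'   `n_atoms x 3` matrices, or a single matrix.
#' @param frame_times optional numeric vector of frame times (ns), strictly
#'   increasing, one per frame.
#' @param source free-text provenance.
#' @return An object of class `conformer_ensemble`.
#' @export
conformer_ensemble <- function(topology, frames, frame_times = NULL, source = "") {
  required <- c("atom_name", "element", "resid", "resno", "insert", "chain",
                "alt", "occupancy")
  missing_cols <- setdiff(required, names(topology))
  if (length(missing_cols))
    stop("topology lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(topology) == 0L) stop("topology has zero atoms")
  if (any(!nzchar(topology$atom_name))) stop("empty atom_name in topology")

  if (is.matrix(frames)) frames <- list(frames)
  if (is.list(frames)) {
    frames <- array(unlist(lapply(frames, function(m) {
      if (!is.matrix(m) || ncol(m) != 3L || nrow(m) != nrow(topology))
        stop("each frame must be an n_atoms x 3 coordinate matrix")
      m
    })), dim = c(nrow(topology), 3L, length(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3L ||
      dim(frames)[1L] != nrow(topology) || dim(frames)[2L] != 3L)
    stop("frames must be an n_atoms x 3 x n_frames array")
  if (dim(frames)[3L] < 1L) stop("ensemble needs at least one frame")
  if (any(!is.finite(frames))) stop("non-finite coordinates in frames")
  occ <- topology$occupancy
  if (any(!is.na(occ) & (occ < 0 | occ > 1)))
    stop("occupancies must lie in [0, 1]")
  if (!is.null(frame_times)) {
    if (length(frame_times) != dim(frames)[3L])
      stop("frame_times must have one entry per frame")
    if (any(diff(frame_times) <= 0))
      stop("frame_times must be strictly increasing")
  }
  structure(list(topology = as.data.frame(topology, stringsAsFactors = FALSE),
                 frames = frames,
                 frame_times = frame_times,
                 source = source),
            class = "conformer_ensemble")
}

#' @rdname conformer_ensemble
#' @param x a `conformer_ensemble`.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "conformer_ensemble"))
  dim(x$frames)[3L]
}

#' Coordinates of one frame
#'
#' @param x a `conformer_ensemble`.
#' @param i frame index (1-based).
#' @return `n_atoms x 3` coordinate matrix.
#' @export
frame_coords <- function(x, i = 1L) {
  stopifnot(inherits(x, "conformer_ensemble"))
  if (i < 1L || i > n_frames(x)) stop("frame index out of range")
  x$frames[, , i, drop = TRUE]
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf("<conformer_ensemble> %d atoms, %d frame(s)\n",
              nrow(x$topology), n_frames(x)))
  ch <- unique(x$topology$chain)
  cat("  chains:", paste(ch, collapse = ", "), "\n")
  if (nzchar(x$source)) cat("  source:", x$source, "\n")
  invisible(x)
}

#' Read a structure or conformational ensemble
#'
#' Reads a (multi-model) PDB or mmCIF file into a [conformer_ensemble].
#' Alternate locations are collapsed per atom site according to
#' `altloc_policy`; hydrogens are kept if present and are never added.
#' Residue numbering is taken verbatim from the file (author numbering).
#'
#' @param path file path.
#' @param format `"pdb"` or `"mmcif"`; by default inferred from the file
#'   extension.
#' @param model_policy `"first"` keeps only the first model, `"all"` returns
#'   one frame per model (all models must share one atom topology).
#' @param altloc_policy `"highest_occupancy"` (default) keeps the alternate
#'   location with the largest occupancy (ties: first in file); `"first"`
#'   keeps the first alternate location encountered.
#' @param keep_altloc optional single character: keep exactly this alternate
#'   location identifier instead of collapsing, exposing one alt-loc
#'   conformer as a what-if input.
#' @return A [conformer_ensemble].
#' @export
read_structure <- function(path,
                           format = c("auto", "pdb", "mmcif"),
                           model_policy = c("first", "all"),
                           altloc_policy = c("highest_occupancy", "first"),
                           keep_altloc = NULL) {
  format <- match.arg(format)
  model_policy <- match.arg(model_policy)
  altloc_policy <- match.arg(altloc_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  pdb <- if (format == "pdb") {
    bio3d::read.pdb(path, multi = (model_policy == "all"), rm.alt = FALSE,
                    verbose = FALSE)
  } else {
    # files without secondary-structure annotation are fine
    withCallingHandlers(
      bio3d::read.cif(path, multi = (model_policy == "all"), rm.alt = FALSE,
                      verbose = FALSE),
      warning = function(w) {
        if (grepl("helix/sheet|beta version", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  }
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("no atoms parsed from ", path)

  xyz <- pdb$xyz
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1L)
  if (model_policy == "first") xyz <- xyz[1L, , drop = FALSE]
  if (ncol(xyz) != 3L * nrow(at))
    stop("inconsistent atom counts across models in ", path)

  alt <- at$alt
  alt[is.na(alt)] <- ""
  keep <- rep(TRUE, nrow(at))
  if (!is.null(keep_altloc)) {
    keep <- alt == "" | alt == keep_altloc
  } else if (any(alt != "")) {
    site <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "\r")
    for (s in unique(site[alt != ""])) {
      idx <- which(site == s)
      if (length(idx) < 2L) next
      pick <- if (altloc_policy == "highest_occupancy") {
        occ <- at$o[idx]
        occ[is.na(occ)] <- 0
        idx[which.max(occ)]
      } else idx[1L]
      keep[setdiff(idx, pick)] <- FALSE
    }
  }
  at <- at[keep, , drop = FALSE]
  cols <- as.vector(rbind(3L * which(keep) - 2L, 3L * which(keep) - 1L, 3L * which(keep)))
  xyz <- xyz[, cols, drop = FALSE]

  nat <- nrow(at)
  nfr <- nrow(xyz)
  frames <- array(NA_real_, dim = c(nat, 3L, nfr))
  for (f in seq_len(nfr)) {
    frames[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  }
  ins <- at$insert
  ins[is.na(ins)] <- ""
  alt2 <- at$alt
  alt2[is.na(alt2)] <- ""
  topo <- data.frame(atom_name = at$elety,
                     element = ifelse(is.na(at$elesy), "", at$elesy),
                     resid = at$resid,
                     resno = at$resno,
                     insert = ins,
                     chain = at$chain,
                     alt = alt2,
                     occupancy = ifelse(is.na(at$o), 1, at$o),
                     stringsAsFactors = FALSE)
  conformer_ensemble(topo, frames, source = path)
}

#' Write an ensemble as a (multi-model) PDB file
#'
#' Writes every frame as one MODEL record block (a single frame is written
#' without MODEL/ENDMDL wrappers). Coordinates are written at the standard
#' PDB precision of 0.001 Angstrom. The optional `bfactor` vector fills the
#' B-factor column (two decimals), e.g. for mapping per-residue scores onto
#' a structure.
#'
#' @param ensemble a [conformer_ensemble].
#' @param path output file path.
#' @param bfactor optional numeric vector, one value per atom.
#' @return Invisibly, `path`.
#' @export
write_ensemble_pdb <- function(ensemble, path, bfactor = NULL) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  topo <- ensemble$topology
  n <- nrow(topo)
  if (is.null(bfactor)) bfactor <- rep(0, n)
  if (length(bfactor) != n) stop("bfactor must have one value per atom")
  bfactor[!is.finite(bfactor)] <- 0

  fmt_name <- function(nm) {
    ifelse(nchar(nm) >= 4L, substr(nm, 1L, 4L), sprintf(" %-3s", nm))
  }
  names4 <- fmt_name(topo$atom_name)
  nfr <- n_frames(ensemble)
  con <- file(path, open = "wt")
  on.exit(close(con))
  multi <- nfr > 1L
  for (f in seq_len(nfr)) {
    if (multi) writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_coords(ensemble, f)
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3L)
    lines <- sprintf(
      "ATOM  %5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      (seq_len(n) - 1L) %% 99999L + 1L,
      names4,
      substr(paste0(topo$alt, " "), 1L, 1L),
      substr(topo$resid, 1L, 3L),
      substr(paste0(topo$chain, " "), 1L, 1L),
      topo$resno,
      substr(paste0(topo$insert, " "), 1L, 1L),
      xyz[, 1L], xyz[, 2L], xyz[, 3L],
      pmin(pmax(topo$occupancy, 0), 1),
      bfactor,
      toupper(topo$element))
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# Residue table of one chain, in file order: one row per (resno, insert)
# with the residue name and the topology index range.
.chain_residues <- function(ensemble, chain) {
  topo <- ensemble$topology
  sel <- which(topo$chain == chain)
  if (!length(sel)) stop("chain not found: ", chain)
  key <- paste(topo$resno[sel], topo$insert[sel], sep = "\r")
  first <- !duplicated(key)
  data.frame(resno = topo$resno[sel][first],
             insert = topo$insert[sel][first],
             resid = topo$resid[sel][first],
             stringsAsFactors = FALSE)
}

# Topology index of one named atom in one residue; NA_integer_ if absent.
.atom_index <- function(ensemble, chain, resno, insert, atom_name) {
  topo <- ensemble$topology
  for (nm in atom_name) {
    i <- which(topo$chain == chain & topo$resno == resno &
                 topo$insert == insert & topo$atom_name == nm)
    if (length(i)) return(i[1L])
  }
  NA_integer_
}

# One-letter sequence of a chain (X for non-standard residues).
.chain_sequence <- function(ensemble, chain) {
  res <- .chain_residues(ensemble, chain)
  aa <- bio3d::aa321(res$resid)
  aa[is.na(aa)] <- "X"
  list(residues = res, seq = paste(aa, collapse = ""))
}
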