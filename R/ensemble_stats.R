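# Ensemble-level summaries of per-frame descriptors: condition counts
# (Table-1 style), attack-angle density grids, strain enrichment, RMSF.

.chi1_bins <- c("+60", "-60", "180", "unassigned")

.bin_counts <- function(bins) {
  out <- vapply(.chi1_bins, function(b) sum(bins == b, na.rm = TRUE), integer(1L))
  names(out) <- .chi1_bins
  out
}

#' Condition counts and rotamer percentages for one replica
#'
#' Counts the frames of one replica satisfying each catalytic-competence
#' condition: attack angles inside the window (default 90 +/- 30 degrees,
#' inclusive), favourable His...Ser/Thr hydrogen-bond geometry, and their
#' conjunction ("GPS-active" frames); plus chi-1 rotamer-bin percentages
#' (over all frames of the replica, the unassigned bin closing the
#' partition) and scissile-bond strain counts over all frames and over the
#' active frames. Frames whose hydrogen-bond geometry is undefined
#' (missing acceptor) are excluded from the H-bond/active denominators and
#' reported in `n_undefined_hbond`.
#'
#' @param descriptors per-frame records from [descriptor_table].
#' @param theta_window numeric length-2 inclusive window for both attack
#'   angles, in degrees.
#' @param replica_id replica label.
#' @return Object of class `condition_summary`.
#' @export
summarize_conditions <- function(descriptors, theta_window = c(60, 120),
                                 replica_id = "r1") {
  if (is.null(descriptors) || nrow(descriptors) == 0L)
    stop("empty descriptor table")
  stopifnot(length(theta_window) == 2L, theta_window[1L] < theta_window[2L])
  th_ok <- descriptors$theta_x >= theta_window[1L] &
    descriptors$theta_x <= theta_window[2L] &
    descriptors$theta_y >= theta_window[1L] &
    descriptors$theta_y <= theta_window[2L]
  hb <- descriptors$flag_hbond
  undef <- is.na(hb)
  active <- th_ok & hb
  strained <- descriptors$flag_strained

  structure(list(
    replica_id = replica_id,
    n_frames = nrow(descriptors),
    theta_window = theta_window,
    n_theta_window = sum(th_ok, na.rm = TRUE),
    n_hbond = sum(hb, na.rm = TRUE),
    n_active = sum(active, na.rm = TRUE),
    n_undefined_hbond = sum(undef),
    chi1_his_counts = .bin_counts(descriptors$chi1_his_bin),
    chi1_nu_counts = .bin_counts(descriptors$chi1_nu_bin),
    pct_chi1_his = 100 * .bin_counts(descriptors$chi1_his_bin) / nrow(descriptors),
    pct_chi1_nu = 100 * .bin_counts(descriptors$chi1_nu_bin) / nrow(descriptors),
    n_strained_all = sum(strained, na.rm = TRUE),
    n_strained_active = sum(strained & active, na.rm = TRUE)
  ), class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("<condition_summary> replica %s: %d frames\n",
              x$replica_id, x$n_frames))
  cat(sprintf("  theta in [%g, %g]: %d   H-bond: %d   active: %d\n",
              x$theta_window[1L], x$theta_window[2L],
              x$n_theta_window, x$n_hbond, x$n_active))
  cat(sprintf("  chi1 His %%: %s\n",
              paste(sprintf("%s=%.1f", names(x$pct_chi1_his), x$pct_chi1_his),
                    collapse = " ")))
  cat(sprintf("  chi1 Ser/Thr %%: %s\n",
              paste(sprintf("%s=%.1f", names(x$pct_chi1_nu), x$pct_chi1_nu),
                    collapse = " ")))
  cat(sprintf("  strained: %d (all) / %d (active)\n",
              x$n_strained_all, x$n_strained_active))
  invisible(x)
}

#' Pool condition summaries over replicas
#'
#' Sums all counts and recomputes the rotamer percentages over the pooled
#' frames (equivalently: the frame-weighted mean of the per-replica
#' percentages).
#'
#' @param summaries list of `condition_summary` objects with distinct
#'   replica ids.
#' @return A pooled `condition_summary` (replica id joins the inputs).
#' @export
merge_replicas <- function(summaries) {
  if (!length(summaries)) stop("no summaries to merge")
  stopifnot(all(vapply(summaries, inherits, logical(1L), "condition_summary")))
  ids <- vapply(summaries, `[[`, character(1L), "replica_id")
  if (anyDuplicated(ids)) stop("duplicate replica ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  win <- summaries[[1L]]$theta_window
  if (!all(vapply(summaries, function(s)
    isTRUE(all.equal(s$theta_window, win)), logical(1L))))
    stop("summaries use different theta windows")
  add <- function(field) Reduce(`+`, lapply(summaries, `[[`, field))
  n <- add("n_frames")
  structure(list(
    replica_id = paste(ids, collapse = "+"),
    n_frames = n,
    theta_window = win,
    n_theta_window = add("n_theta_window"),
    n_hbond = add("n_hbond"),
    n_active = add("n_active"),
    n_undefined_hbond = add("n_undefined_hbond"),
    chi1_his_counts = add("chi1_his_counts"),
    chi1_nu_counts = add("chi1_nu_counts"),
    pct_chi1_his = 100 * add("chi1_his_counts") / n,
    pct_chi1_nu = 100 * add("chi1_nu_counts") / n,
    n_strained_all = add("n_strained_all"),
    n_strained_active = add("n_strained_active")
  ), class = "condition_summary")
}

#' Attack-angle density grid
#'
#' Bins the (theta_x, theta_y) pairs of a descriptor table on a square
#' grid over \[0, 180\]^2. Bins are half-open, lower-inclusive
#' (`[k*w, (k+1)*w)`), with the single value 180 assigned to the last bin,
#' so grid totals exactly equal the number of frames with defined angles.
#'
#' @param descriptors per-frame records from [descriptor_table].
#' @param bin_width bin width in degrees; must divide 180.
#' @return Object of class `theta_density`: `counts` (matrix, rows =
#'   theta_x bins, columns = theta_y bins), `bin_width`, `n`.
#' @export
theta_density <- function(descriptors, bin_width = 1) {
  if (bin_width <= 0 || abs(180 / bin_width - round(180 / bin_width)) > 1e-9)
    stop("bin_width must divide 180")
  nb <- as.integer(round(180 / bin_width))
  ok <- is.finite(descriptors$theta_x) & is.finite(descriptors$theta_y)
  ix <- pmin(floor(descriptors$theta_x[ok] / bin_width) + 1L, nb)
  iy <- pmin(floor(descriptors$theta_y[ok] / bin_width) + 1L, nb)
  counts <- matrix(0L, nb, nb)
  for (k in seq_along(ix)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1L
  mids <- (seq_len(nb) - 0.5) * bin_width
  dimnames(counts) <- list(theta_x = mids, theta_y = mids)
  structure(list(counts = counts, bin_width = bin_width, n = sum(ok)),
            class = "theta_density")
}

#' @export
print.theta_density <- function(x, ...) {
  m <- density_mode(x)
  cat(sprintf("<theta_density> %d frames, %g-degree bins, mode near (%g, %g)\n",
              x$n, x$bin_width, m[1L], m[2L]))
  invisible(x)
}

#' Modal bin of a density grid
#'
#' @param density a `theta_density`.
#' @return Bin-centre coordinates `c(theta_x, theta_y)` of the maximal
#'   count (ties: first in column-major order).
#' @export
density_mode <- function(density) {
  stopifnot(inherits(density, "theta_density"))
  i <- which(density$counts == max(density$counts), arr.ind = TRUE)[1L, ]
  w <- density$bin_width
  c(theta_x = (i[[1L]] - 0.5) * w, theta_y = (i[[2L]] - 0.5) * w)
}

#' Strain enrichment in GPS-active frames
#'
#' Percentage of scissile-bond-strained frames among the GPS-active frames
#' and among all frames, and their ratio. With no active frames the active
#' percentage and the enrichment are undefined (`NA`).
#'
#' @param descriptors per-frame records from [descriptor_table].
#' @return list with `pct_strained_active`, `pct_strained_all`,
#'   `enrichment`, and the underlying counts.
#' @export
strain_enrichment <- function(descriptors) {
  if (is.null(descriptors) || nrow(descriptors) == 0L)
    stop("empty descriptor table")
  strained <- descriptors$flag_strained
  active <- descriptors$flag_active
  n_all <- sum(!is.na(strained))
  pct_all <- 100 * sum(strained, na.rm = TRUE) / n_all
  n_active <- sum(active, na.rm = TRUE)
  pct_active <- if (n_active > 0L)
    100 * sum(strained & active, na.rm = TRUE) / n_active else NA_real_
  enr <- if (!is.na(pct_active) && pct_all > 0) pct_active / pct_all else NA_real_
  list(pct_strained_active = pct_active,
       pct_strained_all = pct_all,
       enrichment = enr,
       n_active = n_active,
       n_strained_active = sum(strained & active, na.rm = TRUE),
       n_strained_all = sum(strained, na.rm = TRUE),
       n_frames = n_all)
}

#' C-alpha atom selection
#'
#' @param ensemble a [conformer_ensemble].
#' @param chain optional chain filter.
#' @return Integer topology indices of the C-alpha atoms.
#' @export
select_calpha <- function(ensemble, chain = NULL) {
  topo <- ensemble$topology
  sel <- topo$atom_name == "CA"
  if (!is.null(chain)) sel <- sel & topo$chain %in% chain
  which(sel)
}

#' Per-atom root mean square fluctuation
#'
#' Least-squares superposes every frame onto a reference over the
#' alignment selection, then computes, for each atom of `selection`, the
#' root mean square displacement from its time-mean position. With
#' `reference_policy = "first_frame"` the reference is frame 1; with
#' `"mean_structure"` the reference is iterated to self-consistency (at
#' most 10 iterations or a mean change below 1e-6 Angstrom). RMSF is
#' invariant under a global rigid motion of every frame, and zero for a
#' static or rigidly moved ensemble.
#'
#' @param ensemble a [conformer_ensemble] with at least two frames.
#' @param selection topology indices to report (default: all C-alpha).
#' @param align_selection topology indices used for the superposition
#'   (default: same as `selection`).
#' @param reference_policy `"first_frame"` or `"mean_structure"`.
#' @return data frame with one row per selected atom: residue key columns
#'   and `rmsf` (Angstrom).
#' @export
rmsf_profile <- function(ensemble, selection = NULL, align_selection = NULL,
                         reference_policy = c("first_frame", "mean_structure")) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  reference_policy <- match.arg(reference_policy)
  nf <- n_frames(ensemble)
  if (nf < 2L) stop("RMSF needs at least two frames")
  if (is.null(selection)) selection <- select_calpha(ensemble)
  if (!length(selection)) stop("empty selection")
  if (is.null(align_selection)) align_selection <- selection

  align_once <- function(ref_align) {
    fitted <- array(NA_real_, dim = c(length(selection), 3L, nf))
    for (f in seq_len(nf)) {
      xyz <- frame_coords(ensemble, f)
      sup <- kabsch_superpose(ref_align, xyz[align_selection, , drop = FALSE])
      fitted[, , f] <- apply_superposition(sup, xyz[selection, , drop = FALSE])
    }
    fitted
  }

  ref <- frame_coords(ensemble, 1L)[align_selection, , drop = FALSE]
  fitted <- align_once(ref)
  if (reference_policy == "mean_structure") {
    # iterate the alignment reference towards the ensemble mean
    sel_in_align <- match(align_selection, selection)
    if (anyNA(sel_in_align))
      stop("with mean_structure, align_selection must be a subset of selection")
    for (it in seq_len(10L)) {
      newref <- apply(fitted[sel_in_align, , , drop = FALSE], c(1L, 2L), mean)
      if (mean(abs(newref - ref)) < 1e-6) break
      ref <- newref
      fitted <- align_once(ref)
    }
  }
  mean_pos <- apply(fitted, c(1L, 2L), mean)
  disp2 <- vapply(seq_len(nf), function(f)
    rowSums((fitted[, , f] - mean_pos)^2), numeric(length(selection)))
  if (is.null(dim(disp2))) disp2 <- matrix(disp2, nrow = 1L)
  topo <- ensemble$topology[selection, , drop = FALSE]
  data.frame(index = selection,
             chain = topo$chain,
             resno = topo$resno,
             insert = topo$insert,
             atom_name = topo$atom_name,
             rmsf = sqrt(rowMeans(disp2)),
             stringsAsFactors = FALSE)
}
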