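# Ortholog conservation profiling: per-column residue frequencies, Shannon
# entropy, and mapping of entropies onto structure residues.

.aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

#' Read a multiple sequence alignment
#'
#' Reads an aligned FASTA or Clustal file into a validated alignment:
#' equal-length rows over the 20 amino acids plus the gap character `-`
#' (`.` is normalised to `-`). Under the default strict policy any other
#' character (ambiguity codes B/Z/X, unknowns) is rejected; with
#' `ambiguity = "as_gap"` such characters are converted to gaps.
#'
#' @param path file path.
#' @param format `"fasta"`, `"clustal"`, or `"auto"` (by extension;
#'   `.aln` is read as Clustal).
#' @param ambiguity `"strict"` (default) or `"as_gap"`.
#' @return Object of class `aa_alignment`: character vector `rows` named
#'   by sequence id, and `width`.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "clustal"),
                           ambiguity = c("strict", "as_gap")) {
  format <- match.arg(format)
  ambiguity <- match.arg(ambiguity)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.(aln|clustal|clw)$", path, ignore.case = TRUE))
      "clustal" else "fasta"
  rows <- if (format == "fasta") {
    s <- Biostrings::readBStringSet(path)
    stats::setNames(as.character(s), names(s))
  } else {
    m <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
    stats::setNames(as.character(m), rownames(m))
  }
  aa_alignment(rows, ambiguity = ambiguity)
}

#' @rdname read_alignment
#' @param rows named character vector of equal-length aligned sequences.
#' @export
aa_alignment <- function(rows, ambiguity = c("strict", "as_gap")) {
  ambiguity <- match.arg(ambiguity)
  if (!length(rows)) stop("alignment has no sequences")
  rows <- toupper(rows)
  rows <- gsub(".", "-", rows, fixed = TRUE)
  w <- unique(nchar(rows))
  if (length(w) != 1L)
    stop("ragged alignment: row lengths ", paste(sort(w), collapse = ", "))
  allowed <- paste0(paste(.aa20, collapse = ""), "-")
  bad <- gsub(sprintf("[%s]", allowed), "", rows)
  if (any(nzchar(bad))) {
    if (ambiguity == "strict")
      stop("illegal alignment characters: ",
           paste(unique(strsplit(paste(bad, collapse = ""), "")[[1L]]),
                 collapse = ", "))
    rows <- gsub(sprintf("[^%s]", allowed), "-", rows)
  }
  if (is.null(names(rows))) names(rows) <- paste0("seq", seq_along(rows))
  structure(list(rows = rows, width = w), class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("<aa_alignment> %d sequences x %d columns\n",
              length(x$rows), x$width))
  invisible(x)
}

#' Write an alignment as aligned FASTA
#'
#' @param alignment an `aa_alignment`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(alignment, path) {
  stopifnot(inherits(alignment, "aa_alignment"))
  writeLines(as.vector(rbind(paste0(">", names(alignment$rows)),
                             alignment$rows)), path)
  invisible(path)
}

#' Residue composition of one alignment column
#'
#' Counts and frequencies of the 20 amino acids in one column. Under
#' `gap_policy = "exclude"` (default) frequencies are renormalised over the
#' non-gap residues; an all-gap column yields an undefined profile
#' (`defined = FALSE`). Under `"count_as_symbol"` the gap is a 21st symbol
#' of the support.
#'
#' @param alignment an `aa_alignment`.
#' @param column column index (1-based).
#' @param gap_policy `"exclude"` or `"count_as_symbol"`.
#' @return Object of class `column_profile`: `counts`, `frequencies`
#'   (summing to 1 over the support when defined), `gap_fraction`,
#'   `support`, `defined`.
#' @export
column_profile <- function(alignment, column,
                           gap_policy = c("exclude", "count_as_symbol")) {
  stopifnot(inherits(alignment, "aa_alignment"))
  gap_policy <- match.arg(gap_policy)
  if (column < 1L || column > alignment$width) stop("column out of range")
  letters_col <- substr(alignment$rows, column, column)
  n <- length(letters_col)
  gap_fraction <- sum(letters_col == "-") / n
  support <- if (gap_policy == "exclude") .aa20 else c(.aa20, "-")
  counts <- vapply(support, function(a) sum(letters_col == a), integer(1L))
  total <- sum(counts)
  defined <- total > 0L
  freqs <- if (defined) counts / total else rep(NA_real_, length(counts))
  names(freqs) <- support
  structure(list(column = column, counts = counts, frequencies = freqs,
                 gap_fraction = gap_fraction, support = support,
                 gap_policy = gap_policy, defined = defined),
            class = "column_profile")
}

#' Shannon entropy of a residue profile
#'
#' `H = -sum p * log(p)` with `0 * log(0) = 0`, in the chosen logarithm
#' base (`"e"`: nats, the default; `"2"`: bits; `"20"`: normalised so the
#' uniform 20-residue profile has entropy 1).
#'
#' @param profile a [column_profile], or a bare numeric frequency vector
#'   (nonnegative, summing to 1).
#' @param base `"e"`, `"2"` or `"20"`.
#' @return Entropy, a nonnegative number; maximal (`log(support size)`)
#'   exactly at the uniform profile.
#' @examples
#' shannon_entropy(rep(1 / 20, 20))            # log(20)
#' shannon_entropy(c(1, rep(0, 19)))           # 0
#' @export
shannon_entropy <- function(profile, base = c("e", "2", "20")) {
  base <- match.arg(base)
  p <- if (inherits(profile, "column_profile")) {
    if (!profile$defined) stop("undefined profile (all-gap column)")
    profile$frequencies
  } else as.numeric(profile)
  if (any(p < -1e-12)) stop("negative frequencies")
  if (abs(sum(p) - 1) > 1e-6) stop("frequencies must sum to 1")
  p <- p[p > 0]
  h <- -sum(p * log(p))
  switch(base, e = h, `2` = h / log(2), `20` = h / log(20))
}

#' Entropy profile over all columns
#'
#' @inheritParams column_profile
#' @inheritParams shannon_entropy
#' @return Numeric vector of per-column entropies (`NA` for undefined
#'   columns).
#' @export
entropy_profile <- function(alignment, base = c("e", "2", "20"),
                            gap_policy = c("exclude", "count_as_symbol")) {
  base <- match.arg(base)
  gap_policy <- match.arg(gap_policy)
  vapply(seq_len(alignment$width), function(j) {
    pr <- column_profile(alignment, j, gap_policy)
    if (!pr$defined) return(NA_real_)
    shannon_entropy(pr, base)
  }, numeric(1L))
}

#' Map per-column entropies onto structure residues
#'
#' Matches one (ungapped) alignment row against the residue sequence of a
#' structure chain and transfers the per-column entropy to each matched
#' residue. The row must share at least `min_identity` sequence identity
#' with the chain over the aligned, non-gap columns. Structure residues
#' without a matched column are returned with `NA` entropy.
#'
#' @param entropies numeric vector of per-column entropies (length =
#'   alignment width), e.g. from [entropy_profile].
#' @param alignment the `aa_alignment` the entropies were computed from.
#' @param row_id name of the alignment row corresponding to the structure.
#' @param ensemble a [conformer_ensemble].
#' @param chain chain identifier.
#' @param min_identity minimum fractional identity (default 0.95).
#' @return data frame with one row per structure residue: residue key,
#'   matched alignment `column` and `entropy`.
#' @export
map_entropy_to_structure <- function(entropies, alignment, row_id, ensemble,
                                     chain, min_identity = 0.95) {
  stopifnot(inherits(alignment, "aa_alignment"))
  if (length(entropies) != alignment$width)
    stop("entropies must have one value per alignment column")
  if (!row_id %in% names(alignment$rows))
    stop("alignment row not found: ", row_id)
  row_chars <- strsplit(alignment$rows[[row_id]], "")[[1L]]
  ungapped_cols <- which(row_chars != "-")
  row_seq <- paste(row_chars[ungapped_cols], collapse = "")
  sc <- .chain_sequence(ensemble, chain)

  letters21 <- c(.aa20, "X")
  m <- matrix(-1, length(letters21), length(letters21),
              dimnames = list(letters21, letters21))
  diag(m) <- 1
  al <- Biostrings::pairwiseAlignment(row_seq, sc$seq, type = "global",
                                      substitutionMatrix = m,
                                      gapOpening = 0, gapExtension = 2)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1L]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1L]]
  ia <- 0L; ib <- 0L
  col_of_res <- rep(NA_integer_, nrow(sc$residues))
  n_match <- 0L; n_aligned <- 0L
  for (k in seq_along(pa)) {
    ga <- pa[k] == "-"; gb <- pb[k] == "-"
    if (!ga) ia <- ia + 1L
    if (!gb) ib <- ib + 1L
    if (ga || gb) next
    n_aligned <- n_aligned + 1L
    if (pa[k] == pb[k]) n_match <- n_match + 1L
    col_of_res[ib] <- ungapped_cols[ia]
  }
  if (n_aligned == 0L || n_match / n_aligned < min_identity)
    stop(sprintf("alignment row and chain differ too much (identity %.1f%% < %.1f%%)",
                 100 * n_match / max(n_aligned, 1L), 100 * min_identity))
  data.frame(chain = chain,
             resno = sc$residues$resno,
             insert = sc$residues$insert,
             resid = sc$residues$resid,
             column = col_of_res,
             entropy = ifelse(is.na(col_of_res), NA_real_,
                              entropies[col_of_res]),
             stringsAsFactors = FALSE)
}

#' Write per-residue entropies into the B-factor column of a PDB file
#'
#' All atoms of a residue receive the residue's entropy value (two-decimal
#' PDB precision); residues without a value are written as 0.00.
#'
#' @param mapping data frame from [map_entropy_to_structure].
#' @param ensemble the [conformer_ensemble] that was mapped (first frame is
#'   written).
#' @param path output PDB path.
#' @return Invisibly, `path`.
#' @export
write_entropy_pdb <- function(mapping, ensemble, path) {
  topo <- ensemble$topology
  key_t <- paste(topo$chain, topo$resno, topo$insert, sep = "\r")
  key_m <- paste(mapping$chain, mapping$resno, mapping$insert, sep = "\r")
  b <- mapping$entropy[match(key_t, key_m)]
  b[is.na(b)] <- 0
  single <- conformer_ensemble(topo, frame_coords(ensemble, 1L),
                               source = ensemble$source)
  write_ensemble_pdb(single, path, bfactor = b)
}
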