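# Dynamic cross-correlation matrix of C-alpha fluctuations.

#' Dynamic cross-correlation matrix
#'
#' For each pair of selected atoms (one per residue), the normalized
#' correlation of their 3-D displacement vectors over the analysis frames,
#' C_ij = <dr_i . dr_j> / sqrt(<dr_i^2><dr_j^2>), with displacements taken
#' about the trajectory mean (default) or the reference frame, after
#' frame-wise least-squares superposition onto the reference.
#'
#' Atoms with zero variance have undefined correlations; their rows/columns
#' are reported as `NA` (never coerced to 0).
#'
#' @param traj an `md_trajectory` with at least 2 analysis frames.
#' @param selection atom indices or selection expression (default `"ca"`).
#' @param fit superpose each frame onto the reference before measuring.
#' @param center displacement reference: `"mean"` (trajectory mean, the
#'   usual convention) or `"initial"` (first analysis frame).
#' @return Object of class `md_dccm`: list with `C` (n x n correlations,
#'   labelled), `cov` (n x n covariances of displacement dot products, A^2),
#'   `labels` (residue ids).
#' @export
dccm <- function(traj, selection = "ca", fit = TRUE,
                 center = c("mean", "initial")) {
  center <- match.arg(center)
  sel <- resolve_selection(traj, selection)
  frames <- analysis_frames(traj)
  if (length(frames) < 2L) stop("dccm needs at least 2 analysis frames")
  n <- length(sel)
  ref <- frame_xyz(traj, frames[1])[sel, , drop = FALSE]
  X <- array(NA_real_, dim = c(length(frames), n, 3L))
  for (k in seq_along(frames)) {
    m <- frame_xyz(traj, frames[k])[sel, , drop = FALSE]
    if (fit && n >= 3L) m <- apply_superposition(m, superpose(m, ref))
    X[k, , ] <- m
  }
  ctr <- if (center == "mean") apply(X, c(2, 3), mean) else X[1, , ]
  D <- sweep(X, c(2, 3), ctr)           # F x n x 3 displacements
  # covariance of dot products: cov_ij = mean_f sum_ax D[f,i,ax] D[f,j,ax]
  cv <- matrix(0, n, n)
  for (ax in 1:3) cv <- cv + crossprod(D[, , ax]) / length(frames)
  v <- diag(cv)
  denom <- sqrt(outer(v, v))
  C <- cv / denom
  zero <- v <= .Machine$double.eps
  if (any(zero)) {
    C[zero, ] <- NA_real_
    C[, zero] <- NA_real_
  }
  diag(C)[!zero] <- 1
  labels <- residue_ids(traj$topology, sel)
  dimnames(C) <- dimnames(cv) <- list(labels, labels)
  structure(list(C = C, cov = cv, labels = labels, center = center),
            class = "md_dccm")
}

#' @export
print.md_dccm <- function(x, ...) {
  off <- x$C[upper.tri(x$C)]
  cat("md_dccm:", nrow(x$C), "residues; mean |C| off-diagonal =",
      sprintf("%.3f", mean(abs(off), na.rm = TRUE)), "\n")
  invisible(x)
}

#' Display-masked copy of a correlation matrix
#'
#' Returns a copy in which entries with |C| below the threshold are blanked
#' (`NA`); the computation-facing matrix is untouched. Mirrors the common
#' practice of whitening weak correlations in DCCM figures.
#'
#' @param x an `md_dccm`.
#' @param threshold absolute-correlation cutoff in \[0, 1\] (default 0.3).
#' @return An `md_dccm` whose `C` has sub-threshold entries set to `NA`.
#' @export
mask_dccm <- function(x, threshold = 0.3) {
  stopifnot(inherits(x, "md_dccm"), threshold >= 0, threshold <= 1)
  y <- x
  y$C[!is.na(y$C) & abs(y$C) < threshold] <- NA_real_
  y$masked_below <- threshold
  y
}

#' Write a correlation matrix as labelled TSV
#'
#' Residue labels form the header row and first column; the same dialect is
#' read back by [read_dccm()].
#'
#' @param x an `md_dccm`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dccm <- function(x, path) {
  m <- as.data.frame(x$C)
  m <- cbind(residue = x$labels, m)
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a correlation matrix written by [write_dccm()]
#'
#' @param path TSV path.
#' @return An `md_dccm` (covariances unavailable, set to `NA`).
#' @export
read_dccm <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(tab[[1]])
  C <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(C) <- list(labels, labels)
  structure(list(C = C, cov = matrix(NA_real_, nrow(C), ncol(C)),
                 labels = labels, center = NA_character_),
            class = "md_dccm")
}
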