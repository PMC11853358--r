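# Rigid-body superposition and deviation / fluctuation metrics.

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between a
#' mobile and a reference coordinate set (uniform weights).
#'
#' @param mobile numeric N x 3 matrix.
#' @param reference numeric N x 3 matrix with the same N (N >= 3,
#'   non-collinear).
#' @return Object of class `superposition` with elements `rotation` (3 x 3,
#'   determinant +1), `translation` (length-3), and `rmsd` (Angstrom). The
#'   fitted mobile coordinates are `mobile %*% t(rotation)` plus
#'   `translation` row-wise; see [apply_superposition()].
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)))
    stop("coordinate sets differ in size: ", nrow(mobile), " vs ", nrow(reference))
  n <- nrow(mobile)
  if (n < 3L) stop("superposition needs at least 3 atoms")
  cm_m <- colMeans(mobile); cm_r <- colMeans(reference)
  P <- sweep(mobile, 2, cm_m); Q <- sweep(reference, 2, cm_r)
  sv_q <- svd(Q)$d
  if (sv_q[2] < 1e-8 * max(sv_q[1], 1))
    stop("degenerate reference: rank-deficient (collinear) coordinates")
  H <- crossprod(P, Q)                  # 3x3
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- P %*% t(R)
  rmsd <- sqrt(sum((fitted - Q)^2) / n)
  structure(list(rotation = R,
                 translation = as.numeric(cm_r - R %*% cm_m),
                 rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

#' Apply a superposition transform to coordinates
#'
#' @param xyz numeric N x 3 matrix.
#' @param sup a `superposition`.
#' @return Transformed N x 3 matrix.
#' @export
apply_superposition <- function(xyz, sup) {
  sweep(as.matrix(xyz) %*% t(sup$rotation), 2, sup$translation, "+")
}

# RMSD between two coordinate sets, optionally after fitting on fit_idx
pair_rmsd <- function(mobile, reference, fit = TRUE, fit_idx = NULL) {
  if (fit) {
    if (is.null(fit_idx)) fit_idx <- seq_len(nrow(mobile))
    sup <- superpose(mobile[fit_idx, , drop = FALSE],
                     reference[fit_idx, , drop = FALSE])
    mobile <- apply_superposition(mobile, sup)
  }
  sqrt(sum((mobile - reference)^2) / nrow(mobile))
}

resolve_selection <- function(traj, selection) {
  if (is.character(selection)) selection <- select_atoms(traj$topology, selection)
  selection <- as.integer(selection)
  if (!length(selection)) stop("empty selection")
  if (any(selection < 1L | selection > dim(traj$coords)[2]))
    stop("selection index out of range")
  selection
}

#' Per-frame RMSD series of a trajectory
#'
#' RMSD of the selected atoms in every frame relative to a reference frame,
#' optionally after least-squares fitting (on the same selection unless
#' `fit_selection` differs).
#'
#' @param traj an `md_trajectory`.
#' @param selection atom indices or a selection expression (e.g. `"ca"`).
#' @param reference_frame frame index of the reference (default 1).
#' @param fit superpose each frame onto the reference before measuring.
#' @param fit_selection optional separate selection used for the fit.
#' @return Numeric vector of length F (all frames), in Angstrom.
#' @export
rmsd_series <- function(traj, selection = "ca", reference_frame = 1L,
                        fit = TRUE, fit_selection = NULL) {
  sel <- resolve_selection(traj, selection)
  fsel <- if (is.null(fit_selection)) sel else resolve_selection(traj, fit_selection)
  nf <- dim(traj$coords)[1]
  ref_full <- frame_xyz(traj, reference_frame)
  out <- numeric(nf)
  for (f in seq_len(nf)) {
    m <- frame_xyz(traj, f)
    if (fit) {
      sup <- superpose(m[fsel, , drop = FALSE], ref_full[fsel, , drop = FALSE])
      m <- apply_superposition(m, sup)
    }
    out[f] <- sqrt(sum((m[sel, , drop = FALSE] -
                        ref_full[sel, , drop = FALSE])^2) / length(sel))
  }
  out
}

#' Per-residue RMSF of a trajectory
#'
#' Root-mean-square fluctuation of each selected atom (conventionally one
#' C-alpha per residue) over the analysis frames, relative either to its
#' position in the initial analysis frame (`reference = "initial"`) or to its
#' trajectory-mean position (`reference = "mean"`). Frames can first be
#' superposed onto the reference frame to remove global motion.
#'
#' @param traj an `md_trajectory`.
#' @param selection atom indices or selection expression mapping 1:1 to
#'   residues (default `"ca"`).
#' @param reference `"initial"` or `"mean"`.
#' @param fit superpose frames (on the selection) before measuring.
#' @return Numeric vector (Angstrom) named by residue id, with attribute
#'   `reference` recording the convention used.
#' @export
rmsf <- function(traj, selection = "ca", reference = c("initial", "mean"),
                 fit = TRUE) {
  reference <- match.arg(reference)
  sel <- resolve_selection(traj, selection)
  frames <- analysis_frames(traj)
  ref_xyz <- frame_xyz(traj, frames[1])[sel, , drop = FALSE]
  nsel <- length(sel)
  X <- array(NA_real_, dim = c(length(frames), nsel, 3L))
  for (k in seq_along(frames)) {
    m <- frame_xyz(traj, frames[k])[sel, , drop = FALSE]
    if (fit && nsel >= 3L) {
      sup <- superpose(m, ref_xyz)
      m <- apply_superposition(m, sup)
    }
    X[k, , ] <- m
  }
  ref_pos <- if (reference == "initial") ref_xyz else
    apply(X, c(2, 3), mean)
  sq <- sweep(X, c(2, 3), ref_pos)^2
  out <- sqrt(apply(sq, 2, sum) / length(frames))
  names(out) <- residue_ids(traj$topology, sel)
  attr(out, "reference") <- reference
  out
}

#' Write an RMSD series as TSV (`frame<TAB>rmsd_A`)
#' @param x numeric RMSD series.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rmsd <- function(x, path) {
  utils::write.table(data.frame(frame = seq_along(x), rmsd_A = x), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an RMSF profile as TSV (`resnum<TAB>rmsf_A`)
#' @param x named RMSF vector from [rmsf()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rmsf <- function(x, path) {
  utils::write.table(data.frame(resnum = names(x), rmsf_A = as.numeric(x)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
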