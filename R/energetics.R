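# Implicit-solvent binding free energy: molecular-mechanics interaction
# terms, generalized-Born polar solvation, linear nonpolar (SASA) solvation,
# end-point binding energy and per-residue decomposition.

# Coulomb conversion, kcal A mol^-1 e^-2
COULOMB_KCAL <- 332.0636

# HCT pairwise descreening scale factors by element
GB_SCREEN <- c(H = 0.85, C = 0.72, N = 0.79, O = 0.85, S = 0.96)
GB_SCREEN_DEFAULT <- 0.80

require_params <- function(model, idx, cols) {
  a <- model$atoms[idx, , drop = FALSE]
  for (col in cols) {
    bad <- which(is.na(a[[col]]))
    if (length(bad))
      stop("missing ", col, " for atom ", a$chain[bad[1]], ":",
           a$resno[bad[1]], ":", a$atom[bad[1]])
  }
  invisible(TRUE)
}

#' Intermolecular molecular-mechanics terms
#'
#' Electrostatic (Coulomb, conversion 332.0636 kcal A / mol e^2) and
#' Lennard-Jones (r_min/epsilon form) energies summed over all cross-group
#' atom pairs, with no distance cutoff.
#'
#' @param model an `md_structure` carrying charges and LJ parameters.
#' @param xyz optional N x 3 coordinates overriding the model's own.
#' @param groupA,groupB disjoint atom groups (chain ids / selections /
#'   indices).
#' @param eps_solute solute dielectric dividing the Coulomb term (default 1).
#' @return List with `ele` and `vdw` (kcal/mol).
#' @export
mm_terms <- function(model, groupA, groupB, xyz = NULL, eps_solute = 1) {
  if (is.null(xyz)) xyz <- model$xyz
  ia <- group_indices(model, groupA); ib <- group_indices(model, groupB)
  if (length(intersect(ia, ib))) stop("groups overlap")
  require_params(model, c(ia, ib), c("charge", "eps", "rmin_half"))
  A <- xyz[ia, , drop = FALSE]; B <- xyz[ib, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  r <- sqrt(pmax(d2, 0))
  qa <- model$atoms$charge[ia]; qb <- model$atoms$charge[ib]
  ele <- COULOMB_KCAL / eps_solute * sum(outer(qa, qb) / r)
  eij <- sqrt(outer(model$atoms$eps[ia], model$atoms$eps[ib]))
  rmin <- outer(model$atoms$rmin_half[ia], model$atoms$rmin_half[ib], "+")
  sr6 <- (rmin / r)^6
  vdw <- sum(eij * (sr6^2 - 2 * sr6))
  list(ele = ele, vdw = vdw)
}

# HCT pairwise descreening integral: contribution of a sphere of scaled
# radius s at distance r to the inverse Born radius of an atom of intrinsic
# radius rho (Hawkins-Cramer-Truhlar form; exact s^3/(3 r^4) far-field limit)
hct_term <- function(r, s, rho) {
  U <- r + s
  if (rho >= U) return(0)
  L <- max(abs(r - s), rho)
  I <- 1 / L - 1 / U + 0.25 * (r - s^2 / r) * (1 / U^2 - 1 / L^2) +
    log(L / U) / (2 * r)
  if (rho < s - r) I <- I + 2 * (1 / rho - 1 / L)
  0.5 * I
}

#' Effective Born radii (HCT pairwise descreening)
#'
#' 1/R_i = 1/rho_i - sum_j H(r_ij, S_j rho_j; rho_i); an isolated atom's
#' effective radius equals its intrinsic radius exactly. Element-specific
#' screening factors follow the usual HCT set.
#'
#' @param xyz N x 3 coordinates.
#' @param rho intrinsic radii (A).
#' @param screen per-atom screening factors; defaults from element symbols
#'   in `elements` (fallback 0.8).
#' @param elements optional element symbols used to look up screens.
#' @return Numeric vector of effective radii (A).
#' @export
born_radii <- function(xyz, rho, screen = NULL, elements = NULL) {
  n <- nrow(xyz)
  if (is.null(screen)) {
    screen <- rep(GB_SCREEN_DEFAULT, n)
    if (!is.null(elements)) {
      hit <- GB_SCREEN[elements]
      screen[!is.na(hit)] <- hit[!is.na(hit)]
    }
  }
  D <- as.matrix(stats::dist(xyz))
  inv <- 1 / rho
  for (i in seq_len(n)) {
    for (j in seq_len(n)[-i])
      inv[i] <- inv[i] - hct_term(D[i, j], screen[j] * rho[j], rho[i])
  }
  1 / pmax(inv, 1e-3)
}

# Still pairwise GB energy over one atom set (ordered pairs incl. self)
gb_energy_xyz <- function(xyz, q, R, eps_solute, eps_solvent) {
  D2 <- as.matrix(stats::dist(xyz))^2
  RR <- outer(R, R)
  f <- sqrt(D2 + RR * exp(-D2 / (4 * RR)))
  -(COULOMB_KCAL / 2) * (1 / eps_solute - 1 / eps_solvent) *
    sum(outer(q, q) / f)
}

# per-atom GB attribution: row sums of the symmetric pair-term matrix
gb_energy_atoms <- function(xyz, q, R, eps_solute, eps_solvent) {
  D2 <- as.matrix(stats::dist(xyz))^2
  RR <- outer(R, R)
  f <- sqrt(D2 + RR * exp(-D2 / (4 * RR)))
  T <- -(COULOMB_KCAL / 2) * (1 / eps_solute - 1 / eps_solvent) *
    (outer(q, q) / f)
  # split each unordered pair half/half = keep diagonal + half the
  # off-diagonal row/column sums; since T is symmetric, row sums do exactly
  # that for the ordered double sum
  rowSums(T)
}

#' Generalized-Born polar solvation energy of an atom group
#'
#' Still pairwise functional form with HCT effective radii; fills the polar
#' slot of the solvation free energy (a Poisson-Boltzmann backend could be
#' substituted without changing the interface).
#'
#' @param model an `md_structure` with charges and intrinsic radii.
#' @param group atom group (chain ids / selection / indices); default all.
#' @param xyz optional N x 3 coordinates (full model) overriding the model's.
#' @param eps_solute,eps_solvent interior and solvent dielectrics
#'   (defaults 1 and 80).
#' @return Polar solvation energy (kcal/mol).
#' @export
gb_polar <- function(model, group = NULL, xyz = NULL, eps_solute = 1,
                     eps_solvent = 80) {
  if (is.null(xyz)) xyz <- model$xyz
  idx <- if (is.null(group)) seq_len(nrow(model$atoms)) else
    group_indices(model, group)
  require_params(model, idx, c("charge", "radius"))
  sub <- xyz[idx, , drop = FALSE]
  q <- model$atoms$charge[idx]
  rho <- model$atoms$radius[idx]
  R <- born_radii(sub, rho, elements = model$atoms$element[idx])
  gb_energy_xyz(sub, q, R, eps_solute, eps_solvent)
}

#' Nonpolar solvation term from SASA
#'
#' The linear surface-area model: gamma * SASA + b.
#'
#' @param sasa_total total SASA in A^2 (must be nonnegative).
#' @param gamma surface tension coefficient, kcal/mol/A^2 (default 0.00542).
#' @param b offset, kcal/mol (default 0.92).
#' @return Nonpolar solvation energy (kcal/mol).
#' @export
nonpolar_term <- function(sasa_total, gamma = 0.00542, b = 0.92) {
  if (any(sasa_total < 0)) stop("SASA must be nonnegative")
  gamma * sasa_total + b
}

#' End-point implicit-solvent binding free energy
#'
#' Single-trajectory protocol: for every analysed complex frame, the
#' receptor-alone and ligand-alone states reuse the complex coordinates, so
#' the intramolecular term cancels exactly and is reported as 0. The binding
#' energy decomposes as dG_binding = dE_MM + dG_sol with
#' dE_MM = dE_vdW + dE_ele + dE_int and dG_sol = dE_polar + dE_nonpolar;
#' the entropy term is excluded and marked so.
#'
#' @param traj an `md_trajectory` whose topology carries charges, radii and
#'   LJ parameters.
#' @param receptor,ligand the two groups partitioning the complex.
#' @param eps_solute,eps_solvent dielectrics (defaults 1 / 80).
#' @param gamma,b nonpolar model coefficients (defaults 0.00542 / 0.92).
#' @param probe,points SASA probe radius and quadrature points.
#' @param stride analyse every stride-th analysis frame (default 1).
#' @return Object of class `energy_breakdown`: data.frame `components`
#'   (component, mean, sd in kcal/mol), per-frame matrix `frames`, and
#'   `entropy` = "excluded".
#' @export
binding_energy <- function(traj, receptor, ligand, eps_solute = 1,
                           eps_solvent = 80, gamma = 0.00542, b = 0.92,
                           probe = 1.4, points = 960L, stride = 1L) {
  top <- traj$topology
  ir <- group_indices(top, receptor); il <- group_indices(top, ligand)
  if (length(intersect(ir, il))) stop("receptor and ligand groups overlap")
  require_params(top, c(ir, il), c("charge", "radius", "eps", "rmin_half"))
  radii <- atom_radii(top)
  frames <- analysis_frames(traj)
  frames <- frames[seq(1L, length(frames), by = stride)]
  per <- matrix(NA_real_, length(frames), 4,
                dimnames = list(NULL, c("vdw", "ele", "polar", "nonpolar")))
  for (k in seq_along(frames)) {
    m <- frame_xyz(traj, frames[k])
    mm <- mm_terms(top, ir, il, xyz = m, eps_solute = eps_solute)
    gAB <- gb_polar(top, c(ir, il), xyz = m, eps_solute = eps_solute,
                    eps_solvent = eps_solvent)
    gA <- gb_polar(top, ir, xyz = m, eps_solute = eps_solute,
                   eps_solvent = eps_solvent)
    gB <- gb_polar(top, il, xyz = m, eps_solute = eps_solute,
                   eps_solvent = eps_solvent)
    sAB <- sum(sasa_xyz(m[c(ir, il), , drop = FALSE], radii[c(ir, il)],
                        probe, points))
    sA <- sum(sasa_xyz(m[ir, , drop = FALSE], radii[ir], probe, points))
    sB <- sum(sasa_xyz(m[il, , drop = FALSE], radii[il], probe, points))
    per[k, ] <- c(mm$vdw, mm$ele, gAB - gA - gB,
                  nonpolar_term(sAB, gamma, b) - nonpolar_term(sA, gamma, b) -
                    nonpolar_term(sB, gamma, b))
  }
  full <- cbind(per,
                int = 0,
                mm = per[, "vdw"] + per[, "ele"],
                sol = per[, "polar"] + per[, "nonpolar"])
  full <- cbind(full, binding = full[, "mm"] + full[, "sol"])
  comp_names <- c(vdw = "dE_vdW", ele = "dE_ele", int = "dE_int",
                  polar = "dE_polar", nonpolar = "dE_nonpolar",
                  mm = "dE_MM", sol = "dG_sol", binding = "dG_binding")
  ord <- names(comp_names)
  components <- data.frame(
    component = unname(comp_names[ord]),
    mean = colMeans(full[, ord, drop = FALSE]),
    sd = apply(full[, ord, drop = FALSE], 2,
               function(x) if (length(x) > 1) stats::sd(x) else 0),
    row.names = NULL)
  structure(list(components = components, frames = full,
                 frame_indices = frames, entropy = "excluded",
                 protocol = "single-trajectory"),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("energy_breakdown (", x$protocol, " protocol, entropy ", x$entropy,
      "):\n", sep = "")
  tab <- x$components
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-12s %9.3f +/- %.3f kcal/mol\n", tab$component[i],
                tab$mean[i], tab$sd[i]))
  invisible(x)
}

#' Extract a component mean from an energy breakdown
#' @param x an `energy_breakdown`.
#' @param component component name (default `"dG_binding"`).
#' @return Mean value in kcal/mol.
#' @export
energy_component <- function(x, component = "dG_binding") {
  i <- match(component, x$components$component)
  if (is.na(i)) stop("no component '", component, "'")
  x$components$mean[i]
}

#' Per-residue decomposition of the binding free energy
#'
#' Pairwise electrostatic, van der Waals and generalized-Born terms are
#' split half to each partner residue (diagonal GB self-terms to their own
#' residue); the nonpolar term is attributed through each atom's SASA change
#' on binding, with the constant offset spread in proportion to
#' |per-residue SASA change|. Row sums reproduce the total binding energy
#' exactly (up to numerical roundoff).
#'
#' @inheritParams binding_energy
#' @return Object of class `residue_energy`: data.frame with one row per
#'   residue (`chain`, `resno`, `resname`, `vdw`, `ele`, `polar`,
#'   `nonpolar`, `total`, kcal/mol, averaged over frames).
#' @export
per_residue_decomposition <- function(traj, receptor, ligand, eps_solute = 1,
                                      eps_solvent = 80, gamma = 0.00542,
                                      b = 0.92, probe = 1.4, points = 960L,
                                      stride = 1L) {
  top <- traj$topology
  ir <- group_indices(top, receptor); il <- group_indices(top, ligand)
  if (length(intersect(ir, il))) stop("receptor and ligand groups overlap")
  require_params(top, c(ir, il), c("charge", "radius", "eps", "rmin_half"))
  all_idx <- c(ir, il)
  rid <- residue_ids(top, all_idx)
  ures <- unique(rid)
  rmap <- match(rid, ures)
  radii <- atom_radii(top)
  q <- top$atoms$charge
  frames <- analysis_frames(traj)
  frames <- frames[seq(1L, length(frames), by = stride)]
  acc <- matrix(0, length(ures), 4,
                dimnames = list(ures, c("vdw", "ele", "polar", "nonpolar")))
  side <- ifelse(all_idx %in% ir, "A", "B")
  for (k in seq_along(frames)) {
    m <- frame_xyz(traj, frames[k])
    A <- m[ir, , drop = FALSE]; B <- m[il, , drop = FALSE]
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    r <- sqrt(pmax(d2, 0))
    ele_pair <- COULOMB_KCAL / eps_solute *
      outer(q[ir], q[il]) / r
    eij <- sqrt(outer(top$atoms$eps[ir], top$atoms$eps[il]))
    rmin <- outer(top$atoms$rmin_half[ir], top$atoms$rmin_half[il], "+")
    sr6 <- (rmin / r)^6
    vdw_pair <- eij * (sr6^2 - 2 * sr6)
    # half to each partner atom, then pool by residue
    atom_ele <- numeric(length(all_idx))
    atom_vdw <- numeric(length(all_idx))
    nr <- length(ir)
    atom_ele[seq_len(nr)] <- rowSums(ele_pair) / 2
    atom_ele[nr + seq_along(il)] <- colSums(ele_pair) / 2
    atom_vdw[seq_len(nr)] <- rowSums(vdw_pair) / 2
    atom_vdw[nr + seq_along(il)] <- colSums(vdw_pair) / 2
    # GB: per-atom attribution in complex minus isolated states
    xyzS <- m[all_idx, , drop = FALSE]
    rhoS <- top$atoms$radius[all_idx]
    elS <- top$atoms$element[all_idx]
    RAB <- born_radii(xyzS, rhoS, elements = elS)
    gb_AB <- gb_energy_atoms(xyzS, q[all_idx], RAB, eps_solute, eps_solvent)
    isA <- side == "A"
    RA <- born_radii(xyzS[isA, , drop = FALSE], rhoS[isA],
                     elements = elS[isA])
    gb_A <- gb_energy_atoms(xyzS[isA, , drop = FALSE], q[all_idx][isA], RA,
                            eps_solute, eps_solvent)
    RB <- born_radii(xyzS[!isA, , drop = FALSE], rhoS[!isA],
                     elements = elS[!isA])
    gb_B <- gb_energy_atoms(xyzS[!isA, , drop = FALSE], q[all_idx][!isA], RB,
                            eps_solute, eps_solvent)
    atom_gb <- gb_AB
    atom_gb[isA] <- atom_gb[isA] - gb_A
    atom_gb[!isA] <- atom_gb[!isA] - gb_B
    # nonpolar: per-atom SASA change; offset -b spread over |dSASA|
    sAB <- sasa_xyz(xyzS, radii[all_idx], probe, points)
    sA <- sasa_xyz(xyzS[isA, , drop = FALSE], radii[all_idx][isA], probe, points)
    sB <- sasa_xyz(xyzS[!isA, , drop = FALSE], radii[all_idx][!isA], probe, points)
    dsasa <- sAB
    dsasa[isA] <- dsasa[isA] - sA
    dsasa[!isA] <- dsasa[!isA] - sB
    atom_np <- gamma * dsasa
    w <- abs(dsasa)
    atom_np <- atom_np + (if (sum(w) > 0) -b * w / sum(w) else
      rep(-b / length(dsasa), length(dsasa)))
    acc[, "vdw"] <- acc[, "vdw"] + rowsum(atom_vdw, rmap)[, 1]
    acc[, "ele"] <- acc[, "ele"] + rowsum(atom_ele, rmap)[, 1]
    acc[, "polar"] <- acc[, "polar"] + rowsum(atom_gb, rmap)[, 1]
    acc[, "nonpolar"] <- acc[, "nonpolar"] + rowsum(atom_np, rmap)[, 1]
  }
  acc <- acc / length(frames)
  first <- all_idx[match(ures, rid)]
  tab <- data.frame(chain = top$atoms$chain[first],
                    resno = top$atoms$resno[first],
                    resname = top$atoms$resname[first],
                    vdw = acc[, "vdw"], ele = acc[, "ele"],
                    polar = acc[, "polar"], nonpolar = acc[, "nonpolar"],
                    total = rowSums(acc), row.names = NULL)
  structure(list(table = tab, frame_indices = frames),
            class = "residue_energy")
}

#' @export
print.residue_energy <- function(x, ...) {
  cat("residue_energy:", nrow(x$table), "residues; total",
      sprintf("%.3f", sum(x$table$total)), "kcal/mol\n")
  ord <- order(x$table$total)
  print.data.frame(utils::head(x$table[ord, ], 8), digits = 4)
  invisible(x)
}

#' Write an energy breakdown as TSV (`component`, `mean`, `sd`)
#' @param x an `energy_breakdown`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_energy <- function(x, path) {
  utils::write.table(x$components, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a per-residue energy table as TSV
#' @param x a `residue_energy`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_residue_energy <- function(x, path) {
  utils::write.table(x$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
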