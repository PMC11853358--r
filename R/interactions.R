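# Geometric interaction detection, occupancy statistics, SASA and
# interface-area distributions.

# Bondi-type van der Waals radii (A) by element; used when a structure
# carries no per-atom radii
DEFAULT_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                   P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

atom_radii <- function(model, idx = seq_len(nrow(model$atoms)),
                       require_all = TRUE) {
  a <- model$atoms[idx, , drop = FALSE]
  r <- a$radius
  miss <- is.na(r)
  r[miss] <- DEFAULT_RADII[a$element[miss]]
  if (any(is.na(r))) {
    bad <- which(is.na(r))[1]
    if (require_all)
      stop("no radius for atom ", a$chain[bad], ":", a$resno[bad], ":",
           a$atom[bad], " (element '", a$element[bad], "')")
  }
  r
}

# deterministic near-uniform unit-sphere quadrature (golden-spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# core Shrake-Rupley on raw coordinates + radii
sasa_xyz <- function(xyz, radii, probe = 1.4, points = 960L) {
  n <- nrow(xyz)
  pts <- sphere_points(points)
  R <- radii + probe
  # neighbour prefilter
  D2 <- as.matrix(stats::dist(xyz))^2
  out <- numeric(n)
  for (i in seq_len(n)) {
    neigh <- which(D2[i, ] < (R[i] + R)^2 & seq_len(n) != i)
    if (!length(neigh)) {
      out[i] <- 4 * pi * R[i]^2
      next
    }
    P <- sweep(pts * R[i], 2, xyz[i, ], "+")   # points x 3
    exposed <- rep(TRUE, points)
    for (j in neigh) {
      dx <- P[, 1] - xyz[j, 1]; dy <- P[, 2] - xyz[j, 2]; dz <- P[, 3] - xyz[j, 3]
      exposed <- exposed & (dx * dx + dy * dy + dz * dz > R[j]^2)
      if (!any(exposed)) break
    }
    out[i] <- 4 * pi * R[i]^2 * sum(exposed) / points
  }
  out
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom SASA by quadrature over a deterministic golden-spiral point set
#' on each atom's solvent-expanded sphere (radius + probe). Radii come from
#' the structure's parameter table, falling back to Bondi-type element
#' defaults.
#'
#' @param model an `md_structure`.
#' @param xyz optional N x 3 coordinates overriding the model's own.
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param points quadrature points per atom (default 960).
#' @return Object of class `sasa_result`: `atom_sasa` (A^2), `total`,
#'   `probe`, `points`.
#' @export
sasa <- function(model, xyz = NULL, probe = 1.4, points = 960L) {
  if (is.null(xyz)) xyz <- model$xyz
  r <- atom_radii(model)
  s <- sasa_xyz(as.matrix(xyz), r, probe, points)
  structure(list(atom_sasa = s, total = sum(s), probe = probe,
                 points = points),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("sasa_result: total %.2f A^2 over %d atoms (probe %.2f A, %d points)\n",
              x$total, length(x$atom_sasa), x$probe, x$points))
  invisible(x)
}

group_indices <- function(model, group) {
  if (is.character(group) && length(group) >= 1L &&
      all(group %in% model$atoms$chain))
    return(which(model$atoms$chain %in% group))
  if (is.character(group) && length(group) == 1L)
    return(select_atoms(model, group))
  as.integer(group)
}

#' Per-frame buried interface area between two chain groups
#'
#' area = (SASA(A alone) + SASA(B alone) - SASA(A union B)) / 2 per analysis
#' frame (half-buried-SASA convention), plus a probability histogram of the
#' series.
#'
#' @param traj an `md_trajectory`.
#' @param groupA,groupB disjoint chain-id vectors (or atom index vectors).
#' @param probe probe radius (default 1.4 A).
#' @param points quadrature points per atom (default 960).
#' @param hist_bins histogram bin count (default 30).
#' @param stride analyse every stride-th analysis frame (default 1).
#' @return Object of class `interface_series`: `frames`, `area` (A^2),
#'   `histogram` (mids, probabilities), grouping and convention metadata.
#' @export
interface_area <- function(traj, groupA, groupB, probe = 1.4, points = 960L,
                           hist_bins = 30L, stride = 1L) {
  top <- traj$topology
  ia <- group_indices(top, groupA)
  ib <- group_indices(top, groupB)
  if (!length(ia) || !length(ib)) stop("groups must be nonempty")
  if (length(intersect(ia, ib))) stop("groups overlap")
  r <- atom_radii(top)
  frames <- analysis_frames(traj)
  frames <- frames[seq(1L, length(frames), by = stride)]
  area <- numeric(length(frames))
  for (k in seq_along(frames)) {
    m <- frame_xyz(traj, frames[k])
    sA <- sum(sasa_xyz(m[ia, , drop = FALSE], r[ia], probe, points))
    sB <- sum(sasa_xyz(m[ib, , drop = FALSE], r[ib], probe, points))
    sAB <- sum(sasa_xyz(m[c(ia, ib), , drop = FALSE], r[c(ia, ib)], probe, points))
    area[k] <- (sA + sB - sAB) / 2
  }
  h <- graphics::hist(area, breaks = hist_bins, plot = FALSE)
  structure(list(frames = frames, area = area,
                 histogram = list(mids = h$mids,
                                  prob = h$counts / sum(h$counts)),
                 groupA = groupA, groupB = groupB,
                 convention = "half-buried-SASA"),
            class = "interface_series")
}

#' @export
print.interface_series <- function(x, ...) {
  cat(sprintf("interface_series: %d frames, mean %.1f A^2, mode %.1f A^2 (%s)\n",
              length(x$area), mean(x$area), interface_mode(x), x$convention))
  invisible(x)
}

#' Modal interface area (histogram peak)
#' @param x an `interface_series`.
#' @return Bin mid-point (A^2) of the most probable histogram bin.
#' @export
interface_mode <- function(x) x$histogram$mids[which.max(x$histogram$prob)]

# ---- residue-pair contact machinery ----------------------------------------

# per-frame residue-pair contact indicator via sparse-free crossprod trick:
# residue x residue "any atom pair within cutoff" boolean matrix
atom_contact_to_residue <- function(D_le, res_fac) {
  M <- stats::model.matrix(~ res_fac - 1)   # atoms x residues indicator
  t(M) %*% D_le %*% M > 0
}

# contact persistence between residues of idxA and idxB over analysis frames
pair_occupancy_matrix <- function(traj, idxA, idxB, cutoff) {
  top <- traj$topology
  ridA <- residue_ids(top, idxA); ridB <- residue_ids(top, idxB)
  uA <- unique(ridA); uB <- unique(ridB)
  MA <- outer(uA, ridA, "==") * 1          # residues x atoms
  MB <- outer(uB, ridB, "==") * 1
  frames <- analysis_frames(traj)
  hits <- matrix(0L, length(uA), length(uB), dimnames = list(uA, uB))
  for (f in frames) {
    m <- frame_xyz(traj, f)
    A <- m[idxA, , drop = FALSE]; B <- m[idxB, , drop = FALSE]
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    close <- (d2 <= cutoff^2) * 1
    hits <- hits + ((MA %*% close %*% t(MB)) > 0)
  }
  list(occ = hits / length(frames), n_frames = length(frames),
       resA = uA, resB = uB)
}

interaction_row <- function(top, ridA, ridB, type, occ, stable_threshold) {
  resinfo <- function(rid) {
    i <- match(rid, residue_ids(top))
    c(top$atoms$chain[i], top$atoms$resno[i], top$atoms$resname[i])
  }
  a <- resinfo(ridA); b <- resinfo(ridB)
  data.frame(chainA = a[1], resnoA = as.integer(a[2]), resnameA = a[3],
             chainB = b[1], resnoB = as.integer(b[2]), resnameB = b[3],
             type = type, occupancy = occ, stable = occ >= stable_threshold,
             stringsAsFactors = FALSE)
}

#' Residue-residue contact occupancies
#'
#' Fraction of analysis frames in which the minimum interatomic distance of a
#' residue pair is within the cutoff (exact frame counting; occupancy times
#' the frame count is always an integer). A contact is flagged stable when
#' its occupancy reaches the threshold (inclusive).
#'
#' @param traj an `md_trajectory`.
#' @param groupA,groupB chain ids, selection expressions or atom indices
#'   delimiting the two sides (e.g. the two chains of a complex).
#' @param cutoff distance cutoff in Angstrom (default 4.5).
#' @param mode `"heavy"` (any heavy-atom pair, default) or `"ca"`
#'   (alpha-carbon distance).
#' @param stable_threshold stable-contact occupancy threshold, inclusive
#'   (default 0.70).
#' @param min_occupancy drop pairs below this occupancy from the table
#'   (default 0: keep all pairs ever in contact).
#' @return data.frame of class `interaction_table` with columns `chainA`,
#'   `resnoA`, `resnameA`, `chainB`, `resnoB`, `resnameB`, `type`,
#'   `occupancy`, `stable`; attribute `n_frames`.
#' @export
contact_occupancy <- function(traj, groupA, groupB, cutoff = 4.5,
                              mode = c("heavy", "ca"),
                              stable_threshold = 0.70, min_occupancy = 0) {
  mode <- match.arg(mode)
  top <- traj$topology
  ia <- group_indices(top, groupA); ib <- group_indices(top, groupB)
  if (mode == "heavy") {
    ia <- ia[top$atoms$element[ia] != "H"]
    ib <- ib[top$atoms$element[ib] != "H"]
  } else {
    ia <- ia[top$atoms$atom[ia] == "CA"]
    ib <- ib[top$atoms$atom[ib] == "CA"]
  }
  po <- pair_occupancy_matrix(traj, ia, ib, cutoff)
  rows <- list()
  for (i in seq_along(po$resA)) for (j in seq_along(po$resB)) {
    occ <- po$occ[i, j]
    if (occ > min_occupancy || (min_occupancy == 0 && occ > 0))
      rows[[length(rows) + 1L]] <-
        interaction_row(top, po$resA[i], po$resB[j], "contact", occ,
                        stable_threshold)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    interaction_row(top, residue_ids(top)[1], residue_ids(top)[1],
                    "contact", 0, stable_threshold)[0, ]
  attr(tab, "n_frames") <- po$n_frames
  attr(tab, "mode") <- mode
  class(tab) <- c("interaction_table", "data.frame")
  tab
}

# residue templates: heavy-atom hydrogen-bond donors and acceptors
HB_TEMPLATES <- list(
  donors = list(
    backbone = "N",
    ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2", HIS = c("ND1", "NE2"),
    LYS = "NZ", SER = "OG", THR = "OG1", TRP = "NE1", TYR = "OH", CYS = "SG"),
  acceptors = list(
    backbone = "O",
    ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
    HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH", MET = "SD",
    CYS = "SG")
)

hb_atoms <- function(model, idx, role) {
  a <- model$atoms[idx, , drop = FALSE]
  tpl <- HB_TEMPLATES[[role]]
  known <- unique(c(names(HB_TEMPLATES$donors), names(HB_TEMPLATES$acceptors),
                    "ALA", "GLY", "VAL", "LEU", "ILE", "PRO", "PHE", "MET"))
  unknown <- setdiff(unique(a$resname), c(known, "backbone"))
  if (length(unknown))
    warning("no hydrogen-bond template for residue(s) ",
            paste(unknown, collapse = ", "), "; skipped")
  keep <- a$atom %in% tpl$backbone
  for (rn in names(tpl)) {
    if (rn == "backbone") next
    keep <- keep | (a$resname == rn & a$atom %in% tpl[[rn]])
  }
  idx[keep]
}

# generic scheduled-pair occupancy scanner over two specific atom sets
typed_occupancy <- function(traj, idxA, idxB, d_max, type, stable_threshold,
                            min_occupancy) {
  top <- traj$topology
  if (!length(idxA) || !length(idxB))
    return(structure(
      interaction_row(top, residue_ids(top)[1], residue_ids(top)[1],
                      type, 0, stable_threshold)[0, ],
      n_frames = n_frames(traj, analysis = TRUE),
      class = c("interaction_table", "data.frame")))
  po <- pair_occupancy_matrix(traj, idxA, idxB, d_max)
  rows <- list()
  for (i in seq_along(po$resA)) for (j in seq_along(po$resB)) {
    occ <- po$occ[i, j]
    if (occ > min_occupancy && po$resA[i] != po$resB[j])
      rows[[length(rows) + 1L]] <-
        interaction_row(top, po$resA[i], po$resB[j], type, occ,
                        stable_threshold)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    interaction_row(top, residue_ids(top)[1], residue_ids(top)[1],
                    type, 0, stable_threshold)[0, ]
  attr(tab, "n_frames") <- po$n_frames
  class(tab) <- c("interaction_table", "data.frame")
  tab
}

#' Hydrogen-bond occupancies between two groups
#'
#' Donors and acceptors are identified from shipped residue templates. With
#' hydrogens present the criterion is donor-acceptor distance <= `d_max` and
#' donor-H...acceptor angle >= `angle_min`; without hydrogens (the usual case
#' for coarse or heavy-atom models) the distance criterion alone applies and
#' the mode is recorded in the output.
#'
#' @param traj an `md_trajectory`.
#' @param groupA,groupB the two sides (chain ids / selections / indices).
#' @param d_max donor-acceptor heavy-atom cutoff (default 3.5 A).
#' @param angle_min D-H...A angle cutoff in degrees (default 135; only used
#'   when hydrogens exist).
#' @param stable_threshold stable flag threshold (default 0.70).
#' @param min_occupancy drop pairs at or below this occupancy (default 0).
#' @return An `interaction_table` (type `"hbond"`), attribute `criterion`.
#' @export
hydrogen_bonds <- function(traj, groupA, groupB, d_max = 3.5,
                           angle_min = 135, stable_threshold = 0.70,
                           min_occupancy = 0) {
  top <- traj$topology
  ia <- group_indices(top, groupA); ib <- group_indices(top, groupB)
  has_h <- any(top$atoms$element == "H")
  dA <- hb_atoms(top, ia, "donors"); aA <- hb_atoms(top, ia, "acceptors")
  dB <- hb_atoms(top, ib, "donors"); aB <- hb_atoms(top, ib, "acceptors")
  t1 <- typed_occupancy(traj, dA, aB, d_max, "hbond", stable_threshold,
                        min_occupancy)
  t2 <- typed_occupancy(traj, aA, dB, d_max, "hbond", stable_threshold,
                        min_occupancy)
  nfr <- attr(t1, "n_frames")
  tab <- rbind(t1, t2)
  # same residue pair reachable via both directions: keep max occupancy
  if (nrow(tab)) {
    key <- paste(tab$chainA, tab$resnoA, tab$chainB, tab$resnoB)
    tab <- tab[order(key, -tab$occupancy), ]
    tab <- tab[!duplicated(paste(tab$chainA, tab$resnoA, tab$chainB, tab$resnoB)), ]
    rownames(tab) <- NULL
  }
  attr(tab, "n_frames") <- nfr
  attr(tab, "criterion") <- if (has_h)
    sprintf("D-A <= %.2f A and D-H...A >= %.0f deg", d_max, angle_min)
  else sprintf("heavy-atom D-A <= %.2f A (no hydrogens present)", d_max)
  class(tab) <- c("interaction_table", "data.frame")
  tab
}

# charged-group atoms for salt bridges
SB_ANIONS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
SB_CATIONS <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"),
                   HIS = c("ND1", "NE2"))

sb_atoms <- function(model, idx, tpl, his_protonated = FALSE) {
  a <- model$atoms[idx, , drop = FALSE]
  keep <- rep(FALSE, nrow(a))
  for (rn in names(tpl)) {
    if (rn == "HIS" && !his_protonated) next
    keep <- keep | (a$resname == rn & a$atom %in% tpl[[rn]])
  }
  idx[keep]
}

#' Salt-bridge occupancies between two groups
#'
#' A bridge is present in a frame iff any anionic carboxylate oxygen
#' (Asp/Glu) of one residue lies within `d_max` of any cationic nitrogen
#' (Lys NZ, Arg NH/NE, optionally protonated His ring N) of the other.
#'
#' @param traj an `md_trajectory`.
#' @param groupA,groupB the two sides.
#' @param d_max N-O distance cutoff (default 4.0 A).
#' @param his_protonated treat His ring nitrogens as cationic (default FALSE).
#' @param stable_threshold stable flag threshold (default 0.70).
#' @param min_occupancy drop pairs at or below this occupancy (default 0).
#' @return An `interaction_table` (type `"saltbridge"`).
#' @export
salt_bridges <- function(traj, groupA, groupB, d_max = 4.0,
                         his_protonated = FALSE, stable_threshold = 0.70,
                         min_occupancy = 0) {
  top <- traj$topology
  ia <- group_indices(top, groupA); ib <- group_indices(top, groupB)
  anA <- sb_atoms(top, ia, SB_ANIONS); catA <- sb_atoms(top, ia, SB_CATIONS, his_protonated)
  anB <- sb_atoms(top, ib, SB_ANIONS); catB <- sb_atoms(top, ib, SB_CATIONS, his_protonated)
  t1 <- typed_occupancy(traj, anA, catB, d_max, "saltbridge",
                        stable_threshold, min_occupancy)
  t2 <- typed_occupancy(traj, catA, anB, d_max, "saltbridge",
                        stable_threshold, min_occupancy)
  nfr <- attr(t1, "n_frames")
  tab <- rbind(t1, t2)
  if (nrow(tab)) {
    tab <- tab[order(-tab$occupancy), ]
    tab <- tab[!duplicated(paste(tab$chainA, tab$resnoA, tab$chainB, tab$resnoB)), ]
    rownames(tab) <- NULL
  }
  attr(tab, "n_frames") <- nfr
  attr(tab, "criterion") <- sprintf("anion O - cation N <= %.2f A", d_max)
  class(tab) <- c("interaction_table", "data.frame")
  tab
}

APOLAR_RESIDUES <- c("ALA", "VAL", "LEU", "ILE", "PHE", "MET", "PRO", "TRP")
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

apolar_atoms <- function(model, idx) {
  a <- model$atoms[idx, , drop = FALSE]
  keep <- a$element == "C" & a$resname %in% APOLAR_RESIDUES &
    !(a$atom %in% BACKBONE_ATOMS)
  idx[keep]
}

#' Hydrophobic-contact occupancies between two groups
#'
#' Apolar side-chain carbon to apolar side-chain carbon within the cutoff,
#' for residues of the hydrophobic set (Ala, Val, Leu, Ile, Phe, Met, Pro,
#' Trp).
#'
#' @inheritParams salt_bridges
#' @param cutoff carbon-carbon cutoff (default 4.5 A).
#' @return An `interaction_table` (type `"hydrophobic"`).
#' @export
hydrophobic_contacts <- function(traj, groupA, groupB, cutoff = 4.5,
                                 stable_threshold = 0.70, min_occupancy = 0) {
  top <- traj$topology
  ia <- apolar_atoms(top, group_indices(top, groupA))
  ib <- apolar_atoms(top, group_indices(top, groupB))
  typed_occupancy(traj, ia, ib, cutoff, "hydrophobic", stable_threshold,
                  min_occupancy)
}

#' Combined typed interface interaction table
#'
#' Runs hydrogen-bond, salt-bridge and hydrophobic-contact detection between
#' two groups and stacks the results; each residue pair is reported once per
#' interaction type with its occupancy.
#'
#' @param traj an `md_trajectory`.
#' @param groupA,groupB the two sides.
#' @param hb_d_max hydrogen-bond cutoff (default 3.5 A).
#' @param sb_d_max salt-bridge cutoff (default 4.0 A).
#' @param hp_cutoff hydrophobic cutoff (default 4.5 A).
#' @param stable_threshold stable flag threshold (default 0.70).
#' @param min_occupancy drop pairs at or below this occupancy (default 0).
#' @return An `interaction_table` with mixed types.
#' @export
classify_interface <- function(traj, groupA, groupB, hb_d_max = 3.5,
                               sb_d_max = 4.0, hp_cutoff = 4.5,
                               stable_threshold = 0.70, min_occupancy = 0) {
  hb <- hydrogen_bonds(traj, groupA, groupB, d_max = hb_d_max,
                       stable_threshold = stable_threshold,
                       min_occupancy = min_occupancy)
  sb <- salt_bridges(traj, groupA, groupB, d_max = sb_d_max,
                     stable_threshold = stable_threshold,
                     min_occupancy = min_occupancy)
  hp <- hydrophobic_contacts(traj, groupA, groupB, cutoff = hp_cutoff,
                             stable_threshold = stable_threshold,
                             min_occupancy = min_occupancy)
  tab <- rbind(as.data.frame(hb), as.data.frame(sb), as.data.frame(hp))
  rownames(tab) <- NULL
  attr(tab, "n_frames") <- attr(hb, "n_frames")
  class(tab) <- c("interaction_table", "data.frame")
  tab
}

#' @export
print.interaction_table <- function(x, ...) {
  cat("interaction_table:", nrow(x), "records over",
      attr(x, "n_frames"), "frames\n")
  if (nrow(x)) print.data.frame(utils::head(x[order(-x$occupancy), ], 10))
  invisible(x)
}

#' Write an interaction table as TSV
#' @param x an `interaction_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an interface-area series as TSV (`frame<TAB>area_A2`)
#' @param x an `interface_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interface <- function(x, path) {
  utils::write.table(data.frame(frame = x$frames, area_A2 = x$area), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
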