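# Synthetic two-chain complexes and stochastic trajectories with planted,
# fully known statistical structure: block-wise collective motion modes, a
# low-frequency approaching/departing interface mode, residue-pair
# interaction schedules hit exactly (occupancy = k/F), and community
# structure in the contact graph.

SYN_D_ON <- c(saltbridge = 3.3, hbond = 2.9, hydrophobic = 4.0, contact = 3.8)

SB_ANION_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
SB_CATION_ATOMS <- list(LYS = "NZ", ARG = c("NH1", "NH2"), HIS = "ND1")
HB_DONOR_ATOMS <- list(TYR = "OH", SER = "OG", THR = "OG1", LYS = "NZ",
                       ARG = "NE", TRP = "NE1")
HP_ATOMS <- c("CG", "CG1", "CG2", "CD1")
CT_ATOMS <- c("CB", "XB", "XC", "XD")

syn_element <- function(atom) {
  c(O = "O", N = "N", C = "C", S = "S", X = "C")[substr(atom, 1, 1)]
}

#' Specify a synthetic two-chain complex and trajectory
#'
#' The specification fixes everything the generator plants: chain/residue
#' layout and block (community) structure, per-block collective motion modes,
#' the low-frequency interface mode (approaching when `drift < 0`),
#' residue-pair interaction schedules with exact target occupancies, a hub
#' residue whose persistent contacts tie the interface together, and the
#' isotropic coordinate noise.
#'
#' @param chains named list (chain id -> data.frame with columns `resno`,
#'   `resname`, `block`); each chain needs at least 3 residues.
#' @param block_centers named list (block -> length-3 numeric center, A).
#' @param modes list of planted collective modes: each a list with `ids`
#'   (residue ids "chain:resno") or `block` (block name), `sd` (amplitude
#'   standard deviation, A), and optional `dir` (3-vector; seeded random
#'   direction when omitted).
#' @param schedules data.frame with columns `resA`, `resB` (residue ids),
#'   `type` (`saltbridge`, `hbond`, `hydrophobic`, `contact`) and
#'   `occupancy`; every occupancy must equal k/frames exactly.
#' @param hub optional list(`id`, `partners`, `occupancy`): persistent
#'   contact schedules from one hub residue to its partners.
#' @param interface list(`drift`, `sd`): rigid displacement of the first
#'   chain along the interface normal (y); `drift` is the total drift over
#'   the run (negative = approaching), `sd` the random amplitude.
#' @param noise_sd per-axis Gaussian coordinate noise (A), applied rigidly
#'   per residue.
#' @param frames number of frames F.
#' @param seed RNG seed; (spec, seed) reproduces trajectories bit-for-bit.
#' @param spacing lattice spacing of residues within a block (default 3.0 A,
#'   making intra-block contacts dense at the 4.5 A cutoff).
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(chains, block_centers, modes = list(),
                           schedules = NULL, hub = NULL,
                           interface = list(drift = 0, sd = 0),
                           noise_sd = 0, frames = 100L, seed = 1L,
                           spacing = 3.0) {
  stopifnot(is.list(chains), length(chains) >= 1L)
  for (cn in names(chains)) {
    df <- chains[[cn]]
    if (!all(c("resno", "resname", "block") %in% names(df)))
      stop("chain table needs columns resno, resname, block")
    if (nrow(df) < 3L) stop("chain ", cn, " has fewer than 3 residues")
    if (anyDuplicated(df$resno)) stop("duplicate resno in chain ", cn)
  }
  blocks <- unique(unlist(lapply(chains, function(d) d$block)))
  miss <- setdiff(blocks, names(block_centers))
  if (length(miss)) stop("no center for block(s): ", paste(miss, collapse = ", "))
  if (is.null(schedules))
    schedules <- data.frame(resA = character(0), resB = character(0),
                            type = character(0), occupancy = numeric(0))
  if (!is.null(hub) && length(hub$partners) && hub$occupancy > 0) {
    schedules <- rbind(schedules,
                       data.frame(resA = hub$partners, resB = hub$id,
                                  type = "contact", occupancy = hub$occupancy))
  }
  frames <- as.integer(frames)
  if (nrow(schedules)) {
    k <- schedules$occupancy * frames
    bad <- abs(k - round(k)) > 1e-9
    if (any(bad))
      stop("occupancy ", schedules$occupancy[which(bad)[1]],
           " is not representable as k/", frames, " frames")
    if (any(schedules$occupancy < 0 | schedules$occupancy > 1))
      stop("occupancies must lie in [0, 1]")
  }
  structure(list(chains = chains, block_centers = block_centers,
                 modes = modes, schedules = schedules, hub = hub,
                 interface = interface, noise_sd = noise_sd,
                 frames = frames, seed = as.integer(seed), spacing = spacing),
            class = "synthetic_spec")
}

# residue table across chains with block and id columns
syn_residues <- function(spec) {
  do.call(rbind, lapply(names(spec$chains), function(cn) {
    d <- spec$chains[[cn]]
    data.frame(chain = cn, resno = d$resno, resname = d$resname,
               block = d$block, id = paste0(cn, ":", d$resno),
               stringsAsFactors = FALSE)
  }))
}

# deterministic lattice slots around a block center, interface-facing first
# (chains are stacked along y; "facing" means toward y = 0)
block_slots <- function(center, n, spacing, face_dir) {
  g <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1)) * spacing
  if (n > nrow(g)) stop("block larger than ", nrow(g), " residues")
  ord <- order(round(g[, 2] * face_dir, 6), rowSums(g^2), g[, 1], g[, 3])
  sweep(g[ord[seq_len(n)], , drop = FALSE], 2, center, "+")
}

pick_atom <- function(pool, used) {
  free <- setdiff(pool, used)
  if (!length(free))
    stop("no free anchor atom left in pool: ", paste(pool, collapse = ","))
  free[1]
}

# resolve anchor atom names/charges for every schedule row
anchor_table <- function(spec, res) {
  sch <- spec$schedules
  if (!nrow(sch)) return(NULL)
  used <- list()
  rows <- list()
  resname_of <- function(id) res$resname[match(id, res$id)]
  take <- function(id, pool) {
    a <- pick_atom(pool, used[[id]])
    used[[id]] <<- c(used[[id]], a)
    a
  }
  for (s in seq_len(nrow(sch))) {
    ty <- sch$type[s]
    idA <- sch$resA[s]; idB <- sch$resB[s]
    rnA <- resname_of(idA); rnB <- resname_of(idB)
    if (any(is.na(c(rnA, rnB))))
      stop("schedule references unknown residue: ", idA, " / ", idB)
    if (ty == "saltbridge") {
      if (rnA %in% names(SB_ANION_ATOMS) && rnB %in% names(SB_CATION_ATOMS)) {
        aA <- take(idA, SB_ANION_ATOMS[[rnA]]); qA <- -1
        aB <- take(idB, SB_CATION_ATOMS[[rnB]]); qB <- +1
      } else if (rnB %in% names(SB_ANION_ATOMS) && rnA %in% names(SB_CATION_ATOMS)) {
        aA <- take(idA, SB_CATION_ATOMS[[rnA]]); qA <- +1
        aB <- take(idB, SB_ANION_ATOMS[[rnB]]); qB <- -1
      } else stop("salt-bridge schedule needs one acidic and one basic residue: ",
                  rnA, "-", rnB)
    } else if (ty == "hbond") {
      if (rnA %in% names(HB_DONOR_ATOMS)) {
        aA <- take(idA, HB_DONOR_ATOMS[[rnA]]); aB <- take(idB, "O")
      } else if (rnB %in% names(HB_DONOR_ATOMS)) {
        aA <- take(idA, "O"); aB <- take(idB, HB_DONOR_ATOMS[[rnB]])
      } else stop("hydrogen-bond schedule needs a donor-capable residue: ",
                  rnA, "-", rnB)
      qA <- qB <- 0
    } else if (ty == "hydrophobic") {
      if (!all(c(rnA, rnB) %in% APOLAR_RESIDUES))
        stop("hydrophobic schedule needs apolar residues: ", rnA, "-", rnB)
      aA <- take(idA, HP_ATOMS); aB <- take(idB, HP_ATOMS)
      qA <- qB <- 0
    } else if (ty == "contact") {
      aA <- take(idA, CT_ATOMS); aB <- take(idB, CT_ATOMS)
      qA <- qB <- 0
    } else stop("unknown schedule type '", ty, "'")
    rows[[s]] <- data.frame(schedule = s, idA = idA, idB = idB,
                            atomA = aA, atomB = aB, qA = qA, qB = qB,
                            d_on = SYN_D_ON[[ty]], type = ty,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Build the synthetic two-chain complex
#'
#' Places each block's residues (C-alpha beads) on a compact lattice blob at
#' its center. Residue pairs joined by a cross-chain schedule are aligned on
#' matched interface-facing lattice sites (so their interaction axis is the
#' interface normal and distinct scheduled pairs stay well separated), and
#' the typed side-chain pseudo-atoms (carboxylate O / amine N / hydroxyl O /
#' apolar C) each schedule needs are created with charges, Bondi-type radii
#' and Lennard-Jones parameters attached. Deterministic given the spec.
#'
#' @param spec a `synthetic_spec`.
#' @return An `md_structure` with force-field parameters filled in.
#' @export
make_complex <- function(spec) {
  res <- syn_residues(spec)
  anch <- anchor_table(spec, res)
  sched_ids <- unique(c(anch$idA, anch$idB))
  chain_sign <- stats::setNames(
    ifelse(seq_along(spec$chains) == 1L, +1, -1), names(spec$chains))
  sp <- spec$spacing
  ca_pos <- matrix(NA_real_, nrow(res), 3)
  placed <- rep(FALSE, nrow(res))
  # facing-layer (x, z) sites, corners first so distinct pairs stay apart
  site_order <- lapply(list(c(-1, -1), c(1, 1), c(-1, 1), c(1, -1), c(0, 0),
                            c(-1, 0), c(1, 0), c(0, -1), c(0, 1)),
                       function(s) s * sp)
  used_sites <- list()
  block_size <- table(res$block)
  if (!is.null(anch)) for (s in seq_len(nrow(anch))) {
    iA <- match(anch$idA[s], res$id); iB <- match(anch$idB[s], res$id)
    if (res$chain[iA] == res$chain[iB] || placed[iA] || placed[iB]) next
    bA <- res$block[iA]; bB <- res$block[iB]
    if (block_size[[bA]] < 2L || block_size[[bB]] < 2L) next
    for (site in site_order) {
      key <- paste(site, collapse = ":")
      if (key %in% used_sites[[bA]] || key %in% used_sites[[bB]]) next
      fA <- chain_sign[[res$chain[iA]]]; fB <- chain_sign[[res$chain[iB]]]
      ca_pos[iA, ] <- spec$block_centers[[bA]] + c(site[1], -fA * sp, site[2])
      ca_pos[iB, ] <- spec$block_centers[[bB]] + c(site[1], -fB * sp, site[2])
      used_sites[[bA]] <- c(used_sites[[bA]], key)
      used_sites[[bB]] <- c(used_sites[[bB]], key)
      placed[c(iA, iB)] <- TRUE
      break
    }
  }
  for (b in unique(res$block)) {
    ridx <- which(res$block == b)
    todo <- ridx[!placed[ridx]]
    if (!length(todo)) next
    face <- chain_sign[[res$chain[ridx[1]]]]   # face toward y = 0
    if (length(ridx) == 1L) {
      ca_pos[todo, ] <- spec$block_centers[[b]]
      next
    }
    slots <- block_slots(spec$block_centers[[b]], 27L, sp, face)
    taken <- ca_pos[ridx[placed[ridx]], , drop = FALSE]
    if (nrow(taken))
      slots <- slots[!apply(slots, 1, function(p)
        any(colSums(abs(t(taken) - p)) < 1e-6)), , drop = FALSE]
    pri <- order(!(res$id[todo] %in% sched_ids), res$resno[todo])
    ca_pos[todo[pri], ] <- slots[seq_along(todo), ]
  }
  rows <- list(); xyz <- list()
  for (i in seq_len(nrow(res))) {
    rows[[length(rows) + 1L]] <-
      data.frame(atom = "CA", element = "C", resname = res$resname[i],
                 resno = res$resno[i], chain = res$chain[i],
                 charge = 0, radius = DEFAULT_RADII[["C"]],
                 eps = 0.15, rmin_half = 1.7, stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1L]] <- ca_pos[i, ]
    if (!is.null(anch)) {
      for (s in which(anch$idA == res$id[i] | anch$idB == res$id[i])) {
        onA <- anch$idA[s] == res$id[i]
        nm <- if (onA) anch$atomA[s] else anch$atomB[s]
        q <- if (onA) anch$qA[s] else anch$qB[s]
        el <- syn_element(nm)
        rows[[length(rows) + 1L]] <-
          data.frame(atom = nm, element = el, resname = res$resname[i],
                     resno = res$resno[i], chain = res$chain[i],
                     charge = q, radius = DEFAULT_RADII[[el]],
                     eps = 0.05, rmin_half = 1.2, stringsAsFactors = FALSE)
        # home position: 1 A inward (away from the interface)
        xyz[[length(xyz) + 1L]] <-
          ca_pos[i, ] + c(0, chain_sign[[res$chain[i]]] * 1.0, 0)
      }
    }
  }
  md_structure(do.call(rbind, rows), do.call(rbind, xyz))
}

#' Simulate a trajectory with planted statistical structure
#'
#' Frames are mean coordinates plus planted collective modes with Gaussian
#' amplitudes, the interface drift/fluctuation mode (rigid displacement of
#' the first chain along y), and per-residue isotropic Gaussian noise.
#' Scheduled interaction pseudo-atoms are then overridden frame-by-frame: on
#' a seeded random subset of exactly k = occupancy x F frames the pair is
#' placed at its interaction distance, otherwise both anchors sit at their
#' inward home positions, so every planted occupancy is hit exactly.
#'
#' @param model the `md_structure` from [make_complex()].
#' @param spec the same `synthetic_spec`.
#' @return List with `trajectory` (an `md_trajectory`) and `truth` (class
#'   `planted_truth`): the planted occupancies, mode table, interface
#'   parameters, block membership, hub identity and noise level.
#' @export
simulate_trajectory <- function(model, spec) {
  res <- syn_residues(spec)
  anch <- anchor_table(spec, res)
  nfr <- spec$frames
  na <- nrow(model$atoms)
  atom_res <- residue_ids(model)
  res_of_atom <- match(atom_res, res$id)
  ca_idx <- which(model$atoms$atom == "CA")
  first_chain <- names(spec$chains)[1]
  set.seed(spec$seed)
  # 1. mode directions
  modes <- spec$modes
  for (m in seq_along(modes)) {
    if (is.null(modes[[m]]$dir)) {
      v <- stats::rnorm(3)
      modes[[m]]$dir <- v / sqrt(sum(v^2))
    }
    if (is.null(modes[[m]]$ids))
      modes[[m]]$ids <- res$id[res$block == modes[[m]]$block]
  }
  # 2. mode amplitudes
  amp <- if (length(modes))
    vapply(modes, function(m) stats::rnorm(nfr, 0, m$sd), numeric(nfr))
  else matrix(0, nfr, 0)
  if (length(modes) == 1L) amp <- matrix(amp, ncol = 1L)
  # 3. interface offsets
  tfrac <- if (nfr > 1L) (seq_len(nfr) - 1L) / (nfr - 1L) else 0
  gap0 <- spec$interface$drift * tfrac +
    stats::rnorm(nfr, 0, spec$interface$sd)
  # 4. residue-level noise
  noise <- array(stats::rnorm(nfr * nrow(res) * 3, 0, spec$noise_sd),
                 dim = c(nfr, nrow(res), 3))
  # 5. schedule frame sets
  on_frames <- list()
  if (!is.null(anch)) {
    for (s in seq_len(nrow(anch))) {
      k <- round(spec$schedules$occupancy[anch$schedule[s]] * nfr)
      on_frames[[s]] <- if (k > 0) sort(sample.int(nfr, k)) else integer(0)
    }
  }
  coords <- array(NA_real_, dim = c(nfr, na, 3))
  is_first <- model$atoms$chain == first_chain
  home_off <- outer(ifelse(is_first, 1, -1), c(0, 1, 0))
  ca_of_res <- ca_idx[match(res$id, atom_res[ca_idx])]
  for (f in seq_len(nfr)) {
    m <- model$xyz
    for (k in seq_along(modes)) {
      hit <- res_of_atom %in% which(res$id %in% modes[[k]]$ids)
      m[hit, ] <- m[hit, ] + rep(amp[f, k] * modes[[k]]$dir,
                                 each = sum(hit))
    }
    m[is_first, 2] <- m[is_first, 2] + gap0[f]
    m <- m + noise[f, res_of_atom, ]
    if (!is.null(anch)) {
      ai <- match(paste(anch$idA, anch$atomA), paste(atom_res, model$atoms$atom))
      bi <- match(paste(anch$idB, anch$atomB), paste(atom_res, model$atoms$atom))
      for (s in seq_len(nrow(anch))) {
        caA <- m[ca_of_res[match(anch$idA[s], res$id)], ]
        caB <- m[ca_of_res[match(anch$idB[s], res$id)], ]
        if (f %in% on_frames[[s]]) {
          mid <- (caA + caB) / 2
          u <- caB - caA
          u <- u / sqrt(sum(u^2))
          m[ai[s], ] <- mid - anch$d_on[s] / 2 * u
          m[bi[s], ] <- mid + anch$d_on[s] / 2 * u
        } else {
          m[ai[s], ] <- caA + home_off[ai[s], ]
          m[bi[s], ] <- caB + home_off[bi[s], ]
        }
      }
    }
    coords[f, , ] <- m
  }
  truth_sched <- spec$schedules
  if (nrow(truth_sched))
    truth_sched$n_on <- vapply(seq_len(nrow(truth_sched)), function(s) {
      rows <- which(anch$schedule == s)
      length(on_frames[[rows[1]]])
    }, 1L)
  mode_tab <- if (length(modes))
    data.frame(mode = seq_along(modes),
               sd = vapply(modes, function(m) m$sd, 1),
               n_residues = vapply(modes, function(m) length(m$ids), 1L))
  else data.frame(mode = integer(0), sd = numeric(0), n_residues = integer(0))
  truth <- structure(list(
    schedules = truth_sched,
    modes = mode_tab,
    mode_details = modes,
    interface = spec$interface,
    blocks = stats::setNames(res$block, res$id),
    hub = spec$hub,
    noise_sd = spec$noise_sd,
    frames = nfr,
    seed = spec$seed), class = "planted_truth")
  list(trajectory = md_trajectory(model, coords), truth = truth)
}

#' @export
print.planted_truth <- function(x, ...) {
  cat("planted_truth:", x$frames, "frames,", nrow(x$schedules),
      "schedules,", nrow(x$modes), "modes, noise_sd", x$noise_sd, "\n")
  invisible(x)
}

# scenario chain/block layout shared by both systems (monobody-like chain M
# against phosphatase-like chain P; residue labels follow the two-loop
# interface motif: acidic loop M1, aromatic loop M2, basic loops P1/P2, and
# a hub cysteine on P)
scenario_chains <- function() {
  m_res <- c(21:28, 79:86, 40:47)
  m_name <- rep("GLY", length(m_res))
  m_name[m_res == 27] <- "ASP"; m_name[m_res == 28] <- "ASP"
  m_name[m_res == 81] <- "PHE"; m_name[m_res == 82] <- "GLU"
  m_name[m_res == 85] <- "LEU"
  m_block <- rep(c("M1", "M2", "M3"), each = 8)
  p_res <- c(148:157, 233:242, 455:464)
  p_name <- rep("GLY", length(p_res))
  p_name[p_res == 151] <- "ARG"; p_name[p_res == 152] <- "TYR"
  p_name[p_res == 156] <- "ILE"
  p_name[p_res == 235] <- "ARG"; p_name[p_res == 237] <- "LYS"
  p_name[p_res == 239] <- "LYS"
  p_name[p_res == 459] <- "CYS"
  p_block <- rep(c("P1", "P2", "P3"), each = 10)
  p_block[p_res == 459] <- "HUB"   # hub floats free of the P3 blob
  list(M = data.frame(resno = m_res, resname = m_name, block = m_block),
       P = data.frame(resno = p_res, resname = p_name, block = p_block))
}

scenario_centers <- function(gap) {
  list(M1 = c(-12, gap / 2, 0), M2 = c(12, gap / 2, 0),
       M3 = c(0, gap / 2 + 9, 0),
       P2 = c(-12, -gap / 2, 0), P1 = c(12, -gap / 2, 0),
       P3 = c(24, -gap / 2, 0),
       HUB = c(18, -1.5, 0))
}

scenario_schedules <- function(occ) {
  data.frame(
    resA = c("M:81", "M:82", "M:27", "M:28", "M:85"),
    resB = c("P:152", "P:151", "P:237", "P:239", "P:156"),
    type = c("hbond", "saltbridge", "saltbridge", "saltbridge",
             "hydrophobic"),
    occupancy = occ, stringsAsFactors = FALSE)
}

#' Generate a matched wild-type-like / mutant-like dataset pair
#'
#' Two complete synthetic datasets sharing one chain/block layout and
#' differing only in the planted contrasts: the wt-like system has low
#' noise, several comparable collective modes, an approaching interface
#' drift, high scheduled polar/hydrophobic occupancies and an active hub
#' residue bridging the interface; the mutant-like system has larger noise,
#' one dominant large-amplitude mode, a departing drift, low occupancies and
#' no hub contacts.
#'
#' @param seed integer seed; the two systems use derived sub-seeds.
#' @param frames frames per system (default 500; all occupancies are exact
#'   multiples of 1/frames).
#' @return List with elements `wt` and `mut`, each a list
#'   (`spec`, `model`, `trajectory`, `truth`).
#' @export
make_scenario_pair <- function(seed = 1L, frames = 500L) {
  chains <- scenario_chains()
  build <- function(style, sub_seed) {
    wt <- style == "wt"
    occ <- if (wt) c(0.632, 0.778, 0.540, 0.360, 0.900)
           else     c(0.026, 0.034, 0.244, 0.094, 0.300)
    blocks <- c("M1", "M2", "M3", "P1", "P2", "P3")
    modes <- lapply(blocks, function(b)
      list(block = b, sd = if (wt) 0.5 else 0.35))
    if (!wt)
      modes <- c(modes, list(list(
        ids = paste0("M:", chains$M$resno), sd = 2.5, dir = c(1, 0, 0))))
    spec <- synthetic_spec(
      chains = chains,
      block_centers = scenario_centers(gap = if (wt) 13 else 15),
      modes = modes,
      schedules = scenario_schedules(occ),
      hub = list(id = "P:459",
                 partners = c("M:83", "M:84", "M:86"),
                 occupancy = if (wt) 1.0 else 0.0),
      interface = list(drift = if (wt) -1.0 else 1.0,
                       sd = if (wt) 0.4 else 0.6),
      noise_sd = if (wt) 0.25 else 0.5,
      frames = frames, seed = sub_seed)
    model <- make_complex(spec)
    sim <- simulate_trajectory(model, spec)
    list(spec = spec, model = model, trajectory = sim$trajectory,
         truth = sim$truth)
  }
  seed <- as.integer(seed)
  list(wt = build("wt", seed * 101L %% 1000003L),
       mut = build("mut", seed * 101L %% 1000003L + 1L))
}

#' Write a synthetic dataset to disk
#'
#' Emits the standard file set consumed by the pipeline: `complex.pdb`
#' (topology + frame-1 coordinates), `traj.pdb` (multi-model trajectory),
#' `params.txt` (force-field parameter table) and `truth.yaml` (planted
#' ground truth).
#'
#' @param dataset one element of [make_scenario_pair()]'s result (or any
#'   list with `model`, `trajectory`, `truth`).
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_scenario <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_structure(dataset$model, file.path(dir, "complex.pdb"))
  write_trajectory_pdb(dataset$trajectory, file.path(dir, "traj.pdb"))
  write_ff_params(dataset$model, file.path(dir, "params.txt"))
  tr <- dataset$truth
  yaml::write_yaml(list(
    frames = tr$frames, seed = tr$seed, noise_sd = tr$noise_sd,
    interface = tr$interface,
    hub = tr$hub,
    schedules = if (nrow(tr$schedules)) lapply(seq_len(nrow(tr$schedules)),
      function(i) as.list(tr$schedules[i, ])) else list(),
    blocks = as.list(tr$blocks)),
    file.path(dir, "truth.yaml"))
  invisible(dir)
}
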