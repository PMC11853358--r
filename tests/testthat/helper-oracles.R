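# Independent oracles and small fixture builders shared across tests.

# Horn quaternion superposition: optimal RMSD via the maximum eigenvalue of
# the 4x4 key matrix -- an algebraic route independent of the SVD path.
quaternion_rmsd <- function(mobile, reference) {
  n <- nrow(mobile)
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  M <- crossprod(P, Q)   # sum over atoms of p_i q_j
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(P^2) + sum(Q^2) - 2 * lam) / n
  sqrt(max(msd, 0))
}

# ---- exhaustive betweenness on tiny weighted graphs ------------------------

# all simple paths between s and t (node indices), DFS
all_simple_paths_idx <- function(adj, s, t) {
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (w in which(adj[v, ] > 0)) {
      if (!(w %in% path)) walk(c(path, w))
    }
  }
  walk(s)
  paths
}

path_len <- function(W, path) {
  if (length(path) < 2) return(0)
  sum(W[cbind(path[-length(path)], path[-1])])
}

# node and edge betweenness by enumerating all shortest paths over all
# unordered node pairs; ties split equally (matches the Brandes convention)
brute_betweenness <- function(n, edges) {
  # edges: data.frame(i, j, w) with 1-based node indices
  W <- matrix(0, n, n)
  for (k in seq_len(nrow(edges))) {
    W[edges$i[k], edges$j[k]] <- edges$w[k]
    W[edges$j[k], edges$i[k]] <- edges$w[k]
  }
  node_b <- numeric(n)
  edge_b <- numeric(nrow(edges))
  ekey <- paste(pmin(edges$i, edges$j), pmax(edges$i, edges$j))
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    paths <- all_simple_paths_idx(W > 0, s, t)
    if (!length(paths)) next
    lens <- vapply(paths, function(p) path_len(W, p), 1)
    short <- paths[abs(lens - min(lens)) < 1e-9]
    ns <- length(short)
    for (p in short) {
      inner <- setdiff(p, c(s, t))
      node_b[inner] <- node_b[inner] + 1 / ns
      if (length(p) > 1) {
        pe <- paste(pmin(p[-length(p)], p[-1]), pmax(p[-length(p)], p[-1]))
        hit <- match(pe, ekey)
        edge_b[hit] <- edge_b[hit] + 1 / ns
      }
    }
  }
  list(node = node_b, edge = edge_b)
}

# random connected weighted graph on n nodes
random_connected_graph <- function(n, p = 0.5) {
  repeat {
    adj <- matrix(stats::runif(n * n) < p, n, n)
    adj[lower.tri(adj, diag = TRUE)] <- FALSE
    # ensure spanning connectivity via a random tree backbone
    perm <- sample(n)
    for (k in 2:n) {
      a <- perm[k]; b <- perm[sample(k - 1, 1)]
      adj[min(a, b), max(a, b)] <- TRUE
    }
    idx <- which(adj, arr.ind = TRUE)
    return(data.frame(i = idx[, 1], j = idx[, 2],
                      w = round(stats::runif(nrow(idx), 0.2, 2), 3)))
  }
}

# ---- exhaustive modularity maximization ------------------------------------

# all set partitions of 1..n as membership vectors (restricted growth)
all_partitions <- function(n) {
  out <- list()
  grow <- function(mem, mx) {
    k <- length(mem) + 1L
    if (k > n) {
      out[[length(out) + 1L]] <<- mem
      return(invisible())
    }
    for (c in seq_len(mx + 1L)) grow(c(mem, c), max(mx, c))
  }
  grow(integer(0), 0L)
  out
}

# Newman-Girvan modularity written out from first principles
brute_modularity <- function(edges_ij, membership) {
  m <- nrow(edges_ij)
  inside <- sum(membership[edges_ij$i] == membership[edges_ij$j]) / m
  deg <- tabulate(c(edges_ij$i, edges_ij$j))
  expect <- 0
  for (c in unique(membership)) {
    dc <- sum(deg[which(membership == c)])
    expect <- expect + (dc / (2 * m))^2
  }
  inside - expect
}

best_partition_bruteforce <- function(n, edges_ij) {
  best_q <- -Inf
  best <- NULL
  for (mem in all_partitions(n)) {
    q <- brute_modularity(edges_ij, mem)
    if (q > best_q + 1e-12) {
      best_q <- q
      best <- mem
    }
  }
  list(membership = best, modularity = best_q)
}

# two 4-cliques joined by one bridge edge (nodes 1-4 and 5-8, bridge 4-5)
two_clique_edges <- function() {
  e <- rbind(t(utils::combn(1:4, 2)), t(utils::combn(5:8, 2)), c(4, 5))
  data.frame(i = e[, 1], j = e[, 2])
}

# residue_graph from a plain (i, j) edge table with uniform |C|
graph_from_edges <- function(n, edges_ij, absC = 0.5) {
  nodes <- data.frame(id = paste0("A:", 1:n), chain = "A", resno = 1:n)
  edges <- data.frame(from = paste0("A:", edges_ij$i),
                      to = paste0("A:", edges_ij$j),
                      absC = absC, persistence = 1)
  residue_graph(nodes, edges)
}

# ---- geometry oracle -------------------------------------------------------

# analytic buried SASA when two solvent-expanded spheres of radii R1, R2
# intersect at center distance d: spherical-cap areas on each sphere
two_sphere_buried <- function(R1, R2, d) {
  if (d >= R1 + R2) return(c(0, 0))
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  c(2 * pi * R1 * h1, 2 * pi * R2 * h2)
}

# ---- tiny fixture builders -------------------------------------------------

# bead structure: one CA per residue at given coordinates
bead_structure <- function(xyz, chain = "A", resno = NULL, resname = "GLY",
                           charge = 0, eps = 0.15, rmin_half = 1.7,
                           atom = "CA", element = "C", radius = 1.7) {
  n <- nrow(xyz)
  if (is.null(resno)) resno <- seq_len(n)
  md_structure(data.frame(atom = rep_len(atom, n),
                          element = rep_len(element, n),
                          resname = rep_len(resname, n),
                          resno = resno, chain = rep_len(chain, n),
                          charge = rep_len(charge, n),
                          radius = rep_len(radius, n),
                          eps = rep_len(eps, n),
                          rmin_half = rep_len(rmin_half, n)), xyz)
}

# trajectory from a list of N x 3 frames
traj_from_frames <- function(model, frames) {
  co <- array(NA_real_, dim = c(length(frames), nrow(model$atoms), 3))
  for (f in seq_along(frames)) co[f, , ] <- frames[[f]]
  md_trajectory(model, co)
}

# small planted-correlation spec: two chains of 3 beads, one shared mode on
# residues M:1 and P:11 giving an analytic correlation rho = Va/(Va+3s^2)
rho_spec <- function(rho, noise_sd = 0.25, frames = 5000L, seed = 1L) {
  va <- 3 * noise_sd^2 * rho / (1 - rho)
  synthetic_spec(
    chains = list(
      M = data.frame(resno = 1:3, resname = "GLY", block = "A"),
      P = data.frame(resno = 11:13, resname = "GLY", block = "B")),
    block_centers = list(A = c(0, 10, 0), B = c(0, -10, 0)),
    modes = list(list(ids = c("M:1", "P:11"), sd = sqrt(va),
                      dir = c(1, 0, 0))),
    noise_sd = noise_sd, frames = frames, seed = seed)
}

# two orthogonal planted modes with variances 4 and 1 on disjoint residues
two_mode_spec <- function(frames = 5000L, seed = 1L) {
  synthetic_spec(
    chains = list(
      M = data.frame(resno = 1:4, resname = "GLY", block = "A"),
      P = data.frame(resno = 11:14, resname = "GLY", block = "B")),
    block_centers = list(A = c(0, 10, 0), B = c(0, -10, 0)),
    modes = list(list(block = "A", sd = 2, dir = c(1, 0, 0)),
                 list(block = "B", sd = 1, dir = c(0, 0, 1))),
    noise_sd = 0, frames = frames, seed = seed)
}

# two dense 6-residue blocks bridged by a single persistent contact
two_block_spec <- function(seed, frames = 2000L) {
  synthetic_spec(
    chains = list(
      M = data.frame(resno = 1:6, resname = "GLY", block = "A"),
      P = data.frame(resno = 11:16, resname = "GLY", block = "B")),
    block_centers = list(A = c(0, 6.5, 0), B = c(0, -6.5, 0)),
    modes = list(list(block = "A", sd = 1, dir = NULL),
                 list(block = "B", sd = 1, dir = NULL)),
    schedules = data.frame(resA = "M:1", resB = "P:11", type = "contact",
                           occupancy = 1),
    noise_sd = 0.2, frames = frames, seed = seed)
}

# minimal hand-written PDB text lines for ATOM records
pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          occ = 1, alt = " ", element = NULL) {
  if (is.null(element)) element <- substr(trimws(name), 1, 1)
  sprintf("ATOM  %5d %-4s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, resname, chain, resno, x, y, z, occ, 0, element)
}
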