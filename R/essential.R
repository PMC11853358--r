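# Essential dynamics: Cartesian PCA, subspace comparison, free-energy
# landscapes and representative conformations.

# Boltzmann constant, kcal mol^-1 K^-1
KB_KCAL <- 0.0019872041

# gather superposed analysis frames of one or more trajectories into an
# F x 3N matrix (flattened x1 y1 z1 x2 ...)
pooled_frames <- function(trajs, selection, reference = NULL, fit = TRUE) {
  if (inherits(trajs, "md_trajectory")) trajs <- list(trajs)
  sels <- lapply(trajs, resolve_selection, selection = selection)
  n <- length(sels[[1]])
  if (any(vapply(sels, length, 1L) != n))
    stop("inconsistent atom counts across trajectories: ",
         paste(vapply(sels, length, 1L), collapse = ", "))
  if (is.null(reference))
    reference <- frame_xyz(trajs[[1]], trajs[[1]]$start)[sels[[1]], , drop = FALSE]
  rows <- list()
  for (t in seq_along(trajs)) {
    traj <- trajs[[t]]; sel <- sels[[t]]
    for (f in analysis_frames(traj)) {
      m <- frame_xyz(traj, f)[sel, , drop = FALSE]
      if (fit && n >= 3L) m <- apply_superposition(m, superpose(m, reference))
      rows[[length(rows) + 1L]] <- as.vector(t(m))
    }
  }
  list(X = do.call(rbind, rows), reference = reference,
       labels = residue_ids(trajs[[1]]$topology, sels[[1]]), n = n)
}

# sign convention: each eigenvector's largest-|loading| element positive
fix_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' Fit an essential-dynamics (Cartesian PCA) model
#'
#' Eigen-decomposition of the 3N x 3N covariance matrix of the pooled,
#' superposed analysis frames of one or more trajectories. Supplying both
#' systems' trajectories yields a shared PCA space in which their
#' conformational distributions are directly comparable.
#'
#' @param trajs an `md_trajectory` or a list of them (pooled).
#' @param selection atom indices or selection expression (default `"ca"`);
#'   must resolve to the same atom count in every trajectory.
#' @param reference N x 3 matrix used as the common fit reference; defaults
#'   to the first trajectory's first analysis frame.
#' @param fit superpose each frame onto the reference (disable only for
#'   ensembles generated without global rigid-body motion).
#' @return Object of class `essential_model`: `mean` (N x 3), `vectors`
#'   (3N x m orthonormal columns, sign-fixed so the largest-magnitude loading
#'   is positive), `values` (variances, A^2, descending), `labels`,
#'   `reference`, `fit`.
#' @export
fit_pca <- function(trajs, selection = "ca", reference = NULL, fit = TRUE) {
  p <- pooled_frames(trajs, selection, reference, fit)
  X <- p$X
  nf <- nrow(X)
  if (nf < 2L) stop("PCA needs at least 2 frames")
  if (nf <= 3L * p$n)
    warning("frame count (", nf, ") not greater than 3N (", 3L * p$n,
            "); covariance is rank-deficient")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  s <- svd(Xc, nu = 0)
  values <- s$d^2 / (nf - 1)
  keep <- seq_len(min(nf - 1L, ncol(Xc)))
  structure(list(mean = matrix(mu, ncol = 3L, byrow = TRUE),
                 vectors = fix_signs(s$v[, keep, drop = FALSE]),
                 values = values[keep],
                 labels = p$labels,
                 reference = p$reference,
                 fit = fit),
            class = "essential_model")
}

#' @export
print.essential_model <- function(x, ...) {
  fr <- variance_fractions(x)
  cat("essential_model:", nrow(x$mean), "atoms,", length(x$values),
      "components\n")
  cat(sprintf("  PC1 %.1f%%, PC2 %.1f%% of variance\n",
              100 * fr[1], 100 * if (length(fr) > 1) fr[2] else 0))
  invisible(x)
}

#' Variance fraction captured by each principal component
#'
#' @param model an `essential_model`.
#' @return Numeric vector summing to 1 (fraction_i = lambda_i / sum lambda).
#' @export
variance_fractions <- function(model) {
  tot <- sum(model$values)
  if (tot <= 0) stop("all eigenvalues are zero; no variance to apportion")
  model$values / tot
}

#' Project trajectory frames onto principal components
#'
#' Each analysis frame is superposed onto the model's fit reference (if the
#' model was fitted with `fit = TRUE`) and scored as
#' (frame - mean) . eigenvector.
#'
#' @param model an `essential_model`.
#' @param traj an `md_trajectory` whose selection matches the model.
#' @param selection atom selection (default `"ca"`); must resolve to the
#'   model's atom count.
#' @param components component indices to score (default 1:2).
#' @return Matrix (frames x components, Angstrom) of class
#'   `pca_projection`, with attribute `components`.
#' @export
project_frames <- function(model, traj, selection = "ca", components = 1:2) {
  sel <- resolve_selection(traj, selection)
  if (length(sel) != nrow(model$mean))
    stop("selection resolves to ", length(sel), " atoms; model has ",
         nrow(model$mean))
  if (max(components) > ncol(model$vectors))
    stop("component index out of range")
  mu <- as.vector(t(model$mean))
  frames <- analysis_frames(traj)
  out <- matrix(NA_real_, length(frames), length(components))
  for (k in seq_along(frames)) {
    m <- frame_xyz(traj, frames[k])[sel, , drop = FALSE]
    if (model$fit && nrow(m) >= 3L)
      m <- apply_superposition(m, superpose(m, model$reference))
    out[k, ] <- (as.vector(t(m)) - mu) %*%
      model$vectors[, components, drop = FALSE]
  }
  colnames(out) <- paste0("PC", components)
  structure(out, components = components, frames = frames,
            class = c("pca_projection", "matrix", "array"))
}

#' Root mean square inner product between two essential subspaces
#'
#' RMSIP = sqrt( (1/k) sum_i sum_j (v_i^A . v_j^B)^2 ) over the first k
#' components of each model; 1 for identical subspaces, 0 for orthogonal.
#'
#' @param modelA,modelB `essential_model`s over the same selection dimension.
#' @param k number of leading components (default 10).
#' @return RMSIP in \[0, 1\].
#' @export
rmsip <- function(modelA, modelB, k = 10L) {
  O <- overlap_matrix(modelA, modelB, k)
  sqrt(sum(O) / k)
}

#' Overlap matrix of two essential subspaces
#'
#' @param modelA,modelB `essential_model`s over the same selection dimension.
#' @param k number of leading components.
#' @return k x k matrix of squared inner products (v_i^A . v_j^B)^2.
#' @export
overlap_matrix <- function(modelA, modelB, k = 10L) {
  if (nrow(modelA$vectors) != nrow(modelB$vectors))
    stop("models have different coordinate dimensions: ",
         nrow(modelA$vectors), " vs ", nrow(modelB$vectors))
  if (ncol(modelA$vectors) < k || ncol(modelB$vectors) < k)
    stop("both models need at least k = ", k, " components")
  A <- modelA$vectors[, seq_len(k), drop = FALSE]
  B <- modelB$vectors[, seq_len(k), drop = FALSE]
  (crossprod(A, B))^2
}

#' Porcupine displacement vectors for one principal component
#'
#' Per-atom 3-vectors (scale x eigenvector slice) anchored on the model mean;
#' optionally written as a two-model PDB (mean, mean + displacement) for
#' rendering arrows in a molecular viewer.
#'
#' @param model an `essential_model`.
#' @param component component index (default 1).
#' @param scale multiplier applied to the eigenvector (default 10).
#' @param topology optional `md_structure` (selection-sized) used to write
#'   the PDB.
#' @param path optional output PDB path.
#' @return N x 3 matrix of displacement vectors (invisibly if written).
#' @export
porcupine <- function(model, component = 1L, scale = 10, topology = NULL,
                      path = NULL) {
  if (component > ncol(model$vectors)) stop("component index out of range")
  v <- matrix(model$vectors[, component], ncol = 3L, byrow = TRUE) * scale
  if (!is.null(path)) {
    if (is.null(topology)) stop("writing a porcupine PDB needs a topology")
    xyz <- array(NA_real_, dim = c(2L, nrow(v), 3L))
    xyz[1, , ] <- model$mean
    xyz[2, , ] <- model$mean + v
    write_structure(topology, path, xyz = xyz)
    return(invisible(v))
  }
  v
}

#' Free-energy landscape over one or two reaction coordinates
#'
#' Bins per-frame reaction-coordinate values and converts populations to
#' relative free energies, G_i = -kB T ln(N_i / N_max), so the most populated
#' bin sits at exactly 0 kcal/mol. Empty bins are undefined (`NA`), not a
#' capped constant.
#'
#' @param coordA numeric per-frame values of the first coordinate.
#' @param coordB optional second coordinate (same length); omit for a 1-D
#'   landscape.
#' @param bins bin count per axis (scalar or length-2; default 100).
#' @param temperature simulation temperature in K (default 310).
#' @return Object of class `fel_grid`: bin mid-points (`midA`, `midB`), bin
#'   `breaks`, `counts`, free energies `G` (kcal/mol), `temperature`.
#' @export
fel <- function(coordA, coordB = NULL, bins = 100L, temperature = 310) {
  if (!length(coordA)) stop("empty reaction-coordinate input")
  two_d <- !is.null(coordB)
  if (two_d && length(coordB) != length(coordA))
    stop("reaction coordinates differ in length")
  bins <- rep(as.integer(bins), length.out = 2L)
  if (any(bins < 2L) && (two_d || bins[1] < 2L))
    stop("need at least 2 bins per axis")
  brA <- seq(min(coordA), max(coordA), length.out = bins[1] + 1L)
  if (brA[1] == brA[length(brA)]) brA <- brA[1] + c(-0.5, 0.5)
  iA <- findInterval(coordA, brA, rightmost.closed = TRUE, all.inside = TRUE)
  if (two_d) {
    brB <- seq(min(coordB), max(coordB), length.out = bins[2] + 1L)
    if (brB[1] == brB[length(brB)]) brB <- brB[1] + c(-0.5, 0.5)
    iB <- findInterval(coordB, brB, rightmost.closed = TRUE, all.inside = TRUE)
    counts <- matrix(0L, length(brA) - 1L, length(brB) - 1L)
    for (k in seq_along(iA)) counts[iA[k], iB[k]] <- counts[iA[k], iB[k]] + 1L
  } else {
    brB <- NULL
    counts <- matrix(tabulate(iA, nbins = length(brA) - 1L), ncol = 1L)
  }
  G <- -KB_KCAL * temperature * log(counts / max(counts))
  G[counts == 0L] <- NA_real_
  mid <- function(br) (br[-1] + br[-length(br)]) / 2
  structure(list(midA = mid(brA), midB = if (two_d) mid(brB),
                 breaks = list(A = brA, B = brB),
                 counts = counts, G = G, temperature = temperature),
            class = "fel_grid")
}

#' @export
print.fel_grid <- function(x, ...) {
  occ <- sum(x$counts > 0)
  cat(sprintf("fel_grid: %s bins, %d occupied, max G = %.3f kcal/mol (T = %g K)\n",
              paste(dim(x$counts), collapse = " x "), occ,
              max(x$G, na.rm = TRUE), x$temperature))
  invisible(x)
}

#' Write a free-energy landscape as long-format TSV
#'
#' Columns: `binA_center`, `binB_center` (NA for 1-D), `G_kcal_mol`, `count`.
#'
#' @param x a `fel_grid`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fel <- function(x, path) {
  idx <- expand.grid(a = seq_along(x$midA),
                     b = seq_len(ncol(x$counts)))
  tab <- data.frame(binA_center = x$midA[idx$a],
                    binB_center = if (is.null(x$midB)) NA_real_ else x$midB[idx$b],
                    G_kcal_mol = x$G[cbind(idx$a, idx$b)],
                    count = x$counts[cbind(idx$a, idx$b)])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Representative conformations by k-means in PC space
#'
#' Clusters the per-frame projections with k-means (multiple restarts,
#' seeded, hence deterministic), reports per-cluster occupancy and the medoid
#' frame (the analysis frame nearest each centroid). Clusters are ordered by
#' decreasing occupancy.
#'
#' @param proj a `pca_projection` (frames x components).
#' @param k cluster count (default 5).
#' @param seed RNG seed (default 1).
#' @param restarts random restarts passed to [stats::kmeans()] (default 50).
#' @return Object of class `cluster_summary`: `centers`, `occupancy`
#'   (percent, sums to 100), `medoid_frames` (original frame indices),
#'   `assignment`.
#' @export
kmeans_representatives <- function(proj, k = 5L, seed = 1L, restarts = 50L) {
  X <- unclass(proj)
  attr_frames <- attr(proj, "frames")
  if (is.null(attr_frames)) attr_frames <- seq_len(nrow(X))
  if (k > nrow(X)) stop("k = ", k, " exceeds the frame count ", nrow(X))
  set.seed(seed)
  km <- stats::kmeans(X, centers = k, nstart = restarts, iter.max = 100L)
  ord <- order(-km$size, km$centers[, 1])
  centers <- km$centers[ord, , drop = FALSE]
  sizes <- km$size[ord]
  remap <- match(km$cluster, ord)
  medoid <- integer(k)
  for (c in seq_len(k)) {
    d2 <- rowSums(sweep(X, 2, centers[c, ])^2)
    d2[remap != c] <- Inf
    medoid[c] <- attr_frames[which.min(d2)]
  }
  structure(list(centers = centers,
                 occupancy = 100 * sizes / nrow(X),
                 medoid_frames = medoid,
                 assignment = remap),
            class = "cluster_summary")
}

#' @export
print.cluster_summary <- function(x, ...) {
  cat("cluster_summary:", length(x$occupancy), "clusters\n")
  for (i in seq_along(x$occupancy))
    cat(sprintf("  C%d: %.1f%% (medoid frame %d)\n", i, x$occupancy[i],
                x$medoid_frames[i]))
  invisible(x)
}

#' Write eigenvalues and variance fractions as TSV
#' @param model an `essential_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eigenvalues <- function(model, path) {
  fr <- variance_fractions(model)
  utils::write.table(
    data.frame(component = seq_along(model$values),
               eigenvalue_A2 = model$values, fraction = fr),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-frame PC projections as TSV
#' @param proj a `pca_projection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_projection <- function(proj, path) {
  tab <- data.frame(frame = attr(proj, "frames"), unclass(proj))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
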