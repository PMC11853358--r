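# Essential dynamics: PCA, subspace comparison, FEL, clustering.

# frames displaced along a single unit mode with amplitudes +/- 1
rank1_traj <- function(n = 4, amp = c(1, -1, 1, -1)) {
  set.seed(11)
  xyz <- matrix(stats::rnorm(n * 3, sd = 5), n, 3)
  v <- stats::rnorm(n * 3)
  v <- v / sqrt(sum(v^2))
  vm <- matrix(v, n, 3, byrow = FALSE)  # arbitrary but fixed layout
  frames <- lapply(amp, function(a) xyz + a * vm)
  list(traj = traj_from_frames(bead_structure(xyz), frames),
       v = as.vector(t(vm)), xyz = xyz)
}

test_that("rank-1 ensembles give a single component equal to the mode", {
  r <- rank1_traj()
  pc <- suppressWarnings(fit_pca(r$traj, "ca", fit = FALSE))
  expect_equal(pc$values[1], var(c(1, -1, 1, -1)), tolerance = 1e-9)
  expect_true(all(pc$values[-1] < 1e-12))
  dot <- abs(sum(pc$vectors[, 1] * r$v))
  expect_equal(dot, 1, tolerance = 1e-9)
  expect_equal(variance_fractions(pc)[1], 1, tolerance = 1e-12)
  # sign convention: largest-magnitude loading is positive
  expect_gt(pc$vectors[which.max(abs(pc$vectors[, 1])), 1], 0)
})

test_that("planted 4:1 variances are recovered within tolerance", {
  spec <- two_mode_spec()
  sim <- simulate_trajectory(make_complex(spec), spec)
  pc <- fit_pca(sim$trajectory, "ca", fit = FALSE)
  fr <- variance_fractions(pc)
  expect_lt(abs(fr[1] - 0.8), 0.02)
  expect_lt(abs(fr[2] - 0.2), 0.02)
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  # eigenvalue ratio: average the sampling estimator over independent draws
  ratios <- vapply(1:5, function(seed) {
    sp <- two_mode_spec(seed = seed)
    p <- fit_pca(simulate_trajectory(make_complex(sp), sp)$trajectory,
                 "ca", fit = FALSE)
    p$values[1] / p$values[2]
  }, 1)
  expect_equal(mean(ratios), 4, tolerance = 0.05)
})

test_that("pooling a trajectory with itself reproduces the eigensystem", {
  spec <- two_mode_spec(frames = 300L, seed = 5)
  sim <- simulate_trajectory(make_complex(spec), spec)
  p1 <- fit_pca(sim$trajectory, "ca", fit = FALSE)
  p2 <- fit_pca(list(sim$trajectory, sim$trajectory), "ca", fit = FALSE)
  # duplicated frames only shift the n-1 variance denominator
  expect_equal(p2$values[1:5], p1$values[1:5], tolerance = 1e-2)
  expect_equal(abs(diag(crossprod(p1$vectors[, 1:2], p2$vectors[, 1:2]))),
               rep(1, 2), tolerance = 1e-6)
})

test_that("eigenvalues sum to the covariance trace and vectors are orthonormal", {
  spec <- two_mode_spec(frames = 500L, seed = 7)
  sim <- simulate_trajectory(make_complex(spec), spec)
  pc <- fit_pca(sim$trajectory, "ca", fit = FALSE)
  X <- apply(sim$trajectory$coords, 1, function(m) as.vector(t(m)))
  tr_cov <- sum(apply(t(X), 2, stats::var))
  expect_equal(sum(pc$values), tr_cov, tolerance = 1e-9 * tr_cov)
  G <- crossprod(pc$vectors)
  expect_equal(G, diag(ncol(pc$vectors)), tolerance = 1e-9)
})

test_that("projections score frames as (x - mean) . eigenvector", {
  r <- rank1_traj()
  pc <- suppressWarnings(fit_pca(r$traj, "ca", fit = FALSE))
  proj <- project_frames(pc, r$traj, "ca", components = 1:2)
  expect_equal(dim(proj), c(4L, 2L), ignore_attr = TRUE)
  # frame = mean + 2 * PC1 scores exactly (2, 0)
  mu <- as.vector(t(pc$mean))
  x2 <- mu + 2 * pc$vectors[, 1]
  f2 <- matrix(x2, ncol = 3, byrow = TRUE)
  tr2 <- traj_from_frames(bead_structure(f2), list(f2, matrix(mu, ncol = 3, byrow = TRUE)))
  p2 <- project_frames(pc, tr2, "ca", components = 1:2)
  expect_equal(unclass(p2)[1, ], c(PC1 = 2, PC2 = 0), tolerance = 1e-9)
  expect_equal(unclass(p2)[2, ], c(PC1 = 0, PC2 = 0), tolerance = 1e-9)
})

test_that("full-rank reconstruction from all components is exact", {
  spec <- two_mode_spec(frames = 50L, seed = 9)
  sim <- simulate_trajectory(make_complex(spec), spec)
  pc <- fit_pca(sim$trajectory, "ca", fit = FALSE)
  k <- ncol(pc$vectors)
  proj <- project_frames(pc, sim$trajectory, "ca", components = seq_len(k))
  mu <- as.vector(t(pc$mean))
  for (f in c(1, 25, 50)) {
    rec <- mu + pc$vectors %*% unclass(proj)[f, ]
    orig <- as.vector(t(sim$trajectory$coords[f, , ]))
    expect_equal(as.vector(rec), orig, tolerance = 1e-9)
  }
})

# hand-built essential models over a 2-atom (6-coordinate) space
toy_model <- function(vectors) {
  v <- as.matrix(vectors)
  structure(list(mean = matrix(0, 2, 3), vectors = v,
                 values = rep(1, ncol(v)), labels = c("A:1", "A:2"),
                 reference = matrix(0, 2, 3), fit = FALSE),
            class = "essential_model")
}

test_that("RMSIP is 1 for identical, 0 for disjoint subspaces", {
  e <- diag(6)
  a <- toy_model(e[, 1:2])
  b <- toy_model(e[, 3:4])
  expect_equal(rmsip(a, a, k = 2), 1, tolerance = 1e-12)
  expect_equal(rmsip(a, b, k = 2), 0, tolerance = 1e-12)
  expect_equal(overlap_matrix(a, a, k = 2), diag(2), tolerance = 1e-12)
  expect_equal(overlap_matrix(a, b, k = 2), matrix(0, 2, 2),
               tolerance = 1e-12)
})

test_that("one-mode RMSIP equals |cos(angle)| between the modes", {
  th <- 60 * pi / 180
  v1 <- c(1, 0, 0, 0, 0, 0)
  v2 <- c(cos(th), sin(th), 0, 0, 0, 0)
  expect_equal(rmsip(toy_model(v1), toy_model(v2), k = 1), cos(th),
               tolerance = 1e-12)
})

test_that("RMSIP of random orthonormal bases stays in [0, 1]", {
  for (seed in 1:10) {
    set.seed(seed)
    qa <- qr.Q(qr(matrix(stats::rnorm(36), 6)))[, 1:3]
    qb <- qr.Q(qr(matrix(stats::rnorm(36), 6)))[, 1:3]
    r <- rmsip(toy_model(qa), toy_model(qb), k = 3)
    expect_gte(r, 0)
    expect_lte(r, 1 + 1e-12)
    O <- overlap_matrix(toy_model(qa), toy_model(qb), k = 3)
    expect_equal(sqrt(sum(O) / 3), r, tolerance = 1e-12)
    expect_true(all(O >= 0 & O <= 1 + 1e-12))
    expect_true(all(rowSums(O) <= 1 + 1e-9))
  }
})

test_that("porcupine vectors scale the eigenvector and anchor on the mean", {
  r <- rank1_traj()
  pc <- suppressWarnings(fit_pca(r$traj, "ca", fit = FALSE))
  v1 <- porcupine(pc, 1, scale = 1)
  expect_equal(as.vector(t(v1)), pc$vectors[, 1], tolerance = 1e-12)
  expect_equal(porcupine(pc, 1, scale = 0), 0 * v1)
  p <- withr::local_tempfile(fileext = ".pdb")
  top <- bead_structure(pc$mean)
  porcupine(pc, 1, scale = 5, topology = top, path = p)
  tr <- read_trajectory(p, top)
  expect_equal(n_frames(tr), 2L)
  expect_equal(frame_xyz(tr, 2) - frame_xyz(tr, 1), 5 * v1,
               tolerance = 1e-3)
})

test_that("free-energy landscapes follow -kT log(N/Nmax) with zero minimum", {
  # all frames in one bin
  f1 <- fel(rep(1.0, 100), rep(2.0, 100), bins = 4, temperature = 310)
  expect_equal(sum(f1$counts > 0), 1L)
  expect_equal(min(f1$G, na.rm = TRUE), 0)
  expect_true(all(is.na(f1$G[f1$counts == 0])))
  # two equally populated bins: both at zero
  f2 <- fel(c(rep(0, 50), rep(1, 50)), bins = 2)
  expect_equal(as.vector(f2$G), c(0, 0))
  # G of a known population ratio (closed-form check near 1/e at T = 310 K)
  f3 <- fel(c(rep(0.25, 100000), rep(0.75, 271828)), bins = 2,
            temperature = 310)
  expect_equal(f3$G[1, 1], 0.0019872041 * 310, tolerance = 1e-4)
  expect_equal(f3$G[2, 1], 0)
  expect_error(fel(numeric(0)), "empty")
})

test_that("FEL of a Gaussian well reconstructs the analytic curvature", {
  set.seed(123)
  sigma <- 0.8
  x <- stats::rnorm(1e5, sd = sigma)
  g <- fel(x, bins = 50, temperature = 310)
  keep <- !is.na(g$G[, 1]) & g$counts[, 1] >= 100
  fit <- stats::lm(g$G[keep, 1] ~ poly(g$midA[keep], 2, raw = TRUE),
                   weights = g$counts[keep, 1])
  curv <- 2 * stats::coef(fit)[3]
  expect_equal(unname(curv), 0.0019872041 * 310 / sigma^2, tolerance = 0.1 *
                 0.0019872041 * 310 / sigma^2)
})

test_that("k-means representatives report exact occupancies and medoids", {
  # k = 1: centroid is the mean, occupancy 100
  set.seed(5)
  proj1 <- structure(cbind(stats::rnorm(40), stats::rnorm(40)),
                     frames = 1:40, class = c("pca_projection", "matrix", "array"))
  c1 <- kmeans_representatives(proj1, k = 1, seed = 1)
  expect_equal(as.vector(c1$centers), colMeans(unclass(proj1)),
               tolerance = 1e-9)
  expect_equal(c1$occupancy, 100)
  # three well-separated blobs recover exact proportions
  set.seed(6)
  blob <- function(n, cx) cbind(stats::rnorm(n, cx, 0.05),
                                stats::rnorm(n, 0, 0.05))
  X <- rbind(blob(50, 0), blob(30, 10), blob(20, 20))
  proj3 <- structure(X, frames = seq_len(100),
                     class = c("pca_projection", "matrix", "array"))
  c3 <- kmeans_representatives(proj3, k = 3, seed = 2)
  expect_equal(sort(c3$occupancy, decreasing = TRUE), c(50, 30, 20))
  expect_equal(sum(c3$occupancy), 100, tolerance = 0.01)
  expect_true(all(c3$medoid_frames %in% 1:100))
  # determinism
  c3b <- kmeans_representatives(proj3, k = 3, seed = 2)
  expect_identical(c3, c3b)
  expect_error(kmeans_representatives(proj3, k = 200), "exceeds")
})
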