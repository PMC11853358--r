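# SASA, interface area, contacts, hydrogen bonds, salt bridges.

test_that("single-sphere SASA matches the analytic area within 1%", {
  m <- bead_structure(matrix(0, 1, 3), radius = 1.7)
  s <- sasa(m, probe = 1.4, points = 960)
  expect_equal(s$total, 4 * pi * 3.1^2, tolerance = 0.01 * 4 * pi * 3.1^2)
  s0 <- sasa(m, probe = 0, points = 960)
  expect_equal(s0$total, 4 * pi * 1.7^2, tolerance = 0.01 * 4 * pi * 1.7^2)
})

test_that("an engulfed atom has zero accessible area", {
  m <- bead_structure(matrix(0, 2, 3), radius = c(1.7, 10))
  s <- sasa(m, probe = 1.4, points = 960)
  expect_equal(s$atom_sasa[1], 0)
})

test_that("doubling the quadrature changes sphere SASA by < 0.5%", {
  xyz <- matrix(c(0, 0, 0, 2.5, 0, 0), 2, 3, byrow = TRUE)
  m <- bead_structure(xyz, radius = 1.7)
  a <- sasa(m, points = 960)$total
  b <- sasa(m, points = 1920)$total
  expect_lt(abs(a - b) / a, 0.005)
})

test_that("missing radii are reported by atom", {
  m <- bead_structure(matrix(0, 1, 3))
  m$atoms$radius <- NA_real_
  m$atoms$element <- "ZZ"
  expect_error(sasa(m), "no radius for atom")
})

test_that("interface area is zero for distant chains and symmetric", {
  xyz <- rbind(c(0, 0, 0), c(100, 0, 0))
  m <- bead_structure(xyz, chain = c("A", "B"), resno = c(1, 1))
  tr <- traj_from_frames(m, list(xyz, xyz))
  ia <- interface_area(tr, "A", "B", points = 480)
  expect_true(all(abs(ia$area) < 1e-6))
  ib <- interface_area(tr, "B", "A", points = 480)
  expect_equal(ib$area, ia$area)
  expect_equal(sum(ia$histogram$prob), 1, tolerance = 1e-9)
  expect_error(interface_area(tr, "A", "A"), "overlap")
})

test_that("two touching spheres bury the analytic cap area", {
  d <- 4.0
  xyz <- rbind(c(0, 0, 0), c(d, 0, 0))
  m <- bead_structure(xyz, chain = c("A", "B"), resno = c(1, 1),
                      radius = 1.7)
  tr <- traj_from_frames(m, list(xyz))
  ia <- interface_area(tr, "A", "B", points = 1920)
  buried <- two_sphere_buried(3.1, 3.1, d)
  expect_equal(ia$area, sum(buried) / 2, tolerance = 0.02 * sum(buried))
})

test_that("interface area never increases while pulling chains apart", {
  xyzA <- rbind(c(0, 0, 0), c(2.5, 0, 0))
  frames <- lapply(seq(4, 12, by = 1), function(d)
    rbind(xyzA, c(d, 0, 0), c(d + 2.5, 0, 0)))
  m <- bead_structure(frames[[1]], chain = c("A", "A", "B", "B"),
                      resno = c(1, 2, 1, 2), radius = 1.7)
  tr <- traj_from_frames(m, frames)
  ia <- interface_area(tr, "A", "B", points = 960)
  expect_true(all(diff(ia$area) <= 1e-9))
  expect_true(all(ia$area >= -1e-9))
})

# two 1-residue chains whose distance follows a per-frame schedule
schedule_traj <- function(d_series, atom = "CA", resname = "GLY",
                          element = "C") {
  mk <- function(d) rbind(c(0, 0, 0), c(d, 0, 0))
  m <- md_structure(
    data.frame(atom = atom, element = element, resname = resname,
               resno = c(1, 2), chain = c("A", "B"),
               charge = 0, radius = 1.7, eps = 0.1, rmin_half = 1.7),
    mk(d_series[1]))
  traj_from_frames(m, lapply(d_series, mk))
}

test_that("contact occupancy counts frames exactly with inclusive stability", {
  tr <- schedule_traj(c(rep(4.0, 7), rep(6.0, 3)))
  tab <- contact_occupancy(tr, "A", "B", cutoff = 4.5)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$occupancy, 0.70)
  expect_true(tab$stable)       # threshold 0.70 is inclusive
  expect_equal(tab$occupancy * attr(tab, "n_frames"), 7)
  tr2 <- schedule_traj(rep(8, 5))
  expect_equal(nrow(contact_occupancy(tr2, "A", "B")), 0L)
})

test_that("planted 75% contact schedules are recovered exactly", {
  tr <- schedule_traj(c(rep(3.0, 15), rep(9.0, 5)))
  tab <- contact_occupancy(tr, "A", "B", cutoff = 4.5)
  expect_identical(tab$occupancy, 0.75)
})

test_that("hydrogen bonds follow the heavy-atom distance criterion", {
  tr <- schedule_traj(rep(2.9, 6), atom = c("OH", "O"),
                      resname = c("TYR", "GLY"), element = "O")
  hb <- hydrogen_bonds(tr, "A", "B")
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$occupancy, 1.0)
  expect_match(attr(hb, "criterion"), "no hydrogens")
  far <- schedule_traj(rep(5.0, 6), atom = c("OH", "O"),
                       resname = c("TYR", "GLY"), element = "O")
  expect_equal(nrow(hydrogen_bonds(far, "A", "B")), 0L)
})

test_that("a planted 63.2% hydrogen-bond schedule is hit exactly", {
  d <- c(rep(2.9, 316), rep(8.0, 184))
  tr <- schedule_traj(d, atom = c("OH", "O"), resname = c("TYR", "PHE"),
                      element = "O")
  hb <- hydrogen_bonds(tr, "A", "B")
  expect_identical(hb$occupancy, 0.632)
  expect_identical(hb$occupancy * attr(hb, "n_frames"), 316)
})

test_that("salt bridges pair anion oxygens with cation nitrogens", {
  tr <- schedule_traj(rep(3.0, 4), atom = c("OD1", "NZ"),
                      resname = c("ASP", "LYS"), element = c("O", "N"))
  sb <- salt_bridges(tr, "A", "B")
  expect_equal(nrow(sb), 1L)
  expect_equal(sb$occupancy, 1.0)
  far <- schedule_traj(rep(8, 4), atom = c("OD1", "NZ"),
                       resname = c("ASP", "LYS"), element = c("O", "N"))
  expect_equal(nrow(salt_bridges(far, "A", "B")), 0L)
})

test_that("a planted 389/500 salt-bridge schedule gives exactly 0.778", {
  d <- c(rep(3.0, 389), rep(9.0, 111))
  tr <- schedule_traj(d, atom = c("OE1", "NH1"),
                      resname = c("GLU", "ARG"), element = c("O", "N"))
  sb <- salt_bridges(tr, "A", "B")
  expect_identical(sb$occupancy, 0.778)
  expect_identical(sb$occupancy * attr(sb, "n_frames"), 389)
})

test_that("interface classification reports one record per planted type", {
  # three isolated pairs, one per interaction type, far from each other
  atoms <- data.frame(
    atom = c("OD1", "OH", "CG", "NZ", "O", "CD1"),
    element = c("O", "O", "C", "N", "O", "C"),
    resname = c("ASP", "TYR", "LEU", "LYS", "GLY", "ILE"),
    resno = c(1, 2, 3, 11, 12, 13),
    chain = c("A", "A", "A", "B", "B", "B"),
    charge = 0, radius = 1.6, eps = 0.1, rmin_half = 1.7)
  xyz <- rbind(c(0, 0, 0), c(50, 0, 0), c(100, 0, 0),
               c(0, 3.8, 0), c(50, 2.9, 0), c(100, 4.0, 0))
  m <- md_structure(atoms, xyz)
  tr <- traj_from_frames(m, list(xyz, xyz))
  tab <- classify_interface(tr, "A", "B")
  expect_equal(nrow(tab), 3L)
  expect_setequal(tab$type, c("saltbridge", "hbond", "hydrophobic"))
  expect_equal(tab$occupancy, rep(1, 3))
  # pull everything apart: nothing is reported
  xyz_far <- xyz
  xyz_far[4:6, 2] <- xyz_far[4:6, 2] + 20
  far <- traj_from_frames(m, list(xyz_far))
  expect_equal(nrow(classify_interface(far, "A", "B")), 0L)
})

test_that("occupancy times frame count is always an integer", {
  pair <- make_scenario_pair(seed = 3, frames = 500)
  tr <- pair$wt$trajectory
  for (tab in list(contact_occupancy(tr, "M", "P"),
                   salt_bridges(tr, "M", "P"),
                   hydrogen_bonds(tr, "M", "P"))) {
    k <- tab$occupancy * attr(tab, "n_frames")
    expect_equal(k, round(k), tolerance = 1e-9)
  }
})
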