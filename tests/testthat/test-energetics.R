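# Molecular-mechanics terms, generalized-Born solvation, binding energy.

two_ion_structure <- function(d, q = c(1, -1), radius = 2.0, eps = 0.1,
                              rmin_half = 1.7) {
  md_structure(
    data.frame(atom = c("NZ", "OD1"), element = c("N", "O"),
               resname = c("LYS", "ASP"), resno = c(1, 2),
               chain = c("A", "B"), charge = q, radius = radius,
               eps = eps, rmin_half = rmin_half),
    rbind(c(0, 0, 0), c(d, 0, 0)))
}

test_that("Coulomb term reproduces the closed form at 3.32 Angstrom", {
  m <- two_ion_structure(3.32)
  mm <- mm_terms(m, "A", "B")
  expect_equal(mm$ele, -332.0636 / 3.32, tolerance = 1e-2)
  expect_equal(mm$ele, -100.02, tolerance = 1e-2)
})

test_that("Lennard-Jones energy at the minimum distance equals -epsilon", {
  m <- two_ion_structure(2 * 1.7, q = c(0, 0), eps = 0.25)
  mm <- mm_terms(m, "A", "B")
  expect_equal(mm$vdw, -0.25, tolerance = 1e-12)
  expect_equal(mm$ele, 0)
})

test_that("widely separated groups have vanishing interaction terms", {
  m <- two_ion_structure(1e4)
  mm <- mm_terms(m, "A", "B")
  expect_lt(abs(mm$vdw), 1e-6)
  expect_lt(abs(mm$ele), 0.1)   # Coulomb decays as 1/r
  expect_equal(mm$ele, -332.0636 / 1e4, tolerance = 1e-9)
})

test_that("missing parameters name the offending atom", {
  m <- two_ion_structure(3)
  m$atoms$charge[2] <- NA
  expect_error(mm_terms(m, "A", "B"), "missing charge for atom B:2:OD1")
  m2 <- two_ion_structure(3)
  m2$atoms$eps[1] <- NA
  expect_error(mm_terms(m2, "A", "B"), "missing eps for atom A:1:NZ")
})

test_that("an isolated ion reproduces the Born solvation energy", {
  m <- md_structure(
    data.frame(atom = "NZ", element = "N", resname = "LYS", resno = 1,
               chain = "A", charge = 1, radius = 2.0, eps = 0.1,
               rmin_half = 1.7),
    matrix(0, 1, 3))
  g <- gb_polar(m)
  born <- -(332.0636 / 2) * (1 - 1 / 80) / 2.0
  expect_equal(g, born, tolerance = 1e-2)
  expect_equal(g, -81.98, tolerance = 1e-2)
  # isolated atom's effective radius is its intrinsic radius
  expect_equal(born_radii(matrix(0, 1, 3), 2.0), 2.0, tolerance = 1e-12)
})

test_that("uncharged systems have zero polar energy", {
  m <- two_ion_structure(3, q = c(0, 0))
  expect_equal(gb_polar(m), 0)
})

test_that("far-separated ions are additive Born terms", {
  m <- two_ion_structure(500, q = c(1, 1))
  g <- gb_polar(m)
  single <- -(332.0636 / 2) * (1 - 1 / 80) / 2.0
  # two self terms plus the residual cross term ~ q1 q2/r
  expect_equal(g, 2 * single, tolerance = 0.05 + 332.0636 / 500)
})

test_that("GB energy is invariant under rigid transformation", {
  set.seed(21)
  xyz <- matrix(stats::rnorm(15, sd = 3), 5, 3)
  m <- bead_structure(xyz, charge = c(1, -1, 0.5, -0.5, 0), radius = 1.8)
  g1 <- gb_polar(m)
  th <- 1.1
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  m2 <- m
  m2$xyz <- sweep(xyz %*% t(R), 2, c(10, -4, 2), "+")
  expect_equal(gb_polar(m2), g1, tolerance = 1e-9 * abs(g1))
})

test_that("the nonpolar term is the exact linear SASA relation", {
  expect_identical(nonpolar_term(0), 0.92)
  expect_equal(nonpolar_term(1000), 6.34, tolerance = 1e-9)
  expect_identical(nonpolar_term(12345, gamma = 0, b = 0), 0)
  expect_error(nonpolar_term(-1), "nonnegative")
})

test_that("single-trajectory binding energy keeps its accounting identities", {
  pair <- make_scenario_pair(seed = 2, frames = 500)
  e <- binding_energy(pair$wt$trajectory, "P", "M", points = 120,
                      stride = 50)
  comp <- function(x) energy_component(e, x)
  expect_identical(comp("dE_int"), 0)
  expect_equal(comp("dE_MM"), comp("dE_vdW") + comp("dE_ele") + comp("dE_int"),
               tolerance = 1e-9)
  expect_equal(comp("dG_sol"), comp("dE_polar") + comp("dE_nonpolar"),
               tolerance = 1e-9)
  expect_equal(comp("dG_binding"), comp("dE_MM") + comp("dG_sol"),
               tolerance = 1e-9)
  expect_identical(e$entropy, "excluded")
})

test_that("uncharged non-interacting pair reduces to the nonpolar difference", {
  atoms <- data.frame(atom = c("CA", "CA"), element = "C",
                      resname = "GLY", resno = c(1, 2), chain = c("A", "B"),
                      charge = 0, radius = 1.7, eps = 0, rmin_half = 1.7)
  xyz <- rbind(c(0, 0, 0), c(10, 0, 0))
  m <- md_structure(atoms, xyz)
  tr <- traj_from_frames(m, list(xyz))
  e <- binding_energy(tr, "A", "B", points = 960)
  sAB <- sasa(m, points = 960)$total
  sA <- sasa_total_subset <- sum(sasa(md_structure(atoms[1, ], xyz[1, , drop = FALSE]),
                                      points = 960)$atom_sasa)
  sB <- sum(sasa(md_structure(atoms[2, ], xyz[2, , drop = FALSE]),
                 points = 960)$atom_sasa)
  expected <- nonpolar_term(sAB) - nonpolar_term(sA) - nonpolar_term(sB)
  expect_equal(energy_component(e, "dG_binding"), expected, tolerance = 1e-9)
  expect_equal(expected, 0.00542 * (sAB - sA - sB) - 0.92, tolerance = 1e-9)
})

test_that("contact ion pairs show negative Coulomb and positive desolvation", {
  m <- two_ion_structure(3.0)
  tr <- traj_from_frames(m, list(m$xyz))
  e <- binding_energy(tr, "A", "B", points = 480)
  expect_lt(energy_component(e, "dE_ele"), 0)
  expect_gt(energy_component(e, "dE_polar"), 0)
})

test_that("per-residue decomposition localizes and conserves the total", {
  pair <- make_scenario_pair(seed = 4, frames = 500)
  tr <- pair$wt$trajectory
  e <- binding_energy(tr, "P", "M", points = 120, stride = 100)
  d <- per_residue_decomposition(tr, "P", "M", points = 120, stride = 100)
  expect_equal(sum(d$table$total), energy_component(e, "dG_binding"),
               tolerance = 0.05)
  # the planted charged interface pairs carry the most negative rows
  lab <- paste0(d$table$chain, ":", d$table$resno)
  ord <- lab[order(d$table$ele)]
  planted <- c("M:82", "P:151", "M:27", "P:237", "M:28", "P:239")
  expect_true(all(utils::head(ord, 4) %in% planted))
})

test_that("only interacting residues receive nonzero contributions", {
  atoms <- data.frame(atom = rep("CA", 4), element = "C", resname = "GLY",
                      resno = c(1, 2, 11, 12), chain = c("A", "A", "B", "B"),
                      charge = c(1, 0, -1, 0), radius = 1.7,
                      eps = c(0.1, 0, 0.1, 0), rmin_half = 1.7)
  xyz <- rbind(c(0, 0, 0), c(200, 0, 0), c(3.5, 0, 0), c(300, 0, 0))
  m <- md_structure(atoms, xyz)
  tr <- traj_from_frames(m, list(xyz))
  d <- per_residue_decomposition(tr, "A", "B", points = 480)
  lab <- paste0(d$table$chain, ":", d$table$resno)
  active <- abs(d$table$total) > 1e-3
  expect_setequal(lab[active], c("A:1", "B:11"))
})

test_that("doubling the charged interface strengthens binding strictly", {
  mk <- function(extra) {
    n <- if (extra) 4 else 2
    atoms <- data.frame(
      atom = c("NZ", "OD1", "NZ", "OD1")[1:n],
      element = c("N", "O", "N", "O")[1:n],
      resname = c("LYS", "ASP", "LYS", "ASP")[1:n],
      resno = c(1, 11, 2, 12)[1:n],
      chain = c("A", "B", "A", "B")[1:n],
      charge = c(1, -1, 1, -1)[1:n],
      radius = 1.7, eps = 0.1, rmin_half = 1.7)
    xyz <- rbind(c(0, 0, 0), c(3.3, 0, 0),
                 c(20, 0, 0), c(23.3, 0, 0))[1:n, , drop = FALSE]
    traj_from_frames(md_structure(atoms, xyz), list(xyz))
  }
  g1 <- energy_component(binding_energy(mk(FALSE), "A", "B", points = 240),
                         "dG_binding")
  g2 <- energy_component(binding_energy(mk(TRUE), "A", "B", points = 240),
                         "dG_binding")
  expect_lt(g2, g1)
})
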