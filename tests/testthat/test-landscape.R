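simple_conf <- function(coms) {
  # one residue per region at the given centres
  atoms <- data.frame(chain = "A", resno = 1:3, resid = "ALA",
                      elety = "N", elesy = "N", stringsAsFactors = FALSE)
  conformation(atoms, do.call(rbind, coms))
}

test_that("the breathing angle is the hinge-vertex angle of region centres", {
  regions <- region_definition(1, 2, 3, atom_filter = "N")
  # collinear with the hinge between the domains
  cf <- simple_conf(list(c(-5, 0, 0), c(0, 0, 0), c(7, 0, 0)))
  expect_equal(breathing_angle(cf, regions), 180)
  cf90 <- simple_conf(list(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)))
  expect_equal(breathing_angle(cf90, regions), 90)
  # rigid motion leaves theta unchanged to 1e-10
  toy <- fixture_toy()
  th0 <- breathing_angle(toy$conformation, toy$regions)
  set.seed(8)
  for (k in 1:5) {
    moved <- apply_rigid(toy$conformation, random_rotation(), rnorm(3, sd = 50))
    expect_equal(breathing_angle(moved, toy$regions), th0, tolerance = 1e-10)
  }
  expect_error(breathing_angle(cf, region_definition(1, 2, 9,
                                                     atom_filter = "N")),
               "selection error")
  expect_error(region_definition(c(1, 2), c(2, 3), 4), "disjoint")
})

test_that("superposed RMSD matches a brute-force rotational minimisation", {
  toy <- fixture_toy()
  sel <- toy$domains$A
  ref <- toy$conformation
  expect_equal(rmsd_to_reference(ref, ref, sel, "N"), 0, tolerance = 1e-9)
  moved <- apply_rigid(ref, diag(3), c(4, -2, 9))
  expect_equal(rmsd_to_reference(moved, ref, sel, "N"), 0, tolerance = 1e-6)
  # random 10-atom pair against brute-force minimisation over rotations
  set.seed(13)
  atoms <- data.frame(chain = "A", resno = 1:10, resid = "ALA", elety = "N",
                      elesy = "N", stringsAsFactors = FALSE)
  a <- conformation(atoms, matrix(rnorm(30, sd = 3), 10, 3))
  b <- conformation(atoms, matrix(rnorm(30, sd = 3), 10, 3))
  r_pkg <- rmsd_to_reference(a, b, 1:10, "N")
  xa <- sweep(a$xyz, 2, colMeans(a$xyz))
  xb <- sweep(b$xyz, 2, colMeans(b$xyz))
  rmsd_at <- function(ang) {
    Rz <- rdcscape::rotation_matrix(c(0, 0, 1), ang[1])
    Ry <- rdcscape::rotation_matrix(c(0, 1, 0), ang[2])
    Rx <- rdcscape::rotation_matrix(c(1, 0, 0), ang[3])
    sqrt(mean(rowSums((xa %*% t(Rz %*% Ry %*% Rx) - xb)^2)))
  }
  best <- Inf
  for (start in list(c(0, 0, 0), c(90, 0, 0), c(0, 90, 0), c(0, 0, 90),
                     c(180, 90, 0), c(45, -45, 120))) {
    o <- optim(start, rmsd_at, method = "Nelder-Mead",
               control = list(maxit = 4000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  expect_equal(r_pkg, best, tolerance = 1e-6)
})

test_that("free-energy surfaces follow -kBT ln H on populated bins", {
  toy <- fixture_toy()
  regions <- toy$regions
  ref <- toy$conformation
  sel <- toy$domains$A
  # all conformations identical: a single populated bin at -kBT ln N
  ens_same <- ensemble(replicate(20, ref, simplify = FALSE))
  g <- free_energy_surface(ens_same, regions, ref, sel, temperature = 310)
  expect_equal(sum(g$H), 20)
  expect_equal(sum(g$H > 0), 1)
  expect_equal(min(g$F, na.rm = TRUE), -kB_kJmol * 310 * log(20))
  # uniform occupancy gives a flat F; counts conserve the ensemble size
  thetas <- rep(c(47.2, 49.2, 51.2, 53.2, 55.2), each = 4)
  ens_u <- ensemble(frames_at_thetas(toy, thetas))
  gu <- free_energy_surface(ens_u, regions, ref, sel, theta_bin = 2)
  expect_equal(sum(gu$H), length(thetas))
  fvals <- gu$F[!is.na(gu$F)]
  expect_equal(max(fvals) - min(fvals), 0, tolerance = 1e-12)
  # empty bins are NA, not zero
  expect_true(anyNA(gu$F))
  expect_error(free_energy_surface(ens_u, regions, ref, sel, theta_bin = 0),
               "binning error")
  # landscape TSV export has one row per grid cell
  path <- tempfile(fileext = ".tsv")
  write_landscape(gu, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), length(gu$H))
  expect_equal(sum(tab$H), length(thetas))
  unlink(path)
})

test_that("two-bin counts give the analytic free-energy difference", {
  toy <- fixture_toy()
  thetas <- c(rep(57.5, 870), rep(49.5, 130))
  confs <- frames_at_thetas(toy, c(57.5, 49.5))
  xyz <- array(NA_real_, c(1000, n_atoms(toy$conformation), 3))
  for (k in seq_len(1000)) {
    xyz[k, , ] <- if (thetas[k] > 53) confs[[1]]$xyz else confs[[2]]$xyz
  }
  ens <- rdcscape:::new_ensemble(toy$conformation$atoms, xyz)
  g <- free_energy_surface(ens, toy$regions, toy$conformation,
                           toy$domains$A, theta_bin = 2, temperature = 310)
  fvals <- sort(g$F[!is.na(g$F)])
  expect_equal(fvals[2] - fvals[1], -kB_kJmol * 310 * log(130 / 870),
               tolerance = 1e-12)
})

test_that("basin populations count fractions and report both centres", {
  toy <- fixture_toy()
  part <- basin_partition(53.5)
  # all frames in one basin
  ens_locked <- ensemble(frames_at_thetas(toy, rep(58, 10)))
  bp <- basin_population(ens_locked, toy$regions, part)
  expect_equal(bp$fraction[bp$basin == "locked"], 1)
  expect_equal(bp$fraction[bp$basin == "unlocked"], 0)
  expect_equal(sum(bp$fraction), 1)
  # 130 of 1000 below the boundary
  thetas <- c(rep(58, 870), rep(49, 130))
  set.seed(2)
  thetas <- thetas + rnorm(1000, sd = 0.2)
  confs2 <- frames_at_thetas(toy, thetas[1:2])
  # build frames quickly by reusing two poses plus per-frame selection
  poses <- frames_at_thetas(toy, c(58, 49))
  xyz <- array(NA_real_, c(1000, n_atoms(toy$conformation), 3))
  for (k in 1:1000) xyz[k, , ] <- poses[[if (k <= 870) 1 else 2]]$xyz
  ens2 <- rdcscape:::new_ensemble(toy$conformation$atoms, xyz)
  bp2 <- basin_population(ens2, toy$regions, part, reference = poses[[1]],
                          selection = c(toy$domains$A, toy$domains$B))
  expect_equal(bp2$fraction[bp2$basin == "unlocked"], 0.13)
  expect_equal(bp2$mean_theta[bp2$basin == "locked"], 58, tolerance = 0.01)
  expect_equal(bp2$mode_theta[bp2$basin == "unlocked"], 49, tolerance = 0.51)
  expect_equal(bp2$mean_rmsd[bp2$basin == "locked"], 0, tolerance = 1e-6)
  expect_gt(bp2$mean_rmsd[bp2$basin == "unlocked"], 0.2)
  expect_error(basin_population(list(), toy$regions, part), "non-empty")
})

test_that("contact occupancy applies geometric criteria per basin", {
  n <- 4
  atoms <- data.frame(chain = "A", resno = rep(1:2, each = 2), resid = "ALA",
                      elety = rep(c("N", "H"), 2), elesy = rep(c("N", "H"), 2),
                      stringsAsFactors = FALSE)
  close_xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(3.5, 0, 0), c(4.5, 0, 0))
  far_xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(15, 0, 0), c(16, 0, 0))
  xyz <- array(NA_real_, c(n, 4, 3))
  for (k in 1:n) xyz[k, , ] <- if (k <= 2) close_xyz else far_xyz
  ens <- rdcscape:::new_ensemble(atoms, xyz)
  donors <- data.frame(resno = 1, atom = "H", antecedent = "N")
  acceptors <- data.frame(resno = 2, atom = "N")
  # donor H at 2.5 A from acceptor, angle N-H...N = 180 in the close pose
  occ <- contact_occupancy(ens, donors, acceptors, dist_cutoff = 3.0,
                           angle_cutoff = 120,
                           labels = c("minor", "minor", "major", "major"))
  expect_equal(occ$occupancy, 0.5)
  expect_equal(occ$occupancy_minor, 1)
  expect_equal(occ$occupancy_major, 0)
  # distance-only criterion without an antecedent
  occ2 <- contact_occupancy(ens, data.frame(resno = 1, atom = "H"),
                            acceptors, dist_cutoff = 3.0)
  expect_equal(occ2$occupancy, 0.5)
  expect_error(contact_occupancy(ens, donors[0, ], acceptors), "selection")
})

test_that("potential-energy profiles bin per-frame energies over theta", {
  toy <- fixture_toy()
  thetas <- c(46.5, 48.5, 50.5, 56.5, 58.5)
  confs <- frames_at_thetas(toy, thetas)
  ens <- ensemble(confs, frame_info = data.frame(E_pot = rep(5, 5)))
  prof <- potential_energy_profile(ens, toy$regions, theta_bin = 2)
  expect_equal(unique(prof$mean_E_pot[prof$n > 0]), 5)
  # empty bins are undefined, not zero
  expect_true(anyNA(prof$mean_E_pot))
  # E_pot = theta: per-bin mean within the bin half-width of the centre
  ens2 <- ensemble(confs, frame_info = data.frame(E_pot = thetas))
  prof2 <- potential_energy_profile(ens2, toy$regions, theta_bin = 2)
  occ <- prof2$n > 0
  expect_true(all(abs(prof2$mean_E_pot[occ] - prof2$theta_mid[occ]) <= 1 + 0.1))
  ens3 <- ensemble(confs)
  expect_error(potential_energy_profile(ens3, toy$regions), "E_pot")
})
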