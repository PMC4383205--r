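test_that("HNHA extraction inverts the tangent-squared intensity relation", {
  xi <- 0.01305
  # zero cross peak means zero coupling
  expect_equal(j_from_hnha(0, 1, xi), 0)
  # ratio -1 forces 2 pi xi J = pi/4, i.e. J = 1/(8 xi)
  expect_equal(j_from_hnha(-1, 1, xi), 1 / (8 * xi), tolerance = 1e-12)
  expect_equal(1 / (8 * xi), 9.5785, tolerance = 1e-4)
  # round trip J -> intensities -> J on the principal branch
  J <- seq(0.05, 11.95, length.out = 200)
  ratio <- hnha_intensity_ratio(J, xi)
  expect_equal(j_from_hnha(ratio, rep(1, 200), xi), J, tolerance = 1e-10)
  # sign convention and branch guards
  expect_error(j_from_hnha(0.5, 1, xi), "sign-convention")
  expect_error(j_from_hnha(-0.5, 0, xi), "nonzero")
  expect_error(hnha_intensity_ratio(1 / (4 * xi) + 1, xi), "branch")
})

test_that("coupling errors propagate to first order and match Monte Carlo", {
  xi <- 0.01305
  # zero noise and zero floor give zero error
  expect_equal(hnha_error(-0.6, 1, noise = 0, xi = xi, rel_floor = 0), 0)
  # first-order linearity: doubling both intensity errors doubles sigma_J
  e1 <- hnha_error(-0.6, 1, noise = 0, xi = xi, rel_floor = 0.05)
  e2 <- hnha_error(-0.6, 1, noise = 0, xi = xi, rel_floor = 0.10)
  expect_equal(e2, 2 * e1, tolerance = 1e-12)
  # propagation agrees with Monte-Carlo resampling of the intensities
  set.seed(6)
  I_x <- -0.6; I_d <- 1; s <- 0.02
  draws <- j_from_hnha(pmin(I_x + rnorm(1e5, sd = s), -1e-9),
                       I_d + rnorm(1e5, sd = s), xi)
  e_prop <- hnha_error(I_x, I_d, noise = s, xi = xi, rel_floor = 0)
  expect_equal(e_prop, sd(draws), tolerance = 0.05)
})

test_that("table-level extraction flags glycines, dead and weak peaks", {
  xi <- 0.01305
  J <- c(4, 6, 8, 9)
  tab <- make_hnha_table(J, noise = 0, seed = 3, xi = xi)
  tab$resid[2] <- "GLY"
  tab$I_cross[3] <- -1e-6          # below the noise level
  tab$noise <- 0.01
  out <- extract_j_couplings(tab, xi = xi)
  expect_equal(out$flag, c("measured", "discarded", "below-noise", "measured"))
  expect_equal(out$J[c(1, 4)], J[c(1, 4)], tolerance = 1e-10)
  expect_true(is.na(out$J[2]))
})

test_that("Karplus back-calculation averages over the ensemble", {
  karplus <- c(A = 7.09, B = -1.42, C = 1.55)
  # a three-residue backbone whose C(2) swings around the N(2)-CA(2) axis
  backbone_at <- function(ang) {
    atoms <- data.frame(chain = "A",
                        resno = c(1, 1, 2, 2, 2, 3),
                        resid = "ALA",
                        elety = c("CA", "C", "N", "CA", "C", "N"),
                        elesy = c("C", "C", "N", "C", "C", "N"),
                        stringsAsFactors = FALSE)
    a <- ang * pi / 180
    c2 <- c(1.5 + 1.5 * cos(70 * pi / 180),
            1.5 * sin(70 * pi / 180) * cos(a),
            1.5 * sin(70 * pi / 180) * sin(a))
    xyz <- rbind(c(-2.5, 1, 0), c(-1.2, 0.9, 0), c(0, 0, 0), c(1.5, 0, 0),
                 c2, c2 + c(1.2, 0.3, -0.2))
    conformation(atoms, xyz)
  }
  phi_of <- function(ang) {
    ph <- residue_phi(backbone_at(ang))
    ph$phi[ph$resno == 2]
  }
  k_of <- function(phi) {
    cs <- cos((phi - 60) * pi / 180)
    karplus[["A"]] * cs^2 + karplus[["B"]] * cs + karplus[["C"]]
  }
  # pose the backbone so that phi is exactly 60 degrees: 3J = A + B + C
  a60 <- uniroot(function(a) phi_of(a) - 60, c(-179, 179), tol = 1e-12)$root
  j1 <- backcalc_j(ensemble(list(backbone_at(a60))), karplus)
  expect_equal(j1$J[j1$resno == 2], sum(karplus), tolerance = 1e-6)
  # an ensemble of two poses averages the two Karplus values analytically
  a40 <- uniroot(function(a) phi_of(a) - 40, c(-179, 179), tol = 1e-12)$root
  am40 <- uniroot(function(a) phi_of(a) + 40, c(-179, 179), tol = 1e-12)$root
  e2 <- ensemble(list(backbone_at(a40), backbone_at(am40)))
  j2 <- backcalc_j(e2, karplus)
  expect_equal(j2$J[j2$resno == 2], mean(k_of(c(40, -40))), tolerance = 1e-6)
  # a uniform-phi ensemble approaches the circular quadrature mean; the
  # swing angle maps to phi by a rigid shift, so a uniform grid in the
  # swing is uniform in phi
  angs <- seq(-179.5, 179.5, by = 1)
  ph3 <- vapply(angs, phi_of, numeric(1))
  expect_equal(diff(range(diff(sort(ph3)))), 0, tolerance = 1e-6)
  e3 <- ensemble(lapply(angs, backbone_at))
  j3 <- backcalc_j(e3, karplus)
  target <- integrate(function(x) k_of(x) / 360, -180, 180)$value
  expect_equal(j3$J[j3$resno == 2], target, tolerance = 0.05)
})

test_that("pseudo-dihedrals make coarse chains J-calculable", {
  toy <- fixture_toy()
  ph <- residue_phi(toy$conformation)
  expect_true(all(is.finite(ph$phi)))
  j <- backcalc_j(ensemble(list(toy$conformation)))
  expect_true(all(j$J > -2 & j$J < 12))
})

test_that("NOE satisfaction is per structure with satisfied + violated = 1", {
  toy <- fixture_toy()
  two <- fixture_two_state()
  ens <- two$ensemble
  noes <- make_noe_table(ens, coverage = 0.2, slack = 0.5, seed = 4)
  out <- noe_satisfaction(ens, noes, tolerance = 0)
  expect_equal(out$per_structure$satisfied, rep(1, n_models(ens)))
  expect_equal(out$per_structure$satisfied + out$per_structure$violated,
               rep(1, n_models(ens)))
  # a bound violated in half the structures splits the distribution
  poses <- frames_at_thetas(toy, c(58, 49))
  xyz <- array(NA_real_, c(10, n_atoms(poses[[1]]), 3))
  for (k in 1:10) xyz[k, , ] <- poses[[if (k <= 5) 1 else 2]]$xyz
  ens2 <- rdcscape:::new_ensemble(poses[[1]]$atoms, xyz)
  a1 <- toy$domains$A[1]; b1 <- toy$domains$B[6]
  d_locked <- sqrt(sum((poses[[1]]$xyz[match(a1, toy$resno) * 2 - 1, ] -
                        poses[[1]]$xyz[match(b1, toy$resno) * 2 - 1, ])^2))
  d_unlocked <- sqrt(sum((poses[[2]]$xyz[match(a1, toy$resno) * 2 - 1, ] -
                          poses[[2]]$xyz[match(b1, toy$resno) * 2 - 1, ])^2))
  noes2 <- data.frame(resno1 = a1, atom1 = "N", resno2 = b1, atom2 = "N",
                      bound = mean(c(d_locked, d_unlocked)))
  class(noes2) <- c("noe_table", "data.frame")
  out2 <- noe_satisfaction(ens2, noes2, tolerance = 0)
  expect_equal(sort(unique(out2$per_structure$satisfied)), c(0, 1))
  expect_equal(mean(out2$per_structure$satisfied), 0.5)
  # unresolvable pairs are excluded and reported
  noes3 <- rbind(noes2, data.frame(resno1 = 999, atom1 = "N", resno2 = b1,
                                   atom2 = "N", bound = 5))
  class(noes3) <- c("noe_table", "data.frame")
  out3 <- noe_satisfaction(ens2, noes3)
  expect_equal(nrow(out3$excluded), 1)
  expect_equal(out3$n_used, 1)
})

test_that("the consolidated report aggregates and is order-invariant", {
  toy <- fixture_toy()
  media <- fixture_media()
  ens <- ensemble(frames_at_thetas(toy, c(58, 55, 49)))
  clean <- ensemble_average_rdc(ens, toy$bonds, media, n_orient = 144)
  rdc <- do.call(rbind, lapply(names(clean), function(nm) {
    data.frame(resno = toy$bonds$resno, pair = toy$bonds$pair, medium = nm,
               D_exp = clean[[nm]], sigma = 1e-6)
  }))
  class(rdc) <- c("rdc_table", "data.frame")
  true_j <- backcalc_j(ens)
  hnha <- make_hnha_table(true_j$J, noise = 0, seed = 1, resno = true_j$resno)
  noes <- make_noe_table(ens, coverage = 0.2, slack = 0.3, seed = 2)
  rep1 <- build_report(ens, toy$bonds, media, rdc = rdc, hnha = hnha,
                       noes = noes, n_orient = 144)
  # noise-free self-consistency: perfect Q, zero J-RMSD, all NOEs satisfied
  expect_equal(rep1$q$pooled, 0, tolerance = 1e-9)
  expect_equal(rep1$j_rmsd, 0, tolerance = 1e-9)
  expect_equal(rep1$noe$mean_satisfied, 1)
  # bookkeeping: counts reflect inputs minus discards
  expect_equal(rep1$counts$rdc_used, nrow(rdc))
  expect_equal(rep1$counts$j_used + rep1$counts$j_discarded, nrow(hnha))
  # shuffling input row order leaves all metrics unchanged
  set.seed(3)
  rdc_sh <- rdc[sample(nrow(rdc)), ]
  class(rdc_sh) <- c("rdc_table", "data.frame")
  hnha_sh <- hnha[sample(nrow(hnha)), ]
  class(hnha_sh) <- c("hnha_table", "data.frame")
  rep2 <- build_report(ens, toy$bonds, media, rdc = rdc_sh, hnha = hnha_sh,
                       noes = noes[sample(nrow(noes)), ], n_orient = 144)
  expect_equal(rep2$q, rep1$q, tolerance = 1e-12)
  expect_equal(rep2$j_rmsd, rep1$j_rmsd, tolerance = 1e-12)
  expect_equal(rep2$noe$mean_satisfied, rep1$noe$mean_satisfied)
  expect_error(build_report(ens), "at least one validation input")
  # machine-readable export
  path <- tempfile(fileext = ".tsv")
  write_report(rep1, path)
  tab <- read.delim(path)
  expect_true(all(c("Q_steric", "J_rmsd_Hz", "NOE_mean_satisfied")
                  %in% tab$metric))
  unlink(path)
})
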