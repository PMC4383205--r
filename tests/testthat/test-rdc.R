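axial_tensor <- function(Azz = 6e-4, medium = "steric") {
  alignment_tensor(diag(c(-Azz / 2, -Azz / 2, Azz)), medium)
}

# conformation with explicitly chosen bond directions (N at origin-ish,
# H displaced along the given unit vectors)
conf_with_bonds <- function(dirs) {
  n <- nrow(dirs)
  atoms <- data.frame(chain = "A", resno = rep(seq_len(n), each = 2),
                      resid = "ALA", elety = rep(c("N", "H"), n),
                      elesy = rep(c("N", "H"), n), stringsAsFactors = FALSE)
  base <- matrix(seq_len(n) * 10, n, 3)
  xyz <- matrix(NA_real_, 2 * n, 3)
  xyz[seq(1, 2 * n, 2), ] <- base
  xyz[seq(2, 2 * n, 2), ] <- base + dirs
  conformation(atoms, xyz)
}

test_that("calc_rdc contracts the tensor with bond direction cosines", {
  A <- 6e-4
  tens <- axial_tensor(A)
  conf <- conf_with_bonds(rbind(c(0, 0, 1), c(1, 1, 1) / sqrt(3)))
  D <- calc_rdc(conf, tens, bond_vector_set(1:2), D_max = -21700)
  # bond along the unique axis picks up D_max * A_zz
  expect_equal(D[1], -21700 * A, tolerance = 1e-12)
  # the magic-angle-like direction (1,1,1)/sqrt(3) sees a traceless tensor
  expect_equal(D[2], 0, tolerance = 1e-9)
  # zero tensor -> all couplings zero
  z <- alignment_tensor(matrix(0, 3, 3))
  expect_equal(calc_rdc(conf, z, bond_vector_set(1:2)), c(0, 0))
  # missing atom is a lookup error naming the residue
  expect_error(calc_rdc(conf, tens, bond_vector_set(5)), "residue 5")
})

test_that("replica averaging obeys its exact identities", {
  toy <- fixture_toy()
  media <- fixture_media()
  conf <- toy$conformation
  tens <- lapply(media, function(md) predict_tensor(conf, md, 144))
  D1 <- calc_rdc(conf, tens$steric, toy$bonds)
  # M identical replicas average to the single-replica couplings
  rs <- replica_set(replicate(4, conf, simplify = FALSE),
                    replicate(4, tens, simplify = FALSE))
  expect_equal(replica_average_rdc(rs, toy$bonds, "steric"), D1,
               tolerance = 1e-12)
  # +d / -d cancellation across two replicas
  tens_neg <- lapply(tens, function(tt) alignment_tensor(-tt$A, tt$medium))
  rs2 <- replica_set(list(conf, conf), list(tens, tens_neg))
  expect_equal(replica_average_rdc(rs2, toy$bonds, "steric"),
               rep(0, nrow(toy$bonds)), tolerance = 1e-12)
  # permuting replica order leaves the average unchanged
  confs <- frames_at_thetas(toy, c(58, 54, 50))
  tens3 <- lapply(confs, function(cf)
    lapply(media, function(md) predict_tensor(cf, md, 144)))
  rs_a <- replica_set(confs, tens3)
  rs_b <- replica_set(confs[c(3, 1, 2)], tens3[c(3, 1, 2)])
  expect_equal(replica_average_rdc(rs_a, toy$bonds, "electrostatic"),
               replica_average_rdc(rs_b, toy$bonds, "electrostatic"),
               tolerance = 1e-12)
})

test_that("restraint energy is the alpha-weighted sum of squared residuals", {
  tab <- data.frame(resno = 1:3, pair = "N-H", medium = "steric",
                    D_exp = c(2, -1, 4), sigma = 0.1)
  class(tab) <- c("rdc_table", "data.frame")
  dcalc <- data.frame(resno = 1:3, pair = "N-H", medium = "steric",
                      D_calc = c(2, -1, 4))
  expect_equal(restraint_energy(dcalc, tab, alpha = 5), 0)
  dcalc$D_calc <- dcalc$D_calc + c(1, -2, 0.5)
  expect_equal(restraint_energy(dcalc, tab, alpha = 0), 0)
  # single-bond residual d with weight alpha gives alpha * d^2
  tab1 <- tab[1, ]
  class(tab1) <- c("rdc_table", "data.frame")
  d1 <- data.frame(resno = 1, pair = "N-H", medium = "steric", D_calc = 2.7)
  expect_equal(restraint_energy(d1, tab1, alpha = 3), 3 * 0.7^2)
  # linearity in alpha
  expect_equal(restraint_energy(dcalc, tab, 10),
               2 * restraint_energy(dcalc, tab, 5))
  # quadratic in D_calc, minimised exactly at D_exp
  for (eps in c(-1, -0.1, 0.1, 1)) {
    shifted <- dcalc
    shifted$D_calc <- tab$D_exp + eps
    expect_gt(restraint_energy(shifted, tab, 1), 0)
  }
  # unmatched experimental rows are a hard mapping error
  expect_error(restraint_energy(dcalc[-2, ], tab, 1), "mapping error")
})

test_that("analytic restraint gradient matches central finite differences", {
  toy <- fixture_toy()
  media <- fixture_media()
  rdc <- fixture_rdc()
  confs <- frames_at_thetas(toy, c(57, 51))
  # perturb coordinates so bonds are not at special orientations
  set.seed(21)
  confs <- lapply(confs, function(cf)
    conformation(cf$atoms, cf$xyz + matrix(rnorm(length(cf$xyz), sd = 0.05),
                                           ncol = 3)))
  tens <- lapply(confs, function(cf)
    lapply(media, function(md) predict_tensor(cf, md, 144)))
  rs <- replica_set(confs, tens)
  alpha <- 2
  grads <- restraint_gradient(rs, toy$bonds, rdc, alpha)
  e_of <- function(rs) {
    restraint_energy(calc_rdc_table(rs, toy$bonds, names(media)), rdc, alpha)
  }
  h <- 1e-5
  for (probe in list(c(1, 3, 1), c(1, 20, 3), c(2, 44, 2), c(2, 9, 1))) {
    m <- probe[1]; a <- probe[2]; d <- probe[3]
    num <- local({
      rp <- rs; rm_ <- rs
      rp$conformations[[m]]$xyz[a, d] <- rp$conformations[[m]]$xyz[a, d] + h
      rm_$conformations[[m]]$xyz[a, d] <- rm_$conformations[[m]]$xyz[a, d] - h
      (e_of(rp) - e_of(rm_)) / (2 * h)
    })
    expect_equal(grads[[m]][a, d], num, tolerance = 1e-5)
  }
})

test_that("with M = 1 the replica-averaged restraint is the single-structure one", {
  toy <- fixture_toy()
  media <- fixture_media()
  rdc <- fixture_rdc()
  conf <- toy$conformation
  tens <- lapply(media, function(md) predict_tensor(conf, md, 144))
  rs1 <- replica_set(list(conf), list(tens))
  D_single <- do.call(rbind, lapply(names(media), function(med) {
    data.frame(resno = toy$bonds$resno, pair = toy$bonds$pair, medium = med,
               D_calc = calc_rdc(conf, tens[[med]], toy$bonds))
  }))
  expect_equal(restraint_energy(calc_rdc_table(rs1, toy$bonds, names(media)),
                                rdc, 7),
               restraint_energy(D_single, rdc, 7), tolerance = 1e-12)
})

test_that("Q factors follow the Bax normalisation", {
  tab <- data.frame(resno = 1:4, pair = "N-H",
                    medium = rep(c("steric", "electrostatic"), each = 2),
                    D_exp = c(3, -4, 2, 1), sigma = 0.1)
  class(tab) <- c("rdc_table", "data.frame")
  exact <- data.frame(resno = tab$resno, pair = tab$pair,
                      medium = tab$medium, D_calc = tab$D_exp)
  q <- q_factor(exact, tab)
  expect_equal(q$steric, 0)
  expect_equal(q$pooled, 0)
  # D_calc identically zero collapses the ratio to 1
  zero <- exact; zero$D_calc <- 0
  expect_equal(q_factor(zero, tab)$pooled, 1)
  # joint rescaling of D_calc and D_exp leaves Q unchanged
  off <- exact; off$D_calc <- tab$D_exp + c(0.5, -0.5, 0.2, 0)
  q1 <- q_factor(off, tab)$pooled
  tab_s <- tab; tab_s$D_exp <- 3 * tab$D_exp
  off_s <- off; off_s$D_calc <- 3 * off$D_calc
  expect_equal(q_factor(off_s, tab_s)$pooled, q1, tolerance = 1e-12)
  # all-zero experimental couplings are an error, not Q = Inf
  tab_z <- tab; tab_z$D_exp <- 0
  expect_error(q_factor(exact, tab_z), "undefined Q")
})

test_that("calculated couplings export as TSV mirroring the table", {
  toy <- fixture_toy()
  rdc <- fixture_rdc()
  conf <- toy$conformation
  tens <- lapply(fixture_media(), function(md) predict_tensor(conf, md, 144))
  rs <- replica_set(list(conf), list(tens))
  Dtab <- calc_rdc_table(rs, toy$bonds, names(fixture_media()))
  path <- tempfile(fileext = ".tsv")
  export_rdc_table(rdc, Dtab, path)
  back <- read.delim(path)
  expect_equal(nrow(back), nrow(rdc))
  expect_true("D_calc" %in% names(back))
  expect_equal(back$D_exp, rdc$D_exp, tolerance = 1e-9)
  unlink(path)
})
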