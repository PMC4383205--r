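#' Coarse-grained two-domain conformational potential
#'
#' A desk-scale stand-in for a molecular-mechanics force field: a particle
#' chain with two quasi-rigid domains joined by a hinge.  The energy is a
#' sum of (i) harmonic chain bonds between consecutive residues, (ii)
#' harmonic restraints on all intra-domain residue-residue distances to
#' their reference values (domain rigidity), and (iii) a smooth double-well
#' term in the interdomain breathing angle theta with configurable basin
#' centres, widths and depths.  The double well is built as
#' `-kB*T0*log` of a two-Gaussian mixture, so at temperature T0 the basin
#' widths equal the stated widths and basin weights follow the depths
#' analytically — which makes sampler occupancies checkable against closed
#' forms.
#'
#' @param theta_ground,theta_minor basin centres in degrees, in (0, 180).
#' @param width_ground,width_minor basin widths (degrees): the standard
#'   deviation of theta within each basin at temperature `T0`.
#' @param depth_ground,depth_minor basin offsets (kJ/mol); a deeper (more
#'   negative) basin is more populated.
#' @param barrier_height Gaussian barrier (kJ/mol) added at the midpoint
#'   between the basin centres: hinge conformations between the two
#'   states are genuinely rare, as in a two-state system.
#' @param barrier_width width (degrees) of the barrier bump.
#' @param k_bond chain-bond stiffness (kJ/mol/A^2).
#' @param k_domain intra-domain distance-restraint stiffness (kJ/mol/A^2).
#' @param T0 reference temperature (K) of the double-well construction.
#' @return object of class `toy_potential`.
#' @export
toy_potential <- function(theta_ground = 58, theta_minor = 49,
                          width_ground = 0.8, width_minor = 0.8,
                          depth_ground = 0, depth_minor = 0,
                          barrier_height = 12, barrier_width = 1.5,
                          k_bond = 10, k_domain = 10, T0 = 310) {
  stopifnot(theta_ground > 0, theta_ground < 180,
            theta_minor > 0, theta_minor < 180,
            width_ground > 0, width_minor > 0, barrier_height >= 0,
            barrier_width > 0, k_bond > 0, k_domain > 0,
            T0 > 0)
  structure(list(theta_ground = theta_ground, theta_minor = theta_minor,
                 width_ground = width_ground, width_minor = width_minor,
                 depth_ground = depth_ground, depth_minor = depth_minor,
                 barrier_height = barrier_height,
                 barrier_width = barrier_width,
                 k_bond = k_bond, k_domain = k_domain, T0 = T0),
            class = "toy_potential")
}

#' @rdname toy_potential
#' @param pot a `toy_potential`.
#' @param theta breathing angle(s) in degrees.
#' @return hinge double-well energy in kJ/mol (vectorised over `theta`).
#' @export
hinge_energy <- function(pot, theta) {
  kT0 <- kB_kJmol * pot$T0
  a <- -pot$depth_ground / kT0 - (theta - pot$theta_ground)^2 /
    (2 * pot$width_ground^2)
  b <- -pot$depth_minor / kT0 - (theta - pot$theta_minor)^2 /
    (2 * pot$width_minor^2)
  m <- pmax(a, b)
  mid <- (pot$theta_ground + pot$theta_minor) / 2
  -kT0 * (m + log(exp(a - m) + exp(b - m))) +
    pot$barrier_height * exp(-(theta - mid)^2 / (2 * pot$barrier_width^2))
}

# reference pair lists for the bonded terms, taken from a reference
# conformation so that the built geometry is an exact minimum
make_pair_terms <- function(toy) {
  xyzN <- toy$conformation$xyz[toy$idxN, , drop = FALSE]
  nres <- length(toy$idxN)
  chain <- cbind(seq_len(nres - 1), 2:nres)
  dom_pairs <- do.call(rbind, lapply(list(toy$domains$A, toy$domains$hinge,
                                          toy$domains$B), function(res) {
    k <- match(res, toy$resno)
    if (length(k) < 2) return(NULL)
    t(utils::combn(k, 2))
  }))
  # alpha-domain/hinge cross restraints rigidify the alpha-domain against
  # the hinge, leaving the beta-domain swing as the single soft hinge mode
  kA <- match(toy$domains$A, toy$resno)
  kh <- match(toy$domains$hinge, toy$resno)
  dom_pairs <- rbind(dom_pairs, as.matrix(expand.grid(kA, kh)))
  # chain bonds already included in domain pairs are dropped there
  key_c <- paste(chain[, 1], chain[, 2])
  dom_pairs <- dom_pairs[!(paste(dom_pairs[, 1], dom_pairs[, 2]) %in% key_c), ,
                         drop = FALSE]
  d0 <- function(p) sqrt(rowSums((xyzN[p[, 1], , drop = FALSE] -
                                  xyzN[p[, 2], , drop = FALSE])^2))
  list(chain = cbind(chain, d0 = d0(chain)),
       domain = cbind(dom_pairs, d0 = d0(dom_pairs)))
}

#' Potential energy of one conformation
#'
#' Full bonded + hinge double-well energy of a conformation under the toy
#' potential attached to a sampler system (see [build_system()]).
#'
#' @param xyz n_atoms x 3 coordinate matrix (or a [conformation()]).
#' @param system a sampler system from [build_system()].
#' @return energy in kJ/mol.
#' @export
potential_energy <- function(xyz, system) {
  if (inherits(xyz, "conformation")) xyz <- xyz$xyz
  pot <- system$potential
  xyzN <- xyz[system$idxN, , drop = FALSE]
  pair_e <- function(p, k) {
    d <- sqrt(rowSums((xyzN[p[, 1], , drop = FALSE] -
                       xyzN[p[, 2], , drop = FALSE])^2))
    k * sum((d - p[, 3])^2)
  }
  e <- pair_e(system$pairs$chain, pot$k_bond) +
    pair_e(system$pairs$domain, pot$k_domain)
  th <- theta_from_xyz(xyz, system)
  e + hinge_energy(pot, th)
}

# breathing angle from raw coordinates given the system's region atom rows
theta_from_xyz <- function(xyz, system) {
  c1 <- colMeans(xyz[system$region_rows[[1]], , drop = FALSE])
  c2 <- colMeans(xyz[system$region_rows[[2]], , drop = FALSE])
  c3 <- colMeans(xyz[system$region_rows[[3]], , drop = FALSE])
  angle_at_vertex(c1, c2, c3)
}
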