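#' Synthetic two-domain test systems with known ground truth
#'
#' Generates every input the pipeline consumes — a coarse-grained
#' two-domain protein with a hinge, two-state conformational ensembles with
#' a known minor-state population, replica/population-averaged noisy RDC
#' tables in a steric and a charged medium, HNHA intensity tables from
#' known J values, and NOE bound tables — together with the ground truth
#' needed to verify every downstream stage.
#'
#' @param n_domain residues per domain.
#' @param n_hinge hinge residues.
#' @param theta_ground,theta_minor basin breathing angles (degrees) of the
#'   ground ("locked") and minor ("unlocked") states.
#' @param minor_population minor-state population p in (0, 1), or 0 for a
#'   pure ground-state system.
#' @param jitter_sd isotropic thermal jitter on residue positions (A).
#' @param rdc_noise relative RDC noise (fraction of the per-medium RMS
#'   coupling).
#' @param arm_length distance from the hinge centre to each domain centroid
#'   (A).
#' @param seed integer seed; every generator output is deterministic in it.
#' @return object of class `generator_spec`.
#' @export
generator_spec <- function(n_domain = 12, n_hinge = 4, theta_ground = 58,
                           theta_minor = 49, minor_population = 0.13,
                           jitter_sd = 0.25, rdc_noise = 0.05,
                           arm_length = 10, seed = 0L) {
  stopifnot(n_domain >= 4, n_hinge >= 2,
            minor_population >= 0, minor_population < 1,
            jitter_sd >= 0, rdc_noise >= 0, arm_length > 0)
  # basin centres must be separated well beyond the jitter-induced theta
  # spread for the two-state picture to be meaningful
  theta_spread <- max(0.2, rad2deg(jitter_sd / sqrt(n_domain) / arm_length) * 3)
  if (abs(theta_ground - theta_minor) <= 3 * theta_spread) {
    stop("basin centres must differ by more than 3x the jitter-induced ",
         "theta spread", call. = FALSE)
  }
  structure(list(n_domain = as.integer(n_domain), n_hinge = as.integer(n_hinge),
                 theta_ground = theta_ground, theta_minor = theta_minor,
                 minor_population = minor_population, jitter_sd = jitter_sd,
                 rdc_noise = rdc_noise, arm_length = arm_length,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

# mean-centred helical offsets in a local (e1, e2, axis) frame
helix_offsets <- function(n, radius = 2.5, rise = 1.6, step = 1.75) {
  i <- seq_len(n)
  off <- cbind(radius * cos(step * i), radius * sin(step * i),
               rise * ((n + 1) / 2 - i))   # last residue closest to the hinge
  sweep(off, 2, colMeans(off))
}

#' Build the reference two-domain toy protein
#'
#' Two helical domains of `n_domain` residues at `arm_length` from a
#' central hinge, joined by `n_hinge` hinge residues, posed at the
#' ground-state breathing angle.  Each residue carries an `N` particle and
#' an `H` particle at 1.02 A in a deterministic, orientationally diverse
#' direction, giving a pseudo N-H bond-vector set; `N` particles carry a
#' deterministic partial-charge pattern used by electrostatic media.
#'
#' @param spec a [generator_spec()].
#' @return object of class `toy_protein`: the reference [conformation()],
#'   a [region_definition()] (alpha-domain / hinge / beta-domain), the
#'   [bond_vector_set()], domain membership, and sampler bookkeeping
#'   (pivot atoms, atom-row indices).
#' @export
make_toy_protein <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "generator_spec"))
  nd <- spec$n_domain; nh <- spec$n_hinge
  th2 <- deg2rad(spec$theta_ground) / 2
  u_A <- c(sin(th2), cos(th2), 0)
  u_B <- c(-sin(th2), cos(th2), 0)
  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  frame_for <- function(u) {
    e1 <- unit_vector(cross3(c(0, 0, 1), u))
    e2 <- cross3(u, e1)
    cbind(e1, e2, u)
  }
  dom_xyz <- function(u) {
    off <- helix_offsets(nd)
    sweep(off %*% t(frame_for(u)), 2, spec$arm_length * u, `+`)
  }
  xyz_A <- dom_xyz(u_A)
  xyz_B <- dom_xyz(u_B)[rev(seq_len(nd)), , drop = FALSE]  # first B residue nearest hinge
  i <- seq_len(nh)
  hinge <- cbind(1.4 * (i - (nh + 1) / 2),
                 0.9 * cos(2.1 * i), 0.8 * sin(1.3 * i))
  hinge <- sweep(hinge, 2, colMeans(hinge))                # hinge COM at origin
  xyzN <- rbind(xyz_A, hinge[rev(i), , drop = FALSE], xyz_B)
  nres <- nd + nh + nd
  resno <- seq_len(nres)
  hdir <- fibonacci_sphere(nres)
  xyzH <- xyzN + 1.02 * hdir
  q <- 0.4 * sin(1.7 * resno)
  q <- q - mean(q)
  atoms <- data.frame(
    chain = "A",
    resno = rep(resno, each = 2),
    resid = "ALA",
    elety = rep(c("N", "H"), nres),
    elesy = rep(c("N", "H"), nres),
    charge = as.vector(rbind(q, 0)),
    stringsAsFactors = FALSE)
  xyz <- matrix(NA_real_, 2 * nres, 3)
  xyz[seq(1, 2 * nres, 2), ] <- xyzN
  xyz[seq(2, 2 * nres, 2), ] <- xyzH
  conf <- conformation(atoms, xyz)
  dom_A <- resno[1:nd]
  dom_h <- resno[(nd + 1):(nd + nh)]
  dom_B <- resno[(nd + nh + 1):nres]
  regions <- region_definition(region1 = dom_A, region2 = dom_h,
                               region3 = dom_B, atom_filter = "N")
  idxN <- seq(1, 2 * nres, 2)
  idxH <- seq(2, 2 * nres, 2)
  toy <- structure(list(
    conformation = conf,
    regions = regions,
    bonds = bond_vector_set(resno),
    domains = list(A = dom_A, hinge = dom_h, B = dom_B),
    resno = resno, idxN = idxN, idxH = idxH,
    pivots = c(A = idxN[nd], B = idxN[nd + nh + 1]),
    spec = spec), class = "toy_protein")
  toy
}

# atom rows belonging to each domain (N and H move rigidly together)
domain_atom_rows <- function(toy, which_domain) {
  res <- toy$domains[[which_domain]]
  k <- match(res, toy$resno)
  sort(c(toy$idxN[k], toy$idxH[k]))
}

# rotate domain B (or A) about its pivot atom so the chain link to the
# hinge is preserved; axis/angle in the global frame
rotate_domain_xyz <- function(xyz, rows, pivot_row, axis, angle_deg) {
  R <- rotation_matrix(axis, angle_deg)
  pv <- xyz[pivot_row, ]
  xyz[rows, ] <- sweep(sweep(xyz[rows, , drop = FALSE], 2, pv) %*% t(R), 2,
                       pv, `+`)
  xyz
}

# reference minor-state conformation: rotate domain B in-plane about its
# pivot until the breathing angle equals the minor basin centre
minor_reference <- function(toy) {
  rows <- domain_atom_rows(toy, "B")
  th_target <- toy$spec$theta_minor
  regions <- toy$regions
  f <- function(phi) {
    xyz <- rotate_domain_xyz(toy$conformation$xyz, rows, toy$pivots["B"],
                             c(0, 0, 1), phi)
    breathing_angle(conformation(toy$conformation$atoms, xyz), regions) -
      th_target
  }
  sol <- stats::uniroot(f, interval = c(-60, 60), tol = 1e-10)
  xyz <- rotate_domain_xyz(toy$conformation$xyz, rows, toy$pivots["B"],
                           c(0, 0, 1), sol$root)
  conformation(toy$conformation$atoms, xyz)
}

#' Generate a two-state ensemble with known labels
#'
#' Frames are drawn from the ground and minor basins with probabilities
#' `(1 - p, p)`, each a rigid pose at the basin's breathing angle with
#' isotropic Gaussian jitter applied per residue (the N-H pair moves
#' rigidly, so bond orientations stay state-defined).
#'
#' @param toy a [make_toy_protein()] result.
#' @param n number of frames (>= 1).
#' @param seed integer seed (defaults to the generator spec's).
#' @return list with `ensemble` (an [ensemble()] whose `frame_info` holds
#'   the state label and breathing angle per frame) and `truth` (class
#'   `ground_truth`: labels, true p, basin centres, the midpoint basin
#'   boundary, and the two reference conformations).
#' @export
make_two_state_ensemble <- function(toy, n, seed = NULL) {
  stopifnot(inherits(toy, "toy_protein"), n >= 1)
  spec <- toy$spec
  seed <- seed %||% spec$seed
  ref_g <- toy$conformation
  ref_m <- minor_reference(toy)
  nres <- length(toy$resno)
  with_local_seed(seed, function() {
    labels <- runif(n) < spec$minor_population
    xyz <- array(NA_real_, c(n, n_atoms(ref_g), 3))
    for (k in seq_len(n)) {
      base <- if (labels[k]) ref_m$xyz else ref_g$xyz
      jit <- matrix(rnorm(3 * nres, sd = spec$jitter_sd), nres, 3)
      base[toy$idxN, ] <- base[toy$idxN, ] + jit
      base[toy$idxH, ] <- base[toy$idxH, ] + jit
      xyz[k, , ] <- base
    }
    ens <- new_ensemble(ref_g$atoms, xyz)
    theta <- vapply(seq_len(n), function(k)
      breathing_angle(get_conformation(ens, k), toy$regions), numeric(1))
    ens$frame_info <- data.frame(
      state = ifelse(labels, "minor", "ground"), theta = theta)
    truth <- structure(list(
      labels = ifelse(labels, "minor", "ground"),
      p = spec$minor_population,
      theta_ground = spec$theta_ground, theta_minor = spec$theta_minor,
      boundary = (spec$theta_ground + spec$theta_minor) / 2,
      ref_ground = ref_g, ref_minor = ref_m), class = "ground_truth")
    list(ensemble = ens, truth = truth)
  })
}

#' Calibrated default steric and electrostatic media for a toy protein
#'
#' One medium of each kind, with the overall alignment scale of each set so
#' that back-calculated couplings on the ground-state reference have the
#' requested RMS magnitude (see [calibrate_medium_scale()]).
#'
#' @param toy a [make_toy_protein()] result.
#' @param target_rms RMS coupling magnitude (Hz).
#' @param n_orient orientation-grid resolution.
#' @return named list of two calibrated [medium_spec()] objects.
#' @export
calibrate_default_media <- function(toy, target_rms = 8, n_orient = 256) {
  base <- list(steric = medium_spec("steric", spacing = 120),
               electrostatic = medium_spec("electrostatic", spacing = 120,
                                           wall_charge = 2, debye_length = 15))
  lapply(base, function(m)
    calibrate_medium_scale(toy$conformation, m, toy$bonds,
                           target_rms = target_rms, n_orient = n_orient))
}

#' Synthesize population-averaged RDC tables
#'
#' For each medium, back-calculates couplings frame by frame (each frame
#' with its own shape/charge-predicted tensor), averages over the ensemble
#' — i.e. a population-weighted mean over the two states — and adds
#' Gaussian noise at the generator's relative level; the `sigma` column
#' records the noise sd.  The clean (noise-free) averages are attached as
#' `attr(, "clean")`.
#'
#' @param ens an [ensemble()] from [make_two_state_ensemble()].
#' @param toy the [make_toy_protein()] result.
#' @param media named list of calibrated [medium_spec()] objects.
#' @param seed integer seed.
#' @param n_orient orientation-grid resolution for tensor prediction.
#' @return an `rdc_table` covering all media (rows keyed by residue, pair,
#'   medium).
#' @export
make_rdc_tables <- function(ens, toy, media, seed = NULL, n_orient = 256) {
  stopifnot(inherits(ens, "ensemble"), inherits(toy, "toy_protein"))
  spec <- toy$spec
  seed <- seed %||% (spec$seed + 1L)
  bonds <- toy$bonds
  clean <- ensemble_average_rdc(ens, bonds, media, n_orient = n_orient)
  with_local_seed(seed, function() {
    tabs <- lapply(names(media), function(nmed) {
      Dbar <- clean[[nmed]]
      sdn <- spec$rdc_noise * sqrt(mean(Dbar^2))
      data.frame(resno = bonds$resno, pair = bonds$pair, medium = nmed,
                 D_exp = Dbar + rnorm(length(Dbar), sd = sdn),
                 sigma = max(sdn, 1e-6), stringsAsFactors = FALSE)
    })
    tab <- validate_rdc_table(do.call(rbind, tabs))
    attr(tab, "clean") <- clean
    tab
  })
}

#' Synthesize an HNHA intensity table from known J couplings
#'
#' Inverts the tangent-squared intensity-ratio relation: diagonal
#' intensities near 1, cross intensities `-tan^2(2 pi xi J)`, both with
#' multiplicative Gaussian noise.
#'
#' @param J true couplings (Hz), all in (0, 12).
#' @param noise relative intensity noise (e.g. 0.05).
#' @param seed integer seed.
#' @param xi HNHA delay in seconds.
#' @param resno residue indices (default `seq_along(J)`).
#' @return an `hnha_table` with `attr(, "true_J")`.
#' @export
make_hnha_table <- function(J, noise = 0.05, seed = 0L, xi = 0.01305,
                            resno = seq_along(J)) {
  if (any(J <= 0 | J >= 12)) {
    stop("generation error: true J values must lie in (0, 12) Hz",
         call. = FALSE)
  }
  with_local_seed(seed, function() {
    n <- length(J)
    I_diag <- 1 * (1 + noise * rnorm(n))
    I_cross <- -tan(2 * pi * xi * J)^2 * I_diag * (1 + noise * rnorm(n))
    tab <- data.frame(resno = as.integer(resno), resid = "ALA",
                      I_cross = I_cross, I_diag = I_diag, noise = noise,
                      stringsAsFactors = FALSE)
    class(tab) <- c("hnha_table", "data.frame")
    attr(tab, "true_J") <- J
    tab
  })
}

#' Synthesize an NOE bound table from an ensemble
#'
#' Bounds are the observed maximum distance plus `slack` for a random
#' subset of residue pairs (satisfied by construction); optionally a stated
#' fraction of bounds is made deliberately violated in every structure by
#' setting them below the observed minimum distance.
#'
#' @param ens an [ensemble()].
#' @param coverage fraction of candidate (non-adjacent N, N) pairs to use,
#'   in (0, 1].
#' @param slack added to the observed maximum distance (A).
#' @param violated_fraction fraction of selected pairs turned into
#'   always-violated bounds.
#' @param seed integer seed.
#' @return an `noe_table`.
#' @export
make_noe_table <- function(ens, coverage = 0.3, slack = 0.5,
                           violated_fraction = 0, seed = 0L) {
  stopifnot(coverage > 0, coverage <= 1,
            violated_fraction >= 0, violated_fraction < 1)
  atoms <- ens$atoms
  iN <- which(atoms$elety == "N")
  res <- atoms$resno[iN]
  cand <- t(utils::combn(seq_along(iN), 2))
  cand <- cand[abs(res[cand[, 1]] - res[cand[, 2]]) >= 2, , drop = FALSE]
  with_local_seed(seed, function() {
    n_pick <- max(1, round(coverage * nrow(cand)))
    pick <- cand[sample(nrow(cand), n_pick), , drop = FALSE]
    a1 <- iN[pick[, 1]]; a2 <- iN[pick[, 2]]
    nm <- n_models(ens)
    dmin <- rep(Inf, n_pick); dmax <- rep(-Inf, n_pick)
    for (k in seq_len(nm)) {
      d <- sqrt(rowSums((matrix(ens$xyz[k, a1, ], ncol = 3) -
                         matrix(ens$xyz[k, a2, ], ncol = 3))^2))
      dmin <- pmin(dmin, d); dmax <- pmax(dmax, d)
    }
    bound <- dmax + slack
    n_viol <- round(violated_fraction * n_pick)
    if (n_viol > 0) {
      vi <- sample(n_pick, n_viol)
      bound[vi] <- pmax(0.5, dmin[vi] - 2 * slack - 1)
    }
    tab <- data.frame(resno1 = atoms$resno[a1], atom1 = atoms$elety[a1],
                      resno2 = atoms$resno[a2], atom2 = atoms$elety[a2],
                      bound = bound, stringsAsFactors = FALSE)
    class(tab) <- c("noe_table", "data.frame")
    tab
  })
}
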