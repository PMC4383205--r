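#' Simulated-annealing schedules and protocol arithmetic
#'
#' Describes the cycle structure of the restrained annealing protocol:
#' temperature alternates between `T_high` and `T_low` (stepwise) over
#' `cycles` cycles; each cycle nominally spans `cycle_ps` picoseconds of
#' dynamics (`count_integrator_steps()` converts that to integrator steps
#' at `timestep_fs`), realised at desk scale as `sweeps_high` + `sweeps_low`
#' Monte Carlo sweeps; frames are collected only in the final `collect_ps`
#' of the low-temperature segment, at `frames_per_ps` per replica, and only
#' in the final `cycles_retained` cycles.
#'
#' @param T_low,T_high annealing temperatures (K), `T_high > T_low > 0`.
#' @param cycles number of annealing cycles (>= 1).
#' @param cycle_ps nominal duration of one cycle (ps).
#' @param timestep_fs nominal integrator time step (fs).
#' @param sweeps_high,sweeps_low MC sweeps per hot / annealed segment.
#' @param collect_ps collection window at the end of a cycle (ps).
#' @param frames_per_ps frames collected per ps per replica.
#' @param cycles_retained number of final cycles that contribute frames.
#' @param equil_sweeps sweeps of the initial alpha-ramp equilibration.
#' @return object of class `annealing_schedule`.
#' @export
annealing_schedule <- function(T_low = 310, T_high = 500, cycles = 50,
                               cycle_ps = 250, timestep_fs = 2,
                               sweeps_high = 30, sweeps_low = 40,
                               collect_ps = 50, frames_per_ps = 1,
                               cycles_retained = 30, equil_sweeps = 100) {
  if (!(T_high > T_low && T_low > 0)) {
    stop("schedule error: need T_high > T_low > 0", call. = FALSE)
  }
  stopifnot(cycles >= 1, cycle_ps > 0, timestep_fs > 0, collect_ps > 0,
            frames_per_ps > 0, sweeps_high >= 1, sweeps_low >= 1)
  if (cycles_retained > cycles) {
    stop("schedule error: cycles_retained cannot exceed cycles", call. = FALSE)
  }
  if (collect_ps > cycle_ps) {
    stop("schedule error: collection window exceeds the cycle", call. = FALSE)
  }
  structure(list(T_low = T_low, T_high = T_high, cycles = as.integer(cycles),
                 cycle_ps = cycle_ps, timestep_fs = timestep_fs,
                 sweeps_high = as.integer(sweeps_high),
                 sweeps_low = as.integer(sweeps_low),
                 collect_ps = collect_ps, frames_per_ps = frames_per_ps,
                 cycles_retained = as.integer(cycles_retained),
                 equil_sweeps = as.integer(equil_sweeps)),
            class = "annealing_schedule")
}

schedule_from_config <- function(cfg) {
  s <- cfg$sampler
  annealing_schedule(T_low = s$T_low, T_high = s$T_high, cycles = s$cycles,
                     cycle_ps = s$cycle_ps, timestep_fs = s$timestep_fs,
                     sweeps_high = s$sweeps_high, sweeps_low = s$sweeps_low,
                     collect_ps = s$collect_ps,
                     frames_per_ps = s$frames_per_ps,
                     cycles_retained = s$cycles_retained,
                     equil_sweeps = s$equil_sweeps)
}

#' @rdname annealing_schedule
#' @param schedule an `annealing_schedule`.
#' @return integrator steps per cycle (`cycle_ps / timestep`); the time
#'   step must divide the cycle duration exactly.
#' @export
count_integrator_steps <- function(schedule) {
  stopifnot(inherits(schedule, "annealing_schedule"))
  steps <- schedule$cycle_ps * 1000 / schedule$timestep_fs
  if (abs(steps - round(steps)) > 1e-9) {
    stop("schedule error: time step does not divide the cycle duration",
         call. = FALSE)
  }
  as.integer(round(steps))
}

#' @rdname annealing_schedule
#' @param replicas replica count M.
#' @return total frames the collection rule emits:
#'   `frames_per_ps * collect_ps * cycles_retained * replicas`.
#' @export
collection_count <- function(schedule, replicas) {
  stopifnot(inherits(schedule, "annealing_schedule"), replicas >= 1)
  n_per <- schedule$frames_per_ps * schedule$collect_ps
  if (abs(n_per - round(n_per)) > 1e-9) {
    stop("schedule error: frames per cycle is not an integer", call. = FALSE)
  }
  as.integer(round(n_per)) * schedule$cycles_retained * as.integer(replicas)
}

#' Assemble a restrained sampling system
#'
#' Binds together everything one annealing run needs: the toy protein and
#' its potential, the experimental RDC table, the (calibrated) alignment
#' media, and the restraint configuration.  Precomputes the pair lists and
#' index maps the Monte Carlo kernel uses.
#'
#' @param toy a [make_toy_protein()] result.
#' @param potential a [toy_potential()].
#' @param rdc an `rdc_table` (its media must all appear in `media`).
#' @param media named list of [medium_spec()] objects.
#' @param M replica count (>= 1).
#' @param alpha target restraint weight (kJ/mol/Hz^2).
#' @param alpha_start,alpha_ramp_factor geometric alpha ramp parameters.
#' @param min_acceptance the ramp stops early if move acceptance drops
#'   below this fraction.
#' @param D_max dipolar constant (Hz).
#' @param jitter_sd,rot_sd proposal widths (A, degrees).
#' @param n_orient orientation-grid resolution for tensor prediction.
#' @return object of class `sampler_system`.
#' @export
build_system <- function(toy, potential = toy_potential(), rdc = NULL,
                         media = NULL, M = 16, alpha = 60,
                         alpha_start = 5, alpha_ramp_factor = 1.6,
                         min_acceptance = 0.2, D_max = -21700,
                         jitter_sd = 0.15, rot_sd = 2, n_orient = 144) {
  stopifnot(inherits(toy, "toy_protein"), inherits(potential, "toy_potential"),
            M >= 1, alpha >= 0, D_max != 0)
  atoms <- toy$conformation$atoms
  nres <- length(toy$resno)
  sys <- list(toy = toy, potential = potential, rdc = rdc, media = media,
              M = as.integer(M), alpha_target = alpha,
              alpha_start = alpha_start, alpha_ramp = alpha_ramp_factor,
              min_acceptance = min_acceptance, D_max = D_max,
              jitter_sd = jitter_sd, rot_sd = rot_sd, n_orient = n_orient,
              idxN = toy$idxN, idxH = toy$idxH, nres = nres,
              charges = atoms$charge, dirs = fibonacci_sphere(n_orient))
  sys$region_rows <- region_atom_rows(atoms, toy$regions)
  sys$region_n <- vapply(sys$region_rows, length, 1L)
  # residue -> region (1 alpha-domain, 2 hinge, 3 beta-domain)
  sys$region_of <- integer(nres)
  sys$region_of[match(toy$regions$region1, toy$resno)] <- 1L
  sys$region_of[match(toy$regions$region2, toy$resno)] <- 2L
  sys$region_of[match(toy$regions$region3, toy$resno)] <- 3L
  sys$pairs <- make_pair_terms(toy)
  # flat pair arrays with stiffness, plus per-residue incidence lists
  P <- rbind(cbind(sys$pairs$chain, k = potential$k_bond),
             cbind(sys$pairs$domain, k = potential$k_domain))
  sys$P1 <- as.integer(P[, 1]); sys$P2 <- as.integer(P[, 2])
  sys$Pd0 <- P[, 3]; sys$Pk <- P[, 4]
  sys$res_pairs <- lapply(seq_len(nres), function(r)
    which(sys$P1 == r | sys$P2 == r))
  sys$res_partners <- lapply(seq_len(nres), function(r) {
    pr <- sys$res_pairs[[r]]
    ifelse(sys$P1[pr] == r, sys$P2[pr], sys$P1[pr])
  })
  sys$dom_rows <- list(A = domain_atom_rows(toy, "A"),
                       B = domain_atom_rows(toy, "B"))
  sys$dom_res <- list(A = match(toy$domains$A, toy$resno),
                      B = match(toy$domains$B, toy$resno))
  sys$pivots <- toy$pivots
  if (!is.null(rdc)) {
    stopifnot(inherits(rdc, "rdc_table"), !is.null(media))
    meds <- unique(rdc$medium)
    if (!all(meds %in% names(media))) {
      stop("rdc table references media missing from `media`", call. = FALSE)
    }
    sys$meds <- meds
    key_b <- paste(toy$bonds$resno, toy$bonds$pair)
    sys$rdc_map <- lapply(meds, function(med) {
      rows <- which(rdc$medium == med)
      bi <- match(paste(rdc$resno[rows], rdc$pair[rows]), key_b)
      if (anyNA(bi)) {
        stop("mapping error: RDC row without a matching bond vector",
             call. = FALSE)
      }
      list(Dexp = rdc$D_exp[rows], bond = bi)
    })
    names(sys$rdc_map) <- meds
  }
  class(sys) <- "sampler_system"
  sys
}

# --- sampler state ---------------------------------------------------------

#' Initialise a sampler state
#'
#' All replicas start from the toy protein's reference conformation;
#' per-replica alignment tensors and couplings are computed up front.
#' The state is an environment mutated in place by [mc_move()] and the
#' annealing driver.
#'
#' @param system a [build_system()] result.
#' @param alpha initial restraint weight (defaults to the ramp start).
#' @return environment of class `sampler_state`.
#' @export
init_sampler <- function(system, alpha = system$alpha_start) {
  st <- new.env(parent = emptyenv())
  st$sys <- system
  M <- system$M
  st$M <- M
  st$X <- replicate(M, system$toy$conformation$xyz, simplify = FALSE)
  st$alpha <- alpha
  st$accepted <- 0L
  st$attempted <- 0L
  resync_state(st)
  class(st) <- c("sampler_state", "environment")
  st
}

ss_from_dbar <- function(sys, Dbar) {
  sum(vapply(sys$meds, function(med) {
    map <- sys$rdc_map[[med]]
    sum((map$Dexp - Dbar[[med]][map$bond])^2)
  }, numeric(1)))
}

# full (non-incremental) recomputation of all bookkeeping from coordinates
resync_state <- function(st) {
  sys <- st$sys
  M <- st$M
  st$com <- lapply(seq_len(M), function(m) {
    t(vapply(sys$region_rows, function(r)
      colMeans(st$X[[m]][r, , drop = FALSE]), numeric(3)))
  })
  st$theta <- vapply(seq_len(M), function(m)
    angle_at_vertex(st$com[[m]][1, ], st$com[[m]][2, ], st$com[[m]][3, ]),
    numeric(1))
  st$EpotB <- vapply(seq_len(M), function(m) {
    xyzN <- st$X[[m]][sys$idxN, , drop = FALSE]
    d <- sqrt(rowSums((xyzN[sys$P1, , drop = FALSE] -
                       xyzN[sys$P2, , drop = FALSE])^2))
    sum(sys$Pk * (d - sys$Pd0)^2)
  }, numeric(1))
  st$Ehinge <- hinge_energy(sys$potential, st$theta)
  if (!is.null(sys$rdc)) {
    # per-replica caches: orientation projections (dirs x atoms) and unit
    # bond vectors
    st$tP <- lapply(seq_len(M), function(m) tcrossprod(sys$dirs, st$X[[m]]))
    st$V <- lapply(seq_len(M), function(m) {
      V <- st$X[[m]][sys$idxH, , drop = FALSE] -
        st$X[[m]][sys$idxN, , drop = FALSE]
      V / sqrt(rowSums(V^2))
    })
    refresh_tensors(st, seq_len(M))
  } else {
    st$SS <- 0
  }
  invisible(st)
}

# recompute tensors and couplings for the given replicas from the cached
# projections, then the global residual sum of squares
refresh_tensors <- function(st, which_m) {
  sys <- st$sys
  if (is.null(st$D)) {
    st$D <- lapply(sys$meds, function(m) matrix(0, st$M, sys$nres))
    names(st$D) <- sys$meds
    st$tensors <- replicate(st$M, list(), simplify = FALSE)
  }
  for (m in which_m) {
    V <- st$V[[m]]
    for (med in sys$meds) {
      w <- weights_from_projections(st$tP[[m]], sys$charges, sys$media[[med]])
      A <- tensor_from_weights(w, sys$dirs, sys$media[[med]])
      st$tensors[[m]][[med]] <- A
      st$D[[med]][m, ] <- sys$D_max * rowSums((V %*% A) * V)
    }
  }
  st$Dbar <- lapply(st$D, colMeans)
  st$SS <- ss_from_dbar(sys, st$Dbar)
  invisible(st)
}

#' Metropolis acceptance decision
#'
#' Accepts an energy change `dE` (kJ/mol) at temperature `T` (K) with
#' probability `min(1, exp(-dE / kB T))`.
#'
#' @param dE energy change (kJ/mol); `+Inf` is always rejected.
#' @param T temperature (K), > 0.
#' @param u uniform random number (drawn if not supplied).
#' @return logical.
#' @export
metropolis_accept <- function(dE, T, u = runif(1)) {
  stopifnot(T > 0)
  if (is.nan(dE)) stop("numerical error: NaN energy change", call. = FALSE)
  dE <= 0 || u < exp(-dE / (kB_kJmol * T))
}

# energy bookkeeping views -------------------------------------------------

#' Current energies of a sampler state
#'
#' `E_Tot = sum_m E_Pot(m) + E_RDC`, with the restraint evaluated on the
#' replica-averaged couplings.
#'
#' @param st a [init_sampler()] state.
#' @return list with `E_pot` (sum over replicas), `E_rdc`, `E_tot`.
#' @export
state_energies <- function(st) {
  E_pot <- sum(st$EpotB + st$Ehinge)
  E_rdc <- st$alpha * st$SS
  list(E_pot = E_pot, E_rdc = E_rdc, E_tot = E_pot + E_rdc)
}

#' @rdname state_energies
#' @description `as_replica_set()` exports the current replicas and their
#'   tensors as a [replica_set()] for independent re-evaluation.
#' @export
as_replica_set <- function(st) {
  sys <- st$sys
  confs <- lapply(seq_len(st$M), function(m)
    conformation(sys$toy$conformation$atoms, st$X[[m]], model = m))
  tensors <- lapply(seq_len(st$M), function(m) {
    tl <- lapply(sys$meds, function(med)
      alignment_tensor(st$tensors[[m]][[med]], medium = med))
    names(tl) <- sys$meds
    tl
  })
  replica_set(confs, tensors)
}

#' Total energy of a replica set
#'
#' Independent (non-incremental) evaluation of
#' `E_Tot = sum_m E_Pot(replica m) + E_RDC(replica average)` for a replica
#' set under a sampler system's potential and restraints.
#'
#' @param rset a [replica_set()].
#' @param system a [build_system()] result.
#' @param alpha restraint weight (kJ/mol/Hz^2).
#' @return list with `E_tot`, `E_pot`, `E_rdc`.
#' @export
total_energy <- function(rset, system, alpha = system$alpha_target) {
  E_pot <- sum(vapply(rset$conformations, function(cf) {
    e <- potential_energy(cf$xyz, system)
    if (!is.finite(e)) {
      stop("numerical error: non-finite potential energy in replica ",
           cf$model, call. = FALSE)
    }
    e
  }, numeric(1)))
  E_rdc <- 0
  if (!is.null(system$rdc) && alpha > 0) {
    Dtab <- calc_rdc_table(rset, system$toy$bonds, system$meds,
                           D_max = system$D_max)
    E_rdc <- restraint_energy(Dtab, system$rdc, alpha)
  }
  list(E_tot = E_pot + E_rdc, E_pot = E_pot, E_rdc = E_rdc)
}

# --- moves -----------------------------------------------------------------

#' One Metropolis move on one replica
#'
#' Proposes either a residue-translation jitter (rigid N-H pair: bond
#' orientations, and hence couplings, unchanged) or a rigid swing of the
#' beta-domain about the breathing-plane normal through its
#' hinge-attachment pivot.  Swing proposals recompute the replica's
#' alignment tensors from the proposed shape, so the restraint energy
#' change — evaluated on the updated replica-averaged couplings, honouring
#' the replica coupling — is exact and detailed balance holds at fixed
#' alpha and temperature.
#'
#' @param st a [init_sampler()] state (mutated in place).
#' @param m replica index.
#' @param T temperature (K).
#' @param type `"jitter"` or `"rotate"` (default: random mix, 25%
#'   rotations).
#' @param scale multiplier on the proposal magnitude (0 gives a
#'   zero-magnitude proposal, which is always accepted and leaves the state
#'   unchanged).
#' @return list with `accepted` and `dE` (kJ/mol), invisibly.
#' @export
mc_move <- function(st, m, T, type = NULL, scale = 1) {
  sys <- st$sys
  if (is.null(type)) type <- if (runif(1) < 0.25) "rotate" else "jitter"
  st$attempted <- st$attempted + 1L
  restrained <- !is.null(sys$rdc)
  if (type == "jitter") {
    r <- sample.int(sys$nres, 1)
    dx <- rnorm(3, sd = sys$jitter_sd * scale)
    ir <- sys$idxN[r]
    ih <- sys$idxH[r]
    xyzN <- st$X[[m]][sys$idxN, , drop = FALSE]
    xn_new <- xyzN[r, ] + dx
    pr <- sys$res_pairs[[r]]
    pmat <- xyzN[sys$res_partners[[r]], , drop = FALSE]
    d_old <- sqrt((pmat[, 1] - xyzN[r, 1])^2 + (pmat[, 2] - xyzN[r, 2])^2 +
                  (pmat[, 3] - xyzN[r, 3])^2)
    d_new <- sqrt((pmat[, 1] - xn_new[1])^2 + (pmat[, 2] - xn_new[2])^2 +
                  (pmat[, 3] - xn_new[3])^2)
    dEb <- sum(sys$Pk[pr] * ((d_new - sys$Pd0[pr])^2 -
                             (d_old - sys$Pd0[pr])^2))
    g <- sys$region_of[r]
    com_new <- st$com[[m]]
    com_new[g, ] <- com_new[g, ] + dx / sys$region_n[g]
    th_new <- angle_at_vertex(com_new[1, ], com_new[2, ], com_new[3, ])
    dEh <- hinge_energy(sys$potential, th_new) - st$Ehinge[m]
    dE <- dEb + dEh
    if (metropolis_accept(dE, T)) {
      st$X[[m]][ir, ] <- xn_new
      st$X[[m]][ih, ] <- st$X[[m]][ih, ] + dx
      if (restrained) {
        st$tP[[m]][, ir] <- sys$dirs %*% xn_new
        st$tP[[m]][, ih] <- sys$dirs %*% st$X[[m]][ih, ]
      }
      st$com[[m]] <- com_new
      st$theta[m] <- th_new
      st$EpotB[m] <- st$EpotB[m] + dEb
      st$Ehinge[m] <- st$Ehinge[m] + dEh
      st$accepted <- st$accepted + 1L
      return(invisible(list(accepted = TRUE, dE = dE)))
    }
    return(invisible(list(accepted = FALSE, dE = dE)))
  }
  # beta-domain swing about the breathing-plane normal, pivoted at the
  # domain's hinge-attachment atom: the chain link is preserved and the
  # proposal moves the system along the physical hinge mode (no twist;
  # the alpha-domain is rigidified against the hinge by the potential)
  com <- st$com[[m]]
  v1 <- com[1, ] - com[2, ]
  v3 <- com[3, ] - com[2, ]
  ax <- c(v1[2] * v3[3] - v1[3] * v3[2],
          v1[3] * v3[1] - v1[1] * v3[3],
          v1[1] * v3[2] - v1[2] * v3[1])
  # mixture proposal: mostly small swings that relax within a basin, plus
  # occasional large swings that hop between basins in one step (both
  # symmetric, so detailed balance is preserved)
  size <- if (runif(1) < 0.3) 6 else 1
  ang <- rnorm(1, sd = sys$rot_sd * size * scale)
  if (scale == 0 || ang == 0) {
    # zero-magnitude proposal: identity, always accepted
    st$accepted <- st$accepted + 1L
    return(invisible(list(accepted = TRUE, dE = 0)))
  }
  R <- rotation_matrix(ax, ang)
  rows <- sys$dom_rows$B
  pv <- st$X[[m]][sys$pivots[["B"]], ]
  Xd <- st$X[[m]][rows, , drop = FALSE]
  Xd[, 1] <- Xd[, 1] - pv[1]; Xd[, 2] <- Xd[, 2] - pv[2]
  Xd[, 3] <- Xd[, 3] - pv[3]
  Xd_new <- Xd %*% t(R)
  Xd_new[, 1] <- Xd_new[, 1] + pv[1]; Xd_new[, 2] <- Xd_new[, 2] + pv[2]
  Xd_new[, 3] <- Xd_new[, 3] + pv[3]
  com_new <- com
  com_new[3, ] <- pv + as.numeric(R %*% (com[3, ] - pv))
  th_new <- angle_at_vertex(com_new[1, ], com_new[2, ], com_new[3, ])
  dEh <- hinge_energy(sys$potential, th_new) - st$Ehinge[m]
  dE <- dEh
  upd <- NULL
  if (restrained) {
    js <- sys$dom_res$B
    Pm <- st$tP[[m]]
    Pm[, rows] <- tcrossprod(sys$dirs, Xd_new)
    Vm <- st$V[[m]]
    Vm[js, ] <- Vm[js, , drop = FALSE] %*% t(R)
    upd <- list(P = Pm, V = Vm, A = list(), D = list(), Dbar = list())
    SS_new <- 0
    for (med in sys$meds) {
      w <- weights_from_projections(Pm, sys$charges, sys$media[[med]])
      A <- tensor_from_weights(w, sys$dirs, sys$media[[med]])
      Dnew <- sys$D_max * rowSums((Vm %*% A) * Vm)
      dbar <- st$Dbar[[med]] + (Dnew - st$D[[med]][m, ]) / st$M
      map <- sys$rdc_map[[med]]
      SS_new <- SS_new + sum((map$Dexp - dbar[map$bond])^2)
      upd$A[[med]] <- A; upd$D[[med]] <- Dnew; upd$Dbar[[med]] <- dbar
    }
    dE <- dE + st$alpha * (SS_new - st$SS)
    upd$SS <- SS_new
  }
  if (metropolis_accept(dE, T)) {
    st$X[[m]][rows, ] <- Xd_new
    st$com[[m]] <- com_new
    st$theta[m] <- th_new
    st$Ehinge[m] <- st$Ehinge[m] + dEh
    if (restrained) {
      st$tP[[m]] <- upd$P
      st$V[[m]] <- upd$V
      for (med in sys$meds) {
        st$tensors[[m]][[med]] <- upd$A[[med]]
        st$D[[med]][m, ] <- upd$D[[med]]
        st$Dbar[[med]] <- upd$Dbar[[med]]
      }
      st$SS <- upd$SS
    }
    st$accepted <- st$accepted + 1L
    return(invisible(list(accepted = TRUE, dE = dE)))
  }
  invisible(list(accepted = FALSE, dE = dE))
}

# one sweep: nres move attempts per replica (rotations mixed in by mc_move)
mc_sweep <- function(st, T) {
  for (m in seq_len(st$M)) {
    for (i in seq_len(st$sys$nres)) mc_move(st, m, T)
  }
  invisible(st)
}

# resynchronise derived scalars from coordinates (guards against float
# drift of the incremental bookkeeping)
resync_energies <- function(st) {
  sys <- st$sys
  for (m in seq_len(st$M)) {
    xyzN <- st$X[[m]][sys$idxN, , drop = FALSE]
    d <- sqrt(rowSums((xyzN[sys$P1, , drop = FALSE] -
                       xyzN[sys$P2, , drop = FALSE])^2))
    st$EpotB[m] <- sum(sys$Pk * (d - sys$Pd0)^2)
    st$com[[m]] <- t(vapply(sys$region_rows, function(r)
      colMeans(st$X[[m]][r, , drop = FALSE]), numeric(3)))
    st$theta[m] <- angle_at_vertex(st$com[[m]][1, ], st$com[[m]][2, ],
                                   st$com[[m]][3, ])
  }
  st$Ehinge <- hinge_energy(sys$potential, st$theta)
  if (!is.null(sys$rdc)) {
    st$Dbar <- lapply(st$D, colMeans)
    st$SS <- ss_from_dbar(sys, st$Dbar)
  }
  invisible(st)
}

#' Run the restrained simulated-annealing protocol
#'
#' First equilibrates at `T_low` while ramping the restraint weight alpha
#' geometrically from its start value towards the target (the ramp stops
#' early if move acceptance falls below the system's `min_acceptance`),
#' then runs `cycles` annealing cycles alternating hot and annealed
#' segments, collecting frames from every replica only in the collection
#' window of the final `cycles_retained` cycles.  Fully reproducible from
#' `seed`.
#'
#' @param system a [build_system()] result.
#' @param schedule an [annealing_schedule()].
#' @param seed integer seed.
#' @return list with `ensemble` (collected frames; `frame_info` has
#'   `cycle`, `replica`, `theta`, `E_pot`), `trace` (per-sweep energies),
#'   `acceptance`, `alpha_final`, and `state` (the final sampler state).
#' @export
run_annealing <- function(system, schedule, seed = 0L) {
  stopifnot(inherits(system, "sampler_system"),
            inherits(schedule, "annealing_schedule"))
  n_collect <- as.integer(round(schedule$frames_per_ps * schedule$collect_ps))
  if (n_collect > schedule$sweeps_low) {
    stop("schedule error: collection window needs more sweeps than ",
         "sweeps_low provides", call. = FALSE)
  }
  with_local_seed(seed, function() {
    st <- init_sampler(system)
    restrained <- !is.null(system$rdc)
    trace <- list()
    tick <- 0L
    log_sweep <- function(phase, cycle, T) {
      resync_energies(st)
      e <- state_energies(st)
      if (!all(is.finite(unlist(e)))) {
        stop("divergent energies at sweep ", tick, " (", phase, ")",
             call. = FALSE)
      }
      tick <<- tick + 1L
      trace[[tick]] <<- data.frame(sweep = tick, phase = phase,
                                   cycle = cycle, T = T, alpha = st$alpha,
                                   E_pot = e$E_pot, E_rdc = e$E_rdc,
                                   E_tot = e$E_tot)
    }
    # --- alpha-ramp equilibration at T_low
    if (restrained && system$alpha_target > 0) {
      n_stages <- max(1, ceiling(log(system$alpha_target / system$alpha_start) /
                                 log(system$alpha_ramp)))
      per_stage <- max(1L, schedule$equil_sweeps %/% n_stages)
      st$alpha <- system$alpha_start
      ramping <- TRUE
      for (stage in seq_len(n_stages)) {
        acc0 <- st$accepted; att0 <- st$attempted
        for (s in seq_len(per_stage)) {
          mc_sweep(st, schedule$T_low)
          log_sweep("equil", 0L, schedule$T_low)
        }
        acc_rate <- (st$accepted - acc0) / max(1L, st$attempted - att0)
        if (ramping && acc_rate < system$min_acceptance) ramping <- FALSE
        if (ramping) {
          st$alpha <- min(st$alpha * system$alpha_ramp, system$alpha_target)
        }
      }
    } else {
      for (s in seq_len(schedule$equil_sweeps)) {
        mc_sweep(st, schedule$T_low)
        log_sweep("equil", 0L, schedule$T_low)
      }
    }
    # --- annealing cycles
    frames <- list()
    finfo <- list()
    fi <- 0L
    first_retained <- schedule$cycles - schedule$cycles_retained + 1L
    for (cyc in seq_len(schedule$cycles)) {
      for (s in seq_len(schedule$sweeps_high)) {
        mc_sweep(st, schedule$T_high)
        log_sweep("high", cyc, schedule$T_high)
      }
      collect_from <- schedule$sweeps_low - n_collect + 1L
      for (s in seq_len(schedule$sweeps_low)) {
        mc_sweep(st, schedule$T_low)
        log_sweep("low", cyc, schedule$T_low)
        if (cyc >= first_retained && s >= collect_from) {
          for (m in seq_len(st$M)) {
            fi <- fi + 1L
            frames[[fi]] <- st$X[[m]]
            finfo[[fi]] <- data.frame(
              cycle = cyc, replica = m, theta = st$theta[m],
              E_pot = st$EpotB[m] + st$Ehinge[m])
          }
        }
      }
    }
    xyz <- array(NA_real_, c(fi, nrow(frames[[1]]), 3))
    for (k in seq_len(fi)) xyz[k, , ] <- frames[[k]]
    ens <- new_ensemble(system$toy$conformation$atoms, xyz,
                        frame_info = do.call(rbind, finfo))
    list(ensemble = ens, trace = do.call(rbind, trace),
         acceptance = st$accepted / max(1L, st$attempted),
         alpha_final = st$alpha, state = st)
  })
}
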