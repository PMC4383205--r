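#' Region definitions for the breathing angle
#'
#' Three disjoint residue selections — one in the alpha-domain, one in the
#' hinge, one in the beta-domain — whose centres of mass define the
#' interdomain breathing angle theta (vertex at the hinge region).
#'
#' @param region1,region2,region3 integer residue indices of the
#'   alpha-domain, hinge and beta-domain selections.
#' @param atom_filter atom name used for the centres of mass (default
#'   `"CA"`; coarse-grained chains without CA fall back to `"N"`).
#' @return object of class `region_definition`.
#' @export
region_definition <- function(region1, region2, region3, atom_filter = "CA") {
  regs <- list(as.integer(region1), as.integer(region2), as.integer(region3))
  if (any(vapply(regs, length, 1L) == 0)) {
    stop("regions must be non-empty", call. = FALSE)
  }
  if (length(unique(unlist(regs))) != length(unlist(regs))) {
    stop("regions must be disjoint", call. = FALSE)
  }
  structure(list(region1 = regs[[1]], region2 = regs[[2]],
                 region3 = regs[[3]], atom_filter = atom_filter),
            class = "region_definition")
}

region_atom_rows <- function(atoms, regions) {
  lapply(list(regions$region1, regions$region2, regions$region3),
         function(r) select_residue_atoms(atoms, r, regions$atom_filter))
}

#' Interdomain breathing angle
#'
#' The angle (degrees, in `[0, 180]`) at the hinge-region centre of mass
#' between the vectors to the alpha-domain and beta-domain centres of mass.
#' Invariant under global rotation and translation.
#'
#' @param conf a [conformation()].
#' @param regions a [region_definition()].
#' @return theta in degrees.
#' @export
breathing_angle <- function(conf, regions) {
  rows <- region_atom_rows(conf$atoms, regions)
  coms <- lapply(rows, function(r) colMeans(conf$xyz[r, , drop = FALSE]))
  angle_at_vertex(coms[[1]], coms[[2]], coms[[3]])
}

# theta for every frame of an ensemble
ensemble_thetas <- function(ens, regions) {
  rows <- region_atom_rows(ens$atoms, regions)
  vapply(seq_len(n_models(ens)), function(k) {
    xyz <- ens$xyz[k, , , drop = TRUE]
    angle_at_vertex(colMeans(xyz[rows[[1]], , drop = FALSE]),
                    colMeans(xyz[rows[[2]], , drop = FALSE]),
                    colMeans(xyz[rows[[3]], , drop = FALSE]))
  }, numeric(1))
}

#' RMSD to a reference after optimal superposition
#'
#' Least-squares (Kabsch) superposition of the selected atoms, then the
#' root-mean-square deviation over the same selection.
#'
#' @param conf a [conformation()].
#' @param reference reference [conformation()].
#' @param selection integer residue indices to superpose on (e.g. the
#'   secondary-structure cores); must resolve in both structures.
#' @param atom_filter atom name per residue (default `"CA"`, falling back
#'   to `"N"`).
#' @return RMSD in Angstrom.
#' @export
rmsd_to_reference <- function(conf, reference, selection,
                              atom_filter = "CA") {
  ia <- select_residue_atoms(conf$atoms, selection, atom_filter)
  ib <- select_residue_atoms(reference$atoms, selection, atom_filter)
  if (length(ia) != length(ib)) {
    stop("selection error: selection sizes differ between structures",
         call. = FALSE)
  }
  if (length(ia) < 3) {
    stop("selection error: at least 3 atoms are required", call. = FALSE)
  }
  a <- as.vector(t(conf$xyz[ia, , drop = FALSE]))
  b <- as.vector(t(reference$xyz[ib, , drop = FALSE]))
  fitted <- bio3d::fit.xyz(fixed = b, mobile = a,
                           fixed.inds = seq_along(b),
                           mobile.inds = seq_along(a))
  sqrt(mean((fitted - b)^2) * 3)
}

#' Free-energy surface over (theta, RMSD)
#'
#' Histograms the ensemble on a (breathing angle, RMSD-to-reference) grid
#' and converts counts H to free energies `F = -kB T ln H` on populated
#' bins (F is undefined — NA — on empty bins).
#'
#' @param ens an [ensemble()].
#' @param regions a [region_definition()].
#' @param reference reference [conformation()] for the RMSD axis.
#' @param selection residue selection for the RMSD (see
#'   [rmsd_to_reference()]).
#' @param theta_bin,rmsd_bin bin widths (degrees, Angstrom).
#' @param temperature temperature in K.
#' @return object of class `landscape_grid`: bin edges, counts `H`, free
#'   energy `F` (kJ/mol), and the per-frame `theta`/`rmsd` values.
#' @export
free_energy_surface <- function(ens, regions, reference, selection,
                                theta_bin = 1, rmsd_bin = 0.1,
                                temperature = 310) {
  stopifnot(inherits(ens, "ensemble"), n_models(ens) >= 1)
  if (theta_bin <= 0 || rmsd_bin <= 0) {
    stop("binning error: bin widths must be positive", call. = FALSE)
  }
  theta <- ensemble_thetas(ens, regions)
  rmsd <- vapply(seq_len(n_models(ens)), function(k)
    rmsd_to_reference(get_conformation(ens, k), reference, selection,
                      regions$atom_filter), numeric(1))
  t_edges <- seq(floor(min(theta) / theta_bin) * theta_bin,
                 ceiling(max(theta) / theta_bin) * theta_bin + theta_bin,
                 by = theta_bin)
  r_edges <- seq(floor(min(rmsd) / rmsd_bin) * rmsd_bin,
                 ceiling(max(rmsd) / rmsd_bin) * rmsd_bin + rmsd_bin,
                 by = rmsd_bin)
  ti <- findInterval(theta, t_edges, rightmost.closed = TRUE)
  ri <- findInterval(rmsd, r_edges, rightmost.closed = TRUE)
  H <- matrix(0L, length(t_edges) - 1, length(r_edges) - 1)
  for (k in seq_along(ti)) H[ti[k], ri[k]] <- H[ti[k], ri[k]] + 1L
  kT <- kB_kJmol * temperature
  F <- matrix(NA_real_, nrow(H), ncol(H))
  F[H > 0] <- -kT * log(H[H > 0])
  structure(list(theta_edges = t_edges, rmsd_edges = r_edges, H = H, F = F,
                 temperature = temperature, theta = theta, rmsd = rmsd),
            class = "landscape_grid")
}

#' @rdname free_energy_surface
#' @param x a `landscape_grid`.
#' @param path output TSV path (columns theta_bin, rmsd_bin, H, F).
#' @export
write_landscape <- function(x, path) {
  stopifnot(inherits(x, "landscape_grid"))
  tc <- (head(x$theta_edges, -1) + x$theta_edges[-1]) / 2
  rc <- (head(x$rmsd_edges, -1) + x$rmsd_edges[-1]) / 2
  df <- expand.grid(theta_bin = tc, rmsd_bin = rc)
  df$H <- as.vector(x$H)
  df$F <- as.vector(x$F)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Basin partitions and basin populations
#'
#' Partitions the breathing-angle range at a boundary into an "unlocked"
#' (closed, theta below the boundary) and a "locked" (theta above) basin
#' and reports the fraction, mean theta, modal theta and mean RMSD of each.
#'
#' @param boundary_deg basin boundary in degrees (default 50: closed
#'   conformations have theta below it).
#' @param below_label,above_label basin names.
#' @return object of class `basin_partition`.
#' @export
basin_partition <- function(boundary_deg = 50, below_label = "unlocked",
                            above_label = "locked") {
  stopifnot(is.finite(boundary_deg))
  structure(list(boundary = boundary_deg, below = below_label,
                 above = above_label), class = "basin_partition")
}

#' @rdname basin_partition
#' @param ens an [ensemble()] (non-empty).
#' @param regions a [region_definition()].
#' @param partition a `basin_partition`.
#' @param reference optional reference [conformation()] for per-basin mean
#'   RMSD.
#' @param selection residue selection for the RMSD.
#' @return data.frame with one row per basin: `basin`, `fraction`,
#'   `mean_theta`, `mode_theta`, `mean_rmsd` (NA without a reference).
#' @export
basin_population <- function(ens, regions, partition = basin_partition(),
                             reference = NULL, selection = NULL) {
  if (!inherits(ens, "ensemble") || n_models(ens) < 1) {
    stop("precondition error: a non-empty ensemble is required", call. = FALSE)
  }
  stopifnot(inherits(partition, "basin_partition"))
  theta <- ensemble_thetas(ens, regions)
  below <- theta < partition$boundary
  rmsd <- rep(NA_real_, length(theta))
  if (!is.null(reference)) {
    rmsd <- vapply(seq_len(n_models(ens)), function(k)
      rmsd_to_reference(get_conformation(ens, k), reference, selection,
                        regions$atom_filter), numeric(1))
  }
  one <- function(label, sel) {
    mode_th <- if (any(sel)) {
      h <- table(round(theta[sel]))
      as.numeric(names(h)[which.max(h)])
    } else NA_real_
    data.frame(basin = label, fraction = mean(sel),
               mean_theta = if (any(sel)) mean(theta[sel]) else NA_real_,
               mode_theta = mode_th,
               mean_rmsd = if (any(sel)) mean(rmsd[sel]) else NA_real_)
  }
  rbind(one(partition$below, below), one(partition$above, !below))
}

#' Contact / hydrogen-bond occupancy over an ensemble
#'
#' A donor-acceptor pair is "formed" in a frame iff the donor-acceptor
#' distance is at most `dist_cutoff` and, when a donor antecedent atom is
#' given, the antecedent-donor-acceptor angle is at least `angle_cutoff`
#' (the standard geometric hydrogen-bond criterion).  Occupancy is the
#' fraction of frames in which the pair is formed, reported overall and,
#' when basin labels are supplied, per basin.
#'
#' @param ens an [ensemble()].
#' @param donors data.frame with columns `resno`, `atom` and optionally
#'   `antecedent` (atom name of the donor heavy-atom antecedent).
#' @param acceptors data.frame with columns `resno`, `atom`.
#' @param dist_cutoff distance cutoff in Angstrom (default 3.5).
#' @param angle_cutoff angle cutoff in degrees (default 120), applied only
#'   where an antecedent is defined.
#' @param labels optional per-frame basin labels (character).
#' @return data.frame with one row per donor x acceptor pair and occupancy
#'   columns (`occupancy`, plus one per basin label).
#' @export
contact_occupancy <- function(ens, donors, acceptors, dist_cutoff = 3.5,
                              angle_cutoff = 120, labels = NULL) {
  stopifnot(inherits(ens, "ensemble"))
  if (nrow(donors) == 0 || nrow(acceptors) == 0) {
    stop("selection error: empty donor or acceptor selection", call. = FALSE)
  }
  if (!is.null(labels)) stopifnot(length(labels) == n_models(ens))
  pairs <- expand.grid(di = seq_len(nrow(donors)),
                       ai = seq_len(nrow(acceptors)))
  d_rows <- atom_rows(ens$atoms, donors$resno, donors$atom)
  a_rows <- atom_rows(ens$atoms, acceptors$resno, acceptors$atom)
  has_ante <- !is.null(donors$antecedent)
  if (has_ante) {
    t_rows <- atom_rows(ens$atoms, donors$resno, donors$antecedent)
  }
  nm <- n_models(ens)
  formed <- matrix(FALSE, nm, nrow(pairs))
  for (k in seq_len(nm)) {
    xyz <- ens$xyz[k, , , drop = TRUE]
    for (j in seq_len(nrow(pairs))) {
      dr <- d_rows[pairs$di[j]]; ar <- a_rows[pairs$ai[j]]
      ok <- vnorm(xyz[dr, ] - xyz[ar, ]) <= dist_cutoff
      if (ok && has_ante) {
        ok <- angle_at_vertex(xyz[t_rows[pairs$di[j]], ], xyz[dr, ],
                              xyz[ar, ]) >= angle_cutoff
      }
      formed[k, j] <- ok
    }
  }
  out <- data.frame(
    donor_resno = donors$resno[pairs$di], donor_atom = donors$atom[pairs$di],
    acceptor_resno = acceptors$resno[pairs$ai],
    acceptor_atom = acceptors$atom[pairs$ai],
    occupancy = colMeans(formed))
  if (!is.null(labels)) {
    for (lb in unique(labels)) {
      out[[paste0("occupancy_", lb)]] <-
        colMeans(formed[labels == lb, , drop = FALSE])
    }
  }
  out
}

#' Mean potential energy versus breathing angle
#'
#' Bins the ensemble's per-frame potential energies (from
#' `frame_info$E_pot`) over theta and reports the per-bin mean and standard
#' error; empty bins are NA, never zero.
#'
#' @param ens an [ensemble()] whose `frame_info` has an `E_pot` column.
#' @param regions a [region_definition()].
#' @param theta_bin bin width in degrees.
#' @return data.frame with `theta_mid`, `n`, `mean_E_pot`, `se_E_pot`.
#' @export
potential_energy_profile <- function(ens, regions, theta_bin = 1) {
  if (is.null(ens$frame_info) || is.null(ens$frame_info$E_pot)) {
    stop("input error: every frame must carry an E_pot value", call. = FALSE)
  }
  e <- ens$frame_info$E_pot
  if (anyNA(e)) stop("input error: frame without an E_pot value", call. = FALSE)
  theta <- ensemble_thetas(ens, regions)
  edges <- seq(floor(min(theta) / theta_bin) * theta_bin,
               ceiling(max(theta) / theta_bin) * theta_bin + theta_bin,
               by = theta_bin)
  bin <- findInterval(theta, edges, rightmost.closed = TRUE)
  mids <- (head(edges, -1) + edges[-1]) / 2
  out <- data.frame(theta_mid = mids, n = 0L, mean_E_pot = NA_real_,
                    se_E_pot = NA_real_)
  for (b in unique(bin)) {
    sel <- bin == b
    out$n[b] <- sum(sel)
    out$mean_E_pot[b] <- mean(e[sel])
    out$se_E_pot[b] <- if (sum(sel) > 1) sd(e[sel]) / sqrt(sum(sel)) else NA_real_
  }
  out
}
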