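#' Bond vector sets
#'
#' Declares which internuclear vectors carry RDCs: one row per (residue,
#' pair), naming the donor and acceptor atoms whose difference vector,
#' normalised per conformation, gives the direction cosines entering the
#' RDC equation.
#'
#' @param resno integer residue indices.
#' @param pair pair labels (default `"N-H"`).
#' @param donor,acceptor atom names of the two nuclei.
#' @return data.frame of class `bond_vector_set`.
#' @export
bond_vector_set <- function(resno, pair = "N-H", donor = "N", acceptor = "H") {
  df <- data.frame(resno = as.integer(resno), pair = pair,
                   donor = donor, acceptor = acceptor,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(paste(df$resno, df$pair))) {
    stop("duplicate (residue, pair) in bond vector set", call. = FALSE)
  }
  class(df) <- c("bond_vector_set", "data.frame")
  df
}

#' @rdname bond_vector_set
#' @param conf a [conformation()].
#' @param bonds a `bond_vector_set`.
#' @return n_bonds x 3 matrix of unit vectors.
#' @export
bond_unit_vectors <- function(conf, bonds) {
  i_d <- atom_rows(conf$atoms, bonds$resno, bonds$donor)
  i_a <- atom_rows(conf$atoms, bonds$resno, bonds$acceptor)
  b <- conf$xyz[i_a, , drop = FALSE] - conf$xyz[i_d, , drop = FALSE]
  n <- sqrt(rowSums(b * b))
  if (any(n == 0)) stop("zero-length bond vector", call. = FALSE)
  b / n
}

#' Back-calculate RDCs for one conformation
#'
#' `D = D_max * sum_ij A_ij cos(phi_i) cos(phi_j)` per bond, where the
#' direction cosines are those of the unit bond vector in the molecular
#' frame carrying the tensor.
#'
#' @param conf a [conformation()].
#' @param tensor an [alignment_tensor()].
#' @param bonds a [bond_vector_set()].
#' @param D_max dipolar interaction constant (Hz).
#' @return numeric vector of couplings (Hz), one per bond row.
#' @export
calc_rdc <- function(conf, tensor, bonds, D_max = -21700) {
  stopifnot(inherits(tensor, "alignment_tensor"))
  V <- bond_unit_vectors(conf, bonds)
  as.numeric(D_max * rowSums((V %*% tensor$A) * V))
}

#' Replica sets and replica-averaged RDCs
#'
#' A replica set is M conformations sharing one topology, each carrying its
#' own alignment tensor per medium.  The calculated coupling entering the
#' restraint is the plain mean over replicas, `D_calc = (1/M) sum_m D_m`:
#' restraining the mean rather than each copy yields the
#' maximum-entropy-consistent ensemble.
#'
#' @param conformations list of M [conformation()] objects.
#' @param tensors list of length M; each element a named list of
#'   [alignment_tensor()] objects keyed by medium.
#' @return object of class `replica_set`.
#' @export
replica_set <- function(conformations, tensors) {
  stopifnot(length(conformations) >= 1,
            length(tensors) == length(conformations))
  ens <- ensemble(conformations)  # validates shared topology
  structure(list(conformations = conformations, tensors = tensors,
                 atoms = ens$atoms, M = length(conformations)),
            class = "replica_set")
}

#' @rdname replica_set
#' @param rset a `replica_set`.
#' @param bonds a [bond_vector_set()].
#' @param medium medium id whose per-replica tensors are used.
#' @param D_max dipolar constant (Hz).
#' @return numeric vector: per-bond replica-averaged couplings (Hz).
#' @export
replica_average_rdc <- function(rset, bonds, medium, D_max = -21700) {
  stopifnot(inherits(rset, "replica_set"))
  D <- vapply(seq_len(rset$M), function(m) {
    tens <- rset$tensors[[m]][[medium]]
    if (is.null(tens)) stop("replica ", m, " has no tensor for medium '",
                            medium, "'", call. = FALSE)
    calc_rdc(rset$conformations[[m]], tens, bonds, D_max = D_max)
  }, numeric(nrow(bonds)))
  if (nrow(bonds) == 1) D <- matrix(D, nrow = 1)
  rowMeans(D)
}

# key-matched lookup of calculated couplings for the rows of an rdc table;
# unmatched experimental rows are a hard error, never silently skipped
match_calc_to_table <- function(D_calc, rdc) {
  stopifnot(is.data.frame(D_calc), all(c("resno", "pair", "medium", "D_calc")
                                       %in% names(D_calc)))
  idx <- match(paste(rdc$resno, rdc$pair, rdc$medium),
               paste(D_calc$resno, D_calc$pair, D_calc$medium))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop("mapping error: no calculated coupling for (residue ", rdc$resno[bad],
         ", ", rdc$pair[bad], ", ", rdc$medium[bad], ")", call. = FALSE)
  }
  D_calc$D_calc[idx]
}

#' RDC restraint energy
#'
#' `E_RDC = alpha * sum_i (D_exp_i - D_calc_i)^2` over all table rows, with
#' a single global weight alpha (kJ/mol/Hz^2).  Every experimental row must
#' be matched by a calculated coupling.
#'
#' @param D_calc data.frame with columns `resno`, `pair`, `medium`,
#'   `D_calc` (Hz) — e.g. from [calc_rdc_table()].
#' @param rdc an `rdc_table`.
#' @param alpha restraint weight (kJ/mol/Hz^2), >= 0.
#' @return energy in kJ/mol.
#' @export
restraint_energy <- function(D_calc, rdc, alpha) {
  stopifnot(alpha >= 0)
  d <- match_calc_to_table(D_calc, rdc)
  alpha * sum((rdc$D_exp - d)^2)
}

#' @rdname restraint_energy
#' @description `calc_rdc_table()` back-calculates replica-averaged
#'   couplings for every (bond, medium) combination as a keyed data.frame.
#' @param rset a [replica_set()].
#' @param bonds a [bond_vector_set()].
#' @param media character vector of medium ids.
#' @param D_max dipolar constant (Hz).
#' @export
calc_rdc_table <- function(rset, bonds, media, D_max = -21700) {
  out <- lapply(media, function(med) {
    data.frame(resno = bonds$resno, pair = bonds$pair, medium = med,
               D_calc = replica_average_rdc(rset, bonds, med, D_max = D_max),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Analytic gradient of the restraint energy
#'
#' Gradient of `E_RDC` with respect to the Cartesian coordinates of every
#' replica, holding the alignment tensors fixed (tensors are recomputed on
#' their own schedule during sampling).  Consistent with central finite
#' differences of [restraint_energy()] under the same fixed tensors.
#'
#' @param rset a [replica_set()].
#' @param bonds a [bond_vector_set()].
#' @param rdc an `rdc_table`.
#' @param alpha restraint weight (kJ/mol/Hz^2).
#' @param D_max dipolar constant (Hz).
#' @return list of n_atoms x 3 gradient matrices (kJ/mol/A), one per replica.
#' @export
restraint_gradient <- function(rset, bonds, rdc, alpha, D_max = -21700) {
  media <- unique(rdc$medium)
  Dtab <- calc_rdc_table(rset, bonds, media, D_max = D_max)
  resid <- rdc$D_exp - match_calc_to_table(Dtab, rdc)
  M <- rset$M
  atoms <- rset$atoms
  i_d <- atom_rows(atoms, bonds$resno, bonds$donor)
  i_a <- atom_rows(atoms, bonds$resno, bonds$acceptor)
  grads <- lapply(seq_len(M), function(m) matrix(0, nrow(atoms), 3))
  key_b <- paste(bonds$resno, bonds$pair)
  for (m in seq_len(M)) {
    conf <- rset$conformations[[m]]
    b <- conf$xyz[i_a, , drop = FALSE] - conf$xyz[i_d, , drop = FALSE]
    lb <- sqrt(rowSums(b * b))
    V <- b / lb
    for (med in media) {
      A <- rset$tensors[[m]][[med]]$A
      rows <- which(rdc$medium == med)
      bi <- match(paste(rdc$resno[rows], rdc$pair[rows]), key_b)
      AV <- V %*% A
      q <- rowSums(AV * V)                       # v^T A v per bond
      # dD/db = (D_max/|b|) * 2 (A v - q v); dE/db = -2 alpha r (1/M) dD/db
      for (jj in seq_along(rows)) {
        k <- bi[jj]
        dDdb <- (D_max / lb[k]) * 2 * (AV[k, ] - q[k] * V[k, ])
        g <- -2 * alpha * resid[rows[jj]] * dDdb / M
        grads[[m]][i_a[k], ] <- grads[[m]][i_a[k], ] + g
        grads[[m]][i_d[k], ] <- grads[[m]][i_d[k], ] - g
      }
    }
  }
  grads
}

#' Q factor between calculated and experimental RDCs
#'
#' `Q = sqrt( sum (D_calc - D_exp)^2 / sum D_exp^2 )`, reported per medium
#' plus pooled over all rows; 0 is perfect agreement.
#'
#' @param D_calc keyed data.frame of calculated couplings (see
#'   [calc_rdc_table()]).
#' @param rdc an `rdc_table`.
#' @return named list: one Q per medium and `pooled`.
#' @export
q_factor <- function(D_calc, rdc) {
  d <- match_calc_to_table(D_calc, rdc)
  one_q <- function(sel) {
    denom <- sum(rdc$D_exp[sel]^2)
    if (denom == 0) {
      stop("undefined Q: experimental couplings are all zero", call. = FALSE)
    }
    sqrt(sum((d[sel] - rdc$D_exp[sel])^2) / denom)
  }
  media <- unique(rdc$medium)
  out <- lapply(media, function(med) one_q(rdc$medium == med))
  names(out) <- media
  out$pooled <- one_q(rep(TRUE, nrow(rdc)))
  out
}

#' @rdname restraint_energy
#' @description `export_rdc_table()` writes the experimental table with an
#'   added `D_calc` column as TSV.
#' @param path output TSV path.
#' @export
export_rdc_table <- function(rdc, D_calc, path) {
  rdc$D_calc <- match_calc_to_table(D_calc, rdc)
  write.table(rdc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Ensemble- and population-averaged back-calculated RDCs
#'
#' Back-calculates couplings frame by frame, each frame with its own
#' shape/charge-predicted tensor per medium, and averages with the
#' ensemble weights (uniform if absent).  This is both how synthetic
#' "experimental" tables are produced and how an ensemble is validated
#' against a measured table.
#'
#' @param ens an [ensemble()].
#' @param bonds a [bond_vector_set()].
#' @param media named list of [medium_spec()] objects.
#' @param n_orient orientation-grid resolution for tensor prediction.
#' @param D_max dipolar constant (Hz).
#' @return named list (per medium) of per-bond mean couplings (Hz).
#' @export
ensemble_average_rdc <- function(ens, bonds, media, n_orient = 256,
                                 D_max = -21700) {
  stopifnot(inherits(ens, "ensemble"))
  nm <- n_models(ens)
  w <- ens$weights %||% rep(1 / nm, nm)
  lapply(media, function(med) {
    D <- matrix(NA_real_, nm, nrow(bonds))
    for (k in seq_len(nm)) {
      conf <- get_conformation(ens, k)
      tens <- predict_tensor(conf, med, n_orient = n_orient)
      D[k, ] <- calc_rdc(conf, tens, bonds, D_max = D_max)
    }
    as.numeric(crossprod(D, w))
  })
}
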