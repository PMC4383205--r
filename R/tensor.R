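#' Alignment tensors and alignment media
#'
#' The alignment tensor A is the symmetric, traceless 3x3 order matrix of a
#' molecule in a partially aligning medium; contracted with a bond's
#' direction cosines it yields the residual dipolar coupling of that bond.
#' Tensors here are either predicted from molecular shape (and charge, for
#' charged media) by [predict_tensor()], or fitted to measured RDCs by
#' [svd_fit_tensor()] (a validation/oracle mode: the fitted tensor best
#' reproduces the data rather than describing the physical alignment of the
#' given structure).
#'
#' @param A 3x3 numeric matrix; must be symmetric (1e-12), traceless
#'   (1e-10) and have largest-magnitude eigenvalue < 1.
#' @param medium medium id string.
#' @return object of class `alignment_tensor`.
#' @export
alignment_tensor <- function(A, medium = "steric") {
  A <- as.matrix(A)
  stopifnot(all(dim(A) == c(3, 3)), all(is.finite(A)))
  if (max(abs(A - t(A))) > 1e-12) {
    stop("alignment tensor must be symmetric", call. = FALSE)
  }
  A <- (A + t(A)) / 2
  if (abs(sum(diag(A))) > 1e-10) {
    stop("alignment tensor must be traceless", call. = FALSE)
  }
  if (max(abs(eigen(A, symmetric = TRUE, only.values = TRUE)$values)) >= 1) {
    stop("alignment tensor eigenvalues must have magnitude < 1", call. = FALSE)
  }
  structure(list(A = unname(A), medium = medium), class = "alignment_tensor")
}

#' @rdname alignment_tensor
#' @param kind `"steric"` or `"electrostatic"`.
#' @param spacing obstruction (wall-to-wall) spacing in Angstrom.
#' @param probe_radius effective atom radius in Angstrom used for steric
#'   exclusion.
#' @param scale overall dimensionless alignment magnitude (> 0); absorbs
#'   the unknown absolute degree of alignment and is calibrated once per
#'   medium (see [calibrate_medium_scale()]).
#' @param wall_charge wall surface-potential parameter, kJ/mol per unit
#'   atomic charge at contact (electrostatic media only).
#' @param debye_length screening length in Angstrom (electrostatic only).
#' @param temperature temperature (K) for the Boltzmann weighting of the
#'   screened wall potential.
#' @export
medium_spec <- function(kind = c("steric", "electrostatic"), spacing = 120,
                        probe_radius = 2.0, scale = 1.0, wall_charge = 2.0,
                        debye_length = 15, temperature = 310) {
  kind <- match.arg(kind)
  stopifnot(spacing > 0, probe_radius >= 0, scale > 0, debye_length > 0,
            temperature > 0)
  structure(list(kind = kind, spacing = spacing, probe_radius = probe_radius,
                 scale = scale, wall_charge = wall_charge,
                 debye_length = debye_length, temperature = temperature),
            class = "medium_spec")
}

medium_from_config <- function(cfg_entry) {
  medium_spec(kind = cfg_entry$kind,
              spacing = cfg_entry$spacing %||% 120,
              probe_radius = cfg_entry$probe_radius %||% 2.0,
              scale = cfg_entry$scale %||% 1.0,
              wall_charge = cfg_entry$wall_charge %||% 2.0,
              debye_length = cfg_entry$debye_length %||% 15)
}

# Orientation-dependent placement weights between two parallel walls.
# dirs: n x 3 wall-normal directions expressed in the molecular frame.
# Returns a nonnegative weight per direction: the accessible placement
# length (steric), Boltzmann-weighted by a screened single-wall potential
# acting on atom charges (electrostatic).
placement_weights <- function(xyz, charges, dirs, medium, n_quad = 9) {
  weights_from_projections(tcrossprod(dirs, xyz), charges, medium, n_quad)
}

# the same weights given the precomputed projection matrix tP
# (dirs x atoms); only projection differences enter, so tP need not be
# centred
weights_from_projections <- function(tP, charges, medium, n_quad = 9) {
  nd <- nrow(tP)
  hi <- tP[cbind(seq_len(nd), max.col(tP, ties.method = "first"))]
  tP_neg <- -tP
  lo <- -tP_neg[cbind(seq_len(nd), max.col(tP_neg, ties.method = "first"))]
  gap <- medium$spacing - (hi - lo + 2 * medium$probe_radius)
  gap[gap < 0] <- 0                         # accessible range of placements
  if (medium$kind == "steric") return(gap)
  lam <- medium$debye_length
  beta <- 1 / (kB_kJmol * medium$temperature)
  rho <- medium$probe_radius
  # per-direction charge moments at the lower/upper contact positions
  # (only charged atoms contribute)
  cz <- which(charges != 0)
  Pq <- tP[, cz, drop = FALSE]
  c_lo <- as.numeric(exp((lo - Pq) / lam) %*% charges[cz])
  c_hi <- as.numeric(exp((Pq - hi) / lam) %*% charges[cz])
  tj <- seq(0, 1, length.out = n_quad)
  z0 <- outer(gap, tj)                      # dirs x quad placements
  E <- medium$wall_charge *
    (exp(-(z0 + rho) / lam) * c_lo + exp(-(gap - z0 + rho) / lam) * c_hi)
  f <- exp(-beta * E)
  trap <- (rowSums(f) - (f[, 1] + f[, n_quad]) / 2) / (n_quad - 1)
  gap * trap
}

#' Predict the alignment tensor from molecular shape and charge
#'
#' Averages the director dyadic over a deterministic spherical Fibonacci
#' grid of molecule orientations, each weighted by how much room the
#' molecule has between two parallel obstructions (hard-sphere exclusion);
#' for electrostatic media the weight additionally carries a Boltzmann
#' factor from a Debye-Hueckel screened wall potential acting on atom
#' charges.  The result is `scale * (<n n^T> - I/3)`.
#'
#' @param conf a [conformation()] with at least 4 non-collinear atoms.
#' @param medium a [medium_spec()].
#' @param n_orient orientation-grid resolution (>= 100).
#' @return an [alignment_tensor()].
#' @export
predict_tensor <- function(conf, medium, n_orient = 256) {
  stopifnot(inherits(conf, "conformation"), inherits(medium, "medium_spec"))
  if (n_orient < 100) {
    stop("resolution error: at least 100 orientations are required",
         call. = FALSE)
  }
  if (nrow(conf$xyz) < 4 || qr(conf$xyz)$rank < 2) {
    stop("conformation must have at least 4 non-collinear atoms", call. = FALSE)
  }
  A <- tensor_core(conf$xyz, conf$atoms$charge, fibonacci_sphere(n_orient),
                   medium)
  alignment_tensor(A, medium = medium$kind)
}

# unchecked tensor computation shared by predict_tensor and the sampler's
# per-replica refresh (dirs precomputed by the caller)
tensor_core <- function(xyz, charges, dirs, medium) {
  tensor_from_weights(placement_weights(xyz, charges, dirs, medium), dirs,
                      medium)
}

tensor_from_weights <- function(w, dirs, medium) {
  sw <- sum(w)
  if (sw <= 0) {
    stop("molecule does not fit between the obstructions in any orientation",
         call. = FALSE)
  }
  M <- crossprod(dirs * sqrt(w / sw))       # sum_k w_k n_k n_k^T
  A <- medium$scale * (M - diag(3) / 3)
  A <- A - diag(3) * sum(diag(A)) / 3       # remove grid-level trace residue
  (A + t(A)) / 2
}

#' Fit an alignment tensor to measured RDCs by SVD
#'
#' Solves the linear least-squares problem for the five independent tensor
#' components that minimise `sum((D_calc - D_exp)^2)` over the table rows
#' of one medium, using the singular value decomposition of the direction-
#' cosine design matrix.
#'
#' @param conf a [conformation()].
#' @param rdc an `rdc_table` (see [read_rdc_table()]).
#' @param bonds a [bond_vector_set()].
#' @param medium medium id to fit; defaults to the single medium present.
#' @param D_max dipolar interaction constant in Hz.
#' @return list with `tensor` (an [alignment_tensor()]), `residuals` (Hz),
#'   `rmsd` (Hz) and `condition` (singular-value ratio).
#' @export
svd_fit_tensor <- function(conf, rdc, bonds, medium = NULL, D_max = -21700) {
  stopifnot(inherits(conf, "conformation"))
  if (is.null(medium)) {
    med <- unique(rdc$medium)
    if (length(med) != 1) {
      stop("table holds several media; pass `medium` explicitly", call. = FALSE)
    }
    medium <- med
  }
  rows <- rdc[rdc$medium == medium, , drop = FALSE]
  if (nrow(rows) < 5) {
    stop("conditioning error: at least 5 RDCs are needed to fit a tensor",
         call. = FALSE)
  }
  V <- bond_unit_vectors(conf, bonds)
  bi <- match(paste(rows$resno, rows$pair), paste(bonds$resno, bonds$pair))
  if (anyNA(bi)) {
    stop("mapping error: RDC row for residue ",
         rows$resno[which(is.na(bi))[1]], " has no bond vector", call. = FALSE)
  }
  v <- V[bi, , drop = FALSE]
  X <- cbind(v[, 1]^2 - v[, 3]^2, v[, 2]^2 - v[, 3]^2,
             2 * v[, 1] * v[, 2], 2 * v[, 1] * v[, 3], 2 * v[, 2] * v[, 3])
  y <- rows$D_exp / D_max
  sv <- svd(X)
  cond <- sv$d[5] / sv$d[1]
  if (!is.finite(cond) || cond < 1e-8) {
    stop("conditioning error: degenerate bond orientations (rank-deficient design)",
         call. = FALSE)
  }
  coef <- sv$v %*% ((crossprod(sv$u, y)) / sv$d)
  A <- matrix(c(coef[1], coef[3], coef[4],
                coef[3], coef[2], coef[5],
                coef[4], coef[5], -coef[1] - coef[2]), 3, 3)
  tensor <- alignment_tensor(A, medium = medium)
  D_fit <- D_max * as.numeric(X %*% coef)
  res <- rows$D_exp - D_fit
  list(tensor = tensor, residuals = res, rmsd = sqrt(mean(res^2)),
       condition = cond)
}

#' Calibrate the overall alignment magnitude of a medium
#'
#' The absolute degree of alignment is not separable from D_max in the RDC
#' equation, so each medium carries one dimensionless scale, set once so
#' that back-calculated couplings on a reference structure have a chosen
#' root-mean-square magnitude, and held fixed afterwards.
#'
#' @param conf reference [conformation()].
#' @param medium a [medium_spec()].
#' @param bonds a [bond_vector_set()].
#' @param target_rms desired RMS coupling in Hz.
#' @param D_max dipolar constant in Hz.
#' @param n_orient orientation-grid resolution.
#' @return a `medium_spec` with calibrated `scale`.
#' @export
calibrate_medium_scale <- function(conf, medium, bonds, target_rms = 8,
                                   D_max = -21700, n_orient = 256) {
  t0 <- predict_tensor(conf, medium, n_orient)
  D0 <- calc_rdc(conf, t0, bonds, D_max = D_max)
  rms <- sqrt(mean(D0^2))
  if (rms == 0) stop("cannot calibrate: zero predicted couplings", call. = FALSE)
  medium$scale <- medium$scale * target_rms / rms
  medium
}

#' @rdname alignment_tensor
#' @param x an `alignment_tensor`.
#' @param path output TSV path.
#' @export
write_tensor <- function(x, path) {
  stopifnot(inherits(x, "alignment_tensor"))
  A <- x$A
  df <- data.frame(medium = x$medium, A_xx = A[1, 1], A_yy = A[2, 2],
                   A_xy = A[1, 2], A_xz = A[1, 3], A_yz = A[2, 3])
  write.table(format(df, digits = 17), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname alignment_tensor
#' @export
read_tensor <- function(path) {
  df <- read_tsv_checked(path, c("medium", "A_xx", "A_yy", "A_xy", "A_xz", "A_yz"))
  A <- matrix(c(df$A_xx, df$A_xy, df$A_xz,
                df$A_xy, df$A_yy, df$A_yz,
                df$A_xz, df$A_yz, -df$A_xx - df$A_yy), 3, 3)
  alignment_tensor(A, medium = df$medium[1])
}
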