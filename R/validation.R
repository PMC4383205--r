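#' Three-bond J couplings from HNHA intensity ratios
#'
#' The HNHA cross- to diagonal-peak intensity ratio encodes the 3J HN-Halpha
#' coupling through `I_X / I_D = -tan^2(2 pi xi J)` with delay `xi`.
#' Extraction inverts this on the principal branch:
#' `J = atan(sqrt(-I_X / I_D)) / (2 pi xi)`.
#'
#' @param I_cross,I_diag cross- and diagonal-peak intensities (vectorised);
#'   `I_diag` must be nonzero and the ratio nonpositive.
#' @param xi HNHA delay in seconds (default 0.01305 s).
#' @return couplings in Hz.
#' @export
j_from_hnha <- function(I_cross, I_diag, xi = 0.01305) {
  if (any(I_diag == 0)) {
    stop("I_diag must be nonzero", call. = FALSE)
  }
  ratio <- I_cross / I_diag
  if (any(ratio > 0)) {
    stop("sign-convention error: I_X/I_D must be <= 0", call. = FALSE)
  }
  atan(sqrt(-ratio)) / (2 * pi * xi)
}

#' @rdname j_from_hnha
#' @description `hnha_intensity_ratio()` is the forward map `J -> I_X/I_D`,
#'   the exact inverse of `j_from_hnha()` on the principal branch.
#' @param J couplings in Hz (must satisfy `2 pi xi J < pi/2`).
#' @export
hnha_intensity_ratio <- function(J, xi = 0.01305) {
  if (any(abs(2 * pi * xi * J) >= pi / 2)) {
    stop("branch error: 2 pi xi J must be below pi/2", call. = FALSE)
  }
  -tan(2 * pi * xi * J)^2
}

#' @rdname j_from_hnha
#' @description `hnha_error()` propagates intensity uncertainties to the
#'   coupling by first-order error propagation; each intensity's
#'   uncertainty is the larger of a relative floor and the spectrum noise
#'   level.
#' @param noise spectrum noise level (intensity units).
#' @param rel_floor relative intensity-uncertainty floor (default 5%).
#' @export
hnha_error <- function(I_cross, I_diag, noise, xi = 0.01305,
                       rel_floor = 0.05) {
  s_x <- pmax(rel_floor * abs(I_cross), noise)
  s_d <- pmax(rel_floor * abs(I_diag), noise)
  ratio <- I_cross / I_diag
  s_r <- ifelse(I_cross == 0,
                s_x / abs(I_diag),
                abs(ratio) * sqrt((s_x / I_cross)^2 + (s_d / I_diag)^2))
  t <- sqrt(-ratio)
  # dJ/dR = -1 / (4 pi xi t (1 + t^2)); singular at t = 0
  dJdR <- ifelse(t > 0, 1 / (4 * pi * xi * t * (1 + t^2)), NA_real_)
  ifelse(is.na(dJdR), Inf * s_r, dJdR * s_r)
}

#' @rdname j_from_hnha
#' @description `extract_j_couplings()` applies extraction, error
#'   propagation and the flagging rules to a whole table: glycine rows and
#'   rows with zero diagonal intensity are `discarded`; rows whose cross
#'   peak is below the noise level are flagged `below-noise`.
#' @param hnha an `hnha_table` (see [read_hnha_table()]).
#' @return data.frame with `resno`, `J`, `error`, `flag`.
#' @export
extract_j_couplings <- function(hnha, xi = 0.01305, rel_floor = 0.05) {
  stopifnot(inherits(hnha, "hnha_table"))
  n <- nrow(hnha)
  J <- rep(NA_real_, n)
  err <- rep(NA_real_, n)
  flag <- rep("measured", n)
  flag[hnha$resid == "GLY"] <- "discarded"
  flag[hnha$I_diag == 0] <- "discarded"
  ok <- flag != "discarded"
  J[ok] <- j_from_hnha(hnha$I_cross[ok], hnha$I_diag[ok], xi = xi)
  err[ok] <- hnha_error(hnha$I_cross[ok], hnha$I_diag[ok], hnha$noise[ok],
                        xi = xi, rel_floor = rel_floor)
  flag[ok & abs(hnha$I_cross) < hnha$noise] <- "below-noise"
  data.frame(resno = hnha$resno, J = J, error = err, flag = flag,
             stringsAsFactors = FALSE)
}

# torsion angle (degrees, in (-180, 180]) of four points
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / vnorm(b2)
  rad2deg(atan2(sum(m1 * n2), sum(n1 * n2)))
}

#' Backbone phi dihedrals of a conformation
#'
#' For all-atom backbones, the standard `phi_i = C(i-1)-N(i)-CA(i)-C(i)`.
#' Coarse-grained chains without C/CA atoms fall back to the pseudo-torsion
#' of four consecutive residue particles centred on residue i.
#'
#' @param conf a [conformation()].
#' @return data.frame with `resno` and `phi` (degrees).
#' @export
residue_phi <- function(conf) {
  atoms <- conf$atoms
  res <- sort(unique(atoms$resno))
  full <- all(c("C", "N", "CA") %in% atoms$elety)
  get1 <- function(rn, el) {
    i <- which(atoms$resno == rn & atoms$elety == el)
    if (length(i) != 1) {
      stop("selection error: residue ", rn, " lacks backbone atom ", el,
           call. = FALSE)
    }
    conf$xyz[i, ]
  }
  if (full) {
    has <- function(rn, el) any(atoms$resno == rn & atoms$elety == el)
    rs <- res[-1]
    rs <- rs[vapply(rs, function(rn) {
      has(rn - 1, "C") && has(rn, "N") && has(rn, "CA") && has(rn, "C")
    }, logical(1))]
    if (length(rs) == 0) {
      stop("selection error: no residue has a complete phi definition",
           call. = FALSE)
    }
    phi <- vapply(rs, function(rn) {
      dihedral_angle(get1(rn - 1, "C"), get1(rn, "N"), get1(rn, "CA"),
                     get1(rn, "C"))
    }, numeric(1))
  } else {
    if (length(res) < 4) stop("too few residues for pseudo-dihedrals",
                              call. = FALSE)
    rs <- res[2:(length(res) - 2)]
    phi <- vapply(rs, function(rn) {
      dihedral_angle(get1(rn - 1, "N"), get1(rn, "N"), get1(rn + 1, "N"),
                     get1(rn + 2, "N"))
    }, numeric(1))
  }
  data.frame(resno = rs, phi = phi)
}

#' Ensemble-averaged Karplus back-calculation of 3J couplings
#'
#' `3J(phi) = A cos^2(phi - 60) + B cos(phi - 60) + C`, evaluated per
#' residue per conformation and averaged over the ensemble.  The
#' coefficients are explicit and overridable.
#'
#' @param ens an [ensemble()].
#' @param karplus named coefficients `c(A=, B=, C=)` in Hz.
#' @return data.frame with `resno` and `J` (Hz).
#' @export
backcalc_j <- function(ens, karplus = c(A = 7.09, B = -1.42, C = 1.55)) {
  stopifnot(inherits(ens, "ensemble"))
  karp <- function(phi) {
    cs <- cos(deg2rad(phi - 60))
    karplus[["A"]] * cs^2 + karplus[["B"]] * cs + karplus[["C"]]
  }
  acc <- NULL
  for (k in seq_len(n_models(ens))) {
    ph <- residue_phi(get_conformation(ens, k))
    if (is.null(acc)) {
      acc <- ph
      acc$J <- karp(ph$phi)
      acc$phi <- NULL
    } else {
      acc$J <- acc$J + karp(ph$phi)
    }
  }
  acc$J <- acc$J / n_models(ens)
  acc
}

#' Per-structure NOE satisfaction
#'
#' An NOE is satisfied in a structure iff the pair distance is at most
#' `bound + tolerance`.  Pairs whose atoms cannot be resolved in the
#' topology are listed, excluded, and counted — never silently dropped.
#'
#' @param ens an [ensemble()].
#' @param noes an `noe_table` (see [read_noe_table()]).
#' @param tolerance added to each bound (A, default 0.5).
#' @return list: `per_structure` data.frame (`model`, `satisfied`,
#'   `violated`, summing to 1), `mean_satisfied`, `n_used`, `excluded`
#'   (data.frame of unresolvable pairs).
#' @export
noe_satisfaction <- function(ens, noes, tolerance = 0.5) {
  stopifnot(inherits(ens, "ensemble"), inherits(noes, "noe_table"))
  atoms <- ens$atoms
  key <- paste(atoms$resno, atoms$elety)
  i1 <- match(paste(noes$resno1, noes$atom1), key)
  i2 <- match(paste(noes$resno2, noes$atom2), key)
  bad <- is.na(i1) | is.na(i2)
  excluded <- noes[bad, , drop = FALSE]
  i1 <- i1[!bad]; i2 <- i2[!bad]
  bounds <- noes$bound[!bad]
  if (length(bounds) == 0) {
    stop("no resolvable NOE pairs", call. = FALSE)
  }
  nm <- n_models(ens)
  sat <- vapply(seq_len(nm), function(k) {
    d1 <- matrix(ens$xyz[k, i1, ], ncol = 3)
    d2 <- matrix(ens$xyz[k, i2, ], ncol = 3)
    d <- sqrt(rowSums((d1 - d2)^2))
    mean(d <= bounds + tolerance)
  }, numeric(1))
  list(per_structure = data.frame(model = seq_len(nm), satisfied = sat,
                                  violated = 1 - sat),
       mean_satisfied = mean(sat), n_used = length(bounds),
       excluded = excluded)
}

#' Consolidated ensemble validation report
#'
#' Aggregates the independent-data checks on an ensemble: per-medium RDC Q
#' factors (couplings back-calculated with per-frame predicted tensors),
#' the RMS deviation between extracted and back-calculated 3J couplings,
#' and per-structure NOE satisfaction.  At least one validation input must
#' be supplied.
#'
#' @param ens an [ensemble()].
#' @param bonds a [bond_vector_set()] (required with `rdc`).
#' @param media named list of [medium_spec()] (required with `rdc`).
#' @param rdc optional `rdc_table`.
#' @param hnha optional `hnha_table`.
#' @param noes optional `noe_table`.
#' @param xi HNHA delay (s).
#' @param karplus Karplus coefficients (Hz).
#' @param noe_tolerance NOE tolerance (A).
#' @param n_orient tensor-prediction grid resolution.
#' @return object of class `validation_report`.
#' @export
build_report <- function(ens, bonds = NULL, media = NULL, rdc = NULL,
                         hnha = NULL, noes = NULL, xi = 0.01305,
                         karplus = c(A = 7.09, B = -1.42, C = 1.55),
                         noe_tolerance = 0.5, n_orient = 256) {
  if (is.null(rdc) && is.null(hnha) && is.null(noes)) {
    stop("precondition error: at least one validation input is required",
         call. = FALSE)
  }
  rep <- list(counts = list())
  if (!is.null(rdc)) {
    stopifnot(!is.null(bonds), !is.null(media))
    clean <- ensemble_average_rdc(ens, bonds, media, n_orient = n_orient)
    Dtab <- do.call(rbind, lapply(names(clean), function(nmed) {
      data.frame(resno = bonds$resno, pair = bonds$pair, medium = nmed,
                 D_calc = clean[[nmed]], stringsAsFactors = FALSE)
    }))
    rep$q <- q_factor(Dtab, rdc)
    rep$counts$rdc_used <- nrow(rdc)
  }
  if (!is.null(hnha)) {
    ext <- extract_j_couplings(hnha, xi = xi)
    calc <- backcalc_j(ens, karplus = karplus)
    use <- ext$flag != "discarded"
    idx <- match(ext$resno[use], calc$resno)
    ok <- !is.na(idx)
    diffs <- ext$J[use][ok] - calc$J[idx[ok]]
    rep$j_rmsd <- sqrt(mean(diffs^2))
    rep$j_extracted <- ext
    rep$counts$j_used <- sum(ok)
    rep$counts$j_discarded <- sum(!use)
  }
  if (!is.null(noes)) {
    rep$noe <- noe_satisfaction(ens, noes, tolerance = noe_tolerance)
    rep$counts$noe_used <- rep$noe$n_used
    rep$counts$noe_excluded <- nrow(rep$noe$excluded)
  }
  class(rep) <- "validation_report"
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  if (!is.null(x$q)) {
    cat("  Q factors:",
        paste(names(x$q), sprintf("%.3f", unlist(x$q)), collapse = ", "),
        "\n")
  }
  if (!is.null(x$j_rmsd)) {
    cat("  3J RMSD:", sprintf("%.3f Hz", x$j_rmsd), "\n")
  }
  if (!is.null(x$noe)) {
    cat("  NOE satisfied (mean over structures):",
        sprintf("%.3f", x$noe$mean_satisfied), "\n")
  }
  invisible(x)
}

#' @rdname build_report
#' @param x a `validation_report`.
#' @param path output TSV path (long format: metric, value).
#' @export
write_report <- function(x, path) {
  stopifnot(inherits(x, "validation_report"))
  rows <- list()
  if (!is.null(x$q)) {
    for (nm in names(x$q)) {
      rows[[length(rows) + 1]] <- data.frame(metric = paste0("Q_", nm),
                                             value = x$q[[nm]])
    }
  }
  if (!is.null(x$j_rmsd)) {
    rows[[length(rows) + 1]] <- data.frame(metric = "J_rmsd_Hz",
                                           value = x$j_rmsd)
  }
  if (!is.null(x$noe)) {
    rows[[length(rows) + 1]] <- data.frame(metric = "NOE_mean_satisfied",
                                           value = x$noe$mean_satisfied)
  }
  for (nm in names(x$counts)) {
    rows[[length(rows) + 1]] <- data.frame(metric = paste0("n_", nm),
                                           value = x$counts[[nm]])
  }
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
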