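#' Read a (multi-model) PDB file as an ensemble
#'
#' Each MODEL record becomes one conformation; a file without MODEL records
#' is a single-model ensemble.  All models must share the same atoms in the
#' same order.  If a weights sidecar (`<path>.weights.tsv`, written by
#' [write_conformations()]) is present it is read back as ensemble weights.
#'
#' @param path PDB file path.
#' @return An [ensemble()].
#' @export
read_conformations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  model_starts <- grep("^MODEL", lines)
  parse_one <- function(lns) {
    tf <- tempfile(fileext = ".pdb")
    on.exit(unlink(tf))
    writeLines(c(lns, "END"), tf)
    pdb <- tryCatch(bio3d::read.pdb(tf, verbose = FALSE),
                    error = function(e) stop("format error: ", conditionMessage(e),
                                             call. = FALSE))
    a <- pdb$atom
    list(atoms = data.frame(chain = a$chain, resno = a$resno, resid = a$resid,
                            elety = a$elety, elesy = a$elesy,
                            stringsAsFactors = FALSE),
         xyz = cbind(a$x, a$y, a$z))
  }
  if (length(model_starts) == 0) {
    m <- parse_one(lines)
    models <- list(m)
  } else {
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_ends) != length(model_starts)) {
      stop("format error: unbalanced MODEL/ENDMDL records", call. = FALSE)
    }
    models <- mapply(function(s, e) parse_one(lines[(s + 1):(e - 1)]),
                     model_starts, model_ends, SIMPLIFY = FALSE)
  }
  ref <- models[[1]]
  confs <- vector("list", length(models))
  for (k in seq_along(models)) {
    mk <- models[[k]]
    if (nrow(mk$atoms) != nrow(ref$atoms) ||
        !identical(mk$atoms[c("chain", "resno", "elety")],
                   ref$atoms[c("chain", "resno", "elety")])) {
      stop("topology error: model ", k, " does not match model 1", call. = FALSE)
    }
    confs[[k]] <- conformation(mk$atoms, mk$xyz, model = k)
  }
  weights <- NULL
  side <- paste0(path, ".weights.tsv")
  if (file.exists(side)) {
    w <- read.delim(side)
    weights <- w$weight
  }
  ensemble(confs, weights = weights)
}

#' Write an ensemble as a multi-model PDB file
#'
#' Coordinates are written at PDB precision (1e-3 Angstrom); ensemble
#' weights, if present, go to a `<path>.weights.tsv` sidecar since the PDB
#' format has no weight field.
#'
#' @param ens an [ensemble()] (non-empty).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_conformations <- function(ens, path) {
  if (!inherits(ens, "ensemble") || n_models(ens) < 1) {
    stop("precondition error: a non-empty ensemble is required", call. = FALSE)
  }
  a <- ens$atoms
  nm <- n_models(ens)
  xyz_flat <- matrix(NA_real_, nrow = nm, ncol = 3 * n_atoms(ens))
  for (k in seq_len(nm)) xyz_flat[k, ] <- as.vector(t(ens$xyz[k, , ]))
  ok <- tryCatch({
    bio3d::write.pdb(pdb = NULL, file = path, xyz = xyz_flat,
                     type = rep("ATOM", nrow(a)), eleno = seq_len(nrow(a)),
                     elety = a$elety, resid = a$resid, chain = a$chain,
                     resno = a$resno, o = rep(1, nrow(a)), b = rep(0, nrow(a)),
                     elesy = a$elesy)
    TRUE
  }, error = function(e) FALSE, warning = function(w) TRUE)
  if (!ok || !file.exists(path)) stop("I/O error: cannot write ", path, call. = FALSE)
  if (!is.null(ens$weights)) {
    write.table(data.frame(model = seq_len(nm), weight = ens$weights),
                paste0(path, ".weights.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(required, names(tab))
  if (length(miss) > 0) {
    stop("validation error: missing column(s) ", paste(miss, collapse = ", "),
         " in ", path, call. = FALSE)
  }
  tab
}

#' Read an RDC table
#'
#' Tab-separated with a one-line header and columns `resno`, `pair`
#' (e.g. "N-H"), `medium` ("steric" or "electrostatic"), `D_exp` (Hz) and
#' `sigma` (Hz).  Lines starting with `#` are comments.
#'
#' @param path TSV file path.
#' @return data.frame of class `rdc_table`.
#' @export
read_rdc_table <- function(path) {
  tab <- read_tsv_checked(path, c("resno", "pair", "medium", "D_exp", "sigma"))
  validate_rdc_table(tab)
}

validate_rdc_table <- function(tab) {
  tab$resno <- as.integer(tab$resno)
  bad_med <- setdiff(unique(tab$medium), c("steric", "electrostatic"))
  if (length(bad_med) > 0) {
    stop("validation error: unknown medium '", bad_med[1], "'", call. = FALSE)
  }
  if (any(!is.finite(tab$sigma)) || any(tab$sigma <= 0)) {
    stop("validation error: sigma must be > 0 for every row", call. = FALSE)
  }
  key <- paste(tab$resno, tab$pair, tab$medium)
  if (anyDuplicated(key)) {
    stop("validation error: duplicate (residue, pair, medium) key: ",
         key[which(duplicated(key))[1]], call. = FALSE)
  }
  class(tab) <- c("rdc_table", "data.frame")
  tab
}

#' Read an NOE distance-bound table
#'
#' Columns: `resno1`, `atom1`, `resno2`, `atom2`, `bound` (upper distance
#' bound, Angstrom).
#'
#' @param path TSV file path.
#' @return data.frame of class `noe_table`.
#' @export
read_noe_table <- function(path) {
  tab <- read_tsv_checked(path, c("resno1", "atom1", "resno2", "atom2", "bound"))
  if (any(tab$bound <= 0)) {
    stop("validation error: NOE bounds must be > 0", call. = FALSE)
  }
  class(tab) <- c("noe_table", "data.frame")
  tab
}

#' Read an HNHA intensity table
#'
#' Columns: `resno`, `resid` (residue name; glycines are excluded from
#' extraction), `I_cross`, `I_diag`, `noise` (same intensity units).
#'
#' @param path TSV file path.
#' @return data.frame of class `hnha_table`.
#' @export
read_hnha_table <- function(path) {
  tab <- read_tsv_checked(path, c("resno", "resid", "I_cross", "I_diag", "noise"))
  if (any(tab$noise < 0)) {
    stop("validation error: noise level must be >= 0", call. = FALSE)
  }
  class(tab) <- c("hnha_table", "data.frame")
  tab
}

#' Default run configuration
#'
#' All sampler, restraint, landscape and medium parameters with their
#' defaults.  `load_config()` overlays a YAML file on these values.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    sampler = list(
      replicas = 16L,          # replica count M for replica averaging
      cycles = 50L,            # simulated-annealing cycles
      T_low = 310,             # K
      T_high = 500,            # K
      cycle_ps = 250,          # ps of nominal dynamics per cycle
      timestep_fs = 2,         # fs, for integrator-step arithmetic
      sweeps_high = 30L,       # MC sweeps in the hot segment of a cycle
      sweeps_low = 40L,        # MC sweeps in the annealed segment
      collect_ps = 50,         # collection window at the end of a cycle
      frames_per_ps = 1,
      cycles_retained = 30L,   # final cycles whose windows are collected
      equil_sweeps = 100L,     # alpha-ramp equilibration sweeps
      jitter_sd = 0.15,        # A, particle-translation proposal
      rot_sd = 2,              # deg, domain-rotation proposal
      seed = 0L
    ),
    restraint = list(
      alpha = 60,              # kJ/mol/Hz^2, target restraint weight
      alpha_ramp_factor = 1.6, # geometric ramp multiplier per stage
      alpha_start = 5,         # kJ/mol/Hz^2
      min_acceptance = 0.2,    # ramp stops if acceptance falls below this
      D_max = -21700           # Hz, N-H dipolar interaction constant
    ),
    landscape = list(
      theta_bin_deg = 1,
      rmsd_bin_A = 0.1,
      basin_boundary_deg = 50,
      temperature_K = 310
    ),
    media = list(
      steric = list(kind = "steric", spacing = 120, probe_radius = 2.0,
                    scale = 1.0),
      electrostatic = list(kind = "electrostatic", spacing = 120,
                           probe_radius = 2.0, wall_charge = 2.0,
                           debye_length = 15, scale = 1.0)
    ),
    validation = list(
      xi_s = 0.01305,          # HNHA delay (s)
      karplus = c(A = 7.09, B = -1.42, C = 1.55),  # Hz
      noe_tolerance_A = 0.5,
      hbond_dist_A = 3.5,
      hbond_angle_deg = 120,
      intensity_floor = 0.05   # relative intensity-uncertainty floor
    )
  )
}

#' Load and validate a YAML run configuration
#'
#' Values from the file override [default_config()]; keys not present in
#' the defaults are rejected, so typos never pass silently.  Media entries
#' must name their `kind`.
#'
#' @param path YAML file path.
#' @return validated nested configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config error: file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  defaults <- default_config()
  merge_checked <- function(def, usr, where) {
    unknown <- setdiff(names(usr), names(def))
    if (length(unknown) > 0) {
      stop("config error: unknown key '",
           paste0(where, unknown[1]), "'", call. = FALSE)
    }
    for (k in names(usr)) {
      if (is.list(def[[k]]) && !is.null(names(def[[k]]))) {
        if (!is.list(usr[[k]])) {
          stop("config error: '", where, k, "' must be a mapping", call. = FALSE)
        }
        def[[k]] <- merge_checked(def[[k]], usr[[k]], paste0(where, k, "."))
      } else {
        def[[k]] <- usr[[k]]
      }
    }
    def
  }
  # media blocks may be replaced wholesale, but each must declare its kind
  if (!is.null(user$media)) {
    for (m in names(user$media)) {
      if (is.null(user$media[[m]]$kind)) {
        stop("config error: missing required key 'media.", m, ".kind'",
             call. = FALSE)
      }
    }
    media <- user$media
    user$media <- NULL
    cfg <- merge_checked(defaults, user, "")
    for (m in names(media)) {
      base <- defaults$media[[media[[m]]$kind]]
      if (is.null(base)) {
        stop("config error: media kind must be steric or electrostatic",
             call. = FALSE)
      }
      cfg$media[[m]] <- modifyList(base, media[[m]])
    }
    cfg
  } else {
    merge_checked(defaults, user, "")
  }
}
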