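#' Conformation and ensemble containers
#'
#' A `conformation` is one set of labelled atom coordinates: an atom table
#' (chain, residue number, residue name, atom name, element, optional
#' partial charge) plus an n x 3 coordinate matrix in Angstrom.  An
#' `ensemble` is an ordered set of conformations sharing one topology,
#' stored as a single atom table plus an n_models x n_atoms x 3 coordinate
#' array, with optional normalised weights and optional per-frame metadata.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resid`, `elety`
#'   (atom name), `elesy` (element); an optional `charge` column (units of
#'   elementary charge) is used by electrostatic alignment media.
#' @param xyz numeric n_atoms x 3 matrix of coordinates (Angstrom).
#' @param model integer model id.
#' @return An object of class `conformation`.
#' @export
conformation <- function(atoms, xyz, model = 1L) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  req <- c("chain", "resno", "resid", "elety", "elesy")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0) {
    stop("atom table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(atoms$charge)) atoms$charge <- 0
  atoms$resno <- as.integer(atoms$resno)
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3 || nrow(xyz) != nrow(atoms)) {
    stop("xyz must be an n_atoms x 3 matrix matching the atom table",
         call. = FALSE)
  }
  if (!all(is.finite(xyz))) stop("non-finite coordinates", call. = FALSE)
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key)) {
    stop("duplicate (chain, residue, atom name) in conformation",
         call. = FALSE)
  }
  structure(list(atoms = atoms, xyz = unname(xyz), model = as.integer(model)),
            class = "conformation")
}

#' @rdname conformation
#' @param conformations list of `conformation` objects with identical
#'   topology (same atoms in the same order).
#' @param weights optional nonnegative weights, one per conformation,
#'   summing to 1 (tolerance 1e-9).
#' @param frame_info optional data.frame of per-frame metadata (e.g.
#'   `E_pot`, `cycle`, `replica`, `state`).
#' @export
ensemble <- function(conformations, weights = NULL, frame_info = NULL) {
  if (length(conformations) < 1) stop("ensemble must be non-empty", call. = FALSE)
  ref <- conformations[[1]]
  stopifnot(inherits(ref, "conformation"))
  sig <- function(a) paste(a$chain, a$resno, a$elety, collapse = "|")
  ref_sig <- sig(ref$atoms)
  n_atoms <- nrow(ref$atoms)
  for (k in seq_along(conformations)) {
    ck <- conformations[[k]]
    if (nrow(ck$atoms) != n_atoms || sig(ck$atoms) != ref_sig) {
      stop("topology mismatch: conformation ", k,
           " does not share the ensemble's atom identities", call. = FALSE)
    }
  }
  xyz <- array(NA_real_, dim = c(length(conformations), n_atoms, 3))
  for (k in seq_along(conformations)) xyz[k, , ] <- conformations[[k]]$xyz
  new_ensemble(ref$atoms, xyz, weights, frame_info)
}

new_ensemble <- function(atoms, xyz_array, weights = NULL, frame_info = NULL) {
  stopifnot(length(dim(xyz_array)) == 3, dim(xyz_array)[3] == 3)
  if (!is.null(weights)) {
    weights <- as.numeric(weights)
    if (length(weights) != dim(xyz_array)[1]) {
      stop("weights length must equal number of conformations", call. = FALSE)
    }
    if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
    if (abs(sum(weights) - 1) > 1e-9) {
      stop("weights must sum to 1 (within 1e-9)", call. = FALSE)
    }
  }
  if (!is.null(frame_info)) {
    frame_info <- as.data.frame(frame_info)
    stopifnot(nrow(frame_info) == dim(xyz_array)[1])
  }
  if (is.null(atoms$charge)) atoms$charge <- 0
  structure(list(atoms = atoms, xyz = xyz_array, weights = weights,
                 frame_info = frame_info),
            class = "ensemble")
}

#' @rdname conformation
#' @param x an ensemble.
#' @param i model index.
#' @export
get_conformation <- function(x, i) {
  stopifnot(inherits(x, "ensemble"), i >= 1, i <= n_models(x))
  conformation(x$atoms, x$xyz[i, , , drop = TRUE], model = i)
}

#' @rdname conformation
#' @export
n_models <- function(x) {
  if (inherits(x, "conformation")) return(1L)
  dim(x$xyz)[1]
}

#' @rdname conformation
#' @export
n_atoms <- function(x) nrow(x$atoms)

#' @export
print.conformation <- function(x, ...) {
  cat("<conformation> ", n_atoms(x), " atoms, ",
      length(unique(x$atoms$resno)), " residues\n", sep = "")
  invisible(x)
}

#' @export
print.ensemble <- function(x, ...) {
  cat("<ensemble> ", n_models(x), " models x ", n_atoms(x), " atoms",
      if (!is.null(x$weights)) ", weighted" else "", "\n", sep = "")
  invisible(x)
}

# row indices of atoms matching (resno, elety); error if any are missing
atom_rows <- function(atoms, resno, elety) {
  idx <- match(paste(resno, elety), paste(atoms$resno, atoms$elety))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop("atom not found in topology: residue ", resno[bad], " atom ",
         elety[bad], call. = FALSE)
  }
  idx
}

# row indices for a residue selection on one atom name (default CA, falling
# back to N for coarse-grained chains that carry no CA atoms)
select_residue_atoms <- function(atoms, resno_list, atom_filter = "CA") {
  present <- atom_filter %in% atoms$elety
  if (!present && atom_filter == "CA" && "N" %in% atoms$elety) atom_filter <- "N"
  idx <- which(atoms$elety == atom_filter & atoms$resno %in% resno_list)
  found <- unique(atoms$resno[idx])
  missing <- setdiff(resno_list, found)
  if (length(missing) > 0) {
    stop("selection error: residue(s) ", paste(missing, collapse = ", "),
         " have no '", atom_filter, "' atom", call. = FALSE)
  }
  idx
}
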