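#' @useDynLib mdtk, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats sd var rnorm rbinom runif setNames
#' @importFrom utils head tail write.table read.table
#' @importFrom yaml read_yaml
NULL

# Standard atomic masses (amu) and a fixed Bondi-style vdW radius set (A).
# Unknown elements fall back to .default_vdw with a warning.
.atomic_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305,
  NA. = 22.990, K = 39.098, CL = 35.45, CA = 40.078
)
.vdw_radii <- c(
  C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80,
  SE = 1.90, FE = 1.45, ZN = 1.39, MG = 1.73
)
.default_vdw <- 1.70
.default_mass <- 12.011

#' Construct a molecular structure
#'
#' An `md_structure` bundles an ordered atom table with one coordinate set.
#' Atom order is significant and preserved by every operation in the package.
#'
#' @param atoms data.frame with columns `serial`, `atom_name`, `element`,
#'   `residue_name`, `residue_index`, `chain_id`, and optionally `occupancy`,
#'   `bfactor`, `mass`, `vdw_radius`.
#' @param xyz numeric N x 3 matrix of coordinates in Angstrom.
#' @return An object of class `md_structure`.
#' @export
md_structure <- function(atoms, xyz) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (nrow(atoms) != nrow(xyz))
    stop("coordinate row count (", nrow(xyz), ") does not match atom count (",
         nrow(atoms), ")")
  if (nrow(xyz) > 0 && !all(is.finite(xyz)))
    stop("non-finite coordinates")
  need <- c("serial", "atom_name", "element", "residue_name",
            "residue_index", "chain_id")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table missing columns: ",
                         paste(miss, collapse = ", "))
  for (col in c("occupancy", "bfactor"))
    if (is.null(atoms[[col]])) atoms[[col]] <- if (col == "occupancy") 1 else 0
  key <- paste(atoms$chain_id, atoms$residue_index, atoms$atom_name)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom_name) records: ",
         paste(unique(key[duplicated(key)])[1:min(3, sum(duplicated(key)))],
               collapse = "; "))
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(atoms = atoms, xyz = xyz), class = "md_structure")
}

#' @export
print.md_structure <- function(x, ...) {
  ch <- unique(x$atoms$chain_id)
  cat("md_structure:", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain_id, x$atoms$residue_index))),
      "residues, chains:", paste(ch, collapse = " "), "\n")
  invisible(x)
}

#' Construct a trajectory
#'
#' An `md_trajectory` holds a topology (an [md_structure] supplying the atom
#' metadata) plus `T` coordinate frames and a frame spacing in picoseconds.
#'
#' @param topology an [md_structure]; its coordinates are frame 1 unless
#'   `frames` is given explicitly.
#' @param frames numeric array of dimension `c(N, 3, T)`.
#' @param frame_dt frame spacing in psec (> 0).
#' @return An object of class `md_trajectory`.
#' @export
md_trajectory <- function(topology, frames, frame_dt = 250) {
  stopifnot(inherits(topology, "md_structure"))
  if (length(dim(frames)) != 3) stop("frames must be an N x 3 x T array")
  if (dim(frames)[1] != nrow(topology$atoms) || dim(frames)[2] != 3)
    stop("frame dimensions do not match topology")
  if (dim(frames)[3] < 1) stop("a trajectory needs at least one frame")
  if (!is.numeric(frame_dt) || frame_dt <= 0) stop("frame_dt must be > 0")
  structure(list(topology = topology, frames = frames,
                 frame_dt = as.numeric(frame_dt)),
            class = "md_trajectory")
}

#' Number of frames in a trajectory
#' @param traj an [md_trajectory]
#' @return integer frame count
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "md_trajectory"))
  dim(traj$frames)[3]
}

#' Extract one frame of a trajectory as a structure
#' @param traj an [md_trajectory]
#' @param i frame index (1-based)
#' @return an [md_structure]
#' @export
get_frame <- function(traj, i) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (i < 1 || i > n_frames(traj)) stop("frame index ", i, " out of range")
  md_structure(traj$topology$atoms, traj$frames[, , i, drop = TRUE])
}

#' @export
print.md_trajectory <- function(x, ...) {
  T <- n_frames(x)
  cat("md_trajectory:", T, "frames x", nrow(x$topology$atoms), "atoms,",
      "dt =", x$frame_dt, "psec (", T * x$frame_dt / 1e6, "usec total )\n")
  invisible(x)
}

#' Assign atomic masses and van der Waals radii
#'
#' Fills the `mass` and `vdw_radius` columns from the element symbol, using
#' standard atomic masses and a fixed Bondi-style radius set (C 1.70, N 1.55,
#' O 1.52, S 1.80, H 1.20 A).  Elements absent from the tables receive the
#' documented defaults (12.011 amu, 1.70 A) with a warning.  Elements are
#' inferred from the atom name when the element field is blank.
#'
#' @param structure an [md_structure]
#' @return the structure with `mass` and `vdw_radius` populated
#' @export
assign_masses_radii <- function(structure) {
  stopifnot(inherits(structure, "md_structure"))
  at <- structure$atoms
  if (nrow(at) == 0) stop("cannot assign masses to an empty structure")
  el <- toupper(trimws(at$element))
  blank <- is.na(el) | el == ""
  if (any(blank)) el[blank] <- .element_from_name(at$atom_name[blank])
  unknown <- !(el %in% names(.atomic_masses))
  if (any(unknown))
    warning("unknown element(s) ", paste(unique(el[unknown]), collapse = ", "),
            ": default mass ", .default_mass, " amu and radius ",
            .default_vdw, " A applied")
  at$element <- el
  at$mass <- unname(ifelse(unknown, .default_mass, .atomic_masses[el]))
  rad <- .vdw_radii[el]
  at$vdw_radius <- unname(ifelse(is.na(rad), .default_vdw, rad))
  structure$atoms <- at
  structure
}

# Element from PDB atom-name column: leading digits stripped, a leading H
# anywhere (1HG1 etc.) means hydrogen, otherwise the first letter.
.element_from_name <- function(name) {
  nm <- toupper(trimws(name))
  nm <- sub("^[0-9']+", "", nm)
  el <- substr(nm, 1, 1)
  two <- substr(nm, 1, 2)
  el[two %in% c("SE", "FE", "ZN", "MG", "CL")] <-
    two[two %in% c("SE", "FE", "ZN", "MG", "CL")]
  el
}

# residue-level bookkeeping: unique (chain, resid) in atom order
.residue_table <- function(atoms) {
  key <- paste(atoms$chain_id, atoms$residue_index)
  first <- !duplicated(key)
  data.frame(chain_id = atoms$chain_id[first],
             residue_index = atoms$residue_index[first],
             residue_name = atoms$residue_name[first],
             key = key[first], stringsAsFactors = FALSE)
}
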