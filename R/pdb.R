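.water_names <- c("HOH", "WAT", "TIP3", "TIP", "SOL", "DOD")
.ion_names <- c("NA", "CL", "K", "MG", "ZN", "CA", "MN", "FE", "CU", "IOD",
                "BR", "CS", "LI", "SO4", "PO4")

#' Read a (multi-model) PDB file
#'
#' Parses fixed-column ATOM/HETATM records.  Files with more than one MODEL
#' block become an [md_trajectory] whose topology is taken from the first
#' model; files with at most one MODEL become an [md_structure].  HETATM
#' waters and ions are excluded by default.  Alternate locations are reduced
#' to the highest-occupancy conformer (ties: first encountered).  Masses and
#' van der Waals radii are assigned on read.
#'
#' @param path PDB file path.
#' @param exclude_solvent drop HETATM water/ion records (default TRUE).
#' @param frame_dt frame spacing in psec attached to multi-model files.
#' @return an [md_structure] or [md_trajectory]
#' @export
read_pdb <- function(path, exclude_solvent = TRUE, frame_dt = 250) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- startsWith(rec, "MODEL")
  is_end <- startsWith(rec, "ENDMDL")
  # model id per line: 0 until the first MODEL record
  model_id <- cumsum(is_model)
  model_id[is_end] <- 0L
  n_models <- max(model_id)

  parse_block <- function(idx, label) {
    ln <- lines[idx]
    het <- substr(ln, 1, 6) == "HETATM"
    at <- data.frame(
      serial = suppressWarnings(as.integer(substr(ln, 7, 11))),
      atom_name = trimws(substr(ln, 13, 16)),
      altloc = substr(ln, 17, 17),
      residue_name = trimws(substr(ln, 18, 20)),
      chain_id = substr(ln, 22, 22),
      residue_index = suppressWarnings(as.integer(substr(ln, 23, 26))),
      occupancy = suppressWarnings(as.numeric(substr(ln, 55, 60))),
      bfactor = suppressWarnings(as.numeric(substr(ln, 61, 66))),
      element = trimws(substr(ln, 77, 78)),
      het = het, stringsAsFactors = FALSE)
    xyz <- cbind(suppressWarnings(as.numeric(substr(ln, 31, 38))),
                 suppressWarnings(as.numeric(substr(ln, 39, 46))),
                 suppressWarnings(as.numeric(substr(ln, 47, 54))))
    bad <- which(!stats::complete.cases(xyz))
    if (length(bad))
      stop("unparsable coordinate field at line ", idx[bad[1]],
           " (", label, "): '", ln[bad[1]], "'")
    at$occupancy[is.na(at$occupancy)] <- 1
    at$bfactor[is.na(at$bfactor)] <- 0
    if (exclude_solvent) {
      drop <- at$het & (at$residue_name %in% c(.water_names, .ion_names))
      at <- at[!drop, , drop = FALSE]
      xyz <- xyz[!drop, , drop = FALSE]
    }
    # altloc: keep highest-occupancy conformer per atom site, tie -> first
    if (any(at$altloc != " ")) {
      key <- paste(at$chain_id, at$residue_index, at$atom_name)
      keep <- rep(TRUE, nrow(at))
      for (k in unique(key[duplicated(key)])) {
        w <- which(key == k)
        best <- w[which.max(at$occupancy[w])]
        keep[setdiff(w, best)] <- FALSE
      }
      at <- at[keep, , drop = FALSE]
      xyz <- xyz[keep, , drop = FALSE]
    }
    at$altloc <- NULL
    at$het <- NULL
    rownames(at) <- NULL
    list(atoms = at, xyz = xyz)
  }

  if (n_models <= 1) {
    idx <- which(is_atom)
    if (!length(idx)) stop("no ATOM/HETATM records in ", path)
    b <- parse_block(idx, "model 1")
    return(assign_masses_radii(md_structure(b$atoms, b$xyz)))
  }

  blocks <- lapply(seq_len(n_models), function(m) {
    idx <- which(is_atom & model_id == m)
    parse_block(idx, paste("model", m))
  })
  ref <- blocks[[1]]
  sig <- function(b) paste(b$atoms$chain_id, b$atoms$residue_index,
                           b$atoms$atom_name, collapse = "|")
  ref_sig <- sig(ref)
  for (m in seq_along(blocks)) {
    if (nrow(blocks[[m]]$atoms) != nrow(ref$atoms) ||
        sig(blocks[[m]]) != ref_sig)
      stop("topology mismatch: model ", m, " has a different atom set/order ",
           "than model 1")
  }
  N <- nrow(ref$atoms)
  frames <- array(0, dim = c(N, 3, n_models))
  for (m in seq_along(blocks)) frames[, , m] <- blocks[[m]]$xyz
  topo <- assign_masses_radii(md_structure(ref$atoms, ref$xyz))
  md_trajectory(topo, frames, frame_dt = frame_dt)
}

.format_pdb_lines <- function(atoms, xyz) {
  name <- atoms$atom_name
  # column convention: 1-letter elements start in column 14
  name4 <- ifelse(nchar(name) >= 4, substr(name, 1, 4),
                  ifelse(nchar(atoms$element) == 1 & nchar(name) <= 3,
                         sprintf(" %-3s", name), sprintf("%-4s", name)))
  sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          atoms$serial %% 100000L, name4, substr(atoms$residue_name, 1, 3),
          atoms$chain_id, atoms$residue_index %% 10000L,
          xyz[, 1], xyz[, 2], xyz[, 3],
          atoms$occupancy, atoms$bfactor, atoms$element)
}

#' Write a structure or trajectory as a PDB file
#'
#' Trajectories are written as MODEL/ENDMDL blocks.  Coordinates round-trip
#' through [read_pdb] to 3 decimals (PDB precision).
#'
#' @param obj an [md_structure] or [md_trajectory]
#' @param path output file path
#' @return invisibly, `path`
#' @export
write_pdb <- function(obj, path) {
  if (inherits(obj, "md_structure")) {
    if (nrow(obj$atoms) == 0) stop("refusing to write an empty structure")
    out <- c(.format_pdb_lines(obj$atoms, obj$xyz), "END")
  } else if (inherits(obj, "md_trajectory")) {
    at <- obj$topology$atoms
    if (nrow(at) == 0) stop("refusing to write an empty trajectory")
    out <- unlist(lapply(seq_len(n_frames(obj)), function(m) {
      c(sprintf("MODEL     %4d", m),
        .format_pdb_lines(at, obj$frames[, , m]),
        "ENDMDL")
    }))
    out <- c(out, "END")
  } else stop("obj must be an md_structure or md_trajectory")
  ok <- tryCatch({ writeLines(out, path); TRUE },
                 error = function(e) stop("cannot write ", path, ": ",
                                          conditionMessage(e)))
  invisible(path)
}
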