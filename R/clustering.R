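#' Pairwise RMSD matrix over trajectory frames
#'
#' Entry (i, j) is the Kabsch-minimized RMSD between frames i and j on the
#' selection, with a fresh pairwise superposition, making the metric
#' independent of any global rigid motion.  Quadratic in frames; use
#' `stride` to subsample long trajectories.
#'
#' @param traj an [md_trajectory]
#' @param selection an `md_selection` or selection string (conventionally
#'   the substrate-chain backbone)
#' @param stride keep every `stride`-th frame (default 1 = all)
#' @return symmetric T x T matrix (A) with zero diagonal; kept frame indices
#'   in the `"frames"` attribute
#' @export
pairwise_rmsd_matrix <- function(traj, selection, stride = 1) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (is.character(selection))
    selection <- resolve_selection(traj$topology, selection)
  keep <- seq(1, n_frames(traj), by = stride)
  if (length(keep) < 2) stop("pairwise RMSD needs at least 2 frames")
  sub <- traj$frames[selection$indices, , keep, drop = FALSE]
  m <- .cpp_pairwise_rmsd(sub, rep(1, length(selection$indices)))
  attr(m, "frames") <- keep
  m
}

#' Quality-Threshold clustering of a distance matrix
#'
#' Iterative QT: every unassigned frame is tried as a seed; its candidate
#' cluster is all unassigned frames within `cutoff` of the seed; the largest
#' candidate (ties: lowest seed index) is committed and removed.  Iteration
#' stops when the largest candidate falls below `min_size_frac * T`; the
#' remaining frames are rejected.  A rejection rate above 5% raises a
#' warning, the conventional quality bar for this clustering.
#'
#' @param rmsd symmetric non-negative matrix with zero diagonal, e.g. from
#'   [pairwise_rmsd_matrix]
#' @param cutoff RMSD cutoff in A (the conventional trajectory setting is
#'   1.75 A, tuned heuristically per system)
#' @param min_size_frac minimum cluster size as a fraction of frames
#' @return a `cluster_set`: list of `clusters` (each with `members`,
#'   `center`, `frequency`), `rejected`, `rejection_rate`, `cutoff`,
#'   `min_size_frac`
#' @export
qt_cluster <- function(rmsd, cutoff, min_size_frac = 0.01) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  rmsd <- as.matrix(rmsd)
  T <- nrow(rmsd)
  if (T != ncol(rmsd) || any(rmsd < 0) || any(abs(diag(rmsd)) > 1e-12))
    stop("rmsd must be a square non-negative matrix with zero diagonal")
  min_size <- min_size_frac * T
  unassigned <- rep(TRUE, T)
  within <- rmsd <= cutoff
  clusters <- list()
  repeat {
    avail <- which(unassigned)
    if (!length(avail)) break
    sizes <- colSums(within[avail, avail, drop = FALSE])
    best <- which.max(sizes)            # ties: lowest index wins
    if (sizes[best] < min_size || sizes[best] < 1) break
    seed <- avail[best]
    members <- avail[within[avail, seed]]
    clusters[[length(clusters) + 1L]] <-
      list(seed = seed, members = members)
    unassigned[members] <- FALSE
  }
  clusters <- lapply(clusters, function(cl) {
    cl$center <- cluster_center(cl$members, rmsd)
    cl$frequency <- length(cl$members) / T
    cl
  })
  rejected <- which(unassigned)
  rate <- length(rejected) / T
  if (rate > 0.05)
    warning(sprintf("rejection rate %.1f%% exceeds 5%%; consider a larger %s",
                    100 * rate, "cutoff"))
  structure(list(clusters = clusters, rejected = rejected,
                 rejection_rate = rate, cutoff = cutoff,
                 min_size_frac = min_size_frac, n_frames = T),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("cluster_set:", length(x$clusters), "clusters over", x$n_frames,
      "frames (cutoff", x$cutoff, "A); rejection rate",
      sprintf("%.2f%%", 100 * x$rejection_rate), "\n")
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  %2d: %5d frames (%.1f%%), center frame %d\n", i,
                length(cl$members), 100 * cl$frequency, cl$center))
  }
  invisible(x)
}

#' Representative (central) frame of a cluster
#'
#' The member minimizing the summed RMSD to all other members; ties go to
#' the lowest frame index.
#'
#' @param members frame indices of the cluster
#' @param rmsd the full pairwise RMSD matrix
#' @return a frame index
#' @export
cluster_center <- function(members, rmsd) {
  if (!length(members)) stop("empty cluster")
  if (length(members) == 1) return(members)
  s <- rowSums(rmsd[members, members, drop = FALSE])
  members[which.min(s)]
}

#' RMSD of a frame against a reference structure
#'
#' Pairs atoms through a residue-correspondence map, superposes with Kabsch,
#' and returns the minimized RMSD.  Used to label cluster centers by their
#' nearest reference conformation (e.g. common vs C-terminally retracted
#' substrate).
#'
#' @param frame an [md_structure]
#' @param reference an [md_structure]
#' @param pairing data.frame with columns `frame_chain`, `frame_resid`,
#'   `ref_chain`, `ref_resid`; NULL pairs identical chain/residue labels
#' @param selection `md_selection`/string on `frame` restricting the atoms
#'   compared (default backbone)
#' @return RMSD in A
#' @export
rmsd_to_reference <- function(frame, reference, pairing = NULL,
                              selection = "backbone") {
  stopifnot(inherits(frame, "md_structure"),
            inherits(reference, "md_structure"))
  if (is.character(selection)) selection <- resolve_selection(frame, selection)
  fa <- frame$atoms[selection$indices, , drop = FALSE]
  fxyz <- frame$xyz[selection$indices, , drop = FALSE]
  ra <- reference$atoms
  if (is.null(pairing)) {
    key <- unique(paste(fa$chain_id, fa$residue_index))
    pairing <- data.frame(
      frame_chain = sub(" .*", "", key),
      frame_resid = as.integer(sub(".* ", "", key)),
      stringsAsFactors = FALSE)
    pairing$ref_chain <- pairing$frame_chain
    pairing$ref_resid <- pairing$frame_resid
  }
  fkey <- paste(fa$chain_id, fa$residue_index)
  pkey <- paste(pairing$frame_chain, pairing$frame_resid)
  ridx <- integer(0); fidx <- integer(0)
  missing <- character(0)
  for (p in seq_len(nrow(pairing))) {
    fsel <- which(fkey == pkey[p])
    for (q in fsel) {
      m <- which(ra$chain_id == pairing$ref_chain[p] &
                   ra$residue_index == pairing$ref_resid[p] &
                   ra$atom_name == fa$atom_name[q])
      if (length(m) == 1) {
        fidx <- c(fidx, q); ridx <- c(ridx, m)
      } else {
        missing <- c(missing, paste0(pairing$ref_chain[p], ":",
                                     pairing$ref_resid[p], ":",
                                     fa$atom_name[q]))
      }
    }
  }
  if (length(missing))
    stop("unpairable atoms in reference: ",
         paste(unique(missing), collapse = ", "))
  kabsch_superpose(fxyz[fidx, , drop = FALSE],
                   reference$xyz[ridx, , drop = FALSE])$rmsd
}

#' Label cluster centers by nearest reference conformation
#'
#' @param traj the clustered [md_trajectory]
#' @param clusters a [qt_cluster] result
#' @param references named list of [md_structure] references
#' @param selection selection string/`md_selection` for the comparison
#' @param pairing optional residue-correspondence map (see
#'   [rmsd_to_reference])
#' @return data.frame with one row per cluster: size, frequency, center
#'   frame, RMSD to every reference, and the nearest-reference `label`
#' @export
label_clusters <- function(traj, clusters, references,
                           selection = "backbone", pairing = NULL) {
  stopifnot(inherits(clusters, "cluster_set"))
  rows <- lapply(seq_along(clusters$clusters), function(i) {
    cl <- clusters$clusters[[i]]
    fr <- get_frame(traj, cl$center)
    d <- vapply(references, function(ref)
      rmsd_to_reference(fr, ref, pairing = pairing, selection = selection),
      numeric(1))
    out <- data.frame(cluster = i, size = length(cl$members),
                      frequency = cl$frequency, center = cl$center)
    for (nm in names(d)) out[[paste0("rmsd_", nm)]] <- d[[nm]]
    out$label <- names(d)[which.min(d)]
    out
  })
  do.call(rbind, rows)
}
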