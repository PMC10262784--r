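#' Shrake-Rupley solvent-accessible surface area
#'
#' Samples each atom's solvent-accessible sphere (radius `vdw + probe`) with
#' a deterministic Fibonacci lattice of `n_points` points; a point is buried
#' when it falls inside any neighbor's expanded sphere.  The accessible area
#' of an atom is its exposed point fraction times `4*pi*(vdw + probe)^2`.
#'
#' @param structure an [md_structure] with radii assigned
#' @param probe probe radius in A (water: 1.4)
#' @param n_points sphere sample points per atom (>= 64; default 960)
#' @param subset optional `md_selection` or selection string: atoms whose
#'   area is reported (all atoms still occlude)
#' @return a `sasa_result`: list with `atom_area`, `residue_area`
#'   (data.frame), `total`, `probe_radius`, `n_sphere_points`
#' @export
shrake_rupley_sasa <- function(structure, probe = 1.4, n_points = 960,
                               subset = NULL) {
  stopifnot(inherits(structure, "md_structure"))
  at <- structure$atoms
  if (is.null(at$vdw_radius) || anyNA(at$vdw_radius))
    stop("radii missing: run assign_masses_radii() first")
  if (n_points < 64) stop("n_points must be >= 64")
  if (probe < 0) stop("probe radius must be >= 0")
  if (is.character(subset)) subset <- resolve_selection(structure, subset)
  idx <- if (is.null(subset)) seq_len(nrow(at)) else subset$indices
  sphere <- .fibonacci_sphere(n_points)
  area <- as.vector(.cpp_sasa(structure$xyz, at$vdw_radius, probe, sphere,
                              as.integer(idx)))
  sub <- at[idx, , drop = FALSE]
  key <- paste(sub$chain_id, sub$residue_index)
  res <- .residue_table(sub)
  rarea <- rowsum(area, match(key, res$key), reorder = TRUE)[, 1]
  structure(list(
    atom_area = data.frame(chain_id = sub$chain_id,
                           residue_index = sub$residue_index,
                           atom_name = sub$atom_name, area = area,
                           stringsAsFactors = FALSE),
    residue_area = data.frame(chain_id = res$chain_id,
                              residue_index = res$residue_index,
                              residue_name = res$residue_name,
                              area = unname(rarea), stringsAsFactors = FALSE),
    total = sum(area), probe_radius = probe, n_sphere_points = n_points),
    class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat("sasa_result: total ", sprintf("%.1f", x$total), " A^2 over ",
      nrow(x$atom_area), " atoms (probe ", x$probe_radius, " A, ",
      x$n_sphere_points, " points)\n", sep = "")
  invisible(x)
}

#' Per-frame SASA series of a target selection
#'
#' Computes, for every frame, the accessible area of the `target` atoms in
#' the context of the `context` atoms (everything in `context` occludes;
#' atoms outside it are ignored).  The canonical use is the exposure of a
#' phosphoacceptor residue (e.g. substrate residue 65) within the whole
#' complex.
#'
#' @param traj an [md_trajectory]
#' @param target `md_selection` or string: atoms whose area is summed
#' @param context `md_selection` or string: occluding environment, must
#'   contain the target (default "all")
#' @param probe probe radius in A
#' @param n_points sphere sample points per atom
#' @return numeric per-frame total target SASA (A^2)
#' @export
sasa_series <- function(traj, target, context = "all", probe = 1.4,
                        n_points = 960) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (is.character(target)) target <- resolve_selection(traj$topology, target)
  if (is.character(context)) context <- resolve_selection(traj$topology,
                                                          context)
  if (!all(target$indices %in% context$indices))
    stop("target selection is not contained in the context selection")
  at <- traj$topology$atoms
  ctx <- context$indices
  tpos <- match(target$indices, ctx)
  sphere <- .fibonacci_sphere(n_points)
  radii <- at$vdw_radius[ctx]
  vapply(seq_len(n_frames(traj)), function(f) {
    xyz <- traj$frames[ctx, , f, drop = TRUE]
    sum(.cpp_sasa(xyz, radii, probe, sphere, as.integer(tpos)))
  }, numeric(1))
}

#' Per-frame buried surface area between two chains
#'
#' For each frame, `BSA = (SASA(A alone) + SASA(B alone) - SASA(complex)) / 2`
#' with the two selections taken alone and together (probe 1.4 A by
#' default).  Values that are negative beyond numerical noise are clamped to
#' zero with a warning.
#'
#' @param traj an [md_trajectory]
#' @param chain_A,chain_B disjoint `md_selection`s or selection strings
#' @param probe probe radius in A
#' @param n_points sphere sample points per atom
#' @return a `bsa_series` numeric vector of per-frame BSA (A^2)
#' @export
buried_surface_area <- function(traj, chain_A, chain_B, probe = 1.4,
                                n_points = 960) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (is.character(chain_A)) chain_A <- resolve_selection(traj$topology,
                                                          chain_A)
  if (is.character(chain_B)) chain_B <- resolve_selection(traj$topology,
                                                          chain_B)
  if (length(intersect(chain_A$indices, chain_B$indices)))
    stop("chain selections overlap")
  at <- traj$topology$atoms
  ia <- chain_A$indices; ib <- chain_B$indices
  iab <- c(ia, ib)
  sphere <- .fibonacci_sphere(n_points)
  sasa_of <- function(xyz, radii)
    sum(.cpp_sasa(xyz, radii, probe, sphere, seq_along(radii)))
  out <- vapply(seq_len(n_frames(traj)), function(f) {
    xyz <- traj$frames[, , f, drop = TRUE]
    sa <- sasa_of(xyz[ia, , drop = FALSE], at$vdw_radius[ia])
    sb <- sasa_of(xyz[ib, , drop = FALSE], at$vdw_radius[ib])
    sab <- sasa_of(xyz[iab, , drop = FALSE], at$vdw_radius[iab])
    (sa + sb - sab) / 2
  }, numeric(1))
  neg <- out < -1e-6
  if (any(neg)) {
    warning(sum(neg), " BSA value(s) negative beyond tolerance; clamped to 0")
  }
  out[out < 0] <- 0
  class(out) <- c("bsa_series", class(out))
  out
}
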