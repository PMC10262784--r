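#' Weighted Kabsch superposition
#'
#' Finds the proper rotation and translation minimizing the weighted
#' least-squares deviation of `mobile` onto `reference`.  Reflections are
#' corrected by flipping the smallest singular direction, so the rotation
#' always has determinant +1.
#'
#' @param mobile,reference N x 3 coordinate matrices (N >= 3, not collinear)
#' @param weights optional per-atom non-negative weights (default: equal)
#' @return a `superposition`: list with `rotation` (3 x 3, acts on row
#'   vectors as `x %*% rotation`), `translation`, and `rmsd` (A).  Apply with
#'   [apply_superposition].
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3)
    stop("mobile and reference must be equal-sized N x 3 matrices")
  n <- nrow(mobile)
  if (n < 3) stop("superposition needs at least 3 atoms")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) == 0)
    stop("weights must be non-negative with positive sum")
  w <- weights / sum(weights)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  Am <- sweep(mobile, 2, cm); Ar <- sweep(reference, 2, cr)
  sv_m <- svd(Am * sqrt(w))$d
  if (sv_m[2] < 1e-8 * max(sv_m[1], 1))
    stop("degenerate point set: atoms are collinear (rank < 2)")
  H <- t(Am) %*% (Ar * w)
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  tr <- cr - as.vector(cm %*% R)
  moved <- sweep(mobile %*% R, 2, tr, "+")
  rmsd <- sqrt(sum(w * rowSums((moved - reference)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat("superposition: rotation ", sprintf("%.2f", ang), " deg, |t| = ",
      sprintf("%.3f", sqrt(sum(x$translation^2))), " A, rmsd = ",
      sprintf("%.4f", x$rmsd), " A\n", sep = "")
  invisible(x)
}

#' Apply a fitted superposition to coordinates
#' @param sp a `superposition` from [kabsch_superpose]
#' @param xyz N x 3 coordinates
#' @return transformed N x 3 coordinates
#' @export
apply_superposition <- function(sp, xyz) {
  sweep(as.matrix(xyz) %*% sp$rotation, 2, sp$translation, "+")
}

#' Align a trajectory onto a reference frame
#'
#' Fits each frame onto `ref_frame` by weighted Kabsch superposition on the
#' atoms of `fit_selection`, then applies that frame's transform to ALL
#' atoms.  This removes the random global rotation/translation while leaving
#' internal motions untouched.
#'
#' @param traj an [md_trajectory]
#' @param fit_selection an `md_selection` (or selection string) naming the
#'   atoms the fit is computed on; conventionally the kinase-chain backbone.
#' @param ref_frame reference frame index (default 1)
#' @param weights optional per-atom weights on the fit selection (default:
#'   atomic masses)
#' @return the aligned [md_trajectory]
#' @export
align_trajectory <- function(traj, fit_selection, ref_frame = 1,
                             weights = NULL) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (is.character(fit_selection))
    fit_selection <- resolve_selection(traj$topology, fit_selection)
  T <- n_frames(traj)
  if (ref_frame < 1 || ref_frame > T)
    stop("ref_frame ", ref_frame, " out of range [1, ", T, "]")
  idx <- fit_selection$indices
  if (is.null(weights)) weights <- traj$topology$atoms$mass[idx]
  ref <- traj$frames[idx, , ref_frame, drop = TRUE]
  out <- traj$frames
  for (f in seq_len(T)) {
    sp <- kabsch_superpose(out[idx, , f, drop = TRUE], ref, weights)
    out[, , f] <- apply_superposition(sp, out[, , f, drop = TRUE])
  }
  traj$frames <- out
  traj
}

#' Per-frame RMSD series
#'
#' RMSD of each frame to a reference frame over a selection.  With
#' `refit = TRUE` a fresh superposition is computed per frame on the
#' selection (rigid-motion-free metric); with `refit = FALSE` the deviation
#' is measured in the current (e.g. pre-aligned) coordinates.
#'
#' @param traj an [md_trajectory]
#' @param selection an `md_selection` or selection string
#' @param ref_frame reference frame index
#' @param refit recompute the superposition per frame?
#' @return numeric vector of per-frame RMSD values (A); zero at `ref_frame`
#' @export
rmsd_series <- function(traj, selection, ref_frame = 1, refit = FALSE) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (is.character(selection))
    selection <- resolve_selection(traj$topology, selection)
  T <- n_frames(traj)
  if (ref_frame < 1 || ref_frame > T) stop("ref_frame out of range")
  idx <- selection$indices
  sub <- traj$frames[idx, , , drop = FALSE]
  ref <- sub[, , ref_frame, drop = TRUE]
  if (refit) {
    as.vector(.cpp_rmsd_to_ref(sub, ref, rep(1, length(idx))))
  } else {
    vapply(seq_len(T), function(f)
      sqrt(mean(rowSums((sub[, , f, drop = TRUE] - ref)^2))), numeric(1))
  }
}

#' Per-residue RMSF profile
#'
#' Root-mean-square fluctuation of each selected atom about its mean
#' position over an aligned trajectory, optionally combined into one value
#' per residue as the mass-weighted mean of the residue's atomic RMSFs.
#'
#' @param aligned an aligned [md_trajectory] (see [align_trajectory])
#' @param selection an `md_selection` or selection string (e.g. "backbone")
#' @param group_by_residue combine atoms into per-residue values?
#' @return an `rmsf_profile` data.frame with columns `chain_id`,
#'   `residue_index`, `residue_name` (or per-atom columns), and `rmsf` (A)
#' @export
rmsf_profile <- function(aligned, selection, group_by_residue = TRUE) {
  stopifnot(inherits(aligned, "md_trajectory"))
  if (is.character(selection))
    selection <- resolve_selection(aligned$topology, selection)
  T <- n_frames(aligned)
  if (T < 2) stop("RMSF needs at least 2 frames")
  idx <- selection$indices
  at <- aligned$topology$atoms[idx, , drop = FALSE]
  n <- length(idx)
  flat <- matrix(aligned$frames[idx, , , drop = FALSE], nrow = n * 3, ncol = T)
  mu <- rowMeans(flat)
  v <- rowMeans((flat - mu)^2)          # per atom-axis variance
  atom_rmsf <- sqrt(rowSums(matrix(v, nrow = n, ncol = 3)))
  if (!group_by_residue) {
    out <- data.frame(chain_id = at$chain_id, residue_index = at$residue_index,
                      atom_name = at$atom_name, rmsf = atom_rmsf,
                      stringsAsFactors = FALSE)
  } else {
    key <- paste(at$chain_id, at$residue_index)
    res <- .residue_table(at)
    wsum <- rowsum(at$mass, key, reorder = FALSE)[, 1]
    rsum <- rowsum(at$mass * atom_rmsf, key, reorder = FALSE)[, 1]
    out <- data.frame(chain_id = res$chain_id,
                      residue_index = res$residue_index,
                      residue_name = res$residue_name,
                      rmsf = unname(rsum / wsum), stringsAsFactors = FALSE)
  }
  class(out) <- c("rmsf_profile", "data.frame")
  out
}

#' @export
plot.rmsf_profile <- function(x, ...) {
  graphics::plot(x$residue_index, x$rmsf, type = "l", xlab = "residue",
                 ylab = "RMSF (A)", ...)
  invisible(x)
}

#' Mass-weighted normalized covariance of residue motions
#'
#' For each residue, the mass-weighted mean displacement vector of its
#' selected atoms is tracked over the aligned trajectory; the normalized
#' covariance is
#' `C(i,j) = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)`, a symmetric matrix
#' with unit diagonal and entries in \[-1, 1\].  Residues with zero variance
#' get a zero row/column (diagonal 1) with a warning.
#'
#' @param aligned an aligned [md_trajectory]
#' @param selection an `md_selection` or selection string; for CA-only
#'   selections the mass weighting cancels under normalization
#' @return a `covariance_matrix`: list with `values` (n x n) and `residues`
#' @export
covariance_matrix <- function(aligned, selection) {
  stopifnot(inherits(aligned, "md_trajectory"))
  if (is.character(selection))
    selection <- resolve_selection(aligned$topology, selection)
  T <- n_frames(aligned)
  if (T < 2) stop("covariance needs at least 2 frames")
  idx <- selection$indices
  at <- aligned$topology$atoms[idx, , drop = FALSE]
  key <- paste(at$chain_id, at$residue_index)
  res <- .residue_table(at)
  n_res <- nrow(res)
  grp <- match(key, res$key)
  w <- at$mass
  wsum <- rowsum(w, grp, reorder = TRUE)[, 1]
  # per-axis residue trajectories: n_res x T
  num <- matrix(0, n_res, n_res)
  vr <- numeric(n_res)
  for (k in 1:3) {
    Xk <- matrix(aligned$frames[idx, k, , drop = FALSE], nrow = length(idx))
    Rk <- rowsum(Xk * w, grp, reorder = TRUE) / wsum
    Dk <- Rk - rowMeans(Rk)
    num <- num + Dk %*% t(Dk) / T
  }
  vr <- diag(num)
  zero <- vr <= 1e-14
  if (any(zero))
    warning(sum(zero), " residue(s) with zero variance: rows/columns set to 0")
  denom <- sqrt(vr); denom[zero] <- 1
  C <- num / outer(denom, denom)
  C[zero, ] <- 0; C[, zero] <- 0
  diag(C) <- 1
  C <- (C + t(C)) / 2
  C[C > 1] <- 1; C[C < -1] <- -1
  rn <- paste0(res$chain_id, res$residue_index)
  dimnames(C) <- list(rn, rn)
  structure(list(values = C, residues = res[c("chain_id", "residue_index",
                                              "residue_name")]),
            class = "covariance_matrix")
}

#' @export
print.covariance_matrix <- function(x, ...) {
  n <- nrow(x$values)
  off <- x$values[upper.tri(x$values)]
  cat("covariance_matrix:", n, "x", n, "residues; off-diagonal range [",
      sprintf("%.3f", min(off)), ",", sprintf("%.3f", max(off)), "]\n")
  invisible(x)
}

#' @export
plot.covariance_matrix <- function(x, ...) {
  # five-point scale: dark red (-1) - white (0) - dark blue (+1)
  pal <- grDevices::colorRampPalette(c("#67000d", "#fb6a4a", "white",
                                       "#6baed6", "#08306b"))(101)
  n <- nrow(x$values)
  graphics::image(seq_len(n), seq_len(n), t(x$values), zlim = c(-1, 1),
                  col = pal, xlab = "residue", ylab = "residue", ...)
  invisible(x)
}

#' Highly correlated partner residues
#'
#' Residues whose motion correlates with a query residue at or beyond a
#' threshold magnitude (default 0.75, the conventional cut for "highly
#' significant" correlated motions).
#'
#' @param cov a [covariance_matrix]
#' @param residue author residue number of the query
#' @param chain optional chain id disambiguating the query
#' @param threshold magnitude threshold in (0, 1]
#' @return data.frame with `chain_id`, `residue_index`, `correlation`, `sign`
#' @export
correlated_partners <- function(cov, residue, chain = NULL, threshold = 0.75) {
  stopifnot(inherits(cov, "covariance_matrix"))
  res <- cov$residues
  hit <- which(res$residue_index == residue)
  if (!is.null(chain)) hit <- hit[res$chain_id[hit] == chain]
  if (length(hit) == 0) stop("residue ", residue, " not in covariance matrix")
  if (length(hit) > 1) stop("residue ", residue, " is ambiguous; give chain=")
  v <- cov$values[hit, ]
  j <- setdiff(which(abs(v) >= threshold), hit)
  out <- data.frame(chain_id = res$chain_id[j],
                    residue_index = res$residue_index[j],
                    correlation = unname(v[j]),
                    sign = ifelse(v[j] >= 0, "positive", "negative"),
                    stringsAsFactors = FALSE)
  out[order(-abs(out$correlation)), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
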