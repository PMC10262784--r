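# Fixture builders and independent oracles used across the suite.

# minimal structure from atom names/positions
make_structure <- function(xyz, atom_name = "CA", element = NULL,
                           residue_index = NULL, chain_id = "A",
                           residue_name = "ALA") {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  atom_name <- rep_len(atom_name, n)
  if (is.null(element)) element <- substr(atom_name, 1, 1)
  if (is.null(residue_index)) residue_index <- seq_len(n)
  atoms <- data.frame(serial = seq_len(n), atom_name = atom_name,
                      element = rep_len(element, n),
                      residue_name = rep_len(residue_name, n),
                      residue_index = rep_len(residue_index, n),
                      chain_id = rep_len(chain_id, n),
                      stringsAsFactors = FALSE)
  assign_masses_radii(md_structure(atoms, xyz))
}

# trajectory from a list of coordinate matrices over a fixed topology
make_trajectory <- function(topology, coord_list, frame_dt = 250) {
  N <- nrow(topology$atoms)
  frames <- array(0, dim = c(N, 3, length(coord_list)))
  for (i in seq_along(coord_list)) frames[, , i] <- coord_list[[i]]
  md_trajectory(topology, frames, frame_dt)
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to det +1
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_rigid <- function(xyz, R, t) sweep(xyz %*% R, 2, t, "+")

# Monte-Carlo SASA oracle: random surface points per atom, occlusion by
# expanded neighbor spheres (independent of the lattice implementation)
mc_sasa <- function(xyz, radii, probe = 1.4, n_mc = 1e5, seed = 42) {
  set.seed(seed)
  xyz <- matrix(xyz, ncol = 3)
  total <- 0
  for (i in seq_len(nrow(xyz))) {
    ri <- radii[i] + probe
    p <- matrix(rnorm(3 * n_mc), ncol = 3)
    p <- p / sqrt(rowSums(p^2))
    pts <- sweep(ri * p, 2, xyz[i, ], "+")
    exposed <- rep(TRUE, n_mc)
    for (j in seq_len(nrow(xyz))[-i]) {
      rj <- radii[j] + probe
      d2 <- rowSums(sweep(pts, 2, xyz[j, ])^2)
      exposed <- exposed & (d2 >= rj^2)
    }
    total <- total + 4 * pi * ri^2 * mean(exposed)
  }
  total
}

# brute-force QT oracle: re-enumerates every seed each round (no caching)
qt_oracle <- function(rmsd, cutoff, min_size_frac = 0.01) {
  T <- nrow(rmsd)
  unassigned <- seq_len(T)
  clusters <- list()
  repeat {
    if (!length(unassigned)) break
    best_members <- integer(0)
    for (seed in unassigned) {
      cand <- unassigned[rmsd[unassigned, seed] <= cutoff]
      if (length(cand) > length(best_members)) best_members <- cand
    }
    if (length(best_members) < min_size_frac * T) break
    clusters[[length(clusters) + 1L]] <- sort(best_members)
    unassigned <- setdiff(unassigned, best_members)
  }
  list(clusters = clusters, rejected = unassigned)
}

# independent rigid-fit RMSD oracle: numerical optimization over axis-angle
# + translation, multi-start (no SVD)
optim_rmsd_oracle <- function(mobile, reference, n_starts = 8, seed = 7) {
  set.seed(seed)
  obj <- function(par) {
    axis <- par[1:3]; nrm <- sqrt(sum(axis^2))
    R <- if (nrm < 1e-12) diag(3) else {
      u <- axis / nrm; th <- nrm
      K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
                  byrow = TRUE)
      t(diag(3) * cos(th) + sin(th) * K + (1 - cos(th)) * (u %o% u))
    }
    moved <- sweep(mobile %*% R, 2, par[4:6], "+")
    sqrt(mean(rowSums((moved - reference)^2)))
  }
  best <- Inf
  for (s in seq_len(n_starts)) {
    p0 <- c(rnorm(3, 0, 1), colMeans(reference) - colMeans(mobile))
    r <- stats::optim(p0, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, r$value)
  }
  best
}

# Kabsch-Sander H-bond energy, written out directly from the published
# formula (independent of the assigner's internals)
ks_energy <- function(N, H, C, O) {
  d <- function(a, b) sqrt(sum((a - b)^2))
  0.084 * 332 * (1 / d(O, N) + 1 / d(C, H) - 1 / d(O, H) - 1 / d(C, N))
}

# canonical partition representation for comparing clusterings
partition_sets <- function(clusters) {
  s <- lapply(clusters, function(x) sort(as.integer(x)))
  s[order(vapply(s, function(x) x[1], integer(1)))]
}
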