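# Synthetic structures and trajectories with planted, recoverable statistics.
# The generator is the test bed for every analysis stage: real counterparts of
# these trajectories (microsecond MD of a kinase-ubiquitin complex) are too
# large to ship and are not deposited, so ground truth is planted instead.

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}

# standard trans-peptide internal coordinates
.bb_geom <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                 ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
                 ang_ca_c_o = 120.8)

#' Build a poly-alanine backbone with given dihedrals
#'
#' Constructs backbone atoms N, CA, C, O for `n_res` residues from standard
#' internal coordinates, with uniform phi/psi/omega dihedrals.  The workhorse
#' behind [build_ideal_helix] and the extended-chain fixtures.
#'
#' @param n_res number of residues (>= 2)
#' @param phi,psi,omega backbone dihedrals in degrees; scalars are recycled,
#'   or vectors give one value per residue for mixed conformations
#' @param chain_id chain identifier
#' @param start_resid author numbering of the first residue
#' @param residue_name 3-letter residue name used for all residues
#' @return an [md_structure] with masses/radii assigned
#' @export
build_peptide_chain <- function(n_res, phi = -57, psi = -47, omega = 180,
                                chain_id = "A", start_resid = 1,
                                residue_name = "ALA") {
  if (n_res < 2) stop("n_res must be >= 2")
  phi <- rep_len(phi, n_res); psi <- rep_len(psi, n_res)
  omega <- rep_len(omega, n_res)
  g <- .bb_geom
  coords <- matrix(NA_real_, nrow = 4 * n_res, ncol = 3)
  idx <- function(i, k) (i - 1) * 4 + k     # k: 1 N, 2 CA, 3 C, 4 O
  coords[idx(1, 1), ] <- c(0, 0, 0)
  coords[idx(1, 2), ] <- c(g$n_ca, 0, 0)
  th <- g$ang_n_ca_c * .deg2rad
  coords[idx(1, 3), ] <- coords[idx(1, 2), ] +
    g$ca_c * c(-cos(th), sin(th), 0)
  for (i in seq_len(n_res)) {
    N <- coords[idx(i, 1), ]; CA <- coords[idx(i, 2), ]; C <- coords[idx(i, 3), ]
    if (i < n_res) {
      Nn <- .place_atom(N, CA, C, g$c_n, g$ang_ca_c_n, psi[i])
      coords[idx(i + 1, 1), ] <- Nn
      coords[idx(i + 1, 2), ] <- .place_atom(CA, C, Nn, g$n_ca, g$ang_c_n_ca,
                                             omega[i])
      coords[idx(i + 1, 3), ] <- .place_atom(C, Nn, coords[idx(i + 1, 2), ],
                                             g$ca_c, g$ang_n_ca_c, phi[i + 1])
    }
    # carbonyl O anti to the next amide N (torsion N-CA-C-O = psi + 180)
    coords[idx(i, 4), ] <- .place_atom(N, CA, C, g$c_o, g$ang_ca_c_o,
                                       psi[i] + 180)
  }
  atoms <- data.frame(
    serial = seq_len(4 * n_res),
    atom_name = rep(c("N", "CA", "C", "O"), n_res),
    element = rep(c("N", "C", "C", "O"), n_res),
    residue_name = residue_name,
    residue_index = rep(seq(start_resid, length.out = n_res), each = 4),
    chain_id = chain_id, stringsAsFactors = FALSE)
  assign_masses_radii(md_structure(atoms, coords))
}

#' Build an ideal alpha-helix
#'
#' Backbone-only helix with phi = -57, psi = -47, omega = 180 degrees;
#' successive CA-CA distances come out near 3.8 A.  Used as the reference
#' fixture for secondary-structure assignment and dihedral round-trips.
#'
#' @param n_res number of residues (>= 4)
#' @param chain_id chain identifier
#' @return an [md_structure]
#' @export
build_ideal_helix <- function(n_res, chain_id = "A") {
  if (n_res < 4) stop("an ideal helix needs n_res >= 4")
  build_peptide_chain(n_res, phi = -57, psi = -47, chain_id = chain_id)
}

#' Build a synthetic two-chain complex
#'
#' Two backbone chains (ids A and U) posed so the minimum inter-chain
#' heavy-atom distance equals `gap` (within 0.5 A).  Chain U receives a
#' seeded random orientation, making distinct but reproducible interfaces.
#' A stand-in for a kinase-substrate complex in tests and examples.
#'
#' @param n_res_A,n_res_B residues per chain (>= 4)
#' @param gap target minimum inter-chain distance in A (> 0)
#' @param seed integer seed controlling chain U's orientation
#' @return an [md_structure] with chains A and U
#' @export
build_two_chain_complex <- function(n_res_A, n_res_B, gap = 4, seed = 1) {
  if (n_res_A < 4 || n_res_B < 4) stop("chain sizes must be >= 4")
  if (gap <= 0) stop("gap must be positive")
  a <- build_ideal_helix(n_res_A, chain_id = "A")
  b <- build_ideal_helix(n_res_B, chain_id = "U")
  b$atoms$serial <- b$atoms$serial + nrow(a$atoms)
  bx <- .with_seed(seed, {
    ax <- .unit(rnorm(3))
    R <- .rotation_matrix(ax, runif(1, 0, 360))
    sweep(b$xyz, 2, colMeans(b$xyz)) %*% R
  })
  ca <- colMeans(a$xyz)
  min_dist <- function(t) {
    shifted <- sweep(bx, 2, ca + c(t, 0, 0), "+")
    min(sqrt(outer(rowSums(a$xyz^2), rowSums(shifted^2), "+") -
               2 * a$xyz %*% t(shifted)))
  }
  upper <- 200
  lower <- 0
  while (min_dist(lower) > gap && lower > -50) lower <- lower - 2
  t_star <- stats::uniroot(function(t) min_dist(t) - gap, c(lower, upper),
                           tol = 1e-4)$root
  bxyz <- sweep(bx, 2, ca + c(t_star, 0, 0), "+")
  md_structure(rbind(a$atoms, b$atoms), rbind(a$xyz, bxyz))
}

#' Specify planted fluctuations for a synthetic trajectory
#'
#' @param per_residue_amplitude target per-residue RMSF in A; a scalar is
#'   recycled over residues, or a vector of one value per residue (topology
#'   order).
#' @param correlation_blocks list of `list(set_a =, set_b =, rho =)` entries
#'   planting cross-correlation `rho` in \[-1, 1\] between two residue sets;
#'   sets are topology-order residue positions (numeric) or `"chain:resid"`
#'   strings.
#' @param rigid_body optional `list(rotation = degrees, translation = A)`:
#'   per-frame random global rotation/translation amplitudes (standard
#'   deviations), removable by alignment.
#' @param seed integer seed (trajectories are bitwise reproducible)
#' @return a `fluctuation_spec`
#' @export
fluctuation_spec <- function(per_residue_amplitude, correlation_blocks = list(),
                             rigid_body = NULL, seed = 1) {
  if (any(per_residue_amplitude < 0)) stop("amplitudes must be >= 0")
  for (b in correlation_blocks) {
    if (!all(c("set_a", "set_b", "rho") %in% names(b)))
      stop("each correlation block needs set_a, set_b, rho")
    if (abs(b$rho) > 1) stop("|target correlation| must be <= 1")
  }
  structure(list(per_residue_amplitude = per_residue_amplitude,
                 correlation_blocks = correlation_blocks,
                 rigid_body = rigid_body, seed = seed),
            class = "fluctuation_spec")
}

# residue-level correlation matrix implied by the blocks; error if not PSD.
# Sets address residues by topology-order position (numeric) or "chain:resid"
# strings.
.planted_correlation <- function(n_res, res, blocks) {
  resolve_set <- function(s) {
    if (is.character(s)) match(s, paste0(res$chain_id, ":", res$residue_index))
    else as.integer(s)
  }
  C <- diag(n_res)
  for (b in blocks) {
    ia <- resolve_set(b$set_a)
    ib <- resolve_set(b$set_b)
    if (anyNA(ia) || anyNA(ib) || any(c(ia, ib) < 1) || any(c(ia, ib) > n_res))
      stop("correlation block names residues absent from the structure")
    for (i in ia) for (j in ib) {
      if (i != j) C[i, j] <- C[j, i] <- b$rho
    }
  }
  ev <- eigen(C, symmetric = TRUE)
  if (min(ev$values) < -1e-8)
    stop("unsatisfiable correlation spec: implied matrix is not positive ",
         "semi-definite (min eigenvalue ", signif(min(ev$values), 3), ")")
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), n_res)
  L
}

#' Simulate a trajectory with planted fluctuation statistics
#'
#' Each frame is `base` plus zero-mean Gaussian per-residue rigid
#' displacements (per-axis sd `amplitude / sqrt(3)`, so the planted amplitude
#' IS the expected RMSF), with inter-residue correlations enforced through a
#' shared latent-factor decomposition, optionally followed by a random global
#' rotation/translation.  Frames are independent draws: the analyses consume
#' per-frame coordinates only, so no temporal kinetics are modelled.
#'
#' @param base an [md_structure]
#' @param spec a [fluctuation_spec]
#' @param n_frames number of frames (>= 2)
#' @param frame_dt frame spacing in psec
#' @return an [md_trajectory]; planted ground truth is attached as the
#'   `"planted"` attribute
#' @export
simulate_trajectory <- function(base, spec, n_frames, frame_dt = 250) {
  stopifnot(inherits(base, "md_structure"), inherits(spec, "fluctuation_spec"))
  if (n_frames < 2) stop("n_frames must be >= 2")
  res <- .residue_table(base$atoms)
  n_res <- nrow(res)
  amp <- spec$per_residue_amplitude
  if (length(amp) == 1) amp <- rep(amp, n_res)
  if (length(amp) != n_res)
    stop("amplitude vector length ", length(amp), " != ", n_res, " residues")
  L <- .planted_correlation(n_res, res, spec$correlation_blocks)
  res_of_atom <- match(paste(base$atoms$chain_id, base$atoms$residue_index),
                       res$key)
  N <- nrow(base$atoms)
  frames <- array(0, dim = c(N, 3, n_frames))
  centroid <- colMeans(base$xyz)
  .with_seed(spec$seed, {
    for (f in seq_len(n_frames)) {
      disp <- matrix(0, n_res, 3)
      for (k in 1:3) disp[, k] <- (L %*% rnorm(n_res)) * amp / sqrt(3)
      xyz <- base$xyz + disp[res_of_atom, , drop = FALSE]
      if (!is.null(spec$rigid_body)) {
        rb <- spec$rigid_body
        ax <- .unit(rnorm(3))
        R <- .rotation_matrix(ax, rnorm(1, 0, rb$rotation))
        tr <- rnorm(3, 0, rb$translation)
        xyz <- sweep(sweep(xyz, 2, centroid) %*% R, 2, centroid + tr, "+")
      }
      frames[, , f] <- xyz
    }
  })
  out <- md_trajectory(base, frames, frame_dt)
  attr(out, "planted") <- list(amplitude = amp,
                               correlation_blocks = spec$correlation_blocks,
                               seed = spec$seed)
  out
}

#' Specify a two-state conformational mixture
#'
#' Emulates a substrate exchanging between two conformations (e.g. a common
#' and a C-terminally retracted state differing in a marker distance and in
#' the exposure of a phosphoacceptor residue), with a stated occupancy of the
#' minor state.
#'
#' @param state_A,state_B two [md_structure]s sharing a topology
#' @param occupancy_B fraction of frames in state B, in \[0, 1\]
#' @param switching `"iid"` (independent frames) or `"block"` (two-state
#'   Markov chain with mean dwell `dwell` frames in state B)
#' @param dwell mean dwell length in frames for `"block"` switching
#' @param seed integer seed
#' @return a `two_state_spec`
#' @export
two_state_spec <- function(state_A, state_B, occupancy_B,
                           switching = c("iid", "block"), dwell = 20,
                           seed = 1) {
  switching <- match.arg(switching)
  stopifnot(inherits(state_A, "md_structure"),
            inherits(state_B, "md_structure"))
  if (nrow(state_A$atoms) != nrow(state_B$atoms) ||
      !all(state_A$atoms$atom_name == state_B$atoms$atom_name) ||
      !all(state_A$atoms$chain_id == state_B$atoms$chain_id))
    stop("state_A and state_B do not share a topology")
  if (occupancy_B < 0 || occupancy_B > 1)
    stop("occupancy_B must be in [0, 1]")
  structure(list(state_A = state_A, state_B = state_B,
                 occupancy_B = occupancy_B, switching = switching,
                 dwell = dwell, seed = seed),
            class = "two_state_spec")
}

#' Simulate a two-state conformational mixture trajectory
#'
#' Each frame is one of the two state structures (chosen per the occupancy
#' and switching model) plus iid Gaussian jitter (per-axis sd `jitter`).
#' The realized state sequence and occupancy are recorded in the `"planted"`
#' attribute, giving clustering and occupancy analyses an exact ground truth.
#'
#' @param spec a [two_state_spec]
#' @param n_frames number of frames (>= 2)
#' @param frame_dt frame spacing in psec
#' @param jitter per-axis Gaussian jitter sd in A
#' @return an [md_trajectory] with `"planted"` attribute carrying
#'   `states` (1/2 per frame) and `realized_occupancy_B`
#' @export
simulate_two_state <- function(spec, n_frames, frame_dt = 250, jitter = 0) {
  stopifnot(inherits(spec, "two_state_spec"))
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (jitter < 0) stop("jitter must be >= 0")
  N <- nrow(spec$state_A$atoms)
  xs <- list(spec$state_A$xyz, spec$state_B$xyz)
  frames <- array(0, dim = c(N, 3, n_frames))
  states <- integer(n_frames)
  p <- spec$occupancy_B
  .with_seed(spec$seed, {
    if (spec$switching == "iid") {
      states <- rbinom(n_frames, 1, p) + 1L
    } else {
      # two-state Markov chain: stationary P(B) = p, mean dwell in B = dwell
      leave_b <- 1 / spec$dwell
      leave_a <- if (p >= 1) 1 else min(1, leave_b * p / (1 - p))
      s <- rbinom(1, 1, p) + 1L
      for (f in seq_len(n_frames)) {
        states[f] <- s
        flip <- runif(1) < (if (s == 2L) leave_b else leave_a)
        if (flip) s <- 3L - s
      }
    }
    for (f in seq_len(n_frames)) {
      xyz <- xs[[states[f]]]
      if (jitter > 0) xyz <- xyz + matrix(rnorm(N * 3, 0, jitter), N, 3)
      frames[, , f] <- xyz
    }
  })
  out <- md_trajectory(spec$state_A, frames, frame_dt)
  attr(out, "planted") <- list(states = states,
                               realized_occupancy_B = mean(states == 2L),
                               occupancy_B = p, seed = spec$seed)
  out
}
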