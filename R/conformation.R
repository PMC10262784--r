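#' Backbone phi/psi dihedrals of one residue
#'
#' Standard IUPAC convention: `phi = C(i-1)-N-CA-C`, `psi = N-CA-C-N(i+1)`,
#' both in (-180, 180].  A terminal residue's missing angle is returned as
#' NA with its `defined` flag FALSE rather than silently propagating NaN;
#' degenerate (collinear) geometry raises an error.
#'
#' @param frame an [md_structure]
#' @param chain chain id
#' @param residue author residue number
#' @return list with `phi`, `psi` (degrees or NA) and logical `defined`
#'   vector flagging which of the two is computable
#' @export
backbone_dihedrals <- function(frame, chain, residue) {
  stopifnot(inherits(frame, "md_structure"))
  at <- frame$atoms
  get <- function(resid, name) {
    i <- which(at$chain_id == chain & at$residue_index == resid &
                 at$atom_name == name)
    if (length(i) != 1) return(NULL)
    frame$xyz[i, ]
  }
  N <- get(residue, "N"); CA <- get(residue, "CA"); C <- get(residue, "C")
  if (is.null(N) || is.null(CA) || is.null(C))
    stop("residue ", chain, ":", residue, " lacks backbone atoms")
  Cprev <- get(residue - 1, "C")
  Nnext <- get(residue + 1, "N")
  phi <- if (is.null(Cprev)) NA_real_ else .dihedral(Cprev, N, CA, C)
  psi <- if (is.null(Nnext)) NA_real_ else .dihedral(N, CA, C, Nnext)
  list(phi = phi, psi = psi,
       defined = c(phi = !is.null(Cprev), psi = !is.null(Nnext)))
}

#' Ramachandran distribution of one residue over a trajectory
#'
#' Collects per-frame (phi, psi) for a residue, evaluates the same residue's
#' angles in each supplied reference structure, and reports the fraction of
#' frames falling within an angular radius of each reference point under a
#' wrap-aware (circular, Euclidean-on-the-torus) metric.  The canonical use
#' is classifying substrate frames as "common-like" vs "retracted-like" by
#' the conformation of a hinge glycine.
#'
#' @param traj an [md_trajectory]
#' @param chain chain id
#' @param residue author residue number
#' @param references named list of [md_structure] reference conformations
#'   (a reference lacking the residue is skipped with a warning)
#' @param radius angular radius in degrees for the near-reference fractions
#' @return a `rama_distribution`: list with `angles` (data.frame `frame`,
#'   `phi`, `psi`), `reference_points`, `near_fractions`, `radius`
#' @export
rama_distribution <- function(traj, chain, residue, references = list(),
                              radius = 30) {
  stopifnot(inherits(traj, "md_trajectory"))
  T <- n_frames(traj)
  phi <- psi <- rep(NA_real_, T)
  for (f in seq_len(T)) {
    d <- backbone_dihedrals(get_frame(traj, f), chain, residue)
    phi[f] <- d$phi; psi[f] <- d$psi
  }
  ok <- !is.na(phi) & !is.na(psi)
  if (!any(ok)) stop("residue ", chain, ":", residue,
                     " has no assignable frames")
  refpts <- list()
  for (nm in names(references)) {
    r <- tryCatch(backbone_dihedrals(references[[nm]], chain, residue),
                  error = function(e) NULL)
    if (is.null(r) || is.na(r$phi) || is.na(r$psi)) {
      warning("reference '", nm, "' lacks residue ", chain, ":", residue,
              "; skipped")
      next
    }
    refpts[[nm]] <- c(phi = r$phi, psi = r$psi)
  }
  near <- vapply(refpts, function(p) {
    d <- sqrt(.circ_diff(phi[ok], p["phi"])^2 + .circ_diff(psi[ok],
                                                           p["psi"])^2)
    mean(d <= radius)
  }, numeric(1))
  structure(list(angles = data.frame(frame = which(ok), phi = phi[ok],
                                     psi = psi[ok]),
                 reference_points = refpts, near_fractions = near,
                 radius = radius, residue = paste0(chain, ":", residue)),
            class = "rama_distribution")
}

#' @export
print.rama_distribution <- function(x, ...) {
  cat("rama_distribution for ", x$residue, ": ", nrow(x$angles),
      " frames\n", sep = "")
  for (nm in names(x$near_fractions))
    cat(sprintf("  within %g deg of %s: %.1f%%\n", x$radius, nm,
                100 * x$near_fractions[[nm]]))
  invisible(x)
}

#' @export
plot.rama_distribution <- function(x, ...) {
  graphics::plot(x$angles$phi, x$angles$psi, pch = 16, cex = 0.4,
                 col = "grey40", xlim = c(-180, 180), ylim = c(-180, 180),
                 xlab = expression(phi), ylab = expression(psi), ...)
  for (nm in names(x$reference_points)) {
    p <- x$reference_points[[nm]]
    graphics::points(p["phi"], p["psi"], col = "red", pch = 19, cex = 1.2)
    graphics::text(p["phi"], p["psi"], nm, pos = 3, col = "red", cex = 0.8)
  }
  invisible(x)
}

#' Per-frame distance between two atoms
#'
#' Euclidean distance series between two named atoms, e.g. the CA-CA
#' distance between a substrate's residue 46 and its C-terminal residue 76
#' as a retraction marker.
#'
#' @param traj an [md_trajectory]
#' @param atom_a,atom_b lists `list(chain =, residue =, name = "CA")`
#' @return a `distance_series` numeric vector (A) with the atom labels as
#'   the `"pair"` attribute
#' @export
distance_series <- function(traj, atom_a, atom_b) {
  stopifnot(inherits(traj, "md_trajectory"))
  find <- function(a) {
    name <- a$name %||% "CA"
    at <- traj$topology$atoms
    i <- which(at$chain_id == a$chain & at$residue_index == a$residue &
                 at$atom_name == name)
    if (length(i) != 1)
      stop("atom ", a$chain, ":", a$residue, ":", name, " not in topology")
    i
  }
  ia <- find(atom_a); ib <- find(atom_b)
  d <- sqrt(colSums((traj$frames[ia, , ] - traj$frames[ib, , ])^2))
  attr(d, "pair") <- c(paste0(atom_a$chain, ":", atom_a$residue, ":",
                              atom_a$name %||% "CA"),
                       paste0(atom_b$chain, ":", atom_b$residue, ":",
                              atom_b$name %||% "CA"))
  class(d) <- c("distance_series", class(d))
  d
}

#' Centered moving average of a per-frame series
#'
#' Window width is `round(window / frame_dt)` frames, forced odd by adding
#' one when even; at the edges the centered window is truncated
#' symmetrically to the available frames, so the output has the input's
#' length.  A 5-nsec window on 250-psec frames averages 21 frames.
#'
#' @param series numeric per-frame values
#' @param window window width in psec (>= frame_dt)
#' @param frame_dt frame spacing in psec
#' @return smoothed numeric vector, same length as the input
#' @export
moving_average <- function(series, window, frame_dt) {
  if (window < frame_dt) stop("window must be >= frame_dt")
  series <- as.numeric(series)
  w <- round(window / frame_dt)
  if (w %% 2 == 0) w <- w + 1
  half <- (w - 1) / 2
  n <- length(series)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    mean(series[lo:hi])
  }, numeric(1))
}
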