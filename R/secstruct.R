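# DSSP-style secondary-structure assignment from backbone geometry.
# Backbone H-bonds are scored with the Kabsch-Sander electrostatic model
#   E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)  [kcal/mol]
# (bond if E < -0.5), with the amide H reconstructed when absent.
# Code alphabet: H (alpha), G (3-10), I (pi), E (strand), B (bridge),
# T (turn), C (coil); priority H > E > B > G > I > T > C.

.ks_cutoff <- -0.5
.ks_q <- 0.084 * 332

# per-residue backbone geometry table for one structure
.bb_table <- function(frame) {
  at <- frame$atoms
  res <- .residue_table(at)
  n <- nrow(res)
  key <- paste(at$chain_id, at$residue_index)
  pick <- function(name) {
    m <- match(paste(res$key, name), paste(key, at$atom_name))
    m
  }
  iN <- pick("N"); iCA <- pick("CA"); iC <- pick("C"); iO <- pick("O")
  iH <- pick("H")
  complete <- !(is.na(iN) | is.na(iCA) | is.na(iC) | is.na(iO))
  xyz <- frame$xyz
  H <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    if (!complete[i]) next
    if (!is.na(iH[i])) { H[i, ] <- xyz[iH[i], ]; next }
    # reconstruct: 1.01 A from N, anti to the bisector of C(prev)->N and CA->N
    prev_same <- i > 1 && res$chain_id[i - 1] == res$chain_id[i] &&
      complete[i - 1]
    if (!prev_same || res$residue_name[i] == "PRO") next  # no amide H
    Np <- xyz[iN[i], ]
    u <- .unit(Np - xyz[iC[i - 1], ]) + .unit(Np - xyz[iCA[i], ])
    if (.norm(u) < 1e-9) next
    H[i, ] <- Np + 1.01 * .unit(u)
  }
  list(res = res, n = n, complete = complete,
       N = xyz[iN, , drop = FALSE], CA = xyz[iCA, , drop = FALSE],
       C = xyz[iC, , drop = FALSE], O = xyz[iO, , drop = FALSE], H = H)
}

# HB[i, j]: does N-H of residue i donate to C=O of residue j?
.ks_hbond_matrix <- function(bb) {
  n <- bb$n
  HB <- matrix(FALSE, n, n)
  if (n < 2) return(HB)
  ca_d2 <- as.matrix(stats::dist(bb$CA))^2
  for (i in seq_len(n)) {
    if (!bb$complete[i] || anyNA(bb$H[i, ])) next
    for (j in seq_len(n)) {
      if (!bb$complete[j]) next
      same_chain <- bb$res$chain_id[i] == bb$res$chain_id[j]
      if (same_chain && abs(i - j) < 2) next
      if (is.na(ca_d2[i, j]) || ca_d2[i, j] > 81) next  # 9 A CA prefilter
      rON <- .norm(bb$O[j, ] - bb$N[i, ])
      rCH <- .norm(bb$C[j, ] - bb$H[i, ])
      rOH <- .norm(bb$O[j, ] - bb$H[i, ])
      rCN <- .norm(bb$C[j, ] - bb$N[i, ])
      if (min(rON, rCH, rOH, rCN) < 0.5) next  # clashing geometry
      E <- .ks_q * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
      HB[i, j] <- E < .ks_cutoff
    }
  }
  HB
}

#' Assign secondary structure to one frame
#'
#' DSSP-style assignment from backbone N, CA, C, O positions.  Backbone
#' hydrogen bonds are detected with the Kabsch-Sander energy (H-bond below
#' -0.5 kcal/mol; amide H reconstructed 1.01 A from N anti to the
#' C(prev)/CA bisector when not present).  n-turns (i -> i+3/4/5) yield
#' 3-10/alpha/pi helices when two start consecutively, bridges and ladders
#' yield B/E, turn spans yield T, everything else C.  Residues with missing
#' backbone atoms are coded C with a warning.
#'
#' @param frame an [md_structure]
#' @return named character vector of per-residue codes (names
#'   `chain:residue`), in topology order
#' @export
assign_secondary_structure <- function(frame) {
  stopifnot(inherits(frame, "md_structure"))
  bb <- .bb_table(frame)
  n <- bb$n
  if (any(!bb$complete))
    warning(sum(!bb$complete),
            " residue(s) missing backbone atoms: coded C")
  codes <- rep("C", n)
  names(codes) <- paste0(bb$res$chain_id, ":", bb$res$residue_index)
  if (n < 3) return(codes)
  HB <- .ks_hbond_matrix(bb)
  same_chain_run <- function(i, j)
    all(bb$res$chain_id[i:j] == bb$res$chain_id[i])
  # n-turns: turn_n[i] true when C=O of i accepts from N-H of i+n
  turn <- list()
  for (nn in 3:5) {
    tn <- rep(FALSE, n)
    for (i in seq_len(n - nn))
      if (same_chain_run(i, i + nn) && HB[i + nn, i]) tn[i] <- TRUE
    turn[[as.character(nn)]] <- tn
  }
  # bridges
  hb <- function(i, j) i >= 1 && j >= 1 && i <= n && j <= n && HB[i, j]
  bridge <- rep(FALSE, n)
  for (i in 2:(n - 1)) {
    for (j in 2:(n - 1)) {
      same <- bb$res$chain_id[i] == bb$res$chain_id[j]
      if (same && abs(i - j) < 3) next
      para <- (hb(i, j - 1) && hb(j + 1, i)) || (hb(j, i - 1) && hb(i + 1, j))
      anti <- (hb(i, j) && hb(j, i)) || (hb(i - 1, j + 1) && hb(j - 1, i + 1))
      if (para || anti) bridge[i] <- TRUE
    }
  }
  in_ladder <- bridge & (c(FALSE, bridge[-n]) | c(bridge[-1], FALSE))
  # helix marks: two consecutive n-turn starts
  mark <- function(tn, span) {
    m <- rep(FALSE, n)
    for (i in seq_len(n - 1))
      if (tn[i] && i > 1 && tn[i - 1]) m[i:min(n, i + span - 1)] <- TRUE
    m
  }
  isH <- mark(turn[["4"]], 4)
  isG <- mark(turn[["3"]], 3)
  isI <- mark(turn[["5"]], 5)
  # turn spans: interior residues of any single n-turn
  isT <- rep(FALSE, n)
  for (nn in 3:5) {
    tn <- turn[[as.character(nn)]]
    for (i in which(tn)) {
      lo <- i + 1; hi <- min(n, i + nn - 1)
      if (lo <= hi) isT[lo:hi] <- TRUE
    }
  }
  # priority H > E > B > G > I > T > C
  codes[isT] <- "T"
  codes[isI] <- "I"
  codes[isG] <- "G"
  codes[bridge & !in_ladder] <- "B"
  codes[in_ladder] <- "E"
  codes[isH] <- "H"
  codes[!bb$complete] <- "C"
  codes
}

#' Secondary-structure timeline of a trajectory
#'
#' Runs [assign_secondary_structure] on every frame.
#'
#' @param traj an [md_trajectory]
#' @return an `ss_timeline`: list with `codes` (T x n_res character matrix),
#'   `residues`, `frame_dt`
#' @export
ss_timeline <- function(traj) {
  stopifnot(inherits(traj, "md_trajectory"))
  T <- n_frames(traj)
  res <- .residue_table(traj$topology$atoms)
  codes <- matrix("C", T, nrow(res))
  colnames(codes) <- paste0(res$chain_id, ":", res$residue_index)
  for (f in seq_len(T))
    codes[f, ] <- assign_secondary_structure(get_frame(traj, f))
  structure(list(codes = codes, residues = res, frame_dt = traj$frame_dt),
            class = "ss_timeline")
}

#' @export
print.ss_timeline <- function(x, ...) {
  tab <- sort(table(x$codes), decreasing = TRUE)
  cat("ss_timeline:", nrow(x$codes), "frames x", ncol(x$codes), "residues;",
      paste(names(tab), sprintf("%.1f%%", 100 * tab / sum(tab)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Secondary-structure occupancy of a residue region
#'
#' Percentage of simulation time a region spends in a set of codes.
#' `per_residue_mean` averages, over the listed residues, each residue's
#' fraction of frames with a code in `codes`; `all_residues` is the fraction
#' of frames in which EVERY listed residue simultaneously has a code in
#' `codes`.  Both are percentages in \[0, 100\].
#'
#' @param timeline an [ss_timeline]
#' @param residues author residue numbers of the region
#' @param codes character vector of structure codes, e.g. `c("T")` or
#'   `c("G")`
#' @param chain optional chain id restricting the region
#' @param mode `"per_residue_mean"` (default) or `"all_residues"`
#' @return percentage (numeric scalar)
#' @export
occupancy <- function(timeline, residues, codes,
                      chain = NULL, mode = c("per_residue_mean",
                                             "all_residues")) {
  stopifnot(inherits(timeline, "ss_timeline"))
  mode <- match.arg(mode)
  if (!length(residues)) stop("empty residue set")
  res <- timeline$residues
  cols <- which(res$residue_index %in% residues &
                  (if (is.null(chain)) TRUE else res$chain_id == chain))
  if (length(cols) == 0)
    stop("no listed residue found in the timeline")
  sub <- timeline$codes[, cols, drop = FALSE]
  hit <- matrix(sub %in% codes, nrow = nrow(sub))
  if (mode == "per_residue_mean") 100 * mean(colMeans(hit))
  else 100 * mean(rowSums(hit) == ncol(hit))
}
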