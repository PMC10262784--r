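#' Contact-count interaction energy of an interface
#'
#' A deliberately simple, deterministic stand-in scorer:
#' `E = -epsilon * (number of inter-selection heavy-atom pairs within r_cut)`.
#' It is NOT a physical force field; it exists so the cluster-weighting
#' machinery has a self-contained provider.  Externally computed per-cluster
#' energies (e.g. from an empirical force-field scorer) can be supplied
#' directly to [weighted_interaction_score].
#'
#' @param frame an [md_structure]
#' @param chain_A,chain_B disjoint `md_selection`s or selection strings
#' @param epsilon per-contact energy in kcal/mol
#' @param r_cut contact distance cutoff in A
#' @return energy in kcal/mol (<= 0)
#' @export
contact_interaction_energy <- function(frame, chain_A, chain_B,
                                       epsilon = 0.1, r_cut = 4.5) {
  stopifnot(inherits(frame, "md_structure"))
  if (is.character(chain_A)) chain_A <- resolve_selection(frame, chain_A)
  if (is.character(chain_B)) chain_B <- resolve_selection(frame, chain_B)
  if (length(intersect(chain_A$indices, chain_B$indices)))
    stop("chain selections overlap")
  heavy <- function(sel) {
    i <- sel$indices
    i[frame$atoms$element[i] != "H"]
  }
  ia <- heavy(chain_A); ib <- heavy(chain_B)
  n <- .cpp_contact_count(frame$xyz[ia, , drop = FALSE],
                          frame$xyz[ib, , drop = FALSE], r_cut)
  -epsilon * n
}

#' Cluster-frequency-weighted interaction score
#'
#' Combines per-cluster raw interaction energies with the fraction of
#' simulation frames each cluster represents:
#' `total = sum_i raw_i * freq_i`.  Frequencies are fractions of ALL frames,
#' so rejected frames dilute the total; they carry no weight of their own.
#'
#' @param raw per-cluster raw energies (kcal/mol)
#' @param frequencies per-cluster frame fractions (>= 0, summing to <= 1)
#' @param provider name of the raw-energy provider recorded in the report
#' @return a `weighted_energy_report`: data.frame of per-cluster terms with
#'   the `total` and `provider` attributes
#' @export
weighted_interaction_score <- function(raw, frequencies,
                                       provider = "contact_count") {
  if (length(raw) != length(frequencies))
    stop("raw and frequencies must have equal length")
  if (any(frequencies < 0)) stop("frequencies must be >= 0")
  if (sum(frequencies) > 1 + 1e-9)
    stop("frequencies sum to more than 1")
  rep <- data.frame(cluster = seq_along(raw), raw = as.numeric(raw),
                    frequency = as.numeric(frequencies),
                    weighted = as.numeric(raw) * as.numeric(frequencies))
  attr(rep, "total") <- sum(rep$weighted)
  attr(rep, "provider") <- provider
  class(rep) <- c("weighted_energy_report", "data.frame")
  rep
}

#' Total of a weighted energy report
#' @param report a `weighted_energy_report`
#' @return total weighted energy in kcal/mol
#' @export
weighted_total <- function(report) {
  stopifnot(inherits(report, "weighted_energy_report"))
  attr(report, "total")
}

#' @export
print.weighted_energy_report <- function(x, ...) {
  cat("weighted_energy_report (provider: ", attr(x, "provider"), ")\n",
      sep = "")
  df <- as.data.frame(x)
  df$frequency <- sprintf("%.1f%%", 100 * df$frequency)
  print.data.frame(df, row.names = FALSE, digits = 4)
  cat(sprintf("total weighted dG: %.4f kcal/mol\n", attr(x, "total")))
  invisible(x)
}

#' Per-cluster interaction energies for a trajectory
#'
#' Scores the center frame of every cluster with
#' [contact_interaction_energy] (or values supplied via `raw_energies`) and
#' weights by cluster frequency.
#'
#' @param traj the clustered [md_trajectory]
#' @param clusters a [qt_cluster] result
#' @param chain_A,chain_B interface selections (strings or `md_selection`s)
#' @param raw_energies optional externally computed per-cluster energies
#'   (kcal/mol), bypassing the stand-in scorer
#' @param epsilon,r_cut stand-in scorer parameters
#' @return a `weighted_energy_report`
#' @export
cluster_energetics <- function(traj, clusters, chain_A, chain_B,
                               raw_energies = NULL, epsilon = 0.1,
                               r_cut = 4.5) {
  stopifnot(inherits(clusters, "cluster_set"))
  freqs <- vapply(clusters$clusters, `[[`, numeric(1), "frequency")
  if (is.null(raw_energies)) {
    raw_energies <- vapply(clusters$clusters, function(cl)
      contact_interaction_energy(get_frame(traj, cl$center), chain_A,
                                 chain_B, epsilon, r_cut), numeric(1))
    provider <- "contact_count"
  } else {
    if (length(raw_energies) != length(freqs))
      stop("raw_energies length does not match cluster count")
    provider <- "external"
  }
  weighted_interaction_score(raw_energies, freqs, provider = provider)
}
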