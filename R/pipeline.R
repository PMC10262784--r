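# Config-driven orchestration: one or two trajectories analyzed with
# identical settings, bundled into a comparison report.

# key -> list(default, source, check); source labels distinguish settings
# carrying the conventional literature values ("convention") from free
# artifact choices ("artifact").
.config_schema <- function() list(
  trajectory = list(default = NULL, source = "required"),
  trajectory_2 = list(default = NULL, source = "optional"),
  kinase_chain = list(default = "A", source = "artifact"),
  substrate_chain = list(default = "U", source = "artifact"),
  fit_selection = list(default = NULL, source = "convention"),
  loop3_selection = list(default = NULL, source = "optional"),
  substrate_residue = list(default = 65, source = "convention"),
  retraction_res_a = list(default = 46, source = "convention"),
  retraction_res_b = list(default = 76, source = "convention"),
  cluster_selection = list(default = NULL, source = "artifact"),
  probe_radius = list(default = 1.4, source = "convention"),
  n_sphere_points = list(default = 960, source = "artifact"),
  qt_cutoff = list(default = 1.75, source = "convention"),
  min_cluster_frac = list(default = 0.01, source = "convention"),
  cluster_stride = list(default = 1, source = "artifact"),
  hbond_distance = list(default = 3.5, source = "artifact"),
  hbond_angle = list(default = 30, source = "artifact"),
  covariance_threshold = list(default = 0.75, source = "convention"),
  ma_window = list(default = 5000, source = "convention"),
  frame_dt = list(default = 250, source = "convention"),
  ref_common = list(default = NULL, source = "optional"),
  ref_cr = list(default = NULL, source = "optional"),
  seed = list(default = 1, source = "artifact")
)

#' Validate a run configuration
#'
#' Accepts a YAML file path or a named list; fills defaults, rejects unknown
#' keys, checks value sanity and referenced paths, and returns a fully
#' resolved `run_config` whose settings echo (key, value, source) is carried
#' into every report.  Errors are aggregated into one message.
#'
#' @param config file path or named list
#' @return a `run_config`
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a file path or a named list")
  schema <- .config_schema()
  errs <- character()
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown))
    errs <- c(errs, paste0("unknown key(s): ", paste(unknown,
                                                     collapse = ", ")))
  out <- lapply(names(schema), function(k)
    if (!is.null(config[[k]])) config[[k]] else schema[[k]]$default)
  names(out) <- names(schema)
  if (is.null(out$trajectory))
    errs <- c(errs, "'trajectory' is required (path or md_trajectory)")
  for (k in c("probe_radius", "qt_cutoff", "min_cluster_frac",
              "hbond_distance", "hbond_angle", "ma_window", "frame_dt",
              "cluster_stride", "n_sphere_points"))
    if (!is.null(out[[k]]) && (!is.numeric(out[[k]]) || out[[k]] <= 0))
      errs <- c(errs, paste0("'", k, "' must be a positive number"))
  if (is.numeric(out$covariance_threshold) &&
      (out$covariance_threshold <= 0 || out$covariance_threshold > 1))
    errs <- c(errs, "'covariance_threshold' must be in (0, 1]")
  for (k in c("trajectory", "trajectory_2", "ref_common", "ref_cr")) {
    v <- out[[k]]
    if (is.character(v) && !file.exists(v))
      errs <- c(errs, paste0("'", k, "' path does not exist: ", v))
  }
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  if (is.null(out$fit_selection))
    out$fit_selection <- paste("chain", out$kinase_chain, "and backbone")
  if (is.null(out$cluster_selection))
    out$cluster_selection <- paste("chain", out$substrate_chain,
                                   "and backbone")
  if (is.null(out$loop3_selection))
    out$loop3_selection <- paste("chain", out$kinase_chain)
  out$settings_echo <- data.frame(
    key = names(schema),
    value = vapply(names(schema), function(k) {
      v <- out[[k]]
      if (is.null(v)) "<none>"
      else if (is.atomic(v)) paste(format(v), collapse = " ")
      else paste0("<", class(v)[1], ">")
    }, character(1)),
    source = vapply(schema, `[[`, character(1), "source"),
    stringsAsFactors = FALSE)
  class(out) <- "run_config"
  out
}

.load_traj <- function(x, frame_dt) {
  if (inherits(x, "md_trajectory")) return(x)
  obj <- read_pdb(x, frame_dt = frame_dt)
  if (!inherits(obj, "md_trajectory"))
    stop("expected a multi-model trajectory: ", x)
  obj
}
.load_struct <- function(x) {
  if (is.null(x) || inherits(x, "md_structure")) return(x)
  read_pdb(x)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

# full analysis bundle for one trajectory under a resolved config
.analyze_one <- function(traj, cfg, references) {
  kin <- cfg$kinase_chain; sub <- cfg$substrate_chain
  crit <- hbond_criteria(cfg$hbond_distance, cfg$hbond_angle)
  aligned <- .stage("align", align_trajectory(traj, cfg$fit_selection))
  bundle <- list()
  bundle$rmsd <- .stage("rmsd", rmsd_series(aligned, "backbone"))
  bundle$rmsf <- .stage("rmsf", rmsf_profile(aligned, "backbone"))
  bundle$covariance <- .stage("covariance",
                              covariance_matrix(aligned, "name CA"))
  bundle$ss <- .stage("secondary structure", ss_timeline(aligned))
  res <- .residue_table(aligned$topology$atoms)
  sub_res <- res$residue_index[res$chain_id == sub]
  tail_res <- sort(tail(sort(sub_res), 4))
  bundle$tail_residues <- tail_res
  bundle$tail_turn_occupancy <-
    .stage("occupancy", occupancy(bundle$ss, tail_res, "T", chain = sub))
  bundle$sasa_s65 <- .stage("sasa", sasa_series(
    aligned, paste("chain", sub, "and resid", cfg$substrate_residue),
    "all", probe = cfg$probe_radius, n_points = cfg$n_sphere_points))
  bundle$sasa_s65_ma <- moving_average(bundle$sasa_s65, cfg$ma_window,
                                       aligned$frame_dt)
  bundle$bsa <- .stage("bsa", buried_surface_area(
    aligned, paste("chain", kin), paste("chain", sub),
    probe = cfg$probe_radius, n_points = cfg$n_sphere_points))
  bundle$bsa_ma <- moving_average(bundle$bsa, cfg$ma_window,
                                  aligned$frame_dt)
  bundle$retraction <- .stage("retraction distance", distance_series(
    aligned, list(chain = sub, residue = cfg$retraction_res_a, name = "CA"),
    list(chain = sub, residue = cfg$retraction_res_b, name = "CA")))
  bundle$retraction_ma <- moving_average(bundle$retraction, cfg$ma_window,
                                         aligned$frame_dt)
  bundle$hbonds <- .stage("hbonds", hbond_count_series(
    aligned, cfg$loop3_selection, paste("chain", sub), crit))
  rmat <- .stage("pairwise rmsd", pairwise_rmsd_matrix(
    aligned, cfg$cluster_selection, stride = cfg$cluster_stride))
  bundle$clusters <- .stage("qt clustering",
                            qt_cluster(rmat, cfg$qt_cutoff,
                                       cfg$min_cluster_frac))
  if (length(references)) {
    bundle$cluster_table <- .stage("reference labeling", label_clusters(
      aligned, bundle$clusters, references,
      selection = cfg$cluster_selection))
  }
  bundle$energetics <- .stage("energetics", cluster_energetics(
    aligned, bundle$clusters, paste("chain", kin), paste("chain", sub)))
  bundle$aligned <- aligned
  bundle
}

#' Run the full comparative analysis
#'
#' Executes the complete pipeline on one or two trajectories with identical
#' settings: alignment, RMSD/RMSF, CA covariance, secondary-structure
#' timeline and tail-turn occupancy, substrate-residue SASA, buried surface
#' area, retraction distance (all with moving averages), hydrogen-bond
#' counts, Quality-Threshold clustering with reference labeling, and
#' frequency-weighted interaction energetics.  With two trajectories a
#' delta block (trajectory 2 minus trajectory 1) is added.
#'
#' @param config a `run_config` from [validate_config], a config file path,
#'   or a named list of settings
#' @return a `comparison_report`
#' @export
run_analysis <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  refs <- list()
  if (!is.null(config$ref_common))
    refs$common <- .load_struct(config$ref_common)
  if (!is.null(config$ref_cr)) refs$cr <- .load_struct(config$ref_cr)
  t1 <- .stage("load trajectory 1",
               .load_traj(config$trajectory, config$frame_dt))
  b1 <- .analyze_one(t1, config, refs)
  b2 <- NULL
  if (!is.null(config$trajectory_2)) {
    t2 <- .stage("load trajectory 2",
                 .load_traj(config$trajectory_2, config$frame_dt))
    b2 <- .analyze_one(t2, config, refs)
  }
  summarize <- function(b) {
    rmsf <- b$rmsf
    kin <- config$kinase_chain; sub <- config$substrate_chain
    cr_freq <- if (!is.null(b$cluster_table) &&
                   "cr" %in% names(refs))
      sum(b$cluster_table$frequency[b$cluster_table$label == "cr"])
    else NA_real_
    c(mean_rmsf_kinase = mean(rmsf$rmsf[rmsf$chain_id == kin]),
      mean_rmsf_substrate = mean(rmsf$rmsf[rmsf$chain_id == sub]),
      mean_sasa_s65 = mean(b$sasa_s65),
      mean_bsa = mean(b$bsa),
      mean_retraction = mean(b$retraction),
      mean_hbonds = mean(b$hbonds),
      tail_turn_occupancy = b$tail_turn_occupancy,
      n_clusters = length(b$clusters$clusters),
      cr_like_frequency = cr_freq,
      weighted_dG = weighted_total(b$energetics))
  }
  s1 <- summarize(b1)
  s2 <- if (!is.null(b2)) summarize(b2) else NULL
  out <- list(bundle_1 = b1, bundle_2 = b2, summary_1 = s1, summary_2 = s2,
              delta = if (!is.null(s2)) s2 - s1 else NULL,
              settings = config$settings_echo, config = config)
  class(out) <- "comparison_report"
  out
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("comparison_report\n")
  tab <- data.frame(metric = names(x$summary_1),
                    trajectory_1 = unname(x$summary_1))
  if (!is.null(x$summary_2)) {
    tab$trajectory_2 <- unname(x$summary_2)
    tab$delta <- unname(x$delta)
  }
  print.data.frame(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a report's tables as TSV files
#'
#' Serializes RMSD/RMSF/SASA/BSA/distance/H-bond series, the covariance
#' matrix, the secondary-structure timeline, the cluster and energetics
#' tables, the summary block, and the resolved settings echo into a
#' directory of TSV files (one per trajectory bundle).
#'
#' @param report a `comparison_report`
#' @param dir output directory (created if missing)
#' @return invisibly, the directory
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "comparison_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, name)
    write.table(x, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  dump_bundle <- function(b, tag) {
    t_ps <- (seq_along(b$rmsd) - 1) * b$aligned$frame_dt
    wt(data.frame(time_ps = t_ps, rmsd = b$rmsd),
       paste0(tag, "_rmsd.tsv"))
    wt(b$rmsf, paste0(tag, "_rmsf.tsv"))
    cv <- as.data.frame(b$covariance$values)
    cv <- cbind(residue = rownames(b$covariance$values), cv)
    wt(cv, paste0(tag, "_covariance.tsv"))
    wt(as.data.frame(b$ss$codes), paste0(tag, "_ss_timeline.tsv"))
    wt(data.frame(time_ps = t_ps, sasa = b$sasa_s65,
                  sasa_ma = b$sasa_s65_ma, bsa = b$bsa, bsa_ma = b$bsa_ma,
                  retraction = as.numeric(b$retraction),
                  retraction_ma = b$retraction_ma, hbonds = b$hbonds),
       paste0(tag, "_series.tsv"))
    if (!is.null(b$cluster_table))
      wt(b$cluster_table, paste0(tag, "_clusters.tsv"))
    else {
      cl <- b$clusters
      wt(data.frame(cluster = seq_along(cl$clusters),
                    size = vapply(cl$clusters, function(c)
                      length(c$members), numeric(1)),
                    frequency = vapply(cl$clusters, `[[`, numeric(1),
                                       "frequency"),
                    center = vapply(cl$clusters, `[[`, numeric(1),
                                    "center")),
         paste0(tag, "_clusters.tsv"))
    }
    en <- as.data.frame(b$energetics)
    wt(en, paste0(tag, "_energetics.tsv"))
  }
  dump_bundle(report$bundle_1, "traj1")
  if (!is.null(report$bundle_2)) dump_bundle(report$bundle_2, "traj2")
  sm <- data.frame(metric = names(report$summary_1),
                   trajectory_1 = unname(report$summary_1))
  if (!is.null(report$summary_2)) {
    sm$trajectory_2 <- unname(report$summary_2)
    sm$delta <- unname(report$delta)
  }
  wt(sm, "summary.tsv")
  wt(report$settings, "settings.tsv")
  invisible(dir)
}
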