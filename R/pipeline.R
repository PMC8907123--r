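#' Pipeline configuration
#'
#' Validated bundle of every knob the full analysis uses. Unknown arguments
#' are rejected so typos cannot silently fall back to defaults.
#'
#' @param particles path to a particle CSV ([read_particles()]); may be
#'   `NULL` when a dataset is passed to [run_pipeline()] directly.
#' @param regions path to a region file ([read_regions()]) or a list of
#'   [az_window()]s.
#' @param n_sims Monte-Carlo simulations per AZ (default 200).
#' @param seed master integer seed; every stochastic stage derives its
#'   substream from it.
#' @param cluster a [cluster_config()].
#' @param r_min,r_max,bandwidth g(r) summary parameters (nm).
#' @param calibration `NULL`, or a list with `n_total_channels`,
#'   `az_total_area_um2`, `extra_area_um2` (densities are measured from the
#'   data).
#' @param efficiency labeling efficiency used to scale particle counts to
#'   channels; if `NULL` and `calibration` is given, the calibrated value is
#'   used.
#' @param out_dir output directory; `NULL` disables file output.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(particles = NULL, regions = NULL,
                            n_sims = 200L, seed = 1L,
                            cluster = cluster_config(),
                            r_min = 10, r_max = 50, bandwidth = 5,
                            calibration = NULL, efficiency = NULL,
                            out_dir = NULL) {
  stopifnot(n_sims >= 1, inherits(cluster, "cluster_config"),
            r_min > 0, r_max > r_min, bandwidth > 0)
  if (!is.null(calibration)) {
    need <- c("n_total_channels", "az_total_area_um2", "extra_area_um2")
    extra <- setdiff(names(calibration), need)
    if (length(extra))
      stop("unknown calibration key(s): ", paste(extra, collapse = ", "),
           call. = FALSE)
    if (!all(need %in% names(calibration)))
      stop("calibration needs: ", paste(need, collapse = ", "), call. = FALSE)
  }
  structure(list(particles = particles, regions = regions,
                 n_sims = as.integer(n_sims), seed = as.integer(seed),
                 cluster = cluster, r_min = r_min, r_max = r_max,
                 bandwidth = bandwidth, calibration = calibration,
                 efficiency = efficiency, out_dir = out_dir),
            class = "pipeline_config")
}

#' Quality-control report for a dataset
#'
#' The in-silico part of the artefact checklist for immunogold replicas:
#' per-face particle counts; density of "wrong-face" background (E-face or
#' cross-fracture particles for an intracellular epitope) and whether that
#' background is itself clustered (clustered background means apparent
#' particle clusters may be antibody artefacts, so a warning is raised);
#' duplicate coordinates; and particles rejected at read time.
#'
#' @param dataset a [replica_dataset()].
#' @param background_cluster_config [cluster_config()] used to test the
#'   background for clustering (default: DBSCAN, minPts 3, 100 nm).
#' @return a list with `per_face` (data frame of counts), `background`
#'   (density and clustering flag, or `NULL` if no background particles),
#'   `n_duplicates`, `n_rejects`, `warnings` (character vector).
#' @export
qc_report <- function(dataset,
                      background_cluster_config = cluster_config(
                        method = "dbscan", min_points = 3L,
                        epsilon_rule = "fixed", epsilon_nm = 100)) {
  stopifnot(inherits(dataset, "replica_dataset"))
  faces <- vapply(dataset$patterns, function(p) p$face, "")
  counts <- vapply(dataset$patterns, npoints, 0L)
  per_face <- stats::aggregate(list(n_particles = counts),
                               by = list(face = faces), FUN = sum)
  warnings <- character(0)

  bg_pats <- Filter(function(p) p$face != "P_face" && npoints(p) > 0,
                    dataset$patterns)
  background <- NULL
  if (length(bg_pats)) {
    n_bg <- sum(vapply(bg_pats, npoints, 0L))
    a_bg <- sum(vapply(bg_pats, function(p) polygon_area(p$window), 0)) /
      NM2_PER_UM2
    clustered <- any(vapply(bg_pats, function(p)
      detect_clusters(p, background_cluster_config)$n_clusters > 0, TRUE))
    if (clustered)
      warnings <- c(warnings,
                    "background (wrong-face) particles form clusters: possible antibody aggregation artefact")
    background <- list(n_particles = n_bg, density_per_um2 = n_bg / a_bg,
                       clustered = clustered)
  }
  n_dup <- sum(vapply(dataset$patterns,
                      function(p) pattern_validity(p)$n_duplicates, 0L))
  if (n_dup > 0)
    warnings <- c(warnings,
                  sprintf("%d duplicated particle coordinate(s)", n_dup))
  n_rej <- if (is.null(dataset$rejects)) 0L else nrow(dataset$rejects)
  if (n_rej > 0)
    warnings <- c(warnings,
                  sprintf("%d particle(s) rejected at read time", n_rej))
  list(per_face = per_face, background = background,
       n_duplicates = n_dup, n_rejects = n_rej, warnings = warnings)
}

#' Run the full analysis pipeline
#'
#' Sequences the whole workflow on one dataset: QC, pooled densities, per-AZ
#' NND / g(r) / CPI, the paired Monte-Carlo clustering test, cluster
#' detection with channel scaling, and (when constants are supplied) the
#' labeling-efficiency calibration. Reruns with the same config and data are
#' bit-identical; the config hash and seed are recorded in the summary.
#'
#' When `config$out_dir` is set, writes `per_az.csv` (one row per AZ),
#' `clusters.csv` (one row per cluster) and `summary.json`. A stage failure
#' aborts with a stage-tagged error and removes partial outputs.
#'
#' @param config a [pipeline_config()].
#' @param dataset optional [replica_dataset()]; if `NULL`, read from
#'   `config$particles` / `config$regions`.
#' @return a list (invisibly when writing files): `qc`, `densities`,
#'   `per_az` (data frame), `paired_tests`, `clusters`, `calibration`,
#'   `config_hash`, `seed`.
#' @export
run_pipeline <- function(config, dataset = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  written <- character(0)
  fail <- function(stage, e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  on_err_cleanup <- function() if (length(written)) unlink(written)

  stage <- function(name, expr)
    tryCatch(expr, error = function(e) { on_err_cleanup(); fail(name, e) })

  dataset <- stage("read", {
    if (is.null(dataset)) {
      if (is.null(config$particles) || is.null(config$regions))
        stop("no dataset given and no input paths configured")
      read_particles(config$particles, config$regions)
    } else dataset
  })

  qc <- stage("qc", qc_report(dataset))
  dens <- stage("density", densities_from_patterns(dataset))

  az <- patterns_by_class(dataset, "AZ")
  az <- Filter(function(p) p$face == "P_face", az)
  per_az <- stage("spatial_stats", {
    rows <- lapply(az, function(p) {
      n <- npoints(p)
      enough <- n >= 2
      s <- if (enough) mean_nnd(p) else NULL
      eps <- if (enough && config$cluster$epsilon_rule == "nnd_mean_plus_2sd")
        s$mean + 2 * s$sd else config$cluster$epsilon_nm
      data.frame(
        region_id = p$window$region_id,
        n_particles = n,
        area_um2 = polygon_area(p$window) / NM2_PER_UM2,
        density_per_um2 = n / (polygon_area(p$window) / NM2_PER_UM2),
        mean_nnd_nm = if (enough) s$mean else NA_real_,
        sd_nnd_nm = if (enough) s$sd else NA_real_,
        g_summary = if (enough)
          g_summary(p, config$r_min, config$r_max, config$bandwidth)
          else NA_real_,
        cpi_mean = if (n >= 1) cpi(p)$mean else NA_real_,
        epsilon_nm = eps,
        null_seed = substream_seed(config$seed, p$window$region_id),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })

  paired <- stage("paired_test", {
    eligible <- Filter(function(p) npoints(p) >= 2, az)
    if (length(eligible) >= 2)
      paired_nnd_test(dataset, n_sims = config$n_sims, seed = config$seed,
                      r_min = config$r_min, r_max = config$r_max,
                      bandwidth = config$bandwidth)
    else NULL
  })

  calib <- stage("calibration", {
    if (is.null(config$calibration)) NULL else {
      inp <- calibration_inputs(
        n_total_channels = config$calibration$n_total_channels,
        az_total_area_um2 = config$calibration$az_total_area_um2,
        extra_area_um2 = config$calibration$extra_area_um2,
        rho_az = dens$rho_az, rho_extra = dens$rho_extra)
      true_density_and_efficiency(inp)
    }
  })

  eff <- config$efficiency %||% (if (!is.null(calib)) calib$efficiency else 1)
  clusters <- stage("cluster", {
    res <- lapply(az, detect_clusters, config = config$cluster)
    cluster_summary(res, efficiency = eff)
  })

  summary <- list(
    synapse_type = dataset$synapse_type,
    n_az = length(az),
    densities = dens,
    paired_nnd_p = if (!is.null(paired)) paired$nnd$p else NULL,
    paired_g_p = if (!is.null(paired)) paired$g$p else NULL,
    clusters_per_az = clusters$summary$clusters_per_az_mean,
    particles_per_cluster = clusters$summary$particles_per_cluster_mean,
    channels_per_cluster = clusters$summary$channels_per_cluster_mean,
    efficiency = eff,
    f_az = if (!is.null(calib)) calib$f_az else NULL,
    true_density_az = if (!is.null(calib)) calib$true_density_az else NULL,
    qc_warnings = qc$warnings,
    seed = config$seed,
    n_sims = config$n_sims,
    config_hash = config_hash(config[setdiff(names(config), "out_dir")]))

  if (!is.null(out_dir)) {
    stage("write", {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      f1 <- file.path(out_dir, "per_az.csv")
      f2 <- file.path(out_dir, "clusters.csv")
      f3 <- file.path(out_dir, "summary.json")
      written <<- c(f1, f2, f3)
      utils::write.csv(per_az, f1, row.names = FALSE)
      utils::write.csv(clusters$per_cluster, f2, row.names = FALSE)
      jsonlite::write_json(summary, f3, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
    })
  }

  res <- list(qc = qc, densities = dens, per_az = per_az,
              paired_tests = paired, clusters = clusters,
              calibration = calib, summary = summary,
              config_hash = summary$config_hash, seed = config$seed)
  if (is.null(out_dir)) res else invisible(res)
}
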