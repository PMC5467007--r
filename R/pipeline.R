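#' Pipeline configuration
#'
#' Aggregates every tunable constant of the analysis: the 2% BOLD amplitude
#' threshold, the 0.05 FDR level, the ±0.015 %/min drift-correction limit,
#' the 0.8 mm smoothing kernel, the 0.05 significance level for group
#' comparisons, and the 0.5 composite-map frequency, together with the
#' window scheme, file paths and master seed.
#'
#' @param label_path,region_table_path,network_table_path atlas file paths.
#' @param manifest_path cohort manifest CSV
#'   (`subject_id,treatment,seed,path`).
#' @param output_dir directory for all outputs.
#' @param baseline,windows passed to [window_scheme()].
#' @param threshold_pct activation amplitude threshold, % BOLD.
#' @param fdr_q voxel-wise false discovery rate.
#' @param drift_limit drift-correction limit, % signal per minute.
#' @param fwhm_mm Gaussian smoothing kernel FWHM, mm.
#' @param alpha significance level for region/network group comparisons.
#' @param min_frequency composite-map retention fraction.
#' @param control control (vehicle) group label.
#' @param seed master seed for any randomness downstream.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(label_path = "atlas_labels.nii.gz",
                            region_table_path = "atlas_regions.csv",
                            network_table_path = "atlas_networks.csv",
                            manifest_path = "cohort/manifest.csv",
                            output_dir = "phmri_out",
                            baseline = c(1L, 50L),
                            windows = list("15-25" = c(150L, 250L),
                                           "25-35" = c(250L, 350L),
                                           "35-45" = c(350L, 450L)),
                            threshold_pct = 2.0,
                            fdr_q = 0.05,
                            drift_limit = 0.015,
                            fwhm_mm = 0.8,
                            alpha = 0.05,
                            min_frequency = 0.5,
                            control = "vehicle",
                            seed = 1L) {
  for (r in c(fdr_q, alpha, min_frequency))
    if (!is.finite(r) || r <= 0 || r >= 1)
      stop("fdr_q, alpha and min_frequency must lie in (0, 1)")
  if (threshold_pct < 0) stop("threshold_pct must be >= 0")
  if (drift_limit <= 0) stop("drift_limit must be positive")
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  scheme <- window_scheme(baseline, windows)   # validates the ranges
  structure(list(label_path = label_path,
                 region_table_path = region_table_path,
                 network_table_path = network_table_path,
                 manifest_path = manifest_path, output_dir = output_dir,
                 baseline = scheme$baseline, windows = scheme$windows,
                 threshold_pct = threshold_pct, fdr_q = fdr_q,
                 drift_limit = drift_limit, fwhm_mm = fwhm_mm,
                 alpha = alpha, min_frequency = min_frequency,
                 control = control, seed = as.integer(seed)),
            class = "pipeline_config")
}

config_scheme <- function(config)
  window_scheme(config$baseline, config$windows)

# relative config paths live under output_dir; absolute paths pass through
resolve_path <- function(config, p) {
  if (grepl("^(/|[A-Za-z]:)", p) || file.exists(p)) p
  else file.path(config$output_dir, p)
}

#' Write / read a pipeline configuration as YAML
#'
#' The YAML round-trips exactly: `read_pipeline_config(write_pipeline_config
#' (cfg, path))` reproduces `cfg`.
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` returns the validated [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$baseline <- as.list(as.integer(x$baseline))
  x$windows <- lapply(x$windows, function(w) as.list(as.integer(w)))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$baseline <- as.integer(unlist(x$baseline))
  x$windows <- lapply(x$windows, function(w) as.integer(unlist(w)))
  do.call(pipeline_config, x)
}

#' Simulate a cohort to disk
#'
#' Generates (or reuses) an atlas, simulates a full cohort under the supplied
#' response specification, and writes everything the analysis stage needs:
#' atlas volume + tables, one 4D NIfTI per subject, the cohort manifest, and
#' the ground-truth response spec (as YAML) for later recovery checks.
#'
#' @param config a [pipeline_config()]; paths are created under
#'   `config$output_dir` unless absolute.
#' @param spec a [response_spec()].
#' @param atlas optional [atlas()]; by default a block atlas with `n_regions`
#'   regions is generated from `config$seed`.
#' @param cfg a [session_config()].
#' @param group_sizes named treatment -> n vector.
#' @param n_regions regions for the generated atlas when `atlas` is NULL.
#' @return Invisibly, the manifest data.frame.
#' @export
run_simulate <- function(config, spec, atlas = NULL,
                         cfg = session_config(),
                         group_sizes = c(vehicle = 9L, idalopirdine = 10L,
                                         donepezil = 8L, combination = 9L),
                         n_regions = 6L) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  under <- function(p) resolve_path(config, p)

  if (is.null(atlas))
    atlas <- generate_atlas(cfg$shape, n_regions, seed = config$seed,
                            voxel_size = cfg$voxel_size)
  write_atlas(atlas, under(config$label_path),
              under(config$region_table_path),
              under(config$network_table_path))

  sessions <- generate_cohort(atlas, spec, cfg, group_sizes,
                              seed = config$seed)
  manifest <- write_cohort(sessions, dirname(under(config$manifest_path)))
  yaml::write_yaml(
    list(response_spec = lapply(seq_len(nrow(spec)), function(i)
      as.list(spec[i, ])),
      session_config = unclass(cfg),
      group_sizes = as.list(group_sizes)),
    file.path(out, "ground_truth.yaml"))
  invisible(manifest)
}

#' Analyse a single subject
#'
#' The per-subject pipeline stage: global drift estimation and (if above the
#' limit) correction, Gaussian smoothing, label propagation, the voxel-wise
#' activation map, and the positive volume-of-activation table.
#'
#' @param session a [bold_session()] in atlas space.
#' @param atlas a [atlas()].
#' @param config a [pipeline_config()].
#' @return List: `statmap` (the `voxel_stat_map`), `drift` (the
#'   `drift_estimate`), `voa` (the [volume_of_activation()] rows).
#' @export
analyze_session <- function(session, atlas, config = pipeline_config()) {
  scheme <- config_scheme(config)
  gm <- global_mean_series(session, atlas)
  est <- estimate_drift(gm, session$tr_seconds, limit = config$drift_limit)
  session <- correct_drift(session, est)
  session <- smooth_gaussian(session, config$fwhm_mm)
  labels <- propagate_labels(session, atlas)
  statmap <- activation_map(session, labels, scheme,
                            threshold_pct = config$threshold_pct,
                            q = config$fdr_q)
  voa <- volume_of_activation(statmap, labels, sign = "+")
  list(statmap = statmap, drift = est, voa = voa)
}

#' Analyse an in-memory cohort
#'
#' Runs the full per-subject pipeline (drift correction, smoothing,
#' voxel-wise statistics, volume of activation) on every session, then the
#' group level: composite maps, treatment-versus-control region tables, and
#' circuit time courses with the mixed ANOVA and Dunnett post-hoc tests.
#'
#' @param sessions list of [bold_session()]s in atlas space.
#' @param atlas a [atlas()].
#' @param config a [pipeline_config()].
#' @param keep_maps retain per-subject stat maps and build composite maps
#'   (disable to save memory on large screening runs).
#' @return List: `drift_log`, `voa`, `statmaps`, `composites`, `rep_counts`,
#'   `comparisons` (one table per treatment vs control), `omnibus`,
#'   `network_means`, `network_anova`, `network_dunnett`.
#' @export
analyze_cohort <- function(sessions, atlas, config = pipeline_config(),
                           keep_maps = TRUE) {
  scheme <- config_scheme(config)
  res <- lapply(sessions, analyze_session, atlas = atlas, config = config)
  drift_log <- data.frame(
    subject_id = vapply(sessions, `[[`, "", "subject_id"),
    slope_pct_per_min = vapply(res, function(r) r$drift$slope, 0.0),
    corrected = vapply(res, function(r) r$drift$corrected, NA),
    stringsAsFactors = FALSE)
  voa <- do.call(rbind, lapply(res, `[[`, "voa"))
  treatments <- unique(vapply(sessions, `[[`, "", "treatment"))

  statmaps <- composites <- NULL
  rep_counts <- NULL
  if (keep_maps) {
    statmaps <- lapply(res, `[[`, "statmap")
    names(statmaps) <- drift_log$subject_id
    composites <- list()
    rc <- list()
    for (tr in treatments) {
      maps_tr <- statmaps[vapply(statmaps, `[[`, "", "treatment") == tr]
      for (win in names(scheme$windows)) {
        cm <- composite_map(maps_tr, win, config$min_frequency)
        composites[[tr]][[win]] <- cm
        cc <- composite_region_counts(cm, atlas$labels, sign = "+")
        rc[[length(rc) + 1L]] <- data.frame(
          region_id = as.integer(names(cc)), window = win, treatment = tr,
          count = as.integer(cc), stringsAsFactors = FALSE)
      }
    }
    rep_counts <- do.call(rbind, rc)
  }

  comparisons <- list()
  control <- config$control
  if (control %in% treatments) {
    for (tr in setdiff(treatments, control)) {
      comparisons[[tr]] <- region_comparison_table(
        voa, c(control, tr), rep_counts = rep_counts, alpha = config$alpha)
    }
  }
  omnibus <- if (length(treatments) >= 2L)
    region_comparison_table(voa, treatments, rep_counts = rep_counts,
                            alpha = config$alpha) else NULL

  network_means <- network_anova <- network_dunnett <- NULL
  if (length(atlas$networks)) {
    nm_rows <- list()
    for (i in seq_along(sessions)) {
      s <- sessions[[i]]
      # re-run the subject-level preprocessing for the time courses
      est <- estimate_drift(global_mean_series(s, atlas), s$tr_seconds,
                            limit = config$drift_limit)
      s <- smooth_gaussian(correct_drift(s, est), config$fwhm_mm)
      for (net in names(atlas$networks)) {
        ts <- network_series(s, atlas$labels, atlas, net, scheme)
        nm_rows[[length(nm_rows) + 1L]] <- data.frame(
          subject = s$subject_id, group = s$treatment, network = net,
          window = names(ts$window_means),
          value = unname(ts$window_means), stringsAsFactors = FALSE)
      }
    }
    network_means <- do.call(rbind, nm_rows)
    if (length(treatments) >= 2L) {
      network_anova <- do.call(rbind, lapply(names(atlas$networks),
        function(net) {
          d <- network_means[network_means$network == net, ]
          a <- rm_anova_interaction(d)
          data.frame(network = net, F = a$F, df1 = a$df1, df2 = a$df2,
                     p = a$p, stringsAsFactors = FALSE)
        }))
      if (control %in% treatments && length(treatments) >= 2L) {
        nd <- list()
        for (net in names(atlas$networks)) {
          for (win in names(scheme$windows)) {
            d <- network_means[network_means$network == net &
                                 network_means$window == win, ]
            p <- dunnett_vs_control(d, control = control)
            nd[[length(nd) + 1L]] <- data.frame(
              network = net, window = win, treatment = names(p),
              p_adjusted = unname(p), stringsAsFactors = FALSE)
          }
        }
        network_dunnett <- do.call(rbind, nd)
      }
    }
  }

  list(drift_log = drift_log, voa = voa, statmaps = statmaps,
       composites = composites, rep_counts = rep_counts,
       comparisons = comparisons, omnibus = omnibus,
       network_means = network_means, network_anova = network_anova,
       network_dunnett = network_dunnett)
}

#' Run the full analysis from files on disk
#'
#' Loads the atlas and cohort manifest named in the configuration, analyses
#' every subject, and writes the complete result set under
#' `config$output_dir`: the per-subject drift log, volume-of-activation
#' table, composite maps (NIfTI), treatment-versus-control comparison tables,
#' network window means with ANOVA/Dunnett reports, and a machine-readable
#' run log (`run_log.yaml`) from which the exact configuration can be
#' re-created.
#'
#' @param config a [pipeline_config()] whose paths exist.
#' @param write_maps also write per-subject stat-map volumes (off by default;
#'   they dominate disk usage).
#' @return Invisibly, the [analyze_cohort()] result list.
#' @export
run_analyze <- function(config, write_maps = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  net_path <- resolve_path(config, config$network_table_path)
  atlas <- load_atlas(resolve_path(config, config$label_path),
                      resolve_path(config, config$region_table_path),
                      if (file.exists(net_path)) net_path else NULL)
  manifest_path <- resolve_path(config, config$manifest_path)
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "treatment", "path")
  if (!all(need %in% names(manifest)))
    stop("manifest needs columns ", paste(need, collapse = ","))
  sessions <- lapply(seq_len(nrow(manifest)), function(i) {
    p <- manifest$path[i]
    if (!file.exists(p))
      p <- file.path(dirname(manifest_path), basename(p))
    tryCatch(read_session(p, manifest$subject_id[i], manifest$treatment[i]),
             error = function(e) stop("subject ", manifest$subject_id[i],
                                      ": ", conditionMessage(e)))
  })

  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  res <- analyze_cohort(sessions, atlas, config)

  utils::write.csv(res$drift_log, file.path(out, "drift_log.csv"),
                   row.names = FALSE)
  utils::write.csv(res$voa, file.path(out, "volume_of_activation.csv"),
                   row.names = FALSE)
  for (tr in names(res$comparisons))
    utils::write.csv(res$comparisons[[tr]],
                     file.path(out, sprintf("comparison_%s_vs_%s.csv",
                                            tr, config$control)),
                     row.names = FALSE)
  if (!is.null(res$omnibus))
    utils::write.csv(res$omnibus, file.path(out, "comparison_omnibus.csv"),
                     row.names = FALSE)
  for (tr in names(res$composites)) {
    for (win in names(res$composites[[tr]])) {
      cm <- res$composites[[tr]][[win]]
      vol <- cm$mean_pct
      vol[!cm$retained] <- 0
      img <- RNifti::asNifti(vol)
      RNifti::pixdim(img) <- atlas$voxel_size
      RNifti::writeNifti(img, file.path(out,
        sprintf("composite_%s_%s.nii.gz", tr,
                gsub("[^0-9A-Za-z]+", "_", win))))
    }
  }
  if (write_maps && !is.null(res$statmaps))
    for (sm in res$statmaps)
      write_stat_map(sm, file.path(out, "statmaps"), atlas$voxel_size)
  if (!is.null(res$network_means)) {
    utils::write.csv(res$network_means,
                     file.path(out, "network_window_means.csv"),
                     row.names = FALSE)
    utils::write.csv(res$network_anova,
                     file.path(out, "network_anova.csv"), row.names = FALSE)
    if (!is.null(res$network_dunnett))
      utils::write.csv(res$network_dunnett,
                       file.path(out, "network_dunnett.csv"),
                       row.names = FALSE)
  }

  cfg_yaml <- yaml::as.yaml(unclass(config))
  yaml::write_yaml(list(
    config = unclass(config),
    config_checksum = sum(utf8ToInt(cfg_yaml)),
    n_subjects = nrow(manifest),
    n_regions = nrow(atlas$regions),
    n_brain_voxels = sum(atlas$labels > 0L),
    n_corrected = sum(res$drift_log$corrected)),
    file.path(out, "run_log.yaml"))
  invisible(res)
}

#' Significant-region listings from an analysis output directory
#'
#' Reads the comparison tables written by [run_analyze()] and returns, per
#' treatment and window, the significant rows sorted by p-value — the
#' machine twin of a published volume-of-activation table.
#'
#' @param config a [pipeline_config()] pointing at an analysed output dir.
#' @param alpha significance level (defaults to `config$alpha`).
#' @return Named list (treatment) of named lists (window) of data.frames.
#' @export
run_tables <- function(config, alpha = config$alpha) {
  out <- config$output_dir
  files <- list.files(out, pattern = "^comparison_.*_vs_.*\\.csv$",
                      full.names = TRUE)
  if (!length(files)) stop("no comparison tables under ", out)
  res <- list()
  for (f in files) {
    tr <- sub(sprintf("_vs_%s\\.csv$", config$control), "",
              sub("^comparison_", "", basename(f)))
    rows <- utils::read.csv(f, stringsAsFactors = FALSE, check.names = FALSE)
    res[[tr]] <- lapply(stats::setNames(nm = unique(rows$window)),
                        function(w) significant_region_table(rows, w, alpha))
  }
  res
}

#' Acquisition geometry summaries
#'
#' Scan duration and in-plane pixel size implied by an acquisition protocol:
#' `n_acquisitions * tr_seconds / 60` minutes, and `fov_cm * 1e4 /
#' matrix_size` micrometres (integer part, matching how pixel sizes are
#' conventionally quoted).
#'
#' @param n_acquisitions volumes per session.
#' @param tr_seconds repetition time, seconds.
#' @param fov_cm in-plane field of view, cm.
#' @param matrix_size in-plane acquisition matrix width.
#' @return List: `duration_min`, `pixel_um`.
#' @export
acquisition_geometry <- function(n_acquisitions = 500L, tr_seconds = 6.0,
                                 fov_cm = 3.0, matrix_size = 96L) {
  list(duration_min = n_acquisitions * tr_seconds / 60,
       pixel_um = floor(fov_cm * 1e4 / matrix_size))
}
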