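#' Drug-response specification for the synthetic cohort generator
#'
#' One row per (treatment, region): a ramp-to-plateau percent-BOLD response
#' superposed on the baseline signal of every voxel in that region. The ramp
#' is piecewise linear: zero before `onset_acquisition`, rising linearly over
#' `ramp_duration` acquisitions, then constant at `plateau_amplitude` (% of
#' baseline; negative allowed for negative BOLD). Treatments without rows
#' (e.g. vehicle) produce no response.
#'
#' @param treatment character vector of treatment labels.
#' @param region_id integer vector of responding region ids.
#' @param onset_acquisition 1-based acquisition at which the response starts;
#'   must be after the 50-acquisition baseline (i.e. >= 51 with defaults).
#' @param ramp_duration acquisitions from onset to plateau; 0 = step.
#' @param plateau_amplitude plateau height, % of baseline signal.
#' @param n_baseline baseline length used to validate the onset (default 50).
#' @return data.frame of class `response_spec`.
#' @export
response_spec <- function(treatment = character(0),
                          region_id = integer(0),
                          onset_acquisition = integer(0),
                          ramp_duration = integer(0),
                          plateau_amplitude = numeric(0),
                          n_baseline = 50L) {
  df <- data.frame(treatment = as.character(treatment),
                   region_id = as.integer(region_id),
                   onset_acquisition = as.integer(onset_acquisition),
                   ramp_duration = as.integer(ramp_duration),
                   plateau_amplitude = as.numeric(plateau_amplitude),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$onset_acquisition <= n_baseline))
      stop("onset_acquisition must fall after the baseline (acquisition ",
           n_baseline, ")")
    if (any(df$ramp_duration < 0L))
      stop("ramp_duration must be >= 0")
    if (any(!is.finite(df$plateau_amplitude)))
      stop("plateau_amplitude must be finite")
  }
  class(df) <- c("response_spec", "data.frame")
  df
}

#' Acquisition and noise configuration for synthetic sessions
#'
#' Defaults follow the study conditions this simulator emulates: 500
#' acquisitions at TR 6.0 s (50 min total, 50 baseline volumes in the first
#' 5 min), in-plane pixel size 0.3125 mm with 1.0 mm slices, on a reduced
#' 24 x 24 x 12 grid for desk-scale work. `full_scale = TRUE` switches to
#' the full 96 x 96 x 22 acquisition matrix.
#'
#' @param shape integer length-3 grid shape (x, y, z).
#' @param voxel_size voxel edge lengths, mm.
#' @param n_acquisitions number of volumes (>= 60).
#' @param tr_seconds repetition time, seconds.
#' @param baseline_level constant pre-drug signal level, arbitrary units.
#' @param noise_sd voxel-wise Gaussian noise SD, % of baseline.
#' @param drift_slope global linear drift, % of baseline per minute.
#' @param n_baseline number of baseline acquisitions before treatment.
#' @param full_scale use the full acquisition grid (96 x 96 x 22).
#' @return list of class `session_config`.
#' @export
session_config <- function(shape = c(24L, 24L, 12L),
                           voxel_size = c(0.3125, 0.3125, 1.0),
                           n_acquisitions = 500L,
                           tr_seconds = 6.0,
                           baseline_level = 1000,
                           noise_sd = 1.0,
                           drift_slope = 0.02,
                           n_baseline = 50L,
                           full_scale = FALSE) {
  if (isTRUE(full_scale)) shape <- c(96L, 96L, 22L)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("shape must be three positive integers")
  if (n_acquisitions < 60L)
    stop("n_acquisitions must be >= 60")
  if (tr_seconds <= 0) stop("tr_seconds must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_baseline < 2L || n_baseline >= n_acquisitions)
    stop("n_baseline must be in [2, n_acquisitions)")
  structure(list(shape = shape, voxel_size = as.numeric(voxel_size),
                 n_acquisitions = as.integer(n_acquisitions),
                 tr_seconds = as.numeric(tr_seconds),
                 baseline_level = as.numeric(baseline_level),
                 noise_sd = as.numeric(noise_sd),
                 drift_slope = as.numeric(drift_slope),
                 n_baseline = as.integer(n_baseline)),
            class = "session_config")
}

#' Generate a synthetic block-packed label atlas
#'
#' Regions are axis-aligned blocks placed on a cell grid with a background
#' margin around every block (2 voxels in-plane, 1 through-plane), so that
#' spatial smoothing at the default 0.8 mm FWHM cannot carry one region's
#' response into another. Which cell hosts which region id is a seeded
#' permutation, so layouts differ by seed but are reproducible.
#'
#' @param shape grid shape (x, y, z).
#' @param n_regions number of regions to place (>= 1).
#' @param seed integer seed.
#' @param voxel_size voxel edge lengths, mm.
#' @param margin background margin per axis inside each cell.
#' @return A [atlas()] with regions ids 1..n_regions, named "region_<id>".
#' @export
generate_atlas <- function(shape, n_regions, seed,
                           voxel_size = c(0.3125, 0.3125, 1.0),
                           margin = c(2L, 2L, 1L)) {
  shape <- as.integer(shape)
  n_regions <- as.integer(n_regions)
  if (n_regions < 1L) stop("n_regions must be >= 1")

  # grow the cell grid one axis at a time, splitting the axis whose cells
  # are currently largest, until there are enough cells
  cells <- c(1L, 1L, 1L)
  while (prod(cells) < n_regions) {
    ext <- shape / cells
    ax <- which.max(ext)
    cells[ax] <- cells[ax] + 1L
  }
  cell_size <- shape %/% cells
  block <- cell_size - 2L * as.integer(margin)
  if (any(block < 1L))
    stop("infeasible packing: grid ", paste(shape, collapse = "x"),
         " cannot host ", n_regions, " regions with the required margins")

  labels <- array(0L, shape)
  cell_index <- expand.grid(cx = seq_len(cells[1]), cy = seq_len(cells[2]),
                            cz = seq_len(cells[3]))
  rng <- local_rng(seed)
  on.exit(rng())
  chosen <- cell_index[sample.int(nrow(cell_index), n_regions), , drop = FALSE]
  for (k in seq_len(n_regions)) {
    start <- (as.integer(chosen[k, ]) - 1L) * cell_size + as.integer(margin) + 1L
    labels[start[1]:(start[1] + block[1] - 1L),
           start[2]:(start[2] + block[2] - 1L),
           start[3]:(start[3] + block[3] - 1L)] <- k
  }
  atlas(labels, voxel_size,
        data.frame(region_id = seq_len(n_regions),
                   region_name = paste0("region_", seq_len(n_regions))))
}

#' Simulate one 4D BOLD session
#'
#' Signal model for a brain voxel in region r:
#' `v(t) = baseline_level * (1 + drift(t)/100 + response_r(t)/100 + e(t)/100)`
#' with `drift(t) = drift_slope * minutes(t)`, `response_r` the ramp-to-
#' plateau kernel from the [response_spec()], and `e(t)` iid Gaussian with
#' SD `noise_sd` (%). Background voxels are exactly zero (non-brain).
#'
#' @param atlas a [atlas()]; sessions are generated in atlas space.
#' @param spec a [response_spec()].
#' @param cfg a [session_config()]; its shape must match the atlas grid.
#' @param treatment treatment label; selects the matching spec rows.
#' @param subject_id subject label for the session.
#' @param seed integer seed for the noise draw.
#' @return A [bold_session()].
#' @export
generate_session <- function(atlas, spec, cfg, treatment,
                             subject_id = "subject", seed = 1L) {
  stopifnot(inherits(atlas, "phmri_atlas"), inherits(cfg, "session_config"))
  if (!identical(dim(atlas$labels), as.integer(cfg$shape)))
    stop("cfg shape does not match the atlas grid")
  rows <- spec[spec$treatment == treatment, , drop = FALSE]
  if (nrow(rows)) {
    bad <- setdiff(rows$region_id, atlas$regions$region_id)
    if (length(bad))
      stop("response spec references missing region(s): ",
           paste(bad, collapse = ", "))
  }

  nt <- cfg$n_acquisitions
  nvox <- prod(cfg$shape)
  minutes <- acq_minutes(seq_len(nt), cfg$tr_seconds)
  drift_pct <- cfg$drift_slope * minutes

  lab <- as.vector(atlas$labels)
  brain <- which(lab > 0L)

  # fractional signal, brain voxels x acquisitions
  frac <- matrix(rep(1 + drift_pct / 100, each = length(brain)),
                 nrow = length(brain))
  if (nrow(rows)) {
    t_idx <- seq_len(nt)
    for (k in seq_len(nrow(rows))) {
      prof <- ramp_profile(t_idx, rows$onset_acquisition[k],
                           rows$ramp_duration[k], rows$plateau_amplitude[k])
      vox <- which(lab[brain] == rows$region_id[k])
      if (length(vox))
        frac[vox, ] <- frac[vox, ] + rep(prof / 100, each = length(vox))
    }
  }
  if (cfg$noise_sd > 0) {
    rng <- local_rng(seed)
    on.exit(rng())
    frac <- frac + matrix(stats::rnorm(length(brain) * nt,
                                       sd = cfg$noise_sd / 100),
                          nrow = length(brain))
  }

  dat <- matrix(0, nrow = nvox, ncol = nt)
  dat[brain, ] <- cfg$baseline_level * frac
  bold_session(array(dat, c(cfg$shape, nt)), cfg$tr_seconds,
               cfg$voxel_size, subject_id, treatment)
}

# piecewise-linear ramp-to-plateau response kernel (percent units)
ramp_profile <- function(t_idx, onset, ramp, amplitude) {
  frac <- numeric(length(t_idx))
  post <- t_idx >= onset
  if (ramp <= 0L) {
    frac[post] <- 1
  } else {
    frac[post] <- pmin(1, (t_idx[post] - onset) / ramp)
  }
  amplitude * frac
}

#' Simulate a cohort of sessions
#'
#' Per-subject seeds are drawn once from the master seed, so the cohort is
#' bit-reproducible and any session can be regenerated in isolation.
#'
#' @param atlas,spec,cfg as in [generate_session()].
#' @param group_sizes named integer vector, treatment -> number of subjects.
#'   Defaults to the study design this simulator emulates: vehicle 9,
#'   idalopirdine 10, donepezil 8, combination 9.
#' @param seed master integer seed.
#' @return List of [bold_session()] objects, with an attribute `manifest`
#'   (data.frame: subject_id, treatment, seed).
#' @export
generate_cohort <- function(atlas, spec, cfg,
                            group_sizes = c(vehicle = 9L, idalopirdine = 10L,
                                            donepezil = 8L, combination = 9L),
                            seed = 1L) {
  stopifnot(length(group_sizes) >= 1L, !is.null(names(group_sizes)))
  treatments <- rep(names(group_sizes), times = group_sizes)
  n <- length(treatments)
  rng <- local_rng(seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n)
  rng()

  ids <- sprintf("%s_%02d", treatments,
                 unlist(lapply(group_sizes, seq_len), use.names = FALSE))
  sessions <- vector("list", n)
  for (i in seq_len(n)) {
    sessions[[i]] <- generate_session(atlas, spec, cfg, treatments[i],
                                      subject_id = ids[i],
                                      seed = subject_seeds[i])
  }
  attr(sessions, "manifest") <- data.frame(
    subject_id = ids, treatment = treatments, seed = subject_seeds,
    stringsAsFactors = FALSE)
  sessions
}

#' Write a cohort to disk with its manifest
#'
#' @param sessions list returned by [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest data.frame (with a `path` column) that was
#'   written to `manifest.csv` in `dir`.
#' @export
write_cohort <- function(sessions, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- attr(sessions, "manifest")
  if (is.null(manifest))
    manifest <- data.frame(
      subject_id = vapply(sessions, `[[`, "", "subject_id"),
      treatment = vapply(sessions, `[[`, "", "treatment"),
      seed = NA_integer_, stringsAsFactors = FALSE)
  manifest$path <- file.path(dir, paste0(manifest$subject_id, ".nii.gz"))
  for (i in seq_along(sessions))
    write_session(sessions[[i]], manifest$path[i])
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

# run code under a private RNG stream; returns a restorer to call on exit
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
    invisible(NULL)
  }
}
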