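#' Baseline / analysis-window scheme
#'
#' Acquisition indices are 1-based. The baseline is a closed range (default
#' acquisitions 1-50, the 5 pre-treatment minutes at TR 6 s). Analysis
#' windows are half-open `[start, end)` so that the conventional shared
#' endpoints (150-250, 250-350, 350-450 — minutes 15-25, 25-35, 35-45) are
#' pairwise disjoint, each spanning exactly 100 acquisitions.
#'
#' @param baseline closed 1-based range `c(first, last)`.
#' @param windows named list of half-open ranges `c(start, end)`.
#' @return Object of class `window_scheme`.
#' @export
window_scheme <- function(baseline = c(1L, 50L),
                          windows = list("15-25" = c(150L, 250L),
                                         "25-35" = c(250L, 350L),
                                         "35-45" = c(350L, 450L))) {
  baseline <- as.integer(baseline)
  if (length(baseline) != 2L || baseline[1] < 1L || baseline[2] < baseline[1])
    stop("baseline must be a non-empty 1-based range c(first, last)")
  if (!length(windows) || is.null(names(windows)))
    stop("windows must be a non-empty named list")
  windows <- lapply(windows, as.integer)
  for (nm in names(windows)) {
    w <- windows[[nm]]
    if (length(w) != 2L || w[2] <= w[1])
      stop("window '", nm, "' must be a non-empty half-open range")
    if (w[1] <= baseline[2])
      stop("window '", nm, "' must start after the baseline")
  }
  ord <- order(vapply(windows, `[`, 0L, 1L))
  ws <- windows[ord]
  starts <- vapply(ws, `[`, 0L, 1L); ends <- vapply(ws, `[`, 0L, 2L)
  if (any(starts[-1] < ends[-length(ws)]))
    stop("windows must be pairwise disjoint")
  structure(list(baseline = baseline, windows = windows),
            class = "window_scheme")
}

# acquisition index vectors for a scheme
baseline_acqs <- function(scheme) scheme$baseline[1]:scheme$baseline[2]
window_acqs <- function(scheme, window) {
  w <- scheme$windows[[window]]
  if (is.null(w)) stop("unknown window '", window, "'")
  w[1]:(w[2] - 1L)
}

#' Percent BOLD change of one voxel series
#'
#' `100 * (mean(window) - mean(baseline)) / mean(baseline)`. Voxels whose
#' baseline mean is zero have no defined percent change; [activation_map()]
#' excludes them from the testable family.
#'
#' @param voxel_series numeric vector over acquisitions.
#' @param scheme a [window_scheme()].
#' @param window window name.
#' @return Signed percent change (scalar).
#' @export
percent_change <- function(voxel_series, scheme, window) {
  b <- mean(voxel_series[baseline_acqs(scheme)])
  if (b == 0) stop("zero baseline mean: percent change undefined")
  w <- mean(voxel_series[window_acqs(scheme, window)])
  100 * (w - b) / b
}

#' Welch two-sample t-test (heteroscedastic, two-tailed)
#'
#' The statistic is `(mean(window) - mean(baseline)) / se` with the unequal-
#' variance standard error and Welch-Satterthwaite degrees of freedom; the
#' p-value is two-tailed. Degenerate inputs follow the conventions needed for
#' voxel maps: both variances zero with equal means gives t = 0, p = 1; both
#' variances zero with different means gives p = 0 (flagged `degenerate`).
#'
#' @param baseline_samples,window_samples numeric vectors, length >= 2 each.
#' @return List: `statistic`, `df`, `p.value`, `degenerate`.
#' @export
welch_t <- function(baseline_samples, window_samples) {
  if (length(baseline_samples) < 2L || length(window_samples) < 2L)
    stop("each sample needs at least 2 values")
  r <- welch_rows(matrix(baseline_samples, nrow = 1),
                  matrix(window_samples, nrow = 1))
  list(statistic = r$t[1], df = r$df[1], p.value = r$p[1],
       degenerate = r$degenerate[1])
}

# vectorized Welch test over rows (voxels): B and W are voxel x acquisition
welch_rows <- function(B, W) {
  nb <- ncol(B); nw <- ncol(W)
  mb <- rowMeans(B); mw <- rowMeans(W)
  vb <- rowSums((B - mb)^2) / (nb - 1)
  vw <- rowSums((W - mw)^2) / (nw - 1)
  se2 <- vb / nb + vw / nw
  t <- (mw - mb) / sqrt(se2)
  df <- se2^2 / ((vb / nb)^2 / (nb - 1) + (vw / nw)^2 / (nw - 1))
  p <- 2 * stats::pt(-abs(t), df)
  zero_var <- se2 == 0
  degenerate <- zero_var & (mw != mb)
  if (any(zero_var)) {
    eq <- zero_var & (mw == mb)
    t[eq] <- 0; p[eq] <- 1; df[eq] <- nb + nw - 2
    t[degenerate] <- Inf * sign((mw - mb)[degenerate])
    p[degenerate] <- 0; df[degenerate] <- nb + nw - 2
  }
  list(t = t, df = df, p = p, degenerate = degenerate)
}

#' Benjamini-Hochberg FDR adjustment with rejection mask
#'
#' Step-up procedure over one family of p-values (one subject's brain voxels,
#' one window). Rejection at level `q` is equivalent to `p_adj <= q`.
#'
#' @param p_values numeric vector of raw p-values in [0, 1] (NA allowed for
#'   untestable entries; they stay NA and are never rejected).
#' @param q target false discovery rate (default 0.05).
#' @return List: `p_adj` (monotone adjusted p per entry), `reject` (logical).
#' @export
fdr_adjust <- function(p_values, q = 0.05) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]")
  p_adj <- stats::p.adjust(p_values, method = "BH")
  reject <- !is.na(p_adj) & p_adj <= q
  list(p_adj = p_adj, reject = reject)
}

#' Per-voxel activation map for one subject
#'
#' For every brain voxel (label > 0) and every analysis window: percent BOLD
#' change versus baseline, Welch t-test of the baseline acquisitions against
#' the window acquisitions, BH-FDR adjustment across the subject's brain
#' voxels (one family per window), and the activation flag
#' `p_adj <= q & |pct_change| >= threshold_pct`. The amplitude threshold
#' (default 2% BOLD) absorbs normal signal fluctuation in the awake brain and
#' gates activation independently of the test. Voxels with zero baseline mean
#' are excluded from the FDR family and never activated.
#'
#' @param session a preprocessed [bold_session()] in atlas space.
#' @param labels 3D region-id grid aligned to the session (see
#'   [propagate_labels()]).
#' @param scheme a [window_scheme()].
#' @param threshold_pct minimum |percent change| for activation (default 2).
#' @param q FDR level (default 0.05).
#' @return Object of class `voxel_stat_map`: per-window 3D arrays
#'   `pct_change`, `t`, `p_raw`, `p_adj`, `activated`, `sign` (NA outside the
#'   brain mask), plus the mask and the parameters used.
#' @export
activation_map <- function(session, labels, scheme = window_scheme(),
                           threshold_pct = 2.0, q = 0.05) {
  stopifnot(inherits(session, "bold_session"))
  d <- dim(session$data)
  if (!identical(d[1:3], dim(labels)))
    stop("labels grid does not match session grid")
  if (max(vapply(scheme$windows, `[`, 0L, 2L)) - 1L > d[4])
    stop("scheme windows exceed the session's acquisitions")
  if (threshold_pct < 0) stop("threshold_pct must be >= 0")

  brain <- which(as.vector(labels) > 0L)
  m <- matrix(session$data, ncol = d[4])
  B <- m[brain, baseline_acqs(scheme), drop = FALSE]
  mb <- rowMeans(B)
  testable <- mb != 0

  empty <- function() array(NA_real_, d[1:3])
  out <- list()
  for (nm in names(scheme$windows)) {
    W <- m[brain, window_acqs(scheme, nm), drop = FALSE]
    pct <- rep(NA_real_, length(brain))
    pct[testable] <- 100 * (rowMeans(W)[testable] - mb[testable]) / mb[testable]
    wt <- welch_rows(B[testable, , drop = FALSE], W[testable, , drop = FALSE])
    p_raw <- t_stat <- rep(NA_real_, length(brain))
    t_stat[testable] <- wt$t
    p_raw[testable] <- wt$p
    adj <- fdr_adjust(p_raw, q)
    activated <- adj$reject & !is.na(pct) & abs(pct) >= threshold_pct
    arrs <- list(pct_change = empty(), t = empty(), p_raw = empty(),
                 p_adj = empty(), activated = array(NA, d[1:3]),
                 sign = empty())
    arrs$pct_change[brain] <- pct
    arrs$t[brain] <- t_stat
    arrs$p_raw[brain] <- p_raw
    arrs$p_adj[brain] <- adj$p_adj
    arrs$activated[brain] <- activated
    arrs$sign[brain] <- sign(pct)
    out[[nm]] <- arrs
  }
  mask <- array(FALSE, d[1:3]); mask[brain] <- TRUE
  structure(list(windows = out, mask = mask, scheme = scheme,
                 threshold_pct = threshold_pct, q = q,
                 subject_id = session$subject_id,
                 treatment = session$treatment),
            class = "voxel_stat_map")
}

#' @export
print.voxel_stat_map <- function(x, ...) {
  counts <- vapply(x$windows, function(w) sum(w$activated, na.rm = TRUE), 0L)
  cat(sprintf("voxel stat map '%s' (%s): %d brain voxels\n", x$subject_id,
              x$treatment, sum(x$mask)))
  for (nm in names(counts))
    cat(sprintf("  %s: %d activated voxels\n", nm, counts[nm]))
  invisible(x)
}

#' Write a stat map's volumes as NIfTI files
#'
#' One file per window per quantity (`pct_change`, `t`, `p_adj`, and the 0/1
#' `activated` mask), named `<subject>_<window>_<quantity>.nii.gz`.
#'
#' @param statmap a `voxel_stat_map`.
#' @param dir output directory.
#' @param voxel_size voxel edge lengths for the headers, mm.
#' @return Invisibly, the written paths.
#' @export
write_stat_map <- function(statmap, dir, voxel_size = c(1, 1, 1)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(statmap$windows)) {
    w <- statmap$windows[[nm]]
    vols <- list(pct_change = w$pct_change, t = w$t, p_adj = w$p_adj,
                 activated = array(as.numeric(w$activated %in% TRUE),
                                   dim(w$pct_change)))
    for (q in names(vols)) {
      p <- file.path(dir, sprintf("%s_%s_%s.nii.gz", statmap$subject_id,
                                  gsub("[^0-9A-Za-z]+", "_", nm), q))
      img <- RNifti::asNifti(vols[[q]])
      RNifti::pixdim(img) <- voxel_size
      RNifti::writeNifti(img, p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
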