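#' Circuit-level BOLD time course for one subject
#'
#' At each post-treatment acquisition the value is the mean, over all voxels
#' belonging to the network's regions, of the voxel-wise percent change
#' `100 * (v(t) - baseline_mean) / baseline_mean`. The series covers every
#' acquisition after the baseline (450 values under the default scheme);
#' window means are arithmetic means of the series over each analysis
#' window's acquisitions.
#'
#' @param session a preprocessed [bold_session()] in atlas space.
#' @param labels 3D region-id grid aligned to the session.
#' @param atlas a [atlas()] whose `networks` defines the circuit.
#' @param network network name.
#' @param scheme a [window_scheme()].
#' @return Object of class `network_timecourse`: `subject_id`, `treatment`,
#'   `network`, `acquisition` (1-based indices covered), `series` (% BOLD),
#'   `window_means` (named).
#' @export
network_series <- function(session, labels, atlas, network,
                           scheme = window_scheme()) {
  stopifnot(inherits(session, "bold_session"), inherits(atlas, "phmri_atlas"))
  ids <- atlas$networks[[network]]
  if (is.null(ids)) stop("network '", network, "' not defined in the atlas")
  lab <- as.vector(labels)
  vox <- which(lab %in% ids)
  if (!length(vox)) stop("network '", network, "' has no voxels on this grid")

  nt <- n_acquisitions(session)
  m <- matrix(session$data, ncol = nt)[vox, , drop = FALSE]
  b <- rowMeans(m[, baseline_acqs(scheme), drop = FALSE])
  ok <- b != 0                      # zero-baseline voxels are untestable
  if (!any(ok)) stop("all network voxels have zero baseline mean")
  pc <- 100 * sweep(m[ok, , drop = FALSE], 1L, b[ok], "/") - 100

  acqs <- (scheme$baseline[2] + 1L):nt
  series <- colMeans(pc)[acqs]
  wm <- vapply(names(scheme$windows), function(nm)
    mean(series[match(window_acqs(scheme, nm), acqs)]), 0.0)
  structure(list(subject_id = session$subject_id,
                 treatment = session$treatment, network = network,
                 acquisition = acqs, series = unname(series),
                 window_means = wm),
            class = "network_timecourse")
}

#' @export
print.network_timecourse <- function(x, ...) {
  cat(sprintf("network '%s', subject '%s' (%s): %d acquisitions\n",
              x$network, x$subject_id, x$treatment, length(x$series)))
  print(round(x$window_means, 4))
  invisible(x)
}

#' Mixed-design repeated-measures ANOVA: group x window interaction
#'
#' Two-way mixed ANOVA with treatment group as the between-subject factor and
#' analysis window as the within-subject factor, on per-subject window means.
#' Returns the group-by-window interaction test. No sphericity correction is
#' applied by default (with three windows the classical F is used);
#' Greenhouse-Geisser style corrections can be layered on by the user.
#'
#' @param window_means data.frame with columns `subject`, `group`, `window`,
#'   `value`; every subject must have every window exactly once.
#' @return List: `F`, `df1`, `df2`, `p`.
#' @export
rm_anova_interaction <- function(window_means) {
  need <- c("subject", "group", "window", "value")
  stopifnot(all(need %in% names(window_means)))
  d <- window_means
  d$subject <- factor(d$subject); d$group <- factor(d$group)
  d$window <- factor(d$window)
  if (nlevels(d$group) < 2L || nlevels(d$window) < 2L)
    stop("need at least 2 groups and 2 windows")
  tab <- table(d$subject, d$window)
  if (any(tab != 1L))
    stop("unbalanced design: every subject needs every window exactly once")
  df1 <- (nlevels(d$group) - 1L) * (nlevels(d$window) - 1L)
  df2 <- (nlevels(d$subject) - nlevels(d$group)) * (nlevels(d$window) - 1L)
  if (stats::var(d$value) == 0)          # no variance anywhere: F = 0
    return(list(F = 0, df1 = df1, df2 = df2, p = 1))
  fit <- stats::aov(value ~ group * window + Error(subject), data = d)
  within <- summary(fit)[["Error: Within"]][[1]]
  row <- grep("group:window", rownames(within))
  res <- grep("Residuals", rownames(within))
  list(F = within[row, "F value"], df1 = within[row, "Df"],
       df2 = within[res, "Df"], p = within[row, "Pr(>F)"])
}

#' Dunnett many-to-one comparisons against a control group
#'
#' Compares each treatment to the designated control on one window's
#' per-subject means, with multiplicity-adjusted two-sided p-values from the
#' multivariate-t distribution of the contrasts (the standard Dunnett
#' procedure; the equal-correlation structure arises automatically under
#' balancedness). The quasi-random integration behind the adjusted p-values
#' runs under a fixed internal seed so results are reproducible; the caller's
#' RNG state is left untouched.
#'
#' @param data data.frame with columns `group` and `value` (one row per
#'   subject).
#' @param control control group label (default "vehicle").
#' @return Named numeric vector of adjusted p-values, one per treatment.
#' @export
dunnett_vs_control <- function(data, control = "vehicle") {
  stopifnot(all(c("group", "value") %in% names(data)))
  groups <- unique(as.character(data$group))
  if (!control %in% groups) stop("control group '", control, "' missing")
  if (length(groups) < 2L) stop("need at least one treatment group")
  d <- data.frame(group = factor(as.character(data$group),
                                 levels = c(control,
                                            setdiff(groups, control))),
                  value = as.numeric(data$value))
  rng <- local_rng(20090427L)
  on.exit(rng())
  fit <- stats::lm(value ~ group, data = d)
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
  sm <- summary(gl)
  p <- as.numeric(sm$test$pvalues)
  names(p) <- setdiff(levels(d$group), control)
  p
}
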