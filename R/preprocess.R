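#' Whole-brain mean intensity series
#'
#' Average intensity over brain voxels (atlas label > 0) at each acquisition;
#' this is the series from which the global drift is estimated.
#'
#' @param session a [bold_session()] in atlas space.
#' @param atlas a [atlas()] on the same grid.
#' @return Numeric vector, one value per acquisition.
#' @export
global_mean_series <- function(session, atlas) {
  stopifnot(inherits(session, "bold_session"), inherits(atlas, "phmri_atlas"))
  if (!identical(dim(session$data)[1:3], dim(atlas$labels)))
    stop("session grid does not match atlas grid")
  brain <- which(as.vector(atlas$labels) > 0L)
  if (!length(brain)) stop("empty brain mask")
  nt <- n_acquisitions(session)
  m <- matrix(session$data, ncol = nt)
  colMeans(m[brain, , drop = FALSE])
}

#' Estimate global linear drift
#'
#' Ordinary least-squares line of the whole-brain mean series against time in
#' minutes (acquisition k at (k-1)*TR/60). The slope is expressed as percent
#' of the fitted intercept per minute; the session is flagged for correction
#' only when |slope| exceeds the predefined limit (default 0.015 %/min).
#'
#' @param series whole-brain mean series, from [global_mean_series()].
#' @param tr_seconds repetition time, seconds.
#' @param limit correction threshold, % signal per minute (> 0).
#' @return List of class `drift_estimate`: `slope` (%/min), `intercept`
#'   (signal units at t = 0), `corrected` (flag), `limit`.
#' @export
estimate_drift <- function(series, tr_seconds, limit = 0.015) {
  if (length(series) < 2L) stop("series must have at least 2 acquisitions")
  if (limit <= 0) stop("limit must be positive")
  minutes <- acq_minutes(seq_along(series), tr_seconds)
  if (stats::sd(minutes) == 0) stop("zero-variance time axis")
  fit <- stats::lm.fit(cbind(1, minutes), as.numeric(series))
  intercept <- fit$coefficients[[1]]
  slope_units <- fit$coefficients[[2]]
  if (intercept == 0) stop("fitted intercept is zero; %/min slope undefined")
  slope <- 100 * slope_units / intercept
  structure(list(slope = slope, intercept = intercept,
                 corrected = abs(slope) > limit, limit = limit),
            class = "drift_estimate")
}

#' @export
print.drift_estimate <- function(x, ...) {
  cat(sprintf("drift: %.5f %%/min (limit %.3f) -> %s\n", x$slope, x$limit,
              if (x$corrected) "corrected" else "left uncorrected"))
  invisible(x)
}

#' Remove the global linear drift from a session
#'
#' Division by the fitted fractional trend, `v'(x,t) = v(x,t) /
#' (1 + slope * minutes(t) / 100)`, applied identically to every voxel.
#' Multiplicative removal preserves percent-change of superposed responses
#' exactly, which is the unit all downstream statistics work in. Sessions
#' whose estimate is below the limit are returned untouched.
#'
#' @param session a [bold_session()].
#' @param est a `drift_estimate` from this session's global mean series.
#' @return A [bold_session()].
#' @export
correct_drift <- function(session, est) {
  stopifnot(inherits(session, "bold_session"), inherits(est, "drift_estimate"))
  if (!est$corrected) return(session)
  nt <- n_acquisitions(session)
  minutes <- acq_minutes(seq_len(nt), session$tr_seconds)
  trend <- 1 + est$slope * minutes / 100
  if (any(trend <= 0))
    stop("fitted trend crosses zero; drift correction undefined")
  d <- dim(session$data)
  m <- matrix(session$data, ncol = nt)
  m <- sweep(m, 2L, trend, "/")
  session$data <- array(m, d)
  session
}

#' Gaussian spatial smoothing
#'
#' Volume-wise separable 3D Gaussian convolution applied to every
#' acquisition, with sigma = FWHM / (2 sqrt(2 ln 2)) converted to voxel units
#' per axis and a symmetric (reflective) boundary, so constants — and
#' percent-change of spatially constant responses — are preserved exactly.
#' `fwhm_mm = 0` is the identity.
#'
#' @param session a [bold_session()].
#' @param fwhm_mm kernel full width at half maximum, mm (default 0.8).
#' @return The smoothed [bold_session()].
#' @export
smooth_gaussian <- function(session, fwhm_mm = 0.8) {
  stopifnot(inherits(session, "bold_session"))
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  if (fwhm_mm == 0) return(session)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / session$voxel_size
  kernels <- lapply(sigma_vox, gaussian_kernel)
  d <- dim(session$data)
  session$data <- smooth_separable4d(as.vector(session$data),
                                     as.integer(d), kernels)
  session
}

# normalized discrete Gaussian, radius ceil(3 sigma); length-1 kernel = skip
gaussian_kernel <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, as.integer(ceiling(3 * sigma_vox)))
  w <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  w / sum(w)
}
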