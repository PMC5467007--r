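#' 9-parameter affine transform (translation, rotation, scale)
#'
#' Rotations are in degrees and are applied in the fixed order x, then y,
#' then z (right-handed), about the volume centre; scaling is applied before
#' rotation, translation last. Transform estimation is out of scope — the
#' transform that maps a subject into atlas space is an input, typically
#' produced interactively and saved as a CSV (see [read_transform()]).
#'
#' @param translation length-3, mm.
#' @param rotation length-3 angles about x, y, z, degrees.
#' @param scale length-3 positive factors.
#' @return Object of class `affine_transform`.
#' @export
affine_transform <- function(translation = c(0, 0, 0),
                             rotation = c(0, 0, 0),
                             scale = c(1, 1, 1)) {
  translation <- as.numeric(translation); rotation <- as.numeric(rotation)
  scale <- as.numeric(scale)
  if (length(translation) != 3 || length(rotation) != 3 || length(scale) != 3)
    stop("translation, rotation and scale must each have length 3")
  if (any(scale <= 0)) stop("scale factors must be positive")
  structure(list(translation = translation, rotation = rotation,
                 scale = scale),
            class = "affine_transform")
}

#' Read a transform from CSV (`tx,ty,tz,rx,ry,rz,sx,sy,sz`)
#'
#' @param path CSV file with one data row in mm / degrees / unitless.
#' @return An [affine_transform()].
#' @export
read_transform <- function(path) {
  df <- utils::read.csv(path)
  need <- c("tx", "ty", "tz", "rx", "ry", "rz", "sx", "sy", "sz")
  if (!all(need %in% names(df)))
    stop("transform file must have columns ", paste(need, collapse = ","))
  affine_transform(unlist(df[1, c("tx", "ty", "tz")]),
                   unlist(df[1, c("rx", "ry", "rz")]),
                   unlist(df[1, c("sx", "sy", "sz")]))
}

#' Homogeneous 4x4 matrix of a transform (mm coordinates)
#'
#' @param xf an [affine_transform()].
#' @return 4x4 matrix mapping source mm coordinates to target mm coordinates.
#' @export
affine_matrix <- function(xf) {
  stopifnot(inherits(xf, "affine_transform"))
  th <- xf$rotation * pi / 180
  rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0),
              c(-sin(th[2]), 0, cos(th[2])))
  rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
              c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  a <- rz %*% ry %*% rx %*% diag(xf$scale)
  m <- diag(4)
  m[1:3, 1:3] <- a
  m[1:3, 4] <- xf$translation
  m
}

#' Resample a session through an affine transform
#'
#' Each acquisition is resampled onto the same grid by pulling values through
#' the inverse transform, with the rotation/scale applied about the volume
#' centre. Nearest-neighbour interpolation is the default (it preserves
#' intensities exactly); trilinear is available for functional data where
#' sub-voxel blending is preferred. Voxels mapping outside the source volume
#' become 0 (background).
#'
#' @param session a [bold_session()].
#' @param xf an [affine_transform()].
#' @param interpolation "nearest" or "trilinear".
#' @return The resampled [bold_session()].
#' @export
apply_affine <- function(session, xf,
                         interpolation = c("nearest", "trilinear")) {
  stopifnot(inherits(session, "bold_session"))
  interpolation <- match.arg(interpolation)
  m <- affine_matrix(xf)
  if (abs(det(m)) < 1e-12) stop("transform is not invertible")
  minv <- solve(m)

  d <- dim(session$data)[1:3]
  vs <- session$voxel_size
  centre <- (d - 1) / 2 * vs
  g <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                             z = seq_len(d[3])))
  # target voxel centres in centred mm coordinates
  tgt <- sweep(sweep(g - 1, 2L, vs, "*"), 2L, centre, "-")
  src <- tgt %*% t(minv[1:3, 1:3])
  src <- sweep(src, 2L, minv[1:3, 4], "+")
  # back to 1-based voxel indices in the source grid
  src_idx <- sweep(sweep(src, 2L, centre, "+"), 2L, vs, "/") + 1

  nt <- dim(session$data)[4]
  vol <- matrix(session$data, ncol = nt)
  out <- matrix(0, nrow = nrow(vol), ncol = nt)

  if (interpolation == "nearest") {
    ni <- round(src_idx)
    ok <- ni[, 1] >= 1 & ni[, 1] <= d[1] & ni[, 2] >= 1 & ni[, 2] <= d[2] &
      ni[, 3] >= 1 & ni[, 3] <= d[3]
    lin <- ni[ok, 1] + d[1] * (ni[ok, 2] - 1) + d[1] * d[2] * (ni[ok, 3] - 1)
    out[ok, ] <- vol[lin, , drop = FALSE]
  } else {
    f <- floor(src_idx)
    w <- src_idx - f
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      ix <- f[, 1] + cx; iy <- f[, 2] + cy; iz <- f[, 3] + cz
      wt <- (if (cx) w[, 1] else 1 - w[, 1]) *
        (if (cy) w[, 2] else 1 - w[, 2]) *
        (if (cz) w[, 3] else 1 - w[, 3])
      ok <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2] &
        iz >= 1 & iz <= d[3] & wt > 0
      if (!any(ok)) next
      lin <- ix[ok] + d[1] * (iy[ok] - 1) + d[1] * d[2] * (iz[ok] - 1)
      out[ok, ] <- out[ok, ] + wt[ok] * vol[lin, , drop = FALSE]
    }
  }
  session$data <- array(out, dim(session$data))
  session
}

#' Propagate atlas labels to a session's voxels
#'
#' The session must already be in atlas space (after [apply_affine()]); each
#' session voxel is tagged with the atlas label at the same grid position
#' (one-to-one correspondence), so every voxel gets exactly one label,
#' possibly background.
#'
#' @param session a [bold_session()] in atlas space.
#' @param atlas a [atlas()].
#' @return 3D integer array of region ids aligned to the session grid.
#' @export
propagate_labels <- function(session, atlas) {
  stopifnot(inherits(session, "bold_session"), inherits(atlas, "phmri_atlas"))
  if (!identical(dim(session$data)[1:3], dim(atlas$labels)))
    stop("session grid does not match atlas grid")
  atlas$labels
}
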