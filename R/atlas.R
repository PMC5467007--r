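#' Segmented brain atlas
#'
#' Bundles a 3D integer label volume with region metadata and named circuit
#' (network) definitions. Label 0 is reserved for background (non-brain), so
#' `labels > 0` doubles as the brain mask. Region ids are arbitrary positive
#' integers and need not be contiguous; a region may belong to any number of
#' networks (circuits overlap in practice).
#'
#' @param labels 3D integer array; 0 = background, k > 0 = region id.
#' @param voxel_size numeric length-3, physical voxel edge lengths in mm.
#' @param regions data.frame with columns `region_id`, `region_name`.
#' @param networks named list mapping network name to an integer vector of
#'   region ids, each a subset of `regions$region_id`.
#' @return An object of class `phmri_atlas`.
#' @export
atlas <- function(labels, voxel_size, regions, networks = list()) {
  if (length(dim(labels)) != 3L)
    stop("labels must be a 3D array")
  labels <- array(as.integer(round(labels)), dim(labels))
  if (any(labels < 0L))
    stop("negative labels are not allowed")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("voxel_size must be three strictly positive lengths (mm)")
  if (!is.data.frame(regions) ||
      !all(c("region_id", "region_name") %in% names(regions)))
    stop("regions must be a data.frame with region_id and region_name")
  regions <- data.frame(region_id = as.integer(regions$region_id),
                        region_name = as.character(regions$region_name),
                        stringsAsFactors = FALSE)
  if (any(regions$region_id <= 0L) || anyDuplicated(regions$region_id))
    stop("region ids must be unique positive integers")

  present <- sort(unique(as.vector(labels)))
  present <- present[present > 0L]
  missing_in_table <- setdiff(present, regions$region_id)
  if (length(missing_in_table))
    stop("unregistered region: label(s) ",
         paste(missing_in_table, collapse = ", "),
         " appear in the volume but not in the region table")
  missing_in_volume <- setdiff(regions$region_id, present)
  if (length(missing_in_volume))
    stop("unregistered region: region id(s) ",
         paste(missing_in_volume, collapse = ", "),
         " listed in the table but absent from the volume")

  if (length(networks)) {
    if (is.null(names(networks)) || any(!nzchar(names(networks))))
      stop("networks must be a named list")
    for (nm in names(networks)) {
      ids <- as.integer(networks[[nm]])
      dangling <- setdiff(ids, regions$region_id)
      if (length(dangling))
        stop("dangling network member: network '", nm, "' references region(s) ",
             paste(dangling, collapse = ", "), " absent from the region table")
      networks[[nm]] <- ids
    }
  }

  structure(list(labels = labels, voxel_size = voxel_size,
                 regions = regions, networks = networks),
            class = "phmri_atlas")
}

#' @export
print.phmri_atlas <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("phmri atlas: %d x %d x %d grid (%.4g x %.4g x %.4g mm)\n",
              d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  %d regions, %d networks, %d brain voxels\n",
              nrow(x$regions), length(x$networks), sum(x$labels > 0L)))
  invisible(x)
}

#' Load an atlas from a NIfTI label volume and CSV tables
#'
#' @param label_path NIfTI-1 file holding the 3D integer label volume; voxel
#'   sizes are taken from its header.
#' @param region_table_path CSV with header `region_id,region_name`.
#' @param network_table_path optional CSV with header
#'   `network_name,region_id`, one row per membership.
#' @return A validated [atlas()].
#' @export
load_atlas <- function(label_path, region_table_path,
                       network_table_path = NULL) {
  img <- RNifti::readNifti(label_path)
  labels <- array(as.integer(round(as.array(img))), dim(img))
  if (length(dim(labels)) != 3L)
    stop("label volume must be 3D")
  voxel_size <- RNifti::pixdim(img)[1:3]
  regions <- utils::read.csv(region_table_path, stringsAsFactors = FALSE)
  networks <- list()
  if (!is.null(network_table_path)) {
    nt <- utils::read.csv(network_table_path, stringsAsFactors = FALSE)
    if (!all(c("network_name", "region_id") %in% names(nt)))
      stop("network table needs columns network_name,region_id")
    networks <- lapply(split(as.integer(nt$region_id), nt$network_name),
                       unique)
  }
  atlas(labels, voxel_size, regions, networks)
}

#' Write an atlas to disk (NIfTI labels + CSV tables)
#'
#' @param x a `phmri_atlas`.
#' @param label_path,region_table_path output paths.
#' @param network_table_path optional output path for network memberships.
#' @return Invisibly, the paths written.
#' @export
write_atlas <- function(x, label_path, region_table_path,
                        network_table_path = NULL) {
  stopifnot(inherits(x, "phmri_atlas"))
  img <- RNifti::asNifti(x$labels)
  RNifti::pixdim(img) <- x$voxel_size
  RNifti::writeNifti(img, label_path, datatype = "int32")
  utils::write.csv(x$regions, region_table_path, row.names = FALSE)
  paths <- c(label_path, region_table_path)
  if (!is.null(network_table_path)) {
    nt <- do.call(rbind, lapply(names(x$networks), function(nm)
      data.frame(network_name = nm, region_id = x$networks[[nm]])))
    if (is.null(nt))
      nt <- data.frame(network_name = character(0), region_id = integer(0))
    utils::write.csv(nt, network_table_path, row.names = FALSE)
    paths <- c(paths, network_table_path)
  }
  invisible(paths)
}

#' Voxel count per atlas region
#'
#' @param x a `phmri_atlas`.
#' @return Named integer vector, names = region ids present in the volume.
#'   Counts sum to the number of nonzero (brain) voxels.
#' @export
region_voxel_counts <- function(x) {
  stopifnot(inherits(x, "phmri_atlas"))
  v <- as.vector(x$labels)
  v <- v[v > 0L]
  tab <- table(v)
  stats::setNames(as.integer(tab), names(tab))
}
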