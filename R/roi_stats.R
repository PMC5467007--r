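#' Volume of activation per region
#'
#' Counts, for each atlas region and analysis window, the subject's activated
#' voxels of the requested sign, and the mean percent change over those
#' voxels (0 when none). Counts over all regions sum to the subject's total
#' activated voxels of that sign.
#'
#' @param statmap a `voxel_stat_map` from [activation_map()].
#' @param labels 3D region-id grid aligned to the map.
#' @param sign "+" for positive BOLD (the convention of reported volume-of-
#'   activation tables) or "-" for negative BOLD.
#' @param region_ids regions to report; defaults to all ids present in
#'   `labels`.
#' @return data.frame: subject_id, treatment, region_id, window,
#'   activated_voxels, mean_pct_change.
#' @export
volume_of_activation <- function(statmap, labels, sign = "+",
                                 region_ids = NULL) {
  stopifnot(inherits(statmap, "voxel_stat_map"), sign %in% c("+", "-"))
  lab <- as.vector(labels)
  if (is.null(region_ids)) {
    region_ids <- sort(unique(lab[lab > 0L]))
  }
  want_sign <- if (sign == "+") 1 else -1
  out <- list()
  for (nm in names(statmap$windows)) {
    w <- statmap$windows[[nm]]
    act <- as.vector(w$activated) %in% TRUE &
      as.vector(w$sign) %in% want_sign
    pct <- as.vector(w$pct_change)
    counts <- vapply(region_ids, function(r) sum(act[lab == r]), 0L)
    mpc <- vapply(region_ids, function(r) {
      sel <- act & lab == r
      if (any(sel)) mean(pct[sel]) else 0
    }, 0.0)
    out[[nm]] <- data.frame(subject_id = statmap$subject_id,
                            treatment = statmap$treatment,
                            region_id = region_ids, window = nm,
                            activated_voxels = counts,
                            mean_pct_change = mpc,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Composite activation map across subjects
#'
#' Voxel-by-voxel average of per-subject percent-change maps for one window;
#' a voxel is retained in the composite when it was activated in at least
#' `min_frequency` of the subjects (default half). This is the group-level
#' image from which representative per-region counts are read.
#'
#' @param statmaps list of `voxel_stat_map`s on a shared grid.
#' @param window window name.
#' @param min_frequency minimum fraction of subjects with the voxel activated.
#' @return List: `mean_pct` (3D array, NA outside the brain), `frequency`
#'   (fraction of subjects activated), `retained` (logical 3D array).
#' @export
composite_map <- function(statmaps, window, min_frequency = 0.5) {
  stopifnot(length(statmaps) >= 1L)
  dims <- lapply(statmaps, function(s) dim(s$mask))
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("stat maps do not share a grid")
  nvox <- prod(dims[[1]])
  pct <- vapply(statmaps,
                function(s) as.vector(s$windows[[window]]$pct_change),
                numeric(nvox))
  act <- vapply(statmaps,
                function(s) as.vector(s$windows[[window]]$activated) %in% TRUE,
                logical(nvox))
  pm <- array(rowMeans(pct), dims[[1]])   # NA propagates outside the brain
  freq <- array(rowMeans(act), dims[[1]])
  list(mean_pct = pm, frequency = freq,
       retained = freq >= min_frequency & !is.na(pm))
}

#' Representative per-region counts from a composite map
#'
#' Number of retained composite voxels per region whose mean percent change
#' has the requested sign.
#'
#' @param composite result of [composite_map()].
#' @param labels 3D region-id grid.
#' @param sign "+" or "-".
#' @param region_ids regions to report (default: all in `labels`).
#' @return Named integer vector keyed by region id.
#' @export
composite_region_counts <- function(composite, labels, sign = "+",
                                    region_ids = NULL) {
  lab <- as.vector(labels)
  if (is.null(region_ids)) region_ids <- sort(unique(lab[lab > 0L]))
  keep <- as.vector(composite$retained) &
    (if (sign == "+") as.vector(composite$mean_pct) > 0
     else as.vector(composite$mean_pct) < 0)
  keep[is.na(keep)] <- FALSE
  stats::setNames(vapply(region_ids, function(r) sum(keep[lab == r]), 0L),
                  region_ids)
}

#' Kruskal-Wallis comparison of per-subject counts
#'
#' Rank-based H with midranks and the standard tie correction, referred to a
#' chi-square distribution with (groups - 1) df. Volume-of-activation counts
#' are heavily tied at zero, so the all-identical case is defined explicitly
#' as H = 0, p = 1.
#'
#' @param counts_by_group named list, group -> numeric vector of per-subject
#'   counts (>= 2 groups, each non-empty).
#' @return List: `H`, `p`.
#' @export
kruskal_wallis_region <- function(counts_by_group) {
  if (length(counts_by_group) < 2L)
    stop("need at least 2 groups")
  if (any(vapply(counts_by_group, length, 0L) < 1L))
    stop("every group needs at least 1 subject")
  x <- unlist(counts_by_group, use.names = FALSE)
  g <- factor(rep(names(counts_by_group),
                  vapply(counts_by_group, length, 0L)))
  if (length(unique(x)) == 1L) return(list(H = 0, p = 1))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), p = kt$p.value)
}

#' Region-level group comparison table
#'
#' Builds, for one treatment-versus-control comparison, the per-region,
#' per-window table: representative counts per group (from the group
#' composite maps when supplied, otherwise group medians of the per-subject
#' counts), the Kruskal-Wallis H on the per-subject counts, its p-value, and
#' the significance flag at `alpha`. The omnibus across more than two groups
#' uses the same function with more treatments.
#'
#' @param voa combined [volume_of_activation()] rows for all subjects (must
#'   carry the `treatment` column).
#' @param treatments treatment labels to compare (>= 2), control included.
#' @param rep_counts optional data.frame `region_id, window, treatment,
#'   count` of composite-map counts used for the printed per-group columns.
#' @param alpha significance level (default 0.05).
#' @param adjust_regions apply BH across regions within each window (off by
#'   default: reported tables apply none, a caveat their readers inherit).
#' @return data.frame: region_id, window, one `count_<group>` column per
#'   group, kw_H, p_value, significant.
#' @export
region_comparison_table <- function(voa, treatments, rep_counts = NULL,
                                    alpha = 0.05, adjust_regions = FALSE) {
  stopifnot(length(treatments) >= 2L)
  voa <- voa[voa$treatment %in% treatments, , drop = FALSE]
  if (!nrow(voa)) stop("no rows for the requested treatments")
  out <- list()
  for (win in unique(voa$window)) {
    vw <- voa[voa$window == win, , drop = FALSE]
    for (r in sort(unique(vw$region_id))) {
      vr <- vw[vw$region_id == r, , drop = FALSE]
      counts_by_group <- lapply(stats::setNames(treatments, treatments),
                                function(tr)
                                  vr$activated_voxels[vr$treatment == tr])
      kw <- kruskal_wallis_region(counts_by_group)
      rep_row <- lapply(treatments, function(tr) {
        if (!is.null(rep_counts)) {
          hit <- rep_counts$region_id == r & rep_counts$window == win &
            rep_counts$treatment == tr
          if (any(hit)) return(rep_counts$count[hit][1])
        }
        stats::median(counts_by_group[[tr]])
      })
      names(rep_row) <- paste0("count_", treatments)
      out[[length(out) + 1L]] <- cbind(
        data.frame(region_id = r, window = win, stringsAsFactors = FALSE),
        as.data.frame(rep_row, check.names = FALSE),
        data.frame(kw_H = kw$H, p_value = kw$p))
    }
  }
  res <- do.call(rbind, out)
  if (adjust_regions) {
    for (win in unique(res$window)) {
      sel <- res$window == win
      res$p_value[sel] <- stats::p.adjust(res$p_value[sel], method = "BH")
    }
  }
  res$significant <- res$p_value <= alpha
  rownames(res) <- NULL
  res
}

#' Filter and sort a comparison table to its significant rows
#'
#' The machine twin of a published significant-region listing: keep rows of
#' the requested window with `p_value <= alpha`, ordered by ascending p.
#'
#' @param rows data.frame with at least `window` and `p_value` columns
#'   (e.g. from [region_comparison_table()] or a CSV of reported rows).
#' @param window window name to filter on.
#' @param alpha significance level (default 0.05).
#' @return The filtered, p-sorted data.frame.
#' @export
significant_region_table <- function(rows, window, alpha = 0.05) {
  stopifnot(all(c("window", "p_value") %in% names(rows)))
  sel <- rows[rows$window == window & rows$p_value <= alpha, , drop = FALSE]
  sel <- sel[order(sel$p_value), , drop = FALSE]
  rownames(sel) <- NULL
  sel
}
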