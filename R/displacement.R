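# Vertex-displacement analysis: how far did a re-exported contour move
# from the original? Distances are from original polygon vertices to the
# nearest location on the re-exported contour (closest point on the closed
# polyline, not nearest vertex), slice by slice, strictly in 2D.

#' Summarize vertex displacement between an original and re-exported structure
#'
#' For every original vertex, the minimum distance to any re-exported
#' contour on the matching slice. Original slices with no matching
#' re-exported slice contribute their vertices at an infinite sentinel:
#' they are excluded from the mean/max and the cumulative curve fractions
#' use all original vertices as denominator (so the curve tops out below 1
#' when slices disappeared — topology evidence).
#'
#' @param original,reexported cleaned `rt_structure`s.
#' @param grid `image_grid` providing the in-plane voxel size (the
#'   normalizer of the cumulative curve) and the slice-matching tolerance
#'   (`dz / 10`).
#' @return object of class `displacement_summary`: fields `mean_mm`,
#'   `max_mm`, `n_vertices_original`, `n_vertices_reexported`,
#'   `distances_mm` (finite per-vertex distances), `n_unmatched_vertices`,
#'   `cumulative` (data.frame distance_voxels, fraction),
#'   `topology_changed`, `per_slice_region_delta`.
#' @export
displacement_summary <- function(original, reexported, grid) {
  z_tol <- grid$dz / 10
  ga <- group_by_slice(original, z_tol)
  gb <- group_by_slice(reexported, z_tol)
  if (!length(ga)) stop("original structure has no contours after cleaning")
  mm <- match_slices(ga, gb, z_tol)
  if (!nrow(mm$pairs)) {
    stop("no matching slices between original and re-exported structure")
  }
  dists <- numeric(0)
  n_unmatched <- 0L
  for (i in seq_along(ga)) {
    pts <- do.call(rbind, lapply(ga[[i]]$contours, `[[`, "vertices"))
    j <- mm$pairs[mm$pairs[, 1] == i, 2]
    if (length(j)) {
      dists <- c(dists, points_to_contours_distance(pts, gb[[j]]$contours))
    } else {
      n_unmatched <- n_unmatched + nrow(pts)
    }
  }
  voxel <- in_plane_voxel_size(grid)
  n_total <- length(dists) + n_unmatched
  cum <- if (length(dists)) {
    d_sorted <- sort(dists) / voxel
    data.frame(distance_voxels = d_sorted,
               fraction = seq_along(d_sorted) / n_total)
  } else {
    data.frame(distance_voxels = numeric(0), fraction = numeric(0))
  }
  topo <- detect_topology_change(original, reexported, grid)
  structure(
    list(mean_mm = if (length(dists)) mean(dists) else NA_real_,
         max_mm = if (length(dists)) max(dists) else NA_real_,
         n_vertices_original = structure_vertex_count(original),
         n_vertices_reexported = structure_vertex_count(reexported),
         distances_mm = dists,
         n_unmatched_vertices = n_unmatched,
         cumulative = cum,
         topology_changed = topo$flag,
         per_slice_region_delta = topo$per_slice_region_delta),
    class = "displacement_summary"
  )
}

#' @export
print.displacement_summary <- function(x, ...) {
  cat(sprintf("<displacement_summary> mean %.6g mm, max %.6g mm (%d -> %d vertices)%s\n",
              x$mean_mm, x$max_mm, x$n_vertices_original, x$n_vertices_reexported,
              if (x$topology_changed) ", TOPOLOGY CHANGED" else ""))
  if (x$n_unmatched_vertices > 0) {
    cat(sprintf("  %d original vertices on slices absent from the re-export\n",
                x$n_unmatched_vertices))
  }
  invisible(x)
}

#' Detect a topology change between original and re-exported structure
#'
#' Flags when (a) per-slice contour-component counts differ on any matched
#' slice, (b) a slice is present in only one structure, or (c) the
#' directional maximum boundary distance original-to-reexported exceeds
#' `asym_threshold_voxels` while the opposite direction does not (or vice
#' versa) — the signature of small disconnected regions being removed.
#'
#' @param original,reexported cleaned `rt_structure`s.
#' @param grid an `image_grid`.
#' @param asym_threshold_voxels directional-asymmetry threshold in in-plane
#'   voxels (default 2).
#' @param sample_spacing boundary sampling step for the directional maxima,
#'   mm.
#' @return list `flag` (logical) and `per_slice_region_delta` (data.frame
#'   z, delta = re-export contour count minus original).
#' @export
detect_topology_change <- function(original, reexported, grid,
                                   asym_threshold_voxels = 2,
                                   sample_spacing = 0.5) {
  z_tol <- grid$dz / 10
  ga <- group_by_slice(original, z_tol)
  gb <- group_by_slice(reexported, z_tol)
  mm <- match_slices(ga, gb, z_tol)
  zs <- numeric(0); deltas <- integer(0)
  flag <- FALSE
  if (nrow(mm$pairs)) {
    for (r in seq_len(nrow(mm$pairs))) {
      i <- mm$pairs[r, 1]; j <- mm$pairs[r, 2]
      delta <- length(gb[[j]]$contours) - length(ga[[i]]$contours)
      zs <- c(zs, ga[[i]]$z); deltas <- c(deltas, delta)
      if (delta != 0L) flag <- TRUE
    }
  }
  for (i in mm$only_a) {
    zs <- c(zs, ga[[i]]$z); deltas <- c(deltas, -length(ga[[i]]$contours))
    flag <- TRUE
  }
  for (j in mm$only_b) {
    zs <- c(zs, gb[[j]]$z); deltas <- c(deltas, length(gb[[j]]$contours))
    flag <- TRUE
  }
  # directional-asymmetry evidence
  if (!flag && nrow(mm$pairs)) {
    d_ab <- directional_max_distance(ga, gb, mm$pairs, sample_spacing)
    d_ba <- directional_max_distance(gb, ga, mm$pairs[, 2:1, drop = FALSE],
                                     sample_spacing)
    thr <- asym_threshold_voxels * in_plane_voxel_size(grid)
    if ((d_ab > thr) != (d_ba > thr)) flag <- TRUE
  }
  ord <- order(zs)
  list(flag = flag,
       per_slice_region_delta = data.frame(z = zs[ord], delta = deltas[ord]))
}

# max over matched slices of the max distance from A's sampled boundary to
# B's polylines
directional_max_distance <- function(ga, gb, pairs, sample_spacing) {
  dmax <- 0
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    pts <- do.call(rbind, lapply(ga[[i]]$contours, function(ct) {
      resample_closed_polygon(ct$vertices, sample_spacing)
    }))
    d <- points_to_contours_distance(pts, gb[[j]]$contours)
    dmax <- max(dmax, max(d))
  }
  dmax
}

#' Export a displacement summary and cumulative curve to CSV
#'
#' @param summaries named list of `displacement_summary` objects.
#' @param summary_path CSV path for one-row-per-structure scalars.
#' @param curve_path optional CSV path for the long-form cumulative curves.
#' @return invisibly, the summary data.frame.
#' @export
write_displacement_csv <- function(summaries, summary_path, curve_path = NULL) {
  rows <- do.call(rbind, lapply(names(summaries), function(nm) {
    x <- summaries[[nm]]
    data.frame(structure = nm, mean_mm = x$mean_mm, max_mm = x$max_mm,
               n_vertices_original = x$n_vertices_original,
               n_vertices_reexported = x$n_vertices_reexported,
               n_unmatched_vertices = x$n_unmatched_vertices,
               topology_changed = x$topology_changed)
  }))
  write.csv(rows, summary_path, row.names = FALSE)
  if (!is.null(curve_path)) {
    curves <- do.call(rbind, lapply(names(summaries), function(nm) {
      cum <- summaries[[nm]]$cumulative
      if (!nrow(cum)) return(NULL)
      cbind(structure = nm, cum)
    }))
    write.csv(curves, curve_path, row.names = FALSE)
  }
  invisible(rows)
}
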