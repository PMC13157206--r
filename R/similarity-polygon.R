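# Contour similarity measures computed directly on the polygon stacks:
# normalised added path length (nAPL) at tolerance, volumetric Dice, and
# the 2D distance family (2DHD, 95%2DHD, 50%2DHD, 2DMSD).

#' Tolerance sweep specification
#'
#' Tolerances are expressed as fractions of the in-plane voxel size; the
#' default sweep is 1%, 10%, 50%, 100%, 200% and 300%.
#'
#' @param fractions_of_voxel strictly increasing positive fractions.
#' @return a `tolerance_spec`.
#' @export
tolerance_spec <- function(fractions_of_voxel = c(0.01, 0.1, 0.5, 1, 2, 3)) {
  f <- as.numeric(fractions_of_voxel)
  if (!length(f)) stop("at least one tolerance fraction is required")
  if (any(f <= 0) || any(diff(f) <= 0)) {
    stop("tolerance fractions must be positive and strictly increasing")
  }
  structure(list(fractions_of_voxel = f), class = "tolerance_spec")
}

#' Resolve a tolerance spec to millimetres
#' @param spec a [tolerance_spec].
#' @param grid an `image_grid`.
#' @return named numeric vector of tolerances in mm (names = fractions).
#' @export
resolve_tolerances <- function(spec, grid) {
  mm <- spec$fractions_of_voxel * in_plane_voxel_size(grid)
  names(mm) <- format(spec$fractions_of_voxel)
  mm
}

#' Closed path length of a contour
#' @param contour a cleaned `planar_contour`.
#' @return perimeter, mm.
#' @export
path_length <- function(contour) polygon_perimeter(contour$vertices)

#' Normalised added path length (nAPL)
#'
#' Fraction of the reference's total perimeter (summed over all slices)
#' lying farther than `tol_mm` from the test's contours on the matching
#' slice: 0 means the reference boundary is within tolerance everywhere, 1
#' means outside everywhere. Each reference edge is subdivided into
#' sub-segments no longer than `max_segment` (default `tol_mm / 4`, floored
#' at 0.05 mm) and classified by the distance of its midpoint to the test
#' polylines; reference slices with no matching test slice count as fully
#' outside.
#'
#' @param reference,test cleaned `rt_structure`s.
#' @param tol_mm tolerance, mm (>= 0).
#' @param z_tol slice-matching tolerance, mm.
#' @param max_segment sub-segment length, mm; `NULL` for the default rule.
#' @return nAPL in `[0, 1]`.
#' @export
napl <- function(reference, test, tol_mm, z_tol = 0.25, max_segment = NULL) {
  stopifnot(tol_mm >= 0)
  if (!length(reference$contours)) {
    stop("empty reference structure after cleaning")
  }
  if (is.null(max_segment)) max_segment <- max(tol_mm / 4, 0.05)
  ga <- group_by_slice(reference, z_tol)
  gb <- group_by_slice(test, z_tol)
  mm <- match_slices(ga, gb, z_tol)
  total <- 0; outside <- 0
  for (i in seq_along(ga)) {
    j <- mm$pairs[mm$pairs[, 1] == i, 2]
    for (ct in ga[[i]]$contours) {
      sub <- subdivide_edges(ct$vertices, max_segment)
      total <- total + sum(sub$len)
      if (!length(j)) {
        outside <- outside + sum(sub$len)
      } else {
        d <- points_to_contours_distance(sub$mid, gb[[j]]$contours)
        # 1e-9 mm slack absorbs floating-point ties for points on the contour
        outside <- outside + sum(sub$len[d > tol_mm + 1e-9])
      }
    }
  }
  if (total <= 0) stop("reference has zero total path length")
  outside / total
}

# midpoints and lengths of edge sub-segments no longer than max_segment
subdivide_edges <- function(vertices, max_segment) {
  n <- nrow(vertices)
  i2 <- c(seq_len(n)[-1], 1L)
  ax <- vertices[, 1]; ay <- vertices[, 2]
  bx <- vertices[i2, 1]; by <- vertices[i2, 2]
  len <- sqrt((bx - ax)^2 + (by - ay)^2)
  k <- pmax(1L, ceiling(len / max_segment))
  idx <- rep.int(seq_len(n), k)
  # midpoint parameter of each sub-segment
  t_mid <- (unlist(lapply(k, seq_len)) - 0.5) / k[idx]
  mid <- cbind(ax[idx] + t_mid * (bx[idx] - ax[idx]),
               ay[idx] + t_mid * (by[idx] - ay[idx]))
  list(mid = mid, len = len[idx] / k[idx])
}

#' nAPL over a voxel-relative tolerance sweep
#'
#' @param reference,test cleaned `rt_structure`s.
#' @param grid an `image_grid`.
#' @param tol_spec a [tolerance_spec].
#' @return named numeric vector (names = voxel fractions).
#' @export
napl_sweep <- function(reference, test, grid, tol_spec = tolerance_spec()) {
  tols <- resolve_tolerances(tol_spec, grid)
  vapply(tols, function(t) napl(reference, test, t, z_tol = grid$dz / 10),
         numeric(1))
}

#' Volumetric Dice similarity coefficient (vDSC)
#'
#' `2 V(A and B) / (V(A) + V(B))` with per-slice areas and intersection
#' areas computed by exact even-odd polygon clipping (holes subtract);
#' slice volume contribution is area x dz. Slices present in only one
#' structure contribute to that structure's volume only.
#'
#' @param a,b cleaned `rt_structure`s on a common slice grid.
#' @param grid an `image_grid` (supplies dz and the slice-matching
#'   tolerance dz / 10).
#' @return vDSC in `[0, 1]`.
#' @export
vdsc <- function(a, b, grid) {
  if (!length(a$contours) && !length(b$contours)) {
    stop("vDSC undefined: both structures are empty")
  }
  z_tol <- grid$dz / 10
  ga <- group_by_slice(a, z_tol)
  gb <- group_by_slice(b, z_tol)
  mm <- match_slices(ga, gb, z_tol)
  va <- sum(vapply(ga, function(g) slice_area(g$contours), numeric(1)))
  vb <- sum(vapply(gb, function(g) slice_area(g$contours), numeric(1)))
  vi <- 0
  if (nrow(mm$pairs)) {
    for (r in seq_len(nrow(mm$pairs))) {
      vi <- vi + slice_intersection_area(ga[[mm$pairs[r, 1]]]$contours,
                                         gb[[mm$pairs[r, 2]]]$contours)
    }
  }
  2 * vi / (va + vb)        # dz cancels: every slice contributes area * dz
}

#' 2D boundary distance family (2DHD, 95%2DHD, 50%2DHD, 2DMSD)
#'
#' Boundaries of both structures are resampled at arc-length spacing
#' `sample_spacing` on each matched slice; for each sample on A the nearest
#' distance to B's polylines on that slice and vice versa. The two
#' directional samples are pooled over all slices: hd2d = max, hd95 = 95th
#' percentile, hd50 = median, msd2d = mean. Directional maxima are reported
#' separately (used by topology diagnosis). Samples on slices with no
#' matching slice are infinite sentinels, reported separately and excluded
#' (with a warning) from the finite aggregates.
#'
#' @param a,b cleaned `rt_structure`s.
#' @param sample_spacing boundary sampling step, mm.
#' @param z_tol slice-matching tolerance, mm.
#' @param per_slice_max if TRUE, hd2d is the max over per-slice Hausdorff
#'   distances (identical value to pooling; provided for symmetry with
#'   other implementations).
#' @return list: `hd2d_mm`, `hd95_2d_mm`, `hd50_2d_mm`, `msd2d_mm`,
#'   `max_a_to_b_mm`, `max_b_to_a_mm`, `n_samples`, `n_infinite`.
#' @export
distances_2d <- function(a, b, sample_spacing = 0.1, z_tol = 0.25,
                         per_slice_max = FALSE) {
  ga <- group_by_slice(a, z_tol)
  gb <- group_by_slice(b, z_tol)
  mm <- match_slices(ga, gb, z_tol)
  sample_dists <- function(gfrom, gto, pairs) {
    out <- numeric(0); n_inf <- 0L
    matched <- pairs[, 1]
    for (i in seq_along(gfrom)) {
      pts <- do.call(rbind, lapply(gfrom[[i]]$contours, function(ct) {
        resample_closed_polygon(ct$vertices, sample_spacing)
      }))
      j <- pairs[matched == i, 2]
      if (length(j)) {
        out <- c(out, points_to_contours_distance(pts, gto[[j]]$contours))
      } else {
        n_inf <- n_inf + nrow(pts)
      }
    }
    list(d = out, n_inf = n_inf)
  }
  ab <- sample_dists(ga, gb, mm$pairs)
  ba <- sample_dists(gb, ga, mm$pairs[, 2:1, drop = FALSE])
  pooled <- c(ab$d, ba$d)
  n_inf <- ab$n_inf + ba$n_inf
  if (n_inf > 0) {
    warning(n_inf, " boundary samples on unmatched slices excluded from 2D aggregates")
  }
  if (!length(pooled)) stop("no matched slices: 2D distances undefined")
  list(hd2d_mm = max(pooled),
       hd95_2d_mm = unname(quantile(pooled, 0.95, type = 7)),
       hd50_2d_mm = median(pooled),
       msd2d_mm = mean(pooled),
       max_a_to_b_mm = if (length(ab$d)) max(ab$d) else NA_real_,
       max_b_to_a_mm = if (length(ba$d)) max(ba$d) else NA_real_,
       n_samples = length(pooled),
       n_infinite = n_inf)
}
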