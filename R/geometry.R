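# 2D polygon primitives shared by preprocessing, displacement analysis and
# the polygon-pathway similarity measures. All coordinates are patient mm.

#' Signed area of a closed polygon (shoelace formula)
#'
#' Positive for counter-clockwise vertex order.
#'
#' @param vertices n x 2 matrix; closing vertex not duplicated.
#' @return signed area in mm^2.
#' @export
polygon_signed_area <- function(vertices) {
  n <- nrow(vertices)
  if (is.null(n) || n < 3L) return(0)
  x <- vertices[, 1]; y <- vertices[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Perimeter of a closed polygon
#' @param vertices n x 2 matrix.
#' @return path length in mm (closed cycle, incl. last-to-first edge).
#' @export
polygon_perimeter <- function(vertices) {
  n <- nrow(vertices)
  if (is.null(n) || n < 2L) return(0)
  dx <- diff(c(vertices[, 1], vertices[1, 1]))
  dy <- diff(c(vertices[, 2], vertices[1, 2]))
  sum(sqrt(dx^2 + dy^2))
}

# closed-cycle edge matrix (x1, y1, x2, y2) for one contour
contour_edges <- function(vertices) {
  n <- nrow(vertices)
  i2 <- c(seq_len(n)[-1], 1L)
  cbind(x1 = vertices[, 1], y1 = vertices[, 2],
        x2 = vertices[i2, 1], y2 = vertices[i2, 2])
}

# edges of several contours stacked into one matrix
contours_edge_matrix <- function(contours) {
  do.call(rbind, lapply(contours, function(ct) contour_edges(ct$vertices)))
}

#' Minimum distances from points to a set of closed polylines
#'
#' Exact point-to-segment distance: perpendicular foot when it falls inside
#' the segment, else the nearer endpoint.
#'
#' @param pts m x 2 matrix of query points (mm).
#' @param contours list of `planar_contour` (their z is ignored; distances
#'   are in-plane).
#' @return numeric vector of length m, mm; `Inf` when `contours` is empty.
#' @export
points_to_contours_distance <- function(pts, contours) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  if (!length(contours)) return(rep(Inf, nrow(pts)))
  cpp_points_to_segments(pts, contours_edge_matrix(contours))
}

#' Distance from one point to the closed boundary of a contour
#'
#' @param p length-2 numeric (x, y) in mm.
#' @param contour a `planar_contour` with at least 3 vertices.
#' @return distance in mm.
#' @export
point_to_polyline_distance <- function(p, contour) {
  if (n_vertices(contour) < 3L) stop("contour must have at least 3 vertices")
  points_to_contours_distance(matrix(p, ncol = 2), list(contour))[1]
}

#' Resample a closed polygon at uniform arc-length spacing
#'
#' Sample positions are `k * L / n` for `k = 0 .. n-1` with
#' `n = max(3, round(L / spacing))`, starting from the first vertex.
#' Original vertices (corners) are not guaranteed to be preserved.
#'
#' @param vertices n x 2 matrix.
#' @param spacing target arc-length spacing, mm (> 0).
#' @return resampled vertex matrix.
#' @export
resample_closed_polygon <- function(vertices, spacing) {
  stopifnot(spacing > 0)
  closed <- rbind(vertices, vertices[1, , drop = FALSE])
  seg <- sqrt(diff(closed[, 1])^2 + diff(closed[, 2])^2)
  L <- sum(seg)
  if (L <= 0) return(vertices)
  n <- max(3L, as.integer(round(L / spacing)))
  s_targets <- (seq_len(n) - 1L) * L / n
  s_cum <- c(0, cumsum(seg))
  seg_idx <- findInterval(s_targets, s_cum, rightmost.closed = TRUE)
  seg_idx[seg_idx > length(seg)] <- length(seg)
  frac <- (s_targets - s_cum[seg_idx]) / pmax(seg[seg_idx], 1e-300)
  cbind(closed[seg_idx, 1] + frac * (closed[seg_idx + 1L, 1] - closed[seg_idx, 1]),
        closed[seg_idx, 2] + frac * (closed[seg_idx + 1L, 2] - closed[seg_idx, 2]))
}

#' Densify a closed polygon without moving its boundary
#'
#' Splits every edge longer than `max_segment` into equal parts; all
#' original vertices are retained.
#'
#' @param vertices n x 2 matrix.
#' @param max_segment maximum edge length after densification, mm.
#' @return densified vertex matrix.
#' @export
densify_closed_polygon <- function(vertices, max_segment) {
  stopifnot(max_segment > 0)
  n <- nrow(vertices)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    a <- vertices[i, ]; b <- vertices[if (i == n) 1L else i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    k <- max(1L, as.integer(ceiling(len / max_segment)))
    t <- (seq_len(k) - 1L) / k
    out[[i]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  do.call(rbind, out)
}

#' Even-odd point-in-polygon test against a set of contours
#'
#' Crossing-number rule with the half-open convention `y1 <= y < y2`;
#' points exactly on an edge are classified deterministically (treated as
#' outside for points on a right-going crossing).
#'
#' @param pts m x 2 matrix.
#' @param contours list of `planar_contour`; even-odd over the union of
#'   their edges (holes handled automatically).
#' @return logical vector of length m.
#' @export
points_in_contours <- function(pts, contours) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  if (!length(contours)) return(rep(FALSE, nrow(pts)))
  cpp_points_in_polygons(pts, contours_edge_matrix(contours))
}

# nesting depth of each contour among the others on the same slice:
# depth 0 = outer boundary, odd depth = hole (even-odd rule)
contour_nesting_depth <- function(contours) {
  k <- length(contours)
  depth <- integer(k)
  if (k < 2L) return(depth)
  for (i in seq_len(k)) {
    p <- contours[[i]]$vertices[1, , drop = FALSE]
    for (j in seq_len(k)) {
      if (i == j) next
      if (points_in_contours(p, contours[j])) depth[i] <- depth[i] + 1L
    }
  }
  depth
}

#' Even-odd enclosed area of the contours on one slice
#'
#' Nesting-parity sum: outer boundaries add their absolute area, odd-depth
#' contours (holes) subtract, regardless of stored orientation.
#'
#' @param contours list of `planar_contour` sharing one slice.
#' @return area in mm^2 (>= 0 for non-crossing input).
#' @export
slice_area <- function(contours) {
  if (!length(contours)) return(0)
  depth <- contour_nesting_depth(contours)
  areas <- vapply(contours, function(ct) abs(polygon_signed_area(ct$vertices)),
                  numeric(1))
  sum(areas * ifelse(depth %% 2L == 0L, 1, -1))
}

# --- exact even-odd intersection area (trapezoidal slab decomposition) ----
#
# The plane is cut into horizontal slabs at every vertex y of either edge
# set and at every A-B edge crossing. Within a slab no two edges cross, so
# each region's even-odd interior is a left-to-right sequence of trapezoids
# bounded by straight edges; intersecting two trapezoid sequences reduces
# to interval intersection with the bounding edge chosen by comparison at
# the slab midline. Exact for simple, non-self-crossing contour sets,
# including identical polygons and shared edges.

# x-position of edges at height y (edges must span y)
edge_x_at <- function(E, y) {
  E[, "x1"] + (y - E[, "y1"]) * (E[, "x2"] - E[, "x1"]) / (E[, "y2"] - E[, "y1"])
}

# y-coordinates of all crossings between edge sets EA and EB
edge_crossing_ys <- function(EA, EB) {
  if (!nrow(EA) || !nrow(EB)) return(numeric(0))
  ys <- numeric(0)
  for (i in seq_len(nrow(EA))) {
    ax1 <- EA[i, "x1"]; ay1 <- EA[i, "y1"]
    dax <- EA[i, "x2"] - ax1; day <- EA[i, "y2"] - ay1
    bx1 <- EB[, "x1"]; by1 <- EB[, "y1"]
    dbx <- EB[, "x2"] - bx1; dby <- EB[, "y2"] - by1
    den <- dax * dby - day * dbx
    ok <- abs(den) > 1e-14
    if (!any(ok)) next
    t <- ((bx1 - ax1) * dby - (by1 - ay1) * dbx)[ok] / den[ok]
    u <- ((bx1 - ax1)[ok] * day - (by1 - ay1)[ok] * dax) / den[ok]
    keep <- t >= 0 & t <= 1 & u >= 0 & u <= 1
    if (any(keep)) ys <- c(ys, ay1 + t[keep] * day)
  }
  ys
}

# even-odd x-intervals of an edge set at slab midline ym; returns a list
# with edge indices of left/right bounding edges, or NULL when empty
slab_intervals <- function(E, ym) {
  span <- (pmin(E[, "y1"], E[, "y2"]) < ym) & (pmax(E[, "y1"], E[, "y2"]) > ym)
  idx <- which(span)
  if (length(idx) < 2L) return(NULL)
  xm <- edge_x_at(E[idx, , drop = FALSE], ym)
  ord <- order(xm)
  idx <- idx[ord]
  k <- length(idx) %/% 2L * 2L
  if (k < 2L) return(NULL)
  list(left = idx[seq(1L, k, by = 2L)], right = idx[seq(2L, k, by = 2L)])
}

# area between two bounding edges over slab [y0, y1] (trapezoid; clamped)
trapezoid_area <- function(El, Er, y0, y1) {
  w0 <- pmax(0, edge_x_at(Er, y0) - edge_x_at(El, y0))
  w1 <- pmax(0, edge_x_at(Er, y1) - edge_x_at(El, y1))
  sum((w0 + w1) / 2 * (y1 - y0))
}

#' Exact even-odd area of intersection of two slice contour sets
#'
#' @param contours_a,contours_b lists of `planar_contour` on one slice.
#' @return intersection area in mm^2.
#' @export
slice_intersection_area <- function(contours_a, contours_b) {
  if (!length(contours_a) || !length(contours_b)) return(0)
  EA <- contours_edge_matrix(contours_a)
  EB <- contours_edge_matrix(contours_b)
  ys <- sort(unique(c(EA[, "y1"], EA[, "y2"], EB[, "y1"], EB[, "y2"],
                      edge_crossing_ys(EA, EB))))
  if (length(ys) < 2L) return(0)
  total <- 0
  for (s in seq_len(length(ys) - 1L)) {
    y0 <- ys[s]; y1 <- ys[s + 1L]
    if (y1 - y0 <= 0) next
    ym <- (y0 + y1) / 2
    ia <- slab_intervals(EA, ym)
    if (is.null(ia)) next
    ib <- slab_intervals(EB, ym)
    if (is.null(ib)) next
    xa_l <- edge_x_at(EA[ia$left, , drop = FALSE], ym)
    xa_r <- edge_x_at(EA[ia$right, , drop = FALSE], ym)
    xb_l <- edge_x_at(EB[ib$left, , drop = FALSE], ym)
    xb_r <- edge_x_at(EB[ib$right, , drop = FALSE], ym)
    for (i in seq_along(xa_l)) {
      for (j in seq_along(xb_l)) {
        lo <- max(xa_l[i], xb_l[j]); hi <- min(xa_r[i], xb_r[j])
        if (hi <= lo) next
        El <- if (xa_l[i] >= xb_l[j]) EA[ia$left[i], , drop = FALSE] else EB[ib$left[j], , drop = FALSE]
        Er <- if (xa_r[i] <= xb_r[j]) EA[ia$right[i], , drop = FALSE] else EB[ib$right[j], , drop = FALSE]
        total <- total + trapezoid_area(El, Er, y0, y1)
      }
    }
  }
  total
}
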