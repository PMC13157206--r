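#' @useDynLib rtssfidelity, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median quantile runif
#' @importFrom utils head tail write.csv
NULL

#' Create a planar contour
#'
#' A single closed planar polygon at a fixed axial position, with vertices in
#' patient millimetre coordinates. The polygon is implicitly closed: the last
#' vertex connects back to the first, and the closing vertex is never
#' duplicated in storage.
#'
#' @param vertices numeric matrix with two columns (x, y) in mm, one row per
#'   vertex, in drawing order.
#' @param z axial position of the contour plane, mm.
#' @param geometric_type contour type label; only `"CLOSED_PLANAR"` is
#'   supported.
#' @return an object of class `planar_contour`.
#' @export
planar_contour <- function(vertices, z, geometric_type = "CLOSED_PLANAR") {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L) stop("vertices must be an n x 2 matrix of (x, y) in mm")
  if (!is.numeric(vertices)) stop("vertices must be numeric")
  if (!identical(geometric_type, "CLOSED_PLANAR")) {
    stop("unsupported geometric type '", geometric_type,
         "': only CLOSED_PLANAR contours are handled")
  }
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  structure(
    list(vertices = vertices, z = as.numeric(z)[1],
         geometric_type = geometric_type),
    class = "planar_contour"
  )
}

#' @export
print.planar_contour <- function(x, ...) {
  cat(sprintf("<planar_contour> %d vertices at z = %g mm\n",
              nrow(x$vertices), x$z))
  invisible(x)
}

n_vertices <- function(contour) nrow(contour$vertices)

#' Create a structure (named stack of planar contours)
#'
#' @param name structure (ROI) name.
#' @param contours list of [planar_contour] objects. Multiple contours may
#'   share one z (disconnected regions or holes).
#' @param frame_of_reference DICOM frame-of-reference UID or any identifier.
#' @return an object of class `rt_structure`.
#' @export
rt_structure <- function(name, contours = list(),
                         frame_of_reference = "1.2.826.0.1.3680043.9.7484.0.1") {
  stopifnot(is.character(name), length(name) == 1L)
  if (!all(vapply(contours, inherits, logical(1), "planar_contour"))) {
    stop("contours must be a list of planar_contour objects")
  }
  structure(
    list(name = name, contours = contours,
         frame_of_reference = frame_of_reference),
    class = "rt_structure"
  )
}

#' @export
print.rt_structure <- function(x, ...) {
  zs <- contour_zs(x)
  nv <- sum(vapply(x$contours, n_vertices, integer(1)))
  cat(sprintf("<rt_structure> '%s': %d contour(s) on %d slice(s), %d vertices",
              x$name, length(x$contours), length(unique(round(zs, 9))), nv))
  if (length(zs)) cat(sprintf(", z in [%g, %g] mm", min(zs), max(zs)))
  cat("\n")
  invisible(x)
}

contour_zs <- function(s) vapply(s$contours, function(c) c$z, numeric(1))

#' Total number of vertices in a structure
#' @param s an `rt_structure`.
#' @return integer vertex count over all contours.
#' @export
structure_vertex_count <- function(s) {
  if (!length(s$contours)) return(0L)
  sum(vapply(s$contours, n_vertices, integer(1)))
}

#' Rigidly translate a structure
#'
#' @param s an `rt_structure`.
#' @param offset numeric length-3 (dx, dy, dz) in mm.
#' @return translated `rt_structure`.
#' @export
translate_structure <- function(s, offset) {
  offset <- as.numeric(offset)
  stopifnot(length(offset) == 3L)
  s$contours <- lapply(s$contours, function(ct) {
    ct$vertices[, 1] <- ct$vertices[, 1] + offset[1]
    ct$vertices[, 2] <- ct$vertices[, 2] + offset[2]
    ct$z <- ct$z + offset[3]
    ct
  })
  s
}

#' Define the image grid a structure set refers to
#'
#' The grid supplies the voxel-relative unit used by displacement histograms
#' and similarity-measure tolerances, and the lattice used by rasterization.
#' `origin` is the patient-space position of the *center* of voxel
#' (0, 0, 0), following DICOM ImagePositionPatient semantics.
#'
#' @param dx,dy in-plane pixel spacing, mm (> 0).
#' @param dz slice spacing, mm (> 0).
#' @param origin numeric length-3, mm; center of the first voxel.
#' @param shape integer length-3 voxel counts (nx, ny, nz).
#' @return an object of class `image_grid`.
#' @export
image_grid <- function(dx, dy, dz, origin = c(0, 0, 0), shape = c(1L, 1L, 1L)) {
  if (any(c(dx, dy, dz) <= 0)) stop("grid spacings dx, dy, dz must be > 0")
  stopifnot(length(origin) == 3L, length(shape) == 3L)
  shape <- as.integer(shape)
  if (any(shape < 1L)) stop("grid shape must be >= 1 voxel per axis")
  structure(
    list(dx = as.numeric(dx), dy = as.numeric(dy), dz = as.numeric(dz),
         origin = as.numeric(origin), shape = shape),
    class = "image_grid"
  )
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d x %d x %d voxels, spacing (%g, %g, %g) mm, origin (%g, %g, %g)\n",
              x$shape[1], x$shape[2], x$shape[3], x$dx, x$dy, x$dz,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' In-plane voxel size used for tolerance normalization
#'
#' The conservative choice `min(dx, dy)` is used when the grid is
#' anisotropic in-plane.
#'
#' @param grid an `image_grid`.
#' @return voxel size in mm.
#' @export
in_plane_voxel_size <- function(grid) min(grid$dx, grid$dy)

#' Build a grid that covers a set of structures
#'
#' Voxel centers are placed so the structure's bounding box sits centrally
#' in the grid with at least `pad` voxels of margin per side. With the
#' default integer spacings this puts polygon faces drawn on whole-mm
#' positions onto voxel-boundary midlines, the usual arrangement for
#' contours drawn on a CT grid.
#'
#' @param structures an `rt_structure` or list of them.
#' @param dx,dy,dz spacings in mm.
#' @param pad margin, voxels.
#' @return an `image_grid`.
#' @export
grid_for_structures <- function(structures, dx = 1, dy = 1, dz = 2.5, pad = 2) {
  if (inherits(structures, "rt_structure")) structures <- list(structures)
  pts <- do.call(rbind, lapply(structures, function(s) {
    do.call(rbind, lapply(s$contours, function(ct) {
      cbind(ct$vertices, ct$z)
    }))
  }))
  if (is.null(pts) || !nrow(pts)) stop("no contours; cannot derive a grid")
  lo <- apply(pts, 2, min) - pad * c(dx, dy, dz)
  hi <- apply(pts, 2, max) + pad * c(dx, dy, dz)
  shape <- pmax(1L, as.integer(ceiling((hi - lo) / c(dx, dy, dz))) + 1L)
  # center voxel lattice on the bounding box; in-plane centers are offset by
  # half a voxel so boundaries drawn on the lattice fall on voxel-boundary
  # midlines (the CT arrangement), while z centers align with contour planes
  mid <- (lo + hi) / 2
  origin <- mid - (shape - 1L) / 2 * c(dx, dy, dz) + c(dx / 2, dy / 2, 0)
  image_grid(dx, dy, dz, origin = origin, shape = shape)
}

#' Warn if contours fall outside the grid extents
#'
#' @param s an `rt_structure`.
#' @param grid an `image_grid`.
#' @return invisibly, TRUE if fully inside.
#' @export
check_structure_in_grid <- function(s, grid) {
  lo <- grid$origin - c(grid$dx, grid$dy, grid$dz) / 2
  hi <- grid$origin + (grid$shape - 0.5) * c(grid$dx, grid$dy, grid$dz)
  ok <- TRUE
  for (ct in s$contours) {
    if (any(ct$vertices[, 1] < lo[1] | ct$vertices[, 1] > hi[1]) ||
        any(ct$vertices[, 2] < lo[2] | ct$vertices[, 2] > hi[2]) ||
        ct$z < lo[3] || ct$z > hi[3]) {
      ok <- FALSE
      break
    }
  }
  if (!ok) warning("structure '", s$name, "' extends beyond the image grid")
  invisible(ok)
}
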