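# Analytic structure generators. The generated world: axis-aligned cuboids
# (sparse corner-only and dense perimeter sampling), regular octahedra
# (diamond cross-sections), and multi-region fixtures (large primary plus
# small satellite) for topology-change testing. Slices are placed at both
# z-extremes inclusive: a structure of height H has floor(H / dz) + 1
# slices.

#' Specify an analytic shape
#'
#' @param kind `"cuboid"`, `"octahedron"` or `"multi_region"`.
#' @param center (x, y, z) mm.
#' @param size mm: cuboid side length; octahedron in-plane half-diagonal
#'   (the shape spans `z_center +/- size`); multi_region primary side.
#' @param sampling `"sparse"` (corner vertices only) or `"dense"`.
#' @param vertex_spacing perimeter vertex spacing in dense mode, mm.
#' @param dz slice spacing, mm.
#' @param satellite_size,satellite_gap multi_region only: satellite side
#'   (mm) and edge-to-edge gap from the primary (mm).
#' @return a `shape_spec` list.
#' @export
shape_spec <- function(kind = c("cuboid", "octahedron", "multi_region"),
                       center = c(0, 0, 0), size = 50,
                       sampling = c("sparse", "dense"),
                       vertex_spacing = 1, dz = 2.5,
                       satellite_size = 2, satellite_gap = 30) {
  kind <- match.arg(kind)
  sampling <- match.arg(sampling)
  stopifnot(size > 0, dz > 0)
  if (sampling == "dense" && vertex_spacing <= 0) {
    stop("vertex_spacing must be > 0 in dense mode")
  }
  structure(list(kind = kind, center = as.numeric(center), size = size,
                 sampling = sampling, vertex_spacing = vertex_spacing,
                 dz = dz, satellite_size = satellite_size,
                 satellite_gap = satellite_gap),
            class = "shape_spec")
}

# square contour centered at (cx, cy), side s; sparse -> 4 corner vertices,
# dense -> vertices every `spacing` along the perimeter, corners included
square_contour <- function(cx, cy, s, z, sampling = "sparse", spacing = 1) {
  h <- s / 2
  corners <- cbind(c(cx - h, cx + h, cx + h, cx - h),
                   c(cy - h, cy - h, cy + h, cy + h))
  if (sampling == "sparse") return(planar_contour(corners, z))
  if (spacing > s) stop("vertex_spacing (", spacing, ") exceeds side length (", s, ")")
  planar_contour(densify_closed_polygon(corners, spacing), z)
}

# axis-aligned diamond (|x-cx|/a + |y-cy|/a <= 1 boundary), half-width a
diamond_contour <- function(cx, cy, a, z, sampling = "sparse", spacing = 1) {
  corners <- cbind(c(cx + a, cx, cx - a, cx),
                   c(cy, cy + a, cy, cy - a))
  if (sampling == "sparse") return(planar_contour(corners, z))
  if (spacing > sqrt(2) * a) {
    stop("vertex_spacing (", spacing, ") exceeds the diamond edge length")
  }
  planar_contour(densify_closed_polygon(corners, spacing), z)
}

# slice z positions spanning [z0 - h, z0 + h] inclusive at spacing dz
slice_positions <- function(z0, h, dz) {
  n <- floor(2 * h / dz) + 1L
  z0 - (n - 1L) / 2 * dz + (seq_len(n) - 1L) * dz
}

#' Generate a cuboid structure
#'
#' One square contour per slice across the full z-extent (end slices
#' inclusive). Sparse sampling stores exactly the 4 corners per slice;
#' dense sampling adds vertices every `vertex_spacing` along the perimeter
#' with corners always included.
#'
#' @param spec a [shape_spec] with `kind = "cuboid"`.
#' @param name structure name.
#' @return an `rt_structure`.
#' @export
make_cuboid <- function(spec, name = "Cuboid") {
  stopifnot(inherits(spec, "shape_spec"), spec$kind == "cuboid")
  zs <- slice_positions(spec$center[3], spec$size / 2, spec$dz)
  contours <- lapply(zs, function(z) {
    square_contour(spec$center[1], spec$center[2], spec$size, z,
                   spec$sampling, spec$vertex_spacing)
  })
  rt_structure(name, contours)
}

#' Generate an octahedron structure
#'
#' Cross-sections are axis-aligned diamonds whose half-width shrinks
#' linearly with |z - z_center|: at offset `h` the half-width is
#' `a * (1 - h / a)` for half-diagonal `a = size`. Apex slices whose area
#' falls below `area_eps` are omitted as degenerate.
#'
#' @param spec a [shape_spec] with `kind = "octahedron"`.
#' @param name structure name.
#' @param area_eps degenerate-slice area threshold, mm^2.
#' @return an `rt_structure`.
#' @export
make_octahedron <- function(spec, name = "Octahedron", area_eps = 1e-6) {
  stopifnot(inherits(spec, "shape_spec"), spec$kind == "octahedron")
  a <- spec$size
  zs <- slice_positions(spec$center[3], a, spec$dz)
  contours <- list()
  for (z in zs) {
    w <- a * (1 - abs(z - spec$center[3]) / a)
    if (2 * w * w < area_eps) next                    # diamond area = 2 w^2
    contours[[length(contours) + 1L]] <-
      diamond_contour(spec$center[1], spec$center[2], w, z,
                      spec$sampling, spec$vertex_spacing)
  }
  rt_structure(name, contours)
}

#' Generate a multi-region fixture (primary + small satellite)
#'
#' A large primary cuboid plus a small satellite cuboid displaced along +x
#' by `satellite_gap` (edge-to-edge), sharing the satellite's slices — the
#' fixture for small-disconnected-region removal and topology-change
#' detection.
#'
#' @param spec a [shape_spec] with `kind = "multi_region"`.
#' @param name structure name.
#' @return an `rt_structure` with two contours on the shared slices.
#' @export
make_multi_region <- function(spec, name = "MultiRegion") {
  stopifnot(inherits(spec, "shape_spec"), spec$kind == "multi_region")
  if (spec$satellite_gap <= 0) {
    stop("satellite must not overlap the primary: satellite_gap must be > 0")
  }
  zs <- slice_positions(spec$center[3], spec$size / 2, spec$dz)
  sat_cx <- spec$center[1] + spec$size / 2 + spec$satellite_gap +
    spec$satellite_size / 2
  # satellite spans the middle third of the primary's slices (at least one)
  n <- length(zs)
  sat_idx <- seq.int(max(1L, floor(n / 3) + 1L), min(n, ceiling(2 * n / 3)))
  contours <- list()
  for (i in seq_len(n)) {
    contours[[length(contours) + 1L]] <-
      square_contour(spec$center[1], spec$center[2], spec$size, zs[i],
                     spec$sampling, spec$vertex_spacing)
    if (i %in% sat_idx) {
      contours[[length(contours) + 1L]] <-
        square_contour(sat_cx, spec$center[2], spec$satellite_size, zs[i],
                       spec$sampling, min(spec$vertex_spacing, spec$satellite_size))
    }
  }
  rt_structure(name, contours)
}

#' Generate the six-pair analytic dataset
#'
#' Objects A and B are sparse corner-only cuboids, C and D dense cuboids,
#' E a sparse and F a dense octahedron, at distinct centers. The test
#' member of each pair is the reference rigidly translated (default 5 mm
#' along x) so every similarity measure has a nonzero, analytically
#' checkable value.
#'
#' @param offset translation of each test member, mm (length 3 or scalar x
#'   offset).
#' @param size cuboid side and octahedron half-diagonal, mm.
#' @param dz slice spacing, mm.
#' @param vertex_spacing dense-mode perimeter spacing, mm.
#' @return named list of six pairs, each `list(reference =, test =)`.
#' @export
make_dataset1 <- function(offset = c(5, 0, 0), size = 50, dz = 2.5,
                          vertex_spacing = 1) {
  if (length(offset) == 1L) offset <- c(offset, 0, 0)
  centers <- list(A = c(0, 0, 0),    B = c(150, 0, 0),
                  C = c(0, 150, 0),  D = c(150, 150, 0),
                  E = c(0, 300, 0),  F = c(150, 300, 0))
  build <- function(obj) {
    switch(obj,
      A = make_cuboid(shape_spec("cuboid", centers$A, size, "sparse", dz = dz), "Object A"),
      B = make_cuboid(shape_spec("cuboid", centers$B, size, "sparse", dz = dz), "Object B"),
      C = make_cuboid(shape_spec("cuboid", centers$C, size, "dense",
                                 vertex_spacing = vertex_spacing, dz = dz), "Object C"),
      D = make_cuboid(shape_spec("cuboid", centers$D, size, "dense",
                                 vertex_spacing = vertex_spacing, dz = dz), "Object D"),
      E = make_octahedron(shape_spec("octahedron", centers$E, size, "sparse", dz = dz), "Object E"),
      F = make_octahedron(shape_spec("octahedron", centers$F, size, "dense",
                                     vertex_spacing = vertex_spacing, dz = dz), "Object F")
    )
  }
  out <- list()
  for (obj in c("A", "B", "C", "D", "E", "F")) {
    ref <- build(obj)
    tst <- translate_structure(ref, offset)
    tst$name <- paste0(ref$name, " test")
    out[[obj]] <- list(reference = ref, test = tst)
  }
  out
}
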