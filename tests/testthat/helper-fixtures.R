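# Small fixtures built in code.

square_at <- function(side = 1, z = 0, center = c(0, 0), sampling = "sparse",
                      spacing = 1) {
  h <- side / 2
  V <- cbind(center[1] + c(-h, h, h, -h), center[2] + c(-h, -h, h, h))
  if (sampling == "dense") V <- densify_closed_polygon(V, spacing)
  planar_contour(V, z)
}

small_cube <- function(side = 10, dz = 2.5, center = c(0, 0, 0),
                       sampling = "sparse", name = "cube") {
  make_cuboid(shape_spec("cuboid", center, side, sampling,
                         vertex_spacing = 1, dz = dz), name)
}

unit_grid <- function(structures, dz = 2.5) {
  grid_for_structures(structures, dx = 1, dy = 1, dz = dz)
}

face_centroids_for_test <- function(mesh) {
  F <- mesh$faces; V <- mesh$vertices
  (V[F[, 1], , drop = FALSE] + V[F[, 2], , drop = FALSE] +
     V[F[, 3], , drop = FALSE]) / 3
}
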