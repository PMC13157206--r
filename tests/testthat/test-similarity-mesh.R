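# Mesh pathway: rasterization, distance field, surface extraction, sDSC,
# 3DMSD. Small grids keep runtimes low; phase and spacing match defaults.

test_that("rasterize: voxel counts, holes, empty structures", {
  s <- small_cube(side = 10, dz = 2.5)
  grid <- unit_grid(s)
  r <- rasterize(s, grid)
  # 10x10 in-plane, 5 contoured slices at dz = 2.5
  expect_equal(sum(r$volume), 10 * 10 * 5)
  # oracle: winding-number membership of every voxel center on one slice
  xs <- grid_axis(r$grid, "x"); ys <- grid_axis(r$grid, "y")
  pts <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  ora <- matrix(oracle_points_in_contours(pts, s$contours[1]), length(xs))
  zs <- grid_axis(r$grid, "z")
  k <- which.min(abs(zs - s$contours[[1]]$z))
  expect_equal(r$volume[, , k], ora)

  # annulus: hole voxels are false
  ring <- rt_structure("Ring", list(square_at(side = 10), square_at(side = 4)))
  rr <- rasterize(ring, unit_grid(ring))
  kk <- which.min(abs(grid_axis(rr$grid, "z")))
  expect_equal(sum(rr$volume[, , kk]), 100 - 16)

  empty <- rt_structure("E", list())
  re <- rasterize(empty, grid)
  expect_false(any(re$volume))
})

test_that("signed distance field matches brute-force EDT oracle", {
  s <- small_cube(side = 6, dz = 2.5)
  grid <- unit_grid(s)
  r <- rasterize(s, grid)
  phi <- signed_distance_field(r$volume, r$grid)
  sp <- c(r$grid$dx, r$grid$dy, r$grid$dz)
  expect_equal(array(phi >= 0, dim(phi)), !r$volume)   # sign convention
  d_in <- oracle_edt(r$volume, sp)
  d_out <- oracle_edt(!r$volume, sp)
  expect_equal(phi, d_in - d_out, tolerance = 1e-9)
})

test_that("extract_mesh: bbox, watertightness, area near analytic", {
  s <- small_cube(side = 50, dz = 2.5)
  grid <- unit_grid(s)
  mesh <- structure_mesh(s, grid)
  expect_true(is_watertight(mesh))
  bb <- apply(mesh$vertices, 2, range)
  expect_equal(bb[, 1], c(-25, 25), tolerance = grid$dx)      # x extent
  expect_equal(bb[, 2], c(-25, 25), tolerance = grid$dy)
  # z extent: slices at +/-25 extruded by dz/2
  expect_equal(bb[, 3], c(-26.25, 26.25), tolerance = grid$dz)
  # area within 5% of the analytic box (50 x 50 x 52.5 by extrusion;
  # the residual is edge/corner rounding of the marching-tetra surface)
  analytic <- 2 * 50^2 + 4 * 50 * 52.5
  expect_lt(abs(mesh_area(mesh) - analytic) / analytic, 0.05)
  expect_error(extract_mesh(array(FALSE, c(4, 4, 4)), grid), "empty volume")
})

test_that("mesh distance kernel agrees with barycentric-sampling oracle", {
  s <- small_cube(side = 6, dz = 2.5)
  mesh <- structure_mesh(s, unit_grid(s))
  set.seed(13)
  pts <- cbind(runif(25, -8, 8), runif(25, -8, 8), runif(25, -8, 8))
  got <- cpp_mesh_point_distances(pts, mesh$vertices, mesh$faces)
  ora <- oracle_point_to_mesh(pts, mesh, k = 15)
  # oracle is an upper bound within the sampling resolution
  expect_true(all(got <= ora + 1e-9))
  expect_lt(max(abs(got - ora)), 0.15)
})

test_that("sdsc identity 1, separated 0, monotone in tolerance", {
  s <- small_cube(side = 10, dz = 2.5)
  grid <- unit_grid(s)
  mesh <- structure_mesh(s, grid)
  expect_identical(sdsc(mesh, mesh, 0.1), 1)
  far <- structure_mesh(translate_structure(s, c(100, 0, 0)), grid)
  expect_equal(sdsc(mesh, far, 1), 0)
  sd <- surface_distances(mesh, far)
  vals <- vapply(c(0.1, 1, 10, 50, 200), function(t) {
    sdsc(mesh, far, t, dists = sd)
  }, numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_equal(vals[length(vals)], 1)                  # tol -> Inf
})

test_that("translated meshes: sdsc at tol >= offset is 1, msd3d <= offset", {
  s <- small_cube(side = 10, dz = 2.5)
  grid <- unit_grid(s)
  m0 <- structure_mesh(s, grid)
  m1 <- structure_mesh(translate_structure(s, c(2, 0, 0)), grid)
  expect_gt(sdsc(m0, m1, 2), 0.99)
  expect_lte(msd3d(m0, m1), 2 + 1e-9)
  expect_gt(msd3d(m0, m1), 0)
  expect_equal(msd3d(m0, m1), msd3d(m1, m0))           # exact symmetry
  # against the brute-force oracle on the same meshes
  sd <- surface_distances(m0, m1)
  ora_a <- oracle_point_to_mesh(face_centroids_for_test(m0), m1, k = 10)
  frac_got <- sdsc(m0, m1, 1, dists = sd)
  frac_ora <- (sum(m0$areas[ora_a <= 1 + 0.1]) + sum(sd$area_b[sd$d_b <= 1 + 0.1])) /
    (sum(m0$areas) + sum(m1$areas))
  expect_lt(abs(frac_got - frac_ora), 0.05)
})

test_that("parallel slabs: facing-surface distance dominates 3DMSD", {
  slab <- function(cx) {
    make_cuboid(shape_spec("cuboid", c(cx, 0, 0), 10, "dense",
                           vertex_spacing = 0.5, dz = 2.5), "slab")
  }
  grid <- grid_for_structures(list(slab(0), slab(13)), dz = 2.5)
  m0 <- structure_mesh(slab(0), grid)
  m1 <- structure_mesh(slab(13), grid)
  d <- msd3d(m0, m1)
  # gap between facing walls is 3 mm; opposite walls are 13 + 10 mm away:
  # area-weighted mean must sit between gap and center offset
  expect_gt(d, 3)
  expect_lt(d, 13 + 10)
})

test_that("identity via the full pipeline: sdsc(extract(S), extract(S)) = 1", {
  d1 <- make_dataset1()
  E <- d1$E$reference
  grid <- unit_grid(E)
  m <- structure_mesh(E, grid)
  expect_identical(sdsc(m, m, 0.01), 1)
  expect_lt(msd3d(m, m), 1e-12)
})
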