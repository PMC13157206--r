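# Vertex displacement summaries, cumulative curves, topology detection.

test_that("identical structures give zero displacement and sane bookkeeping", {
  s <- small_cube()
  grid <- unit_grid(s)
  ds <- displacement_summary(s, s, grid)
  expect_equal(ds$mean_mm, 0)
  expect_equal(ds$max_mm, 0)
  expect_identical(ds$n_vertices_original, ds$n_vertices_reexported)
  expect_false(ds$topology_changed)
  expect_true(all(ds$per_slice_region_delta$delta == 0))
  expect_equal(max(ds$cumulative$fraction), 1)
})

test_that("translated squares: max equals offset, mean below it (feet are nearer)", {
  s <- small_cube(side = 10, sampling = "dense")
  grid <- unit_grid(s)
  moved <- translate_structure(s, c(0.3, 0, 0))
  ds <- displacement_summary(s, moved, grid)
  expect_equal(ds$max_mm, 0.3, tolerance = 1e-9)
  expect_lte(ds$mean_mm, 0.3)
  expect_gt(ds$mean_mm, 0)
  # oracle check of the mean on one slice
  pts <- s$contours[[1]]$vertices
  d_ora <- oracle_points_to_contours(pts, moved$contours[1])
  ds1 <- displacement_summary(
    rt_structure("a", s$contours[1]), rt_structure("b", moved$contours[1]), grid)
  expect_equal(ds1$mean_mm, mean(d_ora), tolerance = 1e-12)
})

test_that("mean/max invariant under rigid translation of both structures", {
  set.seed(21)
  s <- small_cube(side = 10, sampling = "dense")
  grid <- unit_grid(s)
  jit <- perturb(s, perturbation_config("resample_path", target_spacing = 0.7))
  d0 <- displacement_summary(s, jit, grid)
  off <- c(12.3, -4.56, 0)
  d1 <- displacement_summary(translate_structure(s, off),
                             translate_structure(jit, off), grid)
  expect_equal(d1$mean_mm, d0$mean_mm, tolerance = 1e-9)
  expect_equal(d1$max_mm, d0$max_mm, tolerance = 1e-9)
})

test_that("cumulative curve is a normalized non-decreasing ECDF in voxels", {
  s <- small_cube(side = 10, sampling = "dense")
  grid <- unit_grid(s)
  moved <- translate_structure(s, c(0.4, 0, 0))
  ds <- displacement_summary(s, moved, grid)
  cum <- ds$cumulative
  expect_true(all(diff(cum$fraction) >= 0))
  expect_true(all(cum$fraction >= 0 & cum$fraction <= 1))
  expect_equal(max(cum$fraction), 1)                   # no sentinels here
  expect_equal(max(cum$distance_voxels),
               ds$max_mm / in_plane_voxel_size(grid))
})

test_that("asymmetric displacement after satellite removal mirrors separation", {
  mr <- make_multi_region(shape_spec("multi_region", size = 40,
                                     satellite_size = 2, satellite_gap = 30))
  grid <- unit_grid(mr)
  p <- perturb(mr, perturbation_config("drop_small_regions", min_region_area = 10))
  ds <- displacement_summary(mr, p, grid)
  # oracle: nearest distance from satellite vertices to the primary contour
  g <- group_by_slice(mr, 0.25)
  shared <- g[[which(vapply(g, function(x) length(x$contours), integer(1)) == 2L)[1]]]
  ora <- max(oracle_points_to_contours(shared$contours[[2]]$vertices,
                                       shared$contours[1]))
  expect_equal(ds$max_mm, ora, tolerance = 1e-9)
  expect_gte(ds$max_mm, 30)                            # >= configured gap
  # reverse direction: re-export vertices all lie on the original
  rev <- displacement_summary(p, mr, grid)
  expect_equal(rev$max_mm, 0, tolerance = 1e-9)
  expect_true(ds$topology_changed)
})

test_that("detect_topology_change: identity false, removal true, jitter false", {
  mr <- make_multi_region(shape_spec("multi_region", size = 40,
                                     satellite_size = 2, satellite_gap = 30))
  grid <- unit_grid(mr)
  t0 <- detect_topology_change(mr, mr, grid)
  expect_false(t0$flag)
  expect_true(all(t0$per_slice_region_delta$delta == 0))

  p <- perturb(mr, perturbation_config("drop_small_regions", min_region_area = 10))
  t1 <- detect_topology_change(mr, p, grid)
  expect_true(t1$flag)
  expect_true(all(t1$per_slice_region_delta$delta %in% c(0L, -1L)))
  expect_true(any(t1$per_slice_region_delta$delta == -1L))

  # small uniform jitter: no topology change
  set.seed(31)
  jit <- mr
  jit$contours <- lapply(jit$contours, function(ct) {
    ct$vertices <- ct$vertices +
      matrix(runif(length(ct$vertices), -0.1, 0.1), ncol = 2)
    ct
  })
  expect_false(detect_topology_change(mr, jit, grid)$flag)
})

test_that("unmatched slices: sentinel bookkeeping and curve below 1", {
  s <- small_cube(side = 10, dz = 2.5)
  grid <- unit_grid(s)
  # drop the top slice from the re-export
  zs <- vapply(s$contours, `[[`, numeric(1), "z")
  p <- rt_structure(s$name, s$contours[zs < max(zs)])
  ds <- displacement_summary(s, p, grid)
  expect_equal(ds$n_unmatched_vertices, 4L)
  expect_equal(ds$mean_mm, 0)                          # finite part unmoved
  expect_lt(max(ds$cumulative$fraction), 1)
  expect_true(ds$topology_changed)
  # no matching slices at all -> analysis error
  far <- translate_structure(s, c(0, 0, 100))
  expect_error(displacement_summary(s, far, grid), "matching")
})
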