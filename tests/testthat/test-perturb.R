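# Re-export behaviour simulator.

test_that("truncate_precision rounds; empty config is identity; determinism", {
  ct <- planar_contour(rbind(c(1.2345, 6.7891), c(5, 0), c(5, 5)), z = 0)
  s <- rt_structure("S", list(ct))
  p <- perturb(s, perturbation_config("truncate_precision", decimal_places = 2))
  expect_equal(p$contours[[1]]$vertices[1, ], c(1.23, 6.79))

  expect_equal(perturb(s, list()), s)

  grid <- unit_grid(small_cube())
  cfgs <- list(perturbation_config("mask_roundtrip_2d", grid = grid, seed = 9))
  p1 <- perturb(small_cube(), cfgs)
  p2 <- perturb(small_cube(), cfgs)
  expect_identical(p1, p2)                  # bit-reproducible given seed
})

test_that("resample_path yields uniform spacing; subsample/densify change counts only", {
  s <- small_cube(side = 10, sampling = "dense")
  r <- perturb(s, perturbation_config("resample_path", target_spacing = 0.5))
  V <- r$contours[[1]]$vertices
  seg <- sqrt(diff(c(V[, 1], V[1, 1]))^2 + diff(c(V[, 2], V[1, 2]))^2)
  expect_equal(max(seg), min(seg), tolerance = 1e-9)  # uniform arc length
  expect_equal(nrow(V), 80L)                          # 40 mm / 0.5 mm

  sub <- perturb(s, perturbation_config("subsample_vertices", keep_every_k = 2))
  expect_equal(n_vertices(sub$contours[[1]]), n_vertices(s$contours[[1]]) %/% 2L)
  # surviving vertices are a subset of the originals
  expect_true(all(sub$contours[[1]]$vertices[, 1] %in% s$contours[[1]]$vertices[, 1]))

  den <- perturb(s, perturbation_config("densify_vertices", max_segment = 0.25))
  expect_equal(n_vertices(den$contours[[1]]), 160L)
  d <- points_to_contours_distance(den$contours[[1]]$vertices, s$contours[1])
  expect_lt(max(d), 1e-12)                            # boundary unmoved
})

test_that("mask_roundtrip_2d keeps boundary within half a voxel", {
  s <- small_cube(side = 10, sampling = "dense")
  grid <- unit_grid(s)
  p <- perturb(s, perturbation_config("mask_roundtrip_2d", grid = grid))
  ds <- displacement_summary(s, p, grid)
  expect_lt(ds$mean_mm, 0.5 * in_plane_voxel_size(grid))
  # slice count preserved for a shape much larger than a voxel
  expect_equal(length(group_by_slice(p, 0.25)), length(group_by_slice(s, 0.25)))
  # areas approximately preserved
  a0 <- slice_area(group_by_slice(s, 0.25)[[1]]$contours)
  a1 <- slice_area(group_by_slice(p, 0.25)[[1]]$contours)
  expect_lt(abs(a1 - a0) / a0, 0.05)
})

test_that("mask_roundtrip_3d closes small gaps (volumetric smoothing)", {
  s <- small_cube(side = 10, sampling = "dense")
  grid <- unit_grid(s)
  p <- perturb(s, perturbation_config("mask_roundtrip_3d", grid = grid))
  expect_gt(length(p$contours), 0L)
  ds <- displacement_summary(s, p, grid)
  expect_lt(ds$mean_mm, 1)                            # within one voxel
})

test_that("drop_small_regions removes satellites below threshold, never moves survivors", {
  mr <- make_multi_region(shape_spec("multi_region", size = 40,
                                     satellite_size = 2, satellite_gap = 30))
  p <- perturb(mr, perturbation_config("drop_small_regions", min_region_area = 10))
  # satellite area = 4 mm^2 < 10 -> removed everywhere
  expect_true(all(vapply(group_by_slice(p, 0.25), function(g) {
    length(g$contours)
  }, integer(1)) == 1L))
  # survivors identical to the original primary contours
  g0 <- group_by_slice(mr, 0.25); g1 <- group_by_slice(p, 0.25)
  for (k in seq_along(g1)) {
    expect_equal(g1[[k]]$contours[[1]]$vertices, g0[[k]]$contours[[1]]$vertices)
  }
  # threshold below satellite area keeps it
  keep <- perturb(mr, perturbation_config("drop_small_regions", min_region_area = 3))
  expect_identical(structure_vertex_count(keep), structure_vertex_count(mr))
})

test_that("holes are preserved as regions with net area accounting", {
  ring <- rt_structure("Ring", list(square_at(side = 10), square_at(side = 8)))
  # net area = 100 - 64 = 36 >= 20: whole region (outer + hole) kept
  p <- perturb(ring, perturbation_config("drop_small_regions", min_region_area = 20))
  expect_length(p$contours, 2L)
  # net area below a high threshold: both dropped together
  p2 <- perturb(ring, perturbation_config("drop_small_regions", min_region_area = 50))
  expect_length(p2$contours, 0L)
})

test_that("unknown mode is rejected at config time", {
  expect_error(perturbation_config("warp_boundary"), "arg")
  expect_error(perturbation_config("mask_roundtrip_2d"), "requires a grid")
})
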