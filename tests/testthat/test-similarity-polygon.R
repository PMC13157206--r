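# Polygon-pathway measures: nAPL, vDSC, 2D distance family.

test_that("path_length: squares and densified contours", {
  expect_equal(path_length(square_at(side = 1)), 4)
  expect_equal(path_length(square_at(side = 50)), 200)
  dens <- planar_contour(densify_closed_polygon(square_at(side = 50)$vertices, 0.7), 0)
  expect_equal(path_length(dens), 200)
})

test_that("napl identity is exactly 0 and disjoint is exactly 1", {
  s <- small_cube(side = 10)
  for (tol in c(0, 0.01, 0.5, 3)) {
    expect_identical(napl(s, s, tol), 0)
  }
  far <- translate_structure(s, c(100, 0, 0))
  expect_identical(napl(s, far, 0.5), 1)
  expect_error(napl(rt_structure("E", list()), s, 0.5), "empty reference")
})

test_that("napl matches the dense-sampling oracle on offset squares", {
  d1 <- make_dataset1(offset = c(1, 0, 0))
  for (obj in c("A", "E")) {
    ref <- d1[[obj]]$reference; tst <- d1[[obj]]$test
    for (tol in c(0.25, 0.5, 1.5)) {
      got <- napl(ref, tst, tol)
      ora <- oracle_napl(ref, tst, tol, n_per_mm = 50)
      expect_lt(abs(got - ora), 0.02)
    }
  }
})

test_that("napl is anti-monotone in tolerance over the default sweep", {
  d1 <- make_dataset1()
  grid <- unit_grid(list(d1$A$reference, d1$A$test))
  for (obj in c("A", "C")) {
    sweep <- napl_sweep(d1[[obj]]$reference, d1[[obj]]$test, grid)
    expect_true(all(diff(sweep) <= 1e-12))
    expect_true(all(sweep >= 0 & sweep <= 1))
  }
})

test_that("vdsc: identity 1, disjoint 0, symmetry, translation invariance", {
  s <- small_cube(side = 10, sampling = "dense")
  grid <- unit_grid(s)
  expect_equal(vdsc(s, s, grid), 1, tolerance = 1e-12)
  far <- translate_structure(s, c(100, 0, 0))
  expect_equal(vdsc(s, far, grid), 0)
  moved <- translate_structure(s, c(2, 1, 0))
  expect_equal(vdsc(s, moved, grid), vdsc(moved, s, grid), tolerance = 1e-12)
  off <- c(7.7, -3.1, 0)
  expect_equal(vdsc(translate_structure(s, off), translate_structure(moved, off), grid),
               vdsc(s, moved, grid), tolerance = 1e-9)
  expect_error(vdsc(rt_structure("E", list()), rt_structure("E2", list()), grid),
               "undefined")
})

test_that("vdsc matches the voxel-counting oracle on an octahedron pair", {
  d1 <- make_dataset1(offset = c(3, 0, 0))
  got <- vdsc(d1$E$reference, d1$E$test,
              unit_grid(list(d1$E$reference, d1$E$test)))
  ora <- oracle_vdsc(d1$E$reference, d1$E$test, h = 0.5, dz = 2.5)
  expect_lt(abs(got - ora) / ora, 0.02)
})

test_that("distances_2d: identity zeros, offset squares, ordering invariants", {
  s <- small_cube(side = 10)
  d0 <- distances_2d(s, s, sample_spacing = 0.2)
  expect_equal(d0$hd2d_mm, 0)
  expect_equal(d0$msd2d_mm, 0)

  # single-slice 50 mm squares offset 2 mm: hd2d = 2 (corner-to-edge)
  a <- rt_structure("a", list(square_at(side = 50)))
  b <- rt_structure("b", list(square_at(side = 50, center = c(2, 0))))
  d2 <- distances_2d(a, b, sample_spacing = 0.05)
  expect_equal(d2$hd2d_mm, 2, tolerance = 0.05)
  expect_true(d2$hd50_2d_mm <= d2$hd95_2d_mm)
  expect_true(d2$hd95_2d_mm <= d2$hd2d_mm)
  expect_true(d2$msd2d_mm <= d2$hd2d_mm)
  # oracle comparison of the mean
  ora_ab <- oracle_points_to_contours(
    resample_closed_polygon(a$contours[[1]]$vertices, 0.05), b$contours[1])
  ora_ba <- oracle_points_to_contours(
    resample_closed_polygon(b$contours[[1]]$vertices, 0.05), a$contours[1])
  expect_equal(d2$msd2d_mm, mean(c(ora_ab, ora_ba)), tolerance = 1e-9)

  # unmatched slices produce a warning and are excluded from aggregates
  tall <- small_cube(side = 10)
  zs <- vapply(tall$contours, `[[`, numeric(1), "z")
  short <- rt_structure("s", tall$contours[zs < max(zs)])
  expect_warning(d3 <- distances_2d(tall, short, sample_spacing = 0.5),
                 "excluded")
  expect_equal(d3$n_infinite, 80L)   # 40 mm perimeter / 0.5 mm on the lost slice
})

test_that("pooled msd2d equals count-weighted mean of directional means", {
  a <- rt_structure("a", list(square_at(side = 20)))
  b <- rt_structure("b", list(square_at(side = 14, center = c(1, 2))))
  d <- distances_2d(a, b, sample_spacing = 0.1)
  ga <- resample_closed_polygon(a$contours[[1]]$vertices, 0.1)
  gb <- resample_closed_polygon(b$contours[[1]]$vertices, 0.1)
  dab <- oracle_points_to_contours(ga, b$contours[1])
  dba <- oracle_points_to_contours(gb, a$contours[1])
  expect_equal(d$msd2d_mm,
               (sum(dab) + sum(dba)) / (length(dab) + length(dba)),
               tolerance = 1e-9)
  expect_equal(d$max_a_to_b_mm, max(dab), tolerance = 1e-9)
  expect_equal(d$max_b_to_a_mm, max(dba), tolerance = 1e-9)
})

test_that("tolerance_spec validates and resolves against the grid", {
  expect_error(tolerance_spec(c(0.5, 0.1)), "increasing")
  expect_error(tolerance_spec(c(-1, 1)), "positive")
  grid <- image_grid(0.8, 1.2, 3)
  tols <- resolve_tolerances(tolerance_spec(), grid)
  expect_equal(unname(tols), c(0.01, 0.1, 0.5, 1, 2, 3) * 0.8)  # min(dx, dy)
})
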