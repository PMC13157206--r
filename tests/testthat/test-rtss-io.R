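# DICOM RTSS read/write round trips.

test_that("write/read round trip preserves geometry exactly at high precision", {
  sq <- rt_structure("Square", list(square_at(side = 10, z = 0)))
  grid <- unit_grid(sq)
  tf <- withr::local_tempfile(fileext = ".dcm")
  write_rtss(sq, grid, tf, decimal_places = 6)
  back <- read_rtss(tf)
  expect_length(back, 1L)
  expect_identical(back[[1]]$name, "Square")
  expect_equal(nrow(back[[1]]$contours[[1]]$vertices), 4L)
  expect_equal(back[[1]]$contours[[1]]$z, 0)
  expect_equal(back[[1]]$contours[[1]]$vertices,
               sq$contours[[1]]$vertices, tolerance = 1e-12)
})

test_that("multiple ROIs keep names, order, contour and vertex counts", {
  d1 <- make_dataset1()
  s1 <- d1$A$reference; s2 <- d1$E$reference
  grid <- unit_grid(list(s1, s2))
  tf <- withr::local_tempfile(fileext = ".dcm")
  write_rtss(list(s1, s2), grid, tf)
  back <- read_rtss(tf)
  expect_length(back, 2L)
  expect_identical(vapply(back, `[[`, character(1), "name"),
                   c("Object A", "Object E"))
  expect_identical(length(back[[1]]$contours), length(s1$contours))
  expect_identical(structure_vertex_count(back[[1]]), structure_vertex_count(s1))
  # sparse cuboid: every slice polygon has exactly 4 vertices
  expect_true(all(vapply(back[[1]]$contours, function(ct) nrow(ct$vertices),
                         integer(1)) == 4L))
})

test_that("decimal_places rounds coordinates on write", {
  ct <- planar_contour(rbind(c(1.23456789, 2.0), c(5, 0), c(5, 5)), z = 1.2345)
  s <- rt_structure("R", list(ct))
  grid <- image_grid(1, 1, 2.5, origin = c(-10, -10, -5), shape = c(30, 30, 10))
  tf <- withr::local_tempfile(fileext = ".dcm")
  write_rtss(s, grid, tf, decimal_places = 3)
  back <- read_rtss(tf)
  expect_equal(back[[1]]$contours[[1]]$vertices[1, ], c(1.235, 2.0))
  expect_equal(back[[1]]$contours[[1]]$z, 1.234) # round-half-even on .5 digit

  # round trip bound at decimal_places = 6: error <= 5e-7 per coordinate
  set.seed(7)
  V <- matrix(runif(12, -40, 40), ncol = 2)
  s2 <- rt_structure("Rand", list(planar_contour(V, z = runif(1, -10, 10))))
  write_rtss(s2, grid, tf, decimal_places = 6)
  b2 <- read_rtss(tf)
  expect_lt(max(abs(b2[[1]]$contours[[1]]$vertices - V)), 5e-7 + 1e-12)
})

test_that("round-trip identity holds for random polygons (property)", {
  set.seed(42)
  grid <- image_grid(1, 1, 2.5, origin = c(-30, -30, -10), shape = c(60, 60, 10))
  for (rep in 1:5) {
    contours <- lapply(1:3, function(k) {
      planar_contour(random_star_polygon(sample(3:12, 1)), z = 2.5 * (k - 1))
    })
    s <- rt_structure(sprintf("S%d", rep), contours)
    tf <- withr::local_tempfile(fileext = ".dcm")
    write_rtss(s, grid, tf, decimal_places = 8)
    back <- read_rtss(tf)[[1]]
    expect_identical(length(back$contours), 3L)
    for (k in 1:3) {
      expect_equal(back$contours[[k]]$vertices, contours[[k]]$vertices,
                   tolerance = 1e-7)
    }
  }
})

test_that("io errors: bad files, bad precision, oversized decimal strings", {
  tf <- withr::local_tempfile(fileext = ".dcm")
  writeBin(as.raw(rep(0, 200)), tf)
  expect_error(read_rtss(tf), "DICM")

  sq <- rt_structure("S", list(square_at()))
  grid <- unit_grid(sq)
  expect_error(write_rtss(sq, grid, tf, decimal_places = 0), "decimal_places")
  expect_error(write_rtss(sq, grid, tf, decimal_places = 11), "decimal_places")

  far <- rt_structure("Far", list(
    planar_contour(rbind(c(123456.123456789, 0), c(1, 0), c(1, 1)) * 1e3, z = 0)
  ))
  expect_error(write_rtss(far, grid, tf, decimal_places = 10), "16 bytes")
})

test_that("grid sidecar round trips", {
  grid <- image_grid(0.9765625, 0.9765625, 3, origin = c(-250, -250, -100),
                     shape = c(512L, 512L, 60L))
  tf <- withr::local_tempfile(fileext = ".json")
  write_grid_sidecar(grid, tf)
  g2 <- read_grid_sidecar(tf)
  expect_equal(g2$dx, grid$dx)
  expect_equal(g2$origin, grid$origin)
  expect_identical(g2$shape, grid$shape)
})

test_that("round trip leaves displacement at numerical zero (precision >= 6)", {
  d1 <- make_dataset1()
  A <- d1$A$reference
  grid <- unit_grid(A)
  tf <- withr::local_tempfile(fileext = ".dcm")
  write_rtss(A, grid, tf, decimal_places = 6)
  back <- read_rtss(tf)[[1]]
  ds <- displacement_summary(clean_structure(A), clean_structure(back), grid)
  expect_lt(ds$mean_mm, 1e-5)
  expect_lt(ds$max_mm, 1e-5)
})
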