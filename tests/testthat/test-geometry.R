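# Polygon primitives: areas, distances, resampling, intersection areas.

test_that("point distances match the independent oracle on random cases", {
  set.seed(3)
  for (rep in 1:5) {
    contours <- list(planar_contour(random_star_polygon(8), z = 0),
                     planar_contour(random_star_polygon(5) + 30, z = 0))
    pts <- matrix(runif(60, -25, 55), ncol = 2)
    expect_equal(points_to_contours_distance(pts, contours),
                 oracle_points_to_contours(pts, contours), tolerance = 1e-12)
  }
})

test_that("point_to_polyline_distance covers foot, edge and corner branches", {
  sq <- square_at(side = 1, center = c(0.5, 0.5))    # unit square [0,1]^2
  expect_equal(point_to_polyline_distance(c(0.5, 1), sq), 0)
  expect_equal(point_to_polyline_distance(c(0.5, 2), sq), 1)
  expect_equal(point_to_polyline_distance(c(2, 2), sq), sqrt(2))
  expect_error(point_to_polyline_distance(c(0, 0),
                                          planar_contour(rbind(c(0, 0), c(1, 0)), 0)),
               "3 vertices")
})

test_that("even-odd membership agrees with the winding oracle incl. holes", {
  outer <- square_at(side = 10)
  hole <- square_at(side = 4)
  set.seed(5)
  pts <- matrix(runif(400, -7, 7), ncol = 2)
  got <- points_in_contours(pts, list(outer, hole))
  expect_equal(got, oracle_points_in_contours(pts, list(outer, hole)))
  # annulus: inside ring, outside hole
  expect_true(points_in_contours(rbind(c(3, 0)), list(outer, hole)))
  expect_false(points_in_contours(rbind(c(0, 0)), list(outer, hole)))
})

test_that("slice_area applies nesting parity (holes subtract)", {
  outer <- square_at(side = 10)
  hole <- square_at(side = 4)
  island <- square_at(side = 1)
  expect_equal(slice_area(list(outer)), 100)
  expect_equal(slice_area(list(outer, hole)), 84)
  expect_equal(slice_area(list(outer, hole, island)), 85)
  expect_equal(slice_area(list()), 0)
})

test_that("slice_intersection_area is exact on translated/identical squares", {
  a <- square_at(side = 50)
  expect_equal(slice_intersection_area(list(a), list(a)), 2500)
  b <- square_at(side = 50, center = c(5, 0))
  expect_equal(slice_intersection_area(list(a), list(b)), 45 * 50)
  c_ <- square_at(side = 50, center = c(100, 0))
  expect_equal(slice_intersection_area(list(a), list(c_)), 0)
  # rotated square (diamond) against square: lens area is analytic
  dmd <- planar_contour(rbind(c(25, 0), c(0, 25), c(-25, 0), c(0, -25)), 0)
  # diamond fully inside the square's bbox, intersection = diamond area
  expect_equal(slice_intersection_area(list(a), list(dmd)), 2 * 25^2)
})

test_that("slice_intersection_area matches voxel-count oracle on random polygons", {
  set.seed(9)
  for (rep in 1:3) {
    pa <- planar_contour(random_star_polygon(9), z = 0)
    pb <- planar_contour(random_star_polygon(7) + 4, z = 0)
    got <- slice_intersection_area(list(pa), list(pb))
    h <- 0.2
    xs <- seq(-25, 30, by = h); ys <- seq(-25, 30, by = h)
    pts <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
    ora <- sum(oracle_points_in_contours(pts, list(pa)) &
                 oracle_points_in_contours(pts, list(pb))) * h^2
    expect_lt(abs(got - ora), 0.02 * max(got, 1))
  }
})

test_that("resampling and densification preserve perimeter and boundary", {
  V <- square_at(side = 50)$vertices
  expect_equal(polygon_perimeter(V), 200)
  dens <- densify_closed_polygon(V, 1)
  expect_equal(nrow(dens), 200L)
  expect_equal(polygon_perimeter(dens), 200)           # no boundary movement
  # all original corners retained
  expect_true(all(apply(V, 1, function(v) {
    any(dens[, 1] == v[1] & dens[, 2] == v[2])
  })))
  res <- resample_closed_polygon(V, 0.5)
  expect_equal(nrow(res), 400L)
  # resampled points lie on the original boundary
  d <- points_to_contours_distance(res, list(square_at(side = 50)))
  expect_lt(max(d), 1e-9)
})
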