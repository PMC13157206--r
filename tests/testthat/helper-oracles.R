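# Independent oracles, deliberately implemented with different algorithms
# than the package (winding-number instead of crossing-number, plain-R
# vectorized distances, brute-force EDT, barycentric triangle sampling).

# winding-number point-in-polygon; even-odd over multiple contours via
# parity of per-contour winding
oracle_points_in_contours <- function(pts, contours) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  parity <- integer(nrow(pts))
  for (ct in contours) {
    V <- ct$vertices
    n <- nrow(V)
    total <- numeric(nrow(pts))
    for (i in seq_len(n)) {
      a <- V[i, ]; b <- V[if (i == n) 1L else i + 1L, ]
      ax <- a[1] - pts[, 1]; ay <- a[2] - pts[, 2]
      bx <- b[1] - pts[, 1]; by <- b[2] - pts[, 2]
      total <- total + atan2(ax * by - ay * bx, ax * bx + ay * by)
    }
    w <- round(total / (2 * pi))
    parity <- parity + (w %% 2 != 0)
  }
  parity %% 2 == 1
}

# plain-R point-to-segment-set distance (chunked matrix arithmetic)
oracle_points_to_contours <- function(pts, contours) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  E <- do.call(rbind, lapply(contours, function(ct) {
    V <- ct$vertices
    n <- nrow(V)
    i2 <- c(seq_len(n)[-1], 1L)
    cbind(V[, 1], V[, 2], V[i2, 1], V[i2, 2])
  }))
  ex <- E[, 3] - E[, 1]; ey <- E[, 4] - E[, 2]
  len2 <- pmax(ex^2 + ey^2, 1e-300)
  m <- nrow(pts)
  best <- numeric(m)
  chunk <- max(1L, as.integer(2e6 / nrow(E)))
  for (start in seq(1L, m, by = chunk)) {
    idx <- start:min(m, start + chunk - 1L)
    tx <- outer(pts[idx, 1], E[, 1], "-")
    ty <- outer(pts[idx, 2], E[, 2], "-")
    tt <- sweep(sweep(tx, 2, ex, "*") + sweep(ty, 2, ey, "*"), 2, len2, "/")
    tt[tt < 0] <- 0; tt[tt > 1] <- 1
    dx <- tx - sweep(tt, 2, ex, "*")
    dy <- ty - sweep(tt, 2, ey, "*")
    best[idx] <- sqrt(apply(dx^2 + dy^2, 1, min))
  }
  best
}

# scanline even-odd rasterization oracle: membership of the lattice
# xs x ys, computed row-wise from sorted edge crossings (independent of the
# package's per-point crossing kernel)
oracle_raster_slice <- function(contours, xs, ys) {
  E <- do.call(rbind, lapply(contours, function(ct) {
    V <- ct$vertices
    n <- nrow(V)
    i2 <- c(seq_len(n)[-1], 1L)
    cbind(V[, 1], V[, 2], V[i2, 1], V[i2, 2])
  }))
  out <- matrix(FALSE, length(xs), length(ys))
  for (j in seq_along(ys)) {
    y <- ys[j]
    # half-open rule: count an edge when min(y) <= y < max(y)
    span <- ((E[, 2] <= y) & (E[, 4] > y)) | ((E[, 4] <= y) & (E[, 2] > y))
    if (!any(span)) next
    xc <- E[span, 1] + (y - E[span, 2]) * (E[span, 3] - E[span, 1]) /
      (E[span, 4] - E[span, 2])
    # parity of crossings strictly to the right of each lattice x
    out[, j] <- (findInterval(xs, sort(xc)) %% 2L) == 1L
  }
  out
}

# per-slice voxel-counting vdsc oracle on a fine lattice
oracle_vdsc_scanline <- function(a, b, h, z_tol = 0.25) {
  ga <- group_by_slice(a, z_tol)
  gb <- group_by_slice(b, z_tol)
  za <- vapply(ga, `[[`, numeric(1), "z")
  zb <- vapply(gb, `[[`, numeric(1), "z")
  allpts <- do.call(rbind, lapply(c(a$contours, b$contours), `[[`, "vertices"))
  # lattice offset by h/3 to stay clear of boundary ties
  xs <- seq(min(allpts[, 1]) - 2 * h + h / 3, max(allpts[, 1]) + 2 * h, by = h)
  ys <- seq(min(allpts[, 2]) - 2 * h + h / 3, max(allpts[, 2]) + 2 * h, by = h)
  va <- vb <- vi <- 0
  for (z in sort(unique(round(c(za, zb), 6)))) {
    ia <- which(abs(za - z) <= z_tol)
    ib <- which(abs(zb - z) <= z_tol)
    in_a <- if (length(ia)) oracle_raster_slice(ga[[ia]]$contours, xs, ys) else FALSE
    in_b <- if (length(ib)) oracle_raster_slice(gb[[ib]]$contours, xs, ys) else FALSE
    va <- va + sum(in_a)
    vb <- vb + sum(in_b)
    vi <- vi + sum(in_a & in_b)
  }
  2 * vi / (va + vb)
}

# per-slice voxel-counting volume/intersection oracle at spacing h;
# returns list(va, vb, vi) in mm^3 given matched slice groups
oracle_slice_volumes <- function(a, b, h, dz, z_tol = 0.25) {
  ga <- group_by_slice(a, z_tol)
  gb <- group_by_slice(b, z_tol)
  za <- vapply(ga, `[[`, numeric(1), "z")
  zb <- vapply(gb, `[[`, numeric(1), "z")
  allpts <- do.call(rbind, lapply(c(a$contours, b$contours), `[[`, "vertices"))
  xs <- seq(min(allpts[, 1]) - 2 * h, max(allpts[, 1]) + 2 * h, by = h)
  ys <- seq(min(allpts[, 2]) - 2 * h, max(allpts[, 2]) + 2 * h, by = h)
  pts <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  va <- vb <- vi <- 0
  zs <- sort(unique(round(c(za, zb), 6)))
  for (z in zs) {
    ia <- which(abs(za - z) <= z_tol)
    ib <- which(abs(zb - z) <= z_tol)
    in_a <- if (length(ia)) oracle_points_in_contours(pts, ga[[ia]]$contours) else FALSE
    in_b <- if (length(ib)) oracle_points_in_contours(pts, gb[[ib]]$contours) else FALSE
    va <- va + sum(in_a) * h^2 * dz
    vb <- vb + sum(in_b) * h^2 * dz
    vi <- vi + sum(in_a & in_b) * h^2 * dz
  }
  list(va = va, vb = vb, vi = vi)
}

oracle_vdsc <- function(a, b, h, dz) {
  v <- oracle_slice_volumes(a, b, h, dz)
  2 * v$vi / (v$va + v$vb)
}

# dense-sampling nAPL oracle: arc-length samples on the reference boundary,
# fraction of samples farther than tol from the test contours (length-
# weighted via uniform sampling)
oracle_napl <- function(reference, test, tol_mm, n_per_mm = 20, z_tol = 0.25) {
  ga <- group_by_slice(reference, z_tol)
  gb <- group_by_slice(test, z_tol)
  zb <- vapply(gb, `[[`, numeric(1), "z")
  total <- 0; outside <- 0
  for (g in ga) {
    j <- which(abs(zb - g$z) <= z_tol)
    for (ct in g$contours) {
      L <- polygon_perimeter(ct$vertices)
      n <- max(10L, ceiling(L * n_per_mm))
      smp <- resample_closed_polygon(ct$vertices, L / n)
      total <- total + L
      if (!length(j)) {
        outside <- outside + L
      } else {
        d <- oracle_points_to_contours(smp, gb[[j]]$contours)
        outside <- outside + L * mean(d > tol_mm)
      }
    }
  }
  outside / total
}

# brute-force EDT oracle on small volumes (distance to nearest TRUE voxel)
oracle_edt <- function(vol, spacing) {
  dims <- dim(vol)
  idx <- which(vol, arr.ind = TRUE)
  if (!nrow(idx)) return(array(Inf, dims))
  feat <- sweep(idx - 1, 2, spacing, "*")
  out <- array(0, dims)
  all_idx <- which(array(TRUE, dims), arr.ind = TRUE)
  coords <- sweep(all_idx - 1, 2, spacing, "*")
  for (v in seq_len(nrow(coords))) {
    d2 <- (feat[, 1] - coords[v, 1])^2 + (feat[, 2] - coords[v, 2])^2 +
      (feat[, 3] - coords[v, 3])^2
    out[v] <- sqrt(min(d2))
  }
  out
}

# barycentric-sampling point-to-mesh distance oracle (upper bound within
# the sampling resolution; k^2 samples per triangle)
oracle_point_to_mesh <- function(pts, mesh, k = 12) {
  u <- rep(seq(0, 1, length.out = k), times = k)
  v <- rep(seq(0, 1, length.out = k), each = k)
  keep <- u + v <= 1
  u <- u[keep]; v <- v[keep]
  V <- mesh$vertices; F <- mesh$faces
  samples <- do.call(rbind, lapply(seq_len(nrow(F)), function(t) {
    a <- V[F[t, 1], ]; b <- V[F[t, 2], ]; c <- V[F[t, 3], ]
    cbind(a[1] + u * (b[1] - a[1]) + v * (c[1] - a[1]),
          a[2] + u * (b[2] - a[2]) + v * (c[2] - a[2]),
          a[3] + u * (b[3] - a[3]) + v * (c[3] - a[3]))
  }))
  vapply(seq_len(nrow(pts)), function(p) {
    sqrt(min((samples[, 1] - pts[p, 1])^2 + (samples[, 2] - pts[p, 2])^2 +
               (samples[, 3] - pts[p, 3])^2))
  }, numeric(1))
}

# random simple polygon (star-shaped around the origin) for property tests
random_star_polygon <- function(n, rmin = 5, rmax = 20) {
  ang <- sort(runif(n, 0, 2 * pi))
  r <- runif(n, rmin, rmax)
  cbind(r * cos(ang), r * sin(ang))
}
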