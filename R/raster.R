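# Rasterization of polygon stacks to binary volumes, and iso-contour
# re-extraction (marching squares) used by the mask round-trip simulator.

# voxel center coordinates along each axis
grid_axis <- function(grid, axis) {
  i <- match(axis, c("x", "y", "z"))
  d <- c(grid$dx, grid$dy, grid$dz)[i]
  grid$origin[i] + (seq_len(grid$shape[i]) - 1L) * d
}

# logical nx x ny in-plane mask of one slice's contours (even-odd rule,
# voxel centers; centers exactly on an edge count as outside)
rasterize_slice <- function(contours, grid) {
  xs <- grid_axis(grid, "x")
  ys <- grid_axis(grid, "y")
  pts <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  matrix(points_in_contours(pts, contours), nrow = length(xs))
}

#' Rasterize a structure into a binary volume
#'
#' Voxel centers inside the polygon stack (even-odd rule per slice) are set
#' TRUE. Each grid slice takes the contours of the nearest structure slice
#' within half the structure's slice spacing (nearest-slice extrusion), so
#' a structure contoured every `dz_s` mm occupies `z +/- dz_s / 2` around
#' each contoured plane. The grid is auto-expanded (with a warning) when it
#' does not cover the structure, keeping spacing and voxel-center phase.
#'
#' @param s a cleaned `rt_structure`.
#' @param grid an `image_grid`.
#' @return list with `volume` (logical array nx x ny x nz) and `grid` (the
#'   possibly expanded grid).
#' @export
rasterize <- function(s, grid) {
  if (length(s$contours) && !check_structure_in_grid(s, grid)) {
    grid <- expand_grid_to_cover(grid, s, pad = 2)
  }
  vol <- array(FALSE, dim = grid$shape)
  groups <- group_by_slice(s, z_tol = grid$dz / 10)
  if (!length(groups)) return(list(volume = vol, grid = grid))
  gz <- vapply(groups, `[[`, numeric(1), "z")
  dz_s <- if (length(gz) > 1L) stats::median(diff(sort(gz))) else grid$dz
  zs <- grid_axis(grid, "z")
  for (k in seq_along(zs)) {
    d <- abs(gz - zs[k])
    j <- which.min(d)
    if (d[j] <= dz_s / 2) {
      vol[, , k] <- rasterize_slice(groups[[j]]$contours, grid)
    }
  }
  list(volume = vol, grid = grid)
}

# expand a grid by whole voxels (preserving voxel-center phase) until it
# covers the structure with `pad` voxels of margin
expand_grid_to_cover <- function(grid, s, pad = 2) {
  pts <- do.call(rbind, lapply(s$contours, function(ct) cbind(ct$vertices, ct$z)))
  d <- c(grid$dx, grid$dy, grid$dz)
  lo_need <- apply(pts, 2, min) - pad * d
  hi_need <- apply(pts, 2, max) + pad * d
  add_lo <- pmax(0L, as.integer(ceiling((grid$origin - lo_need) / d)))
  hi_now <- grid$origin + (grid$shape - 1L) * d
  add_hi <- pmax(0L, as.integer(ceiling((hi_need - hi_now) / d)))
  image_grid(grid$dx, grid$dy, grid$dz,
             origin = grid$origin - add_lo * d,
             shape = grid$shape + add_lo + add_hi)
}

# ---- marching squares -----------------------------------------------------
# Iso-contours of a binary in-plane mask at the 0.5 level with linear
# interpolation between voxel centers (crossings at link midpoints).
# Ambiguous saddle cases are resolved by disconnecting the inside corners.

.ms_cases <- list(
  NULL,                 # 0
  list(c(1L, 4L)),      # 1  c00
  list(c(1L, 2L)),      # 2  c10
  list(c(4L, 2L)),      # 3
  list(c(2L, 3L)),      # 4  c11
  list(c(1L, 4L), c(2L, 3L)),  # 5 saddle
  list(c(1L, 3L)),      # 6
  list(c(4L, 3L)),      # 7
  list(c(3L, 4L)),      # 8  c01
  list(c(1L, 3L)),      # 9
  list(c(1L, 2L), c(3L, 4L)),  # 10 saddle
  list(c(2L, 3L)),      # 11
  list(c(4L, 2L)),      # 12
  list(c(1L, 2L)),      # 13
  list(c(1L, 4L)),      # 14
  NULL                  # 15
)

# extract closed iso-contours from a logical matrix; xs, ys are voxel
# center coordinates; returns list of vertex matrices (closed loops,
# closing vertex not duplicated)
marching_squares <- function(mask, xs, ys) {
  nx <- nrow(mask); ny <- ncol(mask)
  if (nx < 2L || ny < 2L || !any(mask)) return(list())
  m <- mask
  v00 <- m[-nx, -ny]; v10 <- m[-1L, -ny]; v11 <- m[-1L, -1L]; v01 <- m[-nx, -1L]
  case <- 1L * v00 + 2L * v10 + 4L * v11 + 8L * v01
  active <- which(case != 0L & case != 15L, arr.ind = TRUE)
  if (!nrow(active)) return(list())
  dx <- xs[2] - xs[1]; dy <- ys[2] - ys[1]

  # edge key encoding: horizontal link (i,j)-(i+1,j) -> 2*(j*nx+i),
  # vertical link (i,j)-(i,j+1) -> 2*(j*nx+i)+1   (i, j zero-based)
  edge_key <- function(i, j, edge) {
    # cell (i, j), 1-based; edges 1 bottom, 2 right, 3 top, 4 left
    switch(edge,
           2L * ((j - 1L) * nx + (i - 1L)),            # bottom: H(i, j)
           2L * ((j - 1L) * nx + i) + 1L,              # right:  V(i+1, j)
           2L * (j * nx + (i - 1L)),                   # top:    H(i, j+1)
           2L * ((j - 1L) * nx + (i - 1L)) + 1L)       # left:   V(i, j)
  }
  edge_point <- function(key) {
    vertical <- key %% 2L == 1L
    lin <- key %/% 2L
    i <- lin %% nx; j <- lin %/% nx                     # zero-based
    if (vertical) c(xs[i + 1L], ys[j + 1L] + dy / 2)
    else c(xs[i + 1L] + dx / 2, ys[j + 1L])
  }

  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(active))) {
    i <- active[r, 1]; j <- active[r, 2]
    for (seg in .ms_cases[[case[i, j] + 1L]]) {
      from <- c(from, edge_key(i, j, seg[1]))
      to <- c(to, edge_key(i, j, seg[2]))
    }
  }
  nseg <- length(from)
  # adjacency: every edge point has degree exactly 2 (closed loops)
  keys <- sort(unique(c(from, to)))
  fi <- match(from, keys); ti <- match(to, keys)
  nb <- matrix(NA_integer_, nrow = length(keys), ncol = 2)
  slot <- integer(length(keys))
  add_nb <- function(a, b) {
    slot[a] <<- slot[a] + 1L
    nb[a, slot[a]] <<- b
  }
  for (s in seq_len(nseg)) { add_nb(fi[s], ti[s]); add_nb(ti[s], fi[s]) }
  visited <- logical(length(keys))
  loops <- list()
  for (start in seq_along(keys)) {
    if (visited[start]) next
    loop <- integer(0)
    cur <- start; prev <- 0L
    repeat {
      visited[cur] <- TRUE
      loop <- c(loop, cur)
      nxt <- nb[cur, ]
      nxt <- nxt[!is.na(nxt) & nxt != prev]
      if (!length(nxt)) break
      prev <- cur
      cur <- nxt[1]
      if (cur == start) break
    }
    if (length(loop) >= 3L) {
      pts <- t(vapply(keys[loop], edge_point, numeric(2)))
      loops[[length(loops) + 1L]] <- pts
    }
  }
  loops
}

# 3D binary closing with the 6-connected (cross) structuring element:
# one dilation then one erosion, emulating volumetric smoothing
binary_closing_cross <- function(vol) {
  dilated <- shift_or(vol)
  !shift_or(!dilated)
}

shift_or <- function(vol) {
  d <- dim(vol)
  out <- vol
  out[-1, , ] <- out[-1, , ] | vol[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | vol[-1, , ]
  out[, -1, ] <- out[, -1, ] | vol[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | vol[, -1, ]
  if (d[3] > 1L) {
    out[, , -1] <- out[, , -1] | vol[, , -d[3]]
    out[, , -d[3]] <- out[, , -d[3]] | vol[, , -1]
  }
  out
}
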