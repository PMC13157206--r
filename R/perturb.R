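# Simulator of commercial-system re-export behaviours. Each perturbation
# mode emulates one class of internal-representation round trip; a
# simulated "system" is an ordered sequence of configs.

#' Configure one perturbation mode
#'
#' Modes:
#' * `truncate_precision`: round coordinates to `decimal_places` decimals
#'   (DecimalString precision differences between systems).
#' * `resample_path`: uniform arc-length resampling of every polygon at
#'   `target_spacing`; corners are not guaranteed preserved.
#' * `mask_roundtrip_2d`: rasterize each slice at grid resolution (even-odd
#'   rule) and re-extract iso-contours at the 0.5 level with linear
#'   interpolation (marching squares).
#' * `mask_roundtrip_3d`: rasterize the full stack, apply one binary
#'   closing at 1-voxel radius (volumetric smoothing), re-extract per
#'   slice.
#' * `drop_small_regions`: remove per-slice connected polygon components
#'   (outer contour plus its holes) with net area below `min_region_area`.
#' * `subsample_vertices`: keep every `keep_every_k`-th vertex (at least 3
#'   survive).
#' * `densify_vertices`: split edges longer than `max_segment`, keeping all
#'   original vertices.
#'
#' @param mode one of the modes above.
#' @param decimal_places,target_spacing,grid,min_region_area,keep_every_k,max_segment
#'   mode-specific parameters.
#' @param seed integer recorded for reproducibility (all current modes are
#'   deterministic; the seed is applied around the mode regardless).
#' @return a `perturbation_config`.
#' @export
perturbation_config <- function(mode = c("truncate_precision", "resample_path",
                                         "mask_roundtrip_2d", "mask_roundtrip_3d",
                                         "drop_small_regions", "subsample_vertices",
                                         "densify_vertices"),
                                decimal_places = 6, target_spacing = 1,
                                grid = NULL, min_region_area = 10,
                                keep_every_k = 2L, max_segment = 1,
                                seed = 1L) {
  mode <- match.arg(mode)
  if (mode %in% c("mask_roundtrip_2d", "mask_roundtrip_3d") && is.null(grid)) {
    stop("mode '", mode, "' requires a grid")
  }
  structure(list(mode = mode, decimal_places = decimal_places,
                 target_spacing = target_spacing, grid = grid,
                 min_region_area = min_region_area,
                 keep_every_k = as.integer(keep_every_k),
                 max_segment = max_segment, seed = as.integer(seed)),
            class = "perturbation_config")
}

#' Apply a sequence of perturbations to a structure
#'
#' Modes are applied in list order; an empty list returns the structure
#' unchanged. Deterministic given the configs' seeds.
#'
#' @param s an `rt_structure`.
#' @param configs a `perturbation_config` or ordered list of them.
#' @return perturbed `rt_structure`.
#' @export
perturb <- function(s, configs = list()) {
  if (inherits(configs, "perturbation_config")) configs <- list(configs)
  for (cfg in configs) {
    if (!inherits(cfg, "perturbation_config")) {
      stop("configs must be perturbation_config objects")
    }
    s <- withr_seed(cfg$seed, apply_one_perturbation(s, cfg))
  }
  s
}

# evaluate expr under a local RNG seed without disturbing the caller's RNG
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

apply_one_perturbation <- function(s, cfg) {
  switch(cfg$mode,
    truncate_precision = map_contours(s, function(ct) {
      ct$vertices <- round(ct$vertices, cfg$decimal_places)
      ct$z <- round(ct$z, cfg$decimal_places)
      ct
    }),
    resample_path = map_contours(s, function(ct) {
      if (n_vertices(ct) >= 3L) {
        ct$vertices <- resample_closed_polygon(ct$vertices, cfg$target_spacing)
      }
      ct
    }),
    subsample_vertices = map_contours(s, function(ct) {
      n <- n_vertices(ct)
      idx <- seq(1L, n, by = cfg$keep_every_k)
      if (length(idx) >= 3L) ct$vertices <- ct$vertices[idx, , drop = FALSE]
      ct
    }),
    densify_vertices = map_contours(s, function(ct) {
      if (n_vertices(ct) >= 3L) {
        ct$vertices <- densify_closed_polygon(ct$vertices, cfg$max_segment)
      }
      ct
    }),
    drop_small_regions = drop_small_regions(s, cfg$min_region_area),
    mask_roundtrip_2d = mask_roundtrip_2d(s, cfg$grid),
    mask_roundtrip_3d = mask_roundtrip_3d(s, cfg$grid),
    stop("unknown perturbation mode: ", cfg$mode)
  )
}

map_contours <- function(s, f) {
  s$contours <- lapply(s$contours, f)
  s
}

# remove per-slice connected polygon components (outer contour + holes
# nested inside it) whose net enclosed area is below min_region_area;
# surviving vertices are never moved
drop_small_regions <- function(s, min_region_area) {
  groups <- group_by_slice(s, z_tol = 1e-3)
  kept <- list()
  for (g in groups) {
    cts <- g$contours
    depth <- contour_nesting_depth(cts)
    outers <- which(depth %% 2L == 0L)
    keep <- logical(length(cts))
    for (o in outers) {
      # holes of this outer: odd-depth contours whose first vertex lies inside it
      members <- o
      for (j in seq_along(cts)) {
        if (j == o || depth[j] %% 2L == 0L) next
        if (points_in_contours(cts[[j]]$vertices[1, , drop = FALSE], cts[o])) {
          members <- c(members, j)
        }
      }
      area <- abs(polygon_signed_area(cts[[o]]$vertices)) -
        sum(vapply(setdiff(members, o), function(j) {
          abs(polygon_signed_area(cts[[j]]$vertices))
        }, numeric(1)))
      if (area >= min_region_area) keep[members] <- TRUE
    }
    kept <- c(kept, cts[keep])
  }
  s$contours <- kept
  s
}

mask_roundtrip_2d <- function(s, grid) {
  groups <- group_by_slice(s, z_tol = grid$dz / 10)
  xs <- grid_axis(grid, "x"); ys <- grid_axis(grid, "y")
  contours <- list()
  for (g in groups) {
    # per-slice grid expansion when contours overrun the in-plane extents
    gg <- grid
    allv <- do.call(rbind, lapply(g$contours, `[[`, "vertices"))
    if (min(allv[, 1]) < xs[1] || max(allv[, 1]) > xs[length(xs)] ||
        min(allv[, 2]) < ys[1] || max(allv[, 2]) > ys[length(ys)]) {
      fake <- rt_structure(s$name, g$contours)
      gg <- expand_grid_to_cover(grid, fake, pad = 2)
    }
    mask <- rasterize_slice(g$contours, gg)
    loops <- marching_squares(mask, grid_axis(gg, "x"), grid_axis(gg, "y"))
    for (L in loops) {
      contours[[length(contours) + 1L]] <- planar_contour(L, z = g$z)
    }
  }
  s$contours <- contours
  s
}

mask_roundtrip_3d <- function(s, grid) {
  r <- rasterize(s, grid)
  vol <- binary_closing_cross(r$volume)
  grid <- r$grid
  xs <- grid_axis(grid, "x"); ys <- grid_axis(grid, "y"); zs <- grid_axis(grid, "z")
  contours <- list()
  for (k in seq_along(zs)) {
    if (!any(vol[, , k])) next
    loops <- marching_squares(vol[, , k], xs, ys)
    for (L in loops) {
      contours[[length(contours) + 1L]] <- planar_contour(L, z = zs[k])
    }
  }
  s$contours <- contours
  s
}
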