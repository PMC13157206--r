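# Cleaning applied to both members of every pair before distance analysis,
# so systems that deduplicate vertices or drop zero-area contours during
# re-export are not penalised.

#' Remove consecutive duplicate vertices from a contour
#'
#' Duplicates are removed cyclically: a last vertex within `eps` of the
#' first (an explicitly stored closing point) is also dropped. Vertex order
#' is otherwise preserved and no surviving vertex is moved.
#'
#' @param contour a `planar_contour`.
#' @param eps duplicate distance threshold, mm (>= 0).
#' @return cleaned `planar_contour` (may have < 3 vertices; degeneracy is
#'   handled by [remove_degenerate_contours]).
#' @export
remove_duplicate_vertices <- function(contour, eps = 1e-6) {
  stopifnot(eps >= 0)
  V <- contour$vertices
  n <- nrow(V)
  if (n < 2L) return(contour)
  keep <- rep(TRUE, n)
  prev <- 1L
  for (i in 2L:n) {
    if (sqrt(sum((V[i, ] - V[prev, ])^2)) <= eps) keep[i] <- FALSE else prev <- i
  }
  V <- V[keep, , drop = FALSE]
  # cyclic closure: last vs first
  while (nrow(V) > 1L &&
         sqrt(sum((V[nrow(V), ] - V[1, ])^2)) <= eps) {
    V <- V[-nrow(V), , drop = FALSE]
  }
  contour$vertices <- V
  contour
}

#' Drop degenerate contours from a structure
#'
#' A contour is degenerate when it has fewer than 3 distinct vertices or
#' its absolute enclosed (shoelace) area is below `area_eps`. "Zero volume"
#' is interpreted in-plane: a planar contour contributes volume only
#' through its area. Removals are reported via an attribute and, when
#' `verbose`, a message per contour.
#'
#' @param s an `rt_structure` (duplicates already removed).
#' @param area_eps area threshold, mm^2.
#' @param verbose log removals with `message()`.
#' @return cleaned `rt_structure`; attribute `removed` holds a data.frame of
#'   dropped contours (z, n_vertices, area); attribute `empty` flags a
#'   structure left with no contours.
#' @export
remove_degenerate_contours <- function(s, area_eps = 1e-6, verbose = FALSE) {
  keep <- logical(length(s$contours))
  log_z <- numeric(0); log_n <- integer(0); log_a <- numeric(0)
  for (i in seq_along(s$contours)) {
    ct <- s$contours[[i]]
    a <- abs(polygon_signed_area(ct$vertices))
    ok <- n_vertices(ct) >= 3L && a >= area_eps
    keep[i] <- ok
    if (!ok) {
      log_z <- c(log_z, ct$z); log_n <- c(log_n, n_vertices(ct)); log_a <- c(log_a, a)
      if (verbose) {
        message(sprintf("structure '%s': dropped degenerate contour at z=%g (%d vertices, area %g mm^2)",
                        s$name, ct$z, n_vertices(ct), a))
      }
    }
  }
  s$contours <- s$contours[keep]
  attr(s, "removed") <- data.frame(z = log_z, n_vertices = log_n, area_mm2 = log_a)
  attr(s, "empty") <- length(s$contours) == 0L
  s
}

#' Clean a structure (duplicate vertices, then degenerate contours)
#'
#' @param s an `rt_structure`.
#' @param eps duplicate-vertex threshold, mm.
#' @param area_eps degenerate-area threshold, mm^2.
#' @param verbose log removals.
#' @return cleaned `rt_structure`.
#' @export
clean_structure <- function(s, eps = 1e-6, area_eps = 1e-6, verbose = FALSE) {
  s$contours <- lapply(s$contours, remove_duplicate_vertices, eps = eps)
  remove_degenerate_contours(s, area_eps = area_eps, verbose = verbose)
}

#' Group a structure's contours into slices
#'
#' Contours are clustered by z with single-linkage at tolerance `z_tol`;
#' groups are returned sorted by ascending z and are disjoint. A warning is
#' raised when two adjacent groups are suspiciously close (closer than
#' `warn_below`, e.g. dz / 2) without being merged, which typically signals
#' a mis-gridded export.
#'
#' @param s an `rt_structure`.
#' @param z_tol clustering tolerance, mm (> 0).
#' @param warn_below optional gap below which a warning is raised, mm.
#' @return list of slice groups, each `list(z = <mean z>, contours = ...)`.
#' @export
group_by_slice <- function(s, z_tol = 0.25, warn_below = NULL) {
  stopifnot(z_tol > 0)
  if (!length(s$contours)) return(list())
  zs <- contour_zs(s)
  ord <- order(zs)
  zo <- zs[ord]
  grp <- cumsum(c(1, diff(zo) > z_tol))
  groups <- vector("list", max(grp))
  for (g in seq_len(max(grp))) {
    idx <- ord[grp == g]
    groups[[g]] <- list(z = mean(zs[idx]), contours = s$contours[idx])
  }
  if (!is.null(warn_below) && length(groups) > 1L) {
    gz <- vapply(groups, `[[`, numeric(1), "z")
    gaps <- diff(gz)
    if (any(gaps > z_tol & gaps < warn_below)) {
      warning("slice gaps between z_tol and ", warn_below,
              " mm detected; possible mis-gridded export")
    }
  }
  groups
}

# match slice groups of two structures by z; returns index pairs plus
# unmatched group indices on either side
match_slices <- function(groups_a, groups_b, z_tol) {
  za <- vapply(groups_a, `[[`, numeric(1), "z")
  zb <- vapply(groups_b, `[[`, numeric(1), "z")
  pairs <- matrix(integer(0), ncol = 2)
  used_b <- logical(length(zb))
  for (i in seq_along(za)) {
    if (!length(zb)) break
    d <- abs(zb - za[i])
    j <- which.min(d)
    if (d[j] <= z_tol && !used_b[j]) {
      pairs <- rbind(pairs, c(i, j))
      used_b[j] <- TRUE
    }
  }
  list(pairs = pairs,
       only_a = setdiff(seq_along(za), pairs[, 1]),
       only_b = setdiff(seq_along(zb), pairs[, 2]))
}
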