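# Experiment orchestration: generate/load pairs, apply simulated re-export
# systems, clean, compute displacement summaries and the full measure suite
# over the tolerance sweep, and emit machine-readable reports.

#' Compute the full measure set for one (reference, test) pair
#'
#' Polygon pathway: nAPL sweep, vDSC, 2D distance family. Mesh pathway
#' (optional): sDSC sweep and 3DMSD on marching-tetrahedra meshes.
#'
#' @param reference,test cleaned `rt_structure`s.
#' @param grid an `image_grid`.
#' @param tol_spec a [tolerance_spec].
#' @param include_mesh compute the mesh-pathway measures.
#' @param sample_spacing boundary sampling step for 2D distances, mm.
#' @param mesh_reference,mesh_test optional precomputed meshes (cache).
#' @return a `measure_set` list: `napl` (named by voxel fraction), `vdsc`,
#'   `hd2d_mm`, `hd95_2d_mm`, `hd50_2d_mm`, `msd2d_mm`, `sdsc`, `msd3d_mm`.
#' @export
measure_pair <- function(reference, test, grid, tol_spec = tolerance_spec(),
                         include_mesh = TRUE, sample_spacing = 0.1,
                         mesh_reference = NULL, mesh_test = NULL) {
  tols <- resolve_tolerances(tol_spec, grid)
  d2 <- distances_2d(reference, test, sample_spacing = sample_spacing,
                     z_tol = grid$dz / 10)
  out <- list(
    napl = napl_sweep(reference, test, grid, tol_spec),
    vdsc = vdsc(reference, test, grid),
    hd2d_mm = d2$hd2d_mm, hd95_2d_mm = d2$hd95_2d_mm,
    hd50_2d_mm = d2$hd50_2d_mm, msd2d_mm = d2$msd2d_mm,
    sdsc = NULL, msd3d_mm = NA_real_
  )
  if (include_mesh) {
    if (is.null(mesh_reference)) mesh_reference <- structure_mesh(reference, grid)
    if (is.null(mesh_test)) mesh_test <- structure_mesh(test, grid)
    sd <- surface_distances(mesh_reference, mesh_test)
    out$sdsc <- vapply(tols, function(t) {
      sdsc(mesh_reference, mesh_test, t, dists = sd)
    }, numeric(1))
    out$msd3d_mm <- msd3d(mesh_reference, mesh_test, dists = sd)
  }
  class(out) <- "measure_set"
  out
}

#' Configure a full experiment
#'
#' @param pairs named list of `list(reference =, test =)` pairs; default
#'   [make_dataset1()].
#' @param systems named list of simulated systems; each system is an
#'   ordered list of [perturbation_config]s (an empty list is the identity
#'   system).
#' @param grid `image_grid`; derived from the pairs when NULL.
#' @param tol_spec a [tolerance_spec] (must be non-empty).
#' @param clean apply duplicate/degenerate cleaning to both members before
#'   analysis (default TRUE, mirroring the assessment protocol).
#' @param include_mesh compute mesh-pathway measures.
#' @param sample_spacing 2D boundary sampling step, mm.
#' @param grid_spacing in-plane/slice spacings used when deriving the grid,
#'   mm (dx, dy, dz).
#' @param seed integer master seed.
#' @return an `experiment_config`.
#' @export
experiment_config <- function(pairs = NULL, systems = list(identity = list()),
                              grid = NULL, tol_spec = tolerance_spec(),
                              clean = TRUE, include_mesh = TRUE,
                              sample_spacing = 0.1,
                              grid_spacing = c(1, 1, 2.5), seed = 1L) {
  if (is.null(pairs)) pairs <- make_dataset1()
  if (!length(pairs)) stop("at least one structure pair is required")
  if (!length(systems)) stop("at least one perturbation sequence is required")
  if (is.null(names(systems)) || any(names(systems) == "")) {
    stop("systems must be a named list")
  }
  if (!inherits(tol_spec, "tolerance_spec") ||
      !length(tol_spec$fractions_of_voxel)) {
    stop("tol_spec must be a non-empty tolerance_spec")
  }
  if (is.null(names(pairs))) names(pairs) <- paste0("pair", seq_along(pairs))
  if (is.null(grid)) {
    all_structs <- unlist(lapply(pairs, function(p) list(p$reference, p$test)),
                          recursive = FALSE)
    grid <- grid_for_structures(all_structs, dx = grid_spacing[1],
                                dy = grid_spacing[2], dz = grid_spacing[3])
  }
  structure(list(pairs = pairs, systems = systems, grid = grid,
                 tol_spec = tol_spec, clean = clean,
                 include_mesh = include_mesh,
                 sample_spacing = sample_spacing, seed = as.integer(seed)),
            class = "experiment_config")
}

measure_cols <- function(ms, prefix, fractions) {
  cols <- list()
  cols[[paste0(prefix, "_vdsc")]] <- ms$vdsc
  cols[[paste0(prefix, "_hd2d_mm")]] <- ms$hd2d_mm
  cols[[paste0(prefix, "_hd95_2d_mm")]] <- ms$hd95_2d_mm
  cols[[paste0(prefix, "_hd50_2d_mm")]] <- ms$hd50_2d_mm
  cols[[paste0(prefix, "_msd2d_mm")]] <- ms$msd2d_mm
  cols[[paste0(prefix, "_msd3d_mm")]] <- ms$msd3d_mm
  for (i in seq_along(fractions)) {
    cols[[sprintf("%s_napl_%g", prefix, fractions[i])]] <- unname(ms$napl[i])
    cols[[sprintf("%s_sdsc_%g", prefix, fractions[i])]] <-
      if (is.null(ms$sdsc)) NA_real_ else unname(ms$sdsc[i])
  }
  cols
}

na_measure_cols <- function(prefix, fractions) {
  ms <- list(napl = rep(NA_real_, length(fractions)), vdsc = NA_real_,
             hd2d_mm = NA_real_, hd95_2d_mm = NA_real_,
             hd50_2d_mm = NA_real_, msd2d_mm = NA_real_,
             sdsc = NULL, msd3d_mm = NA_real_)
  measure_cols(ms, prefix, fractions)
}

#' Run the full experiment
#'
#' For every (pair, system): perturb the test structure with the system's
#' config sequence, clean both members, compute the displacement summary
#' (original test to re-export), and the full measure set three ways:
#' `self` (re-export vs the original test — the expected-identity
#' comparison), `ref` (re-export vs the reference), and `base` (original
#' test vs the reference, the no-re-export baseline, computed once per
#' pair). A failing row records its error and the run continues.
#'
#' @param cfg an [experiment_config].
#' @return a `results_table` list: `results` (one row per pair x system),
#'   `curves` (named list of cumulative-curve data.frames), `manifest`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  set.seed(cfg$seed)
  fr <- cfg$tol_spec$fractions_of_voxel
  grid <- cfg$grid
  rows <- list(); curves <- list()
  for (pname in names(cfg$pairs)) {
    pair <- cfg$pairs[[pname]]
    ref <- pair$reference; tst <- pair$test
    if (cfg$clean) {
      ref <- clean_structure(ref)
      tst <- clean_structure(tst)
    }
    mesh_ref <- NULL; mesh_tst <- NULL
    base <- tryCatch({
      if (cfg$include_mesh) {
        mesh_ref <- structure_mesh(ref, grid)
        mesh_tst <- structure_mesh(tst, grid)
      }
      measure_pair(ref, tst, grid, cfg$tol_spec,
                   include_mesh = cfg$include_mesh,
                   sample_spacing = cfg$sample_spacing,
                   mesh_reference = mesh_ref, mesh_test = mesh_tst)
    }, error = function(e) e)

    for (sname in names(cfg$systems)) {
      key <- paste(pname, sname, sep = ":")
      row <- c(list(structure = pname, system = sname), list(error = ""))
      res <- tryCatch({
        reexp <- perturb(tst, cfg$systems[[sname]])
        if (cfg$clean) reexp <- clean_structure(reexp)
        disp <- displacement_summary(tst, reexp, grid)
        mesh_reexp <- if (cfg$include_mesh) structure_mesh(reexp, grid) else NULL
        self_ms <- measure_pair(tst, reexp, grid, cfg$tol_spec,
                                include_mesh = cfg$include_mesh,
                                sample_spacing = cfg$sample_spacing,
                                mesh_reference = mesh_tst,
                                mesh_test = mesh_reexp)
        ref_ms <- measure_pair(ref, reexp, grid, cfg$tol_spec,
                               include_mesh = cfg$include_mesh,
                               sample_spacing = cfg$sample_spacing,
                               mesh_reference = mesh_ref,
                               mesh_test = mesh_reexp)
        list(disp = disp, self_ms = self_ms, ref_ms = ref_ms)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        row$error <- conditionMessage(res)
        row <- c(row, list(mean_mm = NA_real_, max_mm = NA_real_,
                           n_vertices_original = NA_integer_,
                           n_vertices_reexported = NA_integer_,
                           n_unmatched_vertices = NA_integer_,
                           topology_changed = NA),
                 na_measure_cols("self", fr), na_measure_cols("ref", fr))
      } else {
        d <- res$disp
        curves[[key]] <- d$cumulative
        row <- c(row, list(mean_mm = d$mean_mm, max_mm = d$max_mm,
                           n_vertices_original = d$n_vertices_original,
                           n_vertices_reexported = d$n_vertices_reexported,
                           n_unmatched_vertices = d$n_unmatched_vertices,
                           topology_changed = d$topology_changed),
                 measure_cols(res$self_ms, "self", fr),
                 measure_cols(res$ref_ms, "ref", fr))
      }
      if (inherits(base, "error")) {
        row$error <- paste(row$error, "baseline:", conditionMessage(base))
        row <- c(row, na_measure_cols("base", fr))
      } else {
        row <- c(row, measure_cols(base, "base", fr))
      }
      rows[[key]] <- as.data.frame(row, check.names = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  manifest <- list(
    package = "rtssfidelity",
    version = as.character(utils::packageVersion("rtssfidelity")),
    seed = cfg$seed,
    n_pairs = length(cfg$pairs),
    systems = names(cfg$systems),
    tolerance_fractions = fr,
    grid = list(dx = grid$dx, dy = grid$dy, dz = grid$dz,
                origin = grid$origin, shape = grid$shape),
    clean = cfg$clean, include_mesh = cfg$include_mesh,
    sample_spacing = cfg$sample_spacing,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  structure(list(results = results, curves = curves, manifest = manifest),
            class = "results_table")
}

#' @export
print.results_table <- function(x, ...) {
  cat(sprintf("<results_table> %d rows (%d structures x %d systems)\n",
              nrow(x$results), length(unique(x$results$structure)),
              length(unique(x$results$system))))
  invisible(x)
}

#' Write experiment reports
#'
#' Emits `summary.csv` (wide, one row per pair x system),
#' `measures_long.csv` (comparison/measure/tolerance long form),
#' `curves.csv` (cumulative displacement curves) and `manifest.json`.
#' CSVs are deterministic; timestamps go only in the manifest.
#'
#' @param tbl a `results_table` from [run_experiment].
#' @param outdir output directory (created if needed).
#' @param plots also write `cumulative_curves.pdf` (base graphics).
#' @return character vector of written paths, invisibly.
#' @export
write_report <- function(tbl, outdir, plots = FALSE) {
  stopifnot(inherits(tbl, "results_table"))
  if (!nrow(tbl$results)) stop("empty results table")
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE)
  if (!ok || file.access(outdir, 2) != 0) {
    stop("output directory is not writable: ", outdir)
  }
  paths <- character(0)
  p <- file.path(outdir, "summary.csv")
  write.csv(tbl$results, p, row.names = FALSE)
  paths <- c(paths, p)

  long <- results_long_form(tbl$results)
  p <- file.path(outdir, "measures_long.csv")
  write.csv(long, p, row.names = FALSE)
  paths <- c(paths, p)

  crv <- do.call(rbind, lapply(names(tbl$curves), function(k) {
    cum <- tbl$curves[[k]]
    if (!nrow(cum)) return(NULL)
    parts <- strsplit(k, ":", fixed = TRUE)[[1]]
    cbind(structure = parts[1], system = parts[2], cum)
  }))
  p <- file.path(outdir, "curves.csv")
  write.csv(if (is.null(crv)) data.frame() else crv, p, row.names = FALSE)
  paths <- c(paths, p)

  p <- file.path(outdir, "manifest.json")
  jsonlite::write_json(tbl$manifest, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, p)

  if (plots) {
    p <- file.path(outdir, "cumulative_curves.pdf")
    grDevices::pdf(p, width = 8, height = 6)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot_cumulative_curves(tbl)
    paths <- c(paths, p)
  }
  invisible(paths)
}

# wide results -> long (comparison, measure, tolerance_fraction, value)
results_long_form <- function(results) {
  keycols <- c("structure", "system")
  meas <- setdiff(names(results), c(keycols, "error", "topology_changed"))
  out <- list()
  for (m in meas) {
    parts <- strsplit(m, "_")[[1]]
    comparison <- if (parts[1] %in% c("self", "ref", "base")) parts[1] else "displacement"
    tolf <- NA_real_
    mm <- m
    if (comparison != "displacement") {
      mm <- sub(paste0("^", parts[1], "_"), "", m)
      if (grepl("^(napl|sdsc)_", mm)) {
        tolf <- as.numeric(sub("^(napl|sdsc)_", "", mm))
        mm <- sub("_.*$", "", mm)
      }
    }
    out[[m]] <- data.frame(structure = results$structure,
                           system = results$system,
                           comparison = comparison, measure = mm,
                           tolerance_fraction = tolf,
                           value = as.numeric(results[[m]]))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Plot cumulative displacement curves (one panel per structure)
#'
#' @param tbl a `results_table`.
#' @return invisibly, NULL.
#' @export
plot_cumulative_curves <- function(tbl) {
  if (!length(tbl$curves)) return(invisible(NULL))
  keys <- names(tbl$curves)
  parts <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
  structures <- unique(parts[, 1])
  systems <- unique(parts[, 2])
  cols <- grDevices::hcl.colors(max(3L, length(systems)), "Dark 3")
  for (st in structures) {
    sel <- which(parts[, 1] == st)
    xmax <- max(1e-3, vapply(sel, function(i) {
      cum <- tbl$curves[[keys[i]]]
      if (nrow(cum)) max(cum$distance_voxels) else 0
    }, numeric(1)))
    graphics::plot(NULL, xlim = c(0, xmax), ylim = c(0, 1),
                   xlab = "displacement (in-plane voxels)",
                   ylab = "fraction of vertices <= distance",
                   main = st)
    for (i in sel) {
      cum <- tbl$curves[[keys[i]]]
      if (!nrow(cum)) next
      ci <- match(parts[i, 2], systems)
      graphics::lines(stats::stepfun(cum$distance_voxels, c(0, cum$fraction)),
                      col = cols[ci], do.points = FALSE)
    }
    graphics::legend("bottomright", legend = systems,
                     col = cols[seq_along(systems)], lty = 1, cex = 0.8)
  }
  invisible(NULL)
}
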