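# RT Structure Set reading/writing on top of the low-level DICOM codec.

RTSTRUCT_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.481.3"
EXPLICIT_VR_LE <- "1.2.840.10008.1.2.1"
IMPLEMENTATION_UID <- "1.2.826.0.1.3680043.9.7484.1"

#' Write structures to a DICOM RT Structure Set file
#'
#' Writes a minimal but valid RTSS (explicit VR little endian): file meta,
#' SOP identifiers, referenced frame of reference, StructureSetROISequence,
#' and ROIContourSequence with `CLOSED_PLANAR` contours. Coordinates are
#' rendered as DecimalStrings rounded to `decimal_places`, emulating the
#' precision choices of exporting systems. Grid geometry is stored in a
#' JSON sidecar (`<path>.grid.json`) so a re-read needs no image series.
#'
#' @param structures an `rt_structure` or list of them.
#' @param grid `image_grid` associated with the structure set.
#' @param path output file path.
#' @param decimal_places decimals retained in coordinate DecimalStrings,
#'   in `[1, 10]`; default 6.
#' @param sidecar write `<path>.grid.json` with the grid geometry.
#' @return `path`, invisibly.
#' @export
write_rtss <- function(structures, grid, path, decimal_places = 6,
                       sidecar = TRUE) {
  if (inherits(structures, "rt_structure")) structures <- list(structures)
  if (!length(structures)) stop("no structures to write")
  if (decimal_places < 1 || decimal_places > 10) {
    stop("decimal_places must be in [1, 10]")
  }
  for_uid <- structures[[1]]$frame_of_reference
  sop_uid <- dcm_make_uid()

  fmt_coord <- function(x) {
    s <- formatC(round(x, decimal_places), format = "f",
                 digits = decimal_places)
    s <- sub("0+$", "", s)
    s <- sub("\\.$", "", s)
    bad <- nchar(s) > 16L
    if (any(bad)) {
      stop("coordinate DecimalString '", s[which(bad)[1]],
           "' exceeds 16 bytes; use fewer decimal places")
    }
    s
  }

  roi_items <- vector("list", length(structures))
  contour_items <- vector("list", length(structures))
  for (i in seq_along(structures)) {
    s <- structures[[i]]
    roi_items[[i]] <- c(
      dcm_string_element(0x3006, 0x0022, "IS", as.character(i)),
      dcm_string_element(0x3006, 0x0024, "UI", s$frame_of_reference),
      dcm_string_element(0x3006, 0x0026, "LO", s$name),
      dcm_string_element(0x3006, 0x0036, "CS", "AUTOMATIC")
    )
    cseq <- lapply(s$contours, function(ct) {
      V <- ct$vertices
      triplets <- rbind(fmt_coord(V[, 1]), fmt_coord(V[, 2]),
                        fmt_coord(rep(ct$z, nrow(V))))
      c(
        dcm_string_element(0x3006, 0x0042, "CS", ct$geometric_type),
        dcm_string_element(0x3006, 0x0046, "IS", as.character(nrow(V))),
        dcm_string_element(0x3006, 0x0050, "DS",
                           paste(as.vector(triplets), collapse = "\\"))
      )
    })
    contour_items[[i]] <- c(
      dcm_string_element(0x3006, 0x002a, "IS", "255\\0\\0"),
      dcm_sequence(0x3006, 0x0040, cseq),
      dcm_string_element(0x3006, 0x0084, "IS", as.character(i))
    )
  }

  dataset <- c(
    dcm_string_element(0x0008, 0x0016, "UI", RTSTRUCT_SOP_CLASS),
    dcm_string_element(0x0008, 0x0018, "UI", sop_uid),
    dcm_string_element(0x0008, 0x0060, "CS", "RTSTRUCT"),
    dcm_string_element(0x3006, 0x0002, "SH", "rtssfidelity"),
    dcm_sequence(0x3006, 0x0010, list(
      dcm_string_element(0x0020, 0x0052, "UI", for_uid)
    )),
    dcm_sequence(0x3006, 0x0020, roi_items),
    dcm_sequence(0x3006, 0x0039, contour_items)
  )

  meta_body <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_string_element(0x0002, 0x0002, "UI", RTSTRUCT_SOP_CLASS),
    dcm_string_element(0x0002, 0x0003, "UI", sop_uid),
    dcm_string_element(0x0002, 0x0010, "UI", EXPLICIT_VR_LE),
    dcm_string_element(0x0002, 0x0012, "UI", IMPLEMENTATION_UID)
  )
  meta <- c(
    dcm_element(0x0002, 0x0000, "UL", uint32_raw(length(meta_body))),
    meta_body
  )

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, dataset), con)
  if (sidecar && !is.null(grid)) {
    write_grid_sidecar(grid, paste0(path, ".grid.json"))
  }
  invisible(path)
}

#' Read a DICOM RT Structure Set file
#'
#' Parses an explicit-VR little-endian RTSS into the internal polygon-stack
#' model. Contour order and vertex order are preserved exactly; no cleaning
#' is applied at read time.
#'
#' @param path file path.
#' @param z_tol tolerance on within-contour z variation, mm; a contour
#'   whose z spread exceeds it is rejected as non-planar.
#' @return list of `rt_structure` objects, one per ROI.
#' @export
read_rtss <- function(path, z_tol = 1e-3) {
  buf <- readBin(path, "raw", n = file.size(path))
  if (length(buf) < 140L || rawToChar(buf[129:132]) != "DICM") {
    stop("not a DICOM file (missing DICM magic): ", path)
  }
  # file meta group (always explicit VR LE); its group length bounds it
  pos <- 133L
  if (!(dcm_read_u16(buf, pos) == 0x0002 && dcm_read_u16(buf, pos + 2L) == 0x0000)) {
    stop("missing file meta group length element")
  }
  meta_len <- dcm_read_u32(buf, pos + 8L)
  meta <- dcm_parse_dataset(buf, pos + 12L, pos + 11L + meta_len)
  ts <- dcm_element_string(meta, "0002,0010")
  if (!is.null(ts) && ts != EXPLICIT_VR_LE) {
    stop("unsupported transfer syntax '", ts,
         "'; only explicit VR little endian is handled")
  }
  ds <- dcm_parse_dataset(buf, pos + 12L + meta_len, length(buf))

  roi_seq <- ds[["3006,0020"]]
  contour_seq <- ds[["3006,0039"]]
  if (is.null(contour_seq)) {
    stop("not an RT Structure Set: missing ROIContourSequence (3006,0039)")
  }
  if (is.null(roi_seq)) {
    stop("not an RT Structure Set: missing StructureSetROISequence (3006,0020)")
  }
  roi_names <- character(0); roi_for <- character(0)
  for (item in roi_seq) {
    num <- dcm_element_string(item, "3006,0022")
    roi_names[num] <- dcm_element_string(item, "3006,0026")
    forv <- dcm_element_string(item, "3006,0024")
    roi_for[num] <- if (is.null(forv)) NA_character_ else forv
  }

  structures <- list()
  for (item in contour_seq) {
    num <- dcm_element_string(item, "3006,0084")
    name <- if (!is.null(num) && num %in% names(roi_names)) roi_names[[num]] else paste0("ROI_", length(structures) + 1L)
    contours <- list()
    for (cit in if (is.null(item[["3006,0040"]])) list() else item[["3006,0040"]]) {
      gtype <- dcm_element_string(cit, "3006,0042")
      if (!identical(gtype, "CLOSED_PLANAR")) {
        stop("ROI '", name, "': unsupported contour geometric type '",
             gtype, "' (only CLOSED_PLANAR is handled)")
      }
      vals <- as.numeric(dcm_element_values(cit, "3006,0050"))
      if (length(vals) %% 3 != 0) {
        stop("ROI '", name, "': contour data length not a multiple of 3")
      }
      M <- matrix(vals, ncol = 3, byrow = TRUE)
      if (diff(range(M[, 3])) > z_tol) {
        stop("ROI '", name, "': non-planar contour (z varies by ",
             format(diff(range(M[, 3]))), " mm)")
      }
      contours[[length(contours) + 1L]] <-
        planar_contour(M[, 1:2, drop = FALSE], z = M[1, 3])
    }
    fo <- roi_for[num]
    structures[[length(structures) + 1L]] <- rt_structure(
      name = name, contours = contours,
      frame_of_reference = if (is.na(fo)) "unknown" else fo
    )
  }
  structures
}

#' Write an image-grid sidecar file
#'
#' Plain JSON with keys dx, dy, dz, origin, shape; used when an RTSS has no
#' referenced image series to take the geometry from.
#'
#' @param grid an `image_grid`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grid_sidecar <- function(grid, path) {
  jsonlite::write_json(
    list(dx = grid$dx, dy = grid$dy, dz = grid$dz,
         origin = grid$origin, shape = grid$shape),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read an image-grid sidecar file
#'
#' @param path sidecar path, or an RTSS path (then `<path>.grid.json` is
#'   tried).
#' @return an `image_grid`.
#' @export
read_grid_sidecar <- function(path) {
  if (!grepl("\\.grid\\.json$", path) && file.exists(paste0(path, ".grid.json"))) {
    path <- paste0(path, ".grid.json")
  }
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  image_grid(g$dx, g$dy, g$dz, origin = g$origin, shape = g$shape)
}
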