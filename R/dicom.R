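# Minimal DICOM (explicit VR little endian) encoder/decoder, sufficient for
# RT Structure Set round trips. Only the element types the RTSS IOD needs
# are implemented; sequences are written with defined lengths and read with
# defined or undefined lengths.

.short_vrs <- c("AE", "AS", "AT", "CS", "DA", "DS", "DT", "FL", "FD", "IS",
                "LO", "LT", "PN", "SH", "SL", "SS", "ST", "TM", "UI", "UL", "US")
.long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

uint16_raw <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
uint32_raw <- function(x) {
  # avoid 32-bit signed overflow for lengths >= 2^31 (not expected, guard anyway)
  x <- as.numeric(x)
  writeBin(as.integer(c(x %% 65536, x %/% 65536)), raw(), size = 2, endian = "little")
}

dcm_tag_raw <- function(group, element) c(uint16_raw(group), uint16_raw(element))

# encode one data element; value must already be a raw vector of even length
dcm_element <- function(group, element, vr, value) {
  stopifnot(is.raw(value), length(value) %% 2 == 0)
  tag <- dcm_tag_raw(group, element)
  if (vr %in% .long_vrs) {
    c(tag, charToRaw(vr), as.raw(c(0, 0)), uint32_raw(length(value)), value)
  } else {
    if (length(value) > 65534) {
      stop("DICOM element (", sprintf("%04x,%04x", group, element),
           ") value of ", length(value),
           " bytes exceeds the explicit-VR 16-bit length limit; ",
           "reduce the contour density or decimal places")
    }
    c(tag, charToRaw(vr), uint16_raw(length(value)), value)
  }
}

# string-valued element with correct even-length padding (NUL for UI,
# space for text VRs)
dcm_string_element <- function(group, element, vr, value) {
  v <- charToRaw(paste(value, collapse = "\\"))
  if (length(v) %% 2 == 1) {
    v <- c(v, if (vr == "UI") as.raw(0) else charToRaw(" "))
  }
  dcm_element(group, element, vr, v)
}

# sequence element from a list of items (each item: raw vector of encoded
# elements); defined lengths throughout
dcm_sequence <- function(group, element, items) {
  body <- raw(0)
  for (it in items) {
    body <- c(body, dcm_tag_raw(0xFFFE, 0xE000), uint32_raw(length(it)), it)
  }
  dcm_element(group, element, "SQ", body)
}

.uid_counter <- local({
  n <- 0L
  function() {
    n <<- n + 1L
    n
  }
})

# generated UIDs under a private example root
dcm_make_uid <- function() {
  paste0("1.2.826.0.1.3680043.9.7484.",
         format(as.numeric(Sys.time()) * 1000, scientific = FALSE, trim = TRUE),
         ".", .uid_counter(), ".", sample.int(99999L, 1))
}

# ---- decoding -------------------------------------------------------------

dcm_read_u16 <- function(buf, pos) {
  as.integer(buf[pos]) + 256L * as.integer(buf[pos + 1L])
}
dcm_read_u32 <- function(buf, pos) {
  as.numeric(buf[pos]) + 256 * as.numeric(buf[pos + 1L]) +
    65536 * as.numeric(buf[pos + 2L]) + 16777216 * as.numeric(buf[pos + 3L])
}

# parse an explicit-VR LE element stream buf[pos..end] into a named list
# keyed "gggg,eeee" (hex); SQ values become lists of item element-lists
dcm_parse_dataset <- function(buf, pos, end) {
  out <- list()
  while (pos <= end - 7L) {
    group <- dcm_read_u16(buf, pos)
    element <- dcm_read_u16(buf, pos + 2L)
    key <- sprintf("%04x,%04x", group, element)
    if (group == 0xFFFE) {
      # item/sequence delimiters should be consumed by the SQ branch
      stop("unexpected item delimiter at offset ", pos)
    }
    vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
    if (!(vr %in% c(.short_vrs, .long_vrs))) {
      stop("unsupported or implicit VR '", vr, "' at offset ", pos,
           "; only explicit VR little endian is handled")
    }
    if (vr %in% .long_vrs) {
      len <- dcm_read_u32(buf, pos + 8L)
      body_start <- pos + 12L
    } else {
      len <- dcm_read_u16(buf, pos + 6L)
      body_start <- pos + 8L
    }
    if (vr == "SQ") {
      parsed <- dcm_parse_sequence(buf, body_start, len, end)
      out[[key]] <- parsed$items
      pos <- parsed$next_pos
    } else {
      if (len == 4294967295) stop("undefined length on non-SQ element ", key)
      value <- if (len > 0) buf[body_start:(body_start + len - 1L)] else raw(0)
      out[[key]] <- list(vr = vr, bytes = value)
      pos <- body_start + len
    }
  }
  out
}

# parse sequence items; len may be defined or 0xFFFFFFFF (undefined)
dcm_parse_sequence <- function(buf, pos, len, stream_end) {
  undefined <- len == 4294967295
  end <- if (undefined) stream_end else pos + len - 1L
  items <- list()
  while (pos <= end - 7L) {
    group <- dcm_read_u16(buf, pos)
    element <- dcm_read_u16(buf, pos + 2L)
    ilen <- dcm_read_u32(buf, pos + 4L)
    pos <- pos + 8L
    if (group == 0xFFFE && element == 0xE0DD) break            # sequence delimiter
    if (!(group == 0xFFFE && element == 0xE000)) {
      stop("malformed sequence: expected item tag at offset ", pos - 8L)
    }
    if (ilen == 4294967295) {
      # undefined-length item: scan for the item delimiter at this nesting
      # level by parsing elements one by one
      parsed_item <- dcm_parse_undefined_item(buf, pos, end)
      items[[length(items) + 1L]] <- parsed_item$elements
      pos <- parsed_item$next_pos
    } else {
      items[[length(items) + 1L]] <-
        if (ilen > 0) dcm_parse_dataset(buf, pos, pos + ilen - 1L) else list()
      pos <- pos + ilen
    }
  }
  if (undefined) {
    # pos already advanced past the delimiter tag+length by the loop break
    list(items = items, next_pos = pos)
  } else {
    list(items = items, next_pos = end + 1L)
  }
}

dcm_parse_undefined_item <- function(buf, pos, end) {
  elements <- list()
  while (pos <= end - 7L) {
    group <- dcm_read_u16(buf, pos)
    element <- dcm_read_u16(buf, pos + 2L)
    if (group == 0xFFFE && element == 0xE00D) {
      return(list(elements = elements, next_pos = pos + 8L))
    }
    one <- dcm_parse_dataset(buf, pos, pos + element_span(buf, pos) - 1L)
    elements <- utils::modifyList(elements, one)
    pos <- pos + element_span(buf, pos)
  }
  list(elements = elements, next_pos = pos)
}

# byte span of the single element starting at pos (explicit VR LE)
element_span <- function(buf, pos) {
  vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
  if (vr %in% .long_vrs) {
    len <- dcm_read_u32(buf, pos + 8L)
    if (vr == "SQ" && len == 4294967295) {
      stop("undefined-length SQ inside undefined-length item is not supported")
    }
    12L + len
  } else {
    8L + dcm_read_u16(buf, pos + 6L)
  }
}

dcm_element_string <- function(ds, key) {
  el <- ds[[key]]
  if (is.null(el)) return(NULL)
  bytes <- el$bytes
  while (length(bytes) && bytes[length(bytes)] == as.raw(0)) {
    bytes <- bytes[-length(bytes)]            # trailing NUL padding (UI)
  }
  trimws(rawToChar(bytes), which = "right")
}

dcm_element_values <- function(ds, key) {
  s <- dcm_element_string(ds, key)
  if (is.null(s)) return(NULL)
  trimws(strsplit(s, "\\", fixed = TRUE)[[1]])
}
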