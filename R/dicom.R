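# Minimal DICOM codec: Explicit VR Little Endian, single-frame MR slices.
# No DICOM library exists in the supported R stack, so the package carries
# its own reader/writer for exactly the subset it emits.  The element-level
# functions are shared by the session writer and the pseudonymiser.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
SOP_CLASS_MR <- "1.2.840.10008.5.1.4.1.1.4"
UID_ROOT <- "2.25."  # UUID-derived numeric UID root

SERIES_DESCRIPTIONS <- c(fat = "dixon_fat", water = "dixon_water",
                         in_phase = "dixon_ip", out_of_phase = "dixon_op",
                         b50 = "dwi_b50", b900 = "dwi_b900", adc = "adc")

# deterministic numeric UID from a string key
make_uid <- function(key) {
  h <- digest::digest(key, algo = "sha256")
  # map 32 hex chars to a decimal string (no leading zero)
  digits <- strtoi(strsplit(substr(h, 1, 30), "")[[1]], 16L) %% 10L
  paste0(UID_ROOT, "1", paste(digits, collapse = ""))
}

long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

dcm_element <- function(group, element, vr, value) {
  list(group = group, element = element, vr = vr, value = value)
}

encode_value <- function(vr, value) {
  if (vr == "US") {
    v <- writeBin(as.integer(value), raw(), size = 2, endian = "little")
  } else if (vr %in% c("OW", "OB")) {
    v <- value  # raw already
  } else {
    s <- paste(value, collapse = "\\")
    v <- charToRaw(s)
  }
  if (length(v) %% 2 == 1) {
    pad <- if (vr == "UI") as.raw(0) else charToRaw(" ")
    v <- c(v, pad)
  }
  v
}

write_element <- function(con, el) {
  writeBin(as.integer(c(el$group, el$element)), con, size = 2,
           endian = "little")
  v <- encode_value(el$vr, el$value)
  writeChar(el$vr, con, nchars = 2, eos = NULL)
  if (el$vr %in% long_vrs) {
    writeBin(as.integer(c(0)), con, size = 2, endian = "little")
    writeBin(length(v), con, size = 4, endian = "little")
  } else {
    writeBin(length(v), con, size = 2, endian = "little")
  }
  writeBin(v, con)
}

element_bytes <- function(el) {
  v <- encode_value(el$vr, el$value)
  hdr <- if (el$vr %in% long_vrs) 12L else 8L
  hdr + length(v)
}

#' Write a DICOM file from an element list
#'
#' Low-level: 128-byte preamble, `DICM`, a minimal file-meta group
#' (Explicit VR Little Endian transfer syntax) and the given data elements,
#' which must be sorted by (group, element).
#'
#' @param elements list of elements (`group`, `element`, `vr`, `value`)
#' @param path output file
#' @keywords internal
dcm_write <- function(elements, path) {
  sop_uid <- NULL
  for (el in elements)
    if (el$group == 0x0008 && el$element == 0x0018) sop_uid <- el$value
  meta <- list(
    dcm_element(0x0002, 0x0002, "UI", SOP_CLASS_MR),
    dcm_element(0x0002, 0x0003, "UI", sop_uid %||% make_uid(path)),
    dcm_element(0x0002, 0x0010, "UI", TS_EXPLICIT_LE))
  meta_len <- sum(vapply(meta, element_bytes, integer(1)))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(raw(128), con)
  writeChar("DICM", con, nchars = 4, eos = NULL)
  # (0002,0000) GroupLength, VR UL
  writeBin(as.integer(c(0x0002, 0x0000)), con, size = 2, endian = "little")
  writeChar("UL", con, nchars = 2, eos = NULL)
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(as.integer(meta_len), con, size = 4, endian = "little")
  for (el in meta) write_element(con, el)
  for (el in elements) write_element(con, el)
  invisible(path)
}

#' Read the elements of a DICOM file
#'
#' Supports Explicit VR Little Endian only (the syntax this package
#' writes).  String values are decoded and split on `\\`; `US` becomes an
#' integer vector; `OW`/`OB` stay raw.
#'
#' @param path DICOM file
#' @return list of elements (`group`, `element`, `vr`, `value`)
#' @keywords internal
dcm_read <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  readBin(con, "raw", 128)
  if (rawToChar(readBin(con, "raw", 4)) != "DICM")
    stop("not a DICOM file (missing DICM marker): ", path)
  read_one <- function() {
    ge <- readBin(con, "integer", 2, size = 2, endian = "little",
                  signed = FALSE)
    if (length(ge) < 2) return(NULL)
    vr <- rawToChar(readBin(con, "raw", 2))
    if (vr %in% long_vrs) {
      readBin(con, "raw", 2)
      len <- readBin(con, "integer", 1, size = 4, endian = "little")
    } else if (vr == "UL" || grepl("^[A-Z]{2}$", vr)) {
      len <- readBin(con, "integer", 1, size = 2, endian = "little",
                     signed = FALSE)
    } else stop("unsupported or implicit VR encountered: ", path)
    bytes <- readBin(con, "raw", len)
    value <- if (vr %in% c("OW", "OB")) bytes
    else if (vr == "US") readBin(bytes, "integer", len / 2, size = 2,
                                 endian = "little", signed = FALSE)
    else if (vr == "UL") readBin(bytes, "integer", len / 4, size = 4,
                                 endian = "little")
    else {
      nb <- length(bytes)
      while (nb > 0 && bytes[nb] %in% as.raw(c(0L, 32L))) nb <- nb - 1L
      strsplit(rawToChar(bytes[seq_len(nb)]), "\\\\")[[1]]
    }
    dcm_element(ge[1], ge[2], vr, value)
  }
  out <- list()
  ts <- NULL
  repeat {
    if (seek(con, where = NA) >= sz) break
    el <- read_one()
    if (is.null(el)) break
    if (el$group == 0x0002) {
      if (el$element == 0x0010) ts <- el$value
      next
    }
    out[[length(out) + 1L]] <- el
  }
  if (!is.null(ts) && ts != TS_EXPLICIT_LE)
    stop("unsupported transfer syntax: ", ts)
  out
}

dcm_get <- function(elements, group, element) {
  for (el in elements)
    if (el$group == group && el$element == element) return(el$value)
  NULL
}

ds_fmt <- function(x) {
  # DS values are limited to 16 bytes
  vapply(x, function(v) {
    s <- formatC(v, format = "g", digits = 10)
    if (nchar(s) > 16) s <- formatC(v, format = "g", digits = 8)
    s
  }, character(1))
}

#' Write an imaging session as DICOM
#'
#' One file per slice per series, Explicit VR Little Endian, pixel data as
#' uint16 with a per-series rescale (slope/intercept) chosen to span the
#' value range.  Geometry (image position, orientation, pixel spacing) is
#' written as decimal strings and round-trips at 1e-4 mm precision.
#'
#' @param session an [imaging_session()]
#' @param directory output directory (created if needed)
#' @return data.frame manifest: `series`, `instance`, `path`
#' @export
write_session_dicom <- function(session, directory) {
  stopifnot(inherits(session, "imaging_session"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  study_uid <- make_uid(paste0(session$subject_id, "/", session$session_id))
  manifest <- list()
  for (lbl in names(session$series)) {
    st <- session$series[[lbl]]
    desc <- SERIES_DESCRIPTIONS[lbl]
    if (is.na(desc)) desc <- lbl
    series_uid <- make_uid(paste0(study_uid, "/", lbl))
    d <- dim(st$voxels)
    rng <- range(st$voxels)
    slope <- if (diff(rng) > 0) diff(rng) / 65535 else 1
    intercept <- rng[1]
    nrm <- slice_normal(st)
    for (i in seq_len(d[1])) {
      ipp <- st$origin + (st$slice_positions[i] - st$slice_positions[1]) * nrm
      stored <- round((matrix(st$voxels[i, , ], d[2], d[3]) - intercept) /
                        slope)
      # transpose before flattening: DICOM pixel data is row-major
      pix <- writeBin(as.integer(t(stored)), raw(), size = 2,
                      endian = "little")
      els <- list(
        dcm_element(0x0008, 0x0016, "UI", SOP_CLASS_MR),
        dcm_element(0x0008, 0x0018, "UI",
                    make_uid(paste0(series_uid, "/", i))),
        dcm_element(0x0008, 0x103E, "LO", desc),
        dcm_element(0x0010, 0x0010, "PN", session$subject_id),
        dcm_element(0x0010, 0x0020, "LO", session$subject_id),
        dcm_element(0x0018, 0x0050, "DS", ds_fmt(st$nominal_slice_spacing)),
        dcm_element(0x0018, 0x0088, "DS", ds_fmt(st$nominal_slice_spacing)),
        dcm_element(0x0020, 0x000D, "UI", study_uid),
        dcm_element(0x0020, 0x000E, "UI", series_uid),
        dcm_element(0x0020, 0x0013, "IS", as.character(i)),
        dcm_element(0x0020, 0x0032, "DS", ds_fmt(ipp)),
        dcm_element(0x0020, 0x0037, "DS",
                    ds_fmt(c(st$orientation$row, st$orientation$col))),
        dcm_element(0x0028, 0x0002, "US", 1L),
        dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
        dcm_element(0x0028, 0x0010, "US", d[2]),
        dcm_element(0x0028, 0x0011, "US", d[3]),
        dcm_element(0x0028, 0x0030, "DS", ds_fmt(st$pixel_spacing)),
        dcm_element(0x0028, 0x0100, "US", 16L),
        dcm_element(0x0028, 0x0101, "US", 16L),
        dcm_element(0x0028, 0x0102, "US", 15L),
        dcm_element(0x0028, 0x0103, "US", 0L),
        dcm_element(0x0028, 0x1052, "DS", ds_fmt(intercept)),
        dcm_element(0x0028, 0x1053, "DS", ds_fmt(slope)),
        dcm_element(0x7FE0, 0x0010, "OW", pix))
      fname <- sprintf("%s_%04d.dcm", desc, i)
      dcm_write(els, file.path(directory, fname))
      manifest[[length(manifest) + 1L]] <-
        data.frame(series = lbl, instance = i,
                   path = file.path(directory, fname))
    }
  }
  do.call(rbind, manifest)
}

require_tag <- function(els, group, element, name, path) {
  v <- dcm_get(els, group, element)
  if (is.null(v))
    stop(sprintf("missing DICOM tag (%04X,%04X) %s in %s",
                 group, element, name, path))
  v
}

#' Read one session's DICOM directory
#'
#' Groups files by Series Instance UID, sorts slices by the projection of
#' their image position onto the slice normal, and rebuilds one
#' [slice_stack()] per series.  Contrast labels are recovered from the
#' series descriptions written by [write_session_dicom()]; unknown
#' descriptions keep their string as label.
#'
#' @param directory directory containing one session's `.dcm` files
#' @param subject_id,session_id,cohort,protocol session metadata (DICOM
#'   holds only the pseudonymous patient ID)
#' @return an [imaging_session()]
#' @export
read_session_dicom <- function(directory, subject_id = NULL,
                               session_id = basename(directory),
                               cohort = "a_retro_RM",
                               protocol = "transverse_dixon") {
  files <- list.files(directory, pattern = "\\.dcm$", full.names = TRUE)
  if (!length(files)) stop("no DICOM files in ", directory)
  per_file <- lapply(files, function(f) {
    els <- dcm_read(f)
    list(path = f, els = els,
         series_uid = require_tag(els, 0x0020, 0x000E,
                                  "SeriesInstanceUID", f))
  })
  by_series <- split(per_file, vapply(per_file, `[[`, character(1),
                                      "series_uid"))
  label_lookup <- stats::setNames(names(SERIES_DESCRIPTIONS),
                                  SERIES_DESCRIPTIONS)
  series <- list()
  sid <- subject_id
  for (grp in by_series) {
    first <- grp[[1]]$els
    desc <- dcm_get(first, 0x0008, 0x103E) %||% "unknown"
    lbl <- label_lookup[desc]
    if (is.na(lbl)) lbl <- desc
    iop <- as.numeric(require_tag(first, 0x0020, 0x0037,
                                  "ImageOrientationPatient", grp[[1]]$path))
    rdir <- iop[1:3]; cdir <- iop[4:6]
    nrm <- cross3(rdir, cdir)
    slices <- lapply(grp, function(g) {
      els <- g$els
      iop_i <- as.numeric(require_tag(els, 0x0020, 0x0037,
                                      "ImageOrientationPatient", g$path))
      if (max(abs(iop_i - iop)) > 1e-4)
        stop("mixed orientations within one series: ", g$path)
      ipp <- as.numeric(require_tag(els, 0x0020, 0x0032,
                                    "ImagePositionPatient", g$path))
      ps <- as.numeric(require_tag(els, 0x0028, 0x0030,
                                   "PixelSpacing", g$path))
      rows <- require_tag(els, 0x0028, 0x0010, "Rows", g$path)
      cols <- require_tag(els, 0x0028, 0x0011, "Columns", g$path)
      slope <- as.numeric(dcm_get(els, 0x0028, 0x1053) %||% "1")
      inter <- as.numeric(dcm_get(els, 0x0028, 0x1052) %||% "0")
      pix_raw <- require_tag(els, 0x7FE0, 0x0010, "PixelData", g$path)
      stored <- readBin(pix_raw, "integer", rows * cols, size = 2,
                        endian = "little", signed = FALSE)
      img <- t(matrix(stored, nrow = cols, ncol = rows)) * slope + inter
      list(pos = sum(ipp * nrm), ipp = ipp, img = img, ps = ps,
           rows = rows, cols = cols,
           spacing = as.numeric(dcm_get(els, 0x0018, 0x0088) %||%
                                  dcm_get(els, 0x0018, 0x0050) %||% "1"),
           patient = dcm_get(els, 0x0010, 0x0020))
    })
    ord <- order(vapply(slices, `[[`, numeric(1), "pos"))
    slices <- slices[ord]
    rows <- slices[[1]]$rows; cols <- slices[[1]]$cols
    vox <- array(0, dim = c(length(slices), rows, cols))
    for (i in seq_along(slices)) vox[i, , ] <- slices[[i]]$img
    pos <- vapply(slices, `[[`, numeric(1), "pos")
    if (is.null(sid)) sid <- slices[[1]]$patient %||% "UNKNOWN"
    series[[lbl]] <- slice_stack(
      vox, slice_positions = pos,
      orientation = list(row = rdir, col = cdir),
      origin = slices[[1]]$ipp,
      pixel_spacing = slices[[1]]$ps,
      nominal_slice_spacing = slices[[1]]$spacing,
      contrast_label = lbl)
  }
  ord_lbl <- c(intersect(CONTRAST_LABELS, names(series)),
               setdiff(names(series), CONTRAST_LABELS))
  imaging_session(sid %||% "UNKNOWN", session_id, series[ord_lbl],
                  cohort = cohort, protocol = protocol)
}
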