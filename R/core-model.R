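# Core domain types shared by every pipeline stage: image stacks with
# per-slice geometry, station bookkeeping, imaging sessions, disease-pattern
# coding and the count aggregation behind the study's summary tables.

#' Disease-pattern code vocabulary
#'
#' Canonical rendering order for the eight per-session disease codes:
#' focal (F), diffuse (D), paramedullary (PM), extramedullary (EM),
#' micronodular (MN), inactive (I), new diagnosis (N) and healthy (H).
#' @export
PATTERN_CODES <- c("F", "D", "PM", "EM", "MN", "I", "N", "H")

#' Contrast labels of a complete whole-body session
#'
#' The seven series a radiological read requires: four Dixon contrasts,
#' two diffusion b-values and the ADC map.
#' @export
CONTRAST_LABELS <- c("in_phase", "out_of_phase", "fat", "water",
                     "b50", "b900", "adc")

COHORTS <- c("a_retro_RM", "b_iTIMM", "c_healthy", "d_retro_ICHT")
PROTOCOLS <- c("transverse_dixon", "coronal_dixon")

#' Default 18-region skeletal annotation scheme
#'
#' The per-session semantic annotation is recorded against 18 bony regions.
#' The region list is configurable; this default covers the axial and
#' proximal appendicular skeleton read in whole-body myeloma MRI.
#' @return character vector of 18 region names
#' @export
default_region_list <- function() {
  c("skull", "cervical_spine", "thoracic_spine", "lumbar_spine", "sacrum",
    "pelvis_left", "pelvis_right", "sternum",
    "ribs_left", "ribs_right",
    "clavicle_left", "clavicle_right",
    "scapula_left", "scapula_right",
    "humerus_left", "humerus_right",
    "femur_left", "femur_right")
}

vec3 <- function(x) {
  x <- as.numeric(x)
  if (length(x) != 3L || anyNA(x)) stop("expected a numeric length-3 vector")
  x
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Construct a SliceStack
#'
#' A `slice_stack` is one image series: a 3-D voxel array indexed
#' `[slice, row, col]` plus the spatial geometry needed to place every
#' voxel in the patient (LPS) coordinate frame.  `slice_positions` are the
#' mm offsets of each slice along the slice normal (the projection of each
#' slice's position onto `cross(row, col)`); `origin` is the patient-space
#' position of the first voxel of the first slice.
#'
#' @param voxels 3-D numeric array, slices x rows x cols
#' @param slice_positions numeric, mm offset of each slice along the normal
#' @param orientation list with unit vectors `row` (direction of increasing
#'   column index) and `col` (direction of increasing row index), DICOM
#'   image-orientation convention
#' @param origin numeric length 3, mm (LPS)
#' @param pixel_spacing numeric length 2, (row, col) spacing in mm
#' @param nominal_slice_spacing nominal slice-to-slice spacing in mm
#' @param contrast_label one of [CONTRAST_LABELS] (free strings permitted for
#'   extraneous series)
#' @return object of class `slice_stack`
#' @export
slice_stack <- function(voxels, slice_positions, orientation, origin,
                        pixel_spacing, nominal_slice_spacing,
                        contrast_label) {
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a 3-D array (slices x rows x cols)")
  slice_positions <- as.numeric(slice_positions)
  if (length(slice_positions) != dim(voxels)[1])
    stop("slice_positions length must equal the slice count")
  if (!is.list(orientation) || !all(c("row", "col") %in% names(orientation)))
    stop("orientation must be a list with elements 'row' and 'col'")
  r <- vec3(orientation$row); cvec <- vec3(orientation$col)
  if (abs(sqrt(sum(r^2)) - 1) > 1e-6 || abs(sqrt(sum(cvec^2)) - 1) > 1e-6)
    stop("orientation vectors must be unit-norm (tolerance 1e-6)")
  if (abs(sum(r * cvec)) > 1e-6)
    stop("orientation vectors must be orthogonal (tolerance 1e-6)")
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) != 2L || any(pixel_spacing <= 0))
    stop("pixel_spacing must be two positive values (row, col) in mm")
  if (!is.numeric(nominal_slice_spacing) || nominal_slice_spacing <= 0)
    stop("nominal_slice_spacing must be positive")
  structure(list(
    voxels = voxels,
    slice_positions = slice_positions,
    orientation = list(row = r, col = cvec),
    origin = vec3(origin),
    pixel_spacing = pixel_spacing,
    nominal_slice_spacing = as.numeric(nominal_slice_spacing),
    contrast_label = as.character(contrast_label)
  ), class = "slice_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<slice_stack '%s'> %d slices x %d x %d, spacing %.3g/%.3g/%.3g mm\n",
              x$contrast_label, d[1], d[2], d[3],
              x$pixel_spacing[1], x$pixel_spacing[2],
              x$nominal_slice_spacing))
  invisible(x)
}

#' Slice normal of a stack
#' @param stack a [slice_stack()]
#' @return unit length-3 vector, `cross(row, col)`
#' @export
slice_normal <- function(stack) {
  cross3(stack$orientation$row, stack$orientation$col)
}

#' Construct a StationBlock
#'
#' The contiguous run of slices contributed by one couch position within a
#' composed stack.  Ranges are 1-based and inclusive.
#'
#' @param station_index ordinal of the station (1 = first acquired)
#' @param slice_range integer length 2, first and last slice (inclusive)
#' @param source_offset_mm in-plane (x, y) translation applied by the
#'   composition step; `c(0, 0)` for a clean block
#' @return object of class `station_block`
#' @export
station_block <- function(station_index, slice_range,
                          source_offset_mm = c(0, 0)) {
  slice_range <- as.integer(slice_range)
  if (length(slice_range) != 2L || slice_range[1] > slice_range[2])
    stop("slice_range must be c(first, last) with first <= last")
  structure(list(station_index = as.integer(station_index),
                 slice_range = slice_range,
                 source_offset_mm = as.numeric(source_offset_mm)),
            class = "station_block")
}

validate_blocks <- function(blocks, n_slices) {
  idx <- vapply(blocks, function(b) b$station_index, integer(1))
  if (anyDuplicated(idx)) stop("station ordinals must be unique")
  covered <- unlist(lapply(blocks, function(b)
    seq.int(b$slice_range[1], b$slice_range[2])))
  if (anyDuplicated(covered)) stop("station slice_ranges must be disjoint")
  if (!missing(n_slices) && !setequal(covered, seq_len(n_slices)))
    stop("station blocks must partition the stack")
  invisible(TRUE)
}

#' Construct an ImagingSession
#'
#' One subject visit: a named list of series keyed by contrast label,
#' the subject's cohort and the acquisition protocol.  Optionally carries
#' the station-block decomposition of the composed volumes (known for
#' synthetic sessions, inferred for clinical ones).
#'
#' @param subject_id pseudonymous subject identifier
#' @param session_id session identifier
#' @param series named list of [slice_stack()], one per contrast label
#' @param cohort one of `a_retro_RM`, `b_iTIMM`, `c_healthy`, `d_retro_ICHT`
#' @param protocol `transverse_dixon` or `coronal_dixon`
#' @param blocks optional list of [station_block()]
#' @return object of class `imaging_session`
#' @export
imaging_session <- function(subject_id, session_id, series,
                            cohort = "a_retro_RM",
                            protocol = "transverse_dixon",
                            blocks = NULL) {
  cohort <- match.arg(cohort, COHORTS)
  protocol <- match.arg(protocol, PROTOCOLS)
  if (!is.list(series) || is.null(names(series)) || any(names(series) == ""))
    stop("series must be a named list of slice_stack objects")
  if (anyDuplicated(names(series)))
    stop("at most one series per contrast label")
  for (s in series)
    if (!inherits(s, "slice_stack")) stop("series entries must be slice_stack")
  structure(list(subject_id = as.character(subject_id),
                 session_id = as.character(session_id),
                 series = series, cohort = cohort, protocol = protocol,
                 blocks = blocks),
            class = "imaging_session")
}

#' @export
print.imaging_session <- function(x, ...) {
  cat(sprintf("<imaging_session %s/%s> cohort %s, protocol %s, series: %s\n",
              x$subject_id, x$session_id, x$cohort, x$protocol,
              paste(names(x$series), collapse = ", ")))
  invisible(x)
}

# ---- disease-pattern coding ------------------------------------------------

#' Parse a disease-pattern code string
#'
#' Pattern codes are whitespace-separated letters from the study vocabulary
#' (see [PATTERN_CODES]): e.g. `"F D PM"` denotes focal plus diffuse plus
#' paramedullary disease in one imaging session.  Input is case-insensitive;
#' duplicates collapse; `H` (healthy volunteer) may not be combined with any
#' disease code.
#'
#' @param code character scalar, e.g. `"F D PM"`
#' @return object of class `disease_pattern`: a character vector of codes in
#'   canonical order
#' @export
parse_pattern_code <- function(code) {
  if (!is.character(code) || length(code) != 1L || is.na(code) ||
      !nzchar(trimws(code)))
    stop("pattern code must be a non-empty string")
  toks <- toupper(strsplit(trimws(code), "\\s+")[[1]])
  unknown <- setdiff(toks, PATTERN_CODES)
  if (length(unknown))
    stop(sprintf("unknown pattern code(s): %s",
                 paste(sQuote(unknown), collapse = ", ")))
  toks <- unique(toks)
  if ("H" %in% toks && length(toks) > 1L)
    stop("'H' (healthy) cannot be combined with disease codes")
  structure(PATTERN_CODES[PATTERN_CODES %in% toks], class = "disease_pattern")
}

#' Render a disease pattern as its canonical code string
#' @param pattern a `disease_pattern`
#' @return character scalar, codes in canonical order separated by spaces
#' @export
format_pattern <- function(pattern) {
  paste(PATTERN_CODES[PATTERN_CODES %in% pattern], collapse = " ")
}

#' @export
print.disease_pattern <- function(x, ...) {
  cat("<disease_pattern>", format_pattern(x), "\n")
  invisible(x)
}

#' Coalesce a disease pattern into a phase-allocation category
#'
#' Per-session patterns are collapsed to the four categories used for
#' stratified phase allocation: focal (F), diffuse (D), inactive (I) and
#' healthy (H).  `H` always maps to `H`.  Otherwise the first code in
#' `precedence` present in the pattern wins; micronodular (MN) counts as
#' `mn_category` (default focal) before precedence is applied.  EM, PM and N
#' never determine the category on their own.
#'
#' @param pattern a `disease_pattern` (or string parsed on the fly)
#' @param precedence category precedence, default `c("F", "D", "I")`
#' @param mn_category category that MN contributes, default `"F"`
#' @return one of `"F"`, `"D"`, `"I"`, `"H"`
#' @export
coalesce_category <- function(pattern, precedence = c("F", "D", "I"),
                              mn_category = "F") {
  if (is.character(pattern) && !inherits(pattern, "disease_pattern"))
    pattern <- parse_pattern_code(paste(pattern, collapse = " "))
  stopifnot(all(precedence %in% c("F", "D", "I")),
            mn_category %in% c("F", "D", "I"))
  codes <- as.character(pattern)
  if ("H" %in% codes) return("H")
  if ("MN" %in% codes) codes <- union(codes, mn_category)
  for (cat in precedence) if (cat %in% codes) return(cat)
  stop(sprintf("uncategorisable pattern '%s': no focal/diffuse/inactive code",
               format_pattern(pattern)))
}

#' Aggregate disease-pattern counts by phase
#'
#' Builds the per-session pattern-by-phase count table (the layout of the
#' study's per-session summary table): one row per distinct pattern, one
#' column per phase, plus a combined column and a Total row.
#'
#' @param records data.frame with columns `session_id`, `phase` (1, 2 or 3)
#'   and `pattern_code` (strings accepted by [parse_pattern_code()])
#' @return data.frame with columns `pattern`, one `phase_<p>` column per
#'   phase present in `phases`, `combined`, and a final `Total` row
#' @param phases integer phases to tabulate as columns (default 1:2)
#' @export
aggregate_pattern_counts <- function(records, phases = c(1L, 2L)) {
  stopifnot(is.data.frame(records))
  need <- c("session_id", "phase", "pattern_code")
  if (!all(need %in% names(records)))
    stop("records needs columns session_id, phase, pattern_code")
  if (nrow(records) == 0L) {
    out <- data.frame(pattern = character(0))
    for (p in phases) out[[paste0("phase_", p)]] <- integer(0)
    out$combined <- integer(0)
    tot <- data.frame(pattern = "Total")
    for (p in phases) tot[[paste0("phase_", p)]] <- 0L
    tot$combined <- 0L
    return(rbind(out, tot))
  }
  if (anyDuplicated(records$session_id))
    stop("duplicate session_id in pattern records")
  if (!all(records$phase %in% c(1L, 2L, 3L)))
    stop("phase must be 1, 2 or 3")
  canon <- vapply(records$pattern_code,
                  function(s) format_pattern(parse_pattern_code(s)),
                  character(1), USE.NAMES = FALSE)
  keep <- records$phase %in% phases
  canon <- canon[keep]; phase <- records$phase[keep]
  pats <- unique(canon)
  counts <- sapply(phases, function(p)
    vapply(pats, function(pt) sum(canon == pt & phase == p), integer(1)))
  counts <- matrix(counts, nrow = length(pats),
                   dimnames = list(NULL, paste0("phase_", phases)))
  combined <- rowSums(counts)
  ord <- order(-combined, pats)
  out <- data.frame(pattern = pats[ord], counts[ord, , drop = FALSE],
                    combined = combined[ord], row.names = NULL,
                    check.names = FALSE)
  tot <- data.frame(pattern = "Total",
                    t(colSums(counts)), combined = sum(combined),
                    check.names = FALSE)
  rbind(out, tot)
}

#' Construct a semantic annotation record for one bony region
#'
#' The per-region electronic case report captures focal lesion count,
#' maximum lesion size, and booleans for diffuse disease, inactive disease,
#' normal appearance and imaging artefact.  A region marked normal cannot
#' carry focal lesions or diffuse disease.
#'
#' @param region_name region, must be in `regions`
#' @param focal_lesion_count non-negative integer
#' @param max_lesion_size_mm non-negative mm
#' @param diffuse_present,inactive_present,region_normal,artefact_present
#'   logical flags
#' @param regions allowed region vocabulary, default [default_region_list()]
#' @return object of class `annotation_record`
#' @export
annotation_record <- function(region_name, focal_lesion_count = 0L,
                              max_lesion_size_mm = 0,
                              diffuse_present = FALSE,
                              inactive_present = FALSE,
                              region_normal = FALSE,
                              artefact_present = FALSE,
                              regions = default_region_list()) {
  if (!region_name %in% regions)
    stop(sprintf("unknown region '%s'", region_name))
  focal_lesion_count <- as.integer(focal_lesion_count)
  if (is.na(focal_lesion_count) || focal_lesion_count < 0L)
    stop("focal_lesion_count must be a non-negative integer")
  if (max_lesion_size_mm < 0) stop("max_lesion_size_mm must be >= 0")
  if (region_normal && (focal_lesion_count > 0L || diffuse_present))
    stop("a normal region cannot have focal lesions or diffuse disease")
  structure(list(region_name = region_name,
                 focal_lesion_count = focal_lesion_count,
                 max_lesion_size_mm = as.numeric(max_lesion_size_mm),
                 diffuse_present = isTRUE(diffuse_present),
                 inactive_present = isTRUE(inactive_present),
                 region_normal = isTRUE(region_normal),
                 artefact_present = isTRUE(artefact_present)),
            class = "annotation_record")
}

#' Read a disease-pattern table
#'
#' @param path CSV with header `subject_id, session_id, pattern_code, cohort`
#' @return data.frame with those columns, patterns canonicalised
#' @export
read_pattern_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "session_id", "pattern_code", "cohort")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("pattern table missing column(s): ", paste(miss, collapse = ", "))
  df$pattern_code <- vapply(df$pattern_code,
                            function(s) format_pattern(parse_pattern_code(s)),
                            character(1), USE.NAMES = FALSE)
  df
}
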