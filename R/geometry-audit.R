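# Slice-contiguity audit of composed series: classify every slice-to-slice
# gap as contiguous, underlap (missing coverage, red) or overlap (redundant
# coverage, amber), compare series grids within a session, and check that
# station blocks appear in spatial order.

#' Classify slice-to-slice gaps of a composed series
#'
#' Each gap `g` between consecutive slice positions is compared against the
#' nominal spacing `s`: contiguous if `|g - s| <= rel_tol * s`, underlap if
#' `g > s * (1 + rel_tol)`, overlap if `g < s * (1 - rel_tol)` (duplicate
#' positions are a full overlap, `g = 0`).  `n_slices_equivalent` is
#' `round(|g - s| / s)`, the defect size in whole slices.
#'
#' @param slice_positions sorted (ascending) slice positions in mm
#' @param nominal_spacing nominal spacing in mm; if `NULL`, inferred as the
#'   mode of gaps rounded to 0.1 mm (robust when most gaps are clean)
#' @param rel_tol relative tolerance, default 0.05
#' @return object of class `gap_classification`: data.frame `boundaries`
#'   with `gap_mm`, `class`, `n_slices_equivalent`, plus `counts` and the
#'   `nominal_spacing` used
#' @export
classify_gaps <- function(slice_positions, nominal_spacing = NULL,
                          rel_tol = 0.05) {
  p <- as.numeric(slice_positions)
  if (length(p) < 2L) stop("need at least 2 slices to classify gaps")
  if (is.unsorted(p)) stop("slice positions must be sorted ascending")
  if (!(rel_tol > 0 && rel_tol < 0.5)) stop("rel_tol must be in (0, 0.5)")
  g <- diff(p)
  if (is.null(nominal_spacing)) {
    rg <- round(g[g > 0] / 0.1) * 0.1
    if (!length(rg)) stop("cannot infer nominal spacing: all gaps zero")
    tab <- table(rg)
    nominal_spacing <- as.numeric(names(tab)[which.max(tab)])
  }
  s <- nominal_spacing
  if (!is.numeric(s) || s <= 0) stop("nominal spacing must be positive")
  cls <- ifelse(abs(g - s) <= rel_tol * s, "contiguous",
                ifelse(g > s, "underlap", "overlap"))
  neq <- as.integer(round(abs(g - s) / s))
  boundaries <- data.frame(boundary = seq_along(g), gap_mm = g, class = cls,
                           n_slices_equivalent = neq)
  counts <- c(contiguous = sum(cls == "contiguous"),
              underlap = sum(cls == "underlap"),
              overlap = sum(cls == "overlap"))
  structure(list(boundaries = boundaries, counts = counts,
                 nominal_spacing = s, rel_tol = rel_tol),
            class = "gap_classification")
}

#' @export
print.gap_classification <- function(x, ...) {
  cat(sprintf("<gap_classification> %d boundaries: %d contiguous, %d underlap, %d overlap (nominal %.3g mm)\n",
              nrow(x$boundaries), x$counts["contiguous"],
              x$counts["underlap"], x$counts["overlap"], x$nominal_spacing))
  invisible(x)
}

#' ASCII gap map
#'
#' One character per boundary: `c` contiguous, `u` underlap, `o` overlap —
#' a diff-able rendering of the audit graphic.
#' @param gaps a [classify_gaps()] result
#' @return character scalar
#' @export
gap_map_ascii <- function(gaps) {
  paste(substr(gaps$boundaries$class, 1, 1), collapse = "")
}

#' Render the gap map as a colour strip PNG
#'
#' Blue = contiguous, white = underlap (missing data), dark blue = overlap.
#' @param gaps a [classify_gaps()] result
#' @param path output PNG path
#' @export
gap_map_png <- function(gaps, path) {
  cols <- c(contiguous = "#9ecae1", underlap = "#ffffff",
            overlap = "#08519c")
  n <- nrow(gaps$boundaries)
  grDevices::png(path, width = max(2 * n, 64), height = 40)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  graphics::plot(NULL, xlim = c(0, n), ylim = c(0, 1), xaxs = "i",
                 yaxs = "i", axes = FALSE, xlab = "", ylab = "")
  graphics::rect(seq_len(n) - 1, 0, seq_len(n), 1,
                 col = cols[gaps$boundaries$class], border = NA)
  invisible(path)
}

# group consecutive defective boundaries of one class into findings
gap_findings <- function(gaps) {
  b <- gaps$boundaries
  bad <- which(b$class != "contiguous")
  if (!length(bad)) return(data.frame(class = character(0),
                                      first_boundary = integer(0),
                                      last_boundary = integer(0),
                                      n_slices = integer(0),
                                      gap_mm = numeric(0)))
  # one composition event can leave its defective boundaries separated by a
  # contiguous one (interleaved duplicates), so allow a gap of one boundary
  runs <- split(bad, cumsum(c(1, diff(bad) > 2 |
                                b$class[bad][-1] != b$class[bad][-length(bad)])))
  do.call(rbind, lapply(runs, function(ix) {
    data.frame(class = b$class[ix[1]],
               first_boundary = ix[1], last_boundary = ix[length(ix)],
               n_slices = sum(pmax(b$n_slices_equivalent[ix], 1L)),
               gap_mm = sum(b$gap_mm[ix]))
  }))
}

#' Audit one series for slice contiguity
#'
#' Severity is `red` if any underlap is present (missing data), `amber` if
#' only overlaps (repairable by interpolation with no loss of information)
#' and `ok` otherwise.  Findings group runs of consecutive defective
#' boundaries into single events with their total size in slices.
#'
#' @param stack a [slice_stack()]
#' @param rel_tol relative gap tolerance, default 0.05
#' @param nominal_spacing override the stack's nominal spacing (default:
#'   use the stack's tag)
#' @return list with `gaps` ([classify_gaps()]), `findings` (data.frame),
#'   `severity` and human-readable `summary` lines
#' @export
audit_series <- function(stack, rel_tol = 0.05, nominal_spacing = NULL) {
  stopifnot(inherits(stack, "slice_stack"))
  s <- nominal_spacing %||% stack$nominal_slice_spacing
  gaps <- classify_gaps(stack$slice_positions, s, rel_tol)
  f <- gap_findings(gaps)
  severity <- if (any(f$class == "underlap")) "red"
  else if (nrow(f)) "amber" else "ok"
  summary_lines <- if (!nrow(f)) {
    sprintf("%s: all %d gaps contiguous at %.3g mm",
            stack$contrast_label, nrow(gaps$boundaries), s)
  } else {
    sprintf("%s: %s of %d slice(s) at boundaries %d-%d (%.2f mm)",
            stack$contrast_label, f$class, f$n_slices,
            f$first_boundary, f$last_boundary, f$gap_mm)
  }
  list(gaps = gaps, findings = f, severity = severity,
       summary = summary_lines)
}

#' Compare the spatial grids of two series
#'
#' Reports origin and pixel-spacing deltas and the symmetric difference of
#' slice-position sets (0.01 mm match tolerance).  The report is empty iff
#' both series live on the same grid.
#'
#' @param a,b two [slice_stack()] objects from one session
#' @param tol_mm slice-position match tolerance, default 0.01
#' @return list with `origin_delta_mm`, `spacing_delta_mm`,
#'   `slices_only_in_a`, `slices_only_in_b`, and logical `identical`
#' @export
compare_grids <- function(a, b, tol_mm = 0.01) {
  stopifnot(inherits(a, "slice_stack"), inherits(b, "slice_stack"))
  origin_delta <- b$origin - a$origin
  spacing_delta <- b$pixel_spacing - a$pixel_spacing
  pa <- a$slice_positions; pb <- b$slice_positions
  only_a <- pa[vapply(pa, function(p) !any(abs(pb - p) <= tol_mm),
                      logical(1))]
  only_b <- pb[vapply(pb, function(p) !any(abs(pa - p) <= tol_mm),
                      logical(1))]
  # duplicates on one side only also break grid identity
  same_multiset <- length(pa) == length(pb) &&
    all(abs(sort(pa) - sort(pb)) <= tol_mm)
  ident <- all(abs(origin_delta) <= tol_mm) &&
    all(abs(spacing_delta) <= tol_mm) && same_multiset
  list(origin_delta_mm = origin_delta, spacing_delta_mm = spacing_delta,
       slices_only_in_a = only_a, slices_only_in_b = only_b,
       identical = ident)
}

#' Check station ordering of a composed stack
#'
#' Stations are in order iff their mean slice positions increase with their
#' position in the stack.  The inferred permutation sorts blocks by mean
#' position and, applied via [reorder_stations()], restores spatial order.
#'
#' @param stack a [slice_stack()]
#' @param blocks list of [station_block()] partitioning the stack
#' @return list with `verdict` (`"ordered"`/`"misordered"`) and
#'   `permutation` (entry `i`: which current block belongs at position `i`)
#' @export
check_station_order <- function(stack, blocks) {
  stopifnot(inherits(stack, "slice_stack"))
  validate_blocks(blocks, dim(stack$voxels)[1])
  means <- vapply(blocks, function(b)
    mean(stack$slice_positions[seq.int(b$slice_range[1], b$slice_range[2])]),
    numeric(1))
  perm <- order(means)
  verdict <- if (is.unsorted(means, strictly = FALSE)) "misordered"
  else "ordered"
  list(verdict = verdict, permutation = perm, block_mean_positions = means)
}

#' Audit a whole session
#'
#' Runs [audit_series()] on every series, [compare_grids()] on each series
#' against the session's reference grid donor (fat, else the first series),
#' and [check_station_order()] where station blocks are known.
#'
#' @param session an [imaging_session()]
#' @param rel_tol gap tolerance
#' @return object of class `audit_report`
#' @export
audit_session <- function(session, rel_tol = 0.05) {
  stopifnot(inherits(session, "imaging_session"))
  per_series <- lapply(session$series, audit_series, rel_tol = rel_tol)
  sev <- vapply(per_series, `[[`, character(1), "severity")
  ref_lbl <- if ("fat" %in% names(session$series)) "fat"
  else names(session$series)[1]
  grid_vs_ref <- lapply(session$series, compare_grids,
                        b = session$series[[ref_lbl]])
  order_check <- NULL
  if (!is.null(session$blocks)) {
    # ordering is only well-defined for series the blocks partition
    st <- session$series[[ref_lbl]]
    n <- dim(st$voxels)[1]
    last <- max(vapply(session$blocks, function(b) b$slice_range[2],
                       integer(1)))
    if (last == n) order_check <- check_station_order(st, session$blocks)
  }
  structure(list(session_id = session$session_id, per_series = per_series,
                 severity = sev, reference = ref_lbl,
                 grid_vs_reference = grid_vs_ref,
                 station_order = order_check),
            class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  cat(sprintf("<audit_report %s>\n", x$session_id))
  for (lbl in names(x$per_series)) {
    cat(sprintf("  [%-5s] %s\n", x$severity[[lbl]],
                paste(x$per_series[[lbl]]$summary, collapse = "; ")))
  }
  if (!is.null(x$station_order))
    cat("  station order:", x$station_order$verdict, "\n")
  invisible(x)
}
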