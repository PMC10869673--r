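# Repairs for the defects the audit finds: regrid overlapping/underlapping
# stacks onto a uniform slice grid (overlaps averaged + interpolated with no
# information loss, underlaps interpolated but flagged as fabricated),
# estimate and undo per-station in-plane composition offsets by phase
# correlation, and restore misordered stations.

#' Regrid a stack onto a uniform slice grid
#'
#' The output grid spans the input's first to last slice position at the
#' nominal spacing.  Slices sharing a position (full overlap) are averaged;
#' every output slice is then linearly interpolated along the slice normal
#' from the available data.  Output slices falling inside an underlap gap
#' (no source slice within the nominal spacing) are interpolated too but
#' marked `TRUE` in `missing_mask` — they are fabricated, not measured.
#'
#' @param stack a [slice_stack()]
#' @param gaps optional [classify_gaps()] result for the stack (recomputed
#'   if omitted)
#' @param rel_tol gap tolerance used when `gaps` is omitted
#' @return object of class `repaired_stack`: list with `stack` (uniform
#'   grid), `missing_mask` (logical array, same dim) and `repair_log`
#' @export
regrid_overlaps <- function(stack, gaps = NULL, rel_tol = 0.05) {
  stopifnot(inherits(stack, "slice_stack"))
  p <- stack$slice_positions
  if (length(unique(round(p / 0.01))) < 2L)
    stop("degenerate stack: fewer than 2 distinct slice positions")
  if (is.null(gaps)) gaps <- classify_gaps(p, stack$nominal_slice_spacing,
                                           rel_tol)
  s <- gaps$nominal_spacing
  log <- list()

  # average slices that share a position (0.01 mm)
  key <- round(p / 0.01)
  if (anyDuplicated(key)) {
    grp <- match(key, unique(key))
    d <- dim(stack$voxels)
    vox <- array(0, dim = c(length(unique(key)), d[2], d[3]))
    for (g in seq_len(max(grp))) {
      ix <- which(grp == g)
      vox[g, , ] <- if (length(ix) == 1L) stack$voxels[ix, , ]
      else apply(stack$voxels[ix, , , drop = FALSE], c(2, 3), mean)
    }
    log <- c(log, list(list(action = "average_duplicates",
                            n_slices_merged = length(p) - dim(vox)[1])))
    p <- p[!duplicated(key)]
    stack$voxels <- vox
    stack$slice_positions <- p
  }

  n_out <- as.integer(round((p[length(p)] - p[1]) / s)) + 1L
  out_pos <- p[1] + (seq_len(n_out) - 1L) * s
  d <- dim(stack$voxels)
  vox_out <- array(0, dim = c(n_out, d[2], d[3]))
  missing <- array(FALSE, dim = c(n_out, d[2], d[3]))
  interp_needed <- FALSE
  for (i in seq_len(n_out)) {
    t <- out_pos[i]
    j <- findInterval(t + 1e-9, p)
    if (j >= 1L && abs(p[j] - t) <= 0.01) {
      vox_out[i, , ] <- stack$voxels[j, , ]
      next
    }
    interp_needed <- TRUE
    j <- max(1L, min(j, length(p) - 1L))
    w <- (t - p[j]) / (p[j + 1L] - p[j])
    vox_out[i, , ] <- (1 - w) * stack$voxels[j, , ] +
      w * stack$voxels[j + 1L, , ]
    # fabricated iff no measured slice within one nominal spacing
    if (min(abs(p - t)) > s * (1 - 1e-9) / 2 &&
        (p[j + 1L] - p[j]) > s * (1 + gaps$rel_tol))
      missing[i, , ] <- TRUE
  }
  if (interp_needed)
    log <- c(log, list(list(action = "interpolate_to_uniform_grid",
                            nominal_spacing = s)))
  if (any(missing))
    log <- c(log, list(list(
      action = "mask_underlap",
      n_fabricated_slices = sum(apply(missing, 1, any)))))
  out <- stack
  out$voxels <- vox_out
  out$slice_positions <- out_pos
  structure(list(stack = out, missing_mask = missing, repair_log = log),
            class = "repaired_stack")
}

#' @export
print.repaired_stack <- function(x, ...) {
  cat(sprintf("<repaired_stack '%s'> %d slices, %d fabricated, %d action(s)\n",
              x$stack$contrast_label, dim(x$stack$voxels)[1],
              sum(apply(x$missing_mask, 1, any)), length(x$repair_log)))
  invisible(x)
}

grad_mag <- function(img) {
  gx <- img * 0; gy <- img * 0
  n <- nrow(img); m <- ncol(img)
  gy[2:(n - 1), ] <- (img[3:n, ] - img[1:(n - 2), ]) / 2
  gx[, 2:(m - 1)] <- (img[, 3:m] - img[, 1:(m - 2)]) / 2
  sqrt(gx^2 + gy^2)
}

#' Estimate the in-plane composition offset of one station
#'
#' Integer-pixel translation of `moving` relative to `reference` over one
#' station's slices, by phase correlation of the gradient-magnitude images
#' averaged over the block.  Positive `dx` means the moving content sits
#' `dx` columns to the right of the reference (and `dy` rows down).
#'
#' @param moving,reference co-gridded [slice_stack()]s (e.g. fat vs water)
#' @param block a [station_block()] valid in both stacks
#' @param max_shift_px search bound, default 16
#' @param on_out_of_bounds `"error"` (default) or `"flag"`: behaviour when
#'   the correlation peak lies outside the search bound
#' @return integer `c(dx, dy)`; with `on_out_of_bounds = "flag"` the result
#'   carries attribute `out_of_bounds = TRUE` when clipped
#' @export
estimate_inplane_offset <- function(moving, reference, block,
                                    max_shift_px = 16L,
                                    on_out_of_bounds = c("error", "flag")) {
  on_out_of_bounds <- match.arg(on_out_of_bounds)
  stopifnot(inherits(moving, "slice_stack"),
            inherits(reference, "slice_stack"),
            inherits(block, "station_block"))
  idx <- seq.int(block$slice_range[1], block$slice_range[2])
  if (max(idx) > dim(moving$voxels)[1] || max(idx) > dim(reference$voxels)[1])
    stop("block slice range exceeds stack extent")
  avg <- function(stk) {
    m <- apply(stk$voxels[idx, , , drop = FALSE], c(2, 3), mean)
    grad_mag(m)
  }
  a <- avg(reference); b <- avg(moving)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("uninformative block: zero-variance image content")
  Fa <- stats::fft(a); Fb <- stats::fft(b)
  R <- Fb * Conj(Fa)
  R <- R / pmax(Mod(R), .Machine$double.eps)
  corr <- Re(stats::fft(R, inverse = TRUE))
  n <- nrow(corr); m <- ncol(corr)
  wrap <- function(i, N) ifelse(i > N / 2, i - N, i)
  dy_all <- wrap(seq_len(n) - 1L, n)
  dx_all <- wrap(seq_len(m) - 1L, m)
  ok <- outer(abs(dy_all) <= max_shift_px, abs(dx_all) <= max_shift_px)
  peak_global <- which(corr == max(corr), arr.ind = TRUE)[1, ]
  masked <- corr; masked[!ok] <- -Inf
  peak <- which(masked == max(masked), arr.ind = TRUE)[1, ]
  out_of_bounds <- !ok[peak_global[1], peak_global[2]] &&
    corr[peak_global[1], peak_global[2]] > masked[peak[1], peak[2]]
  if (out_of_bounds && on_out_of_bounds == "error")
    stop(sprintf("offset beyond search bound +/-%d px", max_shift_px))
  res <- c(dx = dx_all[peak[2]], dy = dy_all[peak[1]])
  if (out_of_bounds) attr(res, "out_of_bounds") <- TRUE
  res
}

#' Undo per-station in-plane offsets
#'
#' Translates each station's block by the negated estimated shift,
#' zero-padding at the edges.
#'
#' @param stack a [slice_stack()]
#' @param blocks list of [station_block()]
#' @param shifts list (one per block, same order) of `c(dx, dy)` as
#'   returned by [estimate_inplane_offset()]; `NULL` entries skip a block
#' @return list with the corrected `stack` and a `repair_log`
#' @export
apply_offset_correction <- function(stack, blocks, shifts) {
  stopifnot(inherits(stack, "slice_stack"),
            length(blocks) == length(shifts))
  log <- list()
  for (k in seq_along(blocks)) {
    sh <- shifts[[k]]
    if (is.null(sh) || all(sh == 0)) next
    rg <- blocks[[k]]$slice_range
    stack$voxels <- translate_slices(stack$voxels,
                                     seq.int(rg[1], rg[2]),
                                     -as.integer(sh[1]), -as.integer(sh[2]))
    log <- c(log, list(list(action = "undo_inplane_offset",
                            station = blocks[[k]]$station_index,
                            dx_px = unname(sh[1]), dy_px = unname(sh[2]))))
  }
  list(stack = stack, repair_log = log)
}

#' Restore misordered stations
#'
#' Re-sorts the station blocks by the given permutation (entry `i`: the
#' current block that belongs at position `i`, as inferred by
#' [check_station_order()]) and reassigns slice positions monotonically.
#'
#' @param stack a [slice_stack()]
#' @param blocks list of [station_block()] partitioning the stack
#' @param permutation integer permutation of `seq_along(blocks)`
#' @return list with reordered `stack`, updated `blocks`, `repair_log`
#' @export
reorder_stations <- function(stack, blocks, permutation) {
  stopifnot(inherits(stack, "slice_stack"))
  validate_blocks(blocks, dim(stack$voxels)[1])
  permutation <- as.integer(permutation)
  if (!identical(sort(permutation), seq_along(blocks)))
    stop("permutation must be a bijection on the station blocks")
  idx <- unlist(lapply(permutation, function(i) {
    rg <- blocks[[i]]$slice_range
    seq.int(rg[1], rg[2])
  }))
  out <- stack
  out$voxels <- stack$voxels[idx, , , drop = FALSE]
  out$slice_positions <- sort(stack$slice_positions)
  sizes <- vapply(permutation, function(i) {
    rg <- blocks[[i]]$slice_range
    rg[2] - rg[1] + 1L
  }, integer(1))
  stop_at <- cumsum(sizes)
  start_at <- c(1L, utils::head(stop_at, -1L) + 1L)
  new_blocks <- lapply(seq_along(permutation), function(k) {
    b <- blocks[[permutation[k]]]
    b$slice_range <- as.integer(c(start_at[k], stop_at[k]))
    b
  })
  log <- if (identical(permutation, seq_along(blocks))) list()
  else list(list(action = "reorder_stations",
                 permutation = permutation))
  list(stack = out, blocks = new_blocks, repair_log = log)
}

#' Audit and repair one session end to end
#'
#' Runs the full cleaning chain on a session: station-order check and
#' restore, gap audit and regridding, fat-water swap detection and fix,
#' and per-station offset estimation (fat vs water) and undo.  Every action
#' is appended to the session's [run_record()].
#'
#' @param session an [imaging_session()] with station `blocks`
#' @param config list of knobs: `rel_tol`, `max_shift_px`, `swap_theta`,
#'   `swap_min_volume`
#' @param record optional [run_record()] to append to
#' @return list with `session` (repaired), `missing_masks` (per series),
#'   `record`, and `findings` (audit + swap findings)
#' @export
clean_session <- function(session, config = list(), record = NULL) {
  rel_tol <- config$rel_tol %||% 0.05
  max_shift <- config$max_shift_px %||% 16L
  record <- record %||% run_record(config = config)

  # 1. station order (use fat series when blocks partition it)
  findings <- list()
  if (!is.null(session$blocks)) {
    ref <- session$series[[if ("fat" %in% names(session$series)) "fat"
                           else names(session$series)[1]]]
    if (max(vapply(session$blocks, function(b) b$slice_range[2],
                   integer(1))) == dim(ref$voxels)[1]) {
      chk <- check_station_order(ref, session$blocks)
      findings$station_order <- chk
      if (chk$verdict == "misordered") {
        for (lbl in names(session$series)) {
          r <- reorder_stations(session$series[[lbl]], session$blocks,
                                chk$permutation)
          session$series[[lbl]] <- r$stack
          new_blocks <- r$blocks
        }
        session$blocks <- new_blocks
      }
      record <- record_step(record, "check_station_order",
                            params = list(),
                            findings = list(verdict = chk$verdict,
                                            permutation = chk$permutation))
    }
  }

  # 2. gap audit + regrid
  audits <- lapply(session$series, audit_series, rel_tol = rel_tol)
  findings$audit <- audits
  missing_masks <- list()
  for (lbl in names(session$series)) {
    a <- audits[[lbl]]
    record <- record_step(record, paste0("audit_series:", lbl),
                          params = list(rel_tol = rel_tol),
                          findings = list(severity = a$severity,
                                          summary = a$summary))
    if (a$severity != "ok") {
      n_before <- dim(session$series[[lbl]]$voxels)[1]
      rep <- regrid_overlaps(session$series[[lbl]], a$gaps)
      session$series[[lbl]] <- rep$stack
      if (any(rep$missing_mask)) missing_masks[[lbl]] <- rep$missing_mask
      record <- record_step(record, paste0("regrid:", lbl),
                            params = list(),
                            findings = list(
                              slices_in = n_before,
                              slices_out = dim(rep$stack$voxels)[1],
                              actions = rep$repair_log))
    }
  }
  # after regridding, recompute block ranges from slice counts if the grid
  # changed uniformly (defects injected into all series alike)
  if (!is.null(session$blocks)) {
    n_now <- dim(session$series[[1]]$voxels)[1]
    n_st <- length(session$blocks)
    if (n_now %% n_st == 0L) {
      sps <- n_now %/% n_st
      session$blocks <- lapply(seq_len(n_st), function(i) {
        b <- session$blocks[[i]]
        b$slice_range <- c((i - 1L) * sps + 1L, i * sps)
        b
      })
    }
  }

  # 3. per-station in-plane offsets (fat moving vs water reference).
  #    Geometry must be restored before the label checks: a misaligned fat
  #    rim mimics a station swap in the rim statistic.  Phase correlation
  #    itself keys on shared anatomy edges, so it is label-robust.
  if (all(c("fat", "water") %in% names(session$series)) &&
      !is.null(session$blocks)) {
    fat <- session$series$fat; wat <- session$series$water
    if (identical(dim(fat$voxels), dim(wat$voxels)) &&
        max(vapply(session$blocks, function(b) b$slice_range[2],
                   integer(1))) == dim(fat$voxels)[1]) {
      shifts <- lapply(session$blocks, function(b)
        estimate_inplane_offset(fat, wat, b, max_shift_px = max_shift))
      findings$offsets <- shifts
      corr <- apply_offset_correction(fat, session$blocks, shifts)
      session$series$fat <- corr$stack
      record <- record_step(record, "offset_correction",
                            params = list(max_shift_px = max_shift,
                                          reference = "water"),
                            findings = list(shifts = lapply(shifts, unname)))
    }
  }

  # 4. fat-water swaps
  if (all(c("fat", "water") %in% names(session$series))) {
    sw <- detect_swaps(session, config = config)
    findings$swaps <- sw
    record <- record_step(record, "detect_swaps",
                          params = list(theta = config$swap_theta %||% 0.2),
                          findings = list(n = length(sw),
                                          findings = summarise_findings(sw)))
    if (length(sw)) {
      session <- apply_swap_fix(session, sw)
      record <- record_step(record, "apply_swap_fix", params = list(),
                            findings = list(applied = sum(vapply(
                              sw, function(f) f$action == "relabel",
                              logical(1)))))
    }
  }

  list(session = session, missing_masks = missing_masks,
       record = record, findings = findings)
}
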