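# Regridding, offset estimation/correction, station reordering, and the
# end-to-end clean_session chain.

test_that("regrid_overlaps is the identity on a uniform stack", {
  s <- compact_phantom(31)
  r <- regrid_overlaps(s$series$fat)
  expect_identical(r$stack$voxels, s$series$fat$voxels)
  expect_equal(length(r$repair_log), 0L)
  expect_false(any(r$missing_mask))
})

test_that("regrid_overlaps repairs duplicates and masks underlaps", {
  s <- compact_phantom(31)
  sps <- compact_spec(31)$slices_per_station

  d <- inject_defects(s, defect_ledger(slice_gap_events = list(
    list(boundary = 1, class = "overlap", n_slices = 2))))
  r <- regrid_overlaps(d$series$fat)
  expect_equal(dim(r$stack$voxels), dim(s$series$fat$voxels))
  expect_equal(diff(r$stack$slice_positions),
               rep(6, dim(r$stack$voxels)[1] - 1))
  # duplicated slices carry identical content, so averaging restores the
  # original exactly; no voxel is fabricated
  expect_equal(r$stack$voxels, s$series$fat$voxels)
  expect_false(any(r$missing_mask))
  expect_gt(length(r$repair_log), 0L)

  d2 <- inject_defects(s, defect_ledger(slice_gap_events = list(
    list(boundary = 2, class = "underlap", n_slices = 2))))
  r2 <- regrid_overlaps(d2$series$fat)
  expect_equal(dim(r2$stack$voxels), dim(s$series$fat$voxels))
  fabricated <- which(apply(r2$missing_mask, 1, any))
  # exactly the two deleted slice positions are fabricated
  expect_equal(fabricated, 2L * sps + 1:2)
  expect_true(all(r2$missing_mask[fabricated, , ]))
  # measured slices are untouched
  expect_equal(r2$stack$voxels[-fabricated, , ],
               s$series$fat$voxels[-fabricated, , ])

  # conservation: mean body-mask intensity preserved within 1 %
  body <- body_rim_masks(s$series$fat, s$series$water)$body
  expect_lt(abs(mean(r2$stack$voxels[body]) -
                  mean(s$series$fat$voxels[body])) /
              mean(s$series$fat$voxels[body]), 0.01)

  # degenerate stack: all slices at one position
  st <- s$series$fat
  st$slice_positions <- rep(0, length(st$slice_positions))
  expect_error(regrid_overlaps(st), "degenerate")
})

test_that("offset estimation recovers injected shifts exactly", {
  s <- compact_phantom(32)
  fat <- s$series$fat; water <- s$series$water
  expect_equal(unname(estimate_inplane_offset(fat, water, s$blocks[[1]])),
               c(0, 0))

  led <- defect_ledger(offset_events = list(
    list(station = 2, dx_px = 3, dy_px = -2)))
  d <- inject_defects(s, led)
  est <- estimate_inplane_offset(d$series$fat, d$series$water,
                                 d$blocks[[2]])
  expect_equal(unname(est), c(3, -2))

  # parameter-recovery sweep at 2 % noise over a grid of shifts
  for (sh in list(c(-10, -7), c(-5, 5), c(0, 10), c(8, 0), c(10, 10))) {
    di <- inject_defects(s, defect_ledger(offset_events = list(
      list(station = 1, dx_px = sh[1], dy_px = sh[2]))))
    est_i <- estimate_inplane_offset(di$series$fat, di$series$water,
                                     di$blocks[[1]])
    expect_equal(unname(est_i), sh)
  }

  # beyond the search bound -> error (default) or flag
  d20 <- inject_defects(s, defect_ledger(offset_events = list(
    list(station = 2, dx_px = 14, dy_px = 0))))
  expect_error(estimate_inplane_offset(d20$series$fat, d20$series$water,
                                       d20$blocks[[2]], max_shift_px = 8L),
               "bound")
  flagged <- estimate_inplane_offset(d20$series$fat, d20$series$water,
                                     d20$blocks[[2]], max_shift_px = 8L,
                                     on_out_of_bounds = "flag")
  expect_true(isTRUE(attr(flagged, "out_of_bounds")))

  # zero-variance block is uninformative
  flat <- fat
  flat$voxels[] <- 1
  expect_error(estimate_inplane_offset(flat, flat, s$blocks[[1]]),
               "uninformative")
})

test_that("apply_offset_correction undoes shifts and is a fixed point", {
  s <- compact_phantom(32)
  led <- defect_ledger(offset_events = list(
    list(station = 2, dx_px = 4, dy_px = 3)))
  d <- inject_defects(s, led)
  shifts <- lapply(d$blocks, function(b)
    estimate_inplane_offset(d$series$fat, d$series$water, b))
  corr <- apply_offset_correction(d$series$fat, d$blocks, shifts)
  # re-estimation on the corrected stack gives zero everywhere
  for (b in d$blocks)
    expect_equal(unname(estimate_inplane_offset(corr$stack,
                                                d$series$water, b)),
                 c(0, 0))
  # round trip voxel-identical away from the shifted border
  interior_r <- 8:31; interior_c <- 8:31
  expect_equal(corr$stack$voxels[, interior_r, interior_c],
               s$series$fat$voxels[, interior_r, interior_c])
  # zero shifts are the identity
  id <- apply_offset_correction(s$series$fat, s$blocks,
                                list(c(0, 0), c(0, 0), c(0, 0)))
  expect_identical(id$stack$voxels, s$series$fat$voxels)
  expect_equal(length(id$repair_log), 0L)
})

test_that("reorder_stations validates and restores", {
  s <- compact_phantom(33)
  r_id <- reorder_stations(s$series$fat, s$blocks, 1:3)
  expect_identical(r_id$stack$voxels, s$series$fat$voxels)
  expect_equal(length(r_id$repair_log), 0L)
  expect_error(reorder_stations(s$series$fat, s$blocks, c(1, 1, 2)),
               "bijection")

  d <- inject_defects(s, defect_ledger(station_permutation = c(3, 1, 2)))
  chk <- check_station_order(d$series$fat, d$blocks)
  r <- reorder_stations(d$series$fat, d$blocks, chk$permutation)
  expect_identical(r$stack$voxels, s$series$fat$voxels)
  expect_equal(r$stack$slice_positions, s$series$fat$slice_positions)
})

test_that("clean_session repairs any single defect to within noise", {
  s <- compact_phantom(34)
  sigma <- 0.02 * 100
  ledgers <- list(
    overlap = defect_ledger(slice_gap_events = list(
      list(boundary = 1, class = "overlap", n_slices = 2))),
    underlap = defect_ledger(slice_gap_events = list(
      list(boundary = 2, class = "underlap", n_slices = 1))),
    offset = defect_ledger(offset_events = list(
      list(station = 3, dx_px = 5, dy_px = -4))),
    global_swap = defect_ledger(swap_events = list(list(scope = "global"))),
    station_swap = defect_ledger(swap_events = list(
      list(scope = "station", station = 2))),
    misorder = defect_ledger(station_permutation = c(2, 3, 1)))
  for (nm in names(ledgers)) {
    d <- inject_defects(s, ledgers[[nm]])
    out <- clean_session(d)
    dev <- abs(out$session$series$fat$voxels - s$series$fat$voxels)
    if (!is.null(out$missing_masks$fat)) dev[out$missing_masks$fat] <- 0
    if (nm == "offset") dev <- dev[, 8:31, 8:31]
    expect_lt(max(dev), 3 * sigma)
    expect_gt(length(out$record$steps), 0L)
  }
  # audit of a repaired session is never amber (overlaps always repaired)
  d <- inject_defects(s, ledgers$overlap)
  out <- clean_session(d)
  sev <- vapply(out$session$series, function(st) audit_series(st)$severity,
                character(1))
  expect_true(all(sev %in% c("ok", "red")))
  expect_true(all(sev == "ok"))
})
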