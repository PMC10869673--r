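# Harmonisation: resample every series of a session onto one common axial
# grid (the DWI acts as grid donor, since the transverse protocol was
# designed to match the DWI resolution), reformat coronal-protocol Dixon
# volumes to transverse, and export ML-ready NIfTI-1 with a correct
# LPS -> RAS affine.

#' Define the common target grid for a session
#'
#' Default rule: voxel size from the DWI donor series (b900, else b50);
#' field of view = union of the world-space bounding boxes of all series,
#' optionally clipped; axial orientation.  An explicit grid in `config`
#' overrides everything.
#'
#' @param session an [imaging_session()]
#' @param config list; `grid = list(origin, spacing, dims)` for an explicit
#'   grid, `max_extent_mm = c(x, y, z)` to clip the FOV union
#' @return object of class `target_grid`: `origin` (mm, LPS, centre of
#'   voxel (1,1,1)), `spacing` `c(dx, dy, dz)` mm, `dims` `c(nx, ny, nz)`
#' @export
define_target_grid <- function(session, config = list()) {
  if (!is.null(config$grid)) {
    g <- config$grid
    return(target_grid(g$origin, g$spacing, g$dims))
  }
  donor_lbl <- intersect(c("b900", "b50"), names(session$series))[1]
  if (is.na(donor_lbl))
    stop("no DWI donor series (b900/b50) and no explicit grid in config")
  donor <- session$series[[donor_lbl]]
  spacing <- c(donor$pixel_spacing[2], donor$pixel_spacing[1],
               donor$nominal_slice_spacing)
  # union of world-space extents over all series (voxel centres)
  lo <- rep(Inf, 3); hi <- rep(-Inf, 3)
  for (st in session$series) {
    cr <- stack_corners(st)
    lo <- pmin(lo, apply(cr, 2, min))
    hi <- pmax(hi, apply(cr, 2, max))
  }
  if (!is.null(config$max_extent_mm)) {
    centre <- (lo + hi) / 2
    half <- pmin((hi - lo) / 2, config$max_extent_mm / 2)
    lo <- centre - half; hi <- centre + half
  }
  dims <- pmax(1L, as.integer(floor((hi - lo) / spacing + 1e-6)) + 1L)
  target_grid(lo, spacing, dims)
}

#' @rdname define_target_grid
#' @param origin,spacing,dims grid fields (see above)
#' @export
target_grid <- function(origin, spacing, dims) {
  origin <- as.numeric(origin); spacing <- as.numeric(spacing)
  dims <- as.integer(dims)
  stopifnot(length(origin) == 3L, length(spacing) == 3L, length(dims) == 3L)
  if (any(spacing <= 0) || any(dims < 1L))
    stop("target grid spacing and dims must be positive")
  structure(list(origin = origin, spacing = spacing, dims = dims),
            class = "target_grid")
}

#' @export
print.target_grid <- function(x, ...) {
  cat(sprintf("<target_grid> %dx%dx%d @ %.3g/%.3g/%.3g mm, origin (%.1f, %.1f, %.1f)\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

# world coordinates of the 8 voxel-centre corners of a stack
stack_corners <- function(stack) {
  d <- dim(stack$voxels)
  nrm <- slice_normal(stack)
  offs <- stack$slice_positions - stack$slice_positions[1]
  res <- matrix(0, 8, 3)
  i <- 1L
  for (s in c(0, offs[length(offs)]))
    for (r in c(0, (d[2] - 1) * stack$pixel_spacing[1]))
      for (cc in c(0, (d[3] - 1) * stack$pixel_spacing[2])) {
        res[i, ] <- stack$origin + cc * stack$orientation$row +
          r * stack$orientation$col + s * nrm
        i <- i + 1L
      }
  res
}

#' Resample a stack onto a target grid
#'
#' Trilinear (default) or nearest-neighbour interpolation in world
#' coordinates.  Requires a uniform slice grid (regrid first if the audit
#' found gaps).  Voxels outside the source extent are 0 and marked in the
#' returned out-of-field mask.
#'
#' @param stack a [slice_stack()]
#' @param grid a [target_grid()]
#' @param interp `"linear"` or `"nearest"` (use nearest for masks)
#' @return list with `stack` (axial [slice_stack()] on the grid, voxel
#'   array indexed `[slice = z, row = y, col = x]`) and logical
#'   `out_of_field` of the same shape
#' @export
resample_to_grid <- function(stack, grid, interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  stopifnot(inherits(stack, "slice_stack"), inherits(grid, "target_grid"))
  p <- stack$slice_positions
  if (length(p) > 1L) {
    dp <- diff(p)
    if (any(abs(dp - dp[1]) > 0.01) || dp[1] <= 0)
      stop("stack must be on a strictly increasing uniform slice grid")
  }
  dz_src <- if (length(p) > 1L) diff(p)[1] else stack$nominal_slice_spacing
  d <- dim(stack$voxels)
  nrm <- slice_normal(stack)

  nx <- grid$dims[1]; ny <- grid$dims[2]; nz <- grid$dims[3]
  gx <- grid$origin[1] + (seq_len(nx) - 1L) * grid$spacing[1]
  gy <- grid$origin[2] + (seq_len(ny) - 1L) * grid$spacing[2]
  gz <- grid$origin[3] + (seq_len(nz) - 1L) * grid$spacing[3]
  # output array [slice = z, row = y, col = x]
  X <- array(rep(gx, each = nz * ny), dim = c(nz, ny, nx))
  Y <- array(rep(rep(gy, each = nz), times = nx), dim = c(nz, ny, nx))
  Z <- array(rep(gz, times = ny * nx), dim = c(nz, ny, nx))

  delta <- list(X - stack$origin[1], Y - stack$origin[2],
                Z - stack$origin[3])
  rdir <- stack$orientation$row; cdir <- stack$orientation$col
  ci <- (delta[[1]] * rdir[1] + delta[[2]] * rdir[2] +
           delta[[3]] * rdir[3]) / stack$pixel_spacing[2]
  ri <- (delta[[1]] * cdir[1] + delta[[2]] * cdir[2] +
           delta[[3]] * cdir[3]) / stack$pixel_spacing[1]
  si <- (delta[[1]] * nrm[1] + delta[[2]] * nrm[2] +
           delta[[3]] * nrm[3]) / dz_src

  inside <- si >= -1e-6 & si <= d[1] - 1 + 1e-6 &
    ri >= -1e-6 & ri <= d[2] - 1 + 1e-6 &
    ci >= -1e-6 & ci <= d[3] - 1 + 1e-6
  vals <- array(0, dim = c(nz, ny, nx))
  if (any(inside)) {
    siI <- si[inside]; riI <- ri[inside]; ciI <- ci[inside]
    if (interp == "nearest") {
      s0 <- pmin(pmax(round(siI), 0), d[1] - 1)
      r0 <- pmin(pmax(round(riI), 0), d[2] - 1)
      c0 <- pmin(pmax(round(ciI), 0), d[3] - 1)
      vals[inside] <- stack$voxels[1L + s0 + r0 * d[1] +
                                     c0 * d[1] * d[2]]
    } else {
      s0 <- pmin(pmax(floor(siI), 0), d[1] - 1); s1 <- pmin(s0 + 1, d[1] - 1)
      r0 <- pmin(pmax(floor(riI), 0), d[2] - 1); r1 <- pmin(r0 + 1, d[2] - 1)
      c0 <- pmin(pmax(floor(ciI), 0), d[3] - 1); c1 <- pmin(c0 + 1, d[3] - 1)
      fs <- pmin(pmax(siI - s0, 0), 1)
      fr <- pmin(pmax(riI - r0, 0), 1)
      fc <- pmin(pmax(ciI - c0, 0), 1)
      at <- function(s, r, cc) stack$voxels[1L + s + r * d[1] +
                                              cc * d[1] * d[2]]
      vals[inside] <-
        (1 - fs) * ((1 - fr) * ((1 - fc) * at(s0, r0, c0) +
                                  fc * at(s0, r0, c1)) +
                      fr * ((1 - fc) * at(s0, r1, c0) +
                              fc * at(s0, r1, c1))) +
        fs * ((1 - fr) * ((1 - fc) * at(s1, r0, c0) +
                            fc * at(s1, r0, c1)) +
                fr * ((1 - fc) * at(s1, r1, c0) +
                        fc * at(s1, r1, c1)))
    }
  } else stop("degenerate resampling: grid does not intersect source extent")

  out <- slice_stack(vals,
                     slice_positions = gz,
                     orientation = list(row = c(1, 0, 0), col = c(0, 1, 0)),
                     origin = grid$origin,
                     pixel_spacing = c(grid$spacing[2], grid$spacing[1]),
                     nominal_slice_spacing = grid$spacing[3],
                     contrast_label = stack$contrast_label)
  list(stack = out, out_of_field = !inside)
}

#' Harmonise a whole session onto its target grid
#'
#' @param session an [imaging_session()]
#' @param config passed to [define_target_grid()]
#' @return list with `grid`, `series` (named list of resampled stacks) and
#'   `out_of_field` masks
#' @export
harmonise_session <- function(session, config = list()) {
  grid <- define_target_grid(session, config)
  res <- lapply(session$series, resample_to_grid, grid = grid)
  list(grid = grid,
       series = lapply(res, `[[`, "stack"),
       out_of_field = lapply(res, `[[`, "out_of_field"))
}

# ---- NIfTI-1 ---------------------------------------------------------------

# Minimal NIfTI-1 writer/reader for the subset this package emits:
# single-file .nii or .nii.gz, float32 (or uint8 for masks), sform only.
# The affine maps voxel indices (i fastest) to RAS+ world coordinates;
# internal stacks are LPS, so the first two affine rows are negated.

nifti_affine <- function(stack) {
  p <- stack$slice_positions
  dz <- if (length(p) > 1L) diff(p)[1] else stack$nominal_slice_spacing
  nrm <- slice_normal(stack)
  M <- cbind(stack$orientation$row * stack$pixel_spacing[2],
             stack$orientation$col * stack$pixel_spacing[1],
             nrm * dz,
             stack$origin)
  M <- diag(c(-1, -1, 1)) %*% M  # LPS -> RAS
  rbind(M, c(0, 0, 0, 1))
}

#' Export a stack as NIfTI-1
#'
#' Data are written with the column index fastest (i = column, j = row,
#' k = slice); the sform affine maps voxel indices to RAS+ mm and
#' round-trips within 1e-5.  Requires a strictly uniform slice grid.
#'
#' @param stack a [slice_stack()]
#' @param path output path; `.nii.gz` gzip-compresses
#' @param missing_mask optional logical array (same dim as the voxels); if
#'   given, a paired `<path minus extension>_mask.nii.gz` uint8 file is
#'   written
#' @param datatype `"float32"` (default) or `"uint8"`
#' @return invisibly, the path(s) written
#' @export
export_nifti <- function(stack, path, missing_mask = NULL,
                         datatype = c("float32", "uint8")) {
  datatype <- match.arg(datatype)
  stopifnot(inherits(stack, "slice_stack"))
  p <- stack$slice_positions
  if (length(p) > 1L) {
    dp <- diff(p)
    if (any(abs(dp - dp[1]) > 0.01) || any(dp <= 0))
      stop("non-uniform slice spacing: regrid before NIfTI export")
  }
  paths <- write_nifti_array(stack$voxels, nifti_affine(stack), path,
                             pixdim = c(stack$pixel_spacing[2],
                                        stack$pixel_spacing[1],
                                        if (length(p) > 1L) diff(p)[1]
                                        else stack$nominal_slice_spacing),
                             datatype = datatype)
  if (!is.null(missing_mask)) {
    stopifnot(identical(dim(missing_mask), dim(stack$voxels)))
    mpath <- sub("(\\.nii(\\.gz)?)$", "_mask\\1", path)
    write_nifti_array(missing_mask * 1L, nifti_affine(stack), mpath,
                      pixdim = attr(paths, "pixdim") %||%
                        c(stack$pixel_spacing[2], stack$pixel_spacing[1],
                          stack$nominal_slice_spacing),
                      datatype = "uint8")
    paths <- c(paths, mpath)
  }
  invisible(paths)
}

write_nifti_array <- function(vox, affine, path, pixdim, datatype) {
  d <- dim(vox)  # [slice, row, col]
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con), add = TRUE)
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4,
                                endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2,
                                endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), con, size = 4,
                                endian = "little")
  w_raw <- function(x) writeBin(x, con)
  w_i32(348)                                   # 0   sizeof_hdr
  w_raw(raw(36))                               # 4   data_type..dim_info
  w_i16(c(3, d[3], d[2], d[1], 1, 1, 1, 1))    # 40  dim (i=col, j=row, k=slice)
  w_f32(c(0, 0, 0))                            # 56  intent_p1..p3
  w_i16(0)                                     # 68  intent_code
  dt <- switch(datatype, float32 = c(16L, 32L), uint8 = c(2L, 8L))
  w_i16(dt[1]); w_i16(dt[2])                   # 70  datatype, 72 bitpix
  w_i16(0)                                     # 74  slice_start
  w_f32(c(1, pixdim, 0, 0, 0, 0))              # 76  pixdim[0..7]
  w_f32(352)                                   # 108 vox_offset
  w_f32(c(1, 0))                               # 112 scl_slope, scl_inter
  w_i16(0)                                     # 120 slice_end
  w_raw(as.raw(c(0x00, 0x02)))                 # 122 slice_code, xyzt_units (mm)
  w_f32(c(0, 0, 0, 0))                         # 124 cal_max..toffset
  w_i32(c(0, 0))                               # 140 glmax, glmin
  w_raw(raw(80 + 24))                          # 148 descrip, aux_file
  w_i16(c(0, 1))                               # 252 qform_code=0, sform_code=1
  w_f32(rep(0, 6))                             # 256 quatern b,c,d, qoffset x,y,z
  w_f32(affine[1, ]); w_f32(affine[2, ]); w_f32(affine[3, ])  # 280 srow_x/y/z
  w_raw(raw(16))                               # 328 intent_name
  w_raw(c(as.raw(c(0x6e, 0x2b, 0x31)), raw(1)))  # 344 magic "n+1\0"
  w_raw(raw(4))                                # 348 extension flag
  dat <- aperm(vox, c(3, 2, 1))                # i fastest
  if (datatype == "uint8") {
    w_raw(as.raw(as.integer(dat)))
  } else {
    # chunked to bound memory
    v <- as.numeric(dat)
    step <- 1e6
    for (i in seq(1, length(v), by = step))
      w_f32(v[i:min(i + step - 1, length(v))])
  }
  structure(path, pixdim = pixdim)
}

#' Read a NIfTI-1 file written by this package
#'
#' Supports the emitted subset: single-file NIfTI-1, float32 or uint8,
#' little-endian, sform affine.
#'
#' @param path `.nii` or `.nii.gz`
#' @return list with `voxels` (`[slice, row, col]`), `affine` (4x4, RAS+),
#'   `pixdim`
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con), add = TRUE)
  r_i32 <- function(n) readBin(con, "integer", n, size = 4,
                               endian = "little")
  r_i16 <- function(n) readBin(con, "integer", n, size = 2,
                               endian = "little")
  r_f32 <- function(n) readBin(con, "numeric", n, size = 4,
                               endian = "little")
  if (r_i32(1) != 348) stop("not a little-endian NIfTI-1 file")
  readBin(con, "raw", 36)                      # data_type..dim_info
  dim16 <- r_i16(8)
  nx <- dim16[2]; ny <- dim16[3]; nz <- dim16[4]
  r_f32(3)                                     # intent_p
  r_i16(1)                                     # intent_code
  datatype <- r_i16(1); r_i16(1)               # datatype, bitpix
  r_i16(1)                                     # slice_start
  pixdim <- r_f32(8)[2:4]
  vox_offset <- r_f32(1)
  r_f32(2)                                     # scl_slope, scl_inter
  r_i16(1); readBin(con, "raw", 2)             # slice_end, slice_code, units
  r_f32(4)                                     # cal_max..toffset
  r_i32(2)                                     # glmax, glmin
  readBin(con, "raw", 104)                     # descrip, aux_file
  r_i16(2)                                     # qform, sform codes
  r_f32(6)                                     # quaternion fields
  srow <- rbind(r_f32(4), r_f32(4), r_f32(4), c(0, 0, 0, 1))
  readBin(con, "raw", 16)                      # intent_name
  magic <- rawToChar(readBin(con, "raw", 3))
  if (magic != "n+1") stop("unsupported NIfTI magic: ", magic)
  readBin(con, "raw", as.integer(vox_offset) - 347)
  n <- nx * ny * nz
  dat <- if (datatype == 2L) as.integer(readBin(con, "raw", n))
  else readBin(con, "numeric", n, size = 4, endian = "little")
  vox <- aperm(array(dat, dim = c(nx, ny, nz)), c(3, 2, 1))
  list(voxels = vox, affine = srow, pixdim = pixdim)
}
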