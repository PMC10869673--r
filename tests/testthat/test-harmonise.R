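# Target grid, resampling and NIfTI export.

test_that("define_target_grid follows donor rule, union FOV and config", {
  s <- compact_phantom(51)
  g <- define_target_grid(s)
  # DWI donor: 8 mm in-plane, 6 mm slices
  expect_equal(g$spacing, c(8, 8, 6))
  # explicit config grid wins verbatim
  g2 <- define_target_grid(s, config = list(
    grid = list(origin = c(0, 0, 0), spacing = c(2, 2, 2),
                dims = c(10, 10, 10))))
  expect_equal(g2$spacing, c(2, 2, 2))
  expect_equal(g2$dims, c(10L, 10L, 10L))
  # no donor and no explicit grid -> error
  no_dwi <- imaging_session("p", "s", s$series[c("fat", "water")])
  expect_error(define_target_grid(no_dwi), "donor")

  # union of offset FOVs: grid extent covers both series
  shifted <- s$series$fat
  shifted$origin <- shifted$origin + c(40, 0, 0)
  two <- imaging_session("p", "s", list(fat = shifted, b900 = s$series$b900))
  gu <- define_target_grid(two)
  xmax_grid <- gu$origin[1] + (gu$dims[1] - 1) * gu$spacing[1]
  xmax_fat <- shifted$origin[1] +
    (dim(shifted$voxels)[3] - 1) * shifted$pixel_spacing[2]
  expect_gte(xmax_grid + 1e-6, xmax_fat)
  expect_equal(gu$origin[1], s$series$b900$origin[1])
})

test_that("resampling is exact at lattice points and on linear fields", {
  s <- compact_phantom(51)
  st <- s$series$fat
  own <- target_grid(
    origin = c(st$origin[1], st$origin[2], st$slice_positions[1]),
    spacing = c(st$pixel_spacing[2], st$pixel_spacing[1],
                st$nominal_slice_spacing),
    dims = c(dim(st$voxels)[3], dim(st$voxels)[2], dim(st$voxels)[1]))
  r <- resample_to_grid(st, own)
  expect_equal(r$stack$voxels, st$voxels, tolerance = 1e-12)
  expect_false(any(r$out_of_field))

  # constant field stays constant inside, 0 outside
  cst <- st; cst$voxels[] <- 7
  big <- target_grid(own$origin - 16, own$spacing,
                     own$dims + c(4L, 4L, 6L))
  rc <- resample_to_grid(cst, big)
  expect_true(all(rc$stack$voxels[!rc$out_of_field] == 7))
  expect_true(all(rc$stack$voxels[rc$out_of_field] == 0))
  expect_true(any(rc$out_of_field))

  # trilinear reproduces degree-1 polynomials: f = 2x - 3y + z/2 + 1
  lin <- st
  d <- dim(lin$voxels)
  for (k in seq_len(d[1])) {
    x <- lin$origin[1] + (seq_len(d[3]) - 1) * lin$pixel_spacing[2]
    y <- lin$origin[2] + (seq_len(d[2]) - 1) * lin$pixel_spacing[1]
    z <- lin$slice_positions[k]
    lin$voxels[k, , ] <- outer(-3 * y, 2 * x, `+`) + z / 2 + 1
  }
  half <- target_grid(own$origin + c(3, 5, 2), c(5, 7, 4.5),
                      c(20L, 15L, 18L))
  rl <- resample_to_grid(lin, half)
  inside <- !rl$out_of_field
  gx <- half$origin[1] + (seq_len(half$dims[1]) - 1) * half$spacing[1]
  gy <- half$origin[2] + (seq_len(half$dims[2]) - 1) * half$spacing[2]
  gz <- half$origin[3] + (seq_len(half$dims[3]) - 1) * half$spacing[3]
  expected <- array(0, dim = dim(rl$stack$voxels))
  for (k in seq_len(half$dims[3]))
    expected[k, , ] <- outer(-3 * gy, 2 * gx, `+`) + gz[k] / 2 + 1
  expect_equal(rl$stack$voxels[inside], expected[inside], tolerance = 1e-9)

  # nearest-neighbour keeps masks binary
  msk <- st; msk$voxels[] <- as.numeric(st$voxels > 50)
  rn <- resample_to_grid(msk, big, interp = "nearest")
  expect_true(all(rn$stack$voxels %in% c(0, 1)))

  # degenerate: grid entirely outside the source
  far <- target_grid(c(1e4, 1e4, 1e4), c(1, 1, 1), c(2L, 2L, 2L))
  expect_error(resample_to_grid(st, far), "degenerate")
})

test_that("coronal-acquired Dixon reformats to transverse with Dice >= 0.98", {
  # finer grid than the compact fixture: at 8 mm voxels the body surface
  # is a >4% voxel fraction and partial volume alone caps Dice near 0.95
  spec <- phantom_spec(
    body_length_mm = 240, body_radius_mm = 120, n_stations = 3L,
    slice_spacing_mm = 4, in_plane_spacing_mm = 4,
    fat_rim_thickness_mm = 24,
    bone_sites = list(list(centre = c(0, 30, 120), radius = c(15, 15, 80))),
    lesion_sites = list(list(centre = c(40, -20, 60),
                             radius = c(14, 14, 14), adc = 0.7e-3)),
    seed = 52)
  tra <- build_phantom(spec)
  cor <- build_phantom(spec, protocol = "coronal_dixon")
  # coronal fat: slice normal along y
  expect_equal(slice_normal(cor$series$fat), c(0, 1, 0))
  grid <- define_target_grid(tra)
  r_tra <- resample_to_grid(tra$series$fat, grid)
  r_cor <- resample_to_grid(cor$series$fat, grid)
  thr <- 50  # between background and tissue intensities
  a <- r_tra$stack$voxels > thr
  b <- r_cor$stack$voxels > thr
  keep <- !(r_tra$out_of_field | r_cor$out_of_field)
  dice <- 2 * sum(a & b & keep) / (sum(a & keep) + sum(b & keep))
  expect_gte(dice, 0.98)
})

test_that("NIfTI export round-trips and matches the nibabel oracle", {
  set.seed(1)
  vox <- array(rnorm(4 * 5 * 6), dim = c(4, 5, 6))
  st <- slice_stack(vox, slice_positions = c(10, 12, 14, 16),
                    orientation = list(row = c(1, 0, 0), col = c(0, 1, 0)),
                    origin = c(-20, -30, 10), pixel_spacing = c(3, 2),
                    nominal_slice_spacing = 2, contrast_label = "water")
  path <- withr::local_tempfile(fileext = ".nii.gz")
  export_nifti(st, path)
  r <- read_nifti(path)
  expect_lt(max(abs(r$voxels - vox)), 1e-6)  # float32 storage
  # affine as independently decoded by nibabel 5.4.2 from this file
  # (frozen during development): RAS+, x/y negated from the LPS geometry
  nib_affine <- rbind(c(-2, 0, 0, 20),
                      c(0, -3, 0, 30),
                      c(0, 0, 2, 10),
                      c(0, 0, 0, 1))
  expect_equal(r$affine, nib_affine, tolerance = 1e-5)

  # paired mask sidecar
  mask <- array(FALSE, dim(vox)); mask[2, , ] <- TRUE
  path2 <- withr::local_tempfile(fileext = ".nii.gz")
  paths <- export_nifti(st, path2, missing_mask = mask)
  mpath <- sub("\\.nii\\.gz$", "_mask.nii.gz", path2)
  expect_true(file.exists(mpath))
  rm_ <- read_nifti(mpath)
  expect_equal(rm_$voxels == 1, mask)
  expect_equal(rm_$affine, r$affine)

  # non-uniform slice spacing is refused
  bad <- st; bad$slice_positions <- c(10, 12, 15, 16)
  expect_error(export_nifti(bad, path), "non-uniform")
})

test_that("harmonised series share one affine bit-exactly", {
  s <- compact_phantom(51)
  h <- harmonise_session(s)
  affs <- lapply(h$series, wbcure:::nifti_affine)
  for (a in affs[-1]) expect_identical(a, affs[[1]])
})
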