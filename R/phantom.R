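# Synthetic multi-station Dixon + DWI session generator.  The phantom is a
# piecewise-constant body: a cylinder of water-dominated soft tissue wrapped
# in a subcutaneous fat rim, with low-signal bone ellipsoids and
# water-bright lesions carrying their own ADC.  Every contrast is rendered
# analytically from one world-coordinate field, so transverse and coronal
# acquisitions of the same anatomy agree by construction and every repair
# can be checked against a defect-free ground truth.

#' Specify a synthetic whole-body phantom
#'
#' Defaults describe a compact whole-body acquisition: four couch stations
#' covering 800 mm head-foot, 5 mm slices, 4 mm in-plane resolution.
#' All seven contrasts are generated.  Signal levels (arbitrary units):
#' fat rim 100 in the fat image, soft-tissue core 100 in the water image,
#' bone ~5 in both; additive Gaussian noise with sd
#' `noise_frac * 100` on the acquired channels (fat, water, b50).
#'
#' @param body_length_mm head-foot extent of the body cylinder
#' @param body_radius_mm radius of the body cylinder
#' @param n_stations number of couch stations (>= 2)
#' @param station_overlap_slices acquisition overlap capacity between
#'   adjacent stations (defect injection cannot exceed it)
#' @param slice_spacing_mm nominal slice spacing
#' @param in_plane_spacing_mm in-plane pixel size (isotropic)
#' @param fat_rim_thickness_mm thickness of the subcutaneous fat rim
#' @param bone_sites list of `list(centre = c(x,y,z), radius = c(rx,ry,rz))`
#'   ellipsoids (mm, patient LPS); `NULL` for an axial "spine" default
#' @param lesion_sites list of `list(centre, radius, adc)` ellipsoids with
#'   their ADC in mm^2/s; `NULL` for a two-lesion default
#' @param noise_frac Gaussian noise sd as a fraction of the rim intensity
#'   (default 0.02)
#' @param seed RNG seed: same seed, bit-identical voxels
#' @return object of class `phantom_spec`
#' @export
phantom_spec <- function(body_length_mm = 800, body_radius_mm = 150,
                         n_stations = 4L, station_overlap_slices = 4L,
                         slice_spacing_mm = 5, in_plane_spacing_mm = 4,
                         fat_rim_thickness_mm = 20,
                         bone_sites = NULL, lesion_sites = NULL,
                         noise_frac = 0.02, seed = 1L) {
  lens <- c(body_length_mm, body_radius_mm, slice_spacing_mm,
            in_plane_spacing_mm, fat_rim_thickness_mm)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all phantom lengths must be positive")
  n_stations <- as.integer(n_stations)
  if (n_stations < 2L) stop("n_stations must be >= 2")
  if (station_overlap_slices < 0L)
    stop("station_overlap_slices must be >= 0")
  if (fat_rim_thickness_mm >= body_radius_mm)
    stop("fat rim must be thinner than the body radius")
  sps <- ceiling(body_length_mm / n_stations / slice_spacing_mm)
  if (sps * n_stations * slice_spacing_mm < body_length_mm)
    stop("stations do not cover the body length")
  if (is.null(bone_sites)) {
    # central "spine" column plus a pelvic block
    bone_sites <- list(
      list(centre = c(0, 40, body_length_mm * 0.40),
           radius = c(18, 18, body_length_mm * 0.35)),
      list(centre = c(0, 0, body_length_mm * 0.78),
           radius = c(70, 35, 50)))
  }
  if (is.null(lesion_sites)) {
    lesion_sites <- list(
      list(centre = c(55, -20, body_length_mm * 0.30),
           radius = c(16, 16, 16), adc = 0.7e-3),
      list(centre = c(-50, 30, body_length_mm * 0.62),
           radius = c(12, 12, 12), adc = 0.6e-3))
  }
  structure(list(body_length_mm = body_length_mm,
                 body_radius_mm = body_radius_mm,
                 n_stations = n_stations,
                 station_overlap_slices = as.integer(station_overlap_slices),
                 slice_spacing_mm = slice_spacing_mm,
                 in_plane_spacing_mm = in_plane_spacing_mm,
                 fat_rim_thickness_mm = fat_rim_thickness_mm,
                 bone_sites = bone_sites, lesion_sites = lesion_sites,
                 noise_frac = noise_frac,
                 slices_per_station = as.integer(sps),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Compartment intensities (arbitrary units) and ADC (mm^2/s).
PHANTOM_LEVELS <- list(
  fat    = c(rim = 100, core = 10, bone = 5, lesion = 8, background = 0),
  water  = c(rim = 10, core = 100, bone = 5, lesion = 120, background = 0),
  adc    = c(rim = 0.4e-3, core = 1.0e-3, bone = 0.2e-3, lesion = NA,
             background = 0))

# Evaluate the noise-free tissue fields at world coordinates (LPS, mm).
# X, Y, Z are equal-shape arrays; returns list(fat, water, adc) same shape.
phantom_field <- function(spec, X, Y, Z) {
  r2 <- X^2 + Y^2
  inside <- (r2 <= spec$body_radius_mm^2) & (Z >= 0) &
    (Z <= spec$body_length_mm)
  core_r <- spec$body_radius_mm - spec$fat_rim_thickness_mm
  rim <- inside & (r2 > core_r^2)
  core <- inside & !rim
  lv <- PHANTOM_LEVELS
  fat <- water <- adc <- array(0, dim = dim(X))
  fat[core] <- lv$fat["core"];   fat[rim] <- lv$fat["rim"]
  water[core] <- lv$water["core"]; water[rim] <- lv$water["rim"]
  adc[core] <- lv$adc["core"];   adc[rim] <- lv$adc["rim"]
  in_ellipsoid <- function(site) {
    ((X - site$centre[1]) / site$radius[1])^2 +
      ((Y - site$centre[2]) / site$radius[2])^2 +
      ((Z - site$centre[3]) / site$radius[3])^2 <= 1
  }
  for (b in spec$bone_sites) {
    m <- in_ellipsoid(b) & inside
    fat[m] <- lv$fat["bone"]; water[m] <- lv$water["bone"]
    adc[m] <- lv$adc["bone"]
  }
  for (l in spec$lesion_sites) {
    m <- in_ellipsoid(l) & inside
    fat[m] <- lv$fat["lesion"]; water[m] <- lv$water["lesion"]
    adc[m] <- l$adc
  }
  list(fat = fat, water = water, adc = adc)
}

# World coordinates of every voxel of a stack geometry, returned as three
# arrays shaped [slice, row, col].
stack_world_coords <- function(n_slices, n_rows, n_cols, origin, row_dir,
                               col_dir, normal, pixel_spacing, positions) {
  sl <- seq_len(n_slices) - 1L
  rw <- seq_len(n_rows) - 1L
  cl <- seq_len(n_cols) - 1L
  offs <- positions - positions[1]
  S <- array(rep(offs, times = n_rows * n_cols),
             dim = c(n_slices, n_rows, n_cols))
  R <- array(rep(rep(rw * pixel_spacing[1], each = n_slices), times = n_cols),
             dim = c(n_slices, n_rows, n_cols))
  C <- array(rep(cl * pixel_spacing[2], each = n_slices * n_rows),
             dim = c(n_slices, n_rows, n_cols))
  list(X = origin[1] + C * row_dir[1] + R * col_dir[1] + S * normal[1],
       Y = origin[2] + C * row_dir[2] + R * col_dir[2] + S * normal[2],
       Z = origin[3] + C * row_dir[3] + R * col_dir[3] + S * normal[3])
}

#' Build a defect-free synthetic imaging session
#'
#' Renders all seven contrasts on the composed multi-station grid.
#' Acquired channels (fat, water, b50) carry independent Gaussian noise;
#' derived channels obey the Dixon and diffusion identities exactly:
#' `in_phase = fat + water`, `out_of_phase = |water - fat|`, and
#' `b900 = b50 * exp(-(900 - 50) * ADC)` voxelwise, so
#' `ADC = ln(b50/b900)/850` inverts the decay wherever b50 > 0.
#'
#' @param spec a [phantom_spec()]
#' @param protocol `"transverse_dixon"` (slices axial) or `"coronal_dixon"`
#'   (Dixon slices coronal; DWI remains axial as acquired clinically)
#' @param subject_id,session_id identifiers for the session
#' @param cohort cohort label, see [imaging_session()]
#' @return an [imaging_session()] with `blocks` describing the stations
#' @export
build_phantom <- function(spec, protocol = "transverse_dixon",
                          subject_id = "PHANTOM01",
                          session_id = "SESS01",
                          cohort = "c_healthy") {
  stopifnot(inherits(spec, "phantom_spec"))
  protocol <- match.arg(protocol, PROTOCOLS)
  n_slices <- spec$n_stations * spec$slices_per_station
  fov_mm <- 2 * (spec$body_radius_mm + 4 * spec$in_plane_spacing_mm)
  n_px <- ceiling(fov_mm / spec$in_plane_spacing_mm)
  ps <- c(spec$in_plane_spacing_mm, spec$in_plane_spacing_mm)

  # axial geometry: rows along y (A->P is +y in LPS), cols along x (R->L +x)
  ax <- list(row_dir = c(1, 0, 0), col_dir = c(0, 1, 0), normal = c(0, 0, 1),
             origin = c(-(n_px - 1) / 2 * ps[2], -(n_px - 1) / 2 * ps[1], 0),
             positions = (seq_len(n_slices) - 1L) * spec$slice_spacing_mm,
             n_slices = n_slices, n_rows = n_px, n_cols = n_px)

  render <- function(geom) {
    w <- stack_world_coords(geom$n_slices, geom$n_rows, geom$n_cols,
                            geom$origin, geom$row_dir, geom$col_dir,
                            geom$normal, ps, geom$positions)
    phantom_field(spec, w$X, w$Y, w$Z)
  }

  mk_stack <- function(vox, geom, label) {
    slice_stack(vox, geom$positions,
                orientation = list(row = geom$row_dir, col = geom$col_dir),
                origin = geom$origin, pixel_spacing = ps,
                nominal_slice_spacing = spec$slice_spacing_mm,
                contrast_label = label)
  }

  noise <- function(dims) {
    stats::rnorm(prod(dims), sd = spec$noise_frac * 100)
  }

  set.seed(spec$seed)
  dixon_geom <- ax
  if (protocol == "coronal_dixon") {
    # coronal: slice normal along +y (anterior->posterior stepping), rows
    # running head->foot (col direction cosine -z, origin at the top),
    # cols along x; slice spacing is the coarse direction
    n_cor <- ceiling(fov_mm / spec$slice_spacing_mm)
    nz <- ceiling(spec$body_length_mm / spec$in_plane_spacing_mm) + 8L
    dixon_geom <- list(row_dir = c(1, 0, 0), col_dir = c(0, 0, -1),
                       normal = c(0, 1, 0),
                       origin = c(-(n_px - 1) / 2 * ps[2],
                                  -(n_cor - 1) / 2 * spec$slice_spacing_mm,
                                  spec$body_length_mm +
                                    4 * spec$in_plane_spacing_mm),
                       positions = (seq_len(n_cor) - 1L) *
                         spec$slice_spacing_mm -
                         (n_cor - 1) / 2 * spec$slice_spacing_mm,
                       n_slices = n_cor, n_rows = nz, n_cols = n_px)
  }

  fd <- render(dixon_geom)
  dims_d <- dim(fd$fat)
  fat <- fd$fat + noise(dims_d)
  water <- fd$water + noise(dims_d)
  ip <- fat + water
  op <- abs(water - fat)

  fw <- if (protocol == "coronal_dixon") render(ax) else fd
  dims_a <- dim(fw$water)
  b50 <- fw$water + 0.1 * fw$fat + noise(dims_a)
  adc <- fw$adc
  b900 <- b50 * exp(-(900 - 50) * adc)

  series <- list(
    fat = mk_stack(fat, dixon_geom, "fat"),
    water = mk_stack(water, dixon_geom, "water"),
    in_phase = mk_stack(ip, dixon_geom, "in_phase"),
    out_of_phase = mk_stack(op, dixon_geom, "out_of_phase"),
    b50 = mk_stack(b50, ax, "b50"),
    b900 = mk_stack(b900, ax, "b900"),
    adc = mk_stack(adc, ax, "adc"))
  series <- series[CONTRAST_LABELS]

  blocks <- lapply(seq_len(spec$n_stations), function(i)
    station_block(i, c((i - 1L) * spec$slices_per_station + 1L,
                       i * spec$slices_per_station)))
  imaging_session(subject_id, session_id, series,
                  cohort = cohort, protocol = protocol, blocks = blocks)
}

# ---- defect ledger ---------------------------------------------------------

#' Describe a set of composition defects to inject
#'
#' The ledger is the ground truth of every modification applied to a clean
#' session.  Event fields:
#' \describe{
#'   \item{slice_gap_events}{`list(boundary =, class = "overlap"|"underlap",
#'     n_slices =, series = NULL)` — at the station boundary between
#'     stations `boundary` and `boundary + 1`.  Overlap duplicates the first
#'     `n_slices` slices of the next station at their own positions;
#'     underlap deletes them.  `series` restricts the event to given
#'     contrast labels (default all).}
#'   \item{offset_events}{`list(station =, dx_px =, dy_px =, series = "fat")`
#'     — in-plane translation (columns, rows) of one station's block in the
#'     moving series.}
#'   \item{swap_events}{`list(scope = "global"|"station"|"local", station =,
#'     centre =, radius =)` — exchange of fat and water content; local swaps
#'     exchange only inside the ellipsoid (mm, world coordinates).}
#'   \item{station_permutation}{integer permutation: entry `i` gives the
#'     station whose block occupies position `i` of the composed stack.}
#' }
#' @param slice_gap_events,offset_events,swap_events lists of events
#' @param station_permutation integer vector or NULL
#' @return object of class `defect_ledger`
#' @export
defect_ledger <- function(slice_gap_events = list(), offset_events = list(),
                          swap_events = list(),
                          station_permutation = NULL) {
  structure(list(slice_gap_events = slice_gap_events,
                 offset_events = offset_events,
                 swap_events = swap_events,
                 station_permutation = station_permutation),
            class = "defect_ledger")
}

#' @export
print.defect_ledger <- function(x, ...) {
  cat(sprintf("<defect_ledger> %d gap, %d offset, %d swap event(s)%s\n",
              length(x$slice_gap_events), length(x$offset_events),
              length(x$swap_events),
              if (is.null(x$station_permutation)) ""
              else paste0(", permutation ",
                          paste(x$station_permutation, collapse = ","))))
  invisible(x)
}

#' Is a ledger empty (defect-free)?
#' @param ledger a [defect_ledger()]
#' @return logical
#' @export
ledger_empty <- function(ledger) {
  length(ledger$slice_gap_events) == 0L &&
    length(ledger$offset_events) == 0L &&
    length(ledger$swap_events) == 0L &&
    is.null(ledger$station_permutation)
}

#' Write / read a defect ledger as YAML
#' @param ledger a [defect_ledger()]
#' @param path file path
#' @export
write_ledger_yaml <- function(ledger, path) {
  yaml::write_yaml(unclass(ledger), path)
  invisible(path)
}

#' @rdname write_ledger_yaml
#' @export
read_ledger_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  defect_ledger(slice_gap_events = x$slice_gap_events %||% list(),
                offset_events = x$offset_events %||% list(),
                swap_events = x$swap_events %||% list(),
                station_permutation = unlist(x$station_permutation))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

translate_slices <- function(vox, idx, dx, dy) {
  # shift each slice in idx by dx columns / dy rows, zero-filled
  d <- dim(vox)
  out_r <- seq_len(d[2]); out_c <- seq_len(d[3])
  src_r <- out_r - dy; src_c <- out_c - dx
  ok_r <- src_r >= 1L & src_r <= d[2]
  ok_c <- src_c >= 1L & src_c <= d[3]
  shifted <- array(0, dim = c(length(idx), d[2], d[3]))
  shifted[, out_r[ok_r], out_c[ok_c]] <-
    vox[idx, src_r[ok_r], src_c[ok_c], drop = FALSE]
  vox[idx, , ] <- shifted
  vox
}

#' Inject composition defects into a clean session
#'
#' Applies every event in the ledger, returning a new session; the input is
#' untouched.  Station blocks attached to the session are updated to track
#' the slices each station contributes after injection.
#'
#' @param session a clean [imaging_session()] carrying `blocks`
#' @param ledger a [defect_ledger()]
#' @return defective `imaging_session`
#' @export
inject_defects <- function(session, ledger) {
  stopifnot(inherits(session, "imaging_session"),
            inherits(ledger, "defect_ledger"))
  if (is.null(session$blocks)) stop("session must carry station blocks")
  n_st <- length(session$blocks)

  gb <- vapply(ledger$slice_gap_events, function(e) e$boundary, numeric(1))
  if (length(gb) && (anyDuplicated(gb) || any(gb < 1 | gb >= n_st)))
    stop("gap events must reference distinct interior station boundaries")
  ost <- vapply(ledger$offset_events, function(e) e$station, numeric(1))
  if (length(ost) && (anyDuplicated(ost) || any(ost < 1 | ost > n_st)))
    stop("offset events must reference distinct existing stations")
  scopes <- vapply(ledger$swap_events, function(e) e$scope, character(1))
  if (sum(scopes == "global") > 1L)
    stop("contradictory swap events: more than one global swap")
  if (any(scopes == "global") && any(scopes != "global"))
    stop("contradictory swap events: global combined with station/local")
  sst <- vapply(ledger$swap_events,
                function(e) if (e$scope == "station") e$station else NA_real_,
                numeric(1))
  if (anyDuplicated(stats::na.omit(sst)))
    stop("contradictory swap events: repeated station")
  perm <- ledger$station_permutation
  if (!is.null(perm)) {
    perm <- as.integer(perm)
    if (!identical(sort(perm), seq_len(n_st)))
      stop("station_permutation must be a permutation of 1..n_stations")
  }

  series <- session$series
  blocks <- session$blocks
  ranges <- lapply(blocks, function(b) b$slice_range)

  event_series <- function(e, default = names(series)) {
    s <- e$series %||% default
    intersect(default, s)
  }

  # 1. swaps (operate on clean station geometry)
  for (e in ledger$swap_events) {
    if (!all(c("fat", "water") %in% names(series)))
      stop("swap events need fat and water series")
    if (e$scope == "global") {
      f <- series$fat; w <- series$water
      fv <- f$voxels; f$voxels <- w$voxels; w$voxels <- fv
      series$fat <- f; series$water <- w
    } else if (e$scope == "station") {
      rg <- ranges[[e$station]]
      idx <- seq.int(rg[1], rg[2])
      fv <- series$fat$voxels[idx, , , drop = FALSE]
      series$fat$voxels[idx, , ] <-
        series$water$voxels[idx, , , drop = FALSE]
      series$water$voxels[idx, , ] <- fv
    } else if (e$scope == "local") {
      st <- series$fat
      w <- stack_world_coords(dim(st$voxels)[1], dim(st$voxels)[2],
                              dim(st$voxels)[3], st$origin,
                              st$orientation$row, st$orientation$col,
                              slice_normal(st), st$pixel_spacing,
                              st$slice_positions)
      m <- ((w$X - e$centre[1]) / e$radius[1])^2 +
        ((w$Y - e$centre[2]) / e$radius[2])^2 +
        ((w$Z - e$centre[3]) / e$radius[3])^2 <= 1
      fv <- series$fat$voxels[m]
      series$fat$voxels[m] <- series$water$voxels[m]
      series$water$voxels[m] <- fv
    } else stop("unknown swap scope: ", e$scope)
  }

  # 2. per-station in-plane offsets (moving series, default fat)
  for (e in ledger$offset_events) {
    for (lbl in event_series(e, "fat")) {
      rg <- ranges[[e$station]]
      series[[lbl]]$voxels <- translate_slices(
        series[[lbl]]$voxels, seq.int(rg[1], rg[2]), e$dx_px, e$dy_px)
    }
    blocks[[e$station]]$source_offset_mm <-
      c(e$dx_px, e$dy_px) * series[["fat"]]$pixel_spacing[c(2, 1)]
  }

  # 3. slice-gap events; applied per series so patterns can differ between
  #    series (as seen between b-values of one clinical session)
  gap_edit <- function(stack, e) {
    rg_next <- ranges[[e$boundary + 1L]]
    n <- e$n_slices
    if (n < 1L) stop("n_slices must be >= 1")
    take <- seq.int(rg_next[1], rg_next[1] + n - 1L)
    if (e$class == "overlap") {
      # duplicate the first n slices of the next station, interleaved so
      # positions stay sorted: ... p | q1 q1 q2 q2 ... qn qn ...
      keep <- seq_len(dim(stack$voxels)[1])
      newidx <- sort(c(keep, take))
      stack$voxels <- stack$voxels[newidx, , , drop = FALSE]
      stack$slice_positions <- stack$slice_positions[newidx]
    } else if (e$class == "underlap") {
      if (length(take) >= rg_next[2] - rg_next[1] + 1L)
        stop("underlap would delete an entire station")
      keep <- setdiff(seq_len(dim(stack$voxels)[1]), take)
      stack$voxels <- stack$voxels[keep, , , drop = FALSE]
      stack$slice_positions <- stack$slice_positions[keep]
    } else stop("unknown gap class: ", e$class)
    stack
  }
  gap_events <- ledger$slice_gap_events
  if (length(gap_events)) {
    # apply in descending boundary order so earlier indices stay valid
    ord <- order(-vapply(gap_events, function(e) e$boundary, numeric(1)))
    for (e in gap_events[ord]) {
      for (lbl in event_series(e)) series[[lbl]] <- gap_edit(series[[lbl]], e)
    }
    # rebuild block ranges by walking the stations' post-injection sizes;
    # duplicated overlap slices are booked against the earlier station
    sizes <- vapply(ranges, function(r) r[2] - r[1] + 1L, integer(1))
    for (e in gap_events) {
      if (e$class == "overlap") sizes[e$boundary] <- sizes[e$boundary] +
          e$n_slices
      else sizes[e$boundary + 1L] <- sizes[e$boundary + 1L] - e$n_slices
    }
    stop_at <- cumsum(sizes)
    start_at <- c(1L, utils::head(stop_at, -1L) + 1L)
    for (i in seq_len(n_st))
      blocks[[i]]$slice_range <- as.integer(c(start_at[i], stop_at[i]))
  }

  # 4. station misordering: permute blocks (voxels AND their position tags)
  if (!is.null(perm)) {
    for (lbl in names(series)) {
      st <- series[[lbl]]
      idx_list <- lapply(perm, function(i) {
        rg <- blocks[[i]]$slice_range
        seq.int(rg[1], rg[2])
      })
      newidx <- unlist(idx_list)
      st$voxels <- st$voxels[newidx, , , drop = FALSE]
      st$slice_positions <- st$slice_positions[newidx]
      series[[lbl]] <- st
    }
    sizes <- vapply(perm, function(i) {
      rg <- blocks[[i]]$slice_range
      rg[2] - rg[1] + 1L
    }, integer(1))
    stop_at <- cumsum(sizes)
    start_at <- c(1L, utils::head(stop_at, -1L) + 1L)
    blocks <- lapply(seq_len(n_st), function(k) {
      b <- blocks[[perm[k]]]
      b$slice_range <- as.integer(c(start_at[k], stop_at[k]))
      b
    })
  }

  out <- session
  out$series <- series
  out$blocks <- blocks
  out
}
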