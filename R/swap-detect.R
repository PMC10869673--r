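# Fat-water swap detection.  Dixon reconstruction can exchange the fat and
# water channels globally, for whole stations, or in a local region.  The
# detector exploits subcutaneous anatomy: the rim of the body is adipose,
# so mean(fat) - mean(water) over the rim is positive when labels are
# correct and flips sign under a swap.  Global and station swaps are fixed
# by relabelling; local swaps are only flagged — they accompany artefacts
# (e.g. implanted metal) and relabelling sub-regions risks corrupting
# genuine signal.

otsu_threshold <- function(x, n_bins = 256L) {
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  h <- tabulate(pmin(pmax(findInterval(
    x, seq(r[1], r[2], length.out = n_bins + 1L), all.inside = TRUE),
    1L), n_bins), nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  r[1] + diff(r) * k / n_bins
}

erode_inplane <- function(mask, r = 2L) {
  # binary erosion with a (2r+1)^2 square element, applied slice-wise
  out <- mask
  d <- dim(mask)
  for (dr in -r:r) for (dc in -r:r) {
    if (dr == 0 && dc == 0) next
    shifted <- array(FALSE, d)
    rows <- seq_len(d[2]); cols <- seq_len(d[3])
    sr <- rows - dr; sc <- cols - dc
    okr <- sr >= 1L & sr <= d[2]; okc <- sc >= 1L & sc <= d[3]
    shifted[, rows[okr], cols[okc]] <- mask[, sr[okr], sc[okc], drop = FALSE]
    out <- out & shifted
  }
  out
}

dilate_inplane <- function(mask, r = 1L) {
  out <- mask
  d <- dim(mask)
  for (dr in -r:r) for (dc in -r:r) {
    if (dr == 0 && dc == 0) next
    shifted <- array(FALSE, d)
    rows <- seq_len(d[2]); cols <- seq_len(d[3])
    sr <- rows - dr; sc <- cols - dc
    okr <- sr >= 1L & sr <= d[2]; okc <- sc >= 1L & sc <= d[3]
    shifted[, rows[okr], cols[okc]] <- mask[, sr[okr], sc[okc], drop = FALSE]
    out <- out | shifted
  }
  out
}

#' Body and rim masks from fat + water
#'
#' Body mask: Otsu threshold on `fat + water`, cleaned by a one-pixel
#' in-plane morphological opening (removes speckle the way a
#' largest-component step would, but with vectorised operations); rim =
#' body minus its `erosion_px`-voxel in-plane erosion.  On a correctly
#' labelled acquisition the rim is subcutaneous fat.
#'
fill_holes_inplane <- function(mask) {
  # complement of the border-connected background, slice-wise: interior
  # low-signal structures (e.g. bone) must not punch holes in the body
  d <- dim(mask)
  outside <- !mask
  seed <- array(FALSE, d)
  seed[, c(1L, d[2]), ] <- TRUE
  seed[, , c(1L, d[3])] <- TRUE
  reach <- outside & seed
  repeat {
    grown <- dilate_inplane(reach, 1L) & outside
    if (sum(grown) == sum(reach)) break
    reach <- grown
  }
  !reach
}

#' @param fat,water co-gridded [slice_stack()]s
#' @param erosion_px erosion radius in pixels, default 2
#' @return list with logical arrays `body` and `rim`
#' @export
body_rim_masks <- function(fat, water, erosion_px = 2L) {
  s <- fat$voxels + water$voxels
  thr <- otsu_threshold(s)
  body <- fill_holes_inplane(dilate_inplane(erode_inplane(s > thr, 1L), 1L))
  rim <- body & !erode_inplane(body, erosion_px)
  list(body = body, rim = rim)
}

#' Rim fat-dominance statistic
#'
#' `(mean(fat) - mean(water)) / mean(fat + water)` over the subcutaneous rim
#' within `slice_range`.  Positive on correctly labelled anatomy, exactly
#' negated when the labels are exchanged, 0 when fat equals water.
#'
#' @param fat,water co-gridded [slice_stack()]s
#' @param slice_range `c(first, last)` inclusive; default full stack
#' @param masks optional precomputed [body_rim_masks()]
#' @return numeric scalar in `[-1, 1]`
#' @export
rim_statistic <- function(fat, water, slice_range = NULL, masks = NULL) {
  stopifnot(inherits(fat, "slice_stack"), inherits(water, "slice_stack"),
            identical(dim(fat$voxels), dim(water$voxels)))
  if (is.null(masks)) masks <- body_rim_masks(fat, water)
  n <- dim(fat$voxels)[1]
  slice_range <- slice_range %||% c(1L, n)
  sel <- array(FALSE, dim(fat$voxels))
  sel[seq.int(slice_range[1], slice_range[2]), , ] <- TRUE
  rim <- masks$rim & sel
  if (!any(rim)) stop("uninformative slice range: empty body rim")
  f <- mean(fat$voxels[rim]); w <- mean(water$voxels[rim])
  denom <- mean(fat$voxels[rim] + water$voxels[rim])
  if (denom == 0) return(0)
  (f - w) / denom
}

#' Detect fat-water label swaps in a session
#'
#' Whole-volume rim statistic below `-theta` flags a global swap.
#' Otherwise each station block is tested and flagged individually.
#' Local swaps are searched inside otherwise consistent stations as
#' connected components (in-plane 4-connectivity plus slice adjacency) of
#' confidently misclassified body voxels: rim voxels that are water-dominant
#' or interior voxels that are fat-dominant, restricted to voxels with solid
#' combined signal.  Components of at least `min_volume` voxels become
#' `flag_only` findings.
#'
#' @param session an [imaging_session()] with fat and water series
#' @param blocks station blocks; default the session's own
#' @param config list: `swap_theta` (default 0.2), `swap_min_volume`
#'   (default 40 voxels), `rim_erosion_px` (default 2)
#' @return list of `swap_finding` objects (possibly empty)
#' @export
detect_swaps <- function(session, blocks = NULL, config = list()) {
  stopifnot(inherits(session, "imaging_session"))
  if (!all(c("fat", "water") %in% names(session$series)))
    stop("swap detection needs both fat and water series")
  theta <- config$swap_theta %||% 0.2
  min_vol <- config$swap_min_volume %||% 40L
  fat <- session$series$fat; water <- session$series$water
  blocks <- blocks %||% session$blocks
  masks <- body_rim_masks(fat, water,
                          erosion_px = config$rim_erosion_px %||% 2L)
  finding <- function(scope, station = NULL, region_mask = NULL,
                      evidence, action) {
    structure(list(scope = scope, station_index = station,
                   region_mask = region_mask, evidence = evidence,
                   action = action), class = "swap_finding")
  }
  global_stat <- rim_statistic(fat, water, masks = masks)
  if (global_stat < -theta)
    return(list(finding("global", evidence = list(rim_statistic = global_stat),
                        action = "relabel")))

  out <- list()
  station_ok <- rep(TRUE, length(blocks %||% list()))
  if (!is.null(blocks) &&
      max(vapply(blocks, function(b) b$slice_range[2], integer(1))) ==
      dim(fat$voxels)[1]) {
    for (k in seq_along(blocks)) {
      b <- blocks[[k]]
      st <- tryCatch(rim_statistic(fat, water, b$slice_range, masks),
                     error = function(e) NA_real_)
      if (!is.na(st) && st < -theta) {
        station_ok[k] <- FALSE
        out <- c(out, list(finding("station", station = b$station_index,
                                   evidence = list(rim_statistic = st),
                                   action = "relabel")))
      }
    }
  }

  # local swaps: confident misclassifications inside consistent stations
  fv <- fat$voxels; wv <- water$voxels
  solid <- masks$body & (fv + wv) > 0.5 * stats::median(fv[masks$body] +
                                                         wv[masks$body])
  ff <- fv / (fv + wv + .Machine$double.eps)
  # the interior test must sit deeper than the whole subcutaneous fat layer,
  # not just the rim band used for the statistic
  interior <- erode_inplane(masks$body, config$interior_erosion_px %||% 6L)
  anomaly <- solid & ((masks$rim & ff < 0.35) | (interior & ff > 0.65))
  if (!is.null(blocks) && length(station_ok)) {
    keep <- array(FALSE, dim(anomaly))
    for (k in seq_along(blocks)) {
      if (!station_ok[k]) next
      rg <- blocks[[k]]$slice_range
      if (rg[2] <= dim(anomaly)[1]) keep[seq.int(rg[1], rg[2]), , ] <- TRUE
    }
    anomaly <- anomaly & keep
  }
  comps <- label_components_3d(anomaly)
  if (length(comps)) {
    for (cm in comps) {
      if (length(cm) < min_vol) next
      mask <- array(FALSE, dim(anomaly)); mask[cm] <- TRUE
      out <- c(out, list(finding("local",
                                 region_mask = mask,
                                 evidence = list(component_voxels =
                                                   length(cm)),
                                 action = "flag_only")))
    }
  }
  out
}

# connected components of a 3-D logical array, 6-connectivity,
# returned as a list of linear-index vectors
label_components_3d <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) return(list())
  d <- dim(mask)
  lab <- integer(length(idx))
  names(lab) <- idx
  pos <- match(seq_len(prod(d)), idx) # inverse lookup, NA where not anomaly
  arr <- arrayInd(idx, d)
  comps <- list()
  visited <- logical(length(idx))
  nbr_offsets <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                       c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (start in seq_along(idx)) {
    if (visited[start]) next
    queue <- start; visited[start] <- TRUE
    members <- integer(0)
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      members <- c(members, idx[i])
      a <- arr[i, ]
      for (o in seq_len(6)) {
        b <- a + nbr_offsets[o, ]
        if (any(b < 1L) || any(b > d)) next
        lin <- b[1] + (b[2] - 1L) * d[1] + (b[3] - 1L) * d[1] * d[2]
        j <- pos[lin]
        if (!is.na(j) && !visited[j]) { visited[j] <- TRUE
          queue <- c(queue, j) }
      }
    }
    comps <- c(comps, list(members))
  }
  comps
}

summarise_findings <- function(findings) {
  lapply(findings, function(f)
    list(scope = f$scope, station_index = f$station_index,
         action = f$action,
         evidence = f$evidence[!vapply(f$evidence, is.array, logical(1))]))
}

#' @export
print.swap_finding <- function(x, ...) {
  cat(sprintf("<swap_finding %s%s> action=%s\n", x$scope,
              if (!is.null(x$station_index))
                paste0(" station ", x$station_index) else "",
              x$action))
  invisible(x)
}

#' Apply fixes for detected fat-water swaps
#'
#' Global findings exchange the whole fat and water stacks; station
#' findings exchange the block's voxels between the two stacks; local
#' findings are left untouched (persist them to the run record).  Applying
#' a global fix twice is the identity, and re-running [detect_swaps()] on
#' the output yields no global or station findings.
#'
#' @param session an [imaging_session()]
#' @param findings list from [detect_swaps()]
#' @return corrected `imaging_session`
#' @export
apply_swap_fix <- function(session, findings) {
  stopifnot(inherits(session, "imaging_session"))
  scopes <- vapply(findings, function(f) f$scope, character(1))
  if (any(scopes == "global") && any(scopes == "station"))
    stop("conflicting findings (global and station): manual resolution required")
  for (f in findings) {
    if (f$action != "relabel") next
    if (f$scope == "global") {
      fv <- session$series$fat$voxels
      session$series$fat$voxels <- session$series$water$voxels
      session$series$water$voxels <- fv
    } else if (f$scope == "station") {
      b <- Find(function(b) b$station_index == f$station_index,
                session$blocks)
      if (is.null(b)) stop("finding references unknown station ",
                           f$station_index)
      ix <- seq.int(b$slice_range[1], b$slice_range[2])
      fv <- session$series$fat$voxels[ix, , , drop = FALSE]
      session$series$fat$voxels[ix, , ] <-
        session$series$water$voxels[ix, , , drop = FALSE]
      session$series$water$voxels[ix, , ] <- fv
    }
  }
  session
}
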