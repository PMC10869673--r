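# Shared fixtures, all generated in code.  The compact phantom keeps the
# suite fast; its proportions (fat rim, central bone, one lesion) exercise
# every compartment the detectors rely on.

compact_spec <- function(seed = 1L, ...) {
  phantom_spec(
    body_length_mm = 240, body_radius_mm = 120, n_stations = 3L,
    slice_spacing_mm = 6, in_plane_spacing_mm = 8,
    fat_rim_thickness_mm = 24,
    bone_sites = list(list(centre = c(0, 30, 120), radius = c(15, 15, 80))),
    lesion_sites = list(list(centre = c(40, -20, 60),
                             radius = c(14, 14, 14), adc = 0.7e-3)),
    seed = seed, ...)
}

# memoised clean sessions (several test files reuse the same fixture)
.phantom_cache <- new.env(parent = emptyenv())
compact_phantom <- function(seed = 1L, protocol = "transverse_dixon") {
  key <- paste0(seed, "/", protocol)
  if (is.null(.phantom_cache[[key]]))
    .phantom_cache[[key]] <- build_phantom(compact_spec(seed),
                                           protocol = protocol)
  .phantom_cache[[key]]
}

# Published per-session pattern table: pattern, sessions in phase 1, phase 2
table1_rows <- function() {
  data.frame(
    pattern = c("F", "I", "F D", "D", "H", "F EM", "D N", "F D PM",
                "F D N", "F N", "F PM", "F PM EM", "F D PM EM", "F D EM",
                "MN", "D EM", "D MN", "F MN", "MN N"),
    phase1 = c(96, 63, 49, 38, 25, 6, 5, 7, 4, 6, 4, 2, 5, 2, 2, 1, 1, 0, 0),
    phase2 = c(88, 95, 28, 32, 22, 9, 8, 6, 5, 2, 2, 4, 0, 1, 0, 0, 0, 1, 1),
    stringsAsFactors = FALSE)
}

# expand the counts into one record per session
table1_records <- function() {
  rows <- table1_rows()
  recs <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    n1 <- rows$phase1[i]; n2 <- rows$phase2[i]
    if (n1 + n2 == 0) return(NULL)
    data.frame(pattern_code = rows$pattern[i],
               phase = rep(c(1L, 2L), c(n1, n2)))
  }))
  recs$session_id <- sprintf("S%04d", seq_len(nrow(recs)))
  recs
}

# Published per-subject category table: category, subjects phase 1, phase 2
table2_rows <- function() {
  data.frame(category = c("D", "F", "I", "H"),
             phase1 = c(73, 60, 21, 25),
             phase2 = c(72, 62, 41, 22),
             stringsAsFactors = FALSE)
}
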