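# Session-level QA: inventory checks against the expected series list,
# deterministic pseudonymisation of DICOM metadata, an XNAT-like local
# repository layout, and the append-only run record that makes the whole
# curation chain repeatable, auditable and self-documenting.

#' Create a run record
#'
#' An ordered, timestamped log of every curation action applied to a
#' session.  Append-only: each pipeline operation adds exactly one step via
#' [record_step()].  Exportable as JSON and as a crystallised
#' (non-interactive) HTML page suitable for storage as a session resource.
#'
#' @param config named list of pipeline configuration (hashed into the
#'   record)
#' @return object of class `run_record`
#' @export
run_record <- function(config = list()) {
  structure(list(
    tool = "wbcure",
    version = as.character(utils::packageVersion("wbcure")),
    config = config,
    config_hash = digest::digest(config, algo = "sha256"),
    steps = list()), class = "run_record")
}

#' Append a step to a run record
#'
#' @param record a [run_record()]
#' @param name step name
#' @param params parameters the step ran with
#' @param findings what the step found or did
#' @return the updated record
#' @export
record_step <- function(record, name, params = list(), findings = list()) {
  stopifnot(inherits(record, "run_record"))
  record$steps[[length(record$steps) + 1L]] <-
    list(name = name, params = params, findings = findings,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z"))
  record
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf("<run_record> wbcure %s, %d step(s)\n", x$version,
              length(x$steps)))
  for (s in x$steps) cat("  -", s$name, "\n")
  invisible(x)
}

#' Export a run record as JSON / crystallised HTML
#' @param record a [run_record()]
#' @param path output path
#' @return invisibly, `path`
#' @export
write_run_record_json <- function(record, path) {
  jsonlite::write_json(unclass(record), path, auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_record_json
#' @export
write_run_record_html <- function(record, path) {
  esc <- function(s) gsub("<", "&lt;", gsub("&", "&amp;", s))
  step_html <- vapply(record$steps, function(s) {
    paste0("<li><b>", esc(s$name), "</b> <i>", s$timestamp, "</i><pre>",
           esc(jsonlite::toJSON(list(params = s$params,
                                     findings = s$findings),
                                auto_unbox = TRUE, pretty = TRUE,
                                force = TRUE)),
           "</pre></li>")
  }, character(1))
  writeLines(c("<html><head><title>wbcure run record</title></head><body>",
               sprintf("<h1>wbcure %s run record</h1>", record$version),
               sprintf("<p>config hash: <code>%s</code></p>",
                       record$config_hash),
               "<ol>", step_html, "</ol>", "</body></html>"), path)
  invisible(path)
}

read_run_record_json <- function(path) {
  jsonlite::read_json(path)
}

#' Check a session's series inventory
#'
#' Compares the session's contrast labels against the expected series list
#' (default: the seven series a whole-body read requires).  Extraneous
#' series are listed for removal; the verdict is `complete` iff nothing
#' expected is missing.
#'
#' @param session an [imaging_session()]
#' @param expected expected contrast labels, default [CONTRAST_LABELS]
#' @param annotations optional list of [annotation_record()]s for the
#'   session; completeness then additionally requires every region of
#'   `regions` to be annotated
#' @param regions annotation region list, default [default_region_list()]
#' @return object of class `inventory_report`
#' @export
check_inventory <- function(session, expected = CONTRAST_LABELS,
                            annotations = NULL,
                            regions = default_region_list()) {
  stopifnot(inherits(session, "imaging_session"), length(expected) > 0)
  present <- names(session$series)
  missing <- setdiff(expected, present)
  extraneous <- setdiff(present, expected)
  ann_complete <- NA
  if (!is.null(annotations)) {
    done <- vapply(annotations, function(a) a$region_name, character(1))
    ann_complete <- all(regions %in% done)
  }
  structure(list(session_id = session$session_id, expected = expected,
                 present = intersect(expected, present),
                 missing = missing, extraneous = extraneous,
                 annotations_complete = ann_complete,
                 verdict = if (length(missing)) "incomplete" else "complete"),
            class = "inventory_report")
}

#' @export
print.inventory_report <- function(x, ...) {
  cat(sprintf("<inventory_report %s> %s; missing: %s; extraneous: %s\n",
              x$session_id, x$verdict,
              if (length(x$missing)) paste(x$missing, collapse = ", ")
              else "none",
              if (length(x$extraneous)) paste(x$extraneous, collapse = ", ")
              else "none"))
  invisible(x)
}

# DICOM tags removed or replaced by the pseudonymiser: a conservative
# subset of the basic confidentiality profile covering the identifiers our
# writer can emit plus the common clinical ones.
DEIDENT_TAGS <- list(
  c(0x0008, 0x0020), # StudyDate
  c(0x0008, 0x0021), # SeriesDate
  c(0x0008, 0x0022), # AcquisitionDate
  c(0x0008, 0x0023), # ContentDate
  c(0x0008, 0x0050), # AccessionNumber
  c(0x0008, 0x0080), # InstitutionName
  c(0x0008, 0x0090), # ReferringPhysicianName
  c(0x0008, 0x1048), # PhysiciansOfRecord
  c(0x0010, 0x0030), # PatientBirthDate
  c(0x0010, 0x0040), # PatientSex
  c(0x0010, 0x1010), # PatientAge
  c(0x0010, 0x1040)) # PatientAddress

MARKER_GROUP <- 0x0011
MARKER_ELEMENT <- 0x0010
MARKER_VALUE <- "WBCURE DEIDENTIFIED"

#' Deterministic pseudonym for a patient identifier
#'
#' Keyed hash (HMAC-SHA256) of the identifier under `salt`, truncated and
#' prefixed.  The same identifier and salt always give the same pseudonym;
#' without the salt (or the stored map) re-identification is infeasible.
#'
#' @param patient_id original identifier
#' @param salt secret salt string
#' @return character pseudonym, e.g. `"SUB-1a2b3c4d5e6f"`
#' @export
pseudonym_for <- function(patient_id, salt) {
  stopifnot(nzchar(salt))
  paste0("SUB-", substr(digest::hmac(salt, as.character(patient_id),
                                     algo = "sha256"), 1, 12))
}

#' Pseudonymise DICOM files
#'
#' Rewrites each file with the patient name/ID replaced by the
#' deterministic pseudonym, the configured identifying tags removed, and a
#' private marker tag added; files already carrying the marker are skipped
#' with a log entry.  Pixel data and geometry are untouched.
#'
#' @param files character vector of DICOM paths
#' @param out_dir output directory (may equal the input directory)
#' @param salt secret salt for [pseudonym_for()]
#' @param id_map named character vector (original -> pseudonym) to extend;
#'   pass the result of a previous call to keep one study-wide map
#' @param remove_tags list of `c(group, element)` pairs to drop,
#'   default `DEIDENT_TAGS`
#' @return list with `id_map` (updated), `written`, `skipped`
#' @export
pseudonymise <- function(files, out_dir, salt, id_map = character(0),
                         remove_tags = DEIDENT_TAGS) {
  files <- as.character(files)  # force before out_dir exists
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0); skipped <- character(0)
  keys <- vapply(remove_tags, function(t) paste(t, collapse = ","),
                 character(1))
  for (f in files) {
    els <- dcm_read(f)
    marker <- dcm_get(els, MARKER_GROUP, MARKER_ELEMENT)
    out_path <- file.path(out_dir, basename(f))
    if (!is.null(marker)) {
      skipped <- c(skipped, f)
      if (normalizePath(dirname(f)) != normalizePath(out_dir))
        file.copy(f, out_path, overwrite = TRUE)
      next
    }
    pid <- dcm_get(els, 0x0010, 0x0020) %||% "UNKNOWN"
    if (!pid %in% names(id_map)) {
      id_map[pid] <- pseudonym_for(pid, salt)
    }
    pseud <- unname(id_map[pid])
    keep <- vapply(els, function(el)
      !(paste(c(el$group, el$element), collapse = ",") %in% keys),
      logical(1))
    els <- els[keep]
    els <- lapply(els, function(el) {
      if (el$group == 0x0010 && el$element %in% c(0x0010, 0x0020))
        el$value <- pseud
      el
    })
    # insert marker keeping (group, element) order
    marker_el <- dcm_element(MARKER_GROUP, MARKER_ELEMENT, "LO",
                             MARKER_VALUE)
    ord_key <- vapply(els, function(el) el$group * 2^16 + el$element,
                      numeric(1))
    pos <- sum(ord_key < MARKER_GROUP * 2^16 + MARKER_ELEMENT)
    els <- append(els, list(marker_el), after = pos)
    dcm_write(els, out_path)
    written <- c(written, out_path)
  }
  list(id_map = id_map, written = written, skipped = skipped)
}

#' Persist / load the pseudonym map
#'
#' The map is stored as JSON.  If `key` is non-empty the payload is
#' encrypted at rest with an HMAC-SHA256 keystream (the key would normally
#' come from the environment, never from the repository).
#'
#' @param id_map named character vector (original -> pseudonym)
#' @param path output path
#' @param key optional secret; empty string writes plaintext JSON
#' @export
write_id_map <- function(id_map, path, key = "") {
  payload <- jsonlite::toJSON(as.list(id_map), auto_unbox = TRUE)
  if (nzchar(key)) {
    bytes <- charToRaw(payload)
    ks <- keystream(key, length(bytes))
    enc <- jsonlite::base64_enc(as.raw(bitwXor(as.integer(bytes),
                                               as.integer(ks))))
    writeLines(c("WBCURE-ENC-1", enc), path)
  } else {
    writeLines(as.character(payload), path)
  }
  invisible(path)
}

#' @rdname write_id_map
#' @export
read_id_map <- function(path, key = "") {
  lines <- readLines(path, warn = FALSE)
  if (identical(lines[1], "WBCURE-ENC-1")) {
    if (!nzchar(key)) stop("id map is encrypted: key required")
    bytes <- jsonlite::base64_dec(paste(lines[-1], collapse = ""))
    ks <- keystream(key, length(bytes))
    payload <- rawToChar(as.raw(bitwXor(as.integer(bytes),
                                        as.integer(ks))))
  } else payload <- paste(lines, collapse = "\n")
  unlist(jsonlite::fromJSON(payload))
}

keystream <- function(key, n) {
  out <- raw(0); i <- 0L
  while (length(out) < n) {
    h <- digest::hmac(key, paste0("wbcure-ks-", i), algo = "sha256",
                      raw = TRUE)
    out <- c(out, h); i <- i + 1L
  }
  out[seq_len(n)]
}

SESSION_RESOURCES <- c("DICOM", "NIFTI", "REPORTS", "SEGMENTATIONS", "ECRF")

#' Lay out a local project repository
#'
#' Creates the `project/subject/session/{DICOM,NIFTI,REPORTS,SEGMENTATIONS,
#' ECRF}` hierarchy mirroring an XNAT project/subject/experiment/resource
#' tree, so a thin uploader could ingest it.  Idempotent on an existing
#' tree; duplicate session IDs are an error.
#'
#' @param project_dir root directory
#' @param sessions data.frame with `subject_id`, `session_id`
#' @return invisibly, the session directories created
#' @export
layout_repository <- function(project_dir, sessions) {
  stopifnot(is.data.frame(sessions),
            all(c("subject_id", "session_id") %in% names(sessions)))
  if (anyDuplicated(sessions$session_id))
    stop("duplicate session_id in repository layout")
  paths <- character(0)
  for (i in seq_len(nrow(sessions))) {
    sdir <- file.path(project_dir, sessions$subject_id[i],
                      sessions$session_id[i])
    for (res in SESSION_RESOURCES)
      dir.create(file.path(sdir, res), recursive = TRUE,
                 showWarnings = FALSE)
    paths <- c(paths, sdir)
  }
  invisible(paths)
}

#' Store a session's run record in the repository
#'
#' Writes `run_record.json` and the crystallised `run_record.html` under
#' the session's REPORTS resource.
#'
#' @param record a [run_record()]
#' @param project_dir,subject_id,session_id repository coordinates
#' @export
store_run_record <- function(record, project_dir, subject_id, session_id) {
  rdir <- file.path(project_dir, subject_id, session_id, "REPORTS")
  dir.create(rdir, recursive = TRUE, showWarnings = FALSE)
  write_run_record_json(record, file.path(rdir, "run_record.json"))
  write_run_record_html(record, file.path(rdir, "run_record.html"))
  invisible(rdir)
}

#' Aggregate project metrics from stored run records
#'
#' Every number is recomputed from the run records alone, so the table is
#' reproducible and auditable.  Reports sessions curated, exclusions by
#' reason, fat-water swap prevalence and the protocol mix; sessions whose
#' record is missing or unreadable are listed, not fatal.
#'
#' @param project_dir repository root from [layout_repository()]
#' @return list with `n_sessions`, `n_excluded`, `exclusion_reasons`,
#'   `swap_prevalence`, `protocol_mix`, `sessions_without_record`,
#'   `corrupt_records`
#' @export
project_metrics <- function(project_dir) {
  sess_dirs <- list.dirs(project_dir, recursive = FALSE)
  sess_dirs <- unlist(lapply(sess_dirs, list.dirs, recursive = FALSE))
  n_swap <- 0L; n <- 0L
  no_record <- character(0); corrupt <- character(0)
  reasons <- character(0); protocols <- character(0)
  for (sd in sess_dirs) {
    rr_path <- file.path(sd, "REPORTS", "run_record.json")
    if (!file.exists(rr_path)) {
      no_record <- c(no_record, basename(sd))
      next
    }
    rr <- tryCatch(read_run_record_json(rr_path), error = function(e) NULL)
    if (is.null(rr) || is.null(rr$steps)) {
      corrupt <- c(corrupt, basename(sd))
      next
    }
    n <- n + 1L
    for (s in rr$steps) {
      if (identical(s$name, "detect_swaps") &&
          isTRUE((s$findings$n %||% 0) > 0)) n_swap <- n_swap + 1L
      if (identical(s$name, "exclude_session"))
        reasons <- c(reasons, s$findings$reason %||% "unspecified")
      if (identical(s$name, "session_info") &&
          !is.null(s$findings$protocol))
        protocols <- c(protocols, s$findings$protocol)
    }
  }
  list(n_sessions = n,
       n_excluded = length(reasons),
       exclusion_reasons = if (length(reasons)) table(reasons)
       else table(character(0)),
       swap_prevalence = if (n) n_swap / n else NA_real_,
       protocol_mix = if (length(protocols)) table(protocols)
       else table(character(0)),
       sessions_without_record = no_record,
       corrupt_records = corrupt)
}
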