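# Inventory QA, pseudonymisation, repository layout, run records and
# project metrics.

small_session <- function(labels = CONTRAST_LABELS, seed = 61) {
  s <- compact_phantom(seed)
  imaging_session(s$subject_id, s$session_id, s$series[labels],
                  cohort = s$cohort, protocol = s$protocol,
                  blocks = s$blocks)
}

test_that("check_inventory compares against the expected series set", {
  full <- small_session()
  r <- check_inventory(full)
  expect_equal(r$verdict, "complete")
  expect_length(r$missing, 0L)

  no_adc <- small_session(setdiff(CONTRAST_LABELS, "adc"))
  r2 <- check_inventory(no_adc)
  expect_equal(r2$verdict, "incomplete")
  expect_equal(r2$missing, "adc")

  extra <- small_session()
  extra$series$localizer <- extra$series$fat
  r3 <- check_inventory(extra)
  expect_equal(r3$verdict, "complete")
  expect_equal(r3$extraneous, "localizer")

  # annotation completeness needs all 18 regions
  ann <- lapply(default_region_list()[1:3], annotation_record)
  r4 <- check_inventory(full, annotations = ann)
  expect_false(r4$annotations_complete)
  ann_all <- lapply(default_region_list(), annotation_record)
  r5 <- check_inventory(full, annotations = ann_all)
  expect_true(r5$annotations_complete)
})

test_that("pseudonyms are deterministic, salted and injective", {
  expect_identical(pseudonym_for("PATIENT42", "salt"),
                   pseudonym_for("PATIENT42", "salt"))
  expect_false(pseudonym_for("PATIENT42", "salt") ==
                 pseudonym_for("PATIENT42", "other salt"))
  # injectivity over 1e5 synthetic ids under one salt
  ids <- sprintf("PT%06d", 1:100000)
  ps <- vapply(ids, pseudonym_for, character(1), salt = "study-salt",
               USE.NAMES = FALSE)
  expect_equal(anyDuplicated(ps), 0L)
})

test_that("pseudonymise strips tags, keeps pixels, and skips marked files", {
  s <- small_session(c("fat", "water"))
  dir <- withr::local_tempdir()
  write_session_dicom(s, dir)
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE)
  # add an identifying date tag to one file to verify removal
  els <- wbcure:::dcm_read(files[1])
  els <- append(els, list(wbcure:::dcm_element(0x0010, 0x0030, "DA",
                                               "19700101")), after = 4)
  ord <- order(vapply(els, function(e) e$group * 2^16 + e$element,
                      numeric(1)))
  wbcure:::dcm_write(els[ord], files[1])

  out <- file.path(dir, "anon")
  res <- pseudonymise(files, out, salt = "s")
  expect_length(res$written, length(files))
  expect_equal(unname(res$id_map["PHANTOM01"]),
               pseudonym_for("PHANTOM01", "s"))
  for (f in res$written) {
    e <- wbcure:::dcm_read(f)
    expect_null(wbcure:::dcm_get(e, 0x0010, 0x0030))
    expect_equal(wbcure:::dcm_get(e, 0x0010, 0x0020),
                 unname(res$id_map["PHANTOM01"]))
    expect_equal(wbcure:::dcm_get(e, 0x0011, 0x0010),
                 "WBCURE DEIDENTIFIED")
  }
  # pixel data unchanged
  before <- wbcure:::dcm_get(wbcure:::dcm_read(files[2]), 0x7FE0, 0x0010)
  after <- wbcure:::dcm_get(wbcure:::dcm_read(
    file.path(out, basename(files[2]))), 0x7FE0, 0x0010)
  expect_identical(before, after)
  # second pass skips everything
  res2 <- pseudonymise(res$written, file.path(dir, "anon2"), salt = "s",
                       id_map = res$id_map)
  expect_length(res2$skipped, length(files))
  expect_length(res2$written, 0L)
})

test_that("id map persists, plain and encrypted", {
  map <- c(A = "SUB-aaa", B = "SUB-bbb")
  p1 <- withr::local_tempfile(fileext = ".json")
  write_id_map(map, p1)
  expect_identical(read_id_map(p1), map)
  p2 <- withr::local_tempfile(fileext = ".json")
  write_id_map(map, p2, key = "k3y")
  expect_false(any(grepl("SUB-aaa", readLines(p2))))
  expect_identical(read_id_map(p2, key = "k3y"), map)
  expect_error(read_id_map(p2), "key required")
})

test_that("layout_repository builds the resource tree idempotently", {
  root <- withr::local_tempdir()
  sess <- data.frame(subject_id = c("s1", "s1", "s2", "s2"),
                     session_id = c("v1", "v2", "v3", "v4"))
  paths <- layout_repository(root, sess)
  expect_length(paths, 4L)
  for (p in paths)
    expect_setequal(basename(list.dirs(p, recursive = FALSE)),
                    c("DICOM", "NIFTI", "REPORTS", "SEGMENTATIONS", "ECRF"))
  before <- list.dirs(root)
  layout_repository(root, sess)  # no-op on unchanged input
  expect_identical(list.dirs(root), before)
  expect_error(layout_repository(root, rbind(sess, sess[1, ])),
               "duplicate")
})

test_that("run records are ordered, exportable and append-only", {
  rr <- run_record(config = list(rel_tol = 0.05))
  rr <- record_step(rr, "audit_series:fat", findings = list(severity = "ok"))
  rr <- record_step(rr, "detect_swaps", findings = list(n = 0))
  expect_length(rr$steps, 2L)
  expect_equal(vapply(rr$steps, `[[`, character(1), "name"),
               c("audit_series:fat", "detect_swaps"))
  dir <- withr::local_tempdir()
  jp <- file.path(dir, "run_record.json")
  write_run_record_json(rr, jp)
  back <- jsonlite::read_json(jp)
  expect_length(back$steps, 2L)
  hp <- file.path(dir, "run_record.html")
  write_run_record_html(rr, hp)
  expect_true(any(grepl("detect_swaps", readLines(hp))))
})

test_that("project_metrics recomputes everything from run records", {
  root <- withr::local_tempdir()
  sess <- data.frame(subject_id = sprintf("s%02d", 1:10),
                     session_id = sprintf("v%02d", 1:10))
  layout_repository(root, sess)
  for (i in 1:10) {
    rr <- run_record()
    rr <- record_step(rr, "session_info",
                      findings = list(protocol = if (i <= 3)
                        "coronal_dixon" else "transverse_dixon"))
    rr <- record_step(rr, "detect_swaps",
                      findings = list(n = if (i == 4) 1L else 0L))
    if (i == 9)
      rr <- record_step(rr, "exclude_session",
                        findings = list(reason = "incomplete archive"))
    store_run_record(rr, root, sess$subject_id[i], sess$session_id[i])
  }
  # one extra session with no record, one with a corrupt record
  layout_repository(root, data.frame(subject_id = "s11",
                                     session_id = "v11"))
  layout_repository(root, data.frame(subject_id = "s12",
                                     session_id = "v12"))
  writeLines("not json", file.path(root, "s12", "v12", "REPORTS",
                                   "run_record.json"))
  m <- project_metrics(root)
  expect_equal(m$n_sessions, 10L)
  expect_equal(m$swap_prevalence, 0.1)
  expect_equal(m$n_excluded, 1L)
  expect_equal(unname(m$exclusion_reasons["incomplete archive"]), 1L)
  expect_equal(unname(m$protocol_mix[["coronal_dixon"]]), 3L)
  expect_equal(m$sessions_without_record, "v11")
  expect_equal(m$corrupt_records, "v12")
})
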