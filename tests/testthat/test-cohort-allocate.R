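# Phase allocation: stratified split, determinism, subject atomicity,
# published per-subject table arithmetic.

make_subjects <- function(n_per_cat = c(F = 10, D = 10, I = 10, H = 10),
                          n_itimm = 0) {
  subj <- do.call(rbind, lapply(names(n_per_cat), function(cat)
    if (n_per_cat[[cat]] > 0)
      data.frame(subject_id = sprintf("%s%03d", cat,
                                      seq_len(n_per_cat[[cat]])),
                 cohort = "a_retro_RM", category = cat)))
  if (n_itimm > 0)
    subj <- rbind(subj, data.frame(
      subject_id = sprintf("T%03d", seq_len(n_itimm)),
      cohort = "b_iTIMM", category = "F"))
  subj
}

test_that("allocate_phases splits per category and honours iTIMM", {
  subj <- make_subjects(n_itimm = 7)
  plan <- allocate_phases(subj, proportions = 0.5, seed = 3)
  a <- plan$assignments
  expect_true(all(a$phase[a$cohort == "b_iTIMM"] == 3L))
  for (cat in c("F", "D", "I", "H")) {
    in_cat <- a$category == cat & a$cohort != "b_iTIMM"
    expect_equal(sum(a$phase[in_cat] == 1L), 5L)
    expect_equal(sum(a$phase[in_cat] == 2L), 5L)
  }
  # conservation
  expect_equal(sum(table(a$phase)), nrow(subj))
})

test_that("allocation uses round-half-up and per-category fractions", {
  subj <- make_subjects(c(F = 101, D = 0, I = 0, H = 0))
  plan <- allocate_phases(subj, proportions = 0.5, seed = 1)
  expect_equal(sum(plan$assignments$phase == 1L), 51L)
  expect_equal(sum(plan$assignments$phase == 2L), 50L)

  subj2 <- make_subjects(c(F = 20, D = 0, I = 30, H = 0))
  plan2 <- allocate_phases(subj2, proportions = c(F = 0.25, D = 0.5,
                                                  I = 0.4, H = 0.5),
                           seed = 1)
  a2 <- plan2$assignments
  expect_equal(sum(a2$phase == 1L & a2$category == "F"), 5L)
  expect_equal(sum(a2$phase == 1L & a2$category == "I"), 12L)
})

test_that("allocation is deterministic and input-order independent", {
  subj <- make_subjects()
  p1 <- allocate_phases(subj, seed = 11)
  p2 <- allocate_phases(subj, seed = 11)
  expect_identical(p1$assignments, p2$assignments)
  # shuffled input rows give the same subject -> phase map
  shuffled <- subj[sample(nrow(subj)), ]
  p3 <- allocate_phases(shuffled, seed = 11)
  m1 <- p1$assignments$phase[order(p1$assignments$subject_id)]
  m3 <- p3$assignments$phase[order(p3$assignments$subject_id)]
  expect_identical(m1, m3)
  # different seed, different plan (overwhelmingly likely)
  p4 <- allocate_phases(subj, seed = 12)
  expect_false(identical(p1$assignments$phase, p4$assignments$phase))
})

test_that("allocate_phases validates input", {
  subj <- make_subjects()
  expect_error(allocate_phases(rbind(subj, subj[1, ])), "duplicate")
  bad <- subj; bad$category[1] <- "Z"
  expect_error(allocate_phases(bad), "unknown category")
  expect_error(allocate_phases(subj, proportions = 1.2), "\\[0, 1\\]")
})

test_that("subject atomicity holds for arbitrary session tables", {
  set.seed(77)
  for (i in 1:20) {
    subj <- make_subjects(c(F = sample(3:12, 1), D = sample(3:12, 1),
                            I = sample(0:5, 1), H = 0),
                          n_itimm = sample(0:4, 1))
    plan <- allocate_phases(subj, seed = i)
    # random multi-session table over those subjects
    sess <- data.frame(
      subject_id = sample(subj$subject_id, 40, replace = TRUE))
    sess$session_id <- sprintf("S%03d", seq_len(nrow(sess)))
    sess$pattern_code <- "F"
    phase_of <- plan$assignments$phase[match(sess$subject_id,
                                             plan$assignments$subject_id)]
    # every session of one subject lands in that subject's phase
    expect_true(all(tapply(phase_of, sess$subject_id,
                           function(x) length(unique(x))) == 1L))
  }
})

test_that("summarize_allocation reproduces the published per-subject table", {
  rows <- table2_rows()
  subj <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    n1 <- rows$phase1[i]; n2 <- rows$phase2[i]
    data.frame(subject_id = sprintf("%s%03d", rows$category[i],
                                    seq_len(n1 + n2)),
               cohort = "a_retro_RM", category = rows$category[i],
               phase = rep(c(1L, 2L), c(n1, n2)))
  }))
  # build a plan object carrying exactly these published assignments
  plan <- allocate_phases(subj[, 1:3], seed = 1)
  plan$assignments$phase <- subj$phase
  sess <- data.frame(session_id = paste0("S", seq_len(nrow(subj))),
                     subject_id = subj$subject_id,
                     pattern_code = subj$category)
  sess$pattern_code[sess$pattern_code == "I"] <- "I"
  tabs <- summarize_allocation(plan, sess)
  ct <- tabs$category_table
  expect_equal(ct$phase_1[ct$category == "Total"], 179)
  expect_equal(ct$phase_2[ct$category == "Total"], 197)
  expect_equal(ct$combined[ct$category == "Total"], 376)
  expect_equal(ct$combined[ct$category == "D"], 145)

  # orphan session -> error
  bad <- rbind(sess, data.frame(session_id = "SX", subject_id = "nope",
                                pattern_code = "F"))
  expect_error(summarize_allocation(plan, bad), "missing from the plan")

  # per-subject vs per-session distinction
  one <- data.frame(subject_id = "A1", cohort = "a_retro_RM",
                    category = "F")
  p1 <- allocate_phases(one, proportions = 1, seed = 1)
  s2 <- data.frame(session_id = c("s1", "s2"), subject_id = "A1",
                   pattern_code = "F")
  t2 <- summarize_allocation(p1, s2)
  expect_equal(t2$category_table$phase_1[t2$category_table$category == "F"],
               1)
  expect_equal(t2$pattern_table$phase_1[t2$pattern_table$pattern == "F"], 2)
})

test_that("write_allocation emits csv, config and html", {
  dir <- withr::local_tempdir()
  plan <- allocate_phases(make_subjects(), seed = 2)
  files <- write_allocation(plan, dir)
  expect_true(all(file.exists(files)))
  back <- utils::read.csv(file.path(dir, "allocation.csv"))
  expect_equal(nrow(back), 40)
  cfg <- jsonlite::read_json(file.path(dir, "allocation_config.json"))
  expect_equal(cfg$seed, 2)
})
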