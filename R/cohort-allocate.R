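# Deterministic, auditable allocation of subjects to project phases.
# Phase 1 holds training data, Phases 2-3 validation; the prospective
# trial cohort (b_iTIMM) goes to Phase 3 unconditionally, and the rest are
# split per coalesced disease category by a seeded, sorted-then-shuffled
# draw so that the plan is independent of input file order.  Allocation is
# per subject, never per session, so no subject can leak between training
# and validation.

#' Allocate subjects to project phases
#'
#' @param subjects data.frame with columns `subject_id`, `cohort`,
#'   `category` (values in F, D, I, H)
#' @param proportions named fractions (per category) sent to Phase 1;
#'   unnamed scalar recycles to all categories; default 0.5
#' @param seed integer seed controlling the within-category shuffle
#' @return object of class `allocation_plan`: `assignments` data.frame
#'   (subject_id, cohort, category, phase), `counts` (category x phase
#'   subject counts), `seed`, `proportions`
#' @export
allocate_phases <- function(subjects, proportions = 0.5, seed = 1L) {
  stopifnot(is.data.frame(subjects),
            all(c("subject_id", "cohort", "category") %in% names(subjects)))
  if (anyDuplicated(subjects$subject_id))
    stop("duplicate subject_id in allocation input")
  bad <- setdiff(unique(subjects$category), c("F", "D", "I", "H"))
  if (length(bad))
    stop("unknown category: ", paste(bad, collapse = ", "))
  cats <- c("F", "D", "I", "H")
  if (is.null(names(proportions))) {
    stopifnot(length(proportions) == 1L)
    proportions <- stats::setNames(rep(proportions, 4), cats)
  }
  if (any(proportions < 0 | proportions > 1))
    stop("phase-1 fractions must be in [0, 1]")

  phase <- integer(nrow(subjects))
  itimm <- subjects$cohort == "b_iTIMM"
  phase[itimm] <- 3L
  rest <- subjects[!itimm, , drop = FALSE]
  set.seed(as.integer(seed))
  for (cat in sort(unique(rest$category))) {  # fixed order: RNG stream
                                              # independent of row order
    ids <- sort(rest$subject_id[rest$category == cat])
    n <- length(ids)
    shuffled <- ids[sample.int(n)]
    n1 <- as.integer(floor(proportions[[cat]] * n + 0.5))  # round half up
    to1 <- shuffled[seq_len(n1)]
    phase[!itimm][match(to1, subjects$subject_id[!itimm])] <- 1L
  }
  # anything not phase 1 or 3 is phase 2
  phase[phase == 0L] <- 2L
  assignments <- data.frame(subject_id = subjects$subject_id,
                            cohort = subjects$cohort,
                            category = subjects$category,
                            phase = phase, stringsAsFactors = FALSE)
  counts <- table(factor(assignments$category, levels = cats),
                  factor(assignments$phase, levels = 1:3))
  structure(list(assignments = assignments, counts = counts,
                 seed = as.integer(seed),
                 proportions = proportions),
            class = "allocation_plan")
}

#' @export
print.allocation_plan <- function(x, ...) {
  cat(sprintf("<allocation_plan> %d subjects, seed %d\n",
              nrow(x$assignments), x$seed))
  print(x$counts)
  invisible(x)
}

#' Summarise an allocation over a session table
#'
#' Builds the two published summary layouts: a per-subject category-by-
#' phase table and a per-session pattern-by-phase table, each with Total
#' row and combined column.
#'
#' @param plan an [allocation_plan()]
#' @param sessions data.frame with `session_id`, `subject_id`,
#'   `pattern_code`
#' @param phases phases to show as columns, default `c(1, 2)`
#' @return list with `category_table` (per subject) and `pattern_table`
#'   (per session)
#' @export
summarize_allocation <- function(plan, sessions, phases = c(1L, 2L)) {
  stopifnot(inherits(plan, "allocation_plan"), is.data.frame(sessions),
            all(c("session_id", "subject_id", "pattern_code") %in%
                  names(sessions)))
  orphan <- setdiff(sessions$subject_id, plan$assignments$subject_id)
  if (length(orphan))
    stop("session(s) reference subjects missing from the plan: ",
         paste(utils::head(orphan, 5), collapse = ", "))
  a <- plan$assignments
  cats <- c("F", "D", "I", "H")
  keep <- a$phase %in% phases
  cat_tab <- as.data.frame.matrix(
    table(factor(a$category[keep], levels = cats),
          factor(a$phase[keep], levels = phases)))
  names(cat_tab) <- paste0("phase_", phases)
  cat_tab$combined <- rowSums(cat_tab)
  cat_tab <- cbind(category = rownames(cat_tab), cat_tab)
  rownames(cat_tab) <- NULL
  total <- data.frame(category = "Total",
                      t(colSums(cat_tab[, -1, drop = FALSE])),
                      check.names = FALSE)
  names(total) <- names(cat_tab)
  cat_tab <- rbind(cat_tab, total)

  sess <- sessions
  sess$phase <- a$phase[match(sess$subject_id, a$subject_id)]
  pattern_tab <- aggregate_pattern_counts(
    data.frame(session_id = sess$session_id, phase = sess$phase,
               pattern_code = sess$pattern_code), phases = phases)
  list(category_table = cat_tab, pattern_table = pattern_tab)
}

#' Write an allocation plan with its provenance
#'
#' Emits `allocation.csv` (assignments), `allocation_config.json` (seed,
#' fractions) and a small self-documenting `allocation_report.html`.
#'
#' @param plan an [allocation_plan()]
#' @param directory output directory
#' @return invisibly, the files written
#' @export
write_allocation <- function(plan, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(directory, "allocation.csv")
  utils::write.csv(plan$assignments, csv, row.names = FALSE)
  cfg <- file.path(directory, "allocation_config.json")
  jsonlite::write_json(list(seed = plan$seed,
                            proportions = as.list(plan$proportions)),
                       cfg, auto_unbox = TRUE, pretty = TRUE)
  html <- file.path(directory, "allocation_report.html")
  tab <- plan$counts
  rows <- paste(apply(cbind(rownames(tab), tab), 1, function(r)
    paste0("<tr><td>", paste(r, collapse = "</td><td>"), "</td></tr>")),
    collapse = "\n")
  writeLines(c(
    "<html><head><title>Phase allocation</title></head><body>",
    sprintf("<h1>Phase allocation (seed %d)</h1>", plan$seed),
    "<table border='1'><tr><th>category</th><th>Phase 1</th><th>Phase 2</th><th>Phase 3</th></tr>",
    rows, "</table>",
    sprintf("<p>Fractions to Phase 1: %s</p>",
            paste(sprintf("%s=%.3g", names(plan$proportions),
                          plan$proportions), collapse = ", ")),
    "</body></html>"), html)
  invisible(c(csv, cfg, html))
}
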