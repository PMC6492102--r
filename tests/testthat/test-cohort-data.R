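test_that("reading a cohort reproduces the fixture and round-trips through write_cohort", {
  coh <- read_toy_cohort()
  expect_s3_class(coh, "retino_cohort")
  expect_equal(nrow(coh$demographics), 3)
  expect_equal(nrow(coh$episodes), 9)
  expect_equal(sum(coh$episodes$attended), 8)
  expect_equal(attr(coh, "parse_report")$n_rejected, 0)

  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  coh2 <- read_cohort(file.path(dir, "episodes.csv"),
                      file.path(dir, "covariates.csv"),
                      file.path(dir, "demographics.csv"), quiet = TRUE)
  expect_equal(coh$episodes, coh2$episodes)
  expect_equal(coh$covariates, coh2$covariates)
  expect_equal(coh$demographics, coh2$demographics)
})

test_that("schema violations are reported precisely", {
  dir <- withr::local_tempdir()
  p <- write_toy_csvs(dir)
  # unknown grade code on one row -> that row rejected, line number named
  tb <- readr::read_csv(p$episodes, show_col_types = FALSE)
  tb$grade_right[2] <- "R3"
  readr::write_csv(tb, p$episodes, na = "")
  expect_warning(
    coh <- read_cohort(p$episodes, p$covariates, p$demographics, quiet = TRUE),
    "line 3")
  expect_equal(nrow(coh$episodes), 8)
  expect_equal(attr(coh, "parse_report")$rejected_lines, 3L)

  # missing mandatory column -> error naming it
  tb$grade_right <- NULL
  readr::write_csv(tb, p$episodes, na = "")
  expect_error(read_cohort(p$episodes, p$covariates, p$demographics,
                           quiet = TRUE),
               "grade_right")
})

test_that("covariate alignment picks the nearest record, earlier on ties, NA when absent", {
  cov <- tibble::tibble(patient_id = "A", time_years = c(0.9, 2.1),
                        hba1c = c(50, 55), sbp = c(NA, 132),
                        dbp = c(70, 71), chol = c(4, 4.1))
  out <- align_covariates(cov, tibble::tibble(patient_id = "A",
                                              time_years = 2.0))
  expect_equal(out$hba1c, 55)   # 2.1 closer than 0.9
  expect_equal(out$sbp, 132)    # NA records are ignored per variable

  # exact tie: records at 1.0 and 3.0, episode at 2.0 -> earlier record
  cov2 <- tibble::tibble(patient_id = "A", time_years = c(1, 3),
                         hba1c = c(10, 20), sbp = c(1, 2), dbp = c(1, 2),
                         chol = c(1, 2))
  out2 <- align_covariates(cov2, tibble::tibble(patient_id = "A",
                                                time_years = 2))
  expect_equal(out2$hba1c, 10)

  # a patient with no record at all for a variable -> NA everywhere
  cov3 <- cov2
  cov3$sbp <- NA_real_
  out3 <- align_covariates(cov3, tibble::tibble(patient_id = "A",
                                                time_years = c(1, 2)))
  expect_true(all(is.na(out3$sbp)))
  expect_false(anyNA(out3$hba1c))
})

test_that("exclusion rules fire in order and counts add up", {
  tb <- toy_cohort_tables()
  # D: one attended episode only; E: stale covariates; F: STDR at first visit
  episodes <- dplyr::bind_rows(tb$episodes, tibble::tribble(
    ~patient_id, ~time_years, ~grade_right, ~grade_left, ~attended,
    "D", 0.0, "R0", "R0", 1L,
    "E", 0.0, "R0", "R0", 1L,
    "E", 2.0, "R0", "R0", 1L,
    "F", 0.0, "STDR", "R0", 1L,
    "F", 1.0, "STDR", "R0", 1L))
  covariates <- dplyr::bind_rows(tb$covariates, tibble::tribble(
    ~patient_id, ~time_years, ~hba1c_mmol_mol, ~sbp_mmhg, ~dbp_mmhg, ~chol_mmol_l,
    "D", 0.0, 50, 130, 75, 4,
    "E", 0.3, 50, 130, 75, 4,   # 20 months before E's final visit at 2.0
    "F", 0.0, 50, 130, 75, 4,
    "F", 1.0, 50, 130, 75, 4))
  demographics <- dplyr::bind_rows(tb$demographics, tibble::tribble(
    ~patient_id, ~sex, ~age_first_visit, ~diabetes_type, ~duration_first_visit_years,
    "D", "male", 60, "type2", 1,
    "E", "male", 60, "type2", 1,
    "F", "male", 60, "type2", 1))
  coh <- retinorisk:::new_cohort(episodes, dplyr::rename(
    covariates, hba1c = "hba1c_mmol_mol", sbp = "sbp_mmhg",
    dbp = "dbp_mmhg", chol = "chol_mmol_l"), demographics)

  out <- apply_exclusions(coh)
  rep <- exclusion_report(out)
  expect_equal(rep$n_excluded[rep$rule == "single_visit"], 1)          # D
  expect_equal(rep$n_excluded[rep$rule == "no_recent_clinical_visit"], 1)  # E
  expect_equal(rep$n_excluded[rep$rule == "stdr_at_start"], 1)         # F
  expect_equal(sum(rep$n_excluded),
               nrow(coh$demographics) - nrow(out$demographics))
  expect_setequal(out$demographics$patient_id, c("A", "B", "C"))

  path <- file.path(withr::local_tempdir(), "excl.json")
  write_exclusion_report(rep, path)
  expect_equal(jsonlite::read_json(path)$single_visit, 1)
})

test_that("final visit and group follow the earliest STDR detection, either eye", {
  epi <- tibble::tribble(
    ~patient_id, ~time_years, ~grade_right, ~grade_left, ~attended,
    "X", 0, "R0", "R0", TRUE,
    "X", 1, "R0", "R0", TRUE,
    "X", 2, "R0", "STDR", TRUE,   # left eye only
    "X", 3, "R1", "R1", TRUE,     # beyond detection: ignored
    "Y", 0, "R0", "R0", TRUE,
    "Y", 5, "R1", "R0", TRUE)
  coh <- retinorisk:::new_cohort(epi, tibble::tibble(
    patient_id = character(), time_years = numeric(), hba1c = numeric(),
    sbp = numeric(), dbp = numeric(), chol = numeric()),
    tibble::tibble(patient_id = c("X", "Y"), sex = "male",
                   age_first_visit = 60, diabetes_type = "type2",
                   duration_first_visit_years = 1))
  fv <- define_final_visit(coh)
  expect_equal(fv$final_time[fv$patient_id == "X"], 2)
  expect_equal(fv$group[fv$patient_id == "X"], "STDR")
  expect_equal(fv$final_time[fv$patient_id == "Y"], 5)
  expect_equal(fv$group[fv$patient_id == "Y"], "non-STDR")
})

test_that("prediction instances truncate one year before the final visit with the right label", {
  coh <- small_mixed_cohort()
  inst <- small_mixed_instances()
  fv <- define_final_visit(coh)
  m <- dplyr::inner_join(inst, fv, by = "patient_id")
  expect_true(all(abs(m$prediction_time - (m$final_time - 1)) < 1e-9))
  expect_equal(m$label, m$group.y == "STDR")

  # no STDR grade ever enters a history, and every history stops in time
  for (i in seq_len(nrow(inst))) {
    h <- inst$history[[i]]
    expect_true(all(h$y_right %in% 0:1 & h$y_left %in% 0:1))
    expect_true(all(h$time_years <= inst$prediction_time[i] + 1e-9))
  }
})

test_that("missed_previous reflects attendance of the episode before the prediction visit", {
  epi <- tibble::tribble(
    ~patient_id, ~time_years, ~grade_right, ~grade_left, ~attended,
    "P", 0, "R0", "R0", TRUE,
    "P", 1, "R0", "R0", TRUE,
    "P", 2, NA, NA, FALSE,      # missed immediately before prediction visit
    "P", 3, "R0", "R1", TRUE,
    "P", 4, "STDR", "R0", TRUE,
    "Q", 0, "R0", "R0", TRUE,
    "Q", 1, "R0", "R0", TRUE,
    "Q", 2, "R0", "R0", TRUE,
    "Q", 3, "R0", "R0", TRUE)
  cov <- tidyr::expand_grid(patient_id = c("P", "Q"), time_years = 0:4) |>
    dplyr::mutate(hba1c = 50, sbp = 130, dbp = 75, chol = 4)
  dem <- tibble::tibble(patient_id = c("P", "Q"), sex = "female",
                        age_first_visit = 55, diabetes_type = "type2",
                        duration_first_visit_years = 2)
  coh <- retinorisk:::new_cohort(epi, cov, dem)
  inst <- build_prediction_instances(coh)
  expect_true(inst$missed_previous[inst$patient_id == "P"])
  expect_true(inst$label[inst$patient_id == "P"])
  expect_false(inst$missed_previous[inst$patient_id == "Q"])
  expect_false(inst$label[inst$patient_id == "Q"])
  # per-visit missed_prev covariate marks the visit after the missed episode
  hP <- inst$history[[which(inst$patient_id == "P")]]
  expect_equal(hP$missed_prev, c(0L, 0L, 1L))
})
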