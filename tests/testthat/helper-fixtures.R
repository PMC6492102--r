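# Shared fixtures, generated in code and cached per test run.

fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = fixture_env))
    assign(name, expr, envir = fixture_env)
  get(name, envir = fixture_env)
}

# hand-built 3-patient toy cohort exercising grades, misses and alignment
toy_cohort_tables <- function() {
  episodes <- tibble::tribble(
    ~patient_id, ~time_years, ~grade_right, ~grade_left, ~attended,
    "A", 0.0, "R0", "R0", 1L,
    "A", 1.0, "R0", "R1", 1L,
    "A", 2.0, NA,   NA,   0L,
    "A", 3.0, "R1", "R1", 1L,
    "B", 0.0, "R0", "R0", 1L,
    "B", 1.1, "R0", "R0", 1L,
    "B", 2.0, "STDR", "R1", 1L,
    "C", 0.0, "R1", "R0", 1L,
    "C", 1.0, "R1", "R1", 1L)
  covariates <- tibble::tribble(
    ~patient_id, ~time_years, ~hba1c_mmol_mol, ~sbp_mmhg, ~dbp_mmhg, ~chol_mmol_l,
    "A", 0.1, 50, 130, 75, 4.1,
    "A", 0.9, 52, 132, 76, 4.2,
    "A", 2.1, 55, 135, 78, 4.3,
    "B", 0.0, 60, 140, 80, 4.5,
    "B", 1.9, 65, 142, 82, 4.6,
    "C", 0.5, 48, 128, 70, 3.9,
    "C", 1.0, 49, 129, 71, 4.0)
  demographics <- tibble::tribble(
    ~patient_id, ~sex, ~age_first_visit, ~diabetes_type, ~duration_first_visit_years,
    "A", "female", 61.2, "type2", 3.0,
    "B", "male",   55.0, "type1", 8.5,
    "C", "male",   48.3, "type2", 1.2)
  list(episodes = episodes, covariates = covariates,
       demographics = demographics)
}

write_toy_csvs <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  tb <- toy_cohort_tables()
  paths <- list(episodes = file.path(dir, "episodes.csv"),
                covariates = file.path(dir, "covariates.csv"),
                demographics = file.path(dir, "demographics.csv"))
  readr::write_csv(tb$episodes, paths$episodes, na = "")
  readr::write_csv(tb$covariates, paths$covariates, na = "")
  readr::write_csv(tb$demographics, paths$demographics, na = "")
  paths
}

read_toy_cohort <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  p <- write_toy_csvs(dir)
  read_cohort(p$episodes, p$covariates, p$demographics, quiet = TRUE)
}

# mid-size mixed cohort shared across files (group structure + both labels)
small_mixed_cohort <- function() {
  cached("small_mixed", generate_cohort(
    generator_config(n_patients = 400, prevalence_stdr = 0.25,
                     followup_min = 4, followup_max = 7, seed = 2024)))
}

small_mixed_instances <- function() {
  cached("small_mixed_inst", suppressWarnings(
    build_prediction_instances(apply_exclusions(small_mixed_cohort()))))
}

# tiny single-covariate truth used by the cheap model-comparison fits
tiny_truth <- function(or_duration = 3.5) {
  retinorisk:::new_truth(
    model_spec("duration"),
    beta = log(or_duration),
    weights = c(0.5, 0.5),
    means = rbind(c(-1.5, -1.5), c(0.5, 0.5)),
    covs = rbind(c(0.6, 0.3, 0.6), c(0.6, 0.3, 0.6)))
}

tiny_group_instances <- function(n = 120, seed = 1, truth = tiny_truth()) {
  cfg <- generator_config(n_patients = n, followup_min = 4, followup_max = 4,
                          truth_nonstdr = truth, seed = seed)
  suppressWarnings(build_prediction_instances(
    apply_exclusions(generate_group_cohort(n, "non-STDR", cfg))))
}

# instances built directly from hand-made histories (discriminant tests)
manual_instances <- function(histories, type1 = FALSE) {
  n <- length(histories)
  out <- tibble::tibble(
    patient_id = sprintf("M%03d", seq_len(n)),
    group = "non-STDR", label = FALSE,
    prediction_time = vapply(histories, function(h)
      if (nrow(h)) max(h$time_years) else 0, numeric(1)),
    missed_previous = FALSE,
    n_visits = vapply(histories, nrow, integer(1)),
    sex = "female", age_first_visit = 60,
    diabetes_type = if (type1) "type1" else "type2",
    duration_first_visit_years = 2,
    pred_grade = "R0/R0",
    history = histories)
  class(out) <- c("retino_instances", class(out))
  out
}

manual_history <- function(times, y_right, y_left, hba1c = 50, sbp = 130,
                           dbp = 75, chol = 4.2, duration0 = 2) {
  tibble::tibble(time_years = times, y_right = y_right, y_left = y_left,
                 duration_years = duration0 + times, missed_prev = 0L,
                 hba1c = hba1c, sbp = sbp, dbp = dbp, chol = chol)
}
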