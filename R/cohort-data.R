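# Cohort data model, CSV I/O, exclusion filters and prediction instances.
#
# A cohort is three linked tables keyed by patient_id:
#   episodes:     one row per scheduled screening episode (attended or missed);
#                 attended episodes carry a per-eye grade in {R0, R1, STDR}
#   covariates:   irregular clinical records (HbA1c mmol/mol, SBP/DBP mmHg,
#                 total cholesterol mmol/L)
#   demographics: one row per patient (sex, age and diabetes duration at first
#                 screening visit, diabetes type)

GRADE_LEVELS <- c("R0", "R1", "STDR")
COVARIATE_VARS <- c("hba1c", "sbp", "dbp", "chol")

EPISODE_COLS <- c("patient_id", "time_years", "grade_right", "grade_left", "attended")
COVARIATE_COLS <- c("patient_id", "time_years", "hba1c_mmol_mol", "sbp_mmhg",
                    "dbp_mmhg", "chol_mmol_l")
DEMOGRAPHIC_COLS <- c("patient_id", "sex", "age_first_visit", "diabetes_type",
                      "duration_first_visit_years")

new_cohort <- function(episodes, covariates, demographics, truth = NULL,
                       parse_report = NULL) {
  episodes$attended <- as.logical(episodes$attended)
  out <- list(episodes = as_tibble(episodes),
              covariates = as_tibble(covariates),
              demographics = as_tibble(demographics))
  structure(out, truth = truth, parse_report = parse_report,
            class = "retino_cohort")
}

#' @export
print.retino_cohort <- function(x, ...) {
  n_pat <- nrow(x$demographics)
  n_epi <- nrow(x$episodes)
  n_att <- sum(x$episodes$attended)
  cat("<retino_cohort> ", n_pat, " patients, ", n_epi, " scheduled episodes (",
      n_att, " attended), ", nrow(x$covariates), " clinical records\n", sep = "")
  if (!is.null(attr(x, "truth")))
    cat("  generated cohort with stored ground truth (",
        sum(attr(x, "truth")$group == "STDR"), " STDR-group patients)\n", sep = "")
  invisible(x)
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    abort(paste0("missing mandatory column(s) in ", what, " table: ",
                 paste(missing, collapse = ", ")))
  invisible(df)
}

#' Read a screening cohort from CSV files
#'
#' Reads the three cohort tables (episodes, clinical covariates, demographics)
#' and assembles a validated cohort object.  Episode rows with an unknown
#' grade code, an attendance flag outside \{0, 1\}, or grades inconsistent with
#' the attendance flag (grades must be present iff the episode was attended)
#' are rejected with a warning naming the offending CSV line numbers; the
#' parse report records the counts.
#'
#' @param episodes_path CSV with columns `patient_id, time_years, grade_right,
#'   grade_left, attended` (grades `R0|R1|STDR`, empty iff `attended = 0`).
#' @param covariates_path CSV with columns `patient_id, time_years,
#'   hba1c_mmol_mol, sbp_mmhg, dbp_mmhg, chol_mmol_l` (empty cell = missing).
#' @param demographics_path CSV with columns `patient_id, sex,
#'   age_first_visit, diabetes_type, duration_first_visit_years`.
#' @param quiet suppress the parse-report message.
#' @return A `retino_cohort`; the parse report (row counts, rejected lines) is
#'   attached as attribute `"parse_report"`.
#' @export
read_cohort <- function(episodes_path, covariates_path, demographics_path,
                        quiet = FALSE) {
  epi <- readr::read_csv(episodes_path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  check_columns(epi, EPISODE_COLS, "episodes")
  n_in <- nrow(epi)

  time_years <- suppressWarnings(as.numeric(epi$time_years))
  attended_num <- suppressWarnings(as.numeric(epi$attended))
  gr <- ifelse(is.na(epi$grade_right) | epi$grade_right == "", NA, epi$grade_right)
  gl <- ifelse(is.na(epi$grade_left) | epi$grade_left == "", NA, epi$grade_left)

  bad_time <- is.na(time_years) | time_years < 0
  bad_att <- !(attended_num %in% c(0, 1))
  bad_grade <- (!is.na(gr) & !gr %in% GRADE_LEVELS) |
               (!is.na(gl) & !gl %in% GRADE_LEVELS)
  attended <- attended_num == 1
  bad_consistency <- !bad_att &
    ((attended & (is.na(gr) | is.na(gl))) | (!attended & (!is.na(gr) | !is.na(gl))))
  bad <- bad_time | bad_att | bad_grade | bad_consistency
  if (any(bad)) {
    lines <- which(bad) + 1L  # +1 for the header line
    warn(paste0(sum(bad), " episode row(s) rejected (CSV line ",
                paste(utils::head(lines, 10), collapse = ", "),
                if (sum(bad) > 10) ", ..." else "", "): invalid grade code, ",
                "attendance flag or grade/attendance consistency"))
  }
  episodes <- tibble(patient_id = epi$patient_id, time_years = time_years,
                     grade_right = gr, grade_left = gl,
                     attended = attended)[!bad, , drop = FALSE] |>
    arrange(patient_id, time_years)

  cov <- readr::read_csv(covariates_path, progress = FALSE,
                         col_types = readr::cols(patient_id = "c", .default = "d"))
  check_columns(cov, COVARIATE_COLS, "covariates")
  covariates <- tibble(patient_id = cov$patient_id, time_years = cov$time_years,
                       hba1c = cov$hba1c_mmol_mol, sbp = cov$sbp_mmhg,
                       dbp = cov$dbp_mmhg, chol = cov$chol_mmol_l) |>
    arrange(patient_id, time_years)
  soft_range_check(covariates)

  dem <- readr::read_csv(demographics_path, progress = FALSE,
                         col_types = readr::cols(patient_id = "c", sex = "c",
                                                 diabetes_type = "c",
                                                 .default = "d"))
  check_columns(dem, DEMOGRAPHIC_COLS, "demographics")
  bad_dem <- !dem$sex %in% c("female", "male") |
    !dem$diabetes_type %in% c("type1", "type2") |
    is.na(dem$duration_first_visit_years) | dem$duration_first_visit_years < 0
  if (any(bad_dem)) {
    warn(paste0(sum(bad_dem), " demographics row(s) rejected (CSV line ",
                paste(which(bad_dem) + 1L, collapse = ", "), ")"))
    dem <- dem[!bad_dem, , drop = FALSE]
  }
  demographics <- tibble(patient_id = dem$patient_id, sex = dem$sex,
                         age_first_visit = dem$age_first_visit,
                         diabetes_type = dem$diabetes_type,
                         duration_first_visit_years = dem$duration_first_visit_years)

  orphans <- setdiff(unique(episodes$patient_id), demographics$patient_id)
  if (length(orphans) > 0) {
    warn(paste0(length(orphans), " patient(s) with episodes but no demographics ",
                "row dropped"))
    episodes <- filter(episodes, !.data$patient_id %in% orphans)
  }
  report <- list(n_episode_rows = n_in, n_rejected = sum(bad),
                 rejected_lines = which(bad) + 1L,
                 n_patients = nrow(demographics))
  if (!quiet)
    inform(paste0("read_cohort: ", report$n_patients, " patients, ",
                  nrow(episodes), "/", n_in, " episode rows kept"))
  new_cohort(episodes, covariates, demographics, parse_report = report)
}

soft_range_check <- function(covariates) {
  n_bad <- sum(covariates$hba1c < 20 | covariates$hba1c > 200, na.rm = TRUE) +
    sum(covariates$sbp < 70 | covariates$sbp > 260, na.rm = TRUE)
  if (n_bad > 0)
    warn(paste0(n_bad, " covariate value(s) outside plausible physiological ",
                "ranges (HbA1c 20-200 mmol/mol, SBP 70-260 mmHg); kept as-is"))
  invisible(covariates)
}

#' Write a cohort to CSV files
#'
#' Inverse of [read_cohort()]: writes `episodes.csv`, `covariates.csv` and
#' `demographics.csv` (plus `truth.json` when the cohort was generated
#' synthetically and carries ground truth) into `dir`.
#'
#' @param cohort a `retino_cohort`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "retino_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("episodes.csv", "covariates.csv", "demographics.csv"))
  epi <- cohort$episodes |>
    mutate(attended = as.integer(.data$attended))
  readr::write_csv(epi, paths[1], na = "")
  cov <- cohort$covariates
  names(cov) <- COVARIATE_COLS
  readr::write_csv(cov, paths[2], na = "")
  readr::write_csv(cohort$demographics, paths[3], na = "")
  truth <- attr(cohort, "truth")
  if (!is.null(truth)) {
    tp <- file.path(dir, "truth.json")
    rec <- setNames(
      lapply(seq_len(nrow(truth)), function(i)
        list(group = truth$group[i], component = truth$component[i],
             b_right = truth$b_right[i], b_left = truth$b_left[i])),
      truth$patient_id)
    jsonlite::write_json(rec, tp, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, tp)
  }
  invisible(paths)
}

#' Align clinical covariates to episode times
#'
#' For each requested episode time, each covariate takes the value of that
#' patient's record nearest in time (complete-case style: no interpolation or
#' imputation).  When two records are equally near, the earlier one is used.
#' A patient with no record at all for a covariate gets `NA` at every episode,
#' flagging those episodes as unusable for model fitting.
#'
#' @param covariates covariate table (`patient_id, time_years, hba1c, sbp,
#'   dbp, chol`), e.g. `cohort$covariates`.
#' @param episode_times tibble with `patient_id` and `time_years` rows at
#'   which values are required.
#' @return `episode_times` with one aligned column per covariate.
#' @export
align_covariates <- function(covariates, episode_times) {
  vars <- setdiff(names(covariates), c("patient_id", "time_years"))
  cov_split <- split(covariates, covariates$patient_id)
  out <- episode_times |>
    group_by(.data$patient_id) |>
    group_modify(function(d, key) {
      cv <- cov_split[[key$patient_id]]
      for (v in vars) {
        d[[v]] <- if (is.null(cv)) NA_real_ else
          align_nearest(cv$time_years[!is.na(cv[[v]])],
                        cv[[v]][!is.na(cv[[v]])], d$time_years)
      }
      d
    }) |>
    ungroup()
  out
}

# nearest record in time; ties go to the earlier record
align_nearest <- function(rec_times, rec_values, times) {
  if (length(rec_times) == 0) return(rep(NA_real_, length(times)))
  ord <- order(rec_times)
  rec_times <- rec_times[ord]
  rec_values <- rec_values[ord]
  vapply(times, function(t) {
    d <- abs(rec_times - t)
    rec_values[which.min(d)]  # which.min returns the first (earlier) minimum
  }, numeric(1))
}

#' Final visit and prognostic group of each patient
#'
#' A patient's final visit is the earliest attended episode at which STDR was
#' detected in either eye (group `"STDR"`; later data are ignored), or the
#' last attended episode otherwise (group `"non-STDR"`).
#'
#' @param cohort a `retino_cohort`.
#' @return tibble with `patient_id`, `final_time`, `group`.
#' @export
define_final_visit <- function(cohort) {
  cohort$episodes |>
    filter(.data$attended) |>
    group_by(.data$patient_id) |>
    summarise(
      first_stdr = suppressWarnings(
        min(.data$time_years[.data$grade_right == "STDR" |
                               .data$grade_left == "STDR"])),
      last_att = max(.data$time_years), .groups = "drop") |>
    mutate(group = ifelse(is.finite(.data$first_stdr), "STDR", "non-STDR"),
           final_time = ifelse(is.finite(.data$first_stdr),
                               .data$first_stdr, .data$last_att)) |>
    select("patient_id", "final_time", "group")
}

#' Apply the cohort exclusion filters
#'
#' Removes, in order and counting each patient once at the first rule hit:
#' (1) patients with fewer than two attended screening episodes,
#' (2) patients with no clinical (covariate) record within 18 months before
#' their final visit, and (3) patients already showing STDR at their first
#' attended episode.
#'
#' @param cohort a `retino_cohort`.
#' @param window_years recency window for the clinical-visit rule (default
#'   1.5 years = 18 months).
#' @return The filtered cohort; the per-rule counts are attached as attribute
#'   `"exclusion_report"` and available via [exclusion_report()].
#' @export
apply_exclusions <- function(cohort, window_years = 1.5) {
  stopifnot(inherits(cohort, "retino_cohort"))
  att <- filter(cohort$episodes, .data$attended)
  n_att <- att |> count(.data$patient_id, name = "n_attended")
  all_ids <- cohort$demographics$patient_id

  r1 <- union(setdiff(all_ids, n_att$patient_id),
              n_att$patient_id[n_att$n_attended < 2])

  fv <- define_final_visit(cohort)
  has_recent <- cohort$covariates |>
    filter(if_any(all_of(COVARIATE_VARS), ~ !is.na(.x))) |>
    inner_join(fv, by = "patient_id") |>
    filter(.data$time_years > .data$final_time - window_years,
           .data$time_years <= .data$final_time + 1e-9) |>
    distinct(.data$patient_id)
  r2 <- setdiff(setdiff(fv$patient_id, has_recent$patient_id), r1)

  first_epi <- att |>
    group_by(.data$patient_id) |>
    slice_min(.data$time_years, n = 1, with_ties = FALSE) |>
    ungroup()
  r3 <- setdiff(first_epi$patient_id[first_epi$grade_right == "STDR" |
                                       first_epi$grade_left == "STDR"],
                c(r1, r2))

  report <- tibble(
    rule = c("single_visit", "no_recent_clinical_visit", "stdr_at_start"),
    n_excluded = c(length(r1), length(r2), length(r3)))
  drop <- c(r1, r2, r3)
  out <- new_cohort(filter(cohort$episodes, !.data$patient_id %in% drop),
                    filter(cohort$covariates, !.data$patient_id %in% drop),
                    filter(cohort$demographics, !.data$patient_id %in% drop),
                    truth = attr(cohort, "truth"))
  truth <- attr(out, "truth")
  if (!is.null(truth))
    attr(out, "truth") <- filter(truth, !.data$patient_id %in% drop)
  attr(out, "exclusion_report") <- report
  out
}

#' @rdname apply_exclusions
#' @param x a cohort returned by [apply_exclusions()].
#' @export
exclusion_report <- function(x) attr(x, "exclusion_report")

#' Write an exclusion report as JSON
#' @param report tibble from [exclusion_report()].
#' @param path output file.
#' @export
write_exclusion_report <- function(report, path) {
  jsonlite::write_json(setNames(as.list(report$n_excluded), report$rule), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Build labelled one-year prediction instances
#'
#' For every patient the observation window is truncated `horizon` years
#' before the final visit (so the one-year outcome is known), producing one
#' labelled instance: the per-eye binary grade history (R0 = 0, R1 = 1) over
#' all attended, covariate-complete episodes up to the prediction time, with
#' clinical covariates aligned to the nearest record.  The label is whether
#' the patient's final visit carries STDR, i.e. whether STDR is detected
#' within `(prediction_time, prediction_time + horizon]`.
#'
#' @param cohort a `retino_cohort`, normally after [apply_exclusions()].
#' @param horizon prediction horizon in years (default 1).
#' @param required_covariates covariates that must be available for an episode
#'   to enter the model history (complete-case handling; episodes missing one
#'   are dropped, patients left with an empty history are dropped with a
#'   warning).
#' @return A tibble of class `retino_instances`: one row per patient with the
#'   outcome label, prediction-visit metadata and a `history` list-column of
#'   per-visit tibbles (`time_years, y_right, y_left, duration_years,
#'   missed_prev`, aligned covariates).
#' @export
build_prediction_instances <- function(cohort, horizon = 1,
                                       required_covariates = COVARIATE_VARS) {
  stopifnot(inherits(cohort, "retino_cohort"))
  fv <- define_final_visit(cohort)
  epi_split <- split(cohort$episodes, cohort$episodes$patient_id)
  cov_split <- split(cohort$covariates, cohort$covariates$patient_id)
  dem <- cohort$demographics

  rows <- vector("list", nrow(fv))
  dropped <- character(0)
  for (i in seq_len(nrow(fv))) {
    pid <- fv$patient_id[i]
    pred_time <- fv$final_time[i] - horizon
    sched <- epi_split[[pid]]
    sched <- sched[order(sched$time_years), , drop = FALSE]
    in_window <- sched$time_years <= pred_time + 1e-9
    hist_sched <- sched[in_window, , drop = FALSE]
    att <- hist_sched[hist_sched$attended, , drop = FALSE]
    att <- att[att$grade_right != "STDR" & att$grade_left != "STDR", , drop = FALSE]
    if (nrow(att) == 0) {
      dropped <- c(dropped, pid)
      next
    }
    # per-visit missed-previous indicator from the scheduled sequence
    prev_att <- vapply(att$time_years, function(t) {
      before <- hist_sched$time_years < t - 1e-9
      if (!any(before)) TRUE else hist_sched$attended[max(which(before))]
    }, logical(1))

    cv <- cov_split[[pid]]
    aligned <- lapply(COVARIATE_VARS, function(v) {
      if (is.null(cv)) return(rep(NA_real_, nrow(att)))
      ok <- !is.na(cv[[v]])
      align_nearest(cv$time_years[ok], cv[[v]][ok], att$time_years)
    })
    names(aligned) <- COVARIATE_VARS
    d <- dem[dem$patient_id == pid, , drop = FALSE]
    hist_tbl <- tibble(
      time_years = att$time_years,
      y_right = as.integer(att$grade_right == "R1"),
      y_left = as.integer(att$grade_left == "R1"),
      duration_years = d$duration_first_visit_years + att$time_years,
      missed_prev = as.integer(!prev_att)) |>
      bind_cols(as_tibble(aligned))
    complete <- !Reduce(`|`, lapply(required_covariates,
                                    function(v) is.na(hist_tbl[[v]])))
    hist_tbl <- hist_tbl[complete, , drop = FALSE]
    if (nrow(hist_tbl) == 0) {
      dropped <- c(dropped, pid)
      next
    }
    # attendance of the scheduled episode immediately before the prediction visit
    last_time <- max(hist_tbl$time_years)
    before <- hist_sched$time_years < last_time - 1e-9
    missed_previous <- if (any(before)) !hist_sched$attended[max(which(before))] else FALSE

    last_row <- hist_tbl[nrow(hist_tbl), ]
    rows[[i]] <- tibble(
      patient_id = pid, group = fv$group[i],
      label = fv$group[i] == "STDR",
      prediction_time = pred_time,
      missed_previous = missed_previous,
      n_visits = nrow(hist_tbl),
      sex = d$sex, age_first_visit = d$age_first_visit,
      diabetes_type = d$diabetes_type,
      duration_first_visit_years = d$duration_first_visit_years,
      pred_grade = c("R0/R0", "R0/R1", "R1/R1")[last_row$y_right + last_row$y_left + 1L],
      history = list(hist_tbl))
  }
  if (length(dropped) > 0)
    warn(paste0(length(dropped), " patient(s) dropped: empty usable history ",
                "before the prediction time"))
  out <- bind_rows(rows)
  class(out) <- c("retino_instances", class(out))
  out
}
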