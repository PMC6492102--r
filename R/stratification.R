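# The two simple grade-based allocation rules used as comparators.
#
# Both rules look only at retinopathy grades on the scheduled episodes up to
# the prediction time and allocate each patient to biennial (low-risk) or
# annual (high-risk) screening.  Missingness is treated conservatively: a
# missed episode among those a rule needs sends the patient to the high-risk
# group.

#' Grade-based screening allocation rules
#'
#' * `two_episode`: low risk iff the last two scheduled annual episodes
#'   before/at the prediction time were both attended, no more than
#'   `gap_months` apart, and all four eye-grades were R0.  Patients observed
#'   for a single episode are allocated high risk (flagged
#'   `SINGLE_EPISODE`).
#' * `current_episode`: low risk iff the scheduled episode at the prediction
#'   time was attended and both eyes were R0.
#'
#' @param cohort a `retino_cohort` (the rules read the scheduled-episode
#'   table, including missed episodes).
#' @param instances `retino_instances` giving each patient's prediction time
#'   and outcome label.
#' @param rules which rules to apply.
#' @param gap_months maximum gap between the two episodes of the two-episode
#'   rule before the earlier one counts as missed (annual schedule plus the
#'   recall window).
#' @return tibble with `patient_id`, `rule`, `allocation`
#'   (`low_risk`/`high_risk`), `rationale`
#'   (`ALL_R0|R1_PRESENT|MISSED_EPISODE|SINGLE_EPISODE`) and `label`.
#' @export
stratify_cohort <- function(cohort, instances,
                            rules = c("two_episode", "current_episode"),
                            gap_months = 15) {
  stopifnot(inherits(cohort, "retino_cohort"))
  rules <- match.arg(rules, several.ok = TRUE)
  epi_split <- split(cohort$episodes, cohort$episodes$patient_id)
  gap_years <- gap_months / 12

  one_patient <- function(pid, pred_time) {
    sched <- epi_split[[pid]]
    sched <- sched[order(sched$time_years), , drop = FALSE]
    sched <- sched[sched$time_years <= pred_time + 1e-9, , drop = FALSE]
    out <- list()
    n <- nrow(sched)
    if ("two_episode" %in% rules) {
      out$two_episode <- if (n < 2) {
        c("high_risk", "SINGLE_EPISODE")
      } else {
        e2 <- sched[n, ]
        e1 <- sched[n - 1, ]
        if (!e1$attended || !e2$attended ||
            (e2$time_years - e1$time_years) > gap_years) {
          c("high_risk", "MISSED_EPISODE")
        } else if (all(c(e1$grade_right, e1$grade_left,
                         e2$grade_right, e2$grade_left) == "R0")) {
          c("low_risk", "ALL_R0")
        } else c("high_risk", "R1_PRESENT")
      }
    }
    if ("current_episode" %in% rules) {
      out$current_episode <- if (n < 1) {
        c("high_risk", "MISSED_EPISODE")
      } else {
        e <- sched[n, ]
        if (!e$attended) {
          c("high_risk", "MISSED_EPISODE")
        } else if (e$grade_right == "R0" && e$grade_left == "R0") {
          c("low_risk", "ALL_R0")
        } else c("high_risk", "R1_PRESENT")
      }
    }
    bind_rows(lapply(names(out), function(r)
      tibble(rule = r, allocation = out[[r]][1], rationale = out[[r]][2])))
  }

  res <- purrr::map2(instances$patient_id, instances$prediction_time,
                     one_patient)
  out <- bind_rows(res, .id = "row") |>
    mutate(patient_id = instances$patient_id[as.integer(.data$row)],
           label = instances$label[as.integer(.data$row)]) |>
    select("patient_id", "rule", "allocation", "rationale", "label")
  out
}

#' @rdname stratify_cohort
#' @param allocations output of [stratify_cohort()].
#' @param path output CSV file.
#' @export
write_allocations <- function(allocations, path) {
  readr::write_csv(allocations, path)
  invisible(path)
}
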