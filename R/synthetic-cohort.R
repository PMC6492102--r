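# Synthetic screening-cohort generator.
#
# Emulates an annual digital retinopathy screening programme: two prognostic
# groups (progress to STDR within a year of their final visit / never), each
# with its own bivariate logistic mixed model for the per-eye R0/R1 grade
# trajectory, group-dependent missed-appointment behaviour, and autocorrelated
# clinical covariate series.  Ground truth (group, mixture component, random
# intercept pair) is stored per patient so parameter recovery is testable.

#' Default generative truth for the non-progressor group
#'
#' Effects are the published association pattern for patients who do not
#' develop STDR: duration OR 2.25 per 5 years, type 1 diabetes OR 2.44,
#' time OR 0.97 per year, SBP OR 1.07 per 10 mmHg, HbA1c OR 1.04 per
#' 10 mmol/mol.  The mixture puts weight 0.362 on a very-low-risk intercept
#' component; intercept locations are chosen so the grade distribution at the
#' prediction visit roughly matches a screening population (about 8% R1/R1).
#'
#' @return a truth object (model spec + parameters) usable as
#'   `generator_config(truth_nonstdr = ...)`.
#' @export
default_truth_nonstdr <- function() {
  spec <- model_spec(c("duration", "type1", "time", "sbp", "hba1c"))
  new_truth(spec,
            beta = log(c(duration = 2.25, type1 = 2.44, time = 0.97,
                         sbp = 1.07, hba1c = 1.04)),
            weights = c(0.362, 0.638),
            means = rbind(c(-7.0, -7.0), c(-3.7, -3.7)),
            covs = rbind(c(1.5, 1.2, 1.5), c(1.5, 1.2, 1.5)))
}

#' Default generative truth for the STDR (progressor) group
#'
#' Duration OR 1.78 per 5 years, missed-previous-appointment OR 2.12, time
#' OR 1.60 per year, HbA1c null (kept in the model for completeness).  The
#' mixture puts weight 0.292 on a high-initial-risk component, so most
#' progressors show R1 in both eyes by the prediction visit.
#'
#' @return a truth object; see [default_truth_nonstdr()].
#' @export
default_truth_stdr <- function() {
  spec <- model_spec(c("duration", "missed_prev", "time", "hba1c"))
  new_truth(spec,
            beta = log(c(duration = 1.78, missed_prev = 2.12, time = 1.60,
                         hba1c = 1.0)),
            weights = c(0.708, 0.292),
            means = rbind(c(-1.6, -1.6), c(1.4, 1.4)),
            covs = rbind(c(1.2, 1.05, 1.2), c(1.2, 1.05, 1.2)))
}

new_truth <- function(spec, beta, weights, means, covs) {
  stopifnot(length(beta) == length(spec$covariates),
            abs(sum(weights) - 1) < 1e-9, all(weights >= 0),
            nrow(means) == 2, ncol(means) == 2, nrow(covs) == 2)
  for (k in 1:2) {
    S <- matrix(c(covs[k, 1], covs[k, 2], covs[k, 2], covs[k, 3]), 2)
    if (any(eigen(S, symmetric = TRUE, only.values = TRUE)$values <= 0))
      abort("truth covariance matrices must be positive definite")
  }
  structure(list(spec = spec, beta_right = unname(beta),
                 beta_left = unname(beta), weights = weights,
                 means = means, covs = covs),
            class = "retino_truth")
}

#' Default clinical covariate distributions
#'
#' Group-conditional locations and scales calibrated to a UK screening
#' population (all-patient mixtures reproduce age 59.5 (SD 13.3), 5.0% type 1
#' diabetes, HbA1c median 51 mmol/mol).  Skewed variables (diabetes duration,
#' HbA1c) are shifted log-normals fitted to the group medians and quartiles;
#' the remaining variables are Gaussian.  Visit-to-visit variation follows a
#' stationary AR(1) around the patient-level location.
#'
#' @return named list of distribution parameters; entries indexed 1 = non-STDR
#'   group, 2 = STDR group.
#' @export
default_covariate_distributions <- function() {
  list(
    female_prob = c(0.419, 0.349),
    type1_prob = c(0.046, 0.194),
    age_mean = c(59.65, 52.93), age_sd = c(13.27, 14.43), age_range = c(18, 95),
    # shifted log-normal c(shift, meanlog, sdlog), quartile-matched
    duration = rbind(c(-1.765, log(3.605), 0.8407),
                     c(-2.152, log(7.102), 0.7057)),
    hba1c = rbind(c(32.0, log(18.0), 0.6012),
                  c(31.88, log(34.12), 0.7109)),
    sbp_mean = c(131.47, 134.27), sbp_sd = c(14.06, 15.04),
    dbp_mean = c(75.16, 77.09), dbp_sd = c(9.15, 9.18),
    chol_mean = c(4.18, 4.25), chol_sd = c(1.01, 1.07),
    visit_sd = c(hba1c = 5, sbp = 7, dbp = 4.5, chol = 0.35),
    ar_rho = 0.7)
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the structure of a large annual screening cohort:
#' STDR prevalence 2.6%, annual visits with small timing jitter, follow-up
#' uniform between `followup_min` and `followup_max` years (minimum 2, so
#' every patient has at least two attended episodes spanning two years),
#' missed-appointment probability 4.3% for non-progressors versus 23.5% for
#' progressors, and the group-specific trajectory truths of
#' [default_truth_nonstdr()] / [default_truth_stdr()].
#'
#' @param n_patients number of patients.
#' @param prevalence_stdr probability a patient belongs to the STDR group;
#'   must lie strictly inside (0, 1).
#' @param visit_gap_years,visit_jitter_sd mean inter-visit gap and Gaussian
#'   timing jitter (years) applied to interior visits.
#' @param followup_min,followup_max follow-up range in years (min >= 2).
#' @param miss_prob_nonstdr,miss_prob_stdr per-visit non-attendance
#'   probability by group (first and final visits are always attended).
#' @param covariate_missing_prob probability that an individual clinical value
#'   is missing from a record (complete-case stress knob; default 0).
#' @param covariate_time_jitter_sd SD of the offset between clinical record
#'   times and screening times (years).
#' @param covariate_distributions see [default_covariate_distributions()].
#' @param truth_nonstdr,truth_stdr group trajectory truths.
#' @param seed integer master seed; patient `i` uses the derived substream
#'   `seed + i`, so enlarging the cohort leaves existing patients unchanged.
#' @return a `retino_generator_config` list.
#' @export
generator_config <- function(n_patients = 500, prevalence_stdr = 0.026,
                             visit_gap_years = 1, visit_jitter_sd = 0.08,
                             followup_min = 2, followup_max = 9,
                             miss_prob_nonstdr = 0.043, miss_prob_stdr = 0.235,
                             covariate_missing_prob = 0,
                             covariate_time_jitter_sd = 0.05,
                             covariate_distributions = default_covariate_distributions(),
                             truth_nonstdr = default_truth_nonstdr(),
                             truth_stdr = default_truth_stdr(),
                             seed = 1) {
  if (n_patients < 1) abort("n_patients must be at least 1")
  if (prevalence_stdr <= 0 || prevalence_stdr >= 1)
    abort("prevalence_stdr must lie strictly inside (0, 1): both prognostic groups are required")
  if (followup_min < 2) abort("followup_min must be >= 2 years")
  if (followup_max < followup_min) abort("followup_max must be >= followup_min")
  if (miss_prob_nonstdr < 0 || miss_prob_nonstdr >= 1 ||
      miss_prob_stdr < 0 || miss_prob_stdr >= 1)
    abort("miss probabilities must lie in [0, 1)")
  structure(as.list(environment()), class = "retino_generator_config")
}

group_index <- function(group) if (group == "STDR") 2L else 1L

# stationary AR(1) noise of length n
ar1_noise <- function(n, rho, sd) {
  e <- numeric(n)
  e[1] <- rnorm(1, 0, sd)
  if (n > 1)
    for (t in 2:n) e[t] <- rho * e[t - 1] + rnorm(1, 0, sd * sqrt(1 - rho^2))
  e
}

rtrunc_norm <- function(mean, sd, lo, hi) {
  for (i in 1:100) {
    x <- rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mean, lo), hi)
}

rshifted_lnorm <- function(n, par) pmax(0, par[1] + rlnorm(n, par[2], par[3]))

#' Sample demographics and longitudinal covariates for one patient
#'
#' Draws the demographic record and patient-level clinical locations from the
#' group-conditional distributions, then an AR(1) visit-level series at the
#' requested times.
#'
#' @param config a [generator_config()].
#' @param group `"non-STDR"` or `"STDR"`.
#' @param times visit times (years since first screen) at which longitudinal
#'   values are produced.
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @return list with `sex`, `age_first_visit`, `diabetes_type`,
#'   `duration_first_visit_years` and a `covariates` data frame (one row per
#'   time: `hba1c`, `sbp`, `dbp`, `chol`).
#' @export
sample_patient_covariates <- function(config, group = "non-STDR",
                                      times = 0:5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cd <- config$covariate_distributions
  g <- group_index(group)
  n <- length(times)
  sex <- if (runif(1) < cd$female_prob[g]) "female" else "male"
  age <- rtrunc_norm(cd$age_mean[g], cd$age_sd[g], cd$age_range[1], cd$age_range[2])
  type <- if (runif(1) < cd$type1_prob[g]) "type1" else "type2"
  duration0 <- rshifted_lnorm(1, cd$duration[g, ])

  vs <- cd$visit_sd
  rho <- cd$ar_rho
  psd <- function(total, visit) sqrt(max(total^2 - visit^2, (0.25 * total)^2))
  hba1c_loc <- rshifted_lnorm(1, cd$hba1c[g, ])
  sbp_loc <- rnorm(1, cd$sbp_mean[g], psd(cd$sbp_sd[g], vs["sbp"]))
  dbp_loc <- rnorm(1, cd$dbp_mean[g], psd(cd$dbp_sd[g], vs["dbp"]))
  chol_loc <- rnorm(1, cd$chol_mean[g], psd(cd$chol_sd[g], vs["chol"]))
  covs <- data.frame(
    time_years = times,
    hba1c = pmax(20, hba1c_loc + ar1_noise(n, rho, vs["hba1c"])),
    sbp = pmax(70, sbp_loc + ar1_noise(n, rho, vs["sbp"])),
    dbp = pmax(40, dbp_loc + ar1_noise(n, rho, vs["dbp"])),
    chol = pmax(1, chol_loc + ar1_noise(n, rho, vs["chol"])))
  list(sex = sex, age_first_visit = age, diabetes_type = type,
       duration_first_visit_years = duration0, covariates = covs)
}

#' Simulate a per-eye binary grade trajectory
#'
#' Draws the patient's mixture component and random-intercept pair, then, at
#' each visit, each eye's grade as Bernoulli on the logit scale: linear
#' predictor from the truth's fixed effects plus the eye-specific intercept.
#'
#' @param visits data frame with one row per attended visit and all columns
#'   the truth's model spec needs (`time_years`, `duration_years`,
#'   `missed_prev`, clinical covariates, `diabetes_type`, `sex`,
#'   `age_first_visit`).
#' @param truth a truth object (see [default_truth_nonstdr()]).
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @return list with integer vectors `y_right`, `y_left` (1 = R1), the
#'   sampled `component` and intercept pair `b`.
#' @export
simulate_grade_trajectory <- function(visits, truth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  comp <- if (runif(1) < truth$weights[2]) 2L else 1L
  S <- matrix(c(truth$covs[comp, 1], truth$covs[comp, 2],
                truth$covs[comp, 2], truth$covs[comp, 3]), 2)
  L <- chol(S)
  b <- drop(truth$means[comp, ] + t(L) %*% rnorm(2))
  X <- design_matrix(visits, truth$spec)
  pR <- plogis(drop(X %*% truth$beta_right) + b[1])
  pL <- plogis(drop(X %*% truth$beta_left) + b[2])
  list(y_right = as.integer(runif(nrow(X)) < pR),
       y_left = as.integer(runif(nrow(X)) < pL),
       component = comp, b = b)
}

#' Generate a synthetic screening cohort
#'
#' Group labels are drawn first with probability `prevalence_stdr`; each
#' patient then receives an annual visit schedule over their follow-up,
#' attendance flags (missed visits are emitted as `attended = 0` rows with
#' empty grades), clinical covariate records, and a per-eye grade trajectory
#' from the group's truth model.  STDR-group patients are assigned an STDR
#' grade (in one or both eyes) at their final visit; non-progressors never
#' carry STDR.
#'
#' @param config a [generator_config()].
#' @return a `retino_cohort` whose `"truth"` attribute records each patient's
#'   group, mixture component and random-intercept pair.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "retino_generator_config"))
  if (config$prevalence_stdr <= 0 || config$prevalence_stdr >= 1)
    abort("prevalence_stdr must lie strictly inside (0, 1)")
  generate_cohort_core(config)
}

generate_cohort_core <- function(config) {
  n <- config$n_patients
  epi_l <- vector("list", n)
  cov_l <- vector("list", n)
  dem_l <- vector("list", n)
  tru_l <- vector("list", n)
  # per-patient substreams: drawn sequentially from the master stream, so the
  # first k patients are identical whenever the master seed is shared, while
  # different master seeds give unrelated cohorts
  set.seed(config$seed)
  patient_seeds <- sample.int(2^31 - 2, n)
  for (i in seq_len(n)) {
    pid <- sprintf("P%05d", i)
    set.seed(patient_seeds[i])
    group <- if (runif(1) < config$prevalence_stdr) "STDR" else "non-STDR"
    g <- group_index(group)
    truth <- if (g == 2) config$truth_stdr else config$truth_nonstdr

    # annual schedule: integer visits over the follow-up, interior jitter
    fu <- runif(1, config$followup_min, config$followup_max)
    m <- floor(fu / config$visit_gap_years)
    times <- (0:m) * config$visit_gap_years
    if (m > 1) {
      interior <- 2:m
      times[interior] <- times[interior] + rnorm(length(interior), 0,
                                                 config$visit_jitter_sd)
      times <- sort(times)
    }
    miss_p <- if (g == 2) config$miss_prob_stdr else config$miss_prob_nonstdr
    attended <- c(TRUE, runif(m - 1) < 1 - miss_p, TRUE)[seq_along(times)]
    attended[length(attended)] <- TRUE

    pat <- sample_patient_covariates(config, group, times)
    missed_prev <- c(FALSE, !attended[-length(attended)])

    att_idx <- which(attended)
    visits <- pat$covariates[att_idx, , drop = FALSE]
    visits$missed_prev <- as.integer(missed_prev[att_idx])
    visits$duration_years <- pat$duration_first_visit_years + visits$time_years
    visits$diabetes_type <- pat$diabetes_type
    visits$sex <- pat$sex
    visits$age_first_visit <- pat$age_first_visit
    traj <- simulate_grade_trajectory(visits, truth)

    grade_r <- rep(NA_character_, length(times))
    grade_l <- rep(NA_character_, length(times))
    grade_r[att_idx] <- c("R0", "R1")[traj$y_right + 1L]
    grade_l[att_idx] <- c("R0", "R1")[traj$y_left + 1L]
    if (g == 2) {  # STDR detected at the final (always attended) visit
      eye <- runif(1)
      last <- length(times)
      if (eye < 0.5) {
        grade_r[last] <- "STDR"
        grade_l[last] <- "STDR"
      } else if (eye < 0.75) grade_r[last] <- "STDR" else grade_l[last] <- "STDR"
    }

    # clinical records: near-visit times with jitter, optional missingness
    rec_times <- pmax(0, times + rnorm(length(times), 0,
                                       config$covariate_time_jitter_sd))
    rec <- pat$covariates
    rec$time_years <- rec_times
    if (config$covariate_missing_prob > 0)
      for (v in COVARIATE_VARS)
        rec[[v]][runif(nrow(rec)) < config$covariate_missing_prob] <- NA_real_

    epi_l[[i]] <- data.frame(patient_id = pid, time_years = times,
                             grade_right = grade_r, grade_left = grade_l,
                             attended = attended)
    cov_l[[i]] <- cbind(data.frame(patient_id = pid), rec)
    dem_l[[i]] <- data.frame(patient_id = pid, sex = pat$sex,
                             age_first_visit = pat$age_first_visit,
                             diabetes_type = pat$diabetes_type,
                             duration_first_visit_years = pat$duration_first_visit_years)
    tru_l[[i]] <- data.frame(patient_id = pid, group = group,
                             component = traj$component,
                             b_right = traj$b[1], b_left = traj$b[2])
  }
  cov_all <- bind_rows(cov_l)[, c("patient_id", "time_years", COVARIATE_VARS)]
  new_cohort(bind_rows(epi_l), cov_all, bind_rows(dem_l),
             truth = as_tibble(bind_rows(tru_l)))
}

#' Generate a cohort for a single prognostic group
#'
#' Convenience wrapper used for parameter-recovery studies: every patient is
#' forced into `group`, everything else follows [generate_cohort()].  STDR
#' grades are still imposed at the final visit of STDR-group patients.
#'
#' @param n_patients number of patients.
#' @param group `"non-STDR"` or `"STDR"`.
#' @param config a [generator_config()]; its `n_patients` is overridden.
#' @return a `retino_cohort`.
#' @export
generate_group_cohort <- function(n_patients, group = "non-STDR",
                                  config = generator_config()) {
  stopifnot(group %in% c("non-STDR", "STDR"))
  config$n_patients <- n_patients
  # push the group draw to the boundary; everything else is unchanged
  config$prevalence_stdr <- if (group == "STDR") 1 else 0
  generate_cohort_core(config)
}

#' Write a synthetic cohort with manifest
#'
#' Runs [generate_cohort()] and writes the cohort CSVs, the truth JSON, the
#' generator configuration and a manifest with MD5 checksums, so a run is
#' fully reproducible from its output directory.
#'
#' @param config a [generator_config()].
#' @param dir output directory.
#' @return Invisibly, the manifest as a tibble.
#' @export
write_synthetic_cohort <- function(config, dir) {
  cohort <- generate_cohort(config)
  paths <- write_cohort(cohort, dir)
  cfg_path <- file.path(dir, "generator_config.json")
  cfg <- config
  cfg$truth_nonstdr <- truth_to_list(cfg$truth_nonstdr)
  cfg$truth_stdr <- truth_to_list(cfg$truth_stdr)
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  files <- c(paths, cfg_path)
  manifest <- tibble(file = basename(files),
                     md5 = unname(tools::md5sum(files)),
                     seed = config$seed)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

truth_to_list <- function(truth) {
  list(covariates = truth$spec$covariates, beta = truth$beta_right,
       weights = truth$weights, means = truth$means, covs = truth$covs)
}
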