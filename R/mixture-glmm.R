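# Bivariate binary GLMM with two-component Gaussian-mixture random
# intercepts, estimated by Polya-Gamma Gibbs sampling.
#
# For patient i, eye e (right/left) and visit j:
#   y_iej ~ Bernoulli(logit^-1(x_ij' beta_e + b_ie)),
#   (b_iR, b_iL) ~ w_1 N(mu_1, Sigma_1) + w_2 N(mu_2, Sigma_2).
# There is no fixed intercept column: the per-eye intercepts live in the
# mixture-component means, which keeps means and fixed effects identifiable.
# Components are relabelled post hoc by the sum of their mean intercepts
# (component 1 = lower initial risk), resolving label switching.

COVARIATE_REGISTRY <- tibble::tribble(
  ~term,          ~label,                                  ~unit,
  "duration",     "diabetes duration",                     "per 5 years",
  "time",         "time since first screening",            "per year",
  "missed_prev",  "missed previous appointment",           "yes vs no",
  "hba1c",        "HbA1c",                                 "per 10 mmol/mol",
  "sbp",          "systolic blood pressure",               "per 10 mmHg",
  "dbp",          "diastolic blood pressure",              "per 10 mmHg",
  "chol",         "total cholesterol",                     "per mmol/L",
  "type1",        "type 1 diabetes",                       "type 1 vs type 2",
  "sex_male",     "sex",                                   "male vs female",
  "age",          "age at first visit",                    "per 10 years")

#' Specify the fixed-effect structure of the grade-transition model
#'
#' Covariates are entered on clinically conventional scales so that one unit
#' of the coefficient is directly reportable as an odds ratio: diabetes
#' duration per 5 years, time since first screening per year, SBP/DBP per
#' 10 mmHg, HbA1c per 10 mmol/mol, age per 10 years; `type1`, `sex_male` and
#' `missed_prev` are indicators.
#'
#' @param covariates character vector drawn from `duration, time,
#'   missed_prev, hba1c, sbp, dbp, chol, type1, sex_male, age`.
#' @param share_beta if `TRUE` the two eyes share one coefficient vector;
#'   by default each eye has its own (the reported eye-specific odds ratios
#'   are expected to be similar, and sharing is available when that symmetry
#'   is imposed a priori).
#' @return a `retino_model_spec`.
#' @export
model_spec <- function(covariates, share_beta = FALSE) {
  unknown <- setdiff(covariates, COVARIATE_REGISTRY$term)
  if (length(unknown) > 0)
    abort(paste0("unknown covariate(s): ", paste(unknown, collapse = ", ")))
  structure(list(covariates = covariates, share_beta = share_beta,
                 n_components = 2L, link = "logit"),
            class = "retino_model_spec")
}

#' @export
print.retino_model_spec <- function(x, ...) {
  cat("<retino_model_spec> logit link, 2-component mixture intercepts\n",
      "  covariates: ", paste(x$covariates, collapse = ", "),
      if (x$share_beta) "  (coefficients shared across eyes)" else "", "\n",
      sep = "")
  invisible(x)
}

# per-visit design matrix on the registry scalings; df needs the per-visit
# columns plus the patient constants (diabetes_type, sex, age_first_visit)
design_matrix <- function(df, spec) {
  cols <- lapply(spec$covariates, function(term) {
    switch(term,
      duration = df$duration_years / 5,
      time = df$time_years,
      missed_prev = as.numeric(df$missed_prev),
      hba1c = df$hba1c / 10,
      sbp = df$sbp / 10,
      dbp = df$dbp / 10,
      chol = df$chol,
      type1 = as.numeric(df$diabetes_type == "type1"),
      sex_male = as.numeric(df$sex == "male"),
      age = df$age_first_visit / 10)
  })
  X <- do.call(cbind, c(cols, list(deparse.level = 0)))
  if (is.null(X)) X <- matrix(0, nrow(df), 0)
  colnames(X) <- spec$covariates
  X
}

# flatten instance histories into the sampler's inputs (rows grouped by patient)
build_design <- function(instances, spec) {
  hist_all <- instances |>
    select("patient_id", "diabetes_type", "sex", "age_first_visit", "history") |>
    tidyr::unnest("history")
  needed <- intersect(spec$covariates, c("hba1c", "sbp", "dbp", "chol"))
  for (v in needed)
    if (anyNA(hist_all[[v]]))
      abort(paste0("history episodes with missing ", v,
                   " cannot enter the model; rebuild instances with ",
                   "required_covariates including it"))
  list(X = design_matrix(hist_all, spec),
       y_right = as.numeric(hist_all$y_right),
       y_left = as.numeric(hist_all$y_left),
       pid0 = match(hist_all$patient_id, instances$patient_id) - 1L,
       n_pat = nrow(instances),
       patient_ids = instances$patient_id)
}

#' Grade-transition probability under the fitted model
#'
#' Inverse-logit of `x * beta + b`: the probability that an eye shows mild
#' NPDR/BDR (R1) at a visit with scaled covariate vector `x`, fixed effects
#' `beta` and patient random intercept `b`.
#'
#' @param x numeric vector (or matrix with one row per visit) of scaled
#'   covariates.
#' @param beta coefficient vector of matching length.
#' @param b random intercept (default 0).
#' @return probability in (0, 1).
#' @export
transition_probability <- function(x, beta, b = 0) {
  if (is.matrix(x)) {
    if (ncol(x) != length(beta)) abort("ncol(x) must equal length(beta)")
    return(plogis(drop(x %*% beta) + b))
  }
  if (length(x) != length(beta)) abort("length(x) must equal length(beta)")
  plogis(sum(x * beta) + b)
}

default_priors <- function() {
  list(beta_var = 100, mean_var = 100, iw_df = 4, iw_scale = 1,
       dirichlet_alpha = 1)
}

#' Fit the bivariate mixture GLMM by MCMC
#'
#' Gibbs sampler with Polya-Gamma latent-variable augmentation for the logit
#' link: all conditional updates are conjugate (Gaussian fixed effects and
#' random-intercept pairs, Dirichlet mixture weights, Gaussian component
#' means, inverse-Wishart component covariances), so no step-size tuning is
#' needed.  Fit one model per prognostic group on that group's instances.
#'
#' @param instances `retino_instances` for a single prognostic group.
#' @param spec a [model_spec()].
#' @param n_iter,burnin,thin chain length controls (defaults 10000 / 2000 /
#'   5); `chains` independent chains are run and pooled, with convergence
#'   monitored by split potential-scale-reduction (flagged above 1.1).
#' @param chains number of chains.
#' @param seed integer seed; chain seeds are derived from it, and identical
#'   seed + data reproduce the fit exactly.
#' @param priors prior hyperparameters, see `default_priors()`: fixed effects
#'   and component means N(0, 10^2), weights Dirichlet(1, 1), covariances
#'   inverse-Wishart(4, I).
#' @return a `mixture_glmm_fit`: pooled relabelled draws, chain metadata,
#'   split-Rhat diagnostics and penalized-expected-deviance components.
#' @export
fit_mixture_glmm <- function(instances, spec, n_iter = 10000, burnin = 2000,
                             thin = 5, chains = 2, seed = 1,
                             priors = default_priors()) {
  stopifnot(inherits(spec, "retino_model_spec"))
  des <- build_design(instances, spec)
  if (des$n_pat < 30)
    warn("fewer than 30 patients: posterior may be prior-dominated")
  y_all <- c(des$y_right, des$y_left)
  if (length(unique(des$y_right)) < 2 || length(unique(des$y_left)) < 2)
    abort(paste0("complete separation: an outcome level is absent ",
                 "(all grades identical in one eye); the model cannot be fitted"))
  p <- ncol(des$X)
  # initialise fixed effects at the pooled-eye GLM estimate (no random
  # effects) and centre the mixture means on the residual intercept, which
  # shortens the burn-in considerably on large cohorts
  if (p > 0) {
    Xg <- rbind(des$X, des$X)
    init_fit <- suppressWarnings(
      stats::glm.fit(cbind(1, Xg), y_all, family = stats::binomial()))
    beta_init <- init_fit$coefficients[-1]
    m0 <- init_fit$coefficients[1]
    beta_init[!is.finite(beta_init)] <- 0
    if (!is.finite(m0)) m0 <- qlogis(min(max(mean(y_all), 0.02), 0.98))
  } else {
    beta_init <- numeric(0)
    m0 <- qlogis(min(max(mean(y_all), 0.02), 0.98))
  }
  mu_init <- rbind(c(m0 - 1, m0 - 1), c(m0 + 1, m0 + 1))

  set.seed(seed)
  chain_seeds <- sample.int(2^31 - 2, chains)
  raw <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(chain_seeds[ch])
    res <- pg_mixture_gibbs_cpp(des$X, des$y_right, des$y_left, des$pid0,
                                des$n_pat, as.integer(n_iter),
                                as.integer(burnin), as.integer(thin),
                                priors$beta_var, priors$mean_var,
                                priors$iw_df, priors$iw_scale,
                                priors$dirichlet_alpha, spec$share_beta,
                                beta_init, mu_init)
    raw[[ch]] <- relabel_components(res)
  }

  rhat <- chain_diagnostics(raw, spec)
  draws <- list(
    beta_right = do.call(rbind, lapply(raw, `[[`, "beta_right")),
    beta_left = do.call(rbind, lapply(raw, `[[`, "beta_left")),
    weights = do.call(rbind, lapply(raw, `[[`, "weights")),
    means = do.call(rbind, lapply(raw, `[[`, "means")),
    covs = do.call(rbind, lapply(raw, `[[`, "covs")))
  colnames(draws$beta_right) <- colnames(draws$beta_left) <- spec$covariates
  dev_draws <- unlist(lapply(raw, `[[`, "deviance"))
  b_mean <- Reduce(`+`, lapply(raw, `[[`, "b_mean")) / chains
  bR <- colMeans(draws$beta_right)
  bL <- colMeans(draws$beta_left)
  dbar <- mean(dev_draws)
  dev_at_mean <- conditional_deviance_cpp(des$X, des$y_right, des$y_left,
                                          des$pid0, bR, bL, b_mean)
  p_opt <- dbar - dev_at_mean

  out <- list(draws = draws, n_draws = nrow(draws$weights), spec = spec,
              data = des, b_mean = b_mean,
              mcmc = list(n_iter = n_iter, burnin = burnin, thin = thin,
                          chains = chains, seed = seed,
                          chain_seeds = chain_seeds),
              priors = priors, rhat = rhat,
              deviance = list(dbar = dbar, dev_at_mean = dev_at_mean,
                              p_opt = p_opt, ped = dbar + p_opt))
  class(out) <- "mixture_glmm_fit"
  if (nrow(rhat) > 0 && any(rhat$rhat > 1.1, na.rm = TRUE))
    warn(paste0("possible non-convergence: split-Rhat above 1.1 for ",
                paste(rhat$parameter[rhat$rhat > 1.1], collapse = ", ")))
  out
}

# order components by the sum of their mean intercepts (low-risk first)
relabel_components <- function(res) {
  s1 <- res$means[, 1] + res$means[, 2]
  s2 <- res$means[, 3] + res$means[, 4]
  swap <- s1 > s2
  if (any(swap)) {
    res$weights[swap, ] <- res$weights[swap, 2:1, drop = FALSE]
    res$means[swap, ] <- res$means[swap, c(3, 4, 1, 2), drop = FALSE]
    res$covs[swap, ] <- res$covs[swap, c(4, 5, 6, 1, 2, 3), drop = FALSE]
  }
  res
}

# split potential-scale-reduction over chains for the fixed effects and the
# low-risk mixture weight
chain_diagnostics <- function(raw, spec) {
  p <- ncol(raw[[1]]$beta_right)
  params <- list()
  if (p > 0) {
    for (j in seq_len(p)) {
      params[[paste0("beta_right.", spec$covariates[j])]] <-
        lapply(raw, function(r) r$beta_right[, j])
      params[[paste0("beta_left.", spec$covariates[j])]] <-
        lapply(raw, function(r) r$beta_left[, j])
    }
  }
  params[["weight1"]] <- lapply(raw, function(r) r$weights[, 1])
  tibble(parameter = names(params),
         rhat = vapply(params, split_rhat, numeric(1)))
}

split_rhat <- function(chains_list) {
  halves <- unlist(lapply(chains_list, function(x) {
    n <- floor(length(x) / 2)
    list(x[seq_len(n)], x[seq_len(n) + n])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @export
print.mixture_glmm_fit <- function(x, ...) {
  cat("<mixture_glmm_fit> ", x$data$n_pat, " patients, ",
      length(x$data$y_right), " visit-pairs, ", x$n_draws,
      " retained draws (", x$mcmc$chains, " chain(s))\n", sep = "")
  cat("  covariates: ", paste(x$spec$covariates, collapse = ", "), "\n",
      "  mixture weights (posterior median): ",
      paste(sprintf("%.3f", apply(x$draws$weights, 2, median)), collapse = " / "),
      "\n  penalized expected deviance: ",
      sprintf("%.1f", x$deviance$ped), "\n", sep = "")
  invisible(x)
}

#' Posterior odds-ratio table
#'
#' One odds ratio per covariate and eye, on the registry's reporting scale
#' (e.g. duration per 5 years): posterior median of `exp(coefficient)` with a
#' 95% equal-tailed credible interval.
#'
#' @param fit a `mixture_glmm_fit`.
#' @param conf_level credible level (default 0.95).
#' @return tibble with `term`, `eye`, `or`, `conf.low`, `conf.high`, `unit`.
#' @export
posterior_odds_ratios <- function(fit, conf_level = 0.95) {
  stopifnot(inherits(fit, "mixture_glmm_fit"))
  if (fit$n_draws < 100)
    warn("fewer than 100 retained draws: intervals will be unstable")
  a <- (1 - conf_level) / 2
  one_eye <- function(mat, eye) {
    if (ncol(mat) == 0) return(NULL)
    ors <- exp(mat)
    tibble(term = colnames(mat), eye = eye,
           or = apply(ors, 2, median),
           conf.low = apply(ors, 2, quantile, probs = a),
           conf.high = apply(ors, 2, quantile, probs = 1 - a))
  }
  out <- bind_rows(one_eye(fit$draws$beta_right, "right"),
                   one_eye(fit$draws$beta_left, "left"))
  if (is.null(out) || nrow(out) == 0)
    return(tibble(term = character(), eye = character(), or = numeric(),
                  conf.low = numeric(), conf.high = numeric(),
                  unit = character()))
  left_join(out, COVARIATE_REGISTRY[, c("term", "unit")], by = "term")
}

#' @export
tidy.mixture_glmm_fit <- function(x, conf_level = 0.95, ...) {
  posterior_odds_ratios(x, conf_level = conf_level)
}

#' @export
glance.mixture_glmm_fit <- function(x, ...) {
  tibble(n_patients = x$data$n_pat, n_visit_pairs = length(x$data$y_right),
         n_draws = x$n_draws, chains = x$mcmc$chains,
         weight1 = median(x$draws$weights[, 1]),
         ped = x$deviance$ped, dbar = x$deviance$dbar,
         p_opt = x$deviance$p_opt,
         max_rhat = suppressWarnings(max(x$rhat$rhat, na.rm = TRUE)))
}

#' Penalized expected deviance of a fit
#'
#' Model-comparison criterion (lower is better): the posterior-expected
#' conditional deviance plus an optimism penalty equal to the effective number
#' of parameters, `p_opt = E[D] - D(posterior mean)`, i.e. `2 E[D] - D(mean)`.
#' This is the classic plug-in approximation to the penalized expected
#' deviance of hierarchical-model comparison; it is deterministic given the
#' retained draws.
#'
#' @param fit a `mixture_glmm_fit`.
#' @return scalar criterion value.
#' @export
penalized_expected_deviance <- function(fit) {
  stopifnot(inherits(fit, "mixture_glmm_fit"))
  fit$deviance$ped
}

#' Serialize a fitted model to a plain-text archive
#'
#' Writes the retained posterior draws as one CSV (columnar arrays, one
#' column per parameter) plus a JSON metadata file (model spec, chain
#' settings, priors, diagnostics, deviance summaries) and the posterior
#' mean random intercepts as a second CSV.  [read_fit()] restores an object
#' usable for scoring ([score_cohort()]) and reporting
#' ([posterior_odds_ratios()]); the training data themselves are not
#' archived, so deviance-based model comparison requires the original fit.
#'
#' @param fit a `mixture_glmm_fit`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "mixture_glmm_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- fit$draws
  p <- ncol(d$beta_right)
  nm <- function(prefix, cols) paste0(prefix, ".", cols)
  draws <- cbind(d$beta_right, d$beta_left, d$weights, d$means, d$covs)
  colnames(draws) <- c(
    if (p > 0) nm("beta_right", colnames(d$beta_right)),
    if (p > 0) nm("beta_left", colnames(d$beta_left)),
    paste0("weight", 1:2),
    c("mean1.right", "mean1.left", "mean2.right", "mean2.left"),
    c("cov1.rr", "cov1.rl", "cov1.ll", "cov2.rr", "cov2.rl", "cov2.ll"))
  p_draws <- file.path(dir, "draws.csv")
  readr::write_csv(as_tibble(draws), p_draws)
  p_b <- file.path(dir, "b_mean.csv")
  readr::write_csv(tibble(patient_id = fit$data$patient_ids,
                          b_right = fit$b_mean[, 1],
                          b_left = fit$b_mean[, 2]), p_b)
  p_meta <- file.path(dir, "metadata.json")
  jsonlite::write_json(
    list(covariates = fit$spec$covariates,
         share_beta = fit$spec$share_beta,
         mcmc = fit$mcmc, priors = fit$priors,
         n_patients = fit$data$n_pat, n_draws = fit$n_draws,
         rhat = as.list(setNames(fit$rhat$rhat, fit$rhat$parameter)),
         deviance = fit$deviance),
    p_meta, auto_unbox = TRUE, digits = NA)
  invisible(c(p_draws, p_b, p_meta))
}

#' @rdname write_fit
#' @param dir directory written by [write_fit()].
#' @export
read_fit <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  draws <- as.matrix(readr::read_csv(file.path(dir, "draws.csv"),
                                     show_col_types = FALSE))
  spec <- model_spec(as.character(meta$covariates %||% character(0)),
                     isTRUE(meta$share_beta))
  p <- length(spec$covariates)
  pick <- function(prefix) {
    cols <- grep(paste0("^", prefix, "\\."), colnames(draws))
    m <- draws[, cols, drop = FALSE]
    colnames(m) <- sub(paste0(prefix, "."), "", colnames(m), fixed = TRUE)
    m
  }
  b <- readr::read_csv(file.path(dir, "b_mean.csv"), show_col_types = FALSE)
  unnamed <- function(cols) {
    m <- draws[, cols, drop = FALSE]
    dimnames(m) <- NULL
    m
  }
  out <- list(
    draws = list(beta_right = pick("beta_right"), beta_left = pick("beta_left"),
                 weights = unnamed(c("weight1", "weight2")),
                 means = unnamed(c("mean1.right", "mean1.left",
                                   "mean2.right", "mean2.left")),
                 covs = unnamed(c("cov1.rr", "cov1.rl", "cov1.ll",
                                  "cov2.rr", "cov2.rl", "cov2.ll"))),
    n_draws = nrow(draws), spec = spec,
    data = list(n_pat = meta$n_patients, patient_ids = b$patient_id,
                y_right = numeric(0)),
    b_mean = cbind(b$b_right, b$b_left),
    mcmc = meta$mcmc, priors = meta$priors,
    rhat = tibble(parameter = names(meta$rhat),
                  rhat = unlist(meta$rhat)),
    deviance = meta$deviance)
  class(out) <- "mixture_glmm_fit"
  out
}

#' Greedy forward covariate selection by penalized expected deviance
#'
#' Starting from the forced set (always included, whatever the criterion —
#' the place for covariates retained on clinical grounds), repeatedly adds
#' the candidate giving the largest criterion decrease, stopping when no
#' candidate improves it.
#'
#' @param instances single-group `retino_instances`.
#' @param candidates covariates to consider.
#' @param forced covariates always included.
#' @param share_beta see [model_spec()].
#' @param n_iter,burnin,thin,chains MCMC settings for the (cheaper) selection
#'   fits.
#' @param seed seed shared by every candidate fit, making selection
#'   deterministic.
#' @return the selected [model_spec()]; the search trace is attached as
#'   attribute `"trace"`.
#' @export
forward_select <- function(instances, candidates, forced = character(),
                           share_beta = FALSE, n_iter = 2000, burnin = 500,
                           thin = 5, chains = 1, seed = 1) {
  if (length(candidates) == 0) abort("candidates must be non-empty")
  fit_ped <- function(covs) {
    f <- fit_mixture_glmm(instances, model_spec(covs, share_beta),
                          n_iter = n_iter, burnin = burnin, thin = thin,
                          chains = chains, seed = seed)
    penalized_expected_deviance(f)
  }
  current <- forced
  best <- fit_ped(current)
  trace <- tibble(step = 0L, added = NA_character_, ped = best)
  remaining <- setdiff(candidates, forced)
  step <- 0L
  while (length(remaining) > 0) {
    peds <- vapply(remaining, function(cand) fit_ped(c(current, cand)),
                   numeric(1))
    if (min(peds) >= best) break
    step <- step + 1L
    pick <- remaining[which.min(peds)]
    current <- c(current, pick)
    best <- min(peds)
    trace <- bind_rows(trace, tibble(step = step, added = pick, ped = best))
    remaining <- setdiff(remaining, pick)
  }
  out <- model_spec(current, share_beta)
  attr(out, "trace") <- trace
  out
}
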