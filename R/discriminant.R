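# Longitudinal discriminant analysis: score a patient's grade history under
# the fitted model of each prognostic group, weight the two marginal
# likelihoods by group prevalence, and report the probability of developing
# STDR within one year.

#' Pair the two fitted group models
#'
#' @param fit_stdr,fit_nonstdr `mixture_glmm_fit` objects for the STDR and
#'   non-STDR prognostic groups; they must share one model spec.
#' @param prevalence_stdr prior probability of the STDR group, normally the
#'   training-set group fraction (an external incidence value may be supplied
#'   instead).
#' @return a `retino_group_models`.
#' @export
group_models <- function(fit_stdr, fit_nonstdr, prevalence_stdr) {
  stopifnot(inherits(fit_stdr, "mixture_glmm_fit"),
            inherits(fit_nonstdr, "mixture_glmm_fit"))
  if (!identical(fit_stdr$spec$covariates, fit_nonstdr$spec$covariates))
    abort("the two group models must share one model spec")
  if (prevalence_stdr <= 0 || prevalence_stdr >= 1)
    abort("prevalence_stdr must lie strictly inside (0, 1)")
  structure(list(fit_stdr = fit_stdr, fit_nonstdr = fit_nonstdr,
                 prevalence_stdr = prevalence_stdr),
            class = "retino_group_models")
}

# one parameter set from a fit: a single retained draw, or the posterior
# median (plug-in variant)
glmm_params <- function(fit, draw = NULL) {
  d <- fit$draws
  if (is.null(draw)) {
    w1 <- median(d$weights[, 1])
    out <- list(beta_right = apply(d$beta_right, 2, median),
                beta_left = apply(d$beta_left, 2, median),
                weights = c(w1, 1 - w1),
                means = rbind(apply(d$means[, 1:2, drop = FALSE], 2, median),
                              apply(d$means[, 3:4, drop = FALSE], 2, median)),
                covs = rbind(apply(d$covs[, 1:3, drop = FALSE], 2, median),
                             apply(d$covs[, 4:6, drop = FALSE], 2, median)))
  } else {
    out <- list(beta_right = d$beta_right[draw, ],
                beta_left = d$beta_left[draw, ],
                weights = d$weights[draw, ],
                means = rbind(d$means[draw, 1:2], d$means[draw, 3:4]),
                covs = rbind(d$covs[draw, 1:3], d$covs[draw, 4:6]))
  }
  # guard elementwise summaries against indefinite covariances
  for (k in 1:2) {
    s <- out$covs[k, ]
    lim <- 0.99 * sqrt(s[1] * s[3])
    out$covs[k, 2] <- min(max(s[2], -lim), lim)
  }
  out
}

#' Marginal log-likelihood of grade histories
#'
#' For each patient, the random-intercept pair is integrated out of the
#' bivariate Bernoulli likelihood under the mixture-of-normals distribution:
#' `log sum_k w_k \int prod_visits prod_eyes Bern(y | logit^-1(x'beta_e +
#' b_e)) N(b; mu_k, Sigma_k) db`.  The two-dimensional integral is evaluated
#' by adaptive Gauss-Hermite quadrature centred on the per-component
#' conditional mode (default 20 nodes per dimension); components with a
#' numerically zero covariance are treated as point masses (the closed-form
#' Bernoulli product).  Patients whose quadrature value is non-finite fall
#' back to plain Monte-Carlo integration with a warning.
#'
#' @param instances `retino_instances` (an empty history gives log-likelihood
#'   0).
#' @param params a parameter set: a truth object or the list produced by an
#'   MCMC draw (fields `beta_right`, `beta_left`, `weights`, `means`,
#'   `covs`).
#' @param spec the [model_spec()] the parameters belong to.
#' @param nodes Gauss-Hermite nodes per dimension.
#' @param mc_draws Monte-Carlo draws for the fallback path.
#' @return tibble with `patient_id` and `loglik`.
#' @export
marginal_log_likelihood <- function(instances, params, spec, nodes = 20,
                                    mc_draws = 1e5) {
  des <- build_design(instances, spec)
  gh <- pracma::gaussHermite(nodes)
  ll <- as.numeric(
    marginal_loglik_cpp(des$X, des$y_right, des$y_left, des$pid0,
                        des$n_pat, params$beta_right, params$beta_left,
                        params$weights, params$means, params$covs,
                        gh$x, gh$w))
  bad <- !is.finite(ll)
  if (any(bad)) {
    warn(paste0(sum(bad), " patient(s) fell back to Monte-Carlo integration"))
    for (i in which(bad)) {
      rows <- des$pid0 == (i - 1L)
      ll[i] <- mc_marginal_loglik(des$X[rows, , drop = FALSE],
                                  des$y_right[rows], des$y_left[rows],
                                  params, n = mc_draws)
    }
  }
  tibble(patient_id = des$patient_ids, loglik = ll)
}

# plain Monte-Carlo marginal likelihood (fallback path)
mc_marginal_loglik <- function(X, yR, yL, params, n = 1e5) {
  etaR <- drop(X %*% params$beta_right)
  etaL <- drop(X %*% params$beta_left)
  comp_ll <- function(k) {
    S <- matrix(c(params$covs[k, 1], params$covs[k, 2],
                  params$covs[k, 2], params$covs[k, 3]), 2)
    b <- matrix(rnorm(2 * n), n, 2) %*% chol(S)
    b <- sweep(b, 2, params$means[k, ], `+`)
    ll <- numeric(n)
    for (j in seq_along(etaR)) {
      eR <- etaR[j] + b[, 1]
      eL <- etaL[j] + b[, 2]
      ll <- ll + yR[j] * eR - log1p(exp(pmin(eR, 700))) +
        yL[j] * eL - log1p(exp(pmin(eL, 700)))
    }
    m <- max(ll)
    m + log(mean(exp(ll - m)))
  }
  lks <- vapply(1:2, comp_ll, numeric(1))
  m <- max(lks + log(params$weights))
  m + log(sum(exp(lks + log(params$weights) - m)))
}

#' Posterior probability of the STDR group
#'
#' Bayes' allocation with the group prevalence as prior:
#' `pi exp(ll_stdr) / (pi exp(ll_stdr) + (1 - pi) exp(ll_nonstdr))`,
#' computed on the log scale so extreme log-likelihoods never underflow to
#' NaN.
#'
#' @param ll_stdr,ll_nonstdr (vectors of) marginal log-likelihoods under each
#'   group model.
#' @param prevalence prior STDR-group probability, in (0, 1).
#' @return probability vector in \[0, 1\].
#' @export
group_posterior <- function(ll_stdr, ll_nonstdr, prevalence) {
  if (prevalence <= 0 || prevalence >= 1)
    abort("prevalence must lie strictly inside (0, 1)")
  if (any(!is.finite(ll_stdr) & !is.finite(ll_nonstdr)))
    abort("unscorable patient: both log-likelihoods are non-finite")
  lo <- log(prevalence) + ll_stdr
  ln <- log1p(-prevalence) + ll_nonstdr
  1 / (1 + exp(ln - lo))
}

#' Score a cohort with the longitudinal discriminant
#'
#' Computes each patient's marginal history likelihood under the STDR and
#' non-STDR group models and combines them via [group_posterior()].  With
#' `method = "average"` the likelihood is averaged over a seeded subset of
#' retained posterior draws (default 50 per group); `method = "plugin"` uses
#' the posterior-median parameters only.
#'
#' @param instances `retino_instances` to score.
#' @param pair a [group_models()].
#' @param draws posterior draws per group for the averaged variant.
#' @param nodes Gauss-Hermite nodes per dimension.
#' @param seed seed of the draw-selection subsample (scoring is deterministic
#'   given fit and seed).
#' @param method `"average"` (integrate over posterior draws) or `"plugin"`.
#' @return a `retino_scores` tibble: `patient_id`, `prob_stdr`, `ll_stdr`,
#'   `ll_nonstdr`, `n_visits_used`, `flag`, plus the label and subgrouping
#'   columns carried over from the instances.
#' @export
score_cohort <- function(instances, pair, draws = 50, nodes = 20, seed = 1,
                         method = c("average", "plugin")) {
  stopifnot(inherits(pair, "retino_group_models"))
  method <- match.arg(method)
  spec <- pair$fit_stdr$spec

  group_ll <- function(fit, sub_seed) {
    if (method == "plugin")
      return(marginal_log_likelihood(instances, glmm_params(fit), spec,
                                     nodes = nodes)$loglik)
    set.seed(sub_seed)
    idx <- sort(sample.int(fit$n_draws, min(draws, fit$n_draws)))
    mat <- vapply(idx, function(d)
      marginal_log_likelihood(instances, glmm_params(fit, d), spec,
                              nodes = nodes)$loglik,
      numeric(nrow(instances)))
    mat <- matrix(mat, nrow = nrow(instances))
    # average the likelihood (not its log) over draws
    apply(mat, 1, function(v) {
      m <- max(v)
      m + log(mean(exp(v - m)))
    })
  }
  ll_s <- group_ll(pair$fit_stdr, seed)
  ll_n <- group_ll(pair$fit_nonstdr, seed + 1L)
  flag <- !is.finite(ll_s) & !is.finite(ll_n)
  prob <- rep(NA_real_, length(ll_s))
  prob[!flag] <- group_posterior(ll_s[!flag], ll_n[!flag],
                                 pair$prevalence_stdr)
  if (any(flag))
    warn(paste0(sum(flag), " unscorable patient(s) flagged and excluded"))
  out <- tibble(patient_id = instances$patient_id,
                prob_stdr = prob, ll_stdr = ll_s, ll_nonstdr = ll_n,
                n_visits_used = instances$n_visits, flag = flag,
                label = instances$label,
                diabetes_type = instances$diabetes_type,
                pred_grade = instances$pred_grade)
  class(out) <- c("retino_scores", class(out))
  out
}

#' Classify risk scores at a threshold
#'
#' Adds the predicted label: STDR if and only if the probability strictly
#' exceeds the threshold.
#'
#' @param scores a `retino_scores` tibble (or any data frame with a
#'   `prob_stdr` column).
#' @param threshold classification threshold in \[0, 1\], normally from
#'   [select_threshold()].
#' @return `scores` with a logical `pred_stdr` column.
#' @export
classify <- function(scores, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  scores$pred_stdr <- scores$prob_stdr > threshold
  scores
}

#' Export risk scores as CSV
#' @param scores a `retino_scores` tibble.
#' @param path output file.
#' @export
write_scores <- function(scores, path) {
  readr::write_csv(scores, path)
  invisible(path)
}
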