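test_that("transition probability is the inverse-logit of the linear predictor", {
  expect_equal(transition_probability(c(0, 0), c(1, -1), b = 0), 0.5)
  # a 5-year increase in duration multiplies the odds by exp(beta):
  # the design scales duration per 5 years, so beta = log(2.25) reproduces
  # the canonical duration odds ratio
  spec <- model_spec("duration")
  d1 <- retinorisk:::design_matrix(
    tibble::tibble(duration_years = 7), spec)
  d0 <- retinorisk:::design_matrix(
    tibble::tibble(duration_years = 2), spec)
  beta <- log(2.25)
  odds <- function(p) p / (1 - p)
  p1 <- transition_probability(d1[1, ], beta, b = -2)
  p0 <- transition_probability(d0[1, ], beta, b = -2)
  expect_equal(odds(p1) / odds(p0), 2.25, tolerance = 1e-12)
  # monotone in the random intercept
  ps <- vapply(c(-10, -2, 0, 3, 20), function(b)
    transition_probability(c(0.5, 0.5), c(1, 1), b), numeric(1))
  expect_true(all(diff(ps) > 0))
  expect_lt(ps[1], 1e-3)
  expect_error(transition_probability(c(1, 2, 3), c(1, 2)), "length")
})

test_that("design matrix applies the registry scalings", {
  df <- tibble::tibble(duration_years = 10, time_years = 3, missed_prev = 1L,
                       hba1c = 60, sbp = 130, dbp = 80, chol = 4.5,
                       diabetes_type = "type1", sex = "male",
                       age_first_visit = 70)
  X <- retinorisk:::design_matrix(df, model_spec(
    c("duration", "time", "missed_prev", "hba1c", "sbp", "dbp", "chol",
      "type1", "sex_male", "age")))
  expect_equal(unname(X[1, ]), c(2, 3, 1, 6, 13, 8, 4.5, 1, 1, 7))
  expect_error(model_spec("bmi"), "unknown covariate")
})

test_that("the sampler is seed-deterministic and every draw respects the invariants", {
  inst <- tiny_group_instances(n = 120, seed = 5)
  spec <- model_spec("duration")
  f1 <- fit_mixture_glmm(inst, spec, n_iter = 600, burnin = 200, thin = 2,
                         chains = 2, seed = 99)
  f2 <- fit_mixture_glmm(inst, spec, n_iter = 600, burnin = 200, thin = 2,
                         chains = 2, seed = 99)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$deviance, f2$deviance)

  w <- f1$draws$weights
  expect_true(all(abs(rowSums(w) - 1) < 1e-12))
  expect_true(all(w >= 0))
  cv <- f1$draws$covs
  dets <- cv[, 1] * cv[, 3] - cv[, 2]^2
  dets2 <- cv[, 4] * cv[, 6] - cv[, 5]^2
  expect_true(all(cv[, c(1, 3, 4, 6)] > 0))
  expect_true(all(dets > 0 & dets2 > 0))
  # relabelling orders components by mean-intercept sum (low risk first)
  expect_true(all(f1$draws$means[, 1] + f1$draws$means[, 2] <=
                    f1$draws$means[, 3] + f1$draws$means[, 4]))
})

test_that("a balanced covariate-free outcome centres the mixture near zero", {
  truth <- retinorisk:::new_truth(
    model_spec("duration"), beta = 0, weights = c(0.5, 0.5),
    means = rbind(c(0, 0), c(0, 0)),
    covs = rbind(c(1e-4, 0, 1e-4), c(1e-4, 0, 1e-4)))
  inst <- tiny_group_instances(n = 300, seed = 8, truth = truth)
  fit <- fit_mixture_glmm(inst, model_spec(character(0)), n_iter = 1500,
                          burnin = 500, thin = 2, chains = 1, seed = 12)
  # the implied marginal intercept (weight-averaged mixture mean) is near 0
  d <- fit$draws
  mix_mean <- d$weights[, 1] * (d$means[, 1] + d$means[, 2]) / 2 +
    d$weights[, 2] * (d$means[, 3] + d$means[, 4]) / 2
  expect_lt(abs(median(mix_mean)), 0.1)
})

test_that("complete separation is refused", {
  inst <- tiny_group_instances(n = 40, seed = 3)
  inst$history <- lapply(inst$history, function(h) {
    h$y_right <- 0L
    h$y_left <- 0L
    h
  })
  expect_error(
    fit_mixture_glmm(inst, model_spec("duration"), n_iter = 200,
                     burnin = 100, chains = 1, seed = 1),
    "separation")
})

test_that("odds-ratio tables summarise the posterior on the reporting scale", {
  fit <- list(draws = list(
    beta_right = matrix(0, 200, 1, dimnames = list(NULL, "duration")),
    beta_left = matrix(log(2), 200, 1, dimnames = list(NULL, "duration")),
    weights = matrix(0.5, 200, 2), means = matrix(0, 200, 4),
    covs = matrix(c(1, 0, 1, 1, 0, 1), 200, 6, byrow = TRUE)),
    n_draws = 200)
  class(fit) <- "mixture_glmm_fit"
  tab <- posterior_odds_ratios(fit)
  r <- tab[tab$eye == "right", ]
  expect_equal(unname(r$or), 1)
  expect_equal(unname(c(r$conf.low, r$conf.high)), c(1, 1))
  l <- tab[tab$eye == "left", ]
  expect_equal(unname(l$or), 2)
  expect_equal(tab$unit, rep("per 5 years", 2))
})

test_that("a fit round-trips through its text archive", {
  inst <- tiny_group_instances(n = 80, seed = 14)
  fit <- suppressWarnings(fit_mixture_glmm(
    inst, model_spec("duration"), n_iter = 400, burnin = 150, thin = 2,
    chains = 1, seed = 15))
  dir <- withr::local_tempdir()
  write_fit(fit, dir)
  back <- read_fit(dir)
  expect_equal(back$draws$beta_right, fit$draws$beta_right)
  expect_equal(back$draws$covs, fit$draws$covs)
  expect_equal(back$n_draws, fit$n_draws)
  expect_equal(back$spec$covariates, fit$spec$covariates)
  expect_equal(posterior_odds_ratios(back), posterior_odds_ratios(fit))
  # a restored fit can still score a cohort
  pair <- group_models(fit, back, 0.1)
  sc <- score_cohort(inst[1:5, ], pair, draws = 5, nodes = 8, seed = 16)
  expect_true(all(is.finite(sc$prob_stdr)))
})

test_that("penalized expected deviance prefers the generating model", {
  spec_true <- model_spec("duration")
  spec_null <- NULL  # intercept-only comparison uses an empty forced set
  wins <- 0L
  noise_gap <- numeric(20)
  for (r in 1:20) {
    inst <- tiny_group_instances(n = 100, seed = 1000 + r)
    # a pure-noise covariate: permuted SBP carries no signal
    inst$history <- lapply(inst$history, function(h) {
      h$sbp <- h$sbp[sample.int(nrow(h))]
      h
    })
    f_true <- fit_mixture_glmm(inst, spec_true, n_iter = 500, burnin = 200,
                               thin = 2, chains = 1, seed = 2000 + r)
    f_null <- fit_mixture_glmm(inst, model_spec(character(0)), n_iter = 500,
                               burnin = 200, thin = 2, chains = 1,
                               seed = 2000 + r)
    f_noise <- fit_mixture_glmm(inst, model_spec(c("duration", "sbp")),
                                n_iter = 500, burnin = 200, thin = 2,
                                chains = 1, seed = 2000 + r)
    if (penalized_expected_deviance(f_true) <=
          penalized_expected_deviance(f_null)) wins <- wins + 1L
    noise_gap[r] <- penalized_expected_deviance(f_noise) -
      penalized_expected_deviance(f_true)
  }
  expect_gte(wins, 18)
  # the complexity penalty stops a pure-noise covariate from helping
  expect_gt(mean(noise_gap), 0)
})

test_that("forward selection keeps forced covariates and finds the true signal", {
  for (r in 1:4) {
    inst <- tiny_group_instances(n = 120, seed = 3000 + r,
                                 truth = tiny_truth(or_duration = 4))
    sel <- forward_select(inst, candidates = c("duration", "sbp", "chol"),
                          forced = "hba1c", n_iter = 400, burnin = 150,
                          thin = 2, seed = 4000 + r)
    expect_true("hba1c" %in% sel$covariates)
    if (r == 1) expect_s3_class(attr(sel, "trace"), "tbl_df")
    expect_true("duration" %in% sel$covariates)
  }
})

test_that("credible intervals cover the generating effects", {
  spec <- model_spec(c("duration", "time"), share_beta = TRUE)
  truth <- retinorisk:::new_truth(
    model_spec(c("duration", "time")), beta = log(c(2.25, 0.97)),
    weights = c(0.4, 0.6), means = rbind(c(-3.5, -3.5), c(-1.5, -1.5)),
    covs = rbind(c(1, 0.7, 1), c(1, 0.7, 1)))
  covered <- 0L
  for (r in 1:2) {
    cfg <- generator_config(n_patients = 500, followup_min = 6,
                            followup_max = 6, truth_nonstdr = truth,
                            seed = 5000 + r)
    inst <- suppressWarnings(build_prediction_instances(
      apply_exclusions(generate_group_cohort(500, "non-STDR", cfg))))
    fit <- fit_mixture_glmm(inst, spec, n_iter = 2500, burnin = 1000,
                            thin = 3, chains = 1, seed = 6000 + r)
    tab <- posterior_odds_ratios(fit)
    dur <- tab[tab$term == "duration" & tab$eye == "right", ]
    if (dur$conf.low <= 2.25 && 2.25 <= dur$conf.high) covered <- covered + 1L
    expect_gt(dur$or, 1.6)
    expect_lt(dur$or, 3.1)
  }
  expect_gte(covered, 1L)
})
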