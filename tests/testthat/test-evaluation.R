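# brute-force pairwise concordance with half credit for ties
concordance <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}

test_that("the empirical AUC equals pairwise concordance, exactly", {
  sc <- c(0.9, 0.8, 0.3, 0.1)
  y <- c(TRUE, FALSE, TRUE, FALSE)
  d <- tibble::tibble(prob_stdr = sc, label = y)
  roc <- roc_and_auc(d)
  expect_equal(roc$auc, concordance(sc, y))

  # perfectly separated scores
  d2 <- tibble::tibble(prob_stdr = c(0.8, 0.9, 0.1, 0.2),
                       label = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(roc_and_auc(d2)$auc, 1)

  # random cohorts with heavy ties: exact agreement, and the curve is a
  # valid monotone ROC
  set.seed(14)
  for (r in 1:5) {
    n <- sample(50:400, 1)
    sc <- round(runif(n), 2)
    y <- runif(n) < 0.3
    if (sum(y) == 0 || sum(!y) == 0) next
    d <- tibble::tibble(prob_stdr = sc, label = y)
    roc <- roc_and_auc(d)
    expect_equal(roc$auc, concordance(sc, y))
    expect_true(all(diff(roc$curve$sensitivity) <= 1e-12))
    expect_true(all(diff(roc$curve$specificity) >= -1e-12))
    if (requireNamespace("pROC", quietly = TRUE))
      expect_equal(roc$auc,
                   as.numeric(pROC::auc(pROC::roc(
                     y, sc, quiet = TRUE, direction = "<",
                     levels = c(FALSE, TRUE)))))
  }

  # permuted labels give a chance-level AUC
  set.seed(15)
  n <- 10000
  sc <- runif(n)
  y <- sample(rep(c(TRUE, FALSE), c(300, n - 300)))
  auc <- roc_and_auc(tibble::tibble(prob_stdr = sc, label = y))$auc
  se <- sqrt((n + 1) / (12 * 300 * (n - 300)))  # Mann-Whitney null SE
  expect_lt(abs(auc - 0.5), 3 * se)

  expect_error(roc_and_auc(tibble::tibble(prob_stdr = sc[1:5],
                                          label = rep(TRUE, 5))),
               "both outcome classes")
})

test_that("threshold selection picks the point nearest the top-left corner", {
  # a curve containing the perfect point returns it
  d <- tibble::tibble(prob_stdr = c(0.9, 0.8, 0.1, 0.2),
                      label = c(TRUE, TRUE, FALSE, FALSE))
  roc <- roc_and_auc(d)
  thr <- select_threshold(roc)
  cv <- roc$curve
  expect_equal(cv$sensitivity[cv$threshold == thr], 1)
  expect_equal(cv$specificity[cv$threshold == thr], 1)

  # three-point toy curve: brute-force distance minimisation agrees
  d2 <- tibble::tibble(prob_stdr = c(0.9, 0.6, 0.6, 0.2, 0.1),
                       label = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  roc2 <- roc_and_auc(d2)
  dist <- sqrt((1 - roc2$curve$sensitivity)^2 +
                 (1 - roc2$curve$specificity)^2)
  expect_equal(select_threshold(roc2),
               min(roc2$curve$threshold[dist == min(dist)]))

  # symmetric scores: two equal distances, the lower threshold wins
  d3 <- tibble::tibble(prob_stdr = c(0.7, 0.4, 0.6, 0.3),
                       label = c(TRUE, TRUE, FALSE, FALSE))
  roc3 <- roc_and_auc(d3)
  dist3 <- sqrt((1 - roc3$curve$sensitivity)^2 +
                  (1 - roc3$curve$specificity)^2)
  ties <- roc3$curve$threshold[dist3 <= min(dist3) + 1e-12]
  expect_gte(length(ties), 2)
  expect_equal(select_threshold(roc3), min(ties))
})

test_that("confusion metrics and the PCC identity agree", {
  d <- tibble::tibble(
    pred_stdr = c(rep(TRUE, 3), rep(FALSE, 1), rep(FALSE, 4), rep(TRUE, 2)),
    label = c(rep(TRUE, 4), rep(FALSE, 6)))
  m <- confusion_metrics(d)
  expect_equal(m$sensitivity, 75)
  expect_equal(round(m$specificity, 1), 66.7)
  expect_equal(m$pcc, 70)

  perfect <- tibble::tibble(pred_stdr = c(TRUE, FALSE),
                            label = c(TRUE, FALSE))
  expect_equal(unlist(confusion_metrics(perfect)[, 1:3]),
               c(sensitivity = 100, specificity = 100, pcc = 100))

  # PCC always equals the group-size-weighted average of sens and spec
  set.seed(8)
  for (r in 1:10) {
    n <- 200
    d <- tibble::tibble(pred_stdr = runif(n) < 0.4, label = runif(n) < 0.3)
    if (length(unique(d$label)) < 2) next
    m <- confusion_metrics(d)
    expect_equal(m$pcc,
                 pcc_from_rates(m$sensitivity, m$specificity, m$n_pos,
                                m$n_neg))
  }
  expect_equal(pcc_from_rates(62.5, 62.5, 17, 983), 62.5)
})

test_that("PPV arithmetic matches a large simulated confusion table and is monotone", {
  expect_equal(ppv(1, 1, 0.3), 1)
  set.seed(9)
  n <- 1e6
  prev <- 0.025
  sens <- 0.854
  spec <- 0.840
  y <- runif(n) < prev
  pred <- ifelse(y, runif(n) < sens, runif(n) > spec)
  emp <- sum(pred & y) / sum(pred)
  se <- sqrt(emp * (1 - emp) / sum(pred))
  expect_lt(abs(ppv(sens, spec, prev) - emp), 3 * se)

  # increasing in prevalence and specificity
  prevs <- seq(0.01, 0.5, by = 0.01)
  expect_true(all(diff(vapply(prevs, function(p) ppv(0.85, 0.84, p),
                              numeric(1))) > 0))
  specs <- seq(0.5, 0.99, by = 0.01)
  expect_true(all(diff(vapply(specs, function(s) ppv(0.85, s, 0.025),
                              numeric(1))) > 0))
})

test_that("screening reduction is half the low-risk fraction", {
  expect_equal(screening_reduction(0.78), 0.39)
  expect_equal(screening_reduction(0), 0)
  # policy identity: episodes under the policy = n_high + n_low / 2
  n_low <- 700; n_high <- 300
  reduction <- screening_reduction(n_low / (n_low + n_high))
  expect_equal((n_low + n_high) * (1 - reduction), n_high + n_low / 2)
})

test_that("cross-validation stratifies 70/30, is seed-reproducible, and guards small groups", {
  inst <- small_mixed_instances()
  spec <- model_spec("duration", share_beta = TRUE)
  cv <- suppressWarnings(cross_validate(
    inst, spec, n_repeats = 2, n_iter = 400, burnin = 150, thin = 2,
    draws = 8, nodes = 8, seed = 33))
  expect_equal(nrow(cv$repeats), 2)
  # split proportions: per-group training fraction 70% (+- one patient)
  n_s <- sum(inst$label); n_n <- sum(!inst$label)
  expect_equal(cv$repeats$n_pos + cv$repeats$n_neg,
               rep(n_s - round(0.7 * n_s) + n_n - round(0.7 * n_n), 2))
  cv2 <- suppressWarnings(cross_validate(
    inst, spec, n_repeats = 2, n_iter = 400, burnin = 150, thin = 2,
    draws = 8, nodes = 8, seed = 33))
  expect_identical(cv$repeats, cv2$repeats)
  expect_setequal(cv$summary$metric, c("auc", "sensitivity", "specificity",
                                       "pcc"))
  expect_error(cross_validate(inst[1:15, ], spec), "at least 10")
})

test_that("subgroup evaluation matches global metrics on the identity partition", {
  set.seed(41)
  n <- 300
  sc <- tibble::tibble(
    patient_id = as.character(1:n),
    prob_stdr = runif(n),
    label = runif(n) < plogis(3 * runif(n) - 2),
    diabetes_type = sample(c("type1", "type2"), n, TRUE),
    everyone = "all")
  sub <- subgroup_evaluate(sc, 0.5, subgroup = "everyone")
  glob <- confusion_metrics(classify(sc, 0.5))
  expect_equal(sub$sensitivity, glob$sensitivity)
  expect_equal(sub$auc, roc_and_auc(sc)$auc)

  # two-subgroup case agrees with per-subgroup exhaustive concordance
  by_type <- subgroup_evaluate(sc, 0.5)
  for (g in by_type$subgroup) {
    d <- sc[sc$diabetes_type == g, ]
    expect_equal(by_type$auc[by_type$subgroup == g],
                 concordance(d$prob_stdr, d$label))
  }

  # single-class subgroup is skipped with a warning
  sc2 <- sc
  sc2$label[sc2$diabetes_type == "type1"] <- FALSE
  expect_warning(out <- subgroup_evaluate(sc2, 0.5), "skipped")
  expect_false("type1" %in% out$subgroup)
})
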