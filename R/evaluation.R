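# ROC analysis, threshold selection, repeated stratified cross-validation,
# classification metrics and screening-policy arithmetic.

#' Empirical ROC curve and AUC
#'
#' Sweeps every distinct score as a classification threshold (predicted STDR
#' iff score strictly greater), recording sensitivity and specificity.  The
#' AUC is the trapezoidal area, which for this empirical curve equals the
#' Mann-Whitney concordance probability with half credit for ties.
#'
#' @param data data frame of scored patients.
#' @param score,truth tidy-selected columns holding the risk score and the
#'   true outcome (defaults match [score_cohort()] output).  Rows with a
#'   missing score are dropped.
#' @return a `retino_roc`: list with the `curve` tibble (`threshold`,
#'   `sensitivity`, `specificity`), `auc`, `n_pos`, `n_neg`.
#' @export
roc_and_auc <- function(data, score = "prob_stdr", truth = "label") {
  s <- data[[score]]
  y <- as.logical(data[[truth]])
  keep <- !is.na(s) & !is.na(y)
  s <- s[keep]
  y <- y[keep]
  n_pos <- sum(y)
  n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0)
    abort("both outcome classes must be present to build a ROC curve")
  thr <- c(-Inf, sort(unique(s)))
  sens <- vapply(thr, function(t) mean(s[y] > t), numeric(1))
  spec <- vapply(thr, function(t) mean(s[!y] <= t), numeric(1))
  # rank (Mann-Whitney) form of the trapezoidal AUC, ties at half credit
  r <- rank(s)
  auc <- (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  structure(list(curve = tibble(threshold = thr, sensitivity = sens,
                                specificity = spec),
                 auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "retino_roc")
}

#' @export
print.retino_roc <- function(x, ...) {
  cat("<retino_roc> AUC ", sprintf("%.3f", x$auc), " (", x$n_pos, " pos / ",
      x$n_neg, " neg, ", nrow(x$curve), " thresholds)\n", sep = "")
  invisible(x)
}

#' Select the operating threshold nearest the top-left ROC corner
#'
#' Minimises the Euclidean distance `sqrt((1 - sens)^2 + (1 - spec)^2)` to
#' the ideal point; ties are broken toward the lower threshold (higher
#' sensitivity).
#'
#' @param roc a `retino_roc`.
#' @return the selected threshold.
#' @export
select_threshold <- function(roc) {
  stopifnot(inherits(roc, "retino_roc"))
  cv <- roc$curve
  d <- sqrt((1 - cv$sensitivity)^2 + (1 - cv$specificity)^2)
  cand <- which(d <= min(d) + 1e-12)
  min(cv$threshold[cand])
}

#' Classification metrics from predicted and true labels
#'
#' @param data data frame with predictions and truth.
#' @param predicted,truth column names of the predicted and true (logical)
#'   STDR labels.
#' @return one-row tibble: `sensitivity`, `specificity`, `pcc` (percent),
#'   counts `n_pos`, `n_neg`, `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_metrics <- function(data, predicted = "pred_stdr", truth = "label") {
  p <- as.logical(data[[predicted]])
  y <- as.logical(data[[truth]])
  keep <- !is.na(p) & !is.na(y)
  p <- p[keep]
  y <- y[keep]
  tp <- sum(p & y); fn <- sum(!p & y)
  tn <- sum(!p & !y); fp <- sum(p & !y)
  tibble(sensitivity = 100 * tp / (tp + fn),
         specificity = 100 * tn / (tn + fp),
         pcc = 100 * (tp + tn) / length(p),
         n_pos = tp + fn, n_neg = tn + fp, tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Probability of correct classification from published rates
#'
#' The prevalence-weighted average of sensitivity and specificity:
#' `(sens * n_pos + spec * n_neg) / (n_pos + n_neg)`.
#'
#' @param sens,spec percentages in \[0, 100\].
#' @param n_pos,n_neg group sizes.
#' @return PCC percentage (full precision; round for display).
#' @export
pcc_from_rates <- function(sens, spec, n_pos, n_neg) {
  stopifnot(sens >= 0, sens <= 100, spec >= 0, spec <= 100,
            n_pos > 0, n_neg > 0)
  (sens * n_pos + spec * n_neg) / (n_pos + n_neg)
}

#' Positive predictive value from sensitivity, specificity and prevalence
#'
#' @param sens,spec,prevalence proportions in (0, 1\].
#' @return PPV as a proportion.
#' @export
ppv <- function(sens, spec, prevalence) {
  stopifnot(sens > 0, sens <= 1, spec > 0, spec <= 1,
            prevalence > 0, prevalence <= 1)
  den <- sens * prevalence + (1 - spec) * (1 - prevalence)
  if (any(den == 0)) abort("undefined PPV: no patient tests positive")
  sens * prevalence / den
}

#' Screening-episode reduction from a low-risk fraction
#'
#' Low-risk patients move from annual to biennial screening and so attend
#' half their episodes; the steady-state reduction in total episodes is half
#' the low-risk fraction.
#'
#' @param low_risk_fraction proportion allocated to biennial screening.
#' @return reduction as a proportion.
#' @export
screening_reduction <- function(low_risk_fraction) {
  stopifnot(low_risk_fraction >= 0, low_risk_fraction <= 1)
  low_risk_fraction / 2
}

#' Repeated stratified cross-validation of the discriminant pipeline
#'
#' For each repeat: a stratified split keeps `train_frac` of each prognostic
#' group for training; both group models are fitted on the training
#' instances; the threshold is selected on the training ROC (nearest the
#' top-left corner) and frozen; the held-out patients are scored and
#' sensitivity, specificity, PCC and AUC recorded.  Metrics are averaged
#' over repeats with 95% percentile intervals.
#'
#' @param instances labelled `retino_instances` (both groups, each with at
#'   least 10 patients).
#' @param spec a [model_spec()].
#' @param n_repeats number of random splits (the headline protocol uses
#'   100).
#' @param train_frac training fraction per group.
#' @param n_iter,burnin,thin,chains MCMC settings per fold fit.
#' @param draws,nodes scoring settings, see [score_cohort()].
#' @param seed master seed; all per-repeat seeds derive from it.
#' @return a `retino_cv`: list with per-repeat `repeats` tibble, `summary`
#'   tibble (mean and percentile 95% CI per metric) and the configuration.
#' @export
cross_validate <- function(instances, spec, n_repeats = 100,
                           train_frac = 0.7, n_iter = 3000, burnin = 1000,
                           thin = 5, chains = 1, draws = 25, nodes = 12,
                           seed = 1) {
  n_s <- sum(instances$label)
  n_n <- sum(!instances$label)
  if (n_s < 10 || n_n < 10)
    abort("each prognostic group needs at least 10 patients to stratify")
  set.seed(seed)
  rep_seeds <- sample.int(2^31 - 2, n_repeats)
  rows <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    set.seed(rep_seeds[r])
    idx_s <- which(instances$label)
    idx_n <- which(!instances$label)
    tr <- c(sample(idx_s, round(train_frac * n_s)),
            sample(idx_n, round(train_frac * n_n)))
    train <- instances[tr, ]
    test <- instances[-tr, ]
    prev <- mean(train$label)
    fit_s <- fit_mixture_glmm(train[train$label, ], spec, n_iter = n_iter,
                              burnin = burnin, thin = thin, chains = chains,
                              seed = rep_seeds[r] %% 100000L + 1L)
    fit_n <- fit_mixture_glmm(train[!train$label, ], spec, n_iter = n_iter,
                              burnin = burnin, thin = thin, chains = chains,
                              seed = rep_seeds[r] %% 100000L + 2L)
    pair <- group_models(fit_s, fit_n, prev)
    sc_tr <- score_cohort(train, pair, draws = draws, nodes = nodes,
                          seed = rep_seeds[r] %% 100000L + 3L)
    thr <- select_threshold(roc_and_auc(sc_tr))
    sc_te <- score_cohort(test, pair, draws = draws, nodes = nodes,
                          seed = rep_seeds[r] %% 100000L + 4L)
    roc_te <- roc_and_auc(sc_te)
    met <- confusion_metrics(classify(sc_te, thr))
    rows[[r]] <- bind_cols(tibble(repeat_id = r, threshold = thr,
                                  auc = roc_te$auc), met)
  }
  repeats <- bind_rows(rows)
  summarise_metric <- function(v, name) {
    tibble(metric = name, mean = mean(v),
           conf.low = unname(quantile(v, 0.025)),
           conf.high = unname(quantile(v, 0.975)))
  }
  summary <- bind_rows(summarise_metric(repeats$auc, "auc"),
                       summarise_metric(repeats$sensitivity, "sensitivity"),
                       summarise_metric(repeats$specificity, "specificity"),
                       summarise_metric(repeats$pcc, "pcc"))
  structure(list(repeats = repeats, summary = summary,
                 config = list(n_repeats = n_repeats, train_frac = train_frac,
                               n_iter = n_iter, burnin = burnin, thin = thin,
                               chains = chains, draws = draws, nodes = nodes,
                               seed = seed)),
            class = "retino_cv")
}

#' @export
print.retino_cv <- function(x, ...) {
  cat("<retino_cv> ", x$config$n_repeats, " stratified ",
      round(100 * x$config$train_frac), "/",
      round(100 * (1 - x$config$train_frac)), " splits\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.retino_cv <- function(x, ...) x$summary

#' @export
glance.retino_cv <- function(x, ...) {
  tibble(n_repeats = x$config$n_repeats,
         auc = x$summary$mean[x$summary$metric == "auc"],
         sensitivity = x$summary$mean[x$summary$metric == "sensitivity"],
         specificity = x$summary$mean[x$summary$metric == "specificity"],
         pcc = x$summary$mean[x$summary$metric == "pcc"])
}

#' Per-subgroup classification metrics at a global threshold
#'
#' Sensitivity/specificity/PCC are computed within each subgroup at the
#' globally selected threshold; the AUC is the subgroup-specific ROC area.
#' Subgroups with a single outcome class are skipped with a warning.
#'
#' @param scores a `retino_scores` tibble.
#' @param threshold global classification threshold.
#' @param subgroup name of the column to stratify on (default
#'   `"diabetes_type"`).
#' @return tibble with one row per usable subgroup.
#' @export
subgroup_evaluate <- function(scores, threshold, subgroup = "diabetes_type") {
  groups <- split(classify(scores, threshold), scores[[subgroup]])
  rows <- lapply(names(groups), function(g) {
    d <- groups[[g]]
    if (length(unique(d$label[!is.na(d$prob_stdr)])) < 2) {
      warn(paste0("subgroup '", g, "' skipped: single outcome class"))
      return(NULL)
    }
    bind_cols(tibble(subgroup = g, auc = roc_and_auc(d)$auc),
              confusion_metrics(d))
  })
  bind_rows(rows)
}

#' Compare the discriminant model with the stratification rules
#'
#' Juxtaposes the multivariate model (at the supplied threshold) and each
#' allocation rule on sensitivity, specificity, PCC, empirical PPV and the
#' steady-state screening-episode reduction implied by the low-risk
#' fraction.
#'
#' @param scores a `retino_scores` tibble.
#' @param allocations output of [stratify_cohort()] for the same patients.
#' @param threshold model classification threshold.
#' @return tibble with one row per method.
#' @export
compare_methods <- function(scores, allocations, threshold) {
  model <- classify(scores, threshold)
  model_row <- bind_cols(tibble(method = "multivariate_model"),
                         confusion_metrics(model)) |>
    mutate(low_risk_fraction = mean(!model$pred_stdr, na.rm = TRUE))
  rule_rows <- allocations |>
    mutate(pred_stdr = .data$allocation == "high_risk") |>
    group_by(.data$rule) |>
    group_modify(function(d, key)
      bind_cols(confusion_metrics(d),
                tibble(low_risk_fraction = mean(d$allocation == "low_risk")))) |>
    ungroup() |>
    rename(method = "rule")
  out <- bind_rows(model_row, rule_rows) |>
    mutate(prevalence = .data$n_pos / (.data$n_pos + .data$n_neg),
           ppv = 100 * ppv(pmax(.data$sensitivity, 1e-9) / 100,
                           pmin(.data$specificity / 100, 1 - 1e-12),
                           .data$prevalence),
           screening_reduction = 100 * screening_reduction(.data$low_risk_fraction))
  out
}
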