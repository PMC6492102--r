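---
title: "Longitudinal discriminant prediction of sight-threatening diabetic retinopathy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal discriminant prediction of sight-threatening diabetic retinopathy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The prediction problem

Diabetic eye screening programmes photograph both eyes of every person with
diabetes, typically once a year, and grade each eye as R0 (no retinopathy),
R1 (mild non-proliferative / background retinopathy) or STDR
(sight-threatening retinopathy: moderate/severe pre-proliferative or
proliferative disease and/or maculopathy — the referral-triggering
endpoint).  Because the annual incidence of STDR is low (2–3%), risk-based
screening — biennial intervals for low-risk patients, annual for the rest —
could release a large fraction of screening capacity, provided the
risk model is accurate enough.

`retinorisk` implements a longitudinal discriminant approach to this
problem.  Rather than entering the retinopathy grade as one more predictor
in a regression, it models the whole per-eye grade *trajectory* separately
in two prognostic groups — patients who go on to develop STDR within a year
of their final visit and patients who do not — and classifies a new patient
by which group's fitted trajectory model their own history is statistically
closer to.  The package also implements the two simple grade-based
stratification rules used in screening policy (see below), so the two
philosophies can be compared on equal terms.

## The within-group trajectory model

Within a prognostic group, the grade of eye $e \in \{R, L\}$ of patient $i$
at visit $j$ is a binary outcome $y_{iej}$ (0 = R0, 1 = R1; STDR terminates
follow-up and never appears inside a modelling history).  The model is a
bivariate logistic mixed model,

$$\mathrm{logit}\, P(y_{iej} = 1) = x_{ij}^\top \beta_e + b_{ie},$$

with a patient-specific intercept *pair* $(b_{iR}, b_{iL})$ drawn from a
two-component bivariate Gaussian mixture

$$ (b_{iR}, b_{iL}) \sim w_1 N(\mu_1, \Sigma_1) + w_2 N(\mu_2, \Sigma_2). $$

The mixture serves two purposes: the covariance matrices carry the
correlation between the two eyes of one patient (and, through the shared
intercept, the correlation between repeated visits), and the two components
capture latent risk subgroups — empirically, a low-initial-risk and a
high-initial-risk class of patients in each prognostic group.

Two identifiability choices matter:

* **No fixed intercept.**  The design matrix contains no intercept column;
  the per-eye intercepts live entirely in the component means $\mu_k$.  A
  free fixed intercept would be confounded with a common shift of both
  component means.
* **Label switching** is resolved deterministically after sampling by
  ordering the components on the sum of their mean intercepts, so component
  1 is always the lower-initial-risk class.

Covariates enter on conventional reporting scales, so each coefficient
exponentiates directly to a familiar odds ratio: diabetes duration per 5
years, time since first screening per year, SBP/DBP per 10 mmHg, HbA1c per
10 mmol/mol, age per 10 years, plus indicators for type 1 diabetes, male
sex, and a missed previous appointment.  Each eye has its own coefficient
vector by default; `share_beta = TRUE` imposes the (empirically reasonable)
symmetry of one coefficient vector for both eyes, and is what the packaged
recovery studies use, since a single odds ratio per risk factor is the
quantity of scientific interest.

## Estimation: Polya-Gamma Gibbs sampling

The posterior is sampled by a Gibbs sampler with Polya-Gamma latent-variable
augmentation of the logit link.  Given the auxiliary variables, every
conditional update is conjugate — Gaussian for fixed effects and intercept
pairs, Dirichlet for the weights, Gaussian for the component means,
inverse-Wishart for the component covariances — so the sampler has no
step-size tuning at all.  The PG(1, z) variables are drawn with the exact
alternating-series rejection sampler, and all randomness flows through R's
RNG, so a seed fully determines a fit.

One refinement is essential rather than cosmetic: the fixed effects are
drawn from their conditional with the random-intercept pairs *integrated
out* (the augmented model is jointly Gaussian in $(\beta, b)$, so this
marginal is available in closed form; $\beta$ and $b$ are thereby updated as
one block).  Effects identified mainly by between-patient variation —
diabetes duration above all, whose within-patient increment is collinear
with the time covariate — mix extremely slowly under the naive sequential
update, because the flexible intercept distribution can absorb them for long
stretches of the chain.  With the marginal update, chains initialised from a
simple pooled GLM converge within a few hundred iterations, and the
potential-scale-reduction diagnostics (computed per fixed effect and
mixture weight, flagged above 1.1) are routinely below 1.1 at the default
chain settings.

Priors (all overridable): fixed effects and component means $N(0, 10^2)$,
weights Dirichlet(1, 1), covariances inverse-Wishart with 4 degrees of
freedom and identity scale.  Chain defaults: 10 000 iterations, 2 000
burn-in, thinning 5, two chains.  An outcome level absent from the data in
either eye (complete separation) aborts with an explicit error.

### Model comparison

Candidate covariate sets are compared by a penalized expected deviance:
the posterior-expected conditional deviance $\bar D$ plus an optimism
penalty equal to the effective parameter count
$p_{\mathrm{opt}} = \bar D - D(\hat\theta)$, where $D(\hat\theta)$ is the
deviance at the posterior mean of the fixed and random effects — i.e. the
criterion is $2\bar D - D(\hat\theta)$.  This plug-in form is an
approximation to the cross-validatory penalized expected deviance; it is
cheap, deterministic given the retained draws, and ranks models correctly in
the packaged selection simulations (the generating model beats the null in
at least 18/20 replicates, and a pure-noise covariate does not lower the
criterion on average).  `forward_select()` adds candidates greedily under
this criterion; a `forced` set is always retained regardless of the
criterion, which is where clinically mandated covariates such as HbA1c
belong.

## The discriminant

For a new patient with history $y$, each group model yields a marginal
likelihood with the intercept pair integrated out:

$$ L_g(y) = \sum_k w_k \int \prod_{j,e}
   \mathrm{Bern}\!\left(y_{ej} \mid \mathrm{logit}^{-1}(x_j^\top \beta_e + b_e)\right)
   N(b; \mu_k, \Sigma_k)\, db, $$

and the predicted one-year STDR probability is the prevalence-weighted
posterior
$\pi L_{\mathrm{STDR}} / (\pi L_{\mathrm{STDR}} + (1-\pi) L_{\mathrm{non}})$,
computed on the log scale throughout so that even likelihood ratios of
$e^{\pm 1000}$ never produce NaN.  The prevalence $\pi$ defaults to the
training-set group fraction and can be replaced by an external incidence.

Numerics of the 2-D integral: adaptive Gauss–Hermite quadrature, centred per
patient and mixture component on the conditional mode of $b$ (found by
Newton iterations on a concave objective) and scaled by the Hessian there;
20 nodes per dimension by default.  Components with numerically zero
covariance are evaluated in closed form as point masses.  Against a
$10^6$-draw Monte-Carlo oracle on random small histories the quadrature
agrees to well under $10^{-3}$ in log-likelihood (and to $10^{-10}$ against
closed forms); a Monte-Carlo fallback guards the (never observed in
practice) case of a non-finite quadrature value.

Parameter uncertainty is handled by averaging the *likelihood* (not its
log) over a seeded subsample of retained posterior draws, 50 per group by
default; a plug-in posterior-median variant is available
(`method = "plugin"`).  The methodological literature defines several
prediction variants (marginal, conditional, random-effects); the marginal
variant with draw averaging is the default here because it propagates both
integration over $b$ and posterior uncertainty without further
approximation.

Classification is strict: predicted STDR iff the probability *exceeds* the
threshold.  The threshold is chosen on the training ROC as the point
nearest the top-left corner (minimising $\sqrt{(1-\mathrm{sens})^2 +
(1-\mathrm{spec})^2}$, ties toward the lower threshold, i.e. higher
sensitivity), and is then frozen before the test set is touched — selecting it on test data would bias accuracy upward.

## The comparator rules and policy arithmetic

* **Two-episode rule**: a patient is low-risk (biennial recall) iff the
  last two scheduled annual episodes were both attended, at most 15 months
  apart (annual schedule plus the recall window), and all four eye-grades
  were R0.  A missed episode or a single observed episode sends the patient
  to annual screening — the conservative treatment of missingness that such
  a rule requires in practice.
* **Current-episode rule**: low-risk iff both eyes are R0 at the
  prediction-time episode (missed episode → high risk).

The two-episode low-risk set is provably contained in the current-episode
one; this nesting is asserted on every synthetic cohort in the test suite.
Policy metrics are the standard ones — sensitivity, specificity, the
prevalence-weighted probability of correct classification, the positive
predictive value implied by sensitivity/specificity/incidence — plus the
steady-state screening reduction: low-risk patients attend half their
annual episodes, so the reduction is half the low-risk fraction.

Evaluation uses repeated stratified cross-validation: 70% of each
prognostic group trains both models, the remaining 30% is scored, and the
splits are redrawn 100 times (configurable) with metrics averaged and 95%
intervals taken as the 2.5/97.5 percentiles across repeats — a pragmatic
choice where no single interval method is canonical.
Subgroup evaluation (by diabetes type) applies the globally selected
threshold within each subgroup and computes subgroup-specific ROC areas.

## The synthetic cohort generator

No screening dataset of this kind is publicly deposited, so the package
carries a generator that emulates the *statistical structure* the analysis
assumes, with every default chosen once, calibrated to the reported
characteristics of large UK screening populations:

* 2.6% STDR-group prevalence; annual visits with small timing jitter;
  follow-up uniform on 2–9 years (median ≈ 5.5 y); missed-visit
  probability 4.3% (non-progressors) versus 23.5% (progressors), with first
  and final visits always attended.
* Demographics and clinical series from group-conditional distributions
  whose mixture reproduces the familiar all-patient summaries of such populations (age 59.5,
  SD 13.3; 5.0% type 1 diabetes; HbA1c median 51 mmol/mol).  Skewed
  variables (duration, HbA1c) are shifted log-normals matched to the
  group medians and quartiles the generator targets; the duration fit requires a negative
  shift, so draws are clamped at zero (≈20% of non-progressor mass, all
  below the 25th percentile, leaving the matched quartiles intact).
  Visit-level values follow a stationary AR(1) (ρ = 0.7) around the
  patient-level location.
* Trajectory truths: the fixed effects are set to the odds ratios reported in the
  clinical literature for these risk factors (non-progressors: duration 2.25/5 y, type 1 diabetes 2.44, time
  0.97/y, SBP 1.07/10 mmHg, HbA1c 1.04/10 mmol/mol; progressors: duration
  1.78/5 y, missed appointment 2.12, time 1.60/y, HbA1c null).  Mixture
  weights default to a low-risk 36.2% component among non-progressors and
  a high-risk 29.2% component among progressors; the component *means*
  have no literature values to anchor to, so they were
  calibrated once so that the grade distribution at the prediction visit
  approximates the target pattern (non-progressors ≈ 74/20/6%
  R0R0/R0R1/R1R1 against a target of 79/13/8; progressors ≈ 14/23/64%
  against 12/14/74) and were not revisited.  Discordant-eye episodes are
  somewhat over-represented relative to the target because grades are
  conditionally independent Bernoulli draws given the intercept pair;
  matching those targets exactly would require per-visit shared shocks
  the model itself does not posit.
* STDR onset is not itself modelled generatively; the generator imposes an
  STDR grade (both eyes with probability 1/2, otherwise one eye) at the
  final visit of progressor-group patients.  Everything downstream treats
  that as data.

Each patient is generated from an own substream whose seed is drawn
sequentially from the master stream, so enlarging a cohort preserves the
patients already generated, while different master seeds give unrelated
cohorts.  Ground truth — group, mixture component, intercept pair — is
stored per patient, which is what makes parameter-recovery testing
possible.

What passing tests on these cohorts shows is therefore internal validity:
the estimation machinery recovers the parameters of data generated from the
model the analysis assumes, at realistic sizes, rates and effect strengths.
It deliberately cannot show robustness to what real screening data add on
top — grading error, informative missingness, treatment effects, competing
mortality, secular drift — none of which the generator emulates.

## Problem sizes and numerical choices

The packaged recovery studies fit 3 000-patient non-progressor and
1 500-patient progressor cohorts with six annual visits, 10 000 iterations
and 2 000 burn-in — a few minutes per fit with the marginal-update sampler.
The test suite uses deliberately smaller cohorts and shorter chains per
case (hundreds of patients, 400–4 000 iterations) chosen so that each check
still has clear statistical power; stochastic assertions use fixed seeds
and 3-standard-error bands throughout.  Degenerate inputs are handled
explicitly: empty histories carry log-likelihood 0, zero-covariance
components become point masses, equal-distance covariate records resolve to
the earlier one, ROC threshold ties resolve to the higher-sensitivity side,
and an intercept-only model spec (zero covariates) is a valid fit target so
that forward selection can start from nothing.

## Known limitations

* The conditional-independence Bernoulli structure understates
  same-visit eye agreement (see above).
* The penalized-expected-deviance implementation is the plug-in
  approximation, not the full cross-validatory definition.
* One prediction time per patient; dynamic re-scoring as new visits accrue
  is out of scope.
* K = 2 mixture components and random intercepts only (no random slopes),
  matching the scientific model the package implements.
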