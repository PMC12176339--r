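---
title: "Methods: counterfactual impact evaluation of technical notes on preliminary injunctions"
author: "judimpact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: counterfactual impact evaluation of technical notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Health litigation against Brazil's public health system (SUS) is largely
decided at the preliminary-injunction stage: a judge grants or denies the
claimed medication, treatment or procedure early in the lawsuit, usually
under time pressure and information asymmetry. Judicial
health-technology-assessment units (NATJUS) attach technical notes (NTs)
to cases — evidence summaries recommending for or against the claim. The
policy question this package addresses is economic: *for the cases decided
without an NT, what would an NT-informed decision have looked like, and
what would the payer have saved or lost?*

The package answers that question with a two-stage counterfactual model,
a per-case decision-change savings rule, bootstrap uncertainty, and
program-level cost aggregation — exercised end to end on a synthetic
litigation-case generator, because the underlying court databases are not
publicly deposited.

## The model

Cases carry covariates $x$: the annualized claim value $v$ (entering as a
standardized log value), the claim type (medication / treatment /
procedure) and the court. On the NT-bearing cases two probability maps are
fitted:

* **Model 1** — $p_1(x) = P(\text{NT favorable to the patient} \mid x)$;
* **Model 2** — $m_2(x, d) = P(\text{injunction favorable} \mid x,
  \text{NT direction } d)$, queryable under either direction $d$ for any
  $x$.

For a case decided *without* an NT, the counterfactual probability that an
NT-informed injunction would have been favorable is the Model-1 mixture

$$p_{cf}(x) = p_1(x)\, m_2(x, \mathrm{fav}) + \bigl(1 - p_1(x)\bigr)\,
m_2(x, \mathrm{unfav}).$$

### The savings rule

The economic logic is a decision-change rule: a favorable injunction that
an informed decision would have reversed saves the payer the annualized
claim value; the opposite reversal is a loss; no change is zero. Nothing
more is known about what the counterfactual decision would cost, so the
annual value is counted exactly once per case, never expanded over
treatment years. Taking the expectation over the counterfactual decision
gives the signed per-case expected saving

$$s_i = \begin{cases} v_i\,(1 - p_{cf}(x_i)) & \text{observed favorable} \\
 -\,v_i\, p_{cf}(x_i) & \text{observed unfavorable,} \end{cases}$$

so $|s_i| \le v_i$ by construction and losses net against savings. This
formalization of the verbal decision-change logic is the package's core
modelling decision; it is the minimal one consistent with counting each
case's annual value once.

Because claim values are extremely right-skewed, the headline point
estimate is the **median** of $s_i$ over the NT-less cases; the mean is
reported alongside. Note a structural property of the median on this
signed mixture: when the observed granting rate differs from one half, the
median of $s_i$ is nonzero *even under a perfectly null model*, because
the sign mixture is asymmetric. This matters for null-effect testing (see
below).

### Backends

Three exchangeable estimators of the two maps are provided:

* `forest` — probability random forests (ranger), the default; 500 trees
  unless configured otherwise, out-of-bag accuracy reported.
* `sequential_logit` — two logistic regressions; 5-fold cross-validated
  accuracy reported.
* `two_stage_linear` — a two-stage linear-probability estimator: stage 1
  regresses the NT-favorable indicator on the covariates; stage 2
  regresses the injunction outcome on the covariates and the stage-1
  fitted propensity. Predictions are clipped to $[0,1]$, which keeps the
  savings formula well defined; no instrument or exclusion restriction is
  claimed for this variant — it is a robustness backend, not an
  identification strategy.

Model AUCs are computed by the midrank (Wilcoxon) formula, so tied
predictions earn the standard half credit.

### Bootstrap uncertainty

Uncertainty in the savings estimate stems from model estimation, not from
the evaluation set, which is held fixed: each bootstrap replicate
resamples the NT-bearing *training* cases with replacement, refits both
models, re-scores the fixed NT-less cases and records the median (and
mean) saving. The reported interval is the percentile interval of the
bootstrap medians (default 2.5/97.5), chosen because the bootstrap
distribution of the median is visibly skewed. Resamples in which either
training outcome collapses to a single class cannot be fit; they are
redrawn, counted, and reported (`n_degenerate_redrawn`), with a hard cap
of 100 redraws.

A calibration caveat, measured by this package's own coverage experiment
(see the acceptance suite): at small training sizes the fitted maps carry
the usual small-sample bias of flexible estimators — coefficients biased
away from zero inflate $p_{cf}$ and deflate savings — and bootstrap
refits, which see less effective information, are biased slightly further
in the same direction. The percentile interval therefore undercovers when
the number of model parameters is not small relative to the training
size, and forest point estimates additionally carry Monte-Carlo noise
when the tree count is low (coverage in a two-court world rose from 80%
at 60 trees to 95% at 100+ trees). The coverage property is checked in a
compact two-court world (five model parameters, four hundred cases,
100-tree forests with terminal nodes of 30) where the estimators are
inside their asymptotic regime; in wide worlds (ten courts) at a few
hundred cases the interval should be read as approximate.

## The synthetic generator

The generator realizes the assumed causal structure: covariates drive NT
direction; covariates plus NT state drive the injunction. Defaults are
calibrated to the published summary statistics of the study population
this package emulates, fixed once:

* Claim values are log-normal with median BRL 10,120 and 90th percentile
  BRL 140,000 (`value_log_mu = log(10120)`, `value_log_sigma = 2.05`,
  solved from those two quantiles). A Pareto-spliced tail is available for
  sensitivity work.
* `nt_effect = 2.3` — the favorable-vs-unfavorable NT shift in injunction
  log-odds, matching granting rates of roughly 87% under favorable and
  41% under unfavorable notes.
* `beta_inj` intercept $-0.36 = \mathrm{logit}(0.41)$; `beta_nt`
  intercept $0.35$ (about 59% of NTs favorable).
* `no_nt_shift = 1.4` — the no-NT stratum sits *above* the
  NT-unfavorable baseline in granting propensity: judges without
  technical advice grant more readily (roughly 74% at the median case).
  This parameter is what makes informed counterfactual decisions a source
  of savings; with the no-NT stratum pinned to the NT-unfavorable
  baseline, an NT could only ever raise the granting probability and
  expected per-case savings would be structurally non-positive, which
  contradicts the positive median savings and mean-above-median ordering
  the analysis is designed to detect. Setting `no_nt_shift = 0` recovers
  the simpler nested process.
* `p_has_nt = 0.55`, `p_hiae_given_nt = 0.55`; citation probabilities
  0.877 (HIAE-authored notes) and 0.684 (other authors), which pool to a
  79% citation rate at the 55% authorship share.
* Slopes are not published anywhere; they are fixed once at plausible
  values: NT favorability declines with log value (technical notes tend
  to recommend against high-cost claims, `-0.8` per standardized log-value
  unit) and granting declines mildly with value (`-0.25`). Claim-type
  weights are medication-heavy (60/25/15), as in the health-litigation
  literature. Court effects default to zero with uniform weights over ten
  courts.

What the generator does **not** emulate: real court heterogeneity and
their joint distribution with claim types; temporal drift over filing
years; case text; correlated annotation errors; and any dependence of
exclusion flags on covariates (exclusions are drawn uniformly at rate
`exclusion_rate`, default 0). Passing tests on this generator therefore
demonstrate that the estimators recover the quantities of a process with
the assumed structure — not that the assumed structure is true of any
real court system.

## Test-world design choices

The property checks in the test suite each fix a world deliberately;
problem sizes are chosen so every check runs comfortably on one CPU.

* **Null-effect recovery** (n = 5,000, 200 bootstrap replicates): the null
  world sets `nt_effect = 0` *and* `no_nt_shift = 0` (an NT whose presence
  still shifted decisions would not be null) and a balanced granting rate
  (`beta_inj` intercept 0). The balance matters because of the
  median-offset property above: with an unbalanced granting rate the
  median of signed savings is nonzero under a perfect null model, and the
  check would measure that structural offset rather than estimator bias.
  The estimate must be within 5% of the median case value of zero.
* **Interval coverage** (200 worlds of 400 cases, 100 bootstrap
  replicates each, 100-tree forests with terminal-node size 30): each
  world's analytic truth is the median of per-case savings computed from
  the generator's closed-form probabilities on the realized cases; the
  nominal 95% interval must cover it in at least 90% of worlds. Run in
  the compact two-court world for the calibration reasons above.
* **Skew ordering** (20 seeds, n = 3,000, sequential-logit backend): the
  mean-based estimate must exceed the median-based estimate on
  right-skewed values. Run with `value_log_sigma = 1.2` (mean/median
  value ratio about 2): under the full study tail (sigma 2.05) the
  *sample mean* at a few thousand cases is dominated by the top one or
  two draws and occasionally dips below the median — which is precisely
  why the median is the headline estimator — and the forest's
  counterfactual probabilities extrapolate poorly at extreme values,
  adding mean noise of the same kind. The ordering check therefore uses
  a right-skewed world and backend in which the mean is estimable at
  test scale; in it, the population ordering holds in every world
  (true mean about 2.2 times the true median).
* **Backend concordance** (10 seeds, n = 4,000): sequential-logit and
  two-stage estimates must agree with the forest in sign and within a
  factor of two.
* **Counterfactual enumeration** is checked to 1e-12 against explicit
  enumeration of both NT states on a covariate grid.

## Economics

Program-level savings multiply the per-case point estimate (and interval
bounds) by the yearly NT counts, exactly and without intermediate
rounding; presentation rounds half-up to two decimals. Reference-year
adjustment multiplies each year's amount by `index[reference]/index[year]`;
no price index is hard-coded (for Brazilian health spending the national
consumer price index, IPCA, is the natural choice). ROI is
`(benefit - cost)/cost`. The bundled reference tabulations
(`reference_program_counts()`) carry the published triennium NT counts
(84,878 in total, 20,724 HIAE-authored) and HIAE direct costs
(BRL 10,227,301.59), from which the package reproduces the published
program totals and the 1.66 ROI in its acceptance checks.

The published per-year totals imply a full-precision per-case multiplier
(1,312.7408...), while the printed per-case value is rounded to 1,312.74;
the package aggregates at full precision by default, and the printed value
reproduces the published totals to within 0.01%.

## Numerical conventions and degenerate inputs

* Percentages and monetary figures are reported rounded half *away from
  zero* (`round_half_up()`), matching the convention of the published
  tables; internal arithmetic is never rounded.
* Probability outputs are clipped to $[0,1]$ only in the
  linear-probability backend; the logistic and forest backends produce
  probabilities natively.
* Single-class outcomes refuse to fit (`degenerate_fit_error`), naming
  the constant outcome; training sets below 50 cases are refused by
  default; AUC on a single-class set is an error rather than NaN.
* Every stochastic entry point takes an explicit integer seed; no
  function mutates the caller's RNG state.
* The standardization of log value uses training-set moments; predictions
  are invariant to that affine choice for the logistic backend and the
  clipped linear backend alike.

## Known limitations

* The counterfactual is model-based transport, not a quasi-experiment:
  nothing rules out confounding beyond the three modelled covariates, and
  no instrument underwrites the two-stage variant.
* The percentile bootstrap reflects model-estimation uncertainty only;
  it conditions on the evaluation set and undercovers in
  parameter-rich/small-sample regimes (quantified above).
* Downstream health costs of denied care are outside the savings rule:
  a denial that worsens a condition may cost the payer later; such
  dynamics are not modelled.
* The generator's independence assumptions (value independent of court
  and claim type, uniform exclusions) are simplifications; estimates on
  real extracts should treat the synthetic calibration as a harness, not
  as evidence.
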