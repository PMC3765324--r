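---
title: "Measuring socio-economic inequity in health coverage: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring socio-economic inequity in health coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equicover)
```

# The measurement problem

National household surveys with multistage stratified designs are the main
source of population-level evidence on who receives maternal health services.
Three features make their analysis non-trivial: socio-economic position must
be *constructed* (income is rarely collected; asset ownership is), every
estimate must respect the *design* (strata, clusters, post-hoc weights), and
"inequality" must be summarised by statistics that use the *whole*
socio-economic distribution rather than only its extremes. `equicover`
implements that workflow end to end, together with a synthetic-survey
generator whose true inequality parameters are known exactly, so every
estimator in the package can be validated without access to any restricted
microdata.

# The asset-based wealth index

Living standards are proxied by the first dimension of a multiple
correspondence analysis (MCA) of categorical household asset and
infrastructure indicators. Each variable is expanded into its indicator
(disjunctive) columns; the matrix of relative frequencies is double-centred
and standardised by row and column masses; and the leading singular vector,
scaled to standard row coordinates, is the household score.

Choices a user should know about:

* **Survey weights in the MCA.** Sources differ on whether design weights
  belong in the row masses. Both modes are provided
  (`weighted_mca = TRUE` is the default, since the survey is weighted
  everywhere else); on the synthetic battery the two scores correlate above
  0.99, so the choice is not load-bearing there.
* **Missing asset responses.** The default is the complete-indicator
  convention (all indicator columns of the missing variable left at zero),
  which preserves the sample and is standard for DHS-style indices;
  `missing = "complete-case"` is available.
* **Orientation.** An MCA dimension is defined only up to sign. The score is
  oriented so that it correlates positively with the per-row count of
  "advantaged" levels (by default the last level of each variable, e.g. `1`
  for 0/1 ownership coding), making `QI` = poorest deterministic.
* **Quantile cut.** Households are ordered by score and the cumulative
  *weight* distribution is cut at `j/k`. A household exactly on a boundary
  goes to the lower group, and tied scores are never split across groups
  (the boundary moves to the end of the tie); group shares are therefore
  recomputed from the final assignment rather than assumed equal. Quartiles
  are the default because sparsely populated top quintiles are common in
  highly skewed wealth distributions; `k` is configurable.

# Design-based estimation

Prevalences are weighted ratios \(\hat p = \sum w_i y_i / \sum w_i\),
complete-case per outcome within an optional analysis domain (so different
outcomes legitimately carry different `n`). Standard errors are by Taylor
linearisation over PSUs within strata, with out-of-domain records retained
at zero contribution (the correct subpopulation estimator); intervals are
Wald on the logit scale, which keeps bounds inside [0, 1] at extreme
prevalences. Single-PSU strata contribute zero variance with a warning.

Association tests use the first-order Rao–Scott correction: the Pearson
statistic on weighted proportions scaled to the unweighted `n`, divided by
the mean design effect of the cell proportions, referred to
\(F_{(R-1)(C-1),\ \#\mathrm{PSU}-\#\mathrm{strata}}\). The SRS benchmark
variance is \(p(1-p)/(n-1)\), which makes the correction exactly 1 under
equal-weight independent sampling — the property the tests exploit. The
second-order (Satterthwaite) correction is a possible extension, not
implemented.

Clustering deserves a note: when a design has nearly as many PSUs as
respondents, analysts sometimes ignore clustering altogether. Both stances
are supported — passing `psu` to `survey_design()` clusters the
linearisation and bootstrap on PSUs; omitting it (or
`ignore_clustering = TRUE` in the pipeline) treats records as independent,
reproducing that replication stance.

Post-hoc weighting by population margins (age, race, province) is by
iterative proportional fitting with tolerance `1e-6` on the maximum relative
margin discrepancy and at most 50 cycles, preserving the weight total;
raking fails loudly when a positive-target category has no records.

# Equity indices

Ordered groups `q = 1..k` (poorest first) with population shares \(p_q\)
receive midpoint ("ridit") rank scores \(r_q = c_q + p_q/2\), the midpoint
of each group's range in the cumulative population distribution. The rank
scores are always recomputed from the *unrounded* shares; reproducing a
published worked example that was itself computed from rounded shares can
therefore differ in the third decimal, and the package deliberately does not
"correct" toward such prints.

* **SII** — the slope of the least-squares regression of \(h_q\) on
  \(r_q\) weighted by \(p_q\): the absolute change in the outcome from the
  bottom (rank 0) to the top (rank 1) of the distribution. Weighting by
  population share makes the index sensitive to how the population is
  distributed over groups, not only to group means.
* **RII** — SII divided by the population mean \(\mu = \sum_q p_q h_q\);
  the identity RII·μ = SII is asserted on every computed result.
* **Concentration index** — computed in the grouped covariance form
  \(C = \frac{2}{\mu}\sum_q p_q h_q r_q - 1\) and cross-checked at `1e-10`
  against the trapezoid area under the concentration curve; the two are
  algebraically identical, so a discrepancy indicates a numerical defect.
  With k groups, grouped |C| is bounded away from 1 (0.75 for four equal
  groups); this is a property of grouping, not an error.
* **Absolute gap** — top minus bottom group, reported unrounded and at one
  decimal in percentage points. For non-ordinal stratifiers the gap table
  reports max − min alongside last − first, because "difference between
  highest and lowest groups" is ambiguous for ordered groupings and
  published tables are not always consistent about which was used.

Rounding in report tables follows the conventions of published equity
tables: one decimal for prevalences, gaps and SII (percentage points), two
for RII, four for C.

## Uncertainty

Published equity tables often print 95% CIs without naming a method. The
package's primary intervals are nonparametric bootstrap percentile
intervals, resampling PSUs with replacement within strata (default 1,000
seeded replicates), recomputing shares, ranks, μ and all indices in every
replicate; the analytic WLS slope SE is also reported for the SII. Replicates
that empty a group (possible in tiny designs) are dropped and counted. The
bootstrap is vectorised with per-stratum multinomial resampling counts, so
1,000 replicates cost a few small matrix products per stratum.

# Survey-weighted logistic models

Odds-ratio models are fitted by maximum pseudo-likelihood (IRLS with
analysis weights, normalised to mean one — estimates are invariant to the
weight scale and the deviance convergence criterion behaves at survey-scale
weights). Variances are a PSU-clustered sandwich, or model-based when
clustering is ignored. Categories in which the outcome never varies
(separation) are omitted from the fit and flagged, mirroring the `#`
convention of published tables, rather than handled by penalised
alternatives. Backward elimination tests each covariate by a *joint* Wald
test across its levels, so multi-level factors enter and leave whole, drops
the worst p-value above `alpha = 0.05` (the conventional threshold;
configurable), breaks ties by declared covariate order, and logs every step.
The saturated single-factor model reproduces weighted cross-tab odds ratios
to machine precision, which is the oracle the tests use.

# The synthetic survey generator

The generator emulates the structure the estimators assume:

* **Design.** Strata are province × locality (9 × 4 by default), each
  contributing 28 EAs (1,008 total) of 15 households — the scale of a
  national multistage survey. Design weights are inverse products of the two
  stage-selection probabilities against notional frame sizes, jittered by a
  mean-one log-normal factor (σ = 0.2 by default) to create realistic
  unequal weights without changing expectations.
* **Living standards and assets.** Latent SES is standard logistic with a
  locality shift, so the 8-item asset battery (difficulties spanning ±2) is
  a Rasch-type item set with closed-form item prevalences — which is what
  makes tail checks on item ownership exact.
* **Individuals.** Each household's roster holds Poisson numbers of women
  per age band (15–19/20–29/30–39/40–54); Kish-style selection takes one
  woman per occupied band, and the analysis weight multiplies the household
  weight by the band size (the inverse within-band selection probability).
  Stratifiers (race, education, employment, headship, HIV status) are drawn
  with SES-correlated distributions.
* **Outcomes.** Binary outcomes are Bernoulli with
  \(\Pr(y=1) = a + b\,F\), where `F` is the design-weighted midpoint rank of
  the household's latent SES. Linearity in rank is exactly the model the SII
  regression assumes, which yields closed-form truth: SII = b, μ = a + b/2,
  RII = b/μ, and grouped C = 2·b·Var(r)/μ (Var(r) = 0.078125 for equal
  quartiles). Missingness is an optional MCAR mask per outcome (default 0),
  matching the per-outcome varying `n` of real survey tables;
  analysis is complete-case downstream.

**What passing tests do and do not show.** The generator produces MCAR
missingness, perfectly measured assets, a single latent SES dimension and an
exactly linear outcome-rank relationship. Real surveys violate all four, so
estimator recovery here validates the *computation* (unbiasedness and
interval calibration under the assumed model), not robustness to model
misspecification, informative missingness, or reporting biases.

**Problem sizes.** The recovery study in the tests and acceptance script
uses 200 replicate surveys of 4 provinces × 4 localities × 19 EAs
(≈5,000 women each, 304 PSUs) with 1,000 bootstrap replicates per survey —
large enough that the Monte-Carlo standard error of the mean SII is ≈0.002
against a truth of 0.4, and small enough to run in well under a minute.
A tiny deterministic jitter (10⁻¹² · index) is added before cutting the true
SES rank into quartiles in those studies, only to break the exact ties that
women sharing a household otherwise create.

# Degenerate inputs and numerical conventions

* Asset tables with no variation (all profiles identical), quantile requests
  exceeding the number of distinct scores, empty analysis domains,
  all-missing outcomes, zero-mean outcomes for RII/C, degenerate contingency
  tables, and inconsistent response ledgers all raise classed errors named
  for the condition.
* Equity functions never re-sort groups: ordering is taken from the
  wealth-index stage (or the factor levels supplied).
* All computation is on proportions in [0, 1]; the report layer multiplies
  by 100 (`percent = TRUE`), so SII prints in percentage points while RII
  and C are scale-free.
* Determinism: every stochastic step takes a seed; identical configuration
  and seed give byte-identical generator output and report files. The
  generator restores the caller's RNG state.

# Interface notes

The exported functions are the package's interface; `run_pipeline()` +
`write_report()` orchestrate the stages and emit the CSV/JSON report bundle,
and a thin Rscript dispatcher (`inst/cli/equicover.R`) exposes `simulate`
and `run` for shell use — the intermediate stages (wealth index, tabulation,
equity, regression) are single exported function calls and are not
duplicated as subcommands.

# Known limitations

* First-order Rao–Scott only; no Satterthwaite second-order correction.
* No finite-population corrections (sampling fractions assumed negligible)
  and no multiple imputation; missing data are complete-case per outcome.
* No normalised concentration-index variants (Erreygers/Wagstaff) and no
  decomposition of C into contributing factors.
* The raking scheme is a generic IPF stand-in; real surveys' weight
  construction is usually more elaborate (non-response models, trimming).
* Grouped C is attenuated relative to individual-level C by construction;
  comparisons across different k are not meaningful.
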