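# equicover

Measuring socio-economic inequity in health-service coverage and health
status from complex household-survey data.

Health-equity analyses of national household surveys ask a recurring set of
questions: how does coverage of a service (antenatal care, skilled birth
attendance, a doctor at childbirth) or a health outcome vary across
socio-economic groups, and how large is that inequality in absolute and
relative terms? `equicover` packages the full workflow for analysts working
with survey microdata — or, when the microdata are restricted, with a
synthetic survey whose true inequality parameters are known in closed form.

The pipeline:

1. **Wealth index** — an asset-based living-standards score from the first
   dimension of (optionally survey-weighted) multiple correspondence
   analysis of household asset and infrastructure indicators, cut into
   weighted quantile groups (quartiles `QI` poorest … `QIV` wealthiest by
   default).
2. **Design-aware estimation** — weighted prevalences with Taylor-linearised
   standard errors over PSUs within strata, grouped tabulations, first-order
   Rao–Scott corrected association tests, raking (IPF) of weights to
   population margins, and response-rate accounting.
3. **Equity indices** — for ordered groups with population shares
   \(p_q\), midpoint (ridit) rank scores \(r_q = c_q + p_q/2\); the slope
   index of inequality (SII), the slope of the share-weighted regression of
   group prevalence \(h_q\) on \(r_q\), read as the outcome change from the
   bottom (rank 0) to the top (rank 1) of the socio-economic distribution;
   the relative index of inequality RII = SII/μ; the concentration curve and
   index \(C = \frac{2}{\mu}\sum_q p_q h_q r_q - 1\) (equivalently twice the
   area between the curve and the diagonal); absolute top-minus-bottom gaps;
   and prevalence-derived odds ratios. Uncertainty by a seeded bootstrap
   that resamples PSUs within strata.
4. **Association models** — survey-weighted logistic regression (pseudo-ML
   with a PSU-clustered sandwich) with joint-Wald backward elimination and
   combined unadjusted/adjusted odds-ratio tables, including detection of
   separated categories.
5. **Synthetic survey generator** — multistage stratified design (province ×
   locality strata, EAs as PSUs, fixed household take, Kish-style selection
   of one woman per age band), a standard-logistic latent living-standards
   score driving a Rasch-like asset battery, and binary outcomes that are
   linear in the weighted SES rank, so the true SII equals the configured
   gradient exactly.

## Worked example

```r
library(equicover)

cfg <- generator_config(n_provinces = 4, n_ea_per_stratum = 19, seed = 2026)
sim <- simulate_survey(cfg)          # households, women, closed-form truth

hh <- sim$households
wi <- wealth_index(hh[paste0("asset_", 1:8)], weights = hh$design_weight, k = 4)

women <- sim$women
women$seq_group <- wi$group[match(women$household_id, hh$household_id)]
design <- survey_design(women$analysis_weight, women$stratum_id, women$ea_id)

res <- equity_indices(women$coverage, women$seq_group, design,
                      boot = 1000, seed = 2026, percent = TRUE)
res
```

```
Equity indices
 group prevalence_pct share    n
    QI           44.0 0.255 1236
   QII           58.4 0.242 1186
  QIII           62.4 0.257 1255
   QIV           75.6 0.245 1204
  mean: 59.981
  gap (top - bottom): 31.6 (27.4 to 35.6)
  SII: 39.6 (34.5 to 44.8)
  RII: 0.66 (0.57 to 0.75)
  C:   0.1031 (0.0894 to 0.1176)
```

Coverage rises from 44.0% in the poorest to 75.6% in the wealthiest MCA
quartile. The SII of 39.6 percentage points (truth for this configuration:
40, since the generator's gradient is `b = 0.4`) is the estimated coverage
difference between the very bottom and the very top of the socio-economic
distribution; the RII of 0.66 expresses it relative to the 60.0% population
mean (truth 2/3); the positive concentration index 0.1031 (truth 0.1042)
says coverage is concentrated among the better-off. The bootstrap intervals
resample the 304 enumerator areas within strata. A Rao–Scott corrected test
of the same table gives `F = 55.4 on (3, 288) df, p = 2.6e-28`, and the
wealth score's Spearman correlation with the latent living standards it
proxies is 0.88.

The one-shot orchestration does all of the above plus composition,
gap and odds-ratio tables, and writes a CSV/JSON report bundle:

```r
bundle <- run_pipeline(pipeline_config(simulate = cfg,
                                       groupings = c("province", "locality"),
                                       model_covariates = c("education"),
                                       seed = 2026))
write_report(bundle, "report/")
```

A thin command-line dispatcher ships at `inst/cli/equicover.R`
(`Rscript equicover.R simulate|run --config cfg.yaml --seed 7 --out dir/`).

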