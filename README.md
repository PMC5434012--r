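# eventcure

Joint regression modelling of **lifetime disease susceptibility** and
**conditional age of onset** for event-history data with a risk-free (cure)
fraction, plus the candidate-gene SNP analysis pipeline built around it.

## The problem and who this is for

In a cohort followed for a late-onset disease (the motivating application is
alcoholism in a small cohort of unrelated male founders), currently healthy
subjects are not all "controls": some will develop the disease later, and
some are never at risk.  Kaplan–Meier event curves for such data plateau
below 1 — the plateau *is* the susceptible fraction.  Case–control logistic
regression ignores onset ages; Cox regression assumes everyone eventually
converts and its proportional-hazards assumption fails when genotype-specific
event curves cross.  `eventcure` is for biostatisticians and statistical
geneticists who want the two questions answered separately and jointly:
*who is susceptible*, and *among the susceptible, when does onset occur*.

## The model

For onset age $T$ and development indicator $D$, with covariate vectors $Z$
and $Z^*$ (each with leading 1, possibly sharing variables):

$$\Pr(T > t \mid Z, Z^*) = \pi(Z)\,\Pr(T > t \mid D=1, Z^*) + \bigl(1 - \pi(Z)\bigr)$$

* logistic susceptibility submodel: $\operatorname{logit}\,\pi(Z) = \beta'Z$
  — $\exp(\beta)$ is an odds ratio on lifetime susceptibility;
* AFT location-scale submodel:
  $\ln T = \gamma'Z^* + \exp(\alpha'Z^*)\,\varepsilon$, $\varepsilon$
  standard logistic (log-logistic onset ages) — $\exp(\gamma'Z^*)$ is the
  conditional **median onset age**, $\alpha$ controls the onset-age spread.

Unaffected subjects are right-censored at their interview age.  Maximum
likelihood, Wald and likelihood-ratio inference, AIC model selection,
percentile-bootstrap validation, Kaplan–Meier adequacy checks, SNP quality
control (exact Hardy–Weinberg test, EM-based $r^2$/D′ pruning) and
Jaccard-similarity clustering are all included, along with a seeded
synthetic-cohort generator since the motivating cohort data are
access-restricted.

## Worked example

Simulate a cohort from the built-in five-SNP study preset and fit the joint
mixture model:

```r
library(eventcure)

cfg  <- table1_preset(seed = 42, n_subjects = 2000)
cht  <- gen_cohort(cfg)
data <- model_frame(cht, table1_codings())
fit  <- fit_mixture(data, table1_spec())
print(fit)
#> logistic-AFT log-logistic mixture fit: n = 2000, loglik = -3528.6287, AIC = 7073.2573
#>   logistic (Intercept) = -0.6087, snp_drd3_dom = 1.3209
#>   location (Intercept) = 3.4993, snp_grin2b_add = -0.2879, snp_ntrk2_dom = 0.5288, snp_aldh1a1_dom = -0.4089
#>   scale    (Intercept) = -1.4285, snp_drd2_dom = -1.3044

wt <- wald_tests(fit)
wt[wt$term != "(Intercept)", c("part", "term", "estimate", "se", "p", "or")]
#>      part            term estimate      se         p   or
#>  logistic    snp_drd3_dom    1.321 0.11076  8.65e-33 3.75
#>  location  snp_grin2b_add   -0.288 0.00743  0.00e+00   NA
#>  location   snp_ntrk2_dom    0.529 0.01079  0.00e+00   NA
#>  location snp_aldh1a1_dom   -0.409 0.01098 2.35e-303   NA
#>     scale    snp_drd2_dom   -1.304 0.06135 2.57e-100   NA

median_onset(fit$coefficients$gamma[["(Intercept)"]])   # referent profile
#> 33.09  (years)

lrt(fit, fit_mixture(data, mixture_spec()))
#> chi2 = 1411.92, df = 5, p = 3.61e-303
```

Reading the table: carriers of the dominant susceptibility allele have an
odds ratio of about 3.7 on ever developing the disease (generating truth
3.44); each copy of the additive allele advances the median onset age by a
factor of $e^{-0.29} \approx 0.75$; the negative scale coefficient means a
narrower onset-age range for its carriers.  The single-SNP workflow
(`select_model`), joint subset search (`multi_covariate_search`),
QC (`qc_cascade`), bootstrap (`bootstrap_mixture`) and GAP-style clustering
(`gap_cluster`) are documented in the methods vignette
(`vignettes/mixture-cure-methods.Rmd`), and `pipeline_run()` exposes the
whole flow as seeded subcommands (`simulate`, `qc`, `fit-single`,
`fit-multi`, `bootstrap`, `cluster`, `report`).

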