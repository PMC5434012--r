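---
title: "Modelling disease susceptibility and age of onset with a logistic-AFT mixture"
author: "eventcure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling disease susceptibility and age of onset with a logistic-AFT mixture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eventcure)
```

## The model

Case–control analyses of a late-onset disease such as alcoholism discard two
pieces of information: currently healthy subjects may still develop the
disease later, and affected subjects differ in *when* they became affected.
`eventcure` fits an event-history model with a risk-free (cure) fraction that
uses both.  Let $T$ be the onset age and $D$ the indicator of eventual
disease development.  The overall survival of a subject with covariate
vectors $Z$ (susceptibility) and $Z^*$ (onset age) is the two-component
mixture

$$\Pr(T > t \mid Z, Z^*) \;=\; \pi(Z)\, \Pr(T > t \mid D = 1, Z^*) \;+\; \bigl(1 - \pi(Z)\bigr),$$

where $\pi(Z) = \Pr(D = 1 \mid Z)$ follows a logistic regression,
$\operatorname{logit} \pi = \beta'Z$, and the conditional onset age of
susceptible subjects follows an accelerated failure time (AFT)
location-scale model

$$\ln T = \gamma'Z^* + \exp(\alpha'Z^*)\,\varepsilon,$$

with standard logistic error $\varepsilon$, i.e. a log-logistic onset-age
distribution.  Interpretation is factor by factor: $\exp(\beta_j)$ is an
odds ratio on lifetime susceptibility (interpretable as lifetime prevalence
when censoring extends past the onset-age support), $\gamma_j$ shifts the
conditional *median* onset age ($\exp$ of the location linear predictor),
and $\alpha_j$ stretches or shrinks the onset-age *spread*.  The overall
cumulative event curve flattens at $\pi$ — the "flat tail" that a
Kaplan–Meier curve of such data shows instead of rising to one.

Right censoring enters through the interview age of unaffected subjects: an
observed onset at $t$ contributes $\ln \pi + \ln f(t)$ to the
log-likelihood, a subject censored at $c$ contributes
$\ln[\pi S(c \mid D=1) + 1 - \pi]$, mixing susceptible-but-not-yet-onset
subjects with the risk-free fraction.  The error family is fixed to
log-logistic; the code keeps the conditional survival and density in one
place (`conditional_survival`, the internal likelihood) as the seam where
another AFT family could be added, but only this one ships.

Assumptions worth stating plainly: subjects are independent (founders, not
relatives), censoring is independent of onset given covariates, the
nonsusceptible fraction is exactly risk-free (never converts), and covariate
effects are linear on the three linear predictors.  Familial correlation,
frailties, interval censoring and left truncation are out of scope.

## Fitting and inference

`fit_mixture()` maximizes the observed-data likelihood by multi-start BFGS
with an analytic gradient, followed by Newton polishing with step halving
until the gradient infinity-norm falls below `grad_tol` (default `1e-6`).
The first start combines an ordinary logistic fit of the event indicator
with a `survreg` log-logistic fit to the events only; the remaining starts
(default 5 in total) add fixed, deterministic jitters, so fitting consumes
no random numbers and is reproducible by construction.  The covariance is
the inverse observed information, computed as a central-difference Jacobian
of the analytic gradient; Wald tests and 95% CIs come from it, with
logistic-part results also reported on the odds-ratio scale.

Numerical safeguards: linear predictors are clipped at $\pm 700$ before
exponentiation (far beyond any realistic estimate; tested not to bind), the
log-scale linear predictor at $\pm 300$.  Degenerate situations are
reported, not patched over: a non-full-rank design raises a rank error, and
a fit whose fitted susceptibility logits all sit beyond $\pm 10$ is flagged
as a boundary fit with logistic-part Wald inference suppressed — with no
censored subjects $\hat\pi \to 1$ and the logistic intercept is not
estimable.  For exactly that reduction the optimizer supports pinning
parameters (`fixed =`), which is how the test suite checks that with
$\pi \equiv 1$ and no censoring the fit collapses onto an independent AFT
implementation to $10^{-4}$.

Model comparison uses AIC with the free-parameter count of all three parts,
and likelihood ratio tests against the intercept-only model after an
explicit nesting check on identical complete cases.

## The SNP analysis pipeline

**QC.** `qc_cascade()` applies, in order: (1) minor allele frequency
$< 0.05$ or call rate $< 0.85$ (both over all subjects); (2) within-gene
complete-LD pruning — pairs with $r^2 = 1$ from EM haplotype frequencies
lose the member with the lower call rate (ties: the later map position);
(3) an exact conditional Hardy–Weinberg test on the unaffected subjects
only, at $\alpha = 0.05$.  The exact test (not chi-square) is used because
the unaffected stratum is small (~42 subjects) where the asymptotic test
misbehaves; it is validated against full enumeration.  The MAF/GCR versus
HWE population split is deliberate and configurable.  LD blocks are a
display concept and play no role in pruning.

**Coding and selection.** Genotypes are coded general (two indicators,
heterozygote referent), additive (minor-allele count), dominant or
recessive; when any genotype class carries at most one event, only merged
two-group codings are allowed (`sparse_event_rule`).  Which pair to merge is
decided by the smallest sup-distance between genotype-stratified
Kaplan–Meier curves — an explicit operationalization of a judgement the
original analysis made visually; a closest pair of the two homozygotes
(non-contiguous) falls back to the dominant merge.  `select_model()` fits
the full cross of allowed codings and placements of the SNP into the
logistic/location/scale parts, picks minimum AIC (ties toward fewer
parameters), attaches the LRT versus the null, and classifies the SNP:
(a) onset-age parts significant only, (b) logistic part only, (c) both,
(d) neither.  $\alpha$ defaults to 0.05 with a relaxed 0.10 mode, reflecting
the attenuation of mixture-model effects in small samples.  No multiplicity
adjustment is applied to the primary results; a Bonferroni column is
emitted as supplementary output only.

A property worth knowing: because the chosen model is the minimum-AIC
winner over ~28 candidates, the *selected* model's test is not a size-α
test.  In null simulations at $n = 2000$ the procedure returns category (d)
roughly 70% of the time, not $1 - \alpha$; the per-candidate LRT itself is
perfectly calibrated (null mean $\approx$ df).  This selection bias is
inherent to any min-AIC search over many codings and placements and is the
reason the full AIC table is kept in every selection result, so any chosen
model can be audited.

**Bootstrap.** `bootstrap_mixture()` resamples subjects with replacement
(unstratified — resamples of the full cohort size by default) and refits
the *fixed* chosen specification; selection is not re-run inside resamples
unless explicitly requested, because the validation question is the
stability of the already-chosen model.  Percentile CIs use type-7
(linear-interpolation) empirical quantiles — fixed and documented because
at a few hundred resamples the tail definition is visible.  The default is
400 resamples; everything is reproducible bit-for-bit from the seed.

**Clustering.** `binarize()` codes each subject 1 for minor-allele carriage
or habitual smoking (missing genotype = non-carrier, annotated);
`jaccard_matrix()` computes $|x \wedge y| / |x \vee y|$ with the both-empty
convention $J = 0$; `cluster_order()` runs average-linkage agglomeration on
$1 - J$ and fixes the leaf order by deterministic bottom-up node flipping
that minimizes the adjacent boundary-leaf distance, ties broken by label
order.  This flipping heuristic is a documented stand-in for
elliptical-seriation-guided ordering: it optimizes the same
adjacent-distance objective greedily rather than via the seriation
eigenvector, and is exactly reproducible.

## The synthetic-cohort generator

Real data of this kind (a 65-founder alcoholism cohort) are
access-restricted, so `gen_cohort()` generates cohorts with the structure
the model assumes: HWE genotypes at stated MAFs (optionally a two-locus
haplotype draw hitting an $r^2$ target, with the feasibility bound
enforced), independent Bernoulli habitual smoking (prevalence 46/65 by
default), susceptibility from the logistic truth, log-logistic onset ages
from the AFT truth, and uniform interview ages on [25, 70] years — the
emulated population is adult at interview and no particular interview-age
law is implied by the design, so a flat one is the neutral choice; it is
configurable because censoring strength drives the identifiability of
$\pi$.  Nonsusceptible subjects never convert.  Missingness is applied
after the generating truth is computed, so genotype truth and recorded
calls are distinct.  `table1_preset()` encodes the five-SNP study
configuration: baseline susceptibility 0.378, a dominant susceptibility
odds ratio of 3.44, an additive location effect of −0.29 per allele,
dominant location effects +0.52 and −0.41, a dominant scale effect −1.32,
MAFs 0.3–0.4 so every retained genotype class expects at least two events.

What the generator does *not* emulate: family structure, population
stratification, genotyping batch effects, informative censoring, and
linkage beyond explicit pairwise $r^2$ targets.  Passing tests therefore
demonstrate correctness of the estimator under its own assumptions, not
robustness to the ways real cohort data violate them.

The deterministic QC fixture (`qc_demo_cohort()`) is constructed, not
sampled: fixed genotype counts per case/unaffected stratum with rotation
offsets decorrelating SNPs, plus engineered failures — two
(near-)monomorphic SNPs, one low-MAF/low-call-rate SNP, five complete-LD
copies with call-rate gaps, and a heterozygote-deficient SNP violating HWE
in the unaffected stratum (its complete-LD copy overlapping both failure
modes).  The cascade retains 22 of its 31 SNPs on 12 of 14 genes.

## Problem sizes used by the checks

Simulation-based checks run at sizes chosen to give tight Monte-Carlo error
while keeping the suite pleasant to run: parameter recovery and Wald-CI
coverage use 200 replicates at $n = 2000$; the null LRT calibration 300
replicates at $n = 300$; the null selection-size simulation 100 replicates
at $n = 2000$; bootstrap coverage 100 outer replicates at $n = 200$ with
$B = 200$ resamples (the analysis default stays $B = 400$).  Oracle
comparisons are exhaustive where enumeration is cheap (all HWE
configurations up to $n = 30$; all pairs of length-6 binary profiles).

## Known limitations

- Independence of subjects is assumed throughout; a family-based extension
  would need a different likelihood.
- With heavy censoring or very small cohorts the logistic intercept and the
  location intercept compete for the same information; boundary flags and
  the bootstrap are the intended diagnostics, not silent regularization.
- The min-AIC selection is exploratory, with the selection-bias caveat
  described above.
- The leaf-ordering heuristic is one deterministic answer to an
  under-specified ordering problem; different seriation schemes give
  different but equally defensible orders.
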