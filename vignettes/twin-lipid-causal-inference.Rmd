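---
title: "Co-twin causal inference for metabolite-lipid associations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-twin causal inference for metabolite-lipid associations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`twinfalcon` implements the analytical chain of a monozygotic (MZ) twin
metabolomics study of blood lipids: targeted-metabolomics quality control and
transforms, pair-clustered metabolite–lipid association screening with FDR
control, the ICE FALCON co-twin regression procedure for separating predicted
causal effects from familial confounding, and bidirectional causal mediation
linking lipids, metabolites, and other cardiometabolic traits. Because cohort
data of this kind are generally not redistributable, the package is built
around a synthetic MZ-twin generator with known causal structure; every
downstream stage is validated against that generator's planted truth.

# The synthetic twin cohort

Each family carries one standard-normal familial confounder $C$, shared
exactly by co-twins. Two standardized latent traits are generated per
individual $i$ in pair $j$:

$$X_{ij} = \lambda_x C_j + \varepsilon^x_{ij}, \qquad
  Y_{ij} = \beta X_{ij} + \lambda_y C_j + \textstyle\sum_k \gamma_k Z_{kij}
           + \varepsilon^y_{ij},$$

with the causal term reversed for `y_to_x` and absent for `none`. Residual
variances are completed so each latent has unit variance; if explicit noise
SDs are supplied the traits are renormalized instead, and a variance budget
in excess of one is an error naming the offending parameters. The single
shared factor deliberately collapses additive-genetic and shared-environment
components: ICE FALCON's logic needs only "familial, shared within pair",
not the full variance decomposition.

$X$ is mapped onto a target lipid (triglycerides by default) on a log-normal
scale whose location and spread match a middle-aged co-resident MZ cohort
(median TG 1.46 mmol/L, and similarly for the other ten traits); $Y$ is
exposed to the metabolome generator as the "structural" metabolite.
Covariates follow the co-resident MZ design: age, gender, region and survey
year are pair-shared; BMI has a pair-shared and an individual component.
Missing values are injected per trait (defaults: TG 1, BMI 4, HbA1c 36,
HOMA-IR 6 — the per-trait missingness pattern of a real cohort of this size),
and the latent truth (confounder, latents, true effect) is kept in a separate
sidecar table so analyses cannot touch it accidentally.

Default structural parameters are chosen for test power, since within-pair
trait correlations for such cohorts are rarely published: the causal scenario
uses $\lambda_x = 0.7$ (a heritable lipid), $\beta = 0.3$, and $\lambda_y = 0$.
The choice $\lambda_y = 0$ is deliberate: it yields the textbook causal
signature in which the Model 3 self coefficient equals its Model 1 value
while the co-twin coefficient attenuates fully. With $\lambda_y > 0$ the
self coefficient genuinely attenuates too (its confounded share is explained
away by the co-twin's exposure), which is a mixed causal-plus-confounding
pattern, not a clean causal one. The confounding-only scenario uses
$\lambda_x = \lambda_y = 0.7$, $\beta = 0$.

## The synthetic metabolome

Metabolite concentrations are log-normal (log-scale SD 0.3–0.8, locations
spanning three orders of magnitude). Defaults mirror a 350-metabolite
targeted LC-MS/MS panel: 20% of metabolites are planted with analytical CV
above the 30% filter and 9.1% with QC occurrence below 50% (disjoint sets),
leaving 248 after filtering. QC failures are planted *deterministically*:
the QC replicate values are affinely rescaled so each metabolite's sample CV
equals its target exactly, and occurrence counts are planted as exact
integers. This makes filter-count checks exact rather than binomial. The
below-LOD mechanism censors the lowest 2% of each metabolite's study-sample
values by default (`lod_quantile`); censored cells are missing with a flag,
as delivered by a quantification pipeline. QC replicate count defaults to
10 injections. None of these three values is dictated by a published
protocol; they were fixed once as realistic for a targeted assay.

What the generator does *not* emulate: batch and drift structure, skewed or
heavy-tailed measurement error, correlated metabolite blocks (pathways),
dizygotic twins, and longitudinal repeats. Passing tests therefore
demonstrate correctness of the statistical machinery under a clean
linear-Gaussian twin model, not robustness to real-data pathologies.

# Preprocessing

* **CV filter**: CV = sample SD / mean of QC replicates, raw scale; exclusion
  is strictly above 0.30 ("above 30%"), so CV = 0.30 is kept. Metabolites
  with fewer than two detected QC values or a non-positive mean have
  undefined CV and are excluded with the CV verdict.
* **Occurrence filter**: occurrence = fraction of QC injections with a
  detected value; exclusion strictly below 0.50, so exactly 50% is kept.
* **LOD imputation**: below-LOD cells are replaced by the metabolite's lowest
  *detected* study-sample concentration; nothing else is modified, and a
  metabolite with no detected values is an error.
* **Transforms**: metabolites are natural-log-transformed then z-scored with
  the sample SD (denominator $n-1$) of the analysis sample after imputation.
  Standardization is invariant to the log base, so the natural log is purely
  a convention. Lipids and cardiometabolic traits except SBP/DBP are
  natural-log-transformed; non-positive values become missing with a count,
  and missingness is handled complete-case per model fit.

QC filtering never inspects study-sample values and LOD imputation never
inspects QC values; the two information streams are kept separate.

# Association screen

The log-lipid is regressed on the standardized metabolite with age, gender,
region and survey year as fixed effects and a pair-level random intercept
(lme4, REML by default). Treating the metabolite as predictor and the lipid
as outcome is a reporting convention (the screen is cross-sectional); effect
sizes are per SD of metabolite on the log-lipid scale. Singletons enter as
clusters of size one. P values use the large-sample normal reference on
$\hat\beta/\widehat{se}$; no degrees-of-freedom correction is applied. An
exchangeable-correlation marginal (GEE) backend is available behind the same
interface. BH FDR is applied within each lipid family (all metabolites
against one lipid), with calls at $q < 0.05$.

Sensitivity analyses: BMI adjustment as an extra fixed effect, and
overweight-stratified fits with BMI < 24 vs ≥ 24 kg/m² (24.0 is overweight;
the cutoff recommended for defining overweight in Chinese adults). The
interaction is tested by a 1-df likelihood-ratio test between pooled ML fits
with and without the metabolite-by-overweight term — ML rather than REML,
because REML likelihoods are not comparable across fixed-effect structures.

# ICE FALCON

For a trait pair $(X, Y)$ on complete pairs only (each member contributes a
row as "self"), three marginal models are fitted by GEE with an exchangeable
working correlation within pairs and cluster-robust sandwich SEs:

| Model | Mean structure |
|-------|----------------|
| 1 | $E(Y_{self}) = \alpha + \beta_{self} X_{self}$ |
| 2 | $E(Y_{self}) = \alpha + \beta_{cotwin} X_{cotwin}$ |
| 3 | $E(Y_{self}) = \alpha + \beta'_{self} X_{self} + \beta'_{cotwin} X_{cotwin}$ |

and the same with $X$ and $Y$ reversed. The change statistics are
$\Delta_{self} = \beta'_{self} - \beta_{self}$ and
$\Delta_{cotwin} = \beta'_{cotwin} - \beta_{cotwin}$ — pure arithmetic
identities on the fitted coefficients. Their SEs come from a nonparametric
bootstrap that resamples whole pairs with replacement (1,000 resamples by
default, same number of pairs per resample); the SE is the SD of the
bootstrap changes, and resamples that fail to fit are redrawn and counted
(more than 5% failures aborts).

The GEE fitter is implemented in the package (linear, identity link,
exchangeable working correlation estimated by the moment estimator,
sandwich covariance); with a fixed working correlation it is exact
generalized least squares and reduces to OLS at zero correlation, which is
how it is validated against closed-form oracles. Cluster sizes are 1 and 2
by design.

## Covariates

The co-twin model formulas contain no covariates: age, gender, region and
survey year are identical within MZ pairs and cannot confound within-pair
contrasts. They do, however, contribute to the marginal (Model 1/2)
coefficients, so by default both traits are residualized on them (and
z-scored) before the design is built; a flag disables this. This is an
interpretation choice, documented rather than hidden.

## One-sided change tests

The change test is one-sided. The package's default orientation tests the
hypothesis being probed — attenuation toward the null of the corresponding
marginal coefficient:
$p = \Phi\!\big(\mathrm{sign}(\hat\beta_{marginal})\,\Delta/\widehat{se}\big)$,
i.e. $P(Z \ge |\Delta|/\widehat{se})$ when the observed change points toward
the null and one minus that otherwise. An "observed-direction" convention
($P(Z \ge |\Delta|/\widehat{se})$ regardless of direction, the convention
under which published change P values for changes *away* from the null are
small) and a two-sided option are also provided.

A note on calibration: under a null in which the two traits are linked by
neither causation nor confounding *and* the predictor retains its familial
structure ($\lambda_x = 0.7$), the change statistic is asymptotically normal
and the attenuation-oriented test holds its nominal level. If the predictor
also has no within-pair correlation, $\Delta$ degenerates to a product of
two mean-zero estimates, the normal reference does not apply, and the test
becomes strongly conservative — the co-twin design carries no information in
that regime anyway. The package's null scenario for calibration checks is
therefore the former.

## Classification rule set

The evidence pattern is classified at level $\alpha$ (default 0.05) as a
pure function of the stored estimates and P values. The causal template,
evaluated in the direction where the candidate cause is the predictor, is:

1. $\beta_{self}$ significant (Model 1, robust P);
2. $\Delta_{self}$ *not* significant (bootstrap attenuation P);
3. $\Delta_{cotwin}$ significant attenuation toward the null;
4. $\beta'_{cotwin}$ attenuated *to become null* (Model 3 robust P ≥ α).

Familial confounding requires, in at least one direction, a significant
marginal co-twin coefficient with significant attenuation of both Model-3
coefficients. Both causal templates met gives `bidirectional_or_mixed`;
nothing met gives `inconclusive`. Condition 4 is this package's
interpretation (taken from the canonical worked narrative, where the co-twin
coefficient "attenuates to become null" under causation): without it, the
mirror direction's small but systematic change — an arithmetic consequence
of the structural model, of order $\beta \cdot r_{YY}$ — produces spurious
bidirectional calls at large $n$.

# Mediation

For a lipid exposure, metabolite, and cardiometabolic trait, eligibility is
prescreened by Pearson correlation between metabolite and trait
($P < 0.05$). Each ordering is fitted with two linear models (mediator on
exposure; outcome on exposure and mediator, both covariate-adjusted), and the
effects are propagated by quasi-Bayesian Monte Carlo: `n_sims` (default
1,000) coefficient vectors drawn from the asymptotic normal of each fit,
ACME $= a b$ per draw, ADE $= c'$, total $=$ ACME $+$ ADE (a draw-wise
identity in the linear no-interaction model). P values are doubled
Monte-Carlo tail probabilities floored at $2/n_{sims}$; intervals are
percentile. The primary mode has no pair-level term, matching the common
practice for covariate-adjusted mediation in this setting; twin clustering
can be probed by pair-level bootstrap outside the quasi-Bayesian engine.

The *inverse* ordering exchanges the mediator and outcome roles (the
exposure stays fixed; this matches the two-panel structure of
metabolite-as-mediator vs trait-as-mediator linkage summaries). A linkage is
declared only asymmetrically: forward mediation P < α and inverse P > α.
Proportion mediated is reported as ACME/total (flagged when the two disagree
in sign) and rounded to an integer percentage in summary tables.

A structural caveat the package makes explicit: in a linear-Gaussian system
the inverse ordering's ACME, $a_{inv} b_{inv}$, is bounded away from zero
whenever the total effect and the mediator–outcome partial association are —
so for *strong* planted paths both orderings are significant at moderate
sample sizes and the rule correctly returns `no_linkage`. The rule separates
orderings in the small-indirect-effect regime (planted validation uses
$a = b = 0.10$, no direct path, 4,000 individuals), which is also the regime
where such rules are applied in practice.

# Numerical and design choices

* GEE iteration: alternating coefficient/moment updates, tolerance $10^{-8}$,
  at most 25 iterations; working correlation clamped to $[-0.95, 0.95]$.
* Quartiles in descriptive tables are type-7 (linear interpolation); means
  (SD) for age, BMI, SBP, DBP; medians (IQR) for the log-scale traits.
* Bootstrap and simulation sub-seeds are derived deterministically from one
  master seed per module and per direction (the direction seed hashes the
  predictor name so that swapping the trait pair exactly exchanges the two
  directions). Fixed seeds make every result bit-reproducible.
* All thresholds (CV 0.30, occurrence 0.50, FDR 0.05, alpha 0.05, BMI cutoff
  24 kg/m², bootstrap B, mediation draws) are surfaced in the pipeline
  configuration; a run manifest echoes the effective configuration, the
  package version, and the stage-count conservation chain.

## Problem sizes in the shipped checks

The validation suite runs at deliberately chosen scales: classifier recovery
on 200 cohorts of 1,000 pairs (B = 200), null calibration on 200–300 cohorts,
bootstrap-SE calibration against the empirical SD of 500 replicates at 500
pairs (B = 200), BH behaviour on 1,000 replicates of 248-test families,
mediation recovery at 2,000–4,000 individuals. The bootstrap default of
B = 1,000 is retained for analyses; B = 200 in the simulation studies keeps
the SE estimate's own noise well below the effects being measured.

# Known limitations

* ICE FALCON is applied to MZ pairs only; dizygotic twins, sibships, and
  path-analytic decompositions beyond the three-model procedure are out of
  scope, as are Mendelian-randomization validation against external GWAS and
  pathway enrichment.
* The classifier's rule set is an interpretation of the published narrative
  patterns; borderline patterns land in `inconclusive` by design.
* Mediation direction-finding by the asymmetric rule is statistically weak
  in exactly the regime where both orderings carry signal; verdicts should
  be read as screening evidence, not causal proof.
* The generator's clean linear-Gaussian structure means the shipped checks
  validate machinery, not robustness to assay artefacts.
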