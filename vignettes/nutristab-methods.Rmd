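---
title: "Methods: nutritional yield, AMMI, BLUP stability and selection indexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nutritional yield, AMMI, BLUP stability and selection indexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutristab)
```

nutristab analyses balanced multi-environment trials (METs) of wheat
evaluated for grain yield and grain mineral concentrations, the setting of
organic variety testing where both agronomic performance and nutritional
value matter. This vignette explains the models the package implements,
the constants and tunable parameters, the design choices that were
genuinely open, and what the synthetic validation data do and do not show.

## The nutritional-yield metric

For a mineral with daily recommended intake $d$ (mg day$^{-1}$), a plot
with dehulled yield $Y$ (kg ha$^{-1}$) and wholemeal concentration $C$
(mg kg$^{-1}$) feeds

$$\mathrm{NY} = \frac{Y \, C}{d \cdot 365}$$

adults for a year from one hectare ($Y C$ is mg ha$^{-1}$; $365 d$ is
mg adult$^{-1}$ year$^{-1}$). The package uses 365 days per year; this
choice reproduces every recomputable entry of the published benchmark
table exactly after integer rounding (e.g. 6920 kg ha$^{-1}$ at 38.0
mg kg$^{-1}$ Fe and DRI 12 gives 60.04, printed as 60). The default DRI
values are adult averages: 12 (Fe), 8 (Zn), 0.9 (Cu) and 315 (Mg)
mg day$^{-1}$.

Two conventions matter and are fixed in the package:

* **Dehulling before everything.** Spelt and primitive wheats (einkorn,
  emmer) are harvested hulled; their yield is scaled by the dehulling
  factor (default 0.75) per plot, before nutritional yields are computed
  and before any averaging. Which genotype groups count as hulled is a
  config field (`hulled_groups`).
* **Per-plot averaging.** A genotype's mean nutritional yield is the mean
  of its per-plot nutritional yields, not the formula applied to mean
  yield and mean concentration. The two differ whenever yield and
  concentration covary across plots (they do, negatively — the dilution
  effect), and only per-plot averaging is consistent with the published
  genotype summaries. For single published rows of external trials (one
  yield, one concentration) the direct formula is the only option, and
  the benchmark comparisons use it.

Nutrient density is reported as the daily grams of wholemeal needed to
reach 100% of a DRI, $1000\,d/C$; it is undefined at zero concentration
and errors there rather than returning infinity.

Correlations among yield and the mineral nutritional yields are computed
on genotype-by-environment cell means. The source trial did not state the
observational unit of its correlation table; cell means (n = genotypes
times environments) were chosen because the replicate layer carries only
plot noise, and the choice is documented here rather than hidden.

## Variance attribution

`variance_partition()` decomposes the plot-level total sum of squares of a
trait into genotype, environment, G$\times$E and residual shares from the
two-way fixed-effects ANOVA. With one replicate per cell the interaction
and residual are confounded; the function then fits the additive model and
reports the remainder as a single confounded share, with a warning, rather
than pretending to separate them.

## AMMI

The Additive Main effects and Multiplicative Interaction model writes the
cell-mean table as

$$\bar Y_{ij} = \mu + g_i + e_j + \sum_k \lambda_k \alpha_{ik}
\gamma_{jk} + \rho_{ij},$$

where the additive part comes from the two-way ANOVA of the means and the
multiplicative part from the SVD of the double-centred residual
$Z_{ij} = \bar Y_{ij} - \bar Y_{i\cdot} - \bar Y_{\cdot j} + \bar
Y_{\cdot\cdot}$. Numerical choices:

* **Symmetric score scaling.** Genotype and environment scores are
  $u_{ik}\sqrt{\lambda_k}$ and $v_{jk}\sqrt{\lambda_k}$, so the score
  products reconstruct the interaction exactly and the reconstruction
  identity (input = additive part + score products, to 1e-8) is asserted
  in the tests. Published AMMI score magnitudes depend on this convention;
  orderings by |score| do not.
* **Sign rule.** SVD signs are arbitrary; each axis is oriented so the
  environment with the largest absolute score is positive, making outputs
  reproducible across platforms.
* **Variance explained** is $\lambda_k^2 / \sum \lambda^2$, a share of
  the *interaction* sum of squares only.
* **Stability ranking.** Genotypes are split at the grand mean of
  performance; the above-average class is listed first, ordered by |PC1|
  ascending, then the below-average class likewise. Ties break by
  performance descending then name; scores are rounded to 8 decimals
  for ranking so that an exactly additive table (scores at rounding
  noise) degenerates cleanly to performance ordering.
* Retained axes are all min(G, E) − 1; only PC1 (and PC2 in the biplot
  export) is interpreted, and no axis-selection F tests are attempted.
* Incomplete G$\times$E tables are a hard error — the designs targeted
  are balanced, and imputation is out of scope.

## BLUP and the harmonic-mean statistics

The mixed model is a single joint fit across environments,

$$y_{ijr} = \mu + E_j + g_i + (ge)_{ij} + \varepsilon_{ijr},$$

with environments fixed and genotype and interaction effects random. This
is the standard formulation underlying the harmonic-mean genotypic-value
statistics; per-environment fits were rejected because they cannot share
the genotype main effect.

Variance components: for balanced data the ANOVA closed forms are used
($\hat\sigma^2_\varepsilon = MS_{err}$, $\hat\sigma^2_{ge} = (MS_{GE} -
MS_{err})/r$, $\hat\sigma^2_g = (MS_G - MS_{GE})/(re)$, negatives
truncated to zero); otherwise EM-REML, started deterministically at the
method-of-moments values, iterated until the relative REML log-likelihood
change and the relative parameter change fall below 1e-8 and 1e-4
(max 10,000 iterations). For balanced data with interior estimates the
two routes agree to 1e-6 relative, which the tests assert; when a
component is truncated the constrained REML optimum sits on the boundary
and legitimately differs from truncated ANOVA — there the EM path is
cross-checked against an independent REML implementation (lme4) instead.

Genotypic values are obtained from Henderson's mixed-model equations:
$GV_{ij} = \hat\mu_j + \mathrm{BLUP}(g_i) + \mathrm{BLUP}((ge)_{ij})$.
The stability and adaptability statistics over $e$ environments are

$$\mathrm{HMGV}_i = \frac{e}{\sum_j 1/GV_{ij}}, \qquad
\mathrm{RPGV}_i = \frac{1}{e}\sum_j \frac{GV_{ij}}{\hat\mu_j}, \qquad
\mathrm{HMRPGV}_i = \frac{e}{\sum_j \hat\mu_j/GV_{ij}},$$

with $\hat\mu_j$ the observed environment mean of cell means (the model's
fixed-effect environment estimates coincide with these for balanced
data; the observed means are used so the relative statistics stay
interpretable for unbalanced data too). Genotypes are ranked by HMRPGV
descending. The harmonic-arithmetic-mean inequalities (HMGV $\le$ mean
GV; HMRPGV $\le$ RPGV) are asserted on every fitted table, and all three
statistics require strictly positive genotypic values — nonpositive
values raise an error naming the genotype. Published HMGV/RPGV/HMRPGV
values of the source trial depend on its unpublished plot-level data and
are used only as ordering sanity references, never as numeric targets.

## Selection indexes

**Elston's multiplicative index** uses genotype-level mean nutritional
yields across all environments with per-trait lowest acceptable limits
(LALs; defaults 28/40/50/25 adults ha$^{-1}$ year$^{-1}$ for Fe/Zn/Cu/Mg,
the trial minima): $\mathrm{EMI}_i = \prod_t (x_{it} -
\mathrm{LAL}_t)$ when every factor is strictly positive, else 0 with a
threshold-failure flag; flagged genotypes rank last. No recentring is
performed — shifting a trait without shifting its LAL changes scores, and
the tests pin that behaviour down.

**The desired-gains (Pesek–Baker) index** solves $G b = d$ for the
coefficients, where $d$ is the desired-gain vector (defaults 11/4/0/6;
the zero Cu gain asks the index to hold Cu constant, generally with a
nonzero coefficient) and $G$ the genotypic covariance matrix. $G$ is
estimated as the covariance across genotypes of the per-trait BLUP
genotype effects — shrunken values are stable for 19-genotype trials,
where raw mean covariances are noisy; the source publication leaves its
estimator unstated, so this is a documented package choice. An optional
ridge (config `ridge`, default 0) handles ill-conditioned $G$; a
condition number above 1e10 without ridge is an error, not a silent
pseudo-inverse.

**The combined "balanced genotype" ranking** averages the rank of each
genotype over all supplied components (AMMI stability rank and HMRPGV
rank for the dehull-adjusted yield and each mineral nutritional yield,
plus EMI and BDGI ranks — 12 components in the full report), ties broken
by name. Mean rank was preferred over rank products or vote counting for
transparency; the published synthesis is qualitative, so any monotone
aggregation is defensible and this one is the simplest to audit.

## The synthetic generator

`generate_met()` is the generative twin of the AMMI model:
$y_{ijr} = \mu + g_i + e_j + Z_{ij} + \varepsilon_{ijr}$ with $g$ and $e$
drawn Gaussian and recentred to exact zero sum, and $Z = \sum_k \lambda_k
\alpha_k \gamma_k^\top$ built from Gaussian score vectors that are
centred and then orthonormalised by QR — so the interaction has exactly
the requested singular values, exactly zero row and column sums, and the
decomposition tests have algebraic truth to recover. Because the rows of
$Z$ sum to zero, the interaction contributes nothing to genotype means;
the moment-recovery test therefore checks that the variance of genotype
means matches $\sigma_g^2 + \sigma_\varepsilon^2/(er)$.

Concentrations follow a dilution law, $C = \mathrm{base}\cdot(\mu /
\mathbb{E}[y_{ij}])^{\delta}(1+\eta)$ with multiplicative Gaussian noise
of CV `conc_cv`, floored at zero: higher-yielding cells get lower
concentrations, reproducing the negative yield-concentration coupling of
real wheat. Defaults emulate the published trial's conditions: 19
genotypes, 3 year-environments, 2 replicates, mean yield 3960 kg ha$^{-1}$
(the trial's overall mean), genotype/environment/plot SDs of 700/600/450
kg ha$^{-1}$ and one interaction axis of 900 kg ha$^{-1}$ (together
consistent with the printed per-genotype SDs of roughly 1000–1800 over
years and replicates), base concentrations at the trial's population
means (43/36/5.3/1200 mg kg$^{-1}$), and 4 of 19 genotypes hulled.

What the generator does **not** emulate: spatial field trend, weather
covariates, missing plots, genotype-specific dilution exponents, and
mineral-mineral correlations beyond those induced by yield. Passing
recovery tests on this generator therefore validates the estimators'
algebra and calibration, not their robustness to field artefacts.

## The worked example

`worked_example()` rebuilds a plot-level dataset from the published
summaries so the whole pipeline has an end-to-end fixture: genotype mean
yields equal the printed three-year averages; mean concentrations equal
the printed wholemeal values for the six study genotypes and are
back-solved from printed nutritional yields otherwise (inverting the NY
formula); year effects are +500/−800/+300 kg ha$^{-1}$ (the middle season
was the poor one); the yield interaction is rank-one with the published
environment PC1 scores (42.60, −40.48, −2.12 — which sum to zero, as AMMI
environment scores must) and the published genotype PC1 scores where
available, modest alternating-sign values elsewhere. Replicate pairs sit
at cell $\times (1 \pm 0.01)$ for yield and $\times (1 \mp 0.02)$ for
concentrations — anti-phase, like dilution — so cell means are exact,
replicate variance is nonzero (keeping ANOVA and BLUP well defined) but
negligible, and genotype mean nutritional yields stay within 0.02% of
the printed products. The published plot-level spread is unknown; the
$\pm$1–2% choice is deliberately small so that every printed mean
survives, and it is a fixture property, not an estimate of field
variability.

On this fixture the pipeline's `report` command reproduces the published
qualitative findings: the four genotypes the source trial singles out as
"balanced" (Svale, Starke, Jacoby, Walde) land in the top six of the
combined ranking, and the BLUP orderings match the printed top ranks.

```{r, eval = FALSE}
res <- run_pipeline("report", input = worked_example(), out_dir = "out")
head(res$balanced)
```

## Degenerate inputs and numerical conventions

* Report tables round adults ha$^{-1}$ year$^{-1}$ and grams to the
  nearest integer, halves away from zero; all internal computation is
  full precision.
* All ranking ties break lexicographically by genotype name after the
  primary key, so every output is deterministic.
* An all-constant trait makes variance proportions undefined (flagged
  NA, not 0/0), zero-variance traits make correlations NA with a
  warning, and a residual variance of exactly zero is floored at a
  negligible positive value in the mixed-model equations to keep them
  nonsingular.
* CSV output writes numerics at 17 significant digits, so write-read
  round-trips are exact.

## Problem sizes used in validation

The test suite exercises matrices up to 30 $\times$ 5, Monte-Carlo
variance-component recovery over 200 seeded replicates of a 30-genotype,
5-environment, 2-replicate design (mean $\hat\sigma^2_g$ within 10% of
truth), and a 400-genotype single-purpose design for the independence of
genotypic covariances. These sizes give the stochastic checks comfortable
sampling margins while keeping the full suite in the tens of seconds.

## Known limitations

* Only complete (or mildly unbalanced, for EM-REML) layouts are
  supported; no imputation of missing G$\times$E cells.
* Environments are exchangeable labels; no weather or site covariates,
  and no spatial adjustment within trials.
* Mineral bioavailability (phytate binding of Fe/Zn) is outside the
  metric: nutritional yield counts milligrams produced, not absorbed.
* The printed AMMI variance-explained percentages of the source trial
  are not reproducible from published data (its two stated values also
  disagree with each other) and are deliberately not used as targets.
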