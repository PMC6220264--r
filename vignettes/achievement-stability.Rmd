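---
title: "Modelling the developmental stability of polygenic traits with twinpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the developmental stability of polygenic traits with twinpath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinpath)
```

## The scientific problem

A trait like school achievement is measured repeatedly across development
and is strikingly stable from age to age. The question this package
addresses is *why*: how much of that stability is carried by genetic
influences that persist from one age to the next, how much by the family
environment, and how much genuinely new (innovative) influence arises at
each age? twinpath implements the two complementary designs used to answer
it — the classical twin design, which contrasts monozygotic (MZ) and
dizygotic (DZ) co-twin resemblance, and DNA-based methods (GRM/REML SNP
heritability and polygenic-score prediction) that require no family
structure at all — together with a synthetic-data module that generates
cohorts with exactly the covariance structure the models assume, so every
claim is reproducible as a parameter-recovery experiment.

## The twin models

All twin models share one chassis. For a vector of measures on a pair, the
implied covariance is the block matrix

$$\Sigma_z \;=\; \begin{pmatrix} \Sigma_A + \Sigma_C + \Sigma_E &
w_z\,\Sigma_A + \Sigma_C \\ w_z\,\Sigma_A + \Sigma_C &
\Sigma_A + \Sigma_C + \Sigma_E \end{pmatrix},$$

with $w_{MZ} = 1$ and $w_{DZ} = 0.5$: MZ co-twins share all their genes, DZ
co-twins on average half of their segregating genes, both share their
family environment (C) fully, and the non-shared environment (E) never
crosses twins. The models differ only in how $\Sigma_A, \Sigma_C, \Sigma_E$
are built from path coefficients:

* **Univariate ACE** — scalars $a^2, c^2, e^2$. The correlation-based
  shortcut (Falconer's formula, `falconer_estimates()`) gives
  $a^2 = 2(r_{MZ} - r_{DZ})$, $c^2 = r_{MZ} - a^2$, $e^2 = 1 - r_{MZ}$ and
  is used to seed the optimizer.
* **Cholesky** (`fit_cholesky()`) — each component is $LL^\top$ with $L$
  lower triangular, the saturated multivariate decomposition. For two
  measures the genetic correlation is
  $r_G = \Sigma_A[1,2]/\sqrt{\Sigma_A[1,1]\Sigma_A[2,2]}$ and the share of
  the phenotypic correlation carried by A is
  $\Sigma_A[1,2]/\Sigma_P[1,2]$; the A, C and E shares sum to one.
* **Genetic simplex** (`fit_simplex()`) — each component follows a latent
  first-order autoregression across occasions: an initial standard
  deviation, transmission paths $\beta_t$ between adjacent occasions,
  innovation standard deviations at occasions $2..T$, and occasion-specific
  standard deviations at interior occasions. The proportion of occasion
  $t$'s heritability transmitted from occasion $t{-}1$ is
  $h^2_{t-1}\beta_{t-1}^2 / h^2_t$ (`transmitted_share()`); the innovative
  proportion is $(\text{innovation}^2 + \text{specific}^2)/h^2_t$
  (`innovation_share()`).
* **Common pathway** (`fit_common_pathway()`) — one latent factor with unit
  variance, itself split into A, C and E (squared latent paths summing to
  1), loads on every occasion; each occasion's residual gets its own ACE
  decomposition. The latent heritability is the headline "how genetic is
  the stability" quantity.

### Estimation

Fitting works on the per-zygosity sample covariances of the stacked pair
vector, computed from complete-case pairs with the maximum-likelihood
divisor $n$, under the multi-group normal (Wishart) deviance
$\sum_z n_z\left(p\log 2\pi + \log|\Sigma_z| +
\mathrm{tr}(S_z\Sigma_z^{-1})\right)$. This attains the saturated value
exactly when the implied covariance reproduces the sample covariance, which
gives the package its sharpest self-checks: fitting on noiseless implied
covariances must return the generating parameters. Complete-case Wishart
fitting (rather than raw-data FIML) keeps the likelihood auditable; the
composites this design targets have little missingness, and FIML is out of
scope.

Numerical choices that matter:

* **Path parameterization.** Variances enter only as squares, so every
  implied covariance is positive semi-definite without box constraints and
  Heywood-style negative residuals cannot occur. Signs of
  standard-deviation-like paths are fixed non-negative after optimization
  (they are not identified); transmission paths keep their sign.
* **Optimizer.** BFGS on the deviance scaled per pair, from a
  moment-informed start (per-occasion Falconer components, lag-1
  phenotypic regressions, or the leading principal axis for the common
  pathway) plus jittered random restarts (10 by default; the jitter uses
  its own seed and restores the caller's RNG state). A non-positive-definite
  implied covariance — possible only at degenerate parameter values — is
  penalized smoothly rather than made fatal, which keeps the search inside
  the feasible region.
* **Convergence declaration.** The engine reports the finite-difference
  gradient norm of the per-pair deviance and the spread between the best
  restarts. A fit is flagged converged when the scaled gradient norm is
  below 1e-4; a norm above 0.05 raises an error carrying the restart
  trace. The per-pair scaling is deliberate: on the raw deviance (magnitude
  $10^4$–$10^5$ at realistic sizes) a fixed absolute gradient threshold
  would sit below floating-point noise.
* **Identification of the simplex.** Measurement loadings are fixed at 1.
  Occasion-specific paths are fixed to zero at the first occasion (they are
  confounded with the initial variance) and the last occasion (confounded
  with the final innovation). By default occasion-specific paths are freed
  only for A: for a component whose transmission is near zero — the
  generating truth for E here — occasion-specific and innovation variance
  are empirically indistinguishable and freeing both puts the optimizer on
  a ridge. The `specific` argument frees them for C or E when a dataset
  warrants it. E is modelled with free transmission paths; the model is
  allowed to *discover* that non-shared environment is occasion-specific
  rather than assuming it.
* **Identification of the common pathway.** Internally the first loading is
  fixed to 1 and the latent scale is free; reported latent components are
  standardized, reproducing the unit-latent-variance convention exactly
  (the reported latent $a^2 + c^2 + e^2 = 1$ by construction).
* **Shares near a vanishing denominator.** Bivariate component shares are
  reported as flagged `NaN` when the phenotypic correlation is below 0.05,
  and occasion-level genetic shares as `NaN` when the occasion's genetic
  variance is numerically zero, rather than dividing by a near-zero
  number.

Confidence intervals come in two grades: Wald intervals from the inverse
Hessian are attached to every fit (cheap, adequate for well-conditioned
parameters), and `likelihood_ci()` computes profile-likelihood bounds —
the points where the profiled deviance rises by the $\chi^2_1$ critical
value (3.84 at 95%) — on demand, with an expanding search and a flagged
one-sided interval when a bound is not bracketed. Model comparison is by
likelihood ratio (`compare_models()`); a negative statistic beyond
numerical slack is treated as an optimization failure, not a result.
Note one boundary subtlety: because variance-like paths enter squared,
testing a truly-zero component produces a 50:50 mixture of 0 and
$\chi^2_1$ for the statistic, so null p-values are stochastically larger
than uniform while small p-values keep (slightly less than) their nominal
rate — the conservative direction.

## The phenotype preparation

`residualize()` rescoring as standardized OLS residuals on age and sex
comes first (co-twins are identical in age and MZ co-twins in sex, so mean
effects would masquerade as shared environment); coefficients can be
estimated on one randomly chosen twin per pair and applied to both
(`preprocess_twin_measures()`), so families are not double-counted.
Skew correction follows, after residualization: `vdw_transform()` maps the
value of rank $r$ among $n$ to the normal quantile at $r/(n+1)$; ties take
their mid-rank (a documented choice — the convention is not dictated by
the method), which keeps the output invariant to any strictly monotone
transformation of the input. `composite_mean()` averages standardized
components using whatever sources are available per individual, and
`variance_explained_by_groups()` reports the sex-by-zygosity eta-squared
that justifies pooling the groups. Standardization is across the whole
sample, not within zygosity groups. `regress_out_g()` partials a general
cognitive ability composite out of each measure when the question is
achievement beyond intelligence.

## The DNA-based methods

`compute_grm()` builds the GCTA-convention relatedness matrix
$G_{ij} = \tfrac1m\sum_k (x_{ik}-2p_k)(x_{jk}-2p_k)/(2p_k(1-p_k))$ with
sample allele frequencies (the GCTA default), mean-imputing missing
dosages and excluding monomorphic SNPs. `reml_fit()` estimates
$\sigma^2_g, \sigma^2_e$ in $y = X\beta + g + \varepsilon$,
$g \sim N(0, G\sigma^2_g)$, by average-information REML: one
eigendecomposition of $G$ diagonalizes every weight matrix, making each
iteration $O(n^2)$; AI proposals that leave the parameter space are
clamped to a small floor (a variance heading negative is a boundary
solution, where EM crawls), proposals that worsen the restricted
likelihood are halved back toward the current point, and an EM step is the
last resort; starting values are $\sigma^2_g = \sigma^2_e =
\mathrm{var}(y)/2$ and convergence is declared when the restricted
log-likelihood moves by less than 1e-6. Standard errors come from the
inverse AI matrix, with the delta method for $h^2_{SNP}$. An identity-like
GRM makes the two components non-identifiable and is rejected explicitly.

`prune_related()` removes one member of every pair above a relatedness
cutoff (default 0.025, roughly fifth cousins), scanning pairs in id order
and dropping the later member — deterministic given the ordering. One
desk-scale caveat deserves emphasis: with $m$ SNPs the off-diagonal noise
of a GRM has standard deviation $\approx 1/\sqrt m$. At the panel sizes
used here ($m = 5000$) that is 0.014, so the fifth-cousin cutoff sits
within the noise and would prune most of an entirely unrelated cohort;
with the hundreds of thousands of SNPs of a real array the same cutoff is
~20 noise standard deviations and removes only real relatives. The
recovery experiments therefore run REML on the unpruned simulated panel,
whose individuals are unrelated by construction; pruning has its own
tests.

`grm_pca()` supplies the standard ancestry covariates (top eigenvectors
scaled by root eigenvalues), `polygenic_score()` forms standardized
weighted dosage sums with effect-allele matching and flipping, and
`incremental_r2()` / `age_specific_gps_r2()` measure what a score adds
beyond a baseline — ancestry components alone, or ancestry components plus
achievement at all earlier ages.

## What the generators emulate — and what they do not

`simulate_ace()`, `simulate_simplex()` and `simulate_common_pathway()` draw
latent A/C/E scores directly (innovations shared between MZ co-twins,
correlated 0.5 for DZ co-twins via a common/segregating split, C fully
shared, E independent). Every model here is linear in its innovations, so
the population pair covariance equals the implied covariance exactly —
faster than simulating genotypes and exact by construction. DZ
opposite-sex pairs are generated identically to same-sex DZ pairs and
pooled in analysis. Phenotypes can be emitted with arbitrary mean and
scale so the preparation step has real work to do, and an optional
missing-at-random rate is exposed (no claim is made that it matches any
particular cohort's missingness pattern, which is not public).

The default generating regimes encode the study conditions the package's
recovery experiments target: a four-occasion achievement series with
genetic transmission paths 0.86/0.84/0.86, heritabilities
0.73/0.70/0.63/0.58 (a 3% occasion-specific genetic share at the third
occasion), a shared environment holding a stable 20%, and a purely
occasion-specific non-shared environment; a common-pathway regime with
latent ACE = (0.70, 0.24, 0.06); genotype panels in Hardy–Weinberg
equilibrium with frequencies uniform on [0.05, 0.5] and
$h^2_{SNP} = 0.30$; and a polygenic-score cohort whose score explains
4/6/8/10% of variance across the four ages. One arithmetic note: the
conventional transmitted-share formula $h^2_{prev}\beta^2/h^2_{curr}$
treats all of the previous occasion's heritability as transmissible,
whereas in a simplex the occasion-specific part does not transmit; the
standalone share functions reproduce the conventional arithmetic, while
fit-derived shares use the exact model decomposition (the difference is a
few percent here).

In the polygenic-score cohort each achievement variable is
$\sqrt{R^2_t}\,s + \sqrt{0.78}\,u + \varepsilon_t$ with one fixed score
$s$ and one stable factor $u$. The stable variance 0.78 was chosen by a
closed-form calculation at design time: it puts the age-to-age
correlations at 0.80–0.85 (the upper end of the published range) and the
population age-specific increment of the score beyond all earlier ages at
0.006–0.007 — comfortably inside the "below 1%" regime the construction
is meant to exhibit. With three earlier ages as imperfect proxies the
increment can never be exactly zero; high stability is what drives it
down.

What the generators deliberately omit: linkage disequilibrium between
SNPs, assortative mating (the DZ genetic weight stays at 0.5, which makes
twin heritability conservative rather than inflated), dominance,
gene–environment interaction, selection and attrition, rater and
measurement-reliability structure, and realistic missingness patterns.
Passing recovery tests therefore shows that the estimators are correct and
well-calibrated *under the models' own assumptions* — not that real
cohort data satisfy those assumptions.

## Problem sizes and runtime posture

The recovery experiments use the sizes at which the parameters of interest
are estimated with useful precision on a single CPU: 10000 MZ + 10000 DZ
pairs for the simplex and common-pathway recoveries (Monte-Carlo SE of a
transmission path ≈ 0.01), 5000 + 5000 pairs for the univariate regime,
n = 2000 individuals × m = 5000 SNPs for GREML (SE of $h^2_{SNP}$ ≈ 0.05,
with 20 replicates for the bias check), and n = 6000 for the
polygenic-score schedule. Property-style checks (bias across replicates,
profile-CI coverage, likelihood-ratio calibration) run at reduced
replicate counts sized so their own Monte-Carlo error stays well inside
the asserted bounds.

## Known limitations

* Complete-case Wishart fitting discards pairs with any missing occasion;
  with substantial non-random missingness a FIML treatment would be
  needed.
* Wald intervals can be poor for variance-like paths near zero; use
  `likelihood_ci()` there (the package does not automate the choice).
* The simplex identification scheme (specifics for A at interior occasions
  only, by default) is a documented choice among observationally similar
  alternatives; the exact residual topology of a given dataset may warrant
  freeing other specifics.
* Sex-limitation (five-group) models, dominance, bivariate GREML, LD-aware
  polygenic weight construction, and genotype QC/imputation are out of
  scope; polygenic weights are consumed, never derived.
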