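---
title: "Longitudinal twin modeling of hormone levels and grey-matter density"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal twin modeling of hormone levels and grey-matter density}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pubertwin)
```

## The scientific problem

During puberty, circulating hormone levels rise while cortical grey-matter
density falls. If the two processes are coupled, the coupling can arise from
genes that influence both phenotypes (genetic pleiotropy), from environmental
factors shared by children growing up in the same family, or from
environmental factors unique to one individual. Twin cohorts measured at two
occasions can separate these routes: monozygotic (MZ) co-twins share all
segregating genes, dizygotic (DZ) co-twins on average half, and both share
the family environment. If the cross-twin cross-trait correlation (e.g.
density of twin 1 with hormone level of twin 2) is larger in MZ than in DZ
pairs, a genetic component links the traits; if it is more than half the MZ
value, a common-environment component; and a correlation present only within
persons points to the unique environment.

`pubertwin` implements this design as a reusable pipeline: a four-phenotype
structural twin model fitted per voxel of a grey-matter density map, with a
hormone preprocessing stage, latent-change algebra, equality-constrained
refits with likelihood-ratio tests, false-discovery-rate control across
voxels, and a synthetic cohort generator with known ground truth against
which every stage is validated.

## The structural model

The four phenotypes are ordered 1 = hormone at age 9, 2 = density at age 9,
3 = hormone at age 12, 4 = density at age 12. Each phenotype $i$ loads on
its own additive-genetic (A), common-environment (C) and unique-environment
(E) factor with paths $a_i$, $c_i$, $e_i$; same-kind factors correlate
across phenotypes through correlation matrices $R_g$, $R_c$, $R_e$. Across
the two members of a pair, A factors correlate 1 (MZ) or 0.5 (DZ), C factors
correlate 1 by definition, and E factors are uncorrelated. The implied
covariance of the stacked 8-vector of a pair is

$$\Sigma = \begin{pmatrix} A + C + E & r_z A + C \\ r_z A + C & A + C + E
\end{pmatrix},\qquad A = \mathrm{diag}(a)\,R_g\,\mathrm{diag}(a),$$

and likewise for $C$ and $E$ (`expected_cov()`).

### Latent change

Change is never computed per subject — with longitudinal dropout many
subjects have only one occasion. Instead all change quantities are functions
of the fitted parameters. The latent density-change variance is

$$V_{chGM} = a_2^2+c_2^2+e_2^2+a_4^2+c_4^2+e_4^2
  - 2\,(a_2 r_{g(2,4)} a_4 + c_2 r_{c(2,4)} c_4 + e_2 r_{e(2,4)} e_4),$$

$V_{chH}$ analogously over phenotypes (1, 3), and the change-change
covariance expands over the four cross-trait covariances
$(3,4) + (1,2) - (1,4) - (2,3)$, each split over A, C and E
(`change_variance()`, `change_covariance()`). The correlation
$r_{ch} = \mathrm{Cov}_{ch} / \sqrt{V_{chGM} V_{chH}}$ decomposes into
`rph_a`, `rph_c` and `rph_e` — the correlation that would be observed if
only that factor kind linked the traits — which sum exactly to $r_{ch}$
(`rph_decomposition()`). The same decomposition applies to the cross-trait
covariance at age 12, and a reduced bivariate age-12-only model
(`fit_bivariate_age12()`) re-uses the whole machinery with two phenotypes.

### Estimation

Families contribute the multivariate-normal log-density of exactly the
phenotypes they were observed on (full-information maximum likelihood), so
singleton co-twins, occasion-2 dropouts and below-detection-limit hormone
values all stay in the analysis; FIML is consistent under missing-completely-
at-random and missing-at-random dropout. Internally families are grouped by
(zygosity, missingness pattern); each group shares one observed submatrix of
$\Sigma$, and without an age covariate the group likelihood depends on the
data only through its sufficient statistics (n, mean, centered scatter), so
an evaluation costs the same for 40 or 4000 families. The objective and its
analytic gradient are compiled (RcppArmadillo).

Two parameterizations are in play. Results are reported in the
correlated-factor form above (paths plus factor correlations), which is what
the change algebra consumes. Optimization, however, runs over the Cholesky
factors of $A$, $C$ and $E$: the component matrices then stay positive
semidefinite without box constraints, the map has no coordinate
singularities (a spherical-angle parameterization of the correlation
matrices degenerates when a path approaches zero), and every supported
equality constraint is $\mathrm{tr}(W\,G G^\top)$ in a Cholesky factor $G$
with the simple gradient $2WG$. The two parameterizations cover the same
model space; `e_i > 0` is enforced at reporting time.

Constraints (`change_corr_zero`, `cross_trait_age12_zero`, and the
component-zeroing `rph_a/c/e_zero`) are nonlinear equalities handled by an
augmented Lagrangian: multiplier updates at moderate penalty, penalty growth
only when the violation stalls, accepted when $|g| < 10^{-8}$. The
change-correlation-zero hypothesis is imposed on the change covariance,
which defines the same null whenever the change variances are positive and
is much better conditioned than the ratio. Minus twice the log-likelihood
difference between nested fits is referred to $\chi^2$ with one degree of
freedom per constraint (`lrt()`). Variance components may sit on the
boundary of the parameter space; p-values are reported from the nominal
$\chi^2_1$ reference (the usual practice), which is conservative for
boundary hypotheses — the caveat applies to variance-component tests, not to
the correlation constraints tested here, whose nulls are interior.

Starting values come from per-zygosity moment estimates
($\hat A = 2(X_{MZ}-X_{DZ})$, $\hat C = 2X_{DZ}-X_{MZ}$,
$\hat E = W - \hat A - \hat C$, eigenvalue-clipped so the starting pair
covariance is well conditioned); `fit_ace()` adds seeded random restarts
(default 5, best converged likelihood wins, ties broken by parameter norm).
In voxel-wise scans the moment start alone converged in 100% of piloted
voxels, so `voxelwise_scan()` defaults to one start per voxel; restart seeds
derive from the master seed plus the voxel index, so results are identical
regardless of processing order.

## Hormone preprocessing

Urinary hormone levels are divided by the same sample's creatinine
concentration, correcting for urine dilution; salivary hormones pass through
unchanged (`normalize_creatinine()`). The two sampling days of an occasion
are averaged when both are usable; a day below the assay detection limit is
treated as missing, and a child below the limit on both days is missing for
that occasion — the conservative choice, handled downstream by FIML. An
optional mode substitutes $\mathrm{limit}/\sqrt{2}$ per flagged day instead
(off by default). Analyses run on the natural log of the combined value;
the base only rescales paths, leaving correlations and likelihood ratios
unchanged. The one-day-only rule is applied after creatinine correction
(the corrected scale is the analysis scale). `mardia_test()` checks
multivariate normality of the transformed phenotypes via Mardia's
multivariate skewness ($n b_{1,p}/6 \sim \chi^2_{p(p+1)(p+2)/6}$) and
kurtosis ($b_{2,p}$ asymptotically normal with mean $p(p+2)$ and variance
$8p(p+2)/n$, two-sided).

## Voxel-wise analysis

`voxelwise_scan()` fits the full and constrained model in every in-mask
voxel and records the likelihood-ratio statistic, the fitted correlation and
its rph decomposition; non-converged voxels are flagged and excluded from
the multiple-testing pool (reducing m), never silently dropped.
`fdr_threshold()` is the Benjamini–Hochberg step-up rule with constant
$c(V)=1$ (the form recommended for imaging data; the conservative
$c(V)=\sum 1/i$ variant is a flag), reporting the largest rejected p and the
matching critical $\chi^2_1$ deviate. `summarize_significant()` answers the
"driven by" question: within the significant set, each component-zeroing
constraint is refitted per voxel and given its own FDR pass; a voxel is
attributed to a component whose zeroing test survives, and to
"undetermined" when none does. Clusters are reported by 6-connectivity.

## The synthetic cohort generator

No subject-level data are released with the study this package emulates, so
the generator is the test bed. Its defaults are the study conditions of the
female stratum: 21 complete MZ and 16 complete DZ pairs plus 1 MZ and 24 DZ
singleton co-twins (opposite-sex pair members enter the sex-stratified
analysis as incomplete pairs), occasion-2 dropout of $1 - 125/190 \approx
0.34$ (missing completely at random), family ages $\mathcal N(9.2, 0.11^2)$
and a 2.9-year follow-up interval, and an assay detection limit of 0.11 on
the raw scale. Hormone observables are built as
$\exp(\text{latent} + \text{assay noise}) \times \text{creatinine}$ per day
— so the observed scale is log-normal (left-concentrated, long upper tail)
and the preprocessing pipeline's creatinine correction, two-day averaging
and log transform exactly undo the construction up to assay noise.

Where the study reports no value, magnitudes were fixed once at
field-typical levels and not revisited: variance shares $a^2/c^2/e^2 =
0.5/0.2/0.3$ for all four phenotypes; longitudinal factor correlations 0.8
(A), 0.9 (C), 0.2 (E); per-day assay noise sd 0.2 on the log scale;
creatinine log-normal$(\log 8, 0.4)$ mmol/l; smoothing FWHM 3 voxels. The
default hormone–density coupling is unique-environmental with cross-trait
correlation 0.6 at both ages, which implies a latent-change correlation of
exactly 0.5 — a strong, detectable signal appropriate for power checks; a
common-environment variant (`default_path_model("c")`) and a fully null
variant (`"none"`) are provided.

Spatially, only the unique-environment voxel field is smooth: per
individual-occasion a white-noise field is convolved (circularly, via FFT)
with a Gaussian kernel and normalized to unit variance, with the
across-occasion E correlation imposed between the two fields. Voxels inside
the signal cluster all carry the coupled density phenotype (the coupling
paths are active there and nowhere else); outside, the genetic and
common-environment factor values are drawn independently per voxel from the
uncoupled marginal density model. An earlier construction that shared one
uncoupled A/C draw across all non-cluster voxels was rejected: a single
2-dimensional random variable common to a thousand voxels makes every null
voxel inherit the same cohort-level sampling fluctuation, grossly inflating
the within-cohort false-positive rate even though each voxel's test is
marginally calibrated.

What the generator does **not** emulate: real T1 acquisition, segmentation
and warping (density maps are generated directly); spatial autocorrelation
of the genetic and common-environment signal between neighbouring voxels;
sex differences and opposite-sex pair modeling; menstrual-cycle variation;
and assay reliability that degrades near the detection limit. Passing tests
therefore demonstrate correctness of the statistical machinery under the
stated generative assumptions, not robustness to registration error or
assay artefacts in real data.

## Numerical choices and problem sizes

- Optimizer: BFGS with analytic gradients, relative tolerance $10^{-10}$,
  up to 500 iterations per (inner) solve; augmented-Lagrangian constraint
  tolerance $10^{-8}$.
- A fitted change variance below $10^{-10}$ makes the change correlation and
  its components undefined (`NA`), never infinite.
- Degenerate inputs error early and informatively: non-PSD correlation
  matrices, non-positive creatinine or hormone values, singular observed
  submatrices (named by family), grid/mask mismatches, empty p-value pools.
- Validation problem sizes were chosen so the whole suite runs on one CPU in
  tens of minutes: covariance-algebra and rph identities over 1000 random
  models at $10^{-12}$/$10^{-10}$; generative agreement over 10 models
  $\times$ $10^6$ pair draws; parameter recovery over 20 replicates of
  500 MZ + 500 DZ pairs (mean absolute error of variance shares < 0.1);
  null calibration of the change-correlation test over 200 replicates of
  200 + 200 pairs; and end-to-end cluster recovery over 10 seeds of a
  $10\times10\times10$ grid with a planted $3\times3\times3$
  unique-environment cluster at 300 + 300 pairs.

## Known limitations

- No sex-limitation or opposite-sex pair model, no dominance (ADE) models.
- Attribution percentages depend on power: with small significant sets the
  per-component FDR pass is conservative and "undetermined" grows, matching
  the behaviour such analyses show on real cohorts.
- The $\chi^2_1$ reference for boundary (variance-component) hypotheses is
  conservative; the package reports nominal p-values and documents the
  mixture caveat rather than implementing mixture references.
- Voxel fits are embarrassingly parallel but executed serially; the
  per-voxel seeding contract means a parallel driver would give bit-identical
  results.
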