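# pubertwin

Longitudinal bivariate twin modeling of pubertal hormone levels and
voxel-wise grey-matter density.

## What this package is for

In twin cohorts scanned and sampled at two occasions (here: ages 9 and 12),
one can ask not only *whether* changes in a hormone track changes in
grey-matter density, but *why*: through genes that influence both traits,
through the environment shared by a family, or through experiences unique to
one child. `pubertwin` implements the full analysis stack for that question
for researchers in behaviour genetics and developmental neuroimaging:

- a four-phenotype correlated-factor **ACE structural model** (hormone and
  density at both ages) for monozygotic/dizygotic twin pairs, estimated by
  **full-information maximum likelihood** so singleton co-twins, dropouts
  and below-detection-limit assays stay in the analysis;
- **latent-change algebra**: change variances, the change–change covariance
  and correlation, and its decomposition into genetic (`rph-a`),
  common-environment (`rph-c`) and unique-environment (`rph-e`) parts;
- **equality-constrained refits and likelihood-ratio tests** (zero change
  correlation, zero age-12 cross-trait covariance, component zeroing);
- a **voxel-wise driver** with Benjamini–Hochberg FDR control, critical-χ²
  reporting, component attribution and cluster listing, reading/writing
  NIfTI maps;
- **hormone preprocessing**: creatinine correction, two-day averaging with
  detection-limit flags, log transform, and Mardia's multivariate normality
  test;
- a **synthetic twin-cohort generator** with known ground truth, emulating
  the study conditions (pair counts, longitudinal dropout, log-normal
  assay scale with censoring, smooth voxel maps with a planted coupling
  cluster), against which every stage is validated.

## The model in brief

Phenotypes are ordered 1 = hormone age 9, 2 = density age 9, 3 = hormone
age 12, 4 = density age 12. Each loads on its own A, C and E factor with
paths *a*, *c*, *e*; same-kind factors correlate across phenotypes via
R_g, R_c, R_e. Across co-twins, A correlates 1 (MZ) / 0.5 (DZ), C correlates
1, E does not. The pair covariance is `[[A+C+E, rz·A+C], [rz·A+C, A+C+E]]`
with `A = diag(a)·R_g·diag(a)` etc. The latent density-change variance is

    V_chGM = Var(2) + Var(4) − 2(a2·rg(2,4)·a4 + c2·rc(2,4)·c4 + e2·re(2,4)·e4)

(hormone analogously over (1,3)), the change covariance is the cross-trait
sum (3,4) + (1,2) − (1,4) − (2,3) expanded over A/C/E, and
`rph-a + rph-c + rph-e = r_ch` exactly. See the vignette
(`vignettes/longitudinal-twin-modeling.Rmd`) for the estimation details.

## Worked example

Simulate a 300 + 300-pair cohort on a 4×4×4 grid with a planted 2×2×2
unique-environment coupling cluster (generative change correlation 0.5),
prepare the hormone phenotype, fit the longitudinal model, test the change
correlation, and run the voxel-wise scan:

```r
library(pubertwin)

cfg <- simulation_config(n_mz_pairs = 300, n_dz_pairs = 300,
                         n_mz_singletons = 0, n_dz_singletons = 0,
                         grid_shape = c(4, 4, 4),
                         signal_cluster = central_cluster(c(4, 4, 4), 2),
                         rng_seed = 2026)
cohort <- prepare_hormone(simulate_cohort(cfg))

fit <- fit_ace(twin_phenotypes(cohort))
null_fit <- fit_ace(twin_phenotypes(cohort), "change_corr_zero",
                    start = fit$theta, n_starts = 1)
lrt(fit, null_fit)
rph_decomposition(fit$model, "change")

map <- voxelwise_scan(cohort, "change_corr", seed = 1)
fdr <- map_fdr(map, alpha = 0.05)
summarize_significant(map, fdr, cohort)
```

Output (abridged):

```
ACE FIML fit: 4 phenotypes, 600 families, loglik -4775.070 (converged)
     hormone_occ1 density_occ1 hormone_occ2 density_occ2
a2          0.510        0.459        0.502        0.537
c2          0.205        0.286        0.243        0.178
e2          0.333        0.311        0.314        0.304

LRT: chi2 = 198.9476, df = 1, p = 3.544e-45

Correlation decomposition (change)
  r = 0.4996  (rph-a -0.0335 + rph-c 0.0813 + rph-e 0.4518)
  V_chGM = 0.7710  V_chH = 0.7430  Cov = 0.3781

FDR 0.05: 9 / 64 rejected; critical p = 0.002652, critical chi2(1) = 9.033
9 significant voxels, mean r = 0.456
  driven by: A 0%, C 0%, E 89%, undetermined 11%
  2 cluster(s), sizes: 8, 1
```

Reading this: the fitted variance shares recover the generating values
(a² = 0.5, c² = 0.2, e² = 0.3); the change correlation estimate 0.50 matches
the generative 0.5 and is carried almost entirely by the unique-environment
component (rph-e = 0.45), exactly as planted; the likelihood-ratio test
rejects a zero change correlation overwhelmingly; and the voxel scan
recovers 8 of the 8 planted cluster voxels (plus one false positive,
consistent with FDR 0.05), attributing the association to the unique
environment in 89% of significant voxels.

A command-line driver mirroring the pipeline
(`simulate | prep | scan | report`) is installed at
`inst/cli/pubertwin.R`:

```sh
Rscript inst/cli/pubertwin.R simulate --config cfg.yaml --out cohort_dir
Rscript inst/cli/pubertwin.R prep     --cohort cohort_dir
Rscript inst/cli/pubertwin.R scan     --cohort cohort_dir --hypothesis change_corr --seed 1 --out maps
Rscript inst/cli/pubertwin.R report   --cohort cohort_dir --maps maps
```

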