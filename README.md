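# asrpath

Comparative analysis of sex-determination systems, sex-biased demography,
and adult sex ratios in tetrapods.

## The problem

Adult sex ratios (ASR, the proportion of males among adults) vary widely
across amphibians, reptiles, birds, and mammals, and species with ZW/ZZ sex
chromosomes tend to be more male-skewed than XX/XY species. `asrpath`
implements the full statistical pipeline for asking *which demographic
pathway* — birth sex ratio, sex-biased juvenile or adult mortality
(log10 male/female annual mortality), or sex-biased maturation age — links
the genetic sex-determination (GSD) system to ASR, while controlling for
phylogeny:

- **Phylogenetic GLS with ML Pagel's λ.** The model is
  *y = Xβ + ε*, ε ~ N(0, σ²[λC + (1−λ)diag(C)]), with C the Brownian-motion
  covariance of the tree and λ̂ maximizing the profile likelihood on [0, 1].
  On z-scored variables a GSD coefficient reads as a Cohen's *d* and a
  trait slope as a correlation-scale effect. Type-3 marginal F-tests and
  per-group slopes cover the GSD × trait interaction models; quadratic
  refits and a simulation power analysis round out the bivariate layer.
- **Confirmatory d-separation path analysis** over the eight-model DAG set
  on {GSD, JMB, AMB, MAT, ASR}: basis sets under both published
  conventions (per-variable λ-rescaled independent contrasts, and pairwise
  PGLS), Fisher's C = −2Σln pᵢ with χ²(2k) fit tests, AICc/CICc ranking via
  C + 2qn/(n−1−q), nested likelihood-ratio tests, and bootstrap
  standardized path coefficients.
- **Mk models and stochastic character mapping** for the binary XY/ZW
  character: ER/ARD pruning likelihoods, AIC comparison, and exact
  (uniformization-based, seed-reproducible) character histories with
  directional transition counts.
- **A synthetic-data generator** whose `"paperlike"` preset reproduces the
  study regime (453 tips, ≈17 character transitions, trait λ ≈ 0.3,
  path-coefficient magnitudes of the best-supported model, missingness
  leaving ≈95 complete cases), so the whole pipeline is testable without
  the original data.

It is aimed at comparative biologists who want these analyses as ordinary
R model objects (`fit_pgls()`, `fit_mk()`, `dsep()` with `print`,
`summary`, `coef`, `predict`, `simulate`, `residuals` methods) rather than
as a fixed script.

## Worked example

```r
library(asrpath)

sim <- simulate_dataset(generator_config("small", n_tips = 120, seed = 7))
tab <- standardize_traits(sim$table)
tab$gsd <- factor(tab$gsd, levels = c("XY", "ZW"))

fit <- fit_pgls(asr_z ~ gsd, tab, tree = sim$tree)
summary(fit)
#> Phylogenetic GLS: asr_z ~ gsd
#>
#>             Estimate Std. Error t value Pr(>|t|)
#> (Intercept)  -0.9790     0.2603  -3.761 0.000265 ***
#> gsdZW         1.3914     0.1955   7.116 9.31e-11 ***
#>
#> Pagel's lambda: 0.4315 (ML)
#> R2: 0.3003   n: 120   logLik: -119.013   AIC: 246.026
```

The `gsdZW` row says ZW species in this synthetic clade are about 1.4 SD
more male-skewed in ASR than XY species (the generator injects a positive
GSD→ASR path), with moderate phylogenetic signal (λ̂ = 0.43).

```r
pd <- as_path_data(sim$table)        # standardized path variables
tr <- prune_to(sim$tree, pd$species)
dsep(data = pd, tree = tr, style = "santos")
#> d-separation model comparison (santos flavour, n = 120)
#>  model k df     C        p  q   IC  dIC
#>   m1.b 2  4  3.62 0.460000  9 23.3  0.0
#>   m2.b 3  6  6.75 0.345000 12 33.7 10.4
#>   m3.b 3  6  6.75 0.345000 12 33.7 10.4
#>   m1.a 3  6 22.80 0.000852  8 40.1 16.9
#>   ...
```

The generating model (`m1.b`: GSD→AMB plus a direct GSD→ASR link and the
three demographic paths into ASR) fits (p = 0.46) and wins the AICc
ranking; dropping the direct link (`m1.a`) is firmly rejected.

```r
fit_path_coefficients(build_model_set()$m1.b, pd, tr, "hardenberg",
                      n_boot = 500, seed = 7)
#>   from  to   coef  lower   upper n_boot_used
#> 1  GSD AMB -0.525 -0.730 -0.3192         500
#> 2  AMB ASR -0.198 -0.311 -0.0848         500
#> 3  JMB ASR -0.306 -0.409 -0.2022         500
#> 4  MAT ASR -0.192 -0.290 -0.0937         500
#> 5  GSD ASR  0.593  0.473  0.7131         500
```

All five intervals cover the generating coefficients
(−0.5, −0.2, −0.25, −0.2, 0.6).

```r
states <- setNames(sim$table$gsd, sim$table$species)
ard <- fit_mk(sim$tree, states, "ARD")
stochastic_maps(ard, n_maps = 100, seed = 7)
#> Stochastic character maps: 100 maps
#> mean transitions: 8.29 (XY->ZW: 1.47, ZW->XY: 6.82)
```

The mapped mean (8.3 changes) sits right at this replicate's true
simulated count (8).

`run_full_analysis()` chains every stage (bivariate tables, interactions,
quadratic checks, power, both path-analysis flavours, simmap) and writes
TSV/JSON reports plus a `run.log`; `inst/scripts/run_pipeline.R` is a thin
command-line wrapper around it.

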