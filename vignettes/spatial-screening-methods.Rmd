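---
title: "Methods: spatial autocorrelation and spatial regression for district-level screening indicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial autocorrelation and spatial regression for district-level screening indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spareal)
```

## The problem

Health indicators aggregated over administrative areas — here, the
percentage of women screened for cervical or breast cancer per district —
are almost never spatially independent: neighboring districts share health
infrastructure, campaigns, and populations. Ordinary regression applied to
such data understates standard errors and misattributes spatially structured
variation to covariates. `spareal` implements the standard areal-data answer
to this problem: measure the autocorrelation (globally and locally), test
which kind of spatial process the OLS residuals suggest, and refit with a
spatial autoregressive model.

Because district-level microdata of the motivating kind are
access-restricted, the package is built *synthetic-first*: a generator
produces lattice "district maps" and attribute tables with known parameters,
and every statistical claim the package makes is validated by parameter
recovery, calibration, and oracle-equivalence tests on those synthetic
systems rather than on any bundled survey data.

## Spatial weights

Queen contiguity connects two units when their boundaries come within a
**snap distance** of one another, so shared edges and single shared corners
both count. The snap default is `1e-7` map units — effectively "exact
touching" up to floating-point noise in real shapefiles; it is a pure
topology rule, so coordinate reference systems are taken as given and never
reprojected. Contiguity is computed by bounding-box prefiltered
boundary-distance checks (point-to-segment distances in both directions),
which is exact for polygons whose shared boundaries include shared vertices —
true of lattices and of administrative boundary files, which are produced by
polygonization of common borders.

Weights default to **row-standardized** form for every statistic and model.
The tradition this workflow follows (GeoDa, spdep) row-standardizes by
default; it also gives the Moran statistic its usual bounds and makes the
autoregressive stationarity interval end at 1 (the Perron root of a
row-stochastic matrix). Binary weights remain available, and both styles are
serialized to the standard GAL text format with the style recorded in a
header comment.

**Islands** (units with no neighbors) are kept in the weights object with
empty rows, excluded from `S0`, given zero spatial lag and zero local Moran
(labeled NS), and reported loudly. They are removed only inside SEM/SLM
fitting — dropping areal units silently anywhere else would change n without
the analyst noticing. LM diagnostics refuse islands outright and instruct
removal, since their score formulas assume a complete weight matrix over the
fitted units.

## Global and local Moran

Global Moran's I is the weighted cross-product statistic
`(n/S0) Σ_ij w_ij z_i z_j / Σ z_i²`. Inference is by Monte-Carlo
permutation: the values are randomly reassigned to units, and the pseudo
p-value is `(M+1)/(R+1)` with R = 999 by default.

One genuinely open choice is the **tail convention**. The default is
one-sided *toward the observed direction* (the GeoDa convention): if the
observed I exceeds its null expectation `−1/(n−1)`, the upper tail is
counted, otherwise the lower. This is the convention practitioners see in
interactive tools, but it is worth being explicit that under complete
spatial randomness it rejects at about `2α` — the tail is chosen by the
data. The calibration property that a 5%-level test rejects 5% of the time
holds for the fixed-direction alternatives (`"greater"`, the natural test
for clustering in this domain, or `"two.sided"`); the package's calibration
tests therefore use `alternative = "greater"`, and analysts who need exact
size should too.

Local Moran is returned in the **scaled form** `I_i = (z_i/m2) Σ_j w_ij z_j`
as primary, so that `Σ_i I_i = S0 · I` holds exactly (this identity is
enforced by test); the unscaled z-form `z_i Σ w_ij z_j` is available by
flag. Quadrants (HH/LL/HL/LH) come from the signs of the centered value and
the centered lag — the Moran scatter-plot axes; values exactly at the mean
are classed "low", an arbitrary tie-break that only affects
measure-zero inputs. Inference is by **conditional permutation**: `z_i` is
held fixed and the remaining n−1 values are randomly assigned to its
neighbor positions. Each unit draws from its own seeded RNG substream, so
results do not depend on the order in which units are processed. No
multiple-testing correction is applied to the labels by default — raw
per-unit `p < α` is the field convention for these cluster maps — but an
FDR option exists. The consequence, worth repeating, is that a few percent
of units will be labeled significant under pure noise.

## OLS, diagnostics, spatial models

The OLS baseline uses QR least squares, classical t-based coefficient
tests, Gaussian ML log-likelihood (`σ̂² = e'e/n`), and VIFs from auxiliary
regressions. The five Lagrange-multiplier statistics (error, lag, robust
variants, SARMA) use the standard Rao-score forms with
`T = tr(W'W + WW)`; the additive identity
`SARMA = LM_err + RLM_lag = LM_lag + RLM_err` is verified numerically in
the tests. The studentized (Koenker) Breusch-Pagan statistic is `n·R²`
from regressing squared residuals on the design.

SEM (`ε = λWε + ξ`) and SLM (`y = ρWy + Xβ + ε`) are fitted by
**concentrated maximum likelihood**: for a trial spatial parameter p, form
`A = I − pW`, transform the data (SEM transforms both y and X, SLM only y),
profile out β and σ² by least squares, and add `log|A|` computed as
`Σ log(1 − p·ω_k)` over the eigenvalues of W. The eigendecomposition is
dense and exact — adequate to a few thousand units, which covers the
640-district scale this package targets by an order of magnitude; sparse or
approximate log-determinants are deliberately out of scope. The scalar
search runs `optimize()` to tolerance `1e-6` over the stationarity interval
`(1/ω_min + 1e-6, 1/ω_max − 1e-6)`; an estimate within `1e-4` of a boundary
sets `converged = FALSE` with a warning. Standard errors come from the
negative inverse numerical Hessian of the *full* log-likelihood in
(β, p, σ²); likelihood-ratio tests compare against the nested OLS fit
(λ = 0 reduces the SEM exactly to OLS, an identity the tests assert).

Two conventions the literature leaves open are fixed as follows and used
consistently: **AIC parameter counts** are #β + 1 for OLS (σ²) and #β + 2
for SEM/SLM (σ² plus the spatial parameter), with AIC ties broken toward
the simpler model; and **SEM "residuals" are the innovations**
`ξ̂ = (I − λ̂W)(y − Xβ̂)`. The innovations are what the model claims are
i.i.d., so they are what the declustering check must examine: the
generalized-least-squares residuals `y − Xβ̂` remain spatially filtered by
construction and would still show autocorrelation even in a perfectly
specified model. SLM residuals are `y − ρ̂Wy − Xβ̂`.

## The synthetic-data generator

The generator emulates the study system at three levels:

* **Geometry** — a rows × cols square lattice (default 20 × 32, n = 640,
  the district count of the emulated system). Lattices have no islands and
  a degree histogram of {3, 5, 8}; real district maps are irregular, have
  varying degree, and contain true islands, so island handling is tested
  separately on constructed geometries.
* **Covariates** — independent normals clipped to [0, 100], with default
  means/SDs set to the published district-level marginals of the emulated
  system (e.g. cervical screening 21.96 ± 14.62, rural 71.57 ± 21.66). The
  marginal for obesity is not published at district level; its spec
  (mean 20.6, SD 10) is a synthetic stand-in from national prevalence and
  is flagged as such in `district_variable_specs()`. The real
  inter-covariate correlations are unpublished and therefore not emulated —
  a correlation-matrix hook exists, but defaults are independent. This is
  the main respect in which passing tests do *not* certify behavior on real
  data: collinearity patterns, and with them VIFs and robust-LM behavior,
  are milder in the synthetic fixtures than in real district tables.
* **Outcome** — exact draws from the three processes: `csr`
  (`y = Xβ + ξ`), `sem` (`y = Xβ + (I−λW)⁻¹ξ`), `slm`
  (`y = (I−ρW)⁻¹(Xβ + ε)`), Gaussian innovations throughout, matching the
  normality the ML fits assume. The outcome is never clipped: clipping
  would bias spatial-parameter recovery, which is exactly what the tests
  measure. Default effect sizes are the reported spatial-error coefficients
  of the emulated cervical-screening model (wealth +0.33, oral
  contraception −0.18, …), the default λ is 0.69 and the default ρ 0.59
  (the reported cervical estimates), and the default innovation SD of 8
  percentage points puts the OLS R² in the 0.4 region the emulated system
  reports.

## Validation design and problem sizes

The test suite validates by construction rather than by reference dataset:

* exact-oracle equivalence of Moran's I and local Moran against explicit
  double-loop implementations (200 random instances, n ≤ 25, both weight
  styles, tolerance 1e-12);
* the LISA proportionality identity on every instance;
* size calibration of the permutation test (500 CSR datasets on a 10 × 10
  lattice, 999 permutations each);
* SEM/SLM parameter recovery and 95% Wald coverage over 100 replicates at
  the full 640-unit scale, at the default λ = 0.69 and ρ = 0.59;
* residual declustering (SEM innovations vs OLS residuals) over 100
  replicates;
* null calibration of the LM-error statistic (1000 replicates, n = 100)
  against the χ²(1) 95th percentile;
* agreement of λ̂, ρ̂, β̂ and log-likelihoods with an independently coded
  dense-LU/golden-section reference, and of global Moran with
  `ape::Moran.I`, on a 640-unit fixture;
* byte-identical pipeline reruns under a fixed seed.

These sizes were chosen to give each stochastic check a Monte-Carlo error
comfortably inside its assertion band while keeping the whole suite in the
low minutes on a single core.

## Known limitations

* Geometry input is GeoJSON (plus CSV attributes and GAL weights); ESRI
  shapefiles should be converted upstream.
* Contiguity assumes boundaries that share vertices where they touch;
  boundary pairs that cross without nearby vertices (digitization slivers)
  may need a positive snap distance.
* Dense eigendecomposition limits model fitting to a few thousand units.
* Missing attribute values are an error by design — there is no principled
  imputation rule for this workflow, and silently dropping units would
  change the spatial structure.
* The spatial Durbin/SARAR families, GMM estimation, survey-weighted
  regression, and space–time extensions are out of scope.
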