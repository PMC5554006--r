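---
title: "Models and methods for longitudinal biomass GWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for longitudinal biomass GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growthgwas)
```

## Scope

`growthgwas` analyses daily image-based biomass of an inbred diversity
panel grown in several replicated experiments, and maps the temporal
dynamics of its genetic architecture. This vignette documents the models,
the tunable parameters and their defaults, the synthetic-data generator
that stands in for unreleased greenhouse and array data, and the numerical
and design choices that were genuinely open.

## Phenotype models

Plot-level records are indexed by genotype, experiment, replicate, day and
trait. The analysis assumes a completely randomized design within each
experiment (plants on imaging platforms are typically re-randomized
continuously), so no spatial correction is applied.

**Outlier screen.** Within each experiment x day x trait group, the
residual of each observation from its genotype mean is compared to a
robust scale: the median absolute deviation of the group's residuals,
scaled for Gaussian consistency. Observations beyond `threshold_sd` (default
3.5) robust SDs are flagged and skipped downstream, never deleted —
provenance is preserved and the flag rate on clean Gaussian data stays
well below 1%. Groups smaller than five observations are skipped with a
warning. A pure median/MAD screen was chosen because it is insensitive to
the very points it hunts; the threshold is exposed.

**Two-step BLUEs.** Step 1 fits `Y = G + e` per experiment, trait and day
with fixed genotype effects; in this design the best linear unbiased
estimate is the mean of the unflagged replicates, which is computed
directly and verified against a least-squares solver in the tests. Step 2
combines per-experiment BLUEs with `Y = G + E + e`, genotype fixed and
experiment random (REML); with balanced data the generalized-least-squares
estimates collapse to plain genotype means and that fast path is taken.
Whether step 2 should shrink via the random experiment term in unbalanced
cases is not a settled convention; GLS with the REML experiment variance is
used and tested against a brute-force GLS oracle.

**Variance components and heritability.** The one-step model
`Y = G + E + GxE + e`, all effects random, is fit by REML (via `lme4`,
with the profiled deviance re-minimized at tight tolerance so balanced
fits agree with closed-form ANOVA estimators, tested at 1e-6; components
are truncated at zero). Broad-sense heritability on a genotype-mean basis is

$$H^2 = \frac{V_G}{V_G + V_{GE}/O + V_e/(O R)}$$

with `O` the number of experiments observed for that day and `R` the
median number of replicates per genotype-experiment cell.

**Growth curves.** Biomass series follow the three-parameter logistic
$f(t) = a/(1+b e^{-ct})$ with asymptote `a` (biomass units), shape `b`
(dimensionless; sets initial size $a/(1+b)$) and rate `c` (per day). The
inflection point is $t_0 = \ln(b)/c$ with the natural logarithm — any
other base would break the identity between $t_0$ and the argmax of
$df/dt$, which the tests enforce on a fine grid. Fitting is
Levenberg–Marquardt least squares (`minpack.lm`), parameters bounded below
at 1e-8, at most 500 iterations, with self-starting values: `a0 = 1.05 *
max(value)` and `(b0, c0)` from an ordinary regression of
`log(a0/value - 1)` on day. Constant series are unidentifiable and are
rejected. Fits are intended for per-experiment BLUE series (one value per
genotype-day-experiment), but any `(day, value)` series is accepted.

## Linkage disequilibrium

LD is the squared Pearson correlation of 0/1 codes over genotypes
non-missing at both markers; in a fully inbred panel this equals the
haplotype correlation, so no phasing is involved. Only intrachromosomal
mapped pairs are used. The background threshold is the 95th percentile of
`r^2` over pairs more than 50 cM apart, with the linear-interpolation
percentile definition (R type 7) fixed so tests can be exact. The decay
curve is a degree-1 LOESS (tricube weights) of `r^2` on distance; the
default span of 0.3 smooths without chasing noise and is exposed. The LD
extent is the smallest distance at which the fitted curve drops to the
threshold, bracketed on a grid and solved by bisection; fits use an
interpolating LOESS surface and subsample beyond 50,000 pairs, since exact
local regression on hundreds of thousands of pairs costs far more than it
informs.

## Kinship mixed-model scan

The kinship estimator is not uniquely defined in the field's reports; the
standardized-score realized relationship `K = W W'/m` (missing calls
mean-imputed, each marker centered and scaled to unit variance) was chosen.
The genotype effect in the scan has covariance `2 K sigma_G^2`; because the
variance ratio is profiled, any rescaling of `K` — including the factor 2 —
is absorbed, which is tested.

For one trait-day the model on stacked per-experiment BLUEs is
`Y = mu + E + S + G + e` with fixed intercept, experiment indicators and
marker dosage `S` (inbred coding 0/1, mean imputation for missing calls),
random genotype `G`, and iid residuals. The observation covariance
`Z (2K) Z' sigma_G^2 + I sigma_e^2` is eigendecomposed once; the ratio
`lambda = sigma_G^2 / sigma_e^2` is then a one-dimensional REML problem
solved by bounded search over `log10(lambda)` in [-8, 8] (tolerance 1e-8).
By default the ratio is estimated under the no-marker null and reused for
every marker (the standard P3D shortcut); exact per-marker REML is
available via `mode = "full_reml_per_marker"` and agrees with the shortcut
within 0.2 `-log10(p)` units on null data for common markers, which is
tested. The marker term is tested with a single-degree-of-freedom Wald
statistic referred to F(1, n - p) rather than chi-square: at finite sample
size the F reference is the one that reduces *exactly* to the ordinary
fixed-effects F-test when the genetic variance is zero, an identity the
acceptance tests check to 1e-6. FDR control is Benjamini–Hochberg within
each trait-day scan; the field reports per-day significance, and no
cross-day correction is described, so none is applied (the alternative is
one `apply_fdr()` call on the stacked table).

The share of genetic variance of a detected QTL is the adjusted R-squared
of a fixed single-marker regression on across-experiment BLUEs divided by
that day's heritability and clipped to [0, 1]; a joint multi-marker
regression gives the combined share (never the sum of individual shares).
Markers significant on at least one day form temporal trajectories;
the label compares the mean `-log10(p)` of the first and last third of
days, with "peaked" assigned when an interior maximum exceeds both end
means by at least 20%.

## The synthetic-data generator

The generator emulates a spring barley diversity panel of ~99 fully
homozygous lines genotyped at ~4,866 SNPs (MAF > 0.05, < 5% missing) over
seven chromosomes, phenotyped daily from 10 to 58 days after sowing in
three experiments with five replicates.

**Genotypes.** Markers are laid out at uniform positions per chromosome
(default seven chromosomes of 150 cM) and generated in haplotype blocks:
the first marker of a block is an independent Bernoulli draw with allele
frequency uniform between `maf_low` and `maf_high`, and each subsequent
marker copies its predecessor with per-genotype flip probability
`mutation_rate`. This copy-with-mutation scheme produces distance-decaying
`r^2` — sufficient for every analysis here — without pretending to be a
coalescent; genealogies, mutation spectra and ascertainment of array SNPs
are explicitly not modelled. The defaults `ld_block_size = 20` and
`mutation_rate = 0.06` were calibrated once so that, at the panel's marker
density, the measured LD extent is ~8 cM, matching the decay reported for
such panels. Markers whose realized MAF falls below `maf_low/2` are
redrawn.

**Phenotypes.** Each genotype receives latent `(a, b, c)` as a population
base value plus QTL effects plus a polygenic deviation, all additive on
the log scale so parameters stay positive. Planted QTL (`qtl_spec()`)
are calibrated against the realized marker variance so each explains its
`variance_fraction` of the latent genetic variance of its target, and may
carry an `effect_window` outside of which the effect is silent. On the log
scale each parameter has a natural sensitive phase — `b` moves early
biomass, `c` acts most strongly around the inflection, `a` dominates near
the asymptote — so early, mid-peak and late association signals are
planted by aligning the target parameter with the window.

Defaults: base `(a, b, c) = (50, 320, 0.18)` (inflection ~32 days,
early biomass ~2% of the asymptote, near-saturation by day 58, in
arbitrary voxel-like units) with genetic CVs `(0.25, 0.30, 0.08)`;
multiplicative experiment effects (SD 0.05) and genotype-by-experiment
deviations (SD 0.04), matching the one-step model's `GxE` term with
minimal machinery. The residual is multiplicative log-normal,
`value = m * exp(tau z - tau^2/2)`: voxel volumes are positive and their
measurement error scales with plant size, and at a seedling-stage
heritability of ~0.6 with 15 plants per genotype the required residual SD
exceeds the day-10 mean, which an additive Gaussian law can only deliver
by clipping a fifth of the observations at zero and distorting the
variance decomposition. `tau` is solved per day so the mean within-cell
residual variance matches the heritability schedule exactly; the default
schedule interpolates 0.62 at day 10 to 0.91 at day 58. A fraction
`outlier_rate` (default 0.002) of observations receives gross errors of
6–10 residual SD for the outlier screen to find. Endpoint traits are
emitted alongside: fresh weight proportional to final biomass (one day
after the last imaging day), tiller counts at days 27/45/58, and tipping
time proportional to the genotype's inflection point. Lost imaging days
can be masked with `mask_days` (off by default).

What passing tests on these data do **not** show: robustness to image
segmentation artefacts, non-logistic growth (lodging, senescence),
spatial greenhouse gradients, heterozygous or structured panels, or array
ascertainment bias — none of which the generator emulates.

## Power simulation

`run_power_simulation()` plants, per repetition, one marker per requested
variance fraction (defaults 15% and 10%): genetic values are
`g = sum(beta_k x_k) + u` with `beta_k` calibrated against the realized
marker variance and a polygenic `u` drawn with covariance proportional to
`2K` — the model the scan assumes, so the evaluation is of a correctly
specified analysis — scaled to the remaining share of variance. Experiment
effects and residual noise sized for a background heritability of `h2`
(default 0.8, inside the panel's observed 0.62–0.91 band) complete the
per-experiment values. A QTL counts as detected when its own marker, or
any significant marker within `detection_window_cM` (default 8 cM, the LD
extent; set 0 for own-marker-only), passes BH-FDR. Under these conditions
the detection rate of a 15% QTL in a 99-line panel is bounded by the
information in the data: the marker's non-centrality is about
`n R^2/(1-R^2) ~ 13.5` (with `R^2 = 0.15 x 0.8 / (1 + 0.25)` on line
means), while Benjamini–Hochberg at `q = 0.1` over ~4,900 markers demands
roughly `p <= 2e-5` at rank one. The acceptance suite measures the
resulting rate; an ordinary least-squares scan that ignores kinship
appears far more "powerful" on these data but only by mistaking the
polygenic structure for signal, which is exactly the inflation the
kinship term exists to remove.

## Allele stacking

Daily biomass BLUEs are standardized as relative deviations from the day
mean, `(value - mean)/mean` — the population average is the natural
reference when tracking selection groups over a growth curve, and values
below zero read directly as below-average genotypes (a z-score variant is
available via `method = "zscore"`). The favorable allele of a QTL marker
is the allele class with the higher across-experiment BLUE at the
marker's day of peak significance; the rule is deliberately simple and
reproducible, ties go to allele 1 and are reported. For each named QTL
subset, genotypes carrying the favorable allele at every member marker
form `all_favorable`, the complement at every marker `all_unfavorable`,
everything else (including missing calls) `other`; empty groups are
reported rather than dropped, since with many stacked QTL the extreme
groups are often empty in a real panel.

## Numerical choices and degenerate inputs

* Percentile definition: linear interpolation between closest ranks
  (type 7), fixed for exact testing.
* Logistic fits reject series with fewer than 5 points, spanning fewer
  than 10 days, with negative values, or constant.
* REML searches: `log10(lambda)` bounded in [-8, 8], tolerance 1e-8;
  variance components truncated at zero.
* Kinship: zero-variance markers dropped with a warning; a minimal ridge
  restores positive semidefiniteness against round-off.
* Scans skip markers constant over the aligned genotypes; p-values are
  clamped away from exact zero before `-log10`.
* `ld_extent()` returns 0 with a warning when the curve starts below the
  threshold, and `NA` with a warning when it never crosses; raising the
  threshold can only shorten the extent (tested).
* All writers serialize floating-point columns at 12 significant digits so
  reruns diff cleanly.

## Problem sizes in the test suite

The tests exercise the full study scale where the quantity depends on it
(99 genotypes and 4,866 markers for the power simulation; 2,000 markers
for null-scan calibration) and small panels (15–99 genotypes, 30–500
markers) elsewhere; recovery properties use 30–100 simulation seeds per
assertion. The pipeline smoke test runs 20 genotypes, 200 markers and ten
days end to end, twice, and compares artifacts byte for byte.

## Known limitations

* The logistic law is the only growth model; no Gompertz or spline
  alternatives.
* Population structure is corrected by kinship only; principal components
  are not offered as fixed covariates.
* The favorable-allele rule conditions on the scan's peak day; with weak
  or unstable signals the assignment inherits that instability.
* The generator's LD is block-wise; long-range admixture LD and
  interchromosomal LD are absent, and interchromosomal pairs are excluded
  from the decay analysis by design.
* Heterozygous calls are treated as missing on input (with a hard error
  above 5%), so the package applies only to effectively fully inbred
  material.
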