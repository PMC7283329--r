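---
title: "Methods: from grain reflectance to candidate genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from grain reflectance to candidate genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grainspec)
```

## Overview

`grainspec` implements a complete analysis path for visible/near-infrared
(Vis/NIR, 400–1004 nm) hyperspectral imaging of whole rice grain:

1. **Imaging** — white/dark reflectance calibration, grain segmentation,
   per-sample mean spectra.
2. **Chemometrics** — PLS-DA classification of genetic sub-population and
   production environment with VIP wavelength selection and LDA validation;
   K-means wavelength grouping; per-group PC1 spectral traits regressed on
   grain-quality traits (chiefly percent chalk).
3. **Association** — a per-marker REML mixed linear model (MLM) on the
   702–922 nm PC1 trait with principal-component covariates and a kinship
   matrix, FDR control, merging of significant SNPs into genomic segments,
   and a candidate-gene search around segment peaks.

Because no public image archive accompanies the kind of study this models, a
first-class synthetic-data module generates scenes, traits, genotypes and
annotations with the statistical structure the analysis assumes; every stage
is tested against that generator and against independent oracles.

## Imaging model

Raw counts are converted to relative reflectance per pixel and band as

$$ I = \frac{I_0 - D}{W - D}, $$

where $I_0$ is the raw image and $W, D$ are white and dark reference images.
The scale runs from 0 (no reflectance) to 1 (the white reference); values
outside $[0,1]$ are *not* clipped by default because Savitzky–Golay
derivative preprocessing downstream is sensitive to artificially flattened
regions (a `clip` argument exists for display purposes).

The region of interest is segmented on the band nearest **750 nm**, the
wavelength of highest intensity for intact brown rice kernels. A manual
threshold is not reproducible, so the default threshold is **Otsu's method**
on that band, with a fixed-threshold override. Connected components smaller
than `min_area` pixels are treated as background noise and removed (default
50 px; the examples in this package use smaller synthetic grains and pass
10 px). Components are mapped to samples through a grain-centroid sample
map, and the per-sample spectrum is the mean over that sample's masked
pixels. Nearest-band lookup is used for the 750 nm band (band spacing is
~4 nm, making interpolation immaterial).

## Spectral preprocessing

Eight per-spectrum operators are provided: moving-average smoothing, mean/
maximum/range normalization, multiplicative scatter correction (MSC),
standard normal variate (SNV), and Savitzky–Golay first and second
derivatives. Defaults are the conventional chemometrics choices — window 5
for smoothing, window 7 / polynomial order 2 for the SG derivatives — and
all are exposed in `preprocess_spec()`. "Smoothing" is implemented as a
centered moving average (the generic term is ambiguous between moving-average
and SG smoothing; the moving average was chosen and is stated here). The MSC
reference defaults to the column mean of the table it is applied to; to avoid
train/test leakage, store the training mean in the spec and reuse it.

Under controlled acquisition conditions, model results on preprocessed
spectra typically match results on raw spectra, so the pipeline default is
`preprocess: none`; the operators remain available and individually tested
(SNV row moments, MSC idempotence, SG exactness on polynomials).

## PLS-DA, VIP, and wavelength selection

Class membership is coded as a binary indicator matrix (1 = member). X is
centered and scaled per band; components are extracted with the iterative
bilinear NIPALS factorization with deflation, whose score orthogonality is
a tested invariant. When the component count is not fixed it is chosen by
5-fold cross-validation on the training set. A stratified **10% holdback**
of samples is excluded from fitting and used for validation; predicted class
is the argmax of the predicted indicator.

Variable importance in projection is

$$ \mathrm{VIP}_j = \sqrt{\,p \sum_a \mathrm{SSY}_a (w_{ja}/\lVert w_a\rVert)^2
 \big/ \sum_a \mathrm{SSY}_a}, $$

with $\mathrm{SSY}_a$ the Y-variance explained by component $a$ and $p$ the
band count; $\mathrm{mean}(\mathrm{VIP}^2) = 1$ is an algebraic identity and
is asserted on every fitted model in the tests. Wavelengths are selected at
**VIP ≥ 0.8**, optionally intersected with local extrema of $|\beta|$
("contrasting peaks"); the exact rule combining coefficients and VIP in the
motivating analyses is not fully specified anywhere, so the peak intersection
is an explicit flag rather than the default.

Selected wavelengths feed a Fisher LDA with **equal priors** (holdback sets
are balanced by class), at most (classes − 1) canonical axes, classification
by nearest class mean in canonical space, and a ridge fallback
(`1e-6 × mean diagonal`) for the bands ≫ samples regime.

## Wavelength groups and spectral traits

Bands are clustered by K-means on their standardized across-sample profiles
(20 restarts, best within-cluster sum of squares kept). Because the feature
space for the clustering is not dictated by anything observable — while the
reported groups are contiguous nm ranges — the raw K-means labels are
post-processed into exactly *k* contiguous ranges by a dynamic program that
minimizes the number of bands disagreeing with their block's majority label.

For each group, the first principal component of the (column-centered) group
spectra scores the samples; the sign is fixed so PC1 correlates positively
with mean in-group reflectance (higher score = brighter grain). The 702–922
nm group PC1 is the chalk spectral trait: chalky endosperm scatters light and
elevates NIR reflectance roughly linearly in the chalked area fraction.
Trait–PC1 relationships are summarized by simple linear regression with the
F-test p-value and the `**`/`*`/`ns` convention at p < 0.01 / p < 0.05.

## Mixed-model association scan

Genotypes are filtered at missing rate > 0.20 and MAF < 0.05. Structure
covariates are the top 3 principal components of the mean-imputed,
$\sqrt{2pq}$-scaled genotype matrix; kinship is the VanRaden cross-product
$K = ZZ' / (2\sum_j p_j(1-p_j))$. For every marker the model

$$ y = X_0\gamma + x_m\beta + u + \varepsilon,\qquad
   u \sim N(0, \sigma_g^2 K),\ \varepsilon \sim N(0, \sigma_e^2 I) $$

is fitted by REML over the variance ratio $\delta = \sigma_e^2/\sigma_g^2$,
re-estimated **for every marker** (no compression), using one
eigendecomposition of $K$ shared across markers (EMMA-style rotation). The
1-D REML search uses a 61-point $\log_{10}$ grid on $[-5, 5]$ followed by
golden-section refinement; $\beta$ is tested by a Wald $F(1, n-p)$ statistic.
The scan kernel is compiled (RcppArmadillo) because per-marker REML is
O(markers × grid evaluations).

Missing genotype calls are mean-imputed in the scan, exactly as in the PCA
and kinship inputs. Excluding missing calls marker-wise would require a
different kinship eigensystem per marker, defeating the shared
eigendecomposition; with the low, completely-at-random missingness this
pipeline filters to (≤ 20%), mean imputation attenuates single-marker effects
only marginally.

With a bran-color column supplied, only non-pigmented classes (white, light
brown, brown) enter the scan, since pigmented pericarp masks chalk optically.

Multiple testing uses Storey q-values (π₀ by a natural-spline smoother over a
λ grid of 0.05–0.95; π₀ = 1 reduces exactly to Benjamini–Hochberg and is the
fallback for fewer than 100 tests), with the genome-wide significance flag at
**p ≤ 1e-6** by default.

## Segments and candidate genes

Each significant SNP seeds an interval of **±100 kb**, clipped to the
chromosome; intervals on one chromosome that overlap *or abut* are merged
transitively — the only reading of "extended if additional significant SNPs
fall in the flank" that yields deterministic, order-independent segments. A
SNP exactly at a junction would belong to both intervals, hence abutting
intervals merge. Each segment is summarized by its peak SNP (minimum p, ties
broken by the leftmost position, for determinism). Segments are clipped at
chromosome ends when lengths are provided. Candidate genes are all gene spans
intersecting **±150 kb** around the peak SNP; distance is 0 for a gene
containing the peak and otherwise the distance from peak to the nearer gene
edge (span-to-point, not TSS-to-point, since the criterion is "genes within a
distance", not promoter proximity). Interval algebra is delegated to
IRanges/GenomicRanges; brute-force union/intersection oracles verify it in
the tests.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
tested:

* **Genotypes** — Balding–Nichols structured allele frequencies (one
  divergence parameter, default Fst = 0.15, three sub-populations of a
  96-accession panel), 5,000 biallelic SNPs on 12 chromosomes, 2% missing
  calls completely at random. Causal chalk loci (default 3, additive effects
  12/9/7 chalk-% per allele) are drawn among common variants (ancestral
  frequency 0.3–0.7) and kept segregating in every sub-population, so a panel
  of this size carries detectable signal — jointly they explain well over
  40% of chalk variance at the default noise (sd 6%).
* **Traits** — chalk is baseline + additive genetic values + a small
  sub-population shift + Gaussian noise, clipped to [0, 100]; amylose is
  generated at a configurable correlation with chalk; bran-color class
  frequencies differ by sub-population.
* **Scenes** — grains are axis-aligned ellipses with jittered size on a dark
  background (only masks and mean spectra are consumed downstream, so shape
  realism is irrelevant). Per-pixel reflectance = bran visible baseline +
  chalk × loading + environment offset + Gaussian noise. The chalk loading is
  a tapered-flat (Tukey) window supported exactly on 690–920 nm: the whole
  band is elevated (the emulated finding is a broadly chalk-correlated NIR
  region, not a single peak), with smooth edges so the support boundaries are
  exact. The bran multiplier tapers in the NIR (pericarp pigments absorb
  mainly in the visible range), leaving the chalk band dominated by chalk.
  Environment offsets are narrow band shifts (default: +0.03 in the violet
  for one environment, ∓0.008 in two NIR windows for the others) — detectable
  by PLS-DA at these sample sizes yet an order of magnitude below the chalk
  signal, mirroring a setting where chalk dominates NIR variation.
  Raw counts are constructed around fixed white/dark levels so calibration
  recovers the designed reflectance exactly at zero noise.

What the generator does **not** emulate: sensor point-spread and specular
highlights, wavelength-dependent noise, pedigree relatedness, linkage
disequilibrium decay within chromosomes (markers are exchangeable given the
sub-population frequencies), and non-linear chalk–reflectance saturation.
Passing tests therefore demonstrate correctness of the algorithms under the
assumed structure, not performance claims about any particular instrument or
germplasm panel.

## Numerical choices

* NIPALS convergence: relative score change < 1e-10, ≤ 500 iterations;
  components stop early when deflated Y is numerically zero.
* Cross-validated component count: 5-fold, minimum squared prediction error.
* LDA ridge: 1e-6 × mean diagonal, applied only when the pooled covariance is
  computationally singular.
* REML: eigenvalues of K floored at 1e-10; grid then golden section to a
  1e-6 bracket on log10(δ).
* K-means: 20 restarts; contiguity enforced by an exact dynamic program.
* PC1 sign: positive correlation with in-group mean reflectance; regression
  tie-breaks and peak ties are leftmost/deterministic throughout.
* p-values are floored at the smallest positive double to keep q-value and
  log transforms finite.

## Problem sizes used by the tests and acceptance script

Unit tests run on small panels (tens of samples, hundreds of markers) and a
96-sample default scene. The simulation checks use n = 200 accessions with
2,000 markers (null calibration, five seeds) and 5,000 markers (causal
recovery), sizes at which the mixed-model scan completes in seconds with the
compiled kernel while still exhibiting realistic population structure. These
sizes are the package's own test design; all thresholds they are checked
against (type-I error in [0.035, 0.065], causal recovery in ≥ 4/5 seeds,
chalk PC1 correlation ≥ 0.9, chalk-band Jaccard ≥ 0.7) are fixed properties
of the stated study conditions.

## Known limitations

* Per-sample (not per-grain) phenotyping; geometric grain measurements are
  out of scope.
* The scan assumes a single trait and a single random polygenic term; no
  multi-trait or multi-locus models.
* Mean imputation is the only missing-genotype handling.
* Segment definition is flank-based, not linkage-disequilibrium-aware.
* The K-means wavelength grouping assumes the informative spectral regions
  are contiguous in nm; a signal split across distant bands would be divided
  among groups.
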