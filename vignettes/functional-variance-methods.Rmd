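---
title: "Methods: community-weighted trait variance as an indicator of community reorganization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community-weighted trait variance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitvar)
```

## The problem

When warm-affinity species expand into a cold-affinity community, the first
detectable change is often not in *which* traits dominate (the
community-weighted mean, CWM, moves slowly while resident species persist)
but in *how heterogeneous* the trait composition becomes. traitvar
implements a multi-trait community-weighted **variance** (CWV) analysis:
each station's abundance-weighted trait variance is computed per trait, the
station × trait CWV matrix is summarized by PCA, and the first component —
*functional variance PC1* — serves as a single trait-aware indicator of
functional heterogeneity, with loadings naming the traits responsible. The
package pairs this with the classical indices it should be compared against
(richness, Shannon, evenness, dendrogram functional richness, Rao's Q) and
a mixed-model decomposition of dispersion trends.

## Trait coding and standardization

Traits come in three types. Quantitative traits are z-scored over the
**full species pool** — not per community — so that a station's CWV values
are comparable across stations and years; the centering/scaling parameters
are frozen in the `ExpandedTraits` object. Ordinal traits are rank-coded
(average ranks for ties) and then treated as quantitative; this uses only
the order information the coding carries. Categorical traits are fuzzy
coded: each species holds non-negative memberships over the trait's
categories summing to 1. Fuzzy columns are *not* z-scored — memberships are
already commensurate on [0, 1], and z-scoring them would inflate rare
categories. A quantitative column with zero variance is retained as all
zeros (sd treated as 1) with a warning, so downstream matrices keep a
stable shape.

## Distances, dendrogram, indices

**Gower distance.** Pairwise species dissimilarity is the weighted mean of
per-trait dissimilarities over the traits both species have values for
(pairwise deletion, the standard Gower convention):
range-normalized absolute difference for quantitative/ordinal traits, and
total-variation distance $\frac12\sum_c |m_{ic}-m_{jc}|$ for a fuzzy trait,
whose category columns jointly carry the trait's single weight. This keeps
every $d_{ij}$ in [0, 1] and treats a 15-trait table as 15 — not 19 —
sources of evidence. A species pair sharing no non-missing trait is an
error rather than a silent zero.

**UPGMA dendrogram.** Functional richness is measured on an average-linkage
dendrogram of the full pool, as the total branch length of the minimal
subtree spanning a station's species. The agglomeration method and distance
are deliberate conventions of the dendrogram-based functional-richness
literature; both are isolated behind `gowerDistance()`/`upgmaTree()` so a
different choice is a one-line substitution. Node heights are **half** the
linkage distance, making leaf-to-leaf cophenetic distances equal the
linkage distances. Ties in the minimum linkage are broken by the lexicographically
lowest pair of smallest original species indices, which makes the tree —
and the whole pipeline — bit-reproducible; the total branch length is
invariant to the tie choice, which the tests enumerate explicitly.

**Indices.** Shannon entropy uses the natural log (configurable). Evenness
is implemented literally as $J = H/(\log S + 1)$: the `+ 1` differs from
classical Pielou $H/\log S$ but regularizes the single-species case to 0
instead of 0/0, and is the definition this pipeline standardizes on.
Rao's Q uses the full double sum $\sum_i\sum_j p_i p_j d_{ij}$ with no
division by two, matching the quadratic-entropy definition. All stations
are scored on the one pool-level distance matrix and dendrogram, so indices
are comparable across space and time.

## CWV, CWM and the functional variance PCA

CWM and CWV are the abundance-weighted first and second central moments of
each expanded trait column; the variance uses the population convention
(relative abundances are weights, not counts, so a Bessel-type correction
has no referent). For a {0, 1}-membership fuzzy category the CWV reduces to
the Bernoulli variance $q(1-q)$ of the weighted category frequency — a
useful hand-check that the tests exercise.

The PCA centers the CWV columns but does **not** unit-scale them by
default: species-level standardization already put the columns on a common
scale, and scaling would equalize the influence of traits that genuinely
vary less between communities. `scaleColumns = TRUE` exposes the
alternative. The PCA is computed across **all** stations of both regions
jointly, and regional yearly means are taken afterwards, so both regions
are scored on a shared axis. Because eigenvector signs are arbitrary, PC1
is oriented so its scores correlate non-negatively with Rao's Q across the
same stations; the flip decision is recorded in the `TraitPCA` object. The
PCA itself is delegated to `stats::prcomp`; the tests verify the contract
independently (reconstruction of the input to 1e-10, explained fractions
summing to 1, orthonormal loadings, uncorrelated scores).

## Trend models

`fitDispersionModel()` fits $Q \sim S + J + \mathrm{FRic}$ with a random
year intercept, by maximum likelihood (not REML) so fits with different
fixed effects remain comparable; p-values are Wald z, and $r^2$ is the
squared correlation of fitted and observed responses — the pragmatic
definition used for reporting variance explained without committing to a
pseudo-$R^2$ flavour. Standard errors come from the closed form
$(X^\top \hat V^{-1} X)^{-1}$ evaluated at the fitted variance components,
which coincides with the mixed-model machinery's covariance but remains
defined for degenerate (exactly noiseless) fits. With fewer than three
year levels the model degrades to a fixed-intercept linear model with a
warning. With `spatial = TRUE` the residuals carry an exponential
correlation in distance, nested by region within year, with the range
estimated from the data; coordinates are projected to local kilometres by
an equirectangular projection ($y = 111.32\,\mathrm{lat}$,
$x = 111.32\,\mathrm{lon}\cos\overline{\mathrm{lat}}$), which agrees with
great-circle distance to first order at regional scale. The spatial
structure defaults to off: it is the slowest and least deterministic part
of the model and is not needed for the synthetic validation, where
stations are exchangeable within year and region by construction.

## What the synthetic generator emulates

`syntheticConfig()` encodes a stylized two-region bottom-trawl survey:

- **Pools.** 20 Arctic + 29 boreal species (49 total), with 15 traits in
  five groups (habitat affinity, life history, body size, feeding ecology,
  foodweb characteristics). The boreal pool is built as large piscivorous
  generalists — mean gaps of 1–2 pooled SD on body size, growth, maturity,
  trophic links — and is given the wider within-pool spread (SD 1.2 vs
  0.6), reflecting generalists versus specialists. Diet and habitat zone
  are fuzzy traits with pool-specific Dirichlet memberships (Arctic:
  benthivorous/benthic; boreal: piscivorous/demersal). A single `contrast`
  knob interpolates to identical pools (the null configuration).
- **Dynamics.** Species presence is Bernoulli in occupancy; boreal
  occupancy at Arctic stations starts at 0.08 and rises by `beta = 0.05`
  per year over 2004–2017, reaching ~0.73, while home-region occupancies
  (0.6) and the small reverse leakage (0.05) stay flat. An off-by-default
  local-extinction knob erodes Arctic home occupancy for
  peak-then-decline scenarios. Abundances of present species are lognormal
  (meanlog 1, sdlog 0.75), a standard species-abundance convention; the
  survey is unitless because the analysis only uses relative abundances.
- **Geometry.** Stations sit on a fixed grid in two latitude bands (76–80
  and 70–74) — density, not coastline realism. A per-region-year station
  override can mimic under-sampled years.

These choices are invented where the emulated survey's description gives
none; they are exposed in the configuration and fixed as defaults. Fifteen
stations per region-year (420 stations over 14 years) keeps a full
pipeline run in the low seconds while leaving yearly means stable;
validation harnesses that sweep seeds use the same size, and the
mixed-model recovery checks use 500 stations over 10 years.

What passing tests on this generator demonstrate is that the pipeline
detects the constructed signal — rising Arctic functional variance and
dispersion, Arctic–boreal convergence of PC1, the CWV signal halving its
gap before the CWM signal, and no trend under the null — not that any real
community behaves this way. The generator has no mechanistic population
dynamics, no spatial autocorrelation in occupancy, no temperature field,
no observation error model, and independent years; conclusions about real
surveys still require the real data.

## Numerical and degenerate-input conventions

- Empty stations are dropped (with a count) before analysis; a generated
  station drawing no species is redrawn up to 100 times, then forced to
  one species with a warning.
- Fuzzy membership rows are renormalized when within 1e-6 of summing to 1,
  and rejected otherwise; negative memberships and non-positive trait
  weights are errors.
- A CWV entry is clipped at 0 against floating-point negatives of exact
  zeros; a constant CWV matrix is a "no variance to decompose" error
  rather than a degenerate PCA.
- All randomness in a run flows from one integer seed; reruns are
  byte-identical with the spatial structure off, and the run manifest
  records input/output checksums so stale intermediates are detected
  rather than silently reused.

## Known limitations

The evenness denominator and dendrogram-based richness are fixed
conventions of this pipeline, stated above, rather than universal
definitions. The spatial correlation structure assumes isotropy in local
kilometres and exchangeable years. The hull-based flavour of functional
richness, rarefaction or effort correction, temporal autocorrelation
structures, and model selection are out of scope.
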