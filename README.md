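# traitvar

Multi-trait **community-weighted variance** ("functional variance") analysis
of community reorganization, built for ecologists studying climate-driven
range shifts — the motivating case being boreal fish moving into an Arctic
shelf community and reshaping its functional diversity. The package pairs
the functional variance method with the classical taxonomic and functional
diversity indices it is meant to complement (species richness, Shannon
diversity, evenness, dendrogram functional richness, Rao's quadratic
entropy), a mixed-effect trend model that decomposes functional dispersion
into those components, and a synthetic two-region survey generator with
known borealization dynamics so that every stage of the pipeline can be
validated against ground truth.

## The statistics at the core

For a station with relative abundances $p_i$ over the species present, and
species-level trait values $x_{i,t}$ (standardized over the species pool and
fuzzy-coded for categorical traits), the package computes per trait $t$:

- **Community-weighted mean**: $\mathrm{CWM}_t = \sum_i p_i\,x_{i,t}$
- **Community-weighted variance**:
  $\mathrm{CWV}_t = \sum_i p_i\,(x_{i,t}-\mathrm{CWM}_t)^2$
  (population convention, no small-sample correction)

The station × trait CWV matrix is then decomposed by PCA; a station's score
on the first component is its **functional variance PC1** — a single-number
summary of multi-trait functional heterogeneity whose loadings identify the
traits driving it. Its sign is oriented so it correlates non-negatively with
functional dispersion. Alongside it:

- **Rao's Q** (functional dispersion):
  $Q = \sum_i \sum_j p_i\,p_j\,d_{ij}$, with $d_{ij}$ the Gower distance
  between species over mixed trait types (quantitative, ordinal, fuzzy).
- **Functional richness**: total branch length of the minimal subtree of the
  UPGMA trait dendrogram spanning the station's species.
- **Evenness**: $J = H / (\log S + 1)$, Shannon entropy over log richness
  plus one (the regularized variant, which is 0 for a single species).
- **Trend model**: $Q \sim S + J + \mathrm{FRic}$ with a random year
  intercept (ML), optionally with residual correlation declining
  exponentially with great-circle distance, nested by region.

## Worked example

```r
library(traitvar)

cfg    <- syntheticConfig(seed = 1)      # 49 species, 2 regions, 2004-2017
pool   <- generateSpeciesPool(cfg)
survey <- generateSurvey(cfg, pool)
pool$traits
#> TraitTable: 49 species, 15 traits (12 quantitative, 1 ordinal, 2 fuzzy), 19 columns
survey
#> CommunitySurvey: 49 species x 420 stations; regions: arctic, boreal; years 2004-2017

fv <- functionalVariancePC1(survey, pool$traits)
fv$pca
#> TraitPCA: 420 stations x 19 components; PC1 explains 25.1%
round(fv$r2, 3)                          # PC1 vs Rao's Q association
#> [1] 0.514
head(fv$regional[fv$regional$region == "arctic", ], 4)
#>   region year        PC1         Q n_stations
#> 1 arctic 2004 -1.3567450 0.1777205         15
#> 2 arctic 2005 -1.1486014 0.1967184         15
#> 3 arctic 2006 -0.7484093 0.2263319         15
#> 4 arctic 2007 -0.5715602 0.2316318         15

idx <- computeDiversity(survey, pool$traits)
fitDispersionModel(idx)
#> DispersionFit [all]: n = 420 stations, 14 years, r2 = 0.607
#>       term  estimate        se      z         p
#>  intercept  0.029035 0.0193500  1.501 1.335e-01
#>          S -0.001779 0.0004418 -4.026 5.673e-05
#>          J  0.229825 0.0311562  7.377 1.625e-13
#>       FRic  0.043060 0.0049805  8.646 5.345e-18
```

The Arctic-region PC1 yearly means rise steadily from −1.36 toward the
boreal level as boreal species' occupancy increases — the functional
variance signal of the intrusion — while richness, evenness and functional
richness together explain about 61% of the spatio-temporal variation in
dispersion on this survey. A command-line wrapper around the same functions
lives at `inst/scripts/traitvar` (subcommands `simulate`, `indices`, `cwv`,
`pca`, `trends`, `all`).

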