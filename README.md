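# otuassembly

Community-assembly analysis of marine protist OTU tables.

Marine protist communities sampled across seasons, habitats and depth
layers raise a recurring question: are local communities assembled by
*neutral* processes (dispersal and drift from a shared source pool) or by
*niche* processes (environmental filtering)? This package implements the
complete statistical workflow used to answer it for 18S rRNA OTU tables
from a coastal-to-shelf seasonal survey (60 samples: 10 sites x 2 depth
layers x 3 months, rarefied to 1,172 reads per sample), and a synthetic
generator that emulates that design so the whole workflow can be validated
without sequencing data. It is aimed at microbial ecologists working with
mothur/QIIME-style OTU tables.

## What it does

- **Input/normalization** — mothur `.shared` and TSV readers/writers,
  seeded rarefaction (without-replacement subsampling), removal of
  singletons/doubletons and single-sample OTUs, relative-abundance and
  Hellinger transforms.
- **Rarity classification** — the six abundance categories AT / CAT / MT /
  CRAT / CRT / RT from each OTU's range of relative abundance across
  samples (0.1% and 1% cuts), with sub-community summaries.
- **Diversity** — Sobs, Chao1 (bias-corrected and classic), ACE, Shannon,
  Simpson (D and 1-D), Pielou, Good's coverage; analytic rarefaction
  curves; species-accumulation curves; abundance-occupancy relationships;
  Bray-Curtis dissimilarity; shared-OTU (Venn region) counts.
- **Ordination** — PCA, PCoA (negative eigenvalues reported), NMDS
  (multi-start Kruskal stress-1), RDA with the constrained-variance
  fraction, Procrustes superimposition (M²) and the PROTEST permutation
  test.
- **Spatial/environmental inference** — haversine distances, ANOSIM,
  Mantel tests (with exhaustive enumeration for small n), environmental
  distances, PCNM spatial eigenvectors, distance-decay regression.
- **Neutral model** — the Sloan neutral community model: occurrence
  frequency `F = 1 - I_d(Nmp, Nm(1-p))` as a function of mean relative
  abundance `p`, with the immigration rate `m` fitted by bounded least
  squares, `R²` (possibly negative), a 95% Wilson band, and an exact
  beta-binomial detection option that makes `m` recoverable from
  Dirichlet-multinomial count data.
- **Networks** — Spearman co-occurrence screens with pooled-permutation
  p-values, Storey q-values, `|rho| > 0.6` & `q < 0.05` edge thresholds,
  topology metrics (degree, density, clustering, diameter, path length,
  centralizations, Louvain modularity, sub-module count), GraphML and
  edge-list export.
- **Workflow** — `run_pipeline()` runs every stage from a config and
  writes TSV outputs plus a manifest that replays bit-identically;
  the numbered scripts under `analysis/` walk through the same analyses
  narratively.

## Worked example

Simulate the 60-sample study under neutral assembly with immigration rate
`m = 0.1`, filter artifacts, and fit the neutral model:

```r
library(otuassembly)

fix <- generate_study_fixture(mode = "neutral", m = 0.1, seed = 42)
tab <- filter_artifacts(fix$table)
fit <- fit_ncm(tab, allow_unequal = TRUE)
fit
#> Sloan neutral model fit: 548 OTUs, 60 samples
#>   m = 0.0948, Nm = 110.1, R2 = 0.951
#>   partition: above = 19, below = 39, within = 490
```

The fitted immigration rate recovers the generator's `m = 0.1` within a few
percent, `Nm ≈ 110` quantifies dispersal into each 1,172-read local
community, and `R² = 0.95` says occurrence frequencies track the neutral
expectation closely; 490 of 548 OTUs sit inside the 95% band. Classifying
the same table by abundance range:

```r
category_summary(classify_otus(to_relative(tab)), tab)
#>   category n_otus reads pct_otus pct_reads
#> 1 AT            4 23293    0.730   33.4
#> 2 CAT           4  7061    0.730   10.1
#> 3 CRAT        286 35279   52.2     50.6
#> 4 CRT         247  4004   45.1      5.75
#> 5 RT            7    22    1.28     0.0316
```

Conditionally rare-and-abundant taxa (CRAT) dominate the reads while
conditionally rare taxa (CRT) dominate the richness — the oscillating
abundance structure the classification is designed to expose. A seasonal
ANOSIM on this *neutral* fixture finds, correctly, nothing:

```r
res <- anosim(bray_curtis(tab), fix$samples$month, n_perm = 999, seed = 42)
#> R = -0.006, p = 0.6000
```

Niche-structured fixtures (`mode = "niche"` or `"mixed"`) reverse both
results: strong seasonal separation (larger on the coast than the shelf)
and a degraded neutral fit. The scripts in `analysis/` (01 simulate …
07 network) run the full sequence and write their tables under `results/`.

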