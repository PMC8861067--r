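# migcomp

Analysis of the species composition of trans-Saharan migrant passerines
at island stopover sites, built around standardized spring ringing on
nine western Mediterranean islands.

Migrants crossing the Mediterranean in spring can only pause on islands.
Which islands they choose — and therefore which species mix each island
receives — depends on continental source abundances, on each island's
geographic position (especially its distance to the nearest large land
mass toward the south) and on its habitat (area, altitude, vegetation).
`migcomp` implements the full analysis chain for ringing data of this
design, for community ecologists working with island-year × species
capture matrices:

* **Eligibility filters and chord transformation** — island-years with at
  least a week of ringing per fortnight of the standard window; species
  ringed in ≥ 5 years or on ≥ 5 islands; row normalization
  `y'ᵣⱼ = yᵣⱼ / √Σⱼ yᵣⱼ²` so Euclidean distance equals chord distance.
* **Beta diversity as total variance** — `SS_Total = Σᵢⱼₖ (yᵢⱼₖ − ȳⱼ)²`,
  `BD_I,T = SS_Total/(N−1)` ∈ [0, 1] under the chord transform, with local
  (LCBD) and species (SCBD) contributions, partitioned into a
  between-island component `BD_I = SS_I/(n−1)`, a pooled temporal
  component `BD_T = SS_Temp/(Y−n)` and per-island temporal components
  `BD_Ti = SS_Temp,i/(Yᵢ−1)`.
* **Permutation inference** — PERMANOVA on chord coordinates, homogeneity
  of multivariate dispersion with small-sample bias adjustment, pairwise
  island contrasts with Benjamini–Hochberg FDR.
* **Constrained ordination** — RDA of composition on log-transformed
  island descriptors, iterative VIF screening, permutation-based forward
  selection, Ezekiel-adjusted R², two-block variance partitioning, and
  species/descriptor–axis association tables.
* **Species response models** — per-species Poisson / nbinom1 / nbinom2
  count GLMs with ringing-effort offsets (share-of-captures or
  captures-per-100 m-net modes), AICc family and shape selection, and a
  per-descriptor summary of positive / negative / intermediate responses.
* **Wing shape and phylogeny** — Kipp wing-pointedness index, Brownian
  phylogenetic covariances from Newick trees, PGLS with Pagel's λ
  (ML-profiled on [0, 1]) and likelihood-ratio tests of phylogenetic
  signal for comparing wing shape between response groups.

The ringing database behind the original study is available only on
request, so the package ships (a) the published nine-island descriptor
table as a fixture and (b) a synthetic-data generator
(`simulate_ringing()`) that reproduces the study design — the real island
covariates, the published 5–16 used years per island (74 island-years),
35 species spanning three orders of magnitude of continental abundance,
overdispersed counts, and a planted response structure (10 area
responders, 20 southern-distance responders) linked to wing shape.
Every stage is validated against independent brute-force oracles and
recovery simulations.

## Worked example

```r
library(migcomp)

# Published per-island summary: mean LCBD vs island temporal beta diversity
isl <- island_descriptors()
r <- cor_with_p(isl$LCBD, isl$BDTi)
#> r = 0.916, p = 0.00052

# A full synthetic nine-island world, then the core partition
cfg <- synthetic_config()
sim <- simulate_ringing(cfg, seed = 42)
tm  <- chord_transform(pivot_records(sim$records))
beta_partition(tm)
#> Beta diversity partition (74 island-year samples, 9 islands)
#>   Total  BD_I,T = 0.3439  (SS_Total = 25.1066)
#>   Island BD_I   = 0.1669  (SS_I = 1.3349)
#>   Temporal BD_T = 0.2333  (SS_Temp = 15.1648)
#> Per-island temporal beta diversity and mean LCBD:
#>            Y_i  BD_Ti mean_LCBD
#> Aire        16 0.2074    0.0127
#> Cabrera      8 0.1921    0.0099
#> ...

permanova(tm, n_perm = 999, seed = 42)
#> PERMANOVA (pseudo-F)
#>   F(8, 65) = 5.3267, permutation p = 0.001 (999 permutations)
```

The correlation of 0.916 says that islands whose composition fluctuates
more between years (high `BD_Ti`) also contribute more to overall beta
diversity (high mean LCBD). In the synthetic world, total beta diversity
(0.34) splits into a between-island component (0.17) and a within-island
temporal component (0.23), and the PERMANOVA confirms that composition
differs between islands. `run_pipeline(pipeline_config(out_dir, seed))`
executes every stage end to end and writes one CSV per result table plus
a log of every filter decision.

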