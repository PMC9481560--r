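# cdclust — boundary-seeking clustering by local direction centrality

`cdclust` clusters point sets — typically 2–5 dimensional embeddings
(UMAP/t-SNE) of single-cell RNA-seq, CyTOF or other feature data — with
the CDC algorithm, which handles the two regimes that defeat
density-based methods: **heterogeneous density** (sparse clusters get
split or discarded) and **weak connectivity** (nearly-touching clusters
get merged).

## The idea

For each point, the k nearest neighbours define a local **Direction
Centrality Metric (DCM)**. In 2D, the neighbour directions cut the circle
into central angles α₁…α_k (Σαᵢ = 2π) and

```
DCM = k / (4(k−1)π²) · Σᵢ (αᵢ − 2π/k)²  ∈ [0, 1]
```

— 0 when the point is surrounded evenly in all directions (cluster
interior), 1 when all neighbours lie one way (cluster rim). In d ≥ 3 the
neighbour directions are mapped onto the unit hypersphere; the facets of
their convex hull subdivide the sphere, each facet's Gram-determinant
simplex volume (plus an equal share of the global surface deficit) plays
the role of an angle, and the DCM is the analogous normalized variance of
the f subdivision-unit volumes.

Points with DCM ≥ T_DCM form the cluster **boundary**; each internal
point's *reachable distance* rᵢ is its distance to the nearest boundary
point; internal points i, j connect iff d(pᵢ, pⱼ) ≤ rᵢ + rⱼ (the boundary
acts as a cage that blocks cross-cluster connections); boundary points
join their nearest internal point. The threshold is set as a rank of the
DCM distribution via `ratio`, the fraction of internal points (default
0.9), or estimated from the data: in 2D, Euler's formula on the Delaunay
triangulation gives the expected boundary-point count B = 2V − F − 2C
after cross-cluster triangles are removed by a mutual-KNN rule.

Also included: KNN-based noise filters (inverse-distance, reverse-KNN,
local outlier factor) sharing the clustering k, the external metrics
ACC / NMI / ARI / pairwise-F1, seeded generators for the
heterogeneous-density, weak-connectivity, ring-island, spindle and
background-noise regimes, strict CSV/TSV readers/writers, and a CLI.

## Worked example

```r
library(cdclust)

# three Gaussian blobs of very different size and density
ds <- genBlobs(1000, centers = rbind(c(0, 0), c(12, 0), c(6, 10)),
               sigmas = c(0.4, 1.0, 0.7), weights = c(1, 3, 2), seed = 42)
x <- pointCoords(ds)

estimateK(nrow(x))          # empirical k range for n = 1000
#> $kLow  20   $kHigh  50   $k  35

part <- cdcCluster(x, k = 35, ratio = 0.95)
part
#> CdcPartition: 1000 points, 3 clusters
#>   internal: 950  boundary: 50  noise: 0
#>   k = 35 , DCM threshold = 0.2094

table(clusterLabels(part))
#>   1   2   3
#> 167 500 333

round(evaluateClustering(trueLabels(ds), clusterLabels(part)), 4)
#> acc nmi ari  f1
#>   1   1   1   1
```

The three blobs are recovered exactly (all agreement metrics 1) even
though their densities differ several-fold: the 950 internal points are
caged by the 50 highest-DCM rim points, and the reachable-distance rule
never crosses a rim. The printed threshold (0.2094) is the 50th largest
DCM — the same partition is reproduced by
`cdcCluster(x, k = 35, threshold = 0.2094)`.

The adaptive 2D threshold needs no ratio at all:

```r
g <- buildKnn(x, 35)
est <- estimateTdcm(x, g, computeDcmField(x, g))  # Euler-formula estimate
c(est$B, est$ratio)
#> 42.000  0.958
```

From the shell:

```sh
Rscript inst/cli/cdc.R simulate blobs --n 600 --clusters 3 --seed 5 \
    --out data.csv --labels truth.csv
Rscript inst/cli/cdc.R cluster data.csv --k auto --ratio 0.9 \
    --out labels.csv --truth truth.csv --report report.txt
Rscript inst/cli/cdc.R evaluate truth.csv labels.csv
```

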