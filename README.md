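# tilmap

Quantification of tumor-infiltrating lymphocytes (TILs) in
immunohistochemistry image tiles by **density-map regression**, with a
topological introspection suite for the network's deep features.

## The problem

Counting CD3⁺ T cells on stained tissue slides is prognostically relevant
(e.g. in neuroblastoma) and infeasible to do by hand at whole-slide scale.
Bounding-box detectors struggle with packed, irregular cell clusters; the
density-map formulation sidesteps instance boundaries entirely. Each
annotated cell center \(c_k\) contributes a Gaussian bump,

\[ M = \hat M * G_K, \qquad
   G(x, y; \sigma) = \tfrac{1}{2\pi\sigma^2} e^{-(x^2+y^2)/2\sigma^2}, \]

with a unit-mass kernel so that \(\int M\) equals the cell count
(defaults: σ = 4 px ≈ one lymphocyte radius at 0.5 µm/px, window
l = 25 px). A five-stage U-shaped encoder–decoder with concurrent
spatial/channel squeeze-and-excitation (scSE) attention regresses \(M\)
from RGB tiles under a pixel-wise MSE loss (η = 10⁻², plateau scheduler
η ← 0.2 η after 10 stale epochs). Predicted maps are turned back into
coordinates by a deterministic pipeline — negative clipping → Otsu
threshold → seeded watershed → density-weighted centers of mass — and
scored by Hungarian-matched precision/recall/F1 at an 8 px (≈ 4 µm)
acceptance radius, plus ordinal count-class metrics (quadratic-weighted
Cohen's κ, multiclass MCC) over the bins 0, 1–5, 6–10, 11–20, 21–50,
51–200, >200. Per-slide immune density is
\(L = \ln\big(\tfrac1n \sum_i c_i / A_i\big)\) in cells/mm².

Because real CD3 cohorts are proprietary, the package ships a
synthetic-tile simulator (DAB-brown anisotropic blobs on textured tissue
background, slide-grouped cohorts with leakage-safe splits) as a
first-class module, so the entire pipeline is testable end to end. The
introspection suite adds Vietoris–Rips persistent homology (H0/H1), Betti
curves, TwoNN intrinsic-dimension estimation, and UMAP + HDBSCAN
clustering of flattened hidden-layer activations.

## Worked example

```r
library(tilmap)

co <- generate_cohort(n_slides = 4, tiles_per_slide = 3, seed = 7,
                      width = 128, height = 128,
                      count_sampler = function(n) rpois(n, 12))
co
#> <cohort> 12 tiles / 4 slides (9 train, 3 test), 128x128 px

tile <- render_tile(co, co$manifest$tile_id[1])
tile
#> <annotated_tile> 128x128 px, 19 cells, slide 'slide-01', 0.50 um/px

target <- build_density_map(tile)
target
#> <density_map> 128x128, mass 18.2034 (d=1, sigma=4, l=25)
```

The map's mass is the cell count minus border truncation (19 cells, two
near an edge). Detection on this ground-truth map recovers the isolated
cells exactly; packed clusters (the hard case that motivates the method)
merge under the default watershed scale:

```r
pred <- detect(target)
detection_scores(match_detections(tile$annotations, pred))
#> precision    recall        f1
#>     1.000     0.737     0.848
```

The topological worked example — six vertices of a unit hexagon — gives
the textbook persistence diagram: six H0 features born at 0 (five dying at
the side length 1, one essential) and one H1 loop alive on \([1, \sqrt3)\):

```r
pd <- vr_persistence(cbind(cos(0:5 * pi / 3), sin(0:5 * pi / 3)))
betti_number(pd, 1, dim = 0); betti_number(pd, 1, dim = 1)
#> [1] 1
#> [1] 1
```

A full simulate → targets → train → detect → evaluate → quantify chain is
exposed on the command line:

```sh
Rscript -e 'tilmap::run_cli()' simulate --slides 8 --tiles 10 --seed 11 --out run1
Rscript -e 'tilmap::run_cli()' targets  --dir run1
Rscript -e 'tilmap::run_cli()' train    --dir run1 --epochs 20 --preset tiny
Rscript -e 'tilmap::run_cli()' predict  --dir run1
Rscript -e 'tilmap::run_cli()' detect   --dir run1
Rscript -e 'tilmap::run_cli()' evaluate --dir run1
Rscript -e 'tilmap::run_cli()' quantify --dir run1
Rscript -e 'tilmap::run_cli()' report   --dir run1
```

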