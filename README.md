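# landtrax

Trajectory-based detection of cropland conversion from annual categorical
land-cover raster time series, with representative-yield differentials and
habitat-impact accounting.

`landtrax` is aimed at landscape ecologists and land-use analysts who work
with CDL/NLCD-style products: annual 30 m crop-specific rasters plus a
handful of sparse-epoch land-cover snapshots. It answers three linked
questions: *where and when* did land convert between cropland and
noncropland, *how productive* is the newly converted land relative to
existing cropland, and *what habitat* was lost in the conversion. Because
national archives are far too large for development and testing, the
package ships a seeded synthetic-scene generator with known ground truth,
and every stage is validated against it end to end.

## The method

**Detection.** Each year's legend raster is consolidated to binary
crop/noncrop. The per-pixel year sequence becomes a single trajectory code,
and an 8-neighbour majority filter with a one-half replacement threshold is
applied once to the trajectory composite, cleaning edge pixels and isolated
spatio-temporal anomalies simultaneously. Trajectories are then reduced to
five transition classes — stable noncropland, stable cropland, conversion
to cropland, conversion to noncropland, intermittent (rotational)
cropland. A conversion requires the old class in the two preceding annual
years *and* the two most recent sparse-epoch products, the new class in
the two years from the switch onward, and exactly one switch overall;
pixels cropped in ≥ 2 years that switch more than once are intermittent.
Conversions between chronically confused classes (fallow/idle or alfalfa
vs. non-alfalfa hay or grassland/pasture) and developed→crop transitions
are excluded. Finally a 5-acre minimum mapping unit is enforced on the
composite transition map: contiguous patches under 23 pixels (at 30 m) are
removed and voids filled from the nearest surviving patch.

**Yield differentials.** A random-forest regression (250 trees, mtry 21
clamped to the covariate count, node size 5, 30% holdout) is trained on
zone × crop × year records pairing reported yields with zonal covariate
means, then applied pixel-wise to map representative yields y_gc. Each
new-cropland pixel is compared with references:

    diff_nat = (y_gc − y_nat) / y_nat        y_nat: frequency-weighted
                                             mean over stable cropland
    diff_loc = (y_gc − y_neigh) / y_neigh    y_neigh: mean over existing
                                             cropland in the pixel's
                                             10 km × 10 km block

with the national summary of diff_loc area-weighted by the new-cropland
extent of each block.

**Habitat accounting.** Milkweed stems lost = Σ acres × stems/acre by
(cover × CRP) stratum, SE propagated in quadrature; duck breeding-pair
accessibility from categorical range maps via the category-midpoint rule
(60–80 pairs/sq mi → 70; the open-top > 100 class → 110); long-term
habitat = never cultivated or pasture/hay in any epoch of a multi-decade
record. Expected accuracy of each conversion is the product of the binary
superclass accuracies of the post class in the conversion year and the pre
class the year before: `SA_yoc × SA_(yoc−1)`.

## Worked example

```r
library(landtrax)

cfg   <- scene_config(noise_rate = 0.02, speckle_patch_count = 12, seed = 42)
scene <- generate_scene(cfg)          # 200 x 200 px, 2008-2017, known truth

tmap <- reclassify_binary(scene$series) |>
  encode_trajectories() |>
  majority_filter() |>
  classify_transitions(scene$epochs) |>
  attribute_conversion(scene$series) |>
  apply_refinements() |>
  enforce_mmu(pixel_threshold(5, 30))

tidy(tmap)
#> # A tibble: 5 × 3
#>   class          n_pixels acres
#>   <chr>             <int> <dbl>
#> 1 stable_noncrop    15380 3420.
#> 2 stable_crop       12751 2836.
#> 3 to_crop            4271  950.
#> 4 to_noncrop         2695  599.
#> 5 intermittent       4903 1090.
```

Each row is the post-MMU extent of one transition class; at 30 m a pixel
is 0.2224 acres, so 4271 to-crop pixels are ~950 acres of detected
cropland expansion. Against the scene's planted truth this run scores
precision 0.998 and recall 0.994 on conversion pixels despite the 2%
salt-and-pepper label noise and the planted sub-MMU speckle — the
filtering and MMU stages trade a little recall for high map confidence.

The category-midpoint rule used for breeding-pair accessibility:

```r
category_midpoints(default_pair_categories())
#> # A tibble: 6 × 4
#>   category   low  high density
#>      <int> <dbl> <dbl>   <dbl>
#> 1        1     0    20      10
#> ...
#> 4        4    60    80      70
#> 6        6   100    NA     110
```

`autoplot(tmap)` draws the five-class map; `run_pipeline(pipeline_config())`
executes every stage (simulation → trajectories → classification → MMU →
yields → differentials → habitat → accuracy) and writes ASCII-grid/CSV/JSON
artifacts plus a checksummed manifest, reproducible under a fixed seed.
A thin CLI wrapper lives at `exec/landtrax` (`landtrax run-all --seed 1
--out dir/`).

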