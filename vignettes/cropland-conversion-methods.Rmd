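---
title: "Detecting cropland conversion and its consequences: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cropland conversion and its consequences: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landtrax)
```

`landtrax` implements a trajectory-based analysis of cropland expansion
and abandonment for CDL/NLCD-style inputs: a decade of annual 30 m
crop-specific rasters corroborated by a few sparse-epoch land-cover
snapshots. This vignette explains the model and its assumptions, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the numerical and design choices made where the method
left room.

## 1. The detection model

Land-cover classifiers tell crop from non-crop far more reliably than
they tell one class from another, so conversion is detected at the
binary level and the thematic detail is re-attached afterwards.

1. **Binary consolidation.** Every legend class maps to crop, noncrop,
   or excluded (`default_legend()` shows the grouping used by the
   generator; cultivated fallow and alfalfa count as cropland). Excluded
   classes (e.g., water) are masked throughout.
2. **Trajectory encoding.** The per-pixel sequence of binary labels over
   the years becomes a single integer code with an invertible code book.
   Two pixels share a code exactly when their temporal patterns are
   identical.
3. **Majority filtering on the composite.** An 8-neighbour majority
   filter replaces a pixel's trajectory by a neighbouring one when that
   single alternative occupies at least half of the valid neighbourhood
   (`ceiling(valid/2)`; ties between two qualifying values go to the
   smaller code, making the pass deterministic). Filtering the multiyear
   composite — not each year — is what lets one pass remove anomalies in
   space *and* time: a pixel mislabelled in one year differs from its
   whole field in trajectory space and is restored wholesale. Edge
   pixels use only in-grid neighbours; excluded pixels pass through and
   never count toward a majority. The filter runs once by default
   (`passes` is exposed); iteration to convergence is not part of the
   method.
4. **Five transition classes.** A single-switch trajectory whose old
   class holds in the two preceding annual years and in the two most
   recent epoch products before the switch, and whose new class holds
   from the switch year onward (two years minimum), is a conversion;
   the conversion year is the first year of the new class, so a switch
   between 2011 and 2012 is dated 2012. Unbroken sequences are stable.
   Sequences cropped in at least two years that switch more than once
   are intermittent (rotational) cropland. Everything else — including
   single-switch candidates that fail epoch corroboration or sit too
   close to the series edge — falls back to intermittent when it meets
   the two-cropped-years rule and otherwise to the stable class of its
   majority group. The fallback is deliberately conservative toward
   non-conversion: the method prioritises map confidence over
   completeness. With annual input 2008–2017 and epochs 2001/2006/2011
   this rule enforces 6–10 years of prior evidence of the old state
   (`prior_evidence_span()`), and the earliest datable conversion year
   is the third annual year. When only one epoch predates an early
   switch, that epoch must agree and the pixel is flagged in a QA band.
5. **Attribution.** Covers are re-identified from the original legend
   rasters: the preceding cover is the modal legend code of the two
   pre-switch years (a tie goes to the more recent year — the state at
   conversion), the following cover is the code of the conversion year
   itself, the first planting.
6. **Refinement exclusions.** Apparent conversions between fallow/idle
   cropland or alfalfa and non-alfalfa hay or grassland/pasture (in
   either direction) are reassigned to the stable class of their
   final-year group, as are developed→crop transitions. These pairs are
   configuration (`refinement_rules()`), so tree crops, rice, or other
   special classes can be added as exclusion lists without code changes.
7. **Minimum mapping unit.** A 5-acre MMU (23 pixels at 30 m, using
   1 acre = 4046.8564224 m²) is enforced on the composite five-class
   map. Removal of all sub-threshold patches is simultaneous; each void
   pixel then adopts the class and attribution of the nearest surviving
   pixel (Euclidean distance between pixel centres; exact ties broken by
   smaller patch id, then pixel order — squared distances are integers,
   so tie detection is exact). Enforcing the MMU on the composite rather
   than per year is essential: newly converted fields are often detected
   in mixed-year salt-and-pepper fashion, and per-year filtering would
   remove fragments that jointly exceed the MMU (this is a tested
   property). Removal and fill iterate to a fixed point; ordinary scenes
   converge in one pass, and iteration guarantees idempotence in the
   rare geometry where a simultaneous fill strands a sub-threshold
   island.

Patch connectivity is 8-neighbour by default, consistent with the
filter's neighbourhood, and configurable to 4.

## 2. Yield modeling and differentials

Representative yields are modelled, not observed: a per-crop random
forest is trained on zone × year records (reported zonal yield against
zonal means of biophysical covariate grids within the crop's planted
extent) and then applied pixel-wise. The forest uses 250 trees, 21
candidate variables per split, and a minimum node size of 5, with a
random 30% holdout for validation; when fewer than 21 covariates exist
(as in small synthetic runs) mtry is clamped to the covariate count with
a warning. Predictions are deterministic under a fixed seed and bounded
by the training yield range, a property of regression forests. The model
represents average expected yields of the local biophysical setting —
not year-to-year weather, management anomalies, or genetic trend — so
only relative comparisons are meaningful, which is why the module
reports differentials rather than absolute production:

- national: `diff_nat = (y_gc − y_nat)/y_nat`, with `y_nat` the
  frequency-weighted mean prediction over stable cropland of the focal
  crop (weights default to 1 per qualifying pixel when per-year crop
  frequency rasters are not supplied);
- local: `diff_loc = (y_gc − y_neigh)/y_neigh`, with `y_neigh` the mean
  prediction over *existing* cropland in the pixel's enclosing 10 km
  block. Blocks are fixed, non-overlapping tiles anchored at the raster
  origin — a moving window would change the semantics of "encompassing
  neighbourhood" and cost far more; origin anchoring is the natural
  choice absent an administrative grid. The national summary is the
  area-weighted mean of block means, weighted by each block's
  new-cropland pixel count.

Both differentials are invariant under global rescaling of the yield
surface and the weighted mean of `diff_nat` over its own reference mask
is identically zero; both identities are tested to 1e-12.

## 3. Habitat accounting

- **Milkweed.** Stems lost = Σ over converted pixels of stems/acre of
  the pre-conversion cover (CRP-enrolled grassland carries its own,
  higher density) × pixel acres. The SE of the total treats strata
  (cover × CRP × zone) as independent and adds their absolute errors in
  quadrature — the propagation formula is not dictated by the accounting
  itself, and independence is the standard Pleasants-style assumption;
  it is documented rather than hidden. The shipped density table is an
  editable example, not an asserted estimate.
- **Waterfowl.** Breeding-pair accessibility maps arrive as categorical
  ranges; each closed range contributes its midpoint (60–80 → 70) and
  the single open-top class (> 100) a fixed 110 pairs/sq mi. Mean
  accessibility and total nesting opportunities (density × area, with
  1 sq mi = 640 acres) are reported for converted land, stable cropland,
  and unconverted habitat separately.
- **Long-term habitat.** A pixel is long-term habitat if no epoch of the
  multi-decade record labels it cultivated crops or pasture/hay; adding
  epochs can only shrink the mask (monotone, tested).
- **Biophysical contrasts.** Slope, land-capability class, hydric
  fraction, and climate water deficit are compared between new and
  stable cropland as means ± spatial SD (hydric as percent flagged).

**Accuracy propagation.** Each detected conversion's expected accuracy
is `SA(zone, post_cover, yoc) × SA(zone, pre_cover, yoc−1)` — correct
detection requires the pixel to be right both after and before the
change. Year-specific superclass accuracies take precedence; a table
with `year = NA` provides pooled values, so both schemas are accepted.

## 4. The synthetic-scene generator

The generator is first-class, tested code: it defines the study
conditions under which the pipeline's claims are verified.

It emulates: a rectangular-field landscape tiling the grid (side lengths
10–30 px by default on a 200 × 200 grid, ~100 fields); ten annual years
(2008–2017) with two in-series epoch snapshots standing in for the
sparse-epoch cadence; planted single-transition conversions and
abandonments placed inside the detectable window (after two annual years
and two epochs, at least two years before the series end); rotational
fields switching more than once with at least two cropped years;
independent per-pixel-per-year label flips to a random class of the
opposite binary group (salt-and-pepper confusion) at a configurable
rate; and sub-MMU speckle patches (3–4 px side) planted inside stable
noncropland fields as spurious conversion look-alikes. Default fractions
are 15% conversion, 5% abandonment, 10% intermittent — conversion-heavy
relative to real landscapes so that the statistics of interest are well
populated at desk scale. All randomness flows from one seed
(regeneration is bit-identical); covariate generation uses a derived
substream so scene layout is unchanged by yield options.

Two generator design choices exist purely to make the noiseless
invariant ("detection recovers planted truth pixel-for-pixel") hold
exactly, and they are worth understanding. A rectangle's corner pixel
has three same-field neighbours, so it is eroded by the half-threshold
filter whenever a single foreign trajectory occupies four of the
remaining five. That happens exactly when the field across the band
boundary and the lateral neighbour share a trajectory code. The
generator therefore (i) tiles the grid in brick fashion — each band has
its own column cuts, nudged off the cuts of the band above, so fields
meet at T-junctions — and (ii) assigns crop-leaning dynamics (stable
crop, conversion to crop) to odd bands and noncrop-leaning dynamics to
even bands, redrawing intermittent patterns that would collide
vertically. Together these guarantee no two vertically adjacent fields
share a binary trajectory, which is sufficient for corner stability.
This is a statement about the synthetic landscape, not the filter: on
real data the filter *does* nibble corners of fields whose neighbours
are jointly uniform, which is part of the confidence-over-completeness
trade the method makes.

What the generator does **not** emulate: real CDL class frequencies and
confusion structure (noise is independent per pixel-year, with no
spatial autocorrelation), radiometric effects, irregular field shapes
(an extension point), sub-pixel mixing, and registration error. Passing
tests therefore demonstrate the pipeline's logic — rule correctness,
filtering behaviour, conservation properties, statistical recovery —
not its skill on any real landscape.

## 5. Problem sizes, tolerances, and degenerate inputs

The validation suite runs scenes of 200 × 200 pixels × 10 years (the
default), which holds ~100 fields and populates every transition class;
oracle comparisons use one hundred 12 × 12 random grids against
brute-force stencil and flood-fill references; forest recovery uses
2,000 records (200 zones × 10 years) from a smooth 5-covariate response
with zero noise, where the holdout R² comfortably exceeds 0.9. These
sizes were chosen as the smallest at which every class and block
statistic is well populated.

Numerical choices worth noting: unit constants are fixed
(1 acre = 4046.8564224 m², 1 sq mi = 640 acres); the MMU pixel count is
the smallest n with n × pixel-area ≥ MMU; nearest-patch fills compare
squared integer distances so ties are exact and the patch-id tie-break
is reachable; algebraic identities are asserted at 1e-12, unit
arithmetic at 1e-9, stochastic recoveries at the generator's sampling
tolerance. Degenerate inputs are errors, not guesses: unmapped legend
codes (reported with pixel counts), empty reference masks, a
neighbourhood size that is not a pixel multiple, missing
accuracy-table keys (listed), missing density strata (named), and an MMU
scene whose patches are all sub-threshold. An empty prediction mask is
a valid request and returns an empty surface.

## 6. Known limitations

- The epoch products in the generator are sampled from the clean annual
  truth; real sparse-epoch maps have their own error structure, so epoch
  corroboration is exercised logically but not adversarially.
- The fallback class for single-switch candidates that fail epoch
  agreement is a design decision (intermittent, else stable-majority);
  other reasonable conventions exist and would change class totals at
  the margin.
- Milkweed SE propagation assumes independent strata; correlated
  density errors across counties would widen the true interval.
- The RF yield model is as good as its covariates; with few covariates
  mtry clamping changes the forest's variance profile relative to the
  full-scale configuration.
- Raster I/O is plain-text ASCII grid, fine for the scene sizes here
  but not for continental mosaics; the package deliberately does not
  attempt tiled or out-of-core processing.
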