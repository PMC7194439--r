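# endoquant

Quantification of EEA1-positive early endosomes during EGF/EGFR
endocytosis from multi-channel confocal z-stacks — and a synthetic-scene
generator with geometric ground truth that makes the whole pipeline
testable without microscope data.

## Who this is for

Cell biologists (and their analysts) quantifying punctate vesicular
staining in two-channel confocal images: how many marker-positive vesicles
per cell, how bright each one is, and what fraction of cargo-channel
objects touch marker-channel structures over an endocytosis timecourse.
The package re-implements, as tested reusable code, an ImageJ-style
protocol built around median-filter background subtraction and
object-based colocalization, plus the nonparametric statistics that go
with it.

## The method in brief

Per channel, on the 8-bit maximum-intensity projection of the stack:

1. **Enhance:** subtract the disk-median-filtered image (radius 6 px
   green / 10 px red by default) from the original — the local median
   tracks background, so vesicle edges sharpen and blur-driven area
   inflation at binarization is suppressed.
2. **Threshold:** scan all integer thresholds of the enhanced image and
   keep the one maximizing the Pearson correlation between the binary
   mask and the original intensities (Otsu and fixed thresholds
   available); binarize strictly (`pixel > t`).
3. **Filter particles:** label 8-connected components and keep those with
   calibrated area strictly greater than 20 000 nm².
4. **Measure:** integral density (sum of *original* image intensities
   over the footprint), area, centroid; per-cell summaries (count, mean
   integral density, total area).

Object-based colocalization is computed on the single base-plane optical
slice: a source object colocalizes if ≥ 1 of its pixels falls on the
target channel's binarized mask, reported as a percentage under an
explicit normalization (`by_source` or `by_target`), in both directions.

Statistics: Mann–Whitney U (exact for combined n ≤ 12 without ties,
tie-corrected normal approximation otherwise) for per-cell quantities vs
the unstimulated control; one-sample sign tests for densitometry fold
changes (band density / Ponceau loading density, relative to each
replicate's control lane) against 1; Bonferroni–Holm correction within
each family; boxplot five-number summaries with type-7 quartiles.

## Worked example

Simulate one stimulated-cell scene (90 EEA1-like vesicles, 60 cargo
objects of which 70% sit on hybrid two-domain endosomes), analyze it, and
read off the colocalization:

```r
library(endoquant)

cfg <- scene_config(n_green = 90, n_red = 18, n_hybrid = 42, seed = 7)
scn <- generate_scene(cfg)
res <- analyze_cell(scn$stack, run_config())

subset(res$summary, select = c(channel, n_vesicles, mean_integral_density))
#>   channel n_vesicles mean_integral_density
#> 1   green        132              5298.470
#> 2     red         60              5095.633

subset(res$coloc, normalization == "by_source",
       select = c(source_channel, n_source_objects, n_overlapping, percent))
#>   source_channel n_source_objects n_overlapping  percent
#> 1            red               60            42 70.00000
#> 3          green              132            42 31.81818
```

The green channel holds 132 vesicles (90 free + 42 hybrid domains), all
recovered; 42 of the 60 red objects touch green structures, i.e. 70%
cargo-to-marker colocalization, exactly the generator's geometric truth.

The numbered scripts under `analysis/` run the full study-style workflow
on simulated data and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_scenes.R        # scenes + densitometry to results/
Rscript analysis/02_segment_and_count.R      # count recovery on 15 clean cells
Rscript analysis/03_colocalization_timecourse.R
Rscript analysis/04_densitometry_stats.R     # sign tests + Holm under the null
Rscript analysis/05_subtraction_rationale.R  # why median subtraction, quantified
```

For instance `02` prints exact recovery of the ~150-vesicle baseline
population (`exact-count recovery: 100% of cells (bias 0.00)`) and `03`
recovers the programmed 10/50/70/40/10% colocalization course with
`max |estimate - truth|: 0.0 percentage points`.

## Layout

- `R/`, `src/` — the package: image I/O and projections, the scene
  generator, segmentation, quantification/colocalization, statistics, and
  the `run_simulate()`/`run_analyze()`/`run_recovery()` orchestration.
- `analysis/` — the numbered narrative drivers above.
- `vignettes/methods.Rmd` — model, parameter and design documentation.
- `tests/testthat/` — unit, property and end-to-end acceptance tests with
  independent brute-force oracles.
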