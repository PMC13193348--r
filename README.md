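# erquant

Quantitative image analysis of endoplasmic reticulum (ER) cisternae,
Golgi morphology and secretory traffic in plant cells.

## What it does, and for whom

The cortical ER is a network of ~40 nm tubules joined at three-way
junctions, interspersed with expanded cisternae. Cisternae are not all
alike: some are smooth sacs, some are punctured by nanoscale holes, and
some are dense tubular matrices whose compressed lumen excludes soluble
markers. These substructures sit below the resolution of confocal
microscopy, but they leave statistical fingerprints in the lumenal marker
channel. `erquant` is for cell biologists who want to read those
fingerprints quantitatively and reproducibly:

* **ER segmentation** — hysteresis thresholding of the network, cisterna
  identification by morphological opening, and an apparent tubule-radius
  estimate `r = 0.5 · FWHM_psf · med(I_tub)/med(I_cis)` that sets the
  texture neighbourhood scale.
* **Cisternal substructure metrics** — per-cisterna radial intensity
  profiles (edge → centre) and grey-level co-occurrence matrix (GLCM)
  texture properties. With normalised co-occurrence probabilities
  `p(i,j)` accumulated over all pixel pairs within a disc of radius `r`:
  contrast `Σ (i−j)² p(i,j)`, correlation
  `Σ (i−μᵢ)(j−μⱼ)p(i,j)/(σᵢσⱼ)`, energy `Σ p(i,j)²`, homogeneity
  `Σ p(i,j)/(1+|i−j|)`. Properties are pooled per image by pixel-weighted
  mean, and at least five cisternae are required before any averaging.
* **roGFP2 ratiometrics** — background- and bleed-through-corrected
  pixel-wise 405/488 excitation ratios with reducing/oxidising
  classification (reference means 0.45 cytosol, 1.34 ER lumen).
* **Golgi morphometry** — mean absolute curvature of B-spline fits to
  traced cisterna edges (`κ = |x′y″ − y′x″|/(x′²+y′²)^{3/2}`, averaged
  uniformly in arc length) and integrated shortest-distance widths
  between paired edge polylines.
* **Traffic quantification** — Golgi share of background-corrected
  ER+Golgi fluorescence (`100·G/(G+E)` over 3+3+1 polygon ROIs), apoplast
  secretion index (1.5 µm ring / interior mean ratio), and whole-ER
  intensity as a protein-amount proxy.
* **Statistics** — MANOVA (Pillai, Roy) → per-metric ANOVA with
  Bonferroni across metrics → Tukey HSD for texture; Kruskal–Wallis with
  a tie-corrected Dunn post-hoc elsewhere; the usual star convention.
* **Phantoms** — every stage is validated against synthetic scenes with
  known ground truth: tubule networks with three-way junctions, sac /
  nanohole / tubular-matrix cisternae, a Gaussian-PSF + Poisson + read
  noise imaging model, ratio pairs, and whole-cell scenes.

## Worked example

Run the packaged phantom study — hole-free sac cisternae versus
nanohole-punctured cisternae, eight images per condition — through
segmentation, texture metrics and the full statistical chain:

```r
library(erquant)
cfg <- pipeline_config(n_images = 8L)
res <- run_pipeline(cfg, out_dir = "results")

aggregate(cbind(contrast, energy, homogeneity) ~ condition,
          res$pooled, function(x) round(mean(x), 3))
#>   condition contrast energy homogeneity
#> 1 nanoholes    1.011  0.104       0.709
#> 2       sac    0.568  0.466       0.856

res$report$manova
#>     test   statistic approx_F      p_value
#> 1 Pillai   0.9978227 1260.299 1.481259e-14
#> 2    Roy 458.2905707 1260.299 1.481259e-14

subset(res$report$posthoc, metric %in% c("contrast", "energy", "homogeneity"))
#>        metric    comparison difference   p_adjusted stars
#> 1    contrast sac-nanoholes -0.4435663 3.430589e-14   ***
#> 3      energy sac-nanoholes  0.3620996 3.086420e-14   ***
#> 4 homogeneity sac-nanoholes  0.1468146 3.130829e-14   ***
```

Smooth sacs have higher energy and homogeneity and lower contrast than
nanohole cisternae — the texture ordering that reveals sub-resolution
cisternal substructure in diffraction-limited images. The same chain
reports the MANOVA omnibus and starred Tukey comparisons that a study
would quote.

Companion measurements work the same way:

```r
sc <- make_cell_scene(golgi_fraction = 30, spec = phantom_spec(seed = 5))
golgi_transport_fraction(sc$image$channels$marker, sc$rois)
#> transport_result: Golgi 30.3% of corrected ER+Golgi intensity

gp <- make_golgi_phantom(arc_radius_nm = 2000, base_width_nm = 37.5,
                         swelling_amplitude_nm = 6, seed = 2)
stack_summary(gp$traces)
#>   stack_id condition n_cisternae mean_width mean_width_range mean_curvature
#> 1   stack1   phantom           1    41.8647         11.11034    0.000507751
```

The recovered curvature (0.000508 nm⁻¹) matches the constructed arc
(1/2000 = 0.0005 nm⁻¹); the mean width exceeds the 37.5 nm baseline
because this phantom carries 6 nm swelling bumps, which also produce the
~11 nm width range.

See `vignettes/er-cisterna-analysis.Rmd` for the full account of the
models, parameter defaults and their rationale, and validation design.

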