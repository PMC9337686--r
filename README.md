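# NucleoGAN

Transformer-based in-silico nuclear labeling from actin-filament
images, with the downstream positional analysis that turns generated
images into a statistical statement about cell organization.

## The problem

In adherent cells the nucleus sits where the actin cytoskeleton puts
it. NucleoGAN frames that claim as a prediction task on two-channel
fluorescence image pairs: a generator G learns the mapping
`I_nucleus = G(I_actin)` from registered training pairs, and the
analysis then asks how often a *generated* nucleus lands within the
mean nuclear radius (r = 4 µm) of its *real* counterpart. Against a
geometric null — a uniformly placed centroid succeeds with probability
`p₀ = πr²/L²` in an L × L image — a high matched fraction is
overwhelming evidence for actin–nucleus positional coupling.

The package is aimed at quantitative cell biologists and method
developers who want the full chain runnable and testable on a desk:

* **Synthetic data** (`sampleScene`, `renderPair`, `makeDataset`):
  paired actin/nucleus tiles in which the nucleus centroid is a known
  deterministic functional of the rendered fibers (the
  intensity-weighted centroid of fiber midpoints), so parameter
  recovery can be verified exactly.
* **Translator** (`modelConfig`, `trainTranslator`, `predictNucleus`):
  CNN encoder → transformer (pre-norm MSA/MLP blocks over flattened
  feature-map tokens with learned position embeddings) → CNN decoder
  with multi-resolution output heads, plus a 4×4-downsampling
  discriminator. Trained under the pixel-weighted reconstruction loss

  `L_rec = Σ_x { α·M(x)·|I_out − I_gt| + (1 − M(x))·|I_out − I_gt| }`,
  α = 10,

  combined with an adversarial loss; the weighting counters the
  black-background class imbalance that otherwise collapses the
  generator to black images. All forward/backward passes are
  implemented in-package (BLAS matrix ops, C++ conv kernels) with
  finite-difference-verified gradients.
* **Detection** (`detectNuclei`): Otsu or fixed thresholding,
  4/8-connected component labeling, 50-px minimum area, regionprops
  (area, centroid, bounding box).
* **Matching** (`matchNuclei`, `matchedFraction`): greedy one-to-one
  pairing by descending bounding-box IoU (validated against exhaustive
  assignment), Euclidean centroid distances, count error
  `|N_GT − N_Gen|/N_GT × 100`.
* **Statistics** (`pRandomImage`, `pRandomCell`, `proportionCI`,
  `binomialTailLog10`, `placementReport`): image- and cell-level
  random-placement nulls (the cell-level null erodes the cell mask by
  the nuclear radius), Clopper–Pearson / Wilson / Wald intervals, and
  log-space binomial tails that stay finite when p-values underflow
  doubles.
* **Image metrics** (`l1Mean`, `psnr`, `ssim`) and a one-call
  orchestrator (`runPipeline`) that writes TIFFs, CSVs and JSON
  reports, byte-reproducibly per seed.

## Worked example

```r
library(NucleoGAN)

## simulate a two-cell tile and detect its nuclei
sc  <- sampleScene(2, 128, 0.8203, seed = 42, meanCellRadiusUm = 10)
rp  <- renderPair(sc, renderConfig(), seed = 42)
rec <- detectNuclei(rp$pair)
rec[, c("label", "area_px", "centroid_row", "centroid_col")]
#>   label area_px centroid_row centroid_col
#> 1     1      67     76.43284     70.73134
#> 2     2      93     81.36559     32.92473

## ground truth stored in the scene (row, col), for comparison:
t(vapply(cells(sc), function(c) c$nucleus_center, numeric(2)))
#>       [,1]  [,2]
#> [1,] 81.41 32.98
#> [2,] 76.43 70.69
```

Both detected centroids sit within a tenth of a pixel of the planted
truth. The statistics module reproduces the headline numbers of a
full-scale analysis directly from counts — 5,785 of 8,151 generated
nuclei matched within 4 µm:

```r
w <- proportionCI(5785, 8151, method = "wilson_score")
sprintf("matched fraction: %.1f%% +/- %.1f%%",
        100 * w$pHat, 100 * (w$upper - w$lower) / 2)
#> "matched fraction: 71.0% +/- 1.0%"

p0 <- pRandomImage(4, 159.41)      # 4-um radius in a 159.41-um image
sprintf("null p = %.3e (one out of %.0f)", p0, signif(1 / p0, 1))
#> "null p = 1.978e-03 (one out of 500)"

binomialTailLog10(8151, 5785, p0)  # log10 P(X >= k) under the null
#> -13512.9
```

A matched fraction of 71% where random placement succeeds once in 500
tries puts the tail probability thousands of orders of magnitude below
any significance threshold — the positional coupling is unambiguous.

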