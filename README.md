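# speckleseg

Vessel segmentation in laser speckle contrast images (LSCI) **without
target-domain labels**.

LSCI maps cerebral blood flow at high frame rates, but its speckle
noise, non-uniform illumination, and the absence of labeled datasets
make supervised vessel segmentation impractical. `speckleseg`
implements an unsupervised domain-adaptation pipeline for
neuroimaging researchers who have unlabeled speckle images and want a
trained segmenter anyway:

1. **Source domain**: labeled fundus-style vessel photographs
   (thin vessels, good SNR, public labels).
2. **Size matching**: thin retinal vessels are matched to thick
   cerebral vessels either by one pass of morphological dilation with
   the 3×3 cross kernel (*vdSM*) or by keeping only patches whose
   vessel-pixel ratio `N_p / N_t > 0.13` (*psSM*, strict inequality).
3. **Synthesis**: a cycle-consistent adversarial network (two residual
   generators, two patch discriminators) translates source patches into
   speckle style, trained on unpaired patches with

   `L = λ₁ L_GAN(G_A→B, D_B) + λ₂ L_GAN(G_B→A, D_A) + λ₃ L_cyc`,
   λ₁ = λ₂ = 1, λ₃ = 10 (least-squares adversarial terms, L1 cycle).
4. **Segmentation**: a U-Net trained on the synthetic speckle patches
   with their inherited labels under the Dice loss
   `L_dice = 1 − 2Σpᵢgᵢ / (Σpᵢ² + Σgᵢ²)`,
   either two-stage (synthesis first, then segmentation) or end-to-end
   (joint loss with an extra `λ₄ L_dice` term, λ₄ = 1).
5. **Inference**: 80×80 tiles → bilinear upsample to the network size →
   probability map → downsample → exact reassembly → threshold 0.5.
6. **Evaluation**: Otsu-threshold baseline, pixel-wise confusion
   metrics (DSC, precision, sensitivity, specificity), majority-vote
   ground truth, mean ± SEM aggregation.

A seeded synthetic vessel-image generator produces both domains
(thin-dark-vessel "fundus-like" and thick-bright-vessel "lsci-like"
with multiplicative speckle-style noise), so everything trains and
tests with no downloads. The networks run on a compact CPU training
engine built into the package (Rcpp im2col convolutions, hand-derived
backpropagation, Adam); all fits are bit-reproducible under a seed.

## Worked example

Desk-scale run on synthetic fixtures (this is the `tiny_config()`
preset: 64×64 images, 3-residual-block generators, depth-3 U-Net,
5/10 epochs — a few minutes on one CPU):

```r
library(speckleseg)

pair <- make_domain_pair(n_source = 12, n_target = 12, size = 64, seed = 7)
sp   <- split_dataset(length(pair$target$images), 0.8, seed = 7)
data <- list(source = pair$source,
             target = list(images = pair$target$images[sp$train]),
             test   = list(images = pair$target$images[sp$test],
                           labels = pair$target_labels[sp$test]))
rep <- run_experiment(data, strategies = c("otsu", "2step_vdsm"),
                      config = tiny_config(), seed = 7)
print(rep)
#> Segmentation metrics (mean ± SEM, %)
#>    strategy          DSC    precision  sensitivity  specificity
#>  2step_vdsm 68.89 ± 3.66 55.64 ± 4.84 90.90 ± 0.26 66.45 ± 1.69
#>        otsu 85.48 ± 1.66 86.02 ± 3.94 85.06 ± 0.57 93.82 ± 0.57

print(attr(rep, "models")[["2step_vdsm"]])
#> Domain-adaptation vessel segmenter
#>   strategy: 2step_vdsm, seed 7
#> Cycle-consistent synthesis model
#>   generators: 3 residual blocks, base 8 channels (68,417 params each)
#>   discriminators: 2 stride-2 layers, base 8 channels
#>   trained 5 epochs, weights (1, 1, 10), seed 7
#>   final losses: total 6.8002, cycle 0.6230
#> U-Net segmenter
#>   depth 3, base 8 channels, dropout 0.40, batchnorm on (32,841 params)
#>   trained 10 epochs at 64x64; final Dice loss 0.2802
```

Each row aggregates the four confusion-matrix metrics over the held-out
labeled target images (mean ± standard error, in percent). The adapted
segmenter finds essentially all vessel pixels (sensitivity 91%) but, at
this toy scale, over-segments (precision 56%): five epochs of 64×64
adversarial synthesis transfer intensity and caliber, not fine texture.
On these clean synthetic fixtures global thresholding is still
competitive — the ranking between strategies only becomes meaningful at
the full scale encoded in `default_config()` (256×256 patches, 9-block
generators, 150/100 epochs). `predict(fit, image)` segments any new
image via the tiling scheme.

A command-line wrapper over the same functions is installed at
`inst/cli/speckleseg` (subcommands `fixtures`, `run`, `segment`,
`evaluate`).

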