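# latfuse

Multi-modal medical image fusion via latent low-rank representation.

Clinical imaging modalities are complementary: CT resolves dense structure
(bone, implants), MR resolves soft tissue, PET/SPECT map function. Fusing a
co-registered pair into one image that keeps the detail of each source and
loses none of their energy is a standard pre-processing step for diagnosis
and treatment planning. `latfuse` implements a hybrid fusion pipeline for
pairs of co-registered single-channel images (and grayscale + RGB pairs for
PET/SPECT work) together with the five objective quality metrics used to
score fusion results.

## Method

Each source image `Img` (used directly as an H×W data matrix) is split by a
latent low-rank representation (LatLRR),

    min_{X,Y,Z}  ||X||_* + ||Y||_* + λ ||Z||_1
    s.t.         Img = Img·X + Y·Img + Z,

solved with an inexact augmented Lagrangian multiplier scheme (singular-value
thresholding and soft thresholding alternating with multiplier ascent). The
low-rank part `Img·X` carries fine-grained detail; the saliency projection
`Y·Img` carries energy; `Z` is sparse noise.

The two low-rank components are fused through:

1. **score maps** — a C=21-channel per-pixel class-score stack per
   component, from the FCN-32s/16s/8s fully convolutional architecture
   (external weights) or from a deterministic multi-scale
   derivative-of-Gaussian filter bank (default, no weights needed);
2. **weight maps** — per-channel ZCA whitening
   `K = U (Σ + ηI)^(-1/2) Uᵀ`, then a 5×5 windowed average of the per-pixel
   channel l1-norm;
3. **selection** — weighted local energy Φ and the weighted sum of the
   eight-neighborhood modified Laplacian Ψ, computed under the kernel
   `Ω = (1/16)[[1,2,1],[2,4,2],[1,2,1]]`; per pixel the final weight map
   takes source 1 where `Φ₁Ψ₁ ≥ Φ₂Ψ₂`;
4. **pyramid fusion** — Laplacian pyramids of the low-rank components and a
   Gaussian pyramid of the weight map, fused level-wise: a weight-steered
   convex blend where the local similarity `Q ≥ τ`, otherwise a local-energy
   winner-take-all, then pyramid reconstruction.

Saliency components are summed (`F_ls = Ls₁ + Ls₂`), and the final image is
`F = clip(F_lr + F_ls)`. Grayscale+RGB pairs go through BT.601 YUV: the luma
channel is fused, chroma passes through untouched.

Defaults: `λ = 0.8`, `τ = 0.8`, `C = 21`, `k = 2` (l1 window radius),
`r = 1` (Ω radius).

Quality metrics: entropy (EN), normalized mutual information (Q_MI),
gradient preservation (Q^AB/F), sum of correlations of differences (SCD),
and visual information fidelity for fusion (VIFF).

## Worked example

```r
library(latfuse)

# a co-registered synthetic CT/MR-style phantom pair (no downloads)
pair <- make_gray_pair(phantom_spec(size = 64, seed = 7))

res <- fuse_pair(pair$a, pair$b)
print(res)
#> fusion result 64x64 | stages: decompose -> score_maps -> zca_l1_weight_maps
#>   -> wle_wseml_fusion -> pyramid_fuse_low_rank -> sum_saliency -> combine
#>   | clipped 36.50%

fusion_metrics(pair$a, pair$b, res$fused)
#> EN 5.0128 | Q_MI 1.1385 | Q^AB/F 0.6651 | SCD 1.6443 | VIFF 0.6407

print(res$dec1)
#> LatLRR decomposition of a 64x64 image (converged)
#>   component energy  low-rank 64.78 | saliency 62.93 | noise 0.5652
```

The metric line reads: the fused image carries ~5 bits of histogram
information (EN), shares a normalized 1.14 of mutual information with the two
sources (Q_MI, ceiling 2), preserves 67% of source edge strength/orientation
(Q^AB/F, ceiling ≈ 0.975), correlates strongly with both sources after
removing the other (SCD, ceiling 2), and retains 64% of the sources' visual
information (VIFF, ceiling 1 per source-faithful copy). The clipped
percentage is reported because the saliency sum deliberately doubles shared
energy before the final clip.

A command-line interface wraps the same functions:

```sh
Rscript exec/latfuse fixtures --preset ct-mr --seed 7 --size 256 --out-dir fx
Rscript exec/latfuse fuse --img1 fx/a.png --img2 fx/b.png --out fused.png
Rscript exec/latfuse metrics --img1 fx/a.png --img2 fx/b.png --fused fused.png --out report.json
```

Every run writes a JSON provenance record (config, seed, versions).

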