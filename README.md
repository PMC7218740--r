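# pyrfuse

Multi-modality medical image fusion for co-registered 2-D grayscale pairs
(MR/CT, MR-T1/MR-T2, MR/PET slices): a Siamese convolutional patch
classifier supplies a per-pixel activity weight map, the sources are
decomposed by an invertible contrast pyramid, corresponding levels are
fused by region-energy and local-similarity rules, and the fused image is
reconstructed by the inverse transform. Four objective fusion metrics
(Tsallis-entropy index, QAB/F edge preservation, mutual information, VIF)
score the result. The package is aimed at researchers who need a
transparent, fully reproducible fusion baseline — everything, including
the CNN training loop, is implemented in the package and driven by seeds,
and a synthetic phantom generator removes any dependency on external
image archives.

## Method

**Weight map.** Two parameter-sharing branches (conv 3×3 → conv 3×3 →
2×2 max-pool → conv 3×3, ReLU throughout) embed a pair of co-located
16×16 patches; one fully connected layer maps the concatenated features
to two scores and a softmax f(pᵢ) = e^{pᵢ}/Σⱼe^{pⱼ} decides which patch
is *clear*. Training pairs come from progressively Gaussian-blurred
versions of sharp images (σ = 2, 7×7 support, five levels, 20 patch
positions per level, labeled both ways); optimization is momentum SGD
(momentum 0.9, weight decay 5·10⁻⁴, batch 128, Xavier init, lr 10⁻⁴ cut
to 10% at loss plateaus). For fusion, the fully connected head is
rewritten as an equivalent convolution so any-size pairs are scored
densely in one pass; binarized decisions are spread over their source
windows and averaged where windows overlap, yielding a weight map W of
the source size.

**Contrast pyramid.** With the separable 5-tap window w (center 3/8,
taps 1/16, 1/4, 3/8, 1/4, 1/16), REDUCE filters and halves, EXPAND
interpolates back with gain 4, and each level stores local luminance
contrast

    C_l = G_l / EXPAND(G_{l+1}) − 1,   C_N = G_N,

which is exactly inverted by G_l = (C_l + 1) ⊙ EXPAND(G_{l+1}).

**Fusion rule.** Per pixel of each level, window energies
E_A = Σ C_A², E_B = Σ C_B² and the bounded match measure
M = 2·Σ C_A C_B / (E_A + E_B) ∈ [−1, 1] are computed over a 3×3 region.
Where M < T the higher-energy source's coefficient is selected
(choose-max); where M ≥ T a weighted mean W_max·C_larger +
W_min·C_smaller is used with W_min = G_W (the Gaussian-decomposed weight
map) and W_max = 1 − W_min. Defaults: T1 = 3 for all levels below the
top — since M ≤ 1 these levels always choose-max — and T2 = 0.6 at the
coarsest level.

## Worked example

```r
library(pyrfuse)

# train the patch classifier on synthetic phantoms (seeded, ~1 min)
corpus <- training_corpus(40, shape = c(64, 64), seed = 1)
net <- train_siamese(siamese_net("small", seed = 2), corpus,
                     epochs = 4, seed = 3, verbose = TRUE)
#> epoch 1: loss 0.40917 (lr 0.0001)
#> epoch 2: loss 0.04061 (lr 0.0001)
#> epoch 3: loss 0.01568 (lr 0.0001)
#> epoch 4: loss 0.01013 (lr 0.0001)
net <- to_dense(net)

# fuse a pseudo-multimodal phantom pair
ph <- phantom_pair(c(128, 128), seed = 7)
res <- fuse_images(ph$a, ph$b, net)
res
#> Fused image 128x128 (pyramid depth 4, T1 = 3, T2 = 0.6); mean weight 0.827

fusion_metrics(ph$a, ph$b, res$fused)
#> q_te    0.199398
#> q_abf   0.674823
#> q_mi    4.678902
#> q_vif   0.287783
```

The per-epoch loss shows the classifier separating clear from blurred
patches within a few epochs. In the fusion result, `mean weight 0.827`
says the net judged source `a` (the rim/edge-dominated modality) the
more active source over most of the image. Against the plain averaging
baseline (`q_abf` 0.510, `q_vif` 0.213 on the same pair), the
pyramid fusion preserves substantially more edge structure
(`q_abf` 0.675) and visual information (`q_vif` 0.288); averaging scores
slightly higher on the pure intensity-histogram metrics (`q_mi`, `q_te`)
because it blends both sources' gray levels everywhere instead of
selecting the locally salient one.

A command-line wrapper is installed under `inst/scripts/pyrfuse`:

```sh
pyrfuse fixtures --out demo --n 1 --shape 128x128 --seed 7
pyrfuse train --out net.rds --images 40 --epochs 4 --seed 1
pyrfuse fuse demo/phantom01_a.png demo/phantom01_b.png -o fused.png \
        --checkpoint net.rds --metrics
pyrfuse evaluate demo/phantom01_a.png demo/phantom01_b.png fused.png
```

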