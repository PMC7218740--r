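---
title: "Methods: CNN-guided contrast-pyramid image fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CNN-guided contrast-pyramid image fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyrfuse)
```

## The model

`pyrfuse` fuses two co-registered grayscale images by combining a learned
activity measure with a classical multi-scale transform.

The *activity measure* is a Siamese patch classifier: two
parameter-sharing convolutional branches embed co-located 16×16 patches,
and a fully connected head plus softmax outputs the probability that the
first patch is the clearer of the two. Because sharpness is a relative,
local property, training data can be manufactured from any sharp image by
repeated Gaussian blurring (σ = 2, 7×7 support, five iterated levels) and
sampling co-located patch pairs — each position yields one positive
(clear first) and one negative (blurred first) example, so classes are
balanced by construction. Applied fully convolutionally, the classifier
scores every 16×16 window at stride 2 in one pass; binarized decisions
spread over their windows and averaged where windows overlap give a
per-pixel weight map $W \in [0,1]$ for the first source.

The *transform* is a contrast pyramid built on the separable 5-tap window
$w$ whose taps solve the four classical constraints (separability,
normalization, symmetry, equal odd/even contribution) given the center
weight $w(0)$; the default $w(0) = 3/8$ gives $(1/16, 1/4, 3/8, 1/4,
1/16)$. With $G_0$ the image and $G_{l} = \mathrm{REDUCE}(G_{l-1})$,

$$C_l = \frac{G_l}{\mathrm{EXPAND}(G_{l+1})} - 1, \qquad C_N = G_N,$$

each level stores local luminance contrast — the quantity the human
visual system is most sensitive to — and the decomposition is exactly
invertible via $G_l = (C_l + 1) \odot \mathrm{EXPAND}(G_{l+1})$.

The *fusion rule* works per pixel and per level on a small window
(default 3×3): with region energies $E_A = \sum C_A^2$, $E_B = \sum
C_B^2$ and the bounded match measure

$$M = \frac{2 \sum C_A C_B}{E_A + E_B} \in [-1, 1],$$

a similarity threshold $T$ splits the domain into *distinct* regions
($M < T$), where the higher-energy coefficient is selected, and
*redundant* regions ($M \ge T$), where a weighted mean is used with
$W_{\min} = G_W$ (the Gaussian pyramid of the weight map at that level)
and $W_{\max} = 1 - W_{\min}$, $W_{\max}$ applied to the higher-energy
source. The defaults $T_1 = 3$ (levels below the top) and $T_2 = 0.6$
(top level) mean the detail levels always use choose-max — $M$ cannot
exceed 1 — while the coarse approximation blends under the weight map's
control. Both thresholds are plain configuration (`fusion_config()`),
so other operating points are one argument away.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `center_weight` | 3/8 | – | kernel shape; 1/2 degenerates to a 3-tap triangle |
| `depth` | 4 (auto-capped, coarsest ≥ 8 px) | levels | trade-off between spatial selectivity and coarse blending |
| `T1` | 3 | – | similarity threshold below the top; values > 1 force choose-max |
| `T2` | 0.6 | – | top-level threshold; lower = more weighted blending |
| `window` | 3×3 | px | support of the energy/similarity statistics |
| `offset` | 0.01 | intensity | pre-decomposition shift keeping ratios away from 0/0 |
| `eps` | 1e-12 | – | denominator guard (used identically in both directions) |
| lr / momentum / decay / batch | 1e-4 / 0.9 / 5e-4 / 128 | – | SGD schedule of the classifier |
| blur σ, support, levels | 2 / 7×7 / 5 | px | training-set degradation model |
| patches per level | 20 | – | corpus density per image |

Channel counts of the three conv layers are configuration, not method:
the `"paper"` preset (64/128/256) follows the principle that feature
maps grow with depth; the `"small"` preset (16/32/64) is the desk-scale
default used by the test-suite — the clear-vs-blurred task saturates
well below the large preset's capacity.

## Numerical choices

* **Loss scale.** The training loss is the *sum* of per-example
  cross-entropies over a batch, and the stated learning rate 1e-4 is
  calibrated to that scale (with a batch-mean loss the same rate is 128×
  too small to move the weights appreciably). Reported epoch losses are
  per-example means for readability.
* **Plateau rule.** The schedule cuts the learning rate to 10% "when the
  loss reaches a steady state"; steady state is automated as a relative
  epoch-loss improvement below 1%, so training is reproducible.
* **Boundaries.** All filters (pyramid, blur, energy windows, Sobel)
  reflect about the edge pixel without repeating it; this keeps constant
  images exactly constant through REDUCE/EXPAND since the kernel rows
  sum to 1.
* **Odd sizes.** REDUCE ceil-halves; EXPAND takes an explicit target
  shape in {2d−1, 2d}, so round trips are exact for any size.
* **Division guards.** The contrast ratio is formed after an affine
  shift of the input to [0.01, 1.01] (zero backgrounds are the norm in
  medical images) and the identical guarded denominator
  $\mathrm{EXPAND}(G_{l+1}) + \varepsilon$ is reused during
  reconstruction, making the round trip exact to machine precision
  (≤ 1e-15 observed, against a 1e-9 contract).
* **Ties.** $E_A = E_B$ selects source A, deterministically. All-zero
  similarity windows define $M = 0$.
* **Dense borders.** Windows start at odd pixel offsets (stride 2, set
  by the single pooling stage); at most a one-pixel strip on the
  right/bottom of odd-sized images is uncovered and inherits the nearest
  covered weight.

## Design decisions

* **Bounded similarity.** The product-form denominator $E_A E_B$ is
  dimensionally inconsistent with the stated [−1, 1] range of the match
  measure (it is unbounded as energies shrink); the sum form
  $E_A + E_B$ is the standard match measure satisfying that range and is
  the default, with `similarity = "product"` retained for comparison.
* **Weighted branch orientation.** The two weighted-mean branches are
  distinguished by which source has the larger energy; the fourth branch
  of the combined per-pixel rule is the energy-mirrored image of the
  third ($W_{\min} C_A + W_{\max} C_B$ when $E_A < E_B$).
* **Unit image.** The subtractive term in the contrast definition is the
  all-ones image, making the decomposition an exact multiplicative
  residual; anything else would break invertibility.
* **QAB/F normalization.** The Xydeas–Petrović sigmoids evaluate to
  ≈ 0.975 at perfect preservation with their conventional constants
  (Γg = 0.9994, κg = −15, σg = 0.5; Γα = 0.9879, κα = −22, σα = 0.8);
  the package divides by that perfect-preservation value so an exactly
  copied image scores 1 and the index reads as a fraction of attainable
  preservation.
* **Tsallis index.** Only the metric's name fixes it, so the package
  defines it explicitly: with $I_q(X;Y)$ the order-$q$ generalized
  mutual information from 256-bin histograms, each source contributes
  $I_q(X;F)/\sqrt{I_q(X;X)\,I_q(F;F)}$ — a Tsallis analogue of a
  correlation coefficient, 2 in total when $F$ copies both sources and
  near 0 under independence. The raw Tsallis entropy of $F$ is exposed
  as `type = "entropy"`.
* **VIF.** Pixel-domain multi-scale VIF with Gaussian windows
  ($N = 17, 9, 5, 3$, sd $N/5$), channel noise variance 2 on the 0–255
  scale; scales that no longer fit the image are skipped (images below
  32 px per side are rejected).

## What the phantoms emulate — and what they do not

`phantom_pair()` renders one random geometric scene (rotated ellipses
and bars) twice: modality *a* brightens bone-like rims and sharp
boundaries, modality *b* soft-tissue-like interiors with smooth shading
and fine speckle, plus seeded Gaussian noise. This reproduces the two
properties the pipeline actually exercises — shared geometry with
complementary local detail, and locally differing sharpness — without
claiming MR/CT physics (no bias fields, no modality-specific noise
statistics, no partial-volume effects). Passing tests therefore
demonstrate the *mechanics* (exact transforms, correct rules, trainable
activity measure, sane metrics), not clinical image quality; on real
studies the classifier should be retrained or fine-tuned on
representative material.

Training at desk scale uses 64×64 phantoms: 200 images × 5 blur levels ×
20 positions × 2 orientations = 40,000 pairs, and the small preset
reaches its held-out plateau within 3 epochs — the property suite
asserts ≥ 90% accuracy on corpora from disjoint seeds. The pyramid
round-trip property runs over 1000 images of side 16–128; the fusion
rule is checked for exact agreement with a scalar per-pixel oracle on
100 random levels. These sizes are the package's chosen operating
points for routine verification; all of them scale up by changing one
argument.

## Known limitations

* Two sources only; color (PET/SPECT) studies are handled by a
  documented luminance-fusion convention in the CLI rather than true
  chroma modeling.
* Inputs must be co-registered; no registration is attempted.
* The contrast pyramid is 2-D; volumes are fused slice by slice.
* The published metric values for the original atlas studies are not
  reproducible here, since they depend on those images and on network
  weights that were never released; the package's property suite
  (round-trip exactness, oracle equivalence, trainability, metric
  ordering) is the substitute verification surface.
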