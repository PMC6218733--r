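---
title: "Texture-driven glioblastoma characterization by rank-two NMF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture-driven glioblastoma characterization by rank-two NMF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glioseg)
```

## The problem and the model

High-grade gliomas present four radiologically distinct compartments —
peritumoral edema, a necrotic core, contrast-enhancing active tumor, and
nonenhancing solid tumor — whose delineation on multimodal MRI (T2, FLAIR,
contrast-enhanced T1) drives surgical and radiotherapy planning. glioseg
segments all four without any training data, by casting each binary
tissue-vs-rest decision as an unsupervised two-endmember unmixing problem.

Every axial slice is described by a nonnegative feature-by-voxel matrix
$M \in \mathbb{R}_+^{m \times n}$: column $j$ holds the texture signature of
voxel $j$, namely the 16 Haralick statistics of the gray-level co-occurrence
matrix (GLCM) computed on a window centered at that voxel, stacked over the
contributing modalities. The linear mixture model assumes

$$M(:,j) = \sum_{k=1}^{2} W(:,k)\, H(k,j), \qquad \sum_k H(k,j) = 1,$$

i.e. each voxel's signature is a nonnegative combination of two endmember
signatures (tissue-of-interest and everything else), with abundances summing
to one. Rank-two NMF estimates $W$ and $H$; voxel $j$ is assigned to the
region of interest when $H(1,j) \ge H(2,j)$ (ties included) and to the
remainder otherwise.

Four such splits are chained hierarchically, each restricted to the mask the
previous stages left over:

1. **edema** within the brain mask, from T2+FLAIR texture (ROI = FLAIR-bright);
2. **necrosis** within the edema mask, from T1c texture (ROI = T1c-dark);
3. **enhancing tumor** within $I_1$ = edema $\setminus$ necrosis (T1c-bright);
4. **nonenhancing tumor** within $I_2 = I_1 \setminus$ enhancing (T1c-bright).

The four masks are disjoint by construction and assemble into the BraTS
label convention (1 necrosis, 2 edema, 3 nonenhancing, 4 enhancing,
0 elsewhere).

## GLCM features: conventions and corrections

The co-occurrence matrix of a window counts gray-level pairs at distance
$d$ (default 1) along the four principal directions; each pair is counted in
both orderings (symmetric GLCM), direction counts are averaged and the
result normalized to sum 1 — the rotation-invariant form Haralick
recommended. Gray levels are indexed $1..N$ in all formulas; logarithms are
natural (features are min–max rescaled per row before the factorization, so
the log base is immaterial downstream); $0\log 0 = 0$.

Three textbook formulas circulate in degenerate printed forms and are
implemented in their standard versions: correlation as
$\sum_{ij} (i-\mu_x)(j-\mu_y) G(i,j) / (\sigma_x \sigma_y)$ with
$\sigma$ the marginal *standard deviations* (so correlation is scale-free in
$[-1,1]$; $\sigma_x\sigma_y = 0$ returns 0); variance as
$\sum_{ij}(i-\mu)^2 G(i,j)$ with $\mu$ the GLCM mean gray level; sum
variance with $(k - \mathrm{SumEnt})^2$ weights over the sum distribution.
Dissimilarity uses $|i-j|$ — the signed form is identically zero on a
symmetric GLCM. Difference variance is kept as the raw second moment
$\sum_k k^2 p_{x-y}(k)$ (well defined, and what the feature tables in this
literature print), with the central-moment form available via
`haralick_features(..., difference_variance = "corrected")`. Every formula
is cross-checked in the test suite against a literal term-by-term
re-implementation.

## Tunable parameters

| parameter | default | why |
|---|---|---|
| `glcm$levels` | 32 | gray levels $N$ for *windowed* GLCMs. A global 256-level rescale is the classical preprocessing, but an 11×11 window yields ~440 pairs — far too few to populate a 256² matrix; 32 levels keep the matrix ~40% populated. $N = 256$ is supported for whole-slice work. |
| `glcm$window` | 11 | window side (odd, voxels). Smaller windows under-sample the GLCM (Dice drops measurably at 7); larger windows blur boundaries further. |
| `glcm$distance` | 1 | co-occurrence offset $d$, the classical default. |
| `nmf$tol` | 1e-5 | relative Frobenius-objective change for convergence. |
| `nmf$max_iter` | 500 | iteration cap; typical runs converge in well under 50. |
| `nmf$init` | `"spa"` | deterministic successive-projection initialization; `"maxnorm"` and seeded `"random"` exist for robustness experiments. |
| `pipeline$min_region_voxels` | 64 | per-slice floor below which a stage contributes nothing — a rank-two split of a handful of columns is meaningless; small residues keep the enclosing region's label. |

Windows are cropped at the slice border and at the stage mask (no padding);
only pixel pairs with both ends inside mask∩window are counted, so no
intensity outside the brain or the stage region ever influences a feature.
Quantization is per-slice over the stage mask: the masked intensity range is
mapped linearly onto $0..N-1$; a constant slice maps to level 0 (degenerate
range is not an error).

## Numerical choices

- **Row rescaling.** Each row of $M$ is min–max rescaled to $[0,1]$ within
  the stage mask. This enforces the nonnegativity the factorization needs
  (cluster shade/prominence may be negative) and stops 3rd/4th-power
  features from dominating the objective. Constant rows map to zero.
- **Solver.** Alternating exact nonnegative least squares; at rank 2 each
  per-column subproblem is solved in closed form by enumerating the three
  active-set patterns, so the objective is non-increasing by construction
  and the whole path is deterministic (no RNG by default).
- **Initialization.** Successive projection on L2-normalized columns:
  anchor at the largest-norm column, then two argmax-residual picks. The
  two-pass form makes the selection invariant to per-column scaling and
  recovers the pure columns of separable data even when the anchor itself is
  a mixture. All-parallel columns trigger a fallback to the two largest-norm
  columns.
- **Degenerate columns.** All-zero feature signatures (e.g. isolated masked
  pixels with no co-occurrence pair) are excluded from the factorization and
  routed to the background cluster; slices whose whole matrix is zero (e.g.
  a constant modality) contribute an empty mask rather than an error.
- **Ties.** The cluster rule sends $H(1,j) = H(2,j)$ to the region of
  interest; equal cluster mean intensities leave the polarity orientation
  unchanged.
- **Component orientation.** NMF does not label its components. Each stage
  picks as ROI the cluster whose mean intensity on the stage's driving
  modality matches the stage polarity (bright for edema/enhancing/
  nonenhancing, dark for necrosis) — the standard radiological semantics of
  those tissues.

## What the phantom emulates — and what it does not

`generate_phantom()` builds three co-registered modality volumes
(default 64×64×8) from nested ellipsoids: brain ⊃ edema extent ⊃ tumor
core, the core partitioned into central necrosis, an enhancing rim and a
nonenhancing region. Each compartment has a per-modality mean (edema
hyperintense on T2/FLAIR; enhancing rim bright and necrosis dark on T1c) and
its own spatially correlated noise (smoothed Gaussian, per-compartment
amplitude 5–20 units and correlation scale 1–2.5 voxels), so compartments
differ in *texture*, not only mean — the property the method actually
discriminates on. Intensities are integer-rounded and clipped at zero,
matching scanner-style storage; the generator is a pure function of its
spec, seed included.

It does **not** model MRI physics: no bias fields, no partial-volume mixing,
no anatomy (ventricles, CSF, gray/white contrast), no inter-case shape
variability. A green phantom test therefore establishes that the chain
quantization → windowed GLCM → LMM assembly → rank-two NMF → hierarchical
masking behaves as designed on texture-separable data; it does not certify
clinical-grade accuracy on real scans.

## Known limitations

- **Boundary bias.** Windows straddling a tissue boundary mix textures, and
  the edge itself has a high-contrast signature that clusters lesion-ward;
  on the default phantom all edema false positives form a 1–2 voxel shell
  just outside the true boundary (stage-1 Dice ≈ 0.89). For the same reason
  segmentation quality is *not* monotone in lesion contrast — raising
  contrast widens the overshoot shell faster than it improves in-region
  separation — so the test suite asserts a robustness band across contrast
  levels rather than monotonicity.
- **Binary splits over multi-tissue masks.** Stage 2 splits a mask that
  still contains four tissues; intermediate compartments attach to whichever
  endmember is nearer, and on the phantom the T1c-dark edema tissue joins
  the necrosis cluster, inflating that mask (core Dice ≈ 0.4 on the phantom
  while complete-tumor Dice ≈ 0.89). This is inherent to a rank-two split
  of a >2-class region and is the main reason core-region scores trail
  whole-tumor scores.
- Processing is strictly 2D axial slice-wise; a lesion visible on one slice
  only through partial-volume effects is invisible to the method.
- No morphological post-processing is applied anywhere, by design.

## Worked example

```{r example, eval = FALSE}
ph <- generate_phantom()                       # 64x64x8, seed 42
res <- run_pipeline(ph$t2, ph$flair, ph$t1c)
evaluate_segmentation(res$labels, ph$labels)
```

Typical output (the acceptance tests recompute these numbers):
complete-tumor Dice ≈ 0.89, sensitivity ≈ 0.98; the four stage masks are
pairwise disjoint and contained in the edema mask, and the whole run takes a
few seconds on one CPU.
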