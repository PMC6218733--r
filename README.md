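# glioseg

Unsupervised characterization of glioblastoma compartments — edema,
necrosis, enhancing tumor, nonenhancing tumor — from co-registered,
skull-stripped multimodal MRI (T2, FLAIR, T1c), for image-analysis
researchers who need a training-free baseline segmenter and a fully
synthetic test bed for it.

## Method

Each axial slice is encoded as a nonnegative feature-by-voxel matrix
*M* ∈ ℝ₊^(m×n): column *j* is the texture signature of voxel *j* — the 16
Haralick statistics (contrast, energy, entropy, correlation, …) of the
gray-level co-occurrence matrix computed on a sliding window centered at
the voxel, stacked over the contributing modalities and min–max rescaled
per feature. Under the linear mixture model

M(:,j) = Σₖ W(:,k) H(k,j),  Σₖ H(k,j) = 1,  W, H ≥ 0,  k = 1,2

a rank-two NMF (alternating exact nonnegative least squares from a
deterministic successive-projection start) recovers two endmember
signatures and per-voxel abundances; voxel *j* joins the region of interest
when H(1,j) ≥ H(2,j). Four such binary splits run hierarchically — edema
inside the brain mask (T2+FLAIR), then on T1c: necrosis inside edema,
enhancing tumor inside edema∖necrosis, nonenhancing tumor inside the
remainder — and assemble into a BraTS-convention label map
(1 necrosis, 2 edema, 3 nonenhancing, 4 enhancing, 0 elsewhere).
Evaluation reports Dice and sensitivity over the standard BraTS regions
(complete tumor = 1+2+3+4, core = 1+3+4, enhancing = 4).

## Worked example

```r
library(glioseg)
ph  <- generate_phantom()                    # synthetic 64x64x8 T2/FLAIR/T1c + truth
res <- run_pipeline(ph$t2, ph$flair, ph$t1c)
print(res)
evaluate_segmentation(res$labels, ph$labels)
```

```
<glioseg_result>
  edema          8723 voxels  (8 slices, mean residual 0.2901)
  necrosis       5150 voxels  (8 slices, mean residual 0.2131)
  enhanced       2006 voxels  (8 slices, mean residual 0.2299)
  nonenhanced    1264 voxels  (8 slices, mean residual 0.2058)
<glioseg_label_map> 64x64x8 voxels  counts: 0=24045 1=5150 2=303 3=1264 4=2006
     region      dice sensitivity n_pred n_truth n_intersect
1  complete 0.8909261   0.9768873   8723    7312        7143
2      core 0.3924731   0.8940034   8420    2368        2117
3 enhancing 0.4990826   0.6455696   2006    1264         816
```

The complete-tumor outline is recovered almost entirely (Dice 0.89,
sensitivity 0.98; the residual error is a 1–2 voxel shell at the lesion
boundary where windows mix textures). Core scores are lower because a
rank-two split of a mask that still holds four tissues attaches the
T1c-dark edema to the necrosis endmember — see the methods vignette's
limitations section. Per-stage NMF residuals and voxel counts are in
`res$stages$<stage>$diagnostics`.

Command line (same pipeline):

```sh
inst/cli/glioseg phantom --out /tmp/ph --seed 42
inst/cli/glioseg run --t2 /tmp/ph/t2.nii.gz --flair /tmp/ph/flair.nii.gz \
    --t1c /tmp/ph/t1c.nii.gz --out /tmp/ph/pred.nii.gz
inst/cli/glioseg eval --pred /tmp/ph/pred.nii.gz --gt /tmp/ph/truth.nii.gz \
    --report /tmp/ph/report.tsv
```

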