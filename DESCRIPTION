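Package: glioseg
Title: Hierarchical Glioblastoma Segmentation by Rank-Two NMF on GLCM Texture Features
Version: 0.1.0
Authors@R: person("glioseg", "maintainers", email = "glioseg@example.org", role = c("aut", "cre"))
Description: Characterizes glioblastoma compartments (edema, necrosis,
    enhancing tumor, nonenhancing tumor) from co-registered multimodal MRI
    (T2, FLAIR, T1c). Each axial slice is described by sliding-window
    gray-level co-occurrence matrix (GLCM) texture features; the resulting
    nonnegative feature-by-voxel matrix is interpreted as a linear mixture
    model and split into two clusters by a rank-two nonnegative matrix
    factorization. Four such binary splits, chained by mask subtraction,
    yield a BraTS-convention label map. Includes a synthetic multimodal
    phantom generator with ground truth, NIfTI-1 and MetaImage volume I/O,
    and Dice/sensitivity evaluation over the standard BraTS regions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
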