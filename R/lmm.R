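# Linear mixture model assembly: the nonnegative feature-by-voxel matrix M.
#
# Column j of M is the texture signature of masked voxel j; rows stack the 16
# Haralick features of each contributing modality (so m = 16 * n_modalities).
# Each row is min-max rescaled to [0, 1] over the stage mask: NMF requires a
# nonnegative M (cluster shade/prominence can be negative) and without
# rescaling the large-magnitude features (4th-power cluster prominence) would
# dominate the Frobenius objective.

#' Min-max rescale matrix rows to [0, 1]
#'
#' Each row is rescaled by its own finite (min, max); constant rows map to
#' all zeros. `NA`/`NaN` entries become 0 after scaling.
#'
#' @param M_raw numeric matrix.
#' @return list with `M` (nonnegative, same shape) and `row_scaling`
#'   (2-column matrix of the (min, max) used per row).
#' @export
rescale_rows <- function(M_raw) {
  stopifnot(is.matrix(M_raw), nrow(M_raw) >= 1L, ncol(M_raw) >= 1L)
  scaling <- t(apply(M_raw, 1L, function(r) {
    r <- r[is.finite(r)]
    if (length(r) == 0L) c(0, 0) else range(r)
  }))
  colnames(scaling) <- c("min", "max")
  span <- scaling[, "max"] - scaling[, "min"]
  M <- (M_raw - scaling[, "min"]) / ifelse(span > 0, span, 1)
  M[span == 0, ] <- 0
  M[!is.finite(M)] <- 0
  list(M = M, row_scaling = scaling)
}

#' Assemble the feature-by-voxel matrix of one slice
#'
#' Columns enumerate the masked voxels in fixed raster (column-major) order;
#' rows stack each modality's 16 feature planes, then every row is rescaled to
#' [0, 1] by [rescale_rows()]. Voxels whose features are all-`NA` (no valid
#' co-occurrence pair) become all-zero columns, which the factorization
#' routes to the background cluster.
#'
#' @param fmaps named list (by modality) of `nrow x ncol x 16` feature arrays
#'   from [feature_maps()].
#' @param mask 2D logical matrix, same in-plane shape as the feature maps.
#' @param intensity_slices optional named list (same modalities) of raw 2D
#'   intensity matrices; when given, one rescaled intensity row per modality
#'   is appended below the texture rows (off by default: texture is the
#'   model's feature space).
#' @return Object of class `glioseg_feature_matrix`: `M` (m x n nonnegative),
#'   `voxel_index` (n x 2 matrix of (row, col) per column), `row_labels`
#'   (modality:feature per row), `row_scaling`.
#' @export
build_matrix <- function(fmaps, mask, intensity_slices = NULL) {
  if (!is.list(fmaps) || length(fmaps) == 0L) stop("fmaps must be a non-empty list")
  if (!any(mask)) stop_glioseg("empty_mask", "build_matrix: mask selects no voxels")
  for (fm in fmaps) {
    if (!identical(dim(fm)[1:2], dim(mask)))
      stop_glioseg("shape_mismatch", "feature maps and mask shapes differ")
  }
  idx <- which(mask)                       # column-major raster order
  voxel_index <- cbind(row = ((idx - 1L) %% nrow(mask)) + 1L,
                       col = ((idx - 1L) %/% nrow(mask)) + 1L)
  n <- length(idx)
  mods <- names(fmaps)
  if (is.null(mods)) mods <- paste0("mod", seq_along(fmaps))
  M_raw <- do.call(rbind, lapply(fmaps, function(fm) {
    planes <- matrix(fm, nrow = prod(dim(fm)[1:2]), ncol = dim(fm)[3])
    t(planes[idx, , drop = FALSE])         # 16 x n
  }))
  row_labels <- as.vector(t(outer(mods, haralick_feature_names, paste, sep = ":")))
  if (!is.null(intensity_slices)) {
    ints <- do.call(rbind, lapply(intensity_slices, function(s) s[idx]))
    M_raw <- rbind(M_raw, ints)
    row_labels <- c(row_labels, paste0(mods, ":intensity"))
  }
  rownames(M_raw) <- row_labels
  bad <- colSums(!is.finite(M_raw)) > 0L   # voxels with no valid GLCM pair
  sc <- rescale_rows(M_raw)
  M <- sc$M
  M[, bad] <- 0
  structure(list(M = M, voxel_index = voxel_index, row_labels = row_labels,
                 row_scaling = sc$row_scaling),
            class = "glioseg_feature_matrix")
}
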