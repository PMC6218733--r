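# Dice / sensitivity evaluation over the standard BraTS regions.
#
# Regions: complete tumor = labels {1,2,3,4}; tumor core = {1,3,4};
# enhancing tumor = {4}. Metrics are computed in 3D over whole volumes.
# Empty-vs-empty masks score 1 for both metrics (a vacuously perfect match);
# empty-vs-non-empty scores 0.

BRATS_REGIONS <- list(complete = c(1L, 2L, 3L, 4L),
                      core = c(1L, 3L, 4L),
                      enhancing = 4L)

#' Binary mask of a BraTS evaluation region
#'
#' @param map a [label_map()].
#' @param region `"complete"` (labels 1+2+3+4), `"core"` (1+3+4) or
#'   `"enhancing"` (4).
#' @return 3D logical array.
#' @export
region_mask <- function(map, region = c("complete", "core", "enhancing")) {
  stopifnot(inherits(map, "glioseg_label_map"))
  region <- match.arg(region)
  array(map$data %in% BRATS_REGIONS[[region]], dim(map$data))
}

#' Dice overlap coefficient
#'
#' `2|A intersect B| / (|A| + |B|)`, in `[0, 1]`; 1 is a perfect match.
#'
#' @param pred,truth logical arrays of the same shape.
#' @return numeric scalar.
#' @export
dice <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop_glioseg("shape_mismatch", "dice: masks differ in shape")
  na <- sum(pred); nb <- sum(truth)
  if (na + nb == 0L) return(1)
  2 * sum(pred & truth) / (na + nb)
}

#' Sensitivity (true-positive rate)
#'
#' `|A intersect B| / |B|` with `truth` as B; 1 when all ground-truth voxels
#' are recovered.
#'
#' @param pred,truth logical arrays of the same shape.
#' @return numeric scalar.
#' @export
sensitivity <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop_glioseg("shape_mismatch", "sensitivity: masks differ in shape")
  nb <- sum(truth)
  if (nb == 0L) return(1)
  sum(pred & truth) / nb
}

#' Evaluate a predicted label map against ground truth
#'
#' Dice and sensitivity for the three BraTS regions, with the raw voxel
#' counts behind each score.
#'
#' @param pred,truth [label_map()]s of the same shape.
#' @return data frame (`glioseg_eval_report`) with one row per region:
#'   `region`, `dice`, `sensitivity`, `n_pred`, `n_truth`, `n_intersect`.
#' @export
evaluate_segmentation <- function(pred, truth) {
  stopifnot(inherits(pred, "glioseg_label_map"), inherits(truth, "glioseg_label_map"))
  if (!identical(dim(pred$data), dim(truth$data)))
    stop_glioseg("shape_mismatch", "evaluate_segmentation: label maps differ in shape")
  rows <- lapply(names(BRATS_REGIONS), function(rg) {
    a <- region_mask(pred, rg); b <- region_mask(truth, rg)
    data.frame(region = rg, dice = dice(a, b), sensitivity = sensitivity(a, b),
               n_pred = sum(a), n_truth = sum(b), n_intersect = sum(a & b))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("glioseg_eval_report", class(out))
  out
}

#' Write an evaluation report as a TSV table
#'
#' @param report a report from [evaluate_segmentation()].
#' @param path destination file.
#' @export
write_eval_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
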