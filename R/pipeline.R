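# Four-stage hierarchical segmentation.
#
# Stage 1 splits the brain into edema vs other tissue using T2+FLAIR texture;
# the remaining stages run on T1c texture inside a shrinking mask chain:
#   necrosis     inside the edema mask            (dark on T1c)
#   enhancing    inside I1 = edema - necrosis     (bright on T1c)
#   nonenhancing inside I2 = I1 - enhancing       (bright on T1c)
# Each stage processes axial slices independently: feature maps -> feature
# matrix -> rank-two NMF -> cluster rule -> polarity orientation, then the
# per-slice region-of-interest voxels are stacked into the stage's 3D mask.
# The final label map follows the BraTS convention (1 necrosis, 2 edema,
# 3 nonenhancing, 4 enhancing).

#' Default pipeline configuration
#'
#' @return nested list with components `glcm` (`levels` = 32, `window` = 11,
#'   `distance` = 1), `nmf` (`tol` = 1e-5, `max_iter` = 500, `init` = "spa",
#'   `seed` = 1), `lmm` (`include_intensity` = FALSE), `pipeline`
#'   (`min_region_voxels` = 64) and the per-stage modality/polarity table
#'   `stages`.
#' @export
default_config <- function() {
  list(
    glcm = list(levels = 32L, window = 11L, distance = 1L),
    nmf = list(tol = 1e-5, max_iter = 500L, init = "spa", seed = 1L),
    lmm = list(include_intensity = FALSE),
    pipeline = list(min_region_voxels = 64L),
    stages = list(
      edema       = list(modalities = c("T2", "FLAIR"), guide = "FLAIR",
                         polarity = "bright"),
      necrosis    = list(modalities = "T1c", guide = "T1c", polarity = "dark"),
      enhanced    = list(modalities = "T1c", guide = "T1c", polarity = "bright"),
      nonenhanced = list(modalities = "T1c", guide = "T1c", polarity = "bright")))
}

#' Read a configuration file
#'
#' JSON file whose keys override [default_config()] (recursively merged).
#'
#' @param path JSON file path.
#' @return configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_glioseg("missing_file", sprintf("config not found: '%s'", path))
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  merge_config(default_config(), user)
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(user[[k]]))
      merge_config(base[[k]], user[[k]]) else user[[k]]
  }
  base
}

#' Segment one region by rank-two NMF texture clustering
#'
#' Runs the per-slice texture clustering inside `input_mask` and returns the
#' stage's binary region mask. Slices with fewer masked voxels than
#' `min_region_voxels` contribute nothing (a rank-two split of a handful of
#' voxels is meaningless); the result is always contained in `input_mask`.
#'
#' @param volumes named list of [volume()]s (must cover the stage's
#'   modalities and guide).
#' @param input_mask 3D logical array, the region to split.
#' @param stage list with `modalities`, `guide`, `polarity` (see
#'   [default_config()]`$stages`).
#' @param config full configuration list.
#' @return list (`glioseg_stage_result`): `mask` (3D logical), `input_mask`,
#'   `diagnostics` (per-slice data frame with residuals and voxel counts).
#' @export
segment_stage <- function(volumes, input_mask, stage, config = default_config()) {
  shapes <- lapply(volumes, function(v) dim(v$data))
  if (length(unique(shapes)) != 1L || !identical(shapes[[1]], dim(input_mask)))
    stop_glioseg("shape_mismatch", "volumes and mask must share one shape")
  mods <- stage$modalities
  missing_mods <- setdiff(c(mods, stage$guide), names(volumes))
  if (length(missing_mods) > 0L)
    stop(sprintf("volumes list lacks modalities: %s", paste(missing_mods, collapse = ", ")))
  g <- config$glcm
  floor_n <- config$pipeline$min_region_voxels
  nz <- dim(input_mask)[3]
  out <- array(FALSE, dim(input_mask))
  diag_rows <- list()
  for (z in seq_len(nz)) {
    m2 <- input_mask[, , z]
    nvox <- sum(m2)
    if (nvox < floor_n) next
    fmaps <- lapply(volumes[mods], function(v)
      feature_maps(v$data[, , z], m2, g$window, g$levels, g$distance))
    ints <- if (isTRUE(config$lmm$include_intensity))
      lapply(volumes[mods], function(v) v$data[, , z]) else NULL
    fm <- build_matrix(fmaps, m2, intensity_slices = ints)
    # degenerate slices (constant texture -> all-zero feature matrix) simply
    # contribute no region-of-interest voxels
    fact <- tryCatch(
      factorize_rank2(fm, tol = config$nmf$tol,
                      max_iter = config$nmf$max_iter,
                      init = config$nmf$init, seed = config$nmf$seed),
      glioseg_degenerate_matrix = function(e) NULL)
    if (is.null(fact)) next
    cl <- assign_clusters(fact)
    guide_slice <- volumes[[stage$guide]]$data[, , z]
    guide_vals <- guide_slice[cbind(fm$voxel_index[, 1], fm$voxel_index[, 2])]
    cl <- select_roi_component(fact, cl, guide_vals, stage$polarity)
    sel <- fm$voxel_index[cl$C1, , drop = FALSE]
    sl <- matrix(FALSE, nrow(m2), ncol(m2))
    sl[sel] <- TRUE
    out[, , z] <- sl & m2
    diag_rows[[length(diag_rows) + 1L]] <-
      data.frame(slice = z, n_voxels = nvox, n_roi = length(cl$C1),
                 residual = fact$residual, iterations = fact$iterations)
  }
  if (length(diag_rows) == 0L)
    warning("segment_stage: no slice reached min_region_voxels; empty mask")
  structure(list(mask = out, input_mask = input_mask,
                 diagnostics = if (length(diag_rows)) do.call(rbind, diag_rows)
                               else data.frame()),
            class = "glioseg_stage_result")
}

#' Assemble the BraTS label map from the four stage masks
#'
#' Applies the label convention: 1 on necrosis, 4 on enhancing, 3 on
#' nonenhancing, 2 on the remaining edema voxels, 0 elsewhere. The three core
#' masks must be pairwise disjoint and contained in the edema mask.
#'
#' @param edema,necrosis,enhanced,nonenhanced 3D logical arrays, same shape.
#' @param spacing voxel spacing for the output map.
#' @return a [label_map()].
#' @export
assemble_labels <- function(edema, necrosis, enhanced, nonenhanced,
                            spacing = c(1, 1, 1)) {
  stopifnot(identical(dim(edema), dim(necrosis)),
            identical(dim(edema), dim(enhanced)),
            identical(dim(edema), dim(nonenhanced)))
  if (any(necrosis & enhanced) || any(necrosis & nonenhanced) ||
      any(enhanced & nonenhanced))
    stop_glioseg("mask_overlap", "core region masks must be pairwise disjoint")
  if (any((necrosis | enhanced | nonenhanced) & !edema))
    stop_glioseg("mask_overlap", "core region masks must lie inside the edema mask")
  lab <- array(0L, dim(edema))
  lab[edema] <- 2L
  lab[necrosis] <- 1L
  lab[enhanced] <- 4L
  lab[nonenhanced] <- 3L
  label_map(lab, spacing = spacing)
}

#' Run the full four-stage characterization
#'
#' @param t2,flair,t1c co-registered [volume()]s of the three modalities.
#' @param config configuration list, see [default_config()].
#' @return list (`glioseg_result`): `labels` (a [label_map()]), `stages`
#'   (named list of the four `glioseg_stage_result`s), `config`.
#' @export
run_pipeline <- function(t2, flair, t1c, config = default_config()) {
  vols <- list(T2 = t2, FLAIR = flair, T1c = t1c)
  shapes <- lapply(vols, function(v) dim(v$data))
  if (length(unique(shapes)) != 1L)
    stop_glioseg("shape_mismatch", "the three modality volumes must share one shape")
  st <- config$stages
  res <- list()
  brain <- brain_mask(vols[[st$edema$guide]])
  res$edema <- segment_stage(vols, brain, st$edema, config)
  res$necrosis <- segment_stage(vols, res$edema$mask, st$necrosis, config)
  i1 <- res$edema$mask & !res$necrosis$mask
  res$enhanced <- segment_stage(vols, i1, st$enhanced, config)
  i2 <- i1 & !res$enhanced$mask
  res$nonenhanced <- segment_stage(vols, i2, st$nonenhanced, config)
  labels <- assemble_labels(res$edema$mask, res$necrosis$mask,
                            res$enhanced$mask, res$nonenhanced$mask,
                            spacing = t2$spacing)
  structure(list(labels = labels, stages = res, config = config),
            class = "glioseg_result")
}

#' @export
print.glioseg_result <- function(x, ...) {
  cat("<glioseg_result>\n")
  for (s in names(x$stages)) {
    d <- x$stages[[s]]$diagnostics
    cat(sprintf("  %-12s %6d voxels  (%d slices, mean residual %.4f)\n",
                s, sum(x$stages[[s]]$mask), nrow(d),
                if (nrow(d)) mean(d$residual) else NA_real_))
  }
  print(x$labels)
  invisible(x)
}
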