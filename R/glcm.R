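# Gray-level co-occurrence matrices and Haralick texture features.
#
# Conventions (documented because the literature varies):
#  * gray levels are indexed 1..N in all feature formulas (so i + j spans
#    2..2N and |i - j| spans 0..N-1);
#  * the GLCM is symmetric: every pixel pair is counted in both orderings;
#  * the four direction matrices (0, 45, 90, 135 degrees) are averaged as
#    counts, then normalized to sum 1 — the rotation-invariant form Haralick
#    recommends;
#  * logarithms are natural; 0 * log 0 = 0;
#  * three textbook formulas that are degenerate as sometimes printed are
#    implemented in their standard Haralick form: correlation uses
#    (i-mu_x)(j-mu_y)/(sigma_x sigma_y) with sigma the standard deviations,
#    variance uses (i - mu)^2 with mu the GLCM mean gray level, sum variance
#    uses (k - SumEntropy)^2 weights over the sum distribution, and
#    dissimilarity uses |i - j| (the signed form is identically 0 on a
#    symmetric GLCM). Difference variance is the raw second moment
#    sum k^2 p_{x-y}(k), which is well defined and kept as the default;
#    set `difference_variance = "corrected"` for the central-moment form.

#' The 16 Haralick feature names, in canonical order
#' @export
haralick_feature_names <- c(
  "contrast", "energy", "dissimilarity", "entropy", "correlation",
  "homogeneity", "variance", "difference_entropy", "sum_average",
  "cluster_shade", "cluster_prominence", "max_probability",
  "difference_variance", "autocorrelation", "sum_entropy", "sum_variance")

GLCM_DIRECTIONS <- c(0, 45, 90, 135)

# (row, col) offset of one step at angle phi (degrees) and distance d,
# with 0 degrees = horizontal (increasing column)
direction_offset <- function(phi, d) {
  switch(as.character(phi),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop_glioseg("bad_direction", sprintf("unsupported GLCM direction %s", phi)))
}

#' Quantize a slice to N gray levels
#'
#' Linearly rescales the masked intensities from their own `[min, max]` to
#' integer levels `0..levels-1` (rounding to nearest). Unmasked pixels are set
#' to level 0 and excluded from the min/max. A constant masked slice maps to
#' all level 0.
#'
#' @param slice 2D numeric matrix of intensities.
#' @param mask 2D logical matrix, same shape; at least one `TRUE`.
#' @param levels number of gray levels N >= 2.
#' @return Object of class `glioseg_quantized` with fields `data` (integer
#'   matrix of levels) and `levels`.
#' @export
quantize <- function(slice, mask = NULL, levels = 32L) {
  stopifnot(is.matrix(slice), levels >= 2L)
  if (is.null(mask)) mask <- array(TRUE, dim(slice))
  stopifnot(identical(dim(mask), dim(slice)))
  if (!any(mask)) stop_glioseg("empty_mask", "quantize: mask selects no pixels")
  v <- slice[mask]
  lo <- min(v); hi <- max(v)
  q <- matrix(0L, nrow(slice), ncol(slice))
  if (hi > lo)
    q[mask] <- as.integer(floor((v - lo) / (hi - lo) * (levels - 1L) + 0.5))
  structure(list(data = q, levels = as.integer(levels), mask = mask),
            class = "glioseg_quantized")
}

#' Direction-averaged co-occurrence matrix of one window
#'
#' Accumulates symmetric co-occurrence counts of gray-level pairs at offset
#' distance `d` for each requested direction, averages the direction matrices
#' and normalizes the result to sum 1. Only pairs with both pixels inside the
#' mask are counted; windows are never padded.
#'
#' @param window a `glioseg_quantized` (or an integer matrix of levels, in
#'   which case `levels` must be supplied).
#' @param d pixel distance (default 1).
#' @param directions subset of `c(0, 45, 90, 135)` degrees.
#' @param levels gray-level count when `window` is a bare matrix.
#' @param mask optional logical matrix overriding the window's mask.
#' @return Object of class `glioseg_glcm`: fields `G` (N x N, sums to 1,
#'   symmetric), `d`, `directions`, `levels`.
#' @export
compute_glcm <- function(window, d = 1L, directions = GLCM_DIRECTIONS,
                         levels = NULL, mask = NULL) {
  if (inherits(window, "glioseg_quantized")) {
    q <- window$data
    if (is.null(levels)) levels <- window$levels
    if (is.null(mask)) mask <- window$mask
  } else {
    q <- window
    if (is.null(levels)) stop("levels must be given for a bare level matrix")
  }
  if (is.null(mask)) mask <- array(TRUE, dim(q))
  N <- as.integer(levels)
  counts <- matrix(0, N, N)
  for (phi in directions) {
    off <- direction_offset(phi, d)
    counts <- counts + direction_counts(q, mask, off, N)
  }
  total <- sum(counts)
  if (total == 0)
    stop_glioseg("no_pairs",
                 sprintf("window of %dx%d has no pixel pair at distance %d",
                         nrow(q), ncol(q), d))
  structure(list(G = counts / total, d = d, directions = directions, levels = N),
            class = "glioseg_glcm")
}

# symmetric co-occurrence counts for one (drow, dcol) offset, vectorized
direction_counts <- function(q, mask, off, N) {
  nr <- nrow(q); nc <- ncol(q)
  rlo <- max(1L, 1L - off[1]); rhi <- min(nr, nr - off[1])
  clo <- max(1L, 1L - off[2]); chi <- min(nc, nc - off[2])
  if (rlo > rhi || clo > chi) return(matrix(0L, N, N))
  r0 <- rlo:rhi; c0 <- clo:chi
  a <- q[r0, c0, drop = FALSE]
  b <- q[r0 + off[1], c0 + off[2], drop = FALSE]
  ok <- mask[r0, c0, drop = FALSE] & mask[r0 + off[1], c0 + off[2], drop = FALSE]
  if (!any(ok)) return(matrix(0L, N, N))
  ia <- a[ok]; ib <- b[ok]
  # both orderings of each pair -> symmetric counts
  tab <- tabulate(ia * N + ib + 1L, nbins = N * N) +
         tabulate(ib * N + ia + 1L, nbins = N * N)
  matrix(tab, N, N)  # level l maps to row/col l+1
}

#' Marginal distributions of a normalized GLCM
#'
#' With gray levels indexed 1..N: row/column marginal means `mu_x`, `mu_y` and
#' standard deviations `sigma_x`, `sigma_y`; the sum distribution
#' `p_{x+y}(k)`, k = 2..2N; the difference distribution `p_{x-y}(k)`,
#' k = 0..N-1; and the sum entropy.
#'
#' @param glcm a `glioseg_glcm` (or bare normalized matrix).
#' @return list with `mu_x`, `mu_y`, `sigma_x`, `sigma_y`, `p_sum`
#'   (named by k = 2..2N), `p_diff` (named by k = 0..N-1), `sum_entropy`.
#' @export
glcm_marginals <- function(glcm) {
  G <- if (inherits(glcm, "glioseg_glcm")) glcm$G else glcm
  N <- nrow(G)
  j <- seq_len(N)
  px <- colSums(G)  # marginal over the second (column, "x") index j
  py <- rowSums(G)  # marginal over the first (row, "y") index i
  mu_x <- sum(j * px); mu_y <- sum(j * py)
  sigma_x <- sqrt(sum((j - mu_x)^2 * px))
  sigma_y <- sqrt(sum((j - mu_y)^2 * py))
  ii <- row(G); jj <- col(G)
  p_sum <- vapply(2:(2 * N), function(k) sum(G[ii + jj == k]), numeric(1))
  p_diff <- vapply(0:(N - 1), function(k) sum(G[abs(ii - jj) == k]), numeric(1))
  names(p_sum) <- 2:(2 * N); names(p_diff) <- 0:(N - 1)
  list(mu_x = mu_x, mu_y = mu_y, sigma_x = sigma_x, sigma_y = sigma_y,
       p_sum = p_sum, p_diff = p_diff,
       sum_entropy = -sum(xlogx(p_sum)))
}

xlogx <- function(p) ifelse(p > 0, p * log(p), 0)

#' Haralick features of a normalized GLCM
#'
#' Computes the 16 texture features (see [haralick_feature_names]) from a
#' direction-averaged, normalized GLCM. Gray levels are indexed 1..N. The
#' degenerate case sigma_x * sigma_y = 0 returns correlation 0.
#'
#' @param glcm a `glioseg_glcm` or a bare normalized nonnegative matrix.
#' @param difference_variance `"raw"` (default): the raw second moment
#'   `sum k^2 p_{x-y}(k)`; `"corrected"`: the central variance of `p_{x-y}`.
#' @return named numeric vector of the 16 features.
#' @export
haralick_features <- function(glcm, difference_variance = c("raw", "corrected")) {
  difference_variance <- match.arg(difference_variance)
  G <- if (inherits(glcm, "glioseg_glcm")) glcm$G else glcm
  N <- nrow(G)
  m <- glcm_marginals(G)
  ii <- row(G); jj <- col(G)
  ks <- 2:(2 * N)           # support of p_{x+y}
  kd <- 0:(N - 1)           # support of p_{x-y}
  mu <- m$mu_x              # GLCM mean gray level (mu_x = mu_y for symmetric G)

  corr <- if (m$sigma_x * m$sigma_y > 0)
    sum((ii - m$mu_x) * (jj - m$mu_y) * G) / (m$sigma_x * m$sigma_y) else 0
  dvar <- if (difference_variance == "raw") sum(kd^2 * m$p_diff)
          else sum((kd - sum(kd * m$p_diff))^2 * m$p_diff)

  c(contrast            = sum((ii - jj)^2 * G),
    energy              = sum(G^2),
    dissimilarity       = sum(abs(ii - jj) * G),
    entropy             = -sum(xlogx(G)),
    correlation         = corr,
    homogeneity         = sum(G / (1 + (ii - jj)^2)),
    variance            = sum((ii - mu)^2 * G),
    difference_entropy  = -sum(xlogx(m$p_diff)),
    sum_average         = sum(ks * m$p_sum),
    cluster_shade       = sum((ii + jj - m$mu_x - m$mu_y)^3 * G),
    cluster_prominence  = sum((ii + jj - m$mu_x - m$mu_y)^4 * G),
    max_probability     = max(G),
    difference_variance = dvar,
    autocorrelation     = sum(ii * jj * G),
    sum_entropy         = m$sum_entropy,
    sum_variance        = sum((ks - m$sum_entropy)^2 * m$p_sum))
}

#' Per-pixel Haralick feature maps of a slice
#'
#' Quantizes the slice over the mask, then for every masked pixel computes the
#' direction-averaged GLCM of the `window_size` x `window_size` window
#' centered there (cropped at the slice border; only pixel pairs with both
#' ends inside mask-and-window are counted) and assigns its 16 Haralick
#' features to that pixel. Unmasked pixels — and masked pixels whose window
#' contains no valid pair — carry `NA`.
#'
#' @param slice 2D numeric intensity matrix.
#' @param mask 2D logical matrix (default: all `TRUE`).
#' @param window_size odd integer >= 3 (default 11).
#' @param levels gray levels N for quantization (default 32).
#' @param d co-occurrence distance (default 1).
#' @return numeric array `nrow x ncol x 16`, feature planes ordered as
#'   [haralick_feature_names].
#' @export
feature_maps <- function(slice, mask = NULL, window_size = 11L, levels = 32L,
                         d = 1L) {
  stopifnot(is.matrix(slice))
  if (window_size < 3L || window_size %% 2L == 0L)
    stop("window_size must be an odd integer >= 3")
  if (is.null(mask)) mask <- array(TRUE, dim(slice))
  if (!any(mask)) stop_glioseg("empty_mask", "feature_maps: mask selects no pixels")
  q <- quantize(slice, mask, levels)
  out <- glcm_feature_maps_cpp(q$data, mask, as.integer(window_size),
                               as.integer(d), as.integer(levels))
  dimnames(out) <- list(NULL, NULL, haralick_feature_names)
  out
}
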