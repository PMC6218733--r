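# Synthetic multimodal glioblastoma phantom.
#
# Nested ellipsoids emulate the compartment topology of a high-grade glioma:
# brain > edema extent > tumor core, with the core partitioned into a central
# necrotic region, an enhancing rim and a nonenhancing region. Each
# compartment gets a per-modality mean intensity plus spatially correlated
# (smoothed Gaussian) noise with its own amplitude and correlation scale, so
# compartments differ in local texture as well as in mean — texture is what
# the downstream GLCM/NMF pipeline discriminates on.

#' Phantom specification
#'
#' Geometry is given as concentric ellipsoids in voxel units (all centered at
#' `center`): `brain` > `edema` > `core`; inside the core, `necrosis` is the
#' innermost ellipsoid, `inner` bounds the nonenhancing region
#' (nonenhancing = inner minus necrosis) and the enhancing rim is core minus
#' inner. Radii must be componentwise nested.
#'
#' Intensities are arbitrary scanner-like units. Defaults make edema
#' hyperintense on T2/FLAIR relative to normal brain, the enhancing rim
#' hyperintense and necrosis hypointense on T1c, and give every compartment a
#' distinct noise amplitude/correlation scale.
#'
#' @param shape grid dimensions, default `c(64, 64, 8)` (axial slices last).
#' @param seed RNG seed; the phantom is a pure function of the spec.
#' @param center ellipsoid center in voxel coordinates.
#' @param radii named list of per-axis radii for `brain`, `edema`, `core`,
#'   `inner`, `necrosis`.
#' @param means per-compartment, per-modality mean intensities: a named list
#'   (`brain`, `edema`, `necrosis`, `enhancing`, `nonenhancing`) of named
#'   vectors over `T2`, `FLAIR`, `T1c`. Background outside the brain is 0.
#' @param noise_sd per-compartment noise amplitude (intensity units).
#' @param noise_scale per-compartment spatial correlation scale of the noise
#'   (Gaussian smoothing sigma, in voxels; 0 = white noise).
#' @return Object of class `glioseg_phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 8L),
                         seed = 42L,
                         center = (shape + 1) / 2,
                         radii = list(
                           brain    = c(28, 28, 10) * shape / c(64, 64, 8),
                           edema    = c(18, 18, 7)  * shape / c(64, 64, 8),
                           core     = c(11, 11, 5)  * shape / c(64, 64, 8),
                           inner    = c(8, 8, 4)    * shape / c(64, 64, 8),
                           necrosis = c(4.5, 4.5, 3) * shape / c(64, 64, 8)),
                         means = list(
                           brain        = c(T2 = 120, FLAIR = 110, T1c = 120),
                           edema        = c(T2 = 210, FLAIR = 220, T1c = 110),
                           necrosis     = c(T2 = 170, FLAIR = 160, T1c = 45),
                           enhancing    = c(T2 = 150, FLAIR = 180, T1c = 235),
                           nonenhancing = c(T2 = 160, FLAIR = 190, T1c = 165)),
                         noise_sd = c(brain = 8, edema = 10, necrosis = 5,
                                      enhancing = 20, nonenhancing = 14),
                         noise_scale = c(brain = 1, edema = 2, necrosis = 1,
                                         enhancing = 1.5, nonenhancing = 2.5)) {
  spec <- structure(list(shape = as.integer(shape), seed = as.integer(seed),
                         center = center, radii = radii, means = means,
                         noise_sd = noise_sd, noise_scale = noise_scale),
                    class = "glioseg_phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  r <- spec$radii
  nest <- list(c("necrosis", "inner"), c("inner", "core"),
               c("core", "edema"), c("edema", "brain"))
  for (p in nest)
    if (!all(r[[p[1]]] <= r[[p[2]]]))
      stop_glioseg("phantom_geometry",
                   sprintf("phantom radii must nest: %s must fit inside %s", p[1], p[2]))
  for (m in spec$means)
    if (any(m < 0)) stop_glioseg("phantom_geometry", "mean intensities must be >= 0")
  invisible(spec)
}

# squared normalized ellipsoid distance for every voxel; <= 1 means inside
ellipsoid_field <- function(shape, center, radii) {
  ax <- lapply(1:3, function(a) ((seq_len(shape[a]) - center[a]) / radii[a])^2)
  outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
}

# separable Gaussian smoothing of a 3D array, slice-wise in-plane (the
# pipeline is 2D slice-wise, so in-plane correlation is what matters)
smooth_noise <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  sm1 <- function(m, along) {
    # convolve each column (along = 1) or row (along = 2) with edge renorm
    if (along == 2L) return(t(sm1(t(m), 1L)))
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    wt <- numeric(n)
    for (o in -half:half) {
      w <- k[o + half + 1L]
      src <- pmin(pmax(seq_len(n) + o, 1L), n)  # replicate edges
      out <- out + w * m[src, , drop = FALSE]
    }
    out
  }
  for (z in seq_len(dim(arr)[3])) arr[, , z] <- sm1(sm1(arr[, , z], 1L), 2L)
  arr
}

#' Generate a synthetic multimodal phantom
#'
#' Returns three co-registered modality volumes (T2, FLAIR, T1c) and the
#' matching ground-truth label map (1 necrosis, 2 edema, 3 nonenhancing,
#' 4 enhancing, 0 elsewhere). Deterministic for a fixed spec: the RNG state of
#' the session is saved and restored.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `t2`, `flair`, `t1c` ([volume()]s) and
#'   `labels` (a [label_map()]).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  validate_phantom_spec(spec)
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(spec$seed)
  shape <- spec$shape

  inside <- lapply(spec$radii, function(r)
    ellipsoid_field(shape, spec$center, r) <= 1)
  comp <- list(
    brain        = inside$brain & !inside$edema,
    edema        = inside$edema & !inside$core,
    necrosis     = inside$necrosis,
    nonenhancing = inside$inner & !inside$necrosis,
    enhancing    = inside$core & !inside$inner)

  labels <- array(0L, dim = shape)
  labels[comp$edema] <- 2L
  labels[comp$necrosis] <- 1L
  labels[comp$nonenhancing] <- 3L
  labels[comp$enhancing] <- 4L

  vols <- list()
  for (mod in c("T2", "FLAIR", "T1c")) {
    img <- array(0, dim = shape)
    for (cn in names(comp)) {
      idx <- comp[[cn]]
      if (!any(idx)) next
      noise <- smooth_noise(array(stats::rnorm(prod(shape)), dim = shape),
                            spec$noise_scale[[cn]])
      noise <- noise / stats::sd(noise)  # unit amplitude after smoothing
      img[idx] <- spec$means[[cn]][[mod]] + spec$noise_sd[[cn]] * noise[idx]
    }
    img <- round(pmax(img, 0))
    img[img == 0 & inside$brain] <- 1  # keep the brain support strictly positive
    vols[[mod]] <- volume(img, modality = mod)
  }

  list(t2 = vols$T2, flair = vols$FLAIR, t1c = vols$T1c,
       labels = label_map(labels))
}
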