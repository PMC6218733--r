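test_that("quantize rescales linearly, handles degenerate and identity cases", {
  s <- matrix(c(0, 100, 200, 50), 2, 2)
  m <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  q <- quantize(s, m, levels = 3L)
  expect_identical(q$data[1, 1], 0L)
  expect_identical(q$data[2, 1], 1L)
  expect_identical(q$data[1, 2], 2L)
  expect_identical(q$data[2, 2], 0L)  # unmasked -> level 0, excluded from range
  # constant masked slice -> all level 0
  expect_true(all(quantize(matrix(5, 3, 3), levels = 8L)$data == 0L))
  # already 0..N-1 spanning the range -> unchanged
  s2 <- matrix(sample(0:4, 25, replace = TRUE), 5, 5)
  s2[1] <- 0L; s2[25] <- 4L
  expect_identical(quantize(s2, levels = 5L)$data, matrix(as.integer(s2), 5, 5))
  expect_error(quantize(s, m & FALSE, 3L), class = "glioseg_empty_mask")
})

test_that("compute_glcm matches the printed 2x2 hand case and handles degenerate windows", {
  q <- matrix(c(0L, 0L, 0L, 1L), 2, 2, byrow = TRUE)
  g <- compute_glcm(q, d = 1L, directions = 0, levels = 2L)
  expect_equal(g$G, matrix(c(0.5, 0.25, 0.25, 0), 2, 2))
  # constant window: single diagonal entry = 1
  gc <- compute_glcm(matrix(3L, 4, 4), d = 1L, levels = 8L)
  expect_equal(sum(gc$G), 1)
  expect_equal(gc$G[4, 4], 1)
  # no pair at the requested distance
  expect_error(compute_glcm(matrix(0L, 1, 1), d = 1L, levels = 2L),
               class = "glioseg_no_pairs")
})

test_that("per-direction counts match exhaustive brute-force enumeration", {
  set.seed(101)
  for (i in 1:40) {
    w <- random_window()
    if (!any(w$mask)) next
    d <- sample(1:2, 1)
    for (phi in c(0, 45, 90, 135)) {
      got <- glioseg:::direction_counts(w$q, w$mask, glioseg:::direction_offset(phi, d), w$N)
      expect_equal(got, oracle_glcm_counts(w$q, w$mask, d, phi, w$N),
                   info = sprintf("case %d phi %d", i, phi))
    }
  }
})

test_that("direction-averaged GLCM is symmetric, normalized and rotation invariant", {
  set.seed(102)
  for (i in 1:20) {
    w <- random_window(with_mask = FALSE)
    g <- compute_glcm(w$q, d = 1L, levels = w$N)$G
    expect_equal(sum(g), 1, tolerance = 1e-12)
    expect_equal(g, t(g), tolerance = 1e-12)
    # 90-degree rotation of the window leaves the direction average unchanged
    qrot <- t(w$q)[ncol(w$q):1, , drop = FALSE]
    grot <- compute_glcm(qrot, d = 1L, levels = w$N)$G
    expect_equal(g, grot, tolerance = 1e-12)
  }
})

test_that("haralick_features matches the literal formula oracle on random GLCMs", {
  set.seed(103)
  for (i in 1:30) {
    G <- random_glcm(sample(2:6, 1))
    f <- haralick_features(G)
    o <- oracle_haralick(G)
    expect_equal(f, o[names(f)], tolerance = 1e-12)
    expect_true(all(is.finite(f)))
    expect_true(f["energy"] >= 0 && f["energy"] <= 1)
    expect_true(f["max_probability"] >= 0 && f["max_probability"] <= 1)
  }
  # the optional central-moment difference variance
  G <- random_glcm(4)
  m <- glcm_marginals(G)
  kd <- 0:3
  expect_equal(unname(haralick_features(G, "corrected")["difference_variance"]),
               sum((kd - sum(kd * m$p_diff))^2 * m$p_diff))
})

test_that("marginal distributions sum to one and carry valid moments", {
  set.seed(104)
  for (i in 1:20) {
    m <- glcm_marginals(random_glcm(sample(2:8, 1)))
    expect_equal(sum(m$p_sum), 1, tolerance = 1e-12)
    expect_equal(sum(m$p_diff), 1, tolerance = 1e-12)
    expect_gte(m$sigma_x, 0)
    expect_gte(m$sigma_y, 0)
  }
})

test_that("feature_maps agrees with single-window compute_glcm + haralick_features", {
  set.seed(105)
  # two-texture half-plane: smooth left, noisy right
  sl <- matrix(0, 24, 24)
  sl[, 1:12] <- 100 + matrix(rnorm(24 * 12, sd = 2), 24)
  sl[, 13:24] <- 200 + matrix(rnorm(24 * 12, sd = 30), 24)
  fm <- feature_maps(sl, window_size = 7L, levels = 8L, d = 1L)
  q <- quantize(sl, levels = 8L)
  for (px in list(c(12, 6), c(12, 19))) {  # deep inside each half
    win <- q$data[(px[1] - 3):(px[1] + 3), (px[2] - 3):(px[2] + 3)]
    want <- haralick_features(compute_glcm(win, d = 1L, levels = 8L))
    expect_equal(fm[px[1], px[2], ], want, tolerance = 1e-10)
  }
  # constant slice: contrast 0, energy 1 everywhere
  fc <- feature_maps(matrix(7, 9, 9), window_size = 3L, levels = 8L)
  expect_true(all(fc[, , "contrast"] == 0))
  expect_true(all(fc[, , "energy"] == 1))
})

test_that("masked-out pixels cannot influence feature maps", {
  set.seed(106)
  s <- matrix(runif(20 * 20, 0, 300), 20, 20)
  mask <- matrix(TRUE, 20, 20); mask[, 1:10] <- FALSE
  f1 <- feature_maps(s, mask, window_size = 5L, levels = 8L)
  s2 <- s; s2[, 1:10] <- s2[, 1:10] * 3 + 17  # perturb the excluded half
  f2 <- feature_maps(s2, mask, window_size = 5L, levels = 8L)
  expect_identical(f1, f2)
  expect_true(all(is.na(f1[, 1:10, ])))
})
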