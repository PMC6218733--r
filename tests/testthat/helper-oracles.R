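# Independent oracles, written deliberately as literal loops so they share no
# code path with the package's vectorized / compiled implementations.

# offset convention shared with the package: 0 deg = horizontal step
oracle_offset <- function(phi, d) {
  switch(as.character(phi),
         "0" = c(0L, d), "45" = c(-d, d), "90" = c(-d, 0L), "135" = c(-d, -d))
}

# exhaustive enumeration of in-window, in-mask pixel pairs at one direction;
# symmetric counting (both orderings)
oracle_glcm_counts <- function(q, mask, d, phi, N) {
  off <- oracle_offset(phi, d)
  counts <- matrix(0L, N, N)
  for (r in seq_len(nrow(q))) {
    for (c in seq_len(ncol(q))) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 < 1 || r2 > nrow(q) || c2 < 1 || c2 > ncol(q)) next
      if (!mask[r, c] || !mask[r2, c2]) next
      a <- q[r, c] + 1L; b <- q[r2, c2] + 1L
      counts[a, b] <- counts[a, b] + 1L
      counts[b, a] <- counts[b, a] + 1L
    }
  }
  counts
}

# literal term-by-term evaluation of the 16 feature sums (gray levels 1..N,
# natural log, 0*log0 = 0; corrected correlation/variance/sum-variance forms,
# |i-j| dissimilarity, raw-moment difference variance)
oracle_haralick <- function(G) {
  N <- nrow(G)
  mu_x <- 0; mu_y <- 0
  for (i in 1:N) for (j in 1:N) { mu_x <- mu_x + j * G[i, j]; mu_y <- mu_y + i * G[i, j] }
  sg_x <- 0; sg_y <- 0
  for (i in 1:N) for (j in 1:N) {
    sg_x <- sg_x + (j - mu_x)^2 * G[i, j]
    sg_y <- sg_y + (i - mu_y)^2 * G[i, j]
  }
  sg_x <- sqrt(sg_x); sg_y <- sqrt(sg_y)
  p_sum <- numeric(2 * N); p_diff <- numeric(N)     # p_sum[k] = p_{x+y}(k), k>=2
  for (i in 1:N) for (j in 1:N) {
    p_sum[i + j] <- p_sum[i + j] + G[i, j]
    p_diff[abs(i - j) + 1] <- p_diff[abs(i - j) + 1] + G[i, j]
  }
  xlx <- function(p) if (p > 0) p * log(p) else 0
  f <- c(contrast = 0, energy = 0, dissimilarity = 0, entropy = 0,
         correlation = 0, homogeneity = 0, variance = 0, difference_entropy = 0,
         sum_average = 0, cluster_shade = 0, cluster_prominence = 0,
         max_probability = 0, difference_variance = 0, autocorrelation = 0,
         sum_entropy = 0, sum_variance = 0)
  for (i in 1:N) for (j in 1:N) {
    g <- G[i, j]
    f["contrast"] <- f["contrast"] + (i - j)^2 * g
    f["energy"] <- f["energy"] + g^2
    f["dissimilarity"] <- f["dissimilarity"] + abs(i - j) * g
    f["entropy"] <- f["entropy"] - xlx(g)
    if (sg_x * sg_y > 0)
      f["correlation"] <- f["correlation"] + (i - mu_x) * (j - mu_y) * g / (sg_x * sg_y)
    f["homogeneity"] <- f["homogeneity"] + g / (1 + (i - j)^2)
    f["variance"] <- f["variance"] + (i - mu_x)^2 * g
    f["cluster_shade"] <- f["cluster_shade"] + (i + j - mu_x - mu_y)^3 * g
    f["cluster_prominence"] <- f["cluster_prominence"] + (i + j - mu_x - mu_y)^4 * g
    f["autocorrelation"] <- f["autocorrelation"] + i * j * g
    if (g > f["max_probability"]) f["max_probability"] <- g
  }
  for (k in 2:(2 * N)) {
    f["sum_average"] <- f["sum_average"] + k * p_sum[k]
    f["sum_entropy"] <- f["sum_entropy"] - xlx(p_sum[k])
  }
  for (k in 0:(N - 1)) {
    f["difference_entropy"] <- f["difference_entropy"] - xlx(p_diff[k + 1])
    f["difference_variance"] <- f["difference_variance"] + k^2 * p_diff[k + 1]
  }
  for (k in 2:(2 * N))
    f["sum_variance"] <- f["sum_variance"] + (k - f[["sum_entropy"]])^2 * p_sum[k]
  f
}

# random symmetric normalized GLCM of size N
random_glcm <- function(N) {
  A <- matrix(stats::runif(N * N), N, N)
  G <- A + t(A)
  G / sum(G)
}

# random quantized window + mask
random_window <- function(max_side = 8L, max_levels = 8L, with_mask = TRUE) {
  nr <- sample(2:max_side, 1); nc <- sample(2:max_side, 1)
  N <- sample(2:max_levels, 1)
  q <- matrix(sample(0:(N - 1), nr * nc, replace = TRUE), nr, nc)
  mask <- if (with_mask && stats::runif(1) < 0.5)
    matrix(stats::runif(nr * nc) < 0.8, nr, nc)
  else matrix(TRUE, nr, nc)
  list(q = q, mask = mask, N = N)
}

# synthetic separable rank-2 instance: M = W H with pure columns present
separable_instance <- function(m = 12L, n = 40L, pure_frac = 0.2) {
  W <- matrix(stats::runif(m * 2, 0.1, 1), m, 2L)
  # make the two endmember directions well separated
  W[1:(m %/% 2), 1] <- W[1:(m %/% 2), 1] + 2
  W[(m %/% 2 + 1):m, 2] <- W[(m %/% 2 + 1):m, 2] + 2
  a <- stats::runif(n)
  pure <- sample(n, max(2L, round(pure_frac * n)))
  a[pure[seq(1, length(pure), 2)]] <- 1
  a[pure[seq(2, length(pure), 2)]] <- 0
  H <- rbind(a, 1 - a)
  list(M = W %*% H, W = W, H = H, labels = ifelse(a >= 0.5, 1L, 2L))
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# best rank-2 Frobenius error by SVD (unconstrained lower bound)
svd_rank2_error <- function(M) {
  s <- svd(M)$d
  if (length(s) <= 2) 0 else sqrt(sum(s[-(1:2)]^2))
}
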