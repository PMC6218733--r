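# Rank-two nonnegative matrix factorization and the two-cluster rule.
#
# M ~ W H with W (m x 2), H (2 x n) nonnegative: the linear mixture model
# with two endmembers. The solver alternates exact nonnegative least squares
# updates; each 2-variable subproblem is solved in closed form by enumerating
# the three active-set patterns (both free / one clamped at zero), so every
# accepted iteration decreases the Frobenius objective. Initialization is
# deterministic (successive projection on column-normalized data); a seeded
# random mode exists for robustness checks. Cluster 1 ("region of interest")
# collects the columns whose first abundance dominates: H(1,j) >= H(2,j).

#' Successive-projection initialization of the two endmembers
#'
#' Selects two actual columns of `M` as initial endmembers. Columns are first
#' L2-normalized (selection is then invariant to per-column scaling); the
#' first pick maximizes the residual norm after projecting out an arbitrary
#' anchor (the largest-norm column), the second maximizes the residual after
#' projecting out the first — for data that are near-separable mixtures of
#' two endmembers this returns the two pure columns.
#'
#' @param M nonnegative matrix (m x n, n >= 2) or `glioseg_feature_matrix`.
#' @return m x 2 matrix of the selected columns of `M` (original scale), with
#'   attributes `indices` (the chosen column indices) and `degenerate` (TRUE
#'   when all columns are parallel, in which case the two largest-norm
#'   distinct columns are returned).
#' @export
spa_init <- function(M) {
  if (inherits(M, "glioseg_feature_matrix")) M <- M$M
  stopifnot(is.matrix(M), ncol(M) >= 2L)
  nrm <- sqrt(colSums(M^2))
  pos <- which(nrm > 0)
  if (length(pos) < 2L)
    stop_glioseg("degenerate_matrix", "spa_init: fewer than 2 nonzero columns")
  U <- M[, pos, drop = FALSE] / rep(nrm[pos], each = nrow(M))
  anchor <- U[, which.max(nrm[pos])]
  # unit columns: residual norm^2 after projecting out a unit vector u is
  # 1 - (u . column)^2
  resid1 <- pmax(1 - as.vector(crossprod(U, anchor))^2, 0)
  p1 <- which.max(resid1)
  degenerate <- max(resid1) < 1e-12
  if (degenerate) {
    # all columns parallel: fall back to the two largest-norm columns
    ord <- order(nrm[pos], decreasing = TRUE)
    idx <- pos[ord[1:2]]
  } else {
    u1 <- U[, p1]
    resid2 <- pmax(1 - as.vector(crossprod(U, u1))^2, 0)
    p2 <- which.max(resid2)
    idx <- pos[c(p1, p2)]
  }
  W0 <- M[, idx, drop = FALSE]
  attr(W0, "indices") <- idx
  attr(W0, "degenerate") <- degenerate
  W0
}

# Exact NNLS in 2 variables for every column of B (2 x n system W h = m):
# enumerate active sets {both free, h2 = 0, h1 = 0} and keep the feasible
# candidate with smallest residual. Vectorized across columns.
nnls2 <- function(W, M) {
  G <- crossprod(W)                # 2 x 2
  B <- crossprod(W, M)             # 2 x n
  n <- ncol(M)
  det <- G[1, 1] * G[2, 2] - G[1, 2]^2
  # candidate 0: unconstrained solution
  if (det > .Machine$double.eps * max(G[1, 1], G[2, 2], 1)^2) {
    h1u <- (G[2, 2] * B[1, ] - G[1, 2] * B[2, ]) / det
    h2u <- (G[1, 1] * B[2, ] - G[1, 2] * B[1, ]) / det
  } else {
    h1u <- rep(-1, n); h2u <- rep(-1, n)   # force single-variable candidates
  }
  # candidates 1/2: one variable clamped at zero
  h1a <- if (G[1, 1] > 0) pmax(B[1, ] / G[1, 1], 0) else numeric(n)
  h2b <- if (G[2, 2] > 0) pmax(B[2, ] / G[2, 2], 0) else numeric(n)
  # residual difference (up to the constant ||m||^2): h'Gh - 2 h'b
  qobj <- function(h1, h2)
    G[1, 1] * h1^2 + 2 * G[1, 2] * h1 * h2 + G[2, 2] * h2^2 -
      2 * (h1 * B[1, ] + h2 * B[2, ])
  qa <- qobj(h1a, 0); qb <- qobj(0, h2b)
  H <- rbind(ifelse(qa <= qb, h1a, 0), ifelse(qa <= qb, 0, h2b))
  free_ok <- h1u >= 0 & h2u >= 0
  if (any(free_ok)) {
    qu <- qobj(h1u, h2u)
    take <- free_ok & qu <= pmin(qa, qb)
    H[1, take] <- h1u[take]
    H[2, take] <- h2u[take]
  }
  H
}

#' Rank-two NMF by alternating exact nonnegative least squares
#'
#' Factorizes a nonnegative matrix as `M ~ W H` with two endmembers. All-zero
#' columns of `M` are excluded from the factorization (their abundances are
#' set to 0 and they are flagged; [assign_clusters()] routes them to the
#' background cluster). After convergence the columns of `H` are normalized
#' to sum 1 (the abundance sum-to-one constraint); the per-column scale this
#' removes does not change the cluster rule, which compares the two
#' abundances within each column. The reported residual is computed from the
#' unnormalized factorization.
#'
#' @param M nonnegative matrix or `glioseg_feature_matrix`.
#' @param tol relative change of the Frobenius objective below which the
#'   iteration stops (default 1e-5).
#' @param max_iter iteration cap (default 500).
#' @param init `"spa"` (default, deterministic), `"maxnorm"` (two largest
#'   columns), or `"random"` (seeded).
#' @param seed RNG seed used only for `init = "random"`.
#' @return Object of class `glioseg_rank2`: `W` (m x 2), `H` (2 x n, columns
#'   summing to 1 except flagged ones), `residual` (relative Frobenius error
#'   of the fit), `objective_trace`, `iterations`, `zero_columns` (indices of
#'   excluded all-zero columns), `degenerate_columns`.
#' @export
factorize_rank2 <- function(M, tol = 1e-5, max_iter = 500L,
                            init = c("spa", "maxnorm", "random"), seed = 1L) {
  if (inherits(M, "glioseg_feature_matrix")) M <- M$M
  init <- match.arg(init)
  if (!is.matrix(M) || length(M) == 0L)
    stop_glioseg("empty_matrix", "factorize_rank2: M is empty")
  if (anyNA(M) || any(M < 0))
    stop_glioseg("invalid_matrix", "factorize_rank2: M must be finite and nonnegative")
  n_all <- ncol(M)
  zero_cols <- which(colSums(M) == 0)
  act <- setdiff(seq_len(n_all), zero_cols)
  Ma <- M[, act, drop = FALSE]
  if (ncol(Ma) == 0L)
    stop_glioseg("degenerate_matrix", "factorize_rank2: all columns are zero")

  W <- switch(init,
    spa = if (ncol(Ma) >= 2L) spa_init(Ma) else cbind(Ma[, 1], Ma[, 1]),
    maxnorm = {
      ord <- order(colSums(Ma^2), decreasing = TRUE)
      Ma[, ord[c(1L, min(2L, ncol(Ma)))], drop = FALSE]
    },
    random = {
      if (exists(".Random.seed", globalenv())) {
        old <- get(".Random.seed", globalenv())
        on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
      }
      set.seed(seed)
      matrix(stats::runif(2L * nrow(Ma)), nrow(Ma), 2L)
    })

  normM2 <- sum(Ma^2)
  obj_trace <- numeric(0)
  obj_prev <- Inf
  H <- NULL
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    H <- nnls2(W, Ma)
    W <- t(nnls2(t(H), t(Ma)))
    obj <- normM2 - 2 * sum(crossprod(W, Ma) * H) + sum(crossprod(W) * tcrossprod(H))
    obj <- max(obj, 0)
    obj_trace <- c(obj_trace, obj)
    if (is.finite(obj_prev) &&
        (obj_prev - obj) <= tol * max(obj_prev, .Machine$double.eps)) break
    obj_prev <- obj
  }
  residual <- if (normM2 > 0) sqrt(obj_trace[length(obj_trace)] / normM2) else 0

  # abundance sum-to-one; columns with no mass on either endmember are flagged
  H_full <- matrix(0, 2L, n_all)
  H_full[, act] <- H
  cs <- colSums(H_full)
  degen <- which(cs <= 0)
  ok <- cs > 0
  H_full[, ok] <- H_full[, ok, drop = FALSE] / rep(cs[ok], each = 2L)
  structure(list(W = W, H = H_full, r = 2L, residual = residual,
                 objective_trace = obj_trace, iterations = iter,
                 zero_columns = zero_cols,
                 degenerate_columns = sort(union(zero_cols, degen))),
            class = "glioseg_rank2")
}

#' Two-cluster assignment from the abundances
#'
#' Column `j` joins cluster 1 (the region of interest) when
#' `H(1,j) >= H(2,j)` — ties go to cluster 1 — and cluster 2 otherwise.
#' Columns flagged degenerate (all-zero feature signature) go to cluster 2.
#'
#' @param fact a `glioseg_rank2`.
#' @return Object of class `glioseg_clusters`: integer vectors `C1`, `C2`
#'   partitioning `1..n`.
#' @export
assign_clusters <- function(fact) {
  stopifnot(inherits(fact, "glioseg_rank2"))
  n <- ncol(fact$H)
  c1 <- fact$H[1, ] >= fact$H[2, ]
  c1[fact$degenerate_columns] <- FALSE
  structure(list(C1 = which(c1), C2 = which(!c1), n = n),
            class = "glioseg_clusters")
}

#' Orient the region-of-interest cluster by intensity polarity
#'
#' Rank-two NMF does not say which of its two components is the pathological
#' one. This helper swaps the clusters if needed so that `C1` is the cluster
#' whose mean intensity on the stage's driving modality is higher
#' (`polarity = "bright"`, e.g. enhancing tumor on T1c) or lower
#' (`"dark"`, e.g. necrosis on T1c). Equal means, or an empty cluster, leave
#' the assignment unchanged.
#'
#' @param fact a `glioseg_rank2` (returned unchanged; kept for diagnostics).
#' @param assignment a `glioseg_clusters`.
#' @param guide numeric vector of per-column intensities on the driving
#'   modality.
#' @param polarity `"bright"` or `"dark"`.
#' @return the oriented `glioseg_clusters` (attribute `swapped` records
#'   whether the clusters were exchanged).
#' @export
select_roi_component <- function(fact, assignment, guide,
                                 polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(assignment, "glioseg_clusters"),
            length(guide) == assignment$n)
  if (length(assignment$C1) == 0L || length(assignment$C2) == 0L) {
    attr(assignment, "swapped") <- FALSE
    return(assignment)
  }
  m1 <- mean(guide[assignment$C1]); m2 <- mean(guide[assignment$C2])
  swap <- if (polarity == "bright") m1 < m2 else m1 > m2
  if (swap)
    assignment <- structure(list(C1 = assignment$C2, C2 = assignment$C1,
                                 n = assignment$n), class = "glioseg_clusters")
  attr(assignment, "swapped") <- swap
  assignment
}
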