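# Non-negative matrix factorization, X (n x p) ~ W (n x r) H (r x p), by
# hierarchical alternating least squares (HALS) from a deterministic
# NNDSVDa initialization. HALS updates one component at a time in closed
# form and reaches a given Frobenius error in far fewer sweeps than
# multiplicative updates. W holds the per-observation coefficients used as
# the reduced representation downstream; new observations are projected by
# solving for W alone with H held fixed.

nndsvda_init <- function(x, rank) {
  n <- nrow(x); p <- ncol(x)
  sv <- svd(x, nu = rank, nv = rank)
  W <- matrix(0, n, rank); H <- matrix(0, rank, p)
  W[, 1L] <- sqrt(sv$d[1L]) * abs(sv$u[, 1L])
  H[1L, ] <- sqrt(sv$d[1L]) * abs(sv$v[, 1L])
  if (rank > 1L) for (j in 2:rank) {
    u <- sv$u[, j]; v <- sv$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    npos <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
    nneg <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
    if (npos >= nneg && npos > 0) {
      scale <- sqrt(sv$d[j] * npos)
      W[, j] <- scale * up / sqrt(sum(up^2))
      H[j, ] <- scale * vp / sqrt(sum(vp^2))
    } else if (nneg > 0) {
      scale <- sqrt(sv$d[j] * nneg)
      W[, j] <- scale * un / sqrt(sum(un^2))
      H[j, ] <- scale * vn / sqrt(sum(vn^2))
    }
  }
  avg <- mean(x)
  W[W <= 0] <- avg
  H[H <= 0] <- avg
  list(W = W, H = H)
}

# One HALS sweep over all components of W (or, by symmetry, t(H)).
# A: data-side Gram product (x %*% t(H) for W, or t(x) %*% t(W) for t(H));
# G: r x r Gram matrix (H H^T or W^T W).
hals_sweep <- function(M, A, G, eps) {
  for (j in seq_len(ncol(M))) {
    num <- A[, j] - M %*% G[, j] + M[, j] * G[j, j]
    M[, j] <- pmax(num / max(G[j, j], eps), 0)
  }
  M
}

#' Fit a non-negative matrix factorization
#'
#' Frobenius-loss NMF solved by hierarchical alternating least squares
#' (HALS) from a deterministic SVD-based (NNDSVDa) initialization, so
#' repeated fits on the same input are identical without any random seed.
#'
#' @param x Nonnegative numeric matrix (observations x features).
#' @param rank Number of components r, `1 <= r <= min(dim(x))`.
#' @param maxiter Maximum HALS sweeps.
#' @param tol Relative change in Frobenius reconstruction error below which
#'   iteration stops (checked every 10 sweeps).
#' @return An object of class `nmf_fit` with `W` (n x r), `H` (r x p),
#'   `frob_error` (relative), `iterations`, `converged`.
#' @export
nmf_fit <- function(x, rank, maxiter = 200L, tol = 1e-5) {
  x <- stop_if_not_matrix(x)
  if (min(x) < 0) stop("NMF input must be nonnegative")
  rank <- as.integer(rank)
  if (rank < 1L || rank > min(dim(x)))
    stop(sprintf("NMF rank %d outside [1, %d]", rank, min(dim(x))))
  init <- nndsvda_init(x, rank)
  W <- init$W; H <- init$H
  eps <- 1e-12
  xnorm <- sqrt(sum(x^2)) + eps
  err_prev <- Inf; it <- 0L; converged <- FALSE
  avg <- mean(x)
  while (it < maxiter) {
    it <- it + 1L
    Ht <- hals_sweep(t(H), crossprod(x, W), crossprod(W), eps)
    H <- t(Ht)
    W <- hals_sweep(W, x %*% Ht, crossprod(Ht), eps)
    # a component zeroed on either side is dead under HALS; revive it with
    # a flat positive block so the factorization keeps its nominal rank
    dead <- colSums(W) <= 0 | rowSums(H) <= 0
    if (any(dead)) {
      W[, dead] <- avg / rank
      H[dead, ] <- avg / rank
    }
    if (it %% 10L == 0L || it == maxiter) {
      err <- sqrt(sum((x - W %*% H)^2)) / xnorm
      if (is.finite(err_prev) && abs(err_prev - err) < tol * max(err, eps)) {
        converged <- TRUE
        err_prev <- err
        break
      }
      err_prev <- err
    }
  }
  structure(list(W = W, H = H, rank = rank,
                 frob_error = if (is.finite(err_prev)) err_prev else
                   sqrt(sum((x - W %*% H)^2)) / xnorm,
                 iterations = it, converged = converged),
            class = "nmf_fit")
}

#' Project new observations onto a fitted NMF basis
#'
#' Solves the nonnegative least-squares problem for coefficients W' with
#' the basis H fixed, by HALS sweeps from a clipped least-squares start.
#'
#' @param fit An `nmf_fit`.
#' @param newx Nonnegative matrix with the same number of columns as the
#'   training data.
#' @param maxiter HALS sweeps for the coefficient solve.
#' @return Nonnegative coefficient matrix (nrow(newx) x rank).
#' @export
nmf_transform <- function(fit, newx, maxiter = 50L) {
  stopifnot(inherits(fit, "nmf_fit"))
  newx <- stop_if_not_matrix(newx)
  if (ncol(newx) != ncol(fit$H))
    stop(sprintf("width %d does not match fitted width %d",
                 ncol(newx), ncol(fit$H)))
  H <- fit$H
  eps <- 1e-12
  Ht <- t(H)
  HHt <- tcrossprod(H)
  ridge <- diag(1e-8 * max(diag(HHt)) + eps, nrow(HHt))
  W <- pmax(newx %*% Ht %*% solve(HHt + ridge), 0)
  A <- newx %*% Ht
  for (i in seq_len(maxiter)) W <- hals_sweep(W, A, HHt, eps)
  W
}
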