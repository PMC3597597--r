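#' Standardize the columns of an expression block
#'
#' Centers each column to mean 0 and scales it to unit sample variance
#' (denominator N - 1), the form the canonical-variate computation
#' expects.
#'
#' @param M numeric matrix N x d, N >= 2.
#' @return The standardized matrix.
#' @export
standardize_columns <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) < 2L) stop("need at least 2 rows to standardize")
  sds <- apply(M, 2L, sd)
  zero <- sds <= 0 | !is.finite(sds)
  if (any(zero)) {
    nm <- colnames(M)[zero]
    if (is.null(nm)) nm <- which(zero)
    stop("zero-variance column(s): ", paste(nm, collapse = ", "))
  }
  scale(M, center = TRUE, scale = sds)[, , drop = FALSE]
}

# Symmetric inverse square root of S + lambda*I via eigendecomposition.
ridge_inv_sqrt <- function(S, lambda, label) {
  e <- eigen(S + diag(lambda, nrow(S)), symmetric = TRUE)
  if (min(e$values) <= 1e-10) {
    stop("regularized ", label, " covariance is numerically singular; ",
         "increase lambda")
  }
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

#' Regularized canonical variates of two expression blocks
#'
#' Finds coefficient vectors `a_k`, `b_k` maximizing the correlation of
#' the scores `X a_k` and `Y b_k`, with unit variance and mutual
#' uncorrelatedness measured under the ridge-regularized covariances
#' `S_XX + lambda_x I` and `S_YY + lambda_y I`.  Regularization makes
#' the problem well-posed when a gene set has more genes than samples
#' or strongly collinear members.  Computed by the symmetric
#' eigen-decomposition of
#' `(S_XX+l1 I)^{-1/2} S_XY (S_YY+l2 I)^{-1} S_YX (S_XX+l1 I)^{-1/2}`.
#'
#' @param X,Y standardized numeric matrices (N x p and N x q; see
#'   [standardize_columns]).
#' @param lambda_x,lambda_y nonnegative ridge penalties.
#' @param m number of variate pairs requested; `min(m, p, q)` returned.
#'
#' @return An object of class `"canonical_variates"`: list with
#'   `a_coeffs` (p x m), `b_coeffs` (q x m), `x_scores`, `y_scores`
#'   (N x m), `correlations` (non-increasing, in `[0, 1]`), `lambda_x`,
#'   `lambda_y`.
#' @export
regularized_cancor <- function(X, Y, lambda_x = 0, lambda_y = 0,
                               m = min(ncol(X), ncol(Y))) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!all(is.finite(X)) || !all(is.finite(Y))) {
    stop("non-finite values in input")
  }
  if (lambda_x < 0 || lambda_y < 0) stop("lambda must be nonnegative")
  if (m < 1L) stop("m must be at least 1")
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same rows")
  p <- ncol(X); q <- ncol(Y)
  m <- min(m, p, q)
  Sxx <- crossprod(X) / (nrow(X) - 1L)
  Syy <- crossprod(Y) / (nrow(Y) - 1L)
  Sxy <- crossprod(X, Y) / (nrow(X) - 1L)
  Wx <- ridge_inv_sqrt(Sxx, lambda_x, "predictor")
  Syy_r <- Syy + diag(lambda_y, q)
  Syy_inv <- chol2inv(chol(Syy_r))
  Mmat <- Wx %*% Sxy %*% Syy_inv %*% t(Sxy) %*% Wx
  e <- eigen((Mmat + t(Mmat)) / 2, symmetric = TRUE)
  corrs <- sqrt(pmin(pmax(e$values[seq_len(m)], 0), 1))
  A <- Wx %*% e$vectors[, seq_len(m), drop = FALSE]
  B <- matrix(0, q, m)
  for (k in seq_len(m)) {
    bk <- Syy_inv %*% t(Sxy) %*% A[, k]
    nb <- sqrt(drop(crossprod(bk, Syy_r %*% bk)))
    B[, k] <- if (nb > 1e-12) bk / nb else 0
    # sign convention: largest-magnitude predictor coefficient positive
    top <- which.max(abs(A[, k]))
    if (A[top, k] < 0) {
      A[, k] <- -A[, k]
      B[, k] <- -B[, k]
    }
  }
  rownames(A) <- colnames(X); rownames(B) <- colnames(Y)
  structure(list(a_coeffs = A, b_coeffs = B,
                 x_scores = X %*% A, y_scores = Y %*% B,
                 correlations = corrs,
                 lambda_x = lambda_x, lambda_y = lambda_y),
            class = "canonical_variates")
}

#' @export
print.canonical_variates <- function(x, ...) {
  cat(sprintf(
    "canonical_variates: %d pair(s), correlations %s (lambda = %g, %g)\n",
    length(x$correlations),
    paste(sprintf("%.3f", x$correlations), collapse = ", "),
    x$lambda_x, x$lambda_y
  ))
  invisible(x)
}

#' Choose ridge penalties by leave-one-out cross-validation
#'
#' For every `(lambda_x, lambda_y)` in the grid product, the first
#' canonical pair is fitted on each leave-one-out training fold
#' (standardizing within the fold), the held-out sample is scored with
#' the fold's coefficients, and the correlation of the N held-out score
#' pairs is recorded.  The cell with the largest held-out correlation
#' wins; ties go to the smallest `lambda_x + lambda_y`.
#'
#' @param X,Y numeric matrices N x p, N x q (raw scale; standardization
#'   happens inside each fold).
#' @param grid nonempty vector of candidate penalties.
#'
#' @return List with `lambda_x`, `lambda_y` and the full `cv` grid of
#'   held-out correlations.
#' @export
select_lambdas <- function(X, Y, grid = c(1e-4, 1e-3, 1e-2, 1e-1, 1)) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  N <- nrow(X)
  if (N < 3L) stop("need at least 3 samples for leave-one-out selection")
  if (length(grid) == 0L) stop("empty lambda grid")
  grid <- sort(unique(grid))
  cv <- matrix(-Inf, length(grid), length(grid),
               dimnames = list(lambda_x = grid, lambda_y = grid))
  for (ix in seq_along(grid)) {
    for (iy in seq_along(grid)) {
      xs <- ys <- numeric(N)
      ok <- TRUE
      for (i in seq_len(N)) {
        Xt <- X[-i, , drop = FALSE]; Yt <- Y[-i, , drop = FALSE]
        mx <- colMeans(Xt); sx <- apply(Xt, 2L, sd)
        my <- colMeans(Yt); sy <- apply(Yt, 2L, sd)
        if (any(sx <= 0) || any(sy <= 0)) { ok <- FALSE; break }
        fit <- regularized_cancor(
          sweep(sweep(Xt, 2L, mx), 2L, sx, `/`),
          sweep(sweep(Yt, 2L, my), 2L, sy, `/`),
          grid[ix], grid[iy], m = 1L
        )
        xs[i] <- sum((X[i, ] - mx) / sx * fit$a_coeffs[, 1L])
        ys[i] <- sum((Y[i, ] - my) / sy * fit$b_coeffs[, 1L])
      }
      if (ok && sd(xs) > 0 && sd(ys) > 0) {
        cv[ix, iy] <- stats::cor(xs, ys)
      }
    }
  }
  # cells within numerical noise of the maximum count as tied
  best <- which(cv >= max(cv) - 1e-10, arr.ind = TRUE)
  if (nrow(best) > 1L) {
    tot <- grid[best[, 1L]] + grid[best[, 2L]]
    best <- best[order(tot, best[, 1L], best[, 2L])[1L], , drop = FALSE]
  }
  list(lambda_x = grid[best[1L, 1L]], lambda_y = grid[best[1L, 2L]],
       cv = cv)
}

#' Reduce a high-dimensional gene-set pair to canonical variates
#'
#' When either block has at least `threshold_dim` genes, the small-
#' sample empirical cdf becomes too coarse relative to the dimension,
#' so the pair is replaced by the scores of its first
#' `min(max_pairs, p, q)` regularized canonical variate pairs; below
#' the threshold the pair is returned unchanged.  Penalties are chosen
#' by [select_lambdas] unless supplied.
#'
#' @param pair a [paired_gene_sets] object.
#' @param max_pairs maximum number of variate pairs kept (default 3).
#' @param threshold_dim dimension at or above which reduction kicks in
#'   (default 10).
#' @param lambda_x,lambda_y fixed penalties; `NULL` (default) selects
#'   them by leave-one-out cross-validation over `lambda_grid`.
#' @param lambda_grid candidate penalties for [select_lambdas].
#'
#' @return A [paired_gene_sets] object; attribute `reduced` says
#'   whether reduction was applied, and attribute `variates` carries
#'   the [regularized_cancor] fit when it was.
#' @export
reduce_pair <- function(pair, max_pairs = 3L, threshold_dim = 10L,
                        lambda_x = NULL, lambda_y = NULL,
                        lambda_grid = c(1e-4, 1e-3, 1e-2, 1e-1, 1)) {
  stopifnot(inherits(pair, "paired_gene_sets"))
  p <- ncol(pair$X); q <- ncol(pair$Y)
  if (p < threshold_dim && q < threshold_dim) {
    attr(pair, "reduced") <- FALSE
    return(pair)
  }
  if (is.null(lambda_x) || is.null(lambda_y)) {
    sel <- select_lambdas(pair$X, pair$Y, lambda_grid)
    lambda_x <- sel$lambda_x
    lambda_y <- sel$lambda_y
  }
  m <- min(max_pairs, p, q)
  fit <- regularized_cancor(standardize_columns(pair$X),
                            standardize_columns(pair$Y),
                            lambda_x, lambda_y, m = m)
  out <- paired_gene_sets(fit$x_scores, fit$y_scores, pair$sample_ids)
  attr(out, "reduced") <- TRUE
  attr(out, "variates") <- fit
  out
}
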