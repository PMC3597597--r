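#' Largest classical canonical correlation of two blocks
#'
#' The conventional regression-based association score: the first
#' canonical correlation of `X` and `Y` with no regularization.
#'
#' @param X,Y numeric matrices N x p and N x q with `N > max(p, q)`.
#' @return The largest canonical correlation, in `[0, 1]`.
#' @export
cancor_score <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) <= max(ncol(X), ncol(Y))) {
    stop("N must exceed max(p, q) for the unregularized canonical ",
         "correlation; use regularized_cancor() instead")
  }
  fit <- tryCatch(cancor(X, Y),
                  error = function(e) {
                    stop("singular covariance in cancor; use ",
                         "regularized_cancor() instead", call. = FALSE)
                  })
  fit$cor[1L]
}

#' Quantile discretization of a target block
#'
#' Each dimension of `Y` is cut into `r` bins at its sample quantiles
#' `k/r` (`k = 1..r-1`, type-7 interpolation); a value equal to a cut
#' point goes to the lower bin.  The joint cell of a sample is the
#' tuple of its per-dimension bins, and the marginal cell probabilities
#' are the cell counts over N.  This histogram estimate of the density
#' underlies the Kullback-Leibler and Hellinger scores.
#'
#' @param Y numeric matrix N x q.
#' @param r bins per dimension, at least 2 (default 3).
#'
#' @return An object of class `"discretized_distribution"`: list with
#'   `cell_probs` (length `r^q`, sums to 1), `r`, `cuts` (list of
#'   per-dimension cut points) and `cell_index_of_sample` (N integers
#'   in `1..r^q`).
#' @export
quantile_discretize <- function(Y, r = 3L) {
  Y <- as.matrix(Y)
  if (r < 2L) stop("r must be at least 2")
  q <- ncol(Y)
  if (r^q > nrow(Y)) {
    warning("more cells (", r^q, ") than samples (", nrow(Y),
            "); density estimate will be sparse")
  }
  cuts <- lapply(seq_len(q), function(d) {
    quantile(Y[, d], probs = seq_len(r - 1L) / r, type = 7, names = FALSE)
  })
  bins <- vapply(seq_len(q), function(d) {
    # ties to the lower bin: count cut points strictly below the value
    1 + rowSums(outer(Y[, d], cuts[[d]], `>`))
  }, numeric(nrow(Y)))
  bins <- matrix(bins, nrow = nrow(Y))
  cell <- as.integer(bins %*% r^(seq_len(q) - 1L)) - as.integer(
    sum(r^(seq_len(q) - 1L))) + 1L
  probs <- tabulate(cell, nbins = r^q) / nrow(Y)
  structure(list(cell_probs = probs, r = r, cuts = cuts,
                 cell_index_of_sample = cell),
            class = "discretized_distribution")
}

# conditional cell probabilities per subgroup, on the global cells
conditional_cell_probs <- function(disc, labels, K) {
  t(vapply(seq_len(K), function(s) {
    idx <- disc$cell_index_of_sample[labels == s]
    tabulate(idx, nbins = length(disc$cell_probs)) / length(idx)
  }, numeric(length(disc$cell_probs))))
}

#' Kullback-Leibler and Hellinger association scores
#'
#' Distribution-based rivals of the CID: `Y` is discretized into
#' quantile cells ([quantile_discretize]), `X` is clustered into `K`
#' subgroups (same hierarchical complete-linkage procedure as the CID),
#' and the divergence between each subgroup's conditional cell
#' probabilities and the marginal cell probabilities is averaged with
#' subgroup-size weights `n_s / N`.  `kld_score` uses the
#' Kullback-Leibler divergence in nats (with `0 log 0 = 0`);
#' `hd_score` the Hellinger distance
#' `sqrt(1 - sum(sqrt(p_cond * p_marg)))`, giving a value in `[0, 1]`.
#' Both are 0 when `K = 1`.
#'
#' @param X predictor block N x p.
#' @param Y target block N x q.
#' @param K number of predictor subgroups.
#' @param r bins per target dimension (default 3).
#' @param method,seed clustering backend, as [subgroup_by_clustering].
#' @return A nonnegative scalar.
#' @export
kld_score <- function(X, Y, K, r = 3L, method = "hierarchical_complete",
                      seed = NULL) {
  asg <- subgroup_by_clustering(X, K, method, seed)
  disc <- quantile_discretize(Y, r)
  cond <- conditional_cell_probs(disc, asg$labels, asg$K)
  w <- asg$sizes / length(asg$labels)
  sum(vapply(seq_len(asg$K), function(s) {
    pc <- cond[s, ]
    pos <- pc > 0 # occupied conditional cells are occupied marginally too
    w[s] * sum(pc[pos] * log(pc[pos] / disc$cell_probs[pos]))
  }, numeric(1L)))
}

#' @rdname kld_score
#' @export
hd_score <- function(X, Y, K, r = 3L, method = "hierarchical_complete",
                     seed = NULL) {
  asg <- subgroup_by_clustering(X, K, method, seed)
  disc <- quantile_discretize(Y, r)
  cond <- conditional_cell_probs(disc, asg$labels, asg$K)
  w <- asg$sizes / length(asg$labels)
  sum(vapply(seq_len(asg$K), function(s) {
    bc <- sum(sqrt(cond[s, ] * disc$cell_probs))
    w[s] * sqrt(max(0, 1 - bc))
  }, numeric(1L)))
}

#' Projection pursuit regression association score
#'
#' Fits a projection pursuit regression of every target column on the
#' predictor block (`stats::ppr`, Friedman's super smoother) and
#' returns the total residual sum of squares across target columns.  A
#' smaller value indicates a better fit, hence stronger association;
#' the score is used with direction `less` in permutation tests.
#'
#' @param X predictor block N x p.
#' @param Y target block N x q.
#' @param terms number of ridge-function terms (default 2).
#' @return Total residual sum of squares (nonnegative).
#' @export
ppr_score <- function(X, Y, terms = 2L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  fit <- ppr(x = X, y = Y, nterms = terms)
  sum(as.matrix(fit$residuals)^2)
}
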