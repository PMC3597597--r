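#' Multivariate empirical distribution functions
#'
#' The empirical cdf of a multivariate sample at a point `y` is the
#' fraction of sample rows that are componentwise less than or equal to
#' `y` (non-strict in every coordinate, so a row equal to `y` counts).
#' `conditional_ecdf` restricts the comparison to the rows of one
#' subgroup.
#'
#' @param Y numeric matrix N x q (or a vector treated as N x 1), no
#'   missing values.
#' @param y numeric vector of length q, the evaluation point.
#'
#' @return A value in `[0, 1]`.
#' @export
marginal_ecdf <- function(Y, y) {
  Y <- as.matrix(Y)
  if (anyNA(Y) || anyNA(y)) stop("missing values not allowed")
  if (length(y) != ncol(Y)) stop("dimension mismatch: length(y) != ncol(Y)")
  mean(rowSums(sweep(Y, 2L, y, `<=`)) == ncol(Y))
}

#' @rdname marginal_ecdf
#' @param assignment a [subgroup_assignment].
#' @param s subgroup index in `1..K`.
#' @export
conditional_ecdf <- function(Y, assignment, s, y) {
  Y <- as.matrix(Y)
  stopifnot(inherits(assignment, "subgroup_assignment"))
  if (length(assignment$labels) != nrow(Y)) {
    stop("assignment length does not match nrow(Y)")
  }
  if (length(s) != 1L || s < 1L || s > assignment$K) {
    stop("subgroup index out of range")
  }
  marginal_ecdf(Y[assignment$labels == s, , drop = FALSE], y)
}

#' Subgroup assignment
#'
#' A partition of the N samples into K nonempty subgroups, usually
#' obtained by clustering the predictor block (see
#' [subgroup_by_clustering]).
#'
#' @param labels integer vector: subgroup label in `1..K` per sample.
#' @return An object of class `"subgroup_assignment"` with elements
#'   `labels`, `K` and `sizes`.
#' @export
subgroup_assignment <- function(labels) {
  labels <- as.integer(labels)
  K <- max(labels)
  if (min(labels) < 1L) stop("labels must be in 1..K")
  sizes <- tabulate(labels, nbins = K)
  if (any(sizes == 0L)) stop("every subgroup must be nonempty")
  structure(list(labels = labels, K = K, sizes = sizes),
            class = "subgroup_assignment")
}

#' @export
print.subgroup_assignment <- function(x, ...) {
  cat(sprintf("subgroup_assignment: N=%d, K=%d (sizes %s)\n",
              length(x$labels), x$K, paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Partition samples by clustering the predictor block
#'
#' The conditioning device of the CID: samples are grouped by similarity
#' of their predictor expression profiles.  The primary method is
#' agglomerative hierarchical clustering with complete linkage on
#' Euclidean distances, cut to exactly `K` clusters; it is deterministic
#' given the input.  `kmeans` and `som` (batch self-organizing map on a
#' K x 1 grid, via the \pkg{class} package) are alternative backends;
#' both are seeded explicitly.
#'
#' @param X numeric matrix N x p, the predictor block.
#' @param K number of subgroups, `1 <= K <= N`.
#' @param method clustering backend.
#' @param seed integer seed for the randomized backends (ignored by
#'   `hierarchical_complete`).
#'
#' @return A [subgroup_assignment].
#' @export
subgroup_by_clustering <- function(X, K,
                                   method = c("hierarchical_complete",
                                              "kmeans", "som"),
                                   seed = NULL) {
  method <- match.arg(method)
  X <- as.matrix(X)
  N <- nrow(X)
  if (K < 1L) stop("K must be at least 1")
  if (K > N) stop("K cannot exceed the number of samples")
  if (anyNA(X)) stop("missing values not allowed")
  labels <- switch(method,
    hierarchical_complete = {
      if (K == N) {
        seq_len(N)
      } else if (K == 1L) {
        rep(1L, N)
      } else {
        cutree(hclust(dist(X), method = "complete"), k = K)
      }
    },
    kmeans = with_seed(seed, {
      kmeans(X, centers = K, nstart = 10L)$cluster
    }),
    som = with_seed(seed, {
      if (!requireNamespace("class", quietly = TRUE)) {
        stop("the 'class' package is required for method = 'som'")
      }
      if (K == 1L) {
        rep(1L, N)
      } else {
        grid <- class::somgrid(xdim = K, ydim = 1L, topo = "rectangular")
        map <- class::batchSOM(X, grid, radii = c(2, 1, 0))
        d <- as.matrix(dist(rbind(map$codes, X)))[seq_len(K), -seq_len(K),
                                                  drop = FALSE]
        lab <- apply(d, 2L, which.min)
        # SOM units may end up empty; relabel to consecutive 1..K' and
        # split the largest cluster until K nonempty groups exist
        lab <- match(lab, sort(unique(lab)))
        while (max(lab) < K) {
          big <- which.max(tabulate(lab))
          idx <- which(lab == big)
          sub <- cutree(hclust(dist(X[idx, , drop = FALSE]),
                               method = "complete"), k = 2L)
          lab[idx[sub == 2L]] <- max(lab) + 1L
        }
        lab
      }
    })
  )
  subgroup_assignment(labels)
}

#' Normalizing constant of the CID
#'
#' `C(N) = (N^2 - 1) / (6 N^2)`, the value of the mean squared
#' marginal/conditional cdf discrepancy attained under full dependence
#' (distinct univariate targets, singleton subgroups), so that the CID
#' lies in `[0, 1]` with 1 at full dependence.  As `N` grows it tends
#' to `1/6 = integral of F(1-F) dF`.
#'
#' @param N sample size, at least 2.
#' @return A positive scalar.
#' @export
cid_normalizer <- function(N) {
  if (N < 2L) stop("N must be at least 2")
  (N^2 - 1) / (6 * N^2)
}

# Pairwise componentwise-<= indicator: L[i, j] = 1 iff Y[i, ] <= Y[j, ]
# in every coordinate.  The workhorse of the fast CID path.
ecdf_indicator_matrix <- function(Y) {
  Y <- as.matrix(Y)
  L <- matrix(TRUE, nrow(Y), nrow(Y))
  for (d in seq_len(ncol(Y))) {
    L <- L & outer(Y[, d], Y[, d], `<=`)
  }
  storage.mode(L) <- "double"
  L
}

# CID evaluation given the indicator matrix and labels; used directly
# by the permutation test so the O(N^2 q) indicator work is done once.
cid_from_indicators <- function(L, labels, normalizer) {
  N <- ncol(L)
  G <- colMeans(L)
  sizes <- tabulate(labels)
  counts <- rowsum(L, labels) # K x N: counts of members <= y_j
  Gs <- counts / sizes
  dev2 <- (Gs - rep(G, each = nrow(Gs)))^2
  per_sample <- colSums(dev2 * (sizes / N))
  value <- mean(per_sample) / normalizer
  list(value = value, per_sample = per_sample,
       per_subgroup = rowSums(dev2 * (sizes / N)))
}

#' Coefficient of intrinsic dependence of Y given a subgrouping of X
#'
#' For each sample `i` the squared discrepancies between the marginal
#' empirical cdf of the target block and the conditional empirical cdfs
#' within each subgroup are averaged with subgroup-size weights
#' `n_s / N`; the mean over samples, divided by a normalizer, is the
#' CID.  It is 0 when the conditional distributions coincide with the
#' marginal (independence, or `K = 1`) and 1 under full dependence.
#'
#' Two normalizers are available.  `"fixed"` (the default) is the
#' constant [cid_normalizer]`(N) = (N^2-1)/(6N^2)`, the mean squared
#' discrepancy attained at full dependence for a continuous univariate
#' target; it makes values comparable across gene-set pairs on the
#' same samples, but for multivariate targets on small samples the
#' ratio can slightly exceed 1 under near-full dependence.
#' `"empirical"` divides by `mean(G_i (1 - G_i))` over the observed
#' marginal ecdf values, which bounds the CID by 1 for every input
#' (the per-sample discrepancy can never exceed `G_i (1 - G_i)`, since
#' the size-weighted mean of the conditional ecdfs equals the marginal
#' ecdf); for distinct univariate targets the two coincide.
#' Permutation p-values are identical under either choice.
#'
#' @param Y numeric matrix N x q, the target block (no missing values).
#' @param assignment a [subgroup_assignment] of the same N samples,
#'   normally from clustering the predictor block.
#' @param normalizer `"fixed"` or `"empirical"` (see Details).
#'
#' @return An object of class `"cid_result"`: list with `value` (the
#'   CID, in `[0, 1]`), `per_sample` (the N weighted squared
#'   discrepancies, whose mean over `C(N)` is the value),
#'   `per_subgroup_share` (fraction of the total discrepancy
#'   contributed by each subgroup; `NA` when the value is 0), and
#'   `normalizer`.
#' @export
cid <- function(Y, assignment, normalizer = c("fixed", "empirical")) {
  Y <- as.matrix(Y)
  normalizer <- match.arg(normalizer)
  stopifnot(inherits(assignment, "subgroup_assignment"))
  N <- nrow(Y)
  if (N < 2L) stop("need at least 2 samples")
  if (length(assignment$labels) != N) {
    stop("assignment length does not match nrow(Y)")
  }
  if (anyNA(Y)) stop("missing values not allowed")
  L <- ecdf_indicator_matrix(Y)
  normalizer <- if (normalizer == "fixed") {
    cid_normalizer(N)
  } else {
    G <- colMeans(L)
    mean(G * (1 - G))
  }
  if (normalizer == 0) { # all target rows identical: no dependence signal
    normalizer <- cid_normalizer(N)
  }
  res <- cid_from_indicators(L, assignment$labels, normalizer)
  total <- sum(res$per_sample)
  share <- if (total > 0) res$per_subgroup / total else
    rep(NA_real_, assignment$K)
  structure(list(value = res$value, per_sample = res$per_sample,
                 per_subgroup_share = share, normalizer = normalizer,
                 K = assignment$K),
            class = "cid_result")
}

#' @export
print.cid_result <- function(x, ...) {
  cat(sprintf("CID = %.4f (K = %d subgroups, C(N) = %.4f)\n",
              x$value, x$K, x$normalizer))
  invisible(x)
}

#' Symmetrized CID of a gene-set pair
#'
#' The CID is asymmetric: CID(Y|X) conditions on subgroups of X and
#' need not equal CID(X|Y).  When a symmetric level of dependence is
#' wanted, the two directed values (each using a clustering of its own
#' predictor block) are averaged.
#'
#' @param pair a [paired_gene_sets] object.
#' @param K number of subgroups for both directions.
#' @param normalizer passed to [cid].
#' @inheritParams subgroup_by_clustering
#'
#' @return List with `value` (the average), `y_given_x` and
#'   `x_given_y` (the directed [cid] results).
#' @export
symmetric_cid <- function(pair, K, method = "hierarchical_complete",
                          seed = NULL, normalizer = "fixed") {
  stopifnot(inherits(pair, "paired_gene_sets"))
  seeds <- if (is.null(seed)) list(NULL, NULL) else
    as.list(derive_seeds(seed, 2L))
  yx <- cid(pair$Y, subgroup_by_clustering(pair$X, K, method, seeds[[1L]]),
            normalizer)
  xy <- cid(pair$X, subgroup_by_clustering(pair$Y, K, method, seeds[[2L]]),
            normalizer)
  list(value = (yx$value + xy$value) / 2, y_given_x = yx, x_given_y = xy)
}
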