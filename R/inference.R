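#' Permutation test of gene-set association
#'
#' Builds the null distribution of an association measure under
#' independence by random permutation and returns the one-sided
#' permutation p-value `#\{null beats or ties observed\} / B`.
#'
#' The permutation scheme follows the measure:
#' * `"cid"`: the predictor block is clustered once; each iteration the
#'   subgroup *labels* are randomly permuted across samples (the
#'   observed partition sizes are kept fixed) and the CID recomputed.
#' * `"cancor"`, `"kld"`, `"hd"`, `"ppr"`: the rows of `X` are permuted
#'   and the full statistic recomputed (including re-clustering for the
#'   distribution-based measures).
#'
#' Direction is `greater` for all measures except the projection
#' pursuit residual sum of squares, where smaller means stronger
#' association (`less`).  A user-supplied function `statistic(X, Y, K)`
#' is also accepted; rows of `X` are then permuted and `direction`
#' must be given.
#'
#' @param X predictor block N x p (or a [paired_gene_sets] object, in
#'   which case `Y` is ignored).
#' @param Y target block N x q.
#' @param statistic one of `"cid"`, `"cancor"`, `"kld"`, `"hd"`,
#'   `"ppr"`, or a function `(X, Y, K) -> scalar`.
#' @param K number of predictor subgroups (CID/KLD/HD).
#' @param B number of permutations (default 1000).
#' @param seed integer seed; the result is reproducible given the seed.
#' @param direction `"greater"` or `"less"`; chosen automatically for
#'   the built-in measures.
#' @param r bins per target dimension for KLD/HD.
#' @param terms `ppr` terms.
#' @param method clustering backend for the subgrouping.
#'
#' @return An object of class `"permutation_result"`: list with
#'   `observed`, `null_values` (length B), `p_value`, `direction`,
#'   `statistic`, `B`, `seed`.
#' @export
permutation_pvalue <- function(X, Y = NULL, statistic = "cid", K = 5L,
                               B = 1000L, seed = NULL,
                               direction = NULL, r = 3L, terms = 2L,
                               method = "hierarchical_complete") {
  if (inherits(X, "paired_gene_sets")) {
    Y <- X$Y
    X <- X$X
  }
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (B < 1L) stop("B must be at least 1")
  N <- nrow(X)
  stat_name <- if (is.function(statistic)) "custom" else
    match.arg(statistic, c("cid", "cancor", "kld", "hd", "ppr"))
  if (is.null(direction)) {
    direction <- if (identical(stat_name, "ppr")) "less" else "greater"
  }
  direction <- match.arg(direction, c("greater", "less"))

  out <- with_seed(seed, {
    if (stat_name == "cid") {
      asg <- subgroup_by_clustering(X, K, method)
      L <- ecdf_indicator_matrix(Y)
      cn <- cid_normalizer(N)
      observed <- cid_from_indicators(L, asg$labels, cn)$value
      null_values <- vapply(seq_len(B), function(b) {
        cid_from_indicators(L, sample(asg$labels), cn)$value
      }, numeric(1L))
      list(observed = observed, null_values = null_values)
    } else {
      f <- switch(stat_name,
        cancor = function(Xp) cancor_score(Xp, Y),
        kld = function(Xp) kld_score(Xp, Y, K, r, method),
        hd = function(Xp) hd_score(Xp, Y, K, r, method),
        ppr = function(Xp) ppr_score(Xp, Y, terms),
        custom = function(Xp) statistic(Xp, Y, K)
      )
      observed <- f(X)
      null_values <- vapply(seq_len(B), function(b) {
        f(X[sample.int(N), , drop = FALSE])
      }, numeric(1L))
      list(observed = observed, null_values = null_values)
    }
  })
  p <- if (direction == "greater") {
    mean(out$null_values >= out$observed)
  } else {
    mean(out$null_values <= out$observed)
  }
  structure(list(observed = out$observed, null_values = out$null_values,
                 p_value = p, direction = direction,
                 statistic = stat_name, B = B, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation test (%s, %d permutations): observed = %.4f, p = %.4g\n",
              x$statistic, x$B, x$observed, x$p_value))
  invisible(x)
}

#' Median/MAD outlier screen for all-pairs CID values
#'
#' In an all-pairs analysis each predictor gene set `g_j` yields a
#' column of raw CID values `CID(g_i | g_j)` over targets `i != j`.
#' Within each column the median `m_j` and the (by default unscaled)
#' median absolute deviation `mad_j` are taken, and each entry is
#' standardized to `(raw - m_j) / mad_j`.  Adjusted values above
#' `cutoff` (default 3.5, the usual modified z-score screen) are
#' declared significant.  Columns with `mad_j = 0` are flagged
#' degenerate: no calls are made for them.
#'
#' @param raw numeric G x G matrix of directed CID values, target in
#'   rows, predictor in columns, diagonal `NA`.
#' @param cutoff significance cutoff on the adjusted value.
#' @param mad_constant scale factor applied to the MAD (1 = plain MAD;
#'   use `1 / 0.6745` for the normal-consistent modified z-score
#'   convention).
#'
#' @return An object of class `"adjusted_cid_matrix"`: list with
#'   `raw`, `adjusted`, `per_predictor_median`, `per_predictor_mad`,
#'   `significant` (logical matrix), `degenerate_predictors`, `cutoff`.
#' @export
adjusted_cid <- function(raw, cutoff = 3.5, mad_constant = 1) {
  raw <- as.matrix(raw)
  G <- ncol(raw)
  if (nrow(raw) != G) stop("raw must be square (targets x predictors)")
  if (G < 3L) stop("need at least 3 gene sets")
  diag(raw) <- NA_real_
  m <- apply(raw, 2L, median, na.rm = TRUE)
  madv <- vapply(seq_len(G), function(j) {
    v <- raw[, j]
    median(abs(v - m[j]), na.rm = TRUE) * mad_constant
  }, numeric(1L))
  degenerate <- !is.na(madv) & madv == 0
  adjusted <- sweep(sweep(raw, 2L, m), 2L, ifelse(degenerate, NA, madv),
                    `/`)
  sig <- !is.na(adjusted) & adjusted > cutoff
  if (any(degenerate)) {
    nm <- colnames(raw)[degenerate]
    if (is.null(nm)) nm <- which(degenerate)
    warning("degenerate predictor column(s) with zero MAD, no calls ",
            "made: ", paste(nm, collapse = ", "))
  }
  structure(list(raw = raw, adjusted = adjusted,
                 per_predictor_median = m, per_predictor_mad = madv,
                 significant = sig, degenerate_predictors = degenerate,
                 cutoff = cutoff),
            class = "adjusted_cid_matrix")
}

#' @export
print.adjusted_cid_matrix <- function(x, ...) {
  cat(sprintf(
    "adjusted_cid_matrix: %d gene sets, %d significant call(s) at > %.2f\n",
    ncol(x$raw), sum(x$significant), x$cutoff
  ))
  invisible(x)
}
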