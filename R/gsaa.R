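#' Configuration for a gene-set association analysis run
#'
#' Bundles the tuning parameters of the unsupervised (all-pairs) and
#' supervised (two gene sets, one cohort) analyses.  Defaults follow
#' the standard workflow: `K = 3` fixed subgroups for unsupervised
#' screening, `K` about one-tenth of the cohort size for supervised
#' testing, canonical-variate reduction for blocks of 10+ genes keeping
#' at most 3 variate pairs, 1000 permutations, significance at
#' adjusted CID > 3.5 (unsupervised) or permutation p <= 0.05
#' (supervised).
#'
#' @param mode `"unsupervised"` or `"supervised"`.
#' @param K_rule `"fixed"` (use `K_fixed`) or `"n_over_10"`
#'   (`K = max(2, round(N / 10))`).
#' @param K_fixed number of subgroups under the fixed rule.
#' @param max_variate_pairs cap on canonical variate pairs kept.
#' @param reduction_threshold gene count at which reduction applies.
#' @param B permutations for the supervised test.
#' @param alpha supervised significance level.
#' @param adjusted_cutoff unsupervised adjusted-CID cutoff.
#' @param mad_constant MAD scale factor (see [adjusted_cid]).
#' @param lambda_x,lambda_y fixed ridge penalties for reduction;
#'   `NULL` selects them per pair by cross-validation.
#' @param lambda_grid candidate penalties when selecting.
#' @param missing_policy how [extract_pair] treats missing values.
#' @param seed integer seed.
#'
#' @return A list of class `"gsaa_config"`.
#' @export
gsaa_config <- function(mode = c("unsupervised", "supervised"),
                        K_rule = c("fixed", "n_over_10"), K_fixed = 3L,
                        max_variate_pairs = 3L, reduction_threshold = 10L,
                        B = 1000L, alpha = 0.05, adjusted_cutoff = 3.5,
                        mad_constant = 1, lambda_x = NULL,
                        lambda_y = NULL,
                        lambda_grid = c(1e-4, 1e-3, 1e-2, 1e-1, 1),
                        missing_policy = "drop_gene", seed = 1L) {
  mode <- match.arg(mode)
  # default K rule follows the mode when none is given explicitly
  K_rule_missing <- missing(K_rule)
  K_rule <- match.arg(K_rule)
  if (mode == "supervised" && K_rule_missing) K_rule <- "n_over_10"
  structure(list(mode = mode, K_rule = K_rule, K_fixed = as.integer(K_fixed),
                 max_variate_pairs = as.integer(max_variate_pairs),
                 reduction_threshold = as.integer(reduction_threshold),
                 B = as.integer(B), alpha = alpha,
                 adjusted_cutoff = adjusted_cutoff,
                 mad_constant = mad_constant,
                 lambda_x = lambda_x, lambda_y = lambda_y,
                 lambda_grid = lambda_grid,
                 missing_policy = missing_policy,
                 seed = as.integer(seed)),
            class = "gsaa_config")
}

#' Number of subgroups for a supervised cohort
#'
#' Approximately one-tenth of the cohort size, rounded, never below 2:
#' 60 samples give 6 subgroups, 48 give 5, 152 give 15.
#'
#' @param N cohort size.
#' @return Integer number of subgroups.
#' @export
choose_k <- function(N) {
  if (N < 20L) {
    warning("cohort smaller than 20 samples; using the minimum of 2 ",
            "subgroups")
  }
  max(2L, as.integer(round(N / 10)))
}

resolve_k <- function(cfg, N) {
  if (cfg$K_rule == "fixed") cfg$K_fixed else choose_k(N)
}

#' All-pairs (unsupervised) gene set association analysis
#'
#' For every ordered pair of gene sets (target `g_i`, predictor `g_j`,
#' `i != j`) the aligned blocks are extracted, reduced to at most
#' `max_variate_pairs` regularized canonical variate pairs when either
#' block has `reduction_threshold` or more genes, the (possibly
#' reduced) predictor block is clustered into `K` subgroups, and
#' `CID(g_i | g_j)` is computed — `G (G - 1)` directed values in all.
#' Each predictor column of the resulting matrix is then standardized
#' by its median and MAD ([adjusted_cid]) and values above the cutoff
#' are called significant.
#'
#' Pairs are processed in a deterministic order with per-pair seeds
#' derived from `cfg$seed`, so reruns reproduce every value.
#'
#' @param expr an [expression_matrix].
#' @param sets a [gene_set_collection] with at least 3 sets.
#' @param cfg a [gsaa_config] (defaults to the unsupervised defaults).
#'
#' @return A list of class `"gsaa_unsupervised_result"`: `adjusted`
#'   (the matrix result of [adjusted_cid]), `table` (one row per directed pair:
#'   target, predictor, block sizes, whether reduction was applied, K,
#'   raw and adjusted CID, significance), and `skipped` (pairs whose
#'   blocks could not be formed, with reasons).
#' @export
run_unsupervised_gsaa <- function(expr, sets,
                                  cfg = gsaa_config("unsupervised")) {
  stopifnot(inherits(sets, "gene_set_collection"),
            inherits(cfg, "gsaa_config"))
  G <- length(sets)
  if (G < 3L) stop("need at least 3 gene sets")
  nms <- names(sets)

  # cache each set's complete-data block once
  blocks <- lapply(sets, function(s) {
    tryCatch({
      present <- s$genes[s$genes %in% colnames(expr)]
      b <- unclass(expr)[, present, drop = FALSE]
      b <- b[, colSums(is.na(b)) == 0L, drop = FALSE]
      if (ncol(b) == 0L) stop("empty gene set block")
      b
    }, error = function(e) NULL)
  })

  raw <- matrix(NA_real_, G, G, dimnames = list(target = nms,
                                                predictor = nms))
  reduced_flag <- matrix(NA, G, G)
  k_used <- matrix(NA_integer_, G, G)
  skipped <- list()
  pair_seeds <- matrix(derive_seeds(cfg$seed, G * G), G, G)

  for (j in seq_len(G)) {        # predictor
    for (i in seq_len(G)) {      # target
      if (i == j) next
      if (is.null(blocks[[i]]) || is.null(blocks[[j]])) {
        skipped[[length(skipped) + 1L]] <-
          list(target = nms[i], predictor = nms[j],
               reason = "empty gene set block")
        next
      }
      res <- tryCatch({
        pair <- paired_gene_sets(blocks[[j]], blocks[[i]],
                                 rownames(blocks[[j]]))
        pair <- reduce_pair(pair, cfg$max_variate_pairs,
                            cfg$reduction_threshold,
                            cfg$lambda_x, cfg$lambda_y, cfg$lambda_grid)
        N <- nrow(pair$X)
        K <- resolve_k(cfg, N)
        asg <- subgroup_by_clustering(pair$X, K,
                                      seed = pair_seeds[i, j])
        list(value = cid(pair$Y, asg)$value,
             reduced = isTRUE(attr(pair, "reduced")), K = K)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        skipped[[length(skipped) + 1L]] <-
          list(target = nms[i], predictor = nms[j],
               reason = conditionMessage(res))
      } else {
        raw[i, j] <- res$value
        reduced_flag[i, j] <- res$reduced
        k_used[i, j] <- res$K
      }
    }
  }

  adj <- adjusted_cid(raw, cfg$adjusted_cutoff, cfg$mad_constant)
  idx <- which(!is.na(raw), arr.ind = TRUE)
  tab <- data.frame(
    target_set = nms[idx[, 1L]],
    predictor_set = nms[idx[, 2L]],
    reduced = reduced_flag[idx],
    K = k_used[idx],
    cid = raw[idx],
    adjusted = adj$adjusted[idx],
    significant = adj$significant[idx],
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$predictor_set, tab$target_set), ]
  rownames(tab) <- NULL
  structure(list(adjusted = adj, table = tab, skipped = skipped,
                 config = cfg),
            class = "gsaa_unsupervised_result")
}

#' @export
print.gsaa_unsupervised_result <- function(x, ...) {
  cat(sprintf(
    "unsupervised GSAA: %d directed CID values, %d significant, %d skipped\n",
    nrow(x$table), sum(x$table$significant, na.rm = TRUE),
    length(x$skipped)
  ))
  invisible(x)
}

#' Supervised gene set association test for one cohort
#'
#' Tests whether a target gene set (e.g. a signaling pathway or TF
#' subnetwork) is associated with a predictor gene set (e.g. a pair of
#' transcription factors) within a designated sample cohort.  Blocks
#' are extracted for the cohort, reduced if high-dimensional, and the
#' CID permutation test is run with `K` subgroups (by default about
#' one-tenth of the cohort size).
#'
#' @param expr an [expression_matrix].
#' @param set1 predictor [gene_set] (the regulators).
#' @param set2 target [gene_set] (the pathway / subnetwork).
#' @param cohort_samples sample ids defining the cohort; `NULL` uses
#'   all samples.
#' @param cfg a [gsaa_config]; its `K_rule` defaults to `n_over_10`
#'   in supervised mode.
#'
#' @return A [permutation_pvalue] result with extra fields `K`, `N`,
#'   `significant` and `reduced`.
#' @export
run_supervised_gsaa <- function(expr, set1, set2, cohort_samples = NULL,
                                cfg = gsaa_config("supervised",
                                                  K_rule = "n_over_10")) {
  stopifnot(inherits(cfg, "gsaa_config"))
  if (!is.null(cohort_samples)) {
    missing_s <- setdiff(cohort_samples, rownames(expr))
    if (length(missing_s)) {
      stop("cohort samples absent from the expression matrix: ",
           paste(utils::head(missing_s, 5L), collapse = ", "))
    }
    expr <- expression_matrix(unclass(expr)[cohort_samples, ,
                                            drop = FALSE])
  }
  pair <- extract_pair(expr, set1, set2, cfg$missing_policy,
                       quiet = TRUE)
  pair <- reduce_pair(pair, cfg$max_variate_pairs,
                      cfg$reduction_threshold, cfg$lambda_x,
                      cfg$lambda_y, cfg$lambda_grid)
  N <- nrow(pair$X)
  K <- resolve_k(cfg, N)
  res <- permutation_pvalue(pair$X, pair$Y, statistic = "cid", K = K,
                            B = cfg$B, seed = cfg$seed)
  res$K <- K
  res$N <- N
  res$reduced <- isTRUE(attr(pair, "reduced"))
  res$significant <- res$p_value <= cfg$alpha
  res
}

#' Write an association table to TSV
#'
#' @param x the `table` data frame of a [run_unsupervised_gsaa] result
#'   (or any data frame).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(x, path) {
  if (inherits(x, "gsaa_unsupervised_result")) x <- x$table
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
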